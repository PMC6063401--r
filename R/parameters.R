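.param_table <- function() {
  data.frame(
    name = c("sigma0_vest", "sigma0_vis_high", "sigma0_vis_med",
             "sigma0_vis_low", "w_vest", "w_vis", "lambda", "p_c",
             "kappa_c", "sigma_prior", "delta_prior",
             "eta_low", "eta_med", "eta_high"),
    lower = c(0.5, 0.5, 0.5, 0.5, 0, 0, 0, 0, 0.25, 1, 1, 0, 0, 0),
    upper = c(80, 80, 80, 80, 1, 1, 1, 1, 180, 120, 120, 1, 1, 1),
    log_space = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE,
                  TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Parameter space of an observer model
#'
#' Enumerates the free parameters active for a given model and task set,
#' in a fixed canonical order, with their allowed ranges and log-space
#' transform flags. Scale parameters (base noise SDs, the fixed criterion,
#' and the prior widths) are fitted and sampled in log space.
#'
#' @param model \code{\link{model_spec}}.
#' @param tasks Tasks to cover; defaults to \code{model$tasks}.
#' @return Data frame of class \code{"param_space"} with columns
#'   \code{name}, \code{lower}, \code{upper}, \code{log_space}.
#' @examples
#' m <- model_spec(explicit = "Bay", implicit = "Bay",
#'                 noise = "X", prior = "E")
#' build_parameter_space(m)$name   # the 10 joint-fit parameters
#' @export
build_parameter_space <- function(model, tasks = model$tasks) {
  stopifnot(inherits(model, "model_spec"))
  ex <- model$explicit; im <- model$implicit
  bisensory <- any(c("unity", "inertial") %in% tasks)
  sfu_only <- identical(ex, "SFu") && identical(tasks, "unity")

  active <- character()
  if (!sfu_only) {
    needs_vis <- TRUE
    needs_vest <- TRUE
    # explicit-only Fix and SFu make no use of internal posteriors, but
    # Fix still filters noisy measurements, so noise parameters stay.
    active <- c(active, if (needs_vest) "sigma0_vest",
                if (needs_vis) c("sigma0_vis_high", "sigma0_vis_med",
                                 "sigma0_vis_low"))
    if (model$noise == "X")
      active <- c(active, if (needs_vest) "w_vest", if (needs_vis) "w_vis")
    active <- c(active, "lambda")
  }
  strategies <- c(if ("unity" %in% tasks) ex,
                  if ("inertial" %in% tasks) im)
  if (any(strategies %in% c("Bay", "BayPM"))) active <- c(active, "p_c")
  if (any(strategies %in% "Fix")) active <- c(active, "kappa_c")
  uses_prior <- ("inertial" %in% tasks) ||
    ("unity" %in% tasks && ex %in% c("Bay", "BayPM"))
  if (uses_prior) {
    active <- c(active, "sigma_prior")
    if (model$prior == "E") active <- c(active, "delta_prior")
  }
  if (identical(ex, "SFu") && "unity" %in% tasks)
    active <- c(active, "eta_low", "eta_med", "eta_high")

  tab <- .param_table()
  ps <- tab[match(intersect(tab$name, active), tab$name), , drop = FALSE]
  rownames(ps) <- NULL
  class(ps) <- c("param_space", "data.frame")
  ps
}

# theta (natural space, named) -> z (sampling space) and back.
ps_transform <- function(theta, ps) {
  z <- unname(theta[ps$name])
  z[ps$log_space] <- log(z[ps$log_space])
  z
}

ps_untransform <- function(z, ps) {
  v <- z
  v[ps$log_space] <- exp(v[ps$log_space])
  names(v) <- ps$name
  v
}

ps_bounds_z <- function(ps) {
  lo <- ps$lower; hi <- ps$upper
  lo[ps$log_space] <- log(lo[ps$log_space])
  hi[ps$log_space] <- log(hi[ps$log_space])
  list(lower = lo, upper = hi)
}

# Latin-hypercube starts in the (transformed) box, kept off the edges.
ps_lhs <- function(ps, n, margin = 0.05) {
  b <- ps_bounds_z(ps)
  u <- lhs::randomLHS(n, nrow(ps))
  u <- margin + (1 - 2 * margin) * u
  t(apply(u, 1, function(r) b$lower + r * (b$upper - b$lower)))
}

.check_bounds <- function(theta, ps, tol = 1e-9) {
  v <- unname(theta[ps$name])
  all(v >= ps$lower - tol & v <= ps$upper + tol)
}
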