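#' Maximum-likelihood fit of an observer model
#'
#' Fits the model by multistart derivative-free maximization of the trial
#' log likelihood. Starts are drawn by Latin-hypercube sampling inside
#' the parameter box (in the transformed space: log space for scale
#' parameters) and each is refined with Nelder-Mead through a smooth
#' bounded reparameterization, so every evaluated point respects the
#' allowed ranges.
#'
#' @param data Trial table data frame.
#' @param model \code{\link{model_spec}} covering the data's tasks.
#' @param n_starts Number of multistarts (>= 1).
#' @param seed Integer seed; fits are reproducible given the seed.
#' @param maxit Nelder-Mead iteration cap per start.
#' @param opts \code{\link{ci_opts}} quadrature settings.
#' @param start Optional named parameter vector used as the first start.
#' @return List with \code{theta} (best parameters, natural space),
#'   \code{logLik}, \code{trace} (per-start best log likelihoods),
#'   \code{param_space}, and \code{convergence} codes.
#' @export
fit_mle <- function(data, model, n_starts = 10, seed = 1, maxit = 500,
                    opts = ci_opts(), start = NULL) {
  stopifnot(nrow(data) >= 1, n_starts >= 1)
  ps <- build_parameter_space(model, tasks = intersect(
    model$tasks, unique(data$task)))
  b <- ps_bounds_z(ps)
  k <- nrow(ps)

  to_z <- function(u) b$lower + (b$upper - b$lower) * stats::plogis(u)
  to_u <- function(z) {
    p <- (z - b$lower) / (b$upper - b$lower)
    p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
    stats::qlogis(p)
  }
  negll <- function(u) {
    theta <- ps_untransform(to_z(u), ps)
    v <- tryCatch(-dataset_log_likelihood(data, model, theta, opts)$total,
                  error = function(e) NA_real_)
    # numerically unusable corners of the box act as a hard penalty
    if (!is.finite(v)) 0.5 * nrow(data) * .Machine$double.xmax^0.25 else v
  }

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  starts <- ps_lhs(ps, n_starts)
  if (!is.null(start)) starts[1, ] <- ps_transform(start, ps)

  best <- NULL
  trace <- numeric(n_starts)
  conv <- integer(n_starts)
  for (i in seq_len(n_starts)) {
    fit <- stats::optim(to_u(starts[i, ]), negll, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-7))
    trace[i] <- -fit$value
    conv[i] <- fit$convergence
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (all(conv != 0))
    warning("no start converged within maxit; returning best-so-far")
  theta <- ps_untransform(to_z(best$par), ps)
  list(theta = theta, logLik = -best$value, trace = trace,
       param_space = ps, convergence = conv, seed = seed)
}
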