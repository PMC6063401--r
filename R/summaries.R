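#' Proportion of 'unity' reports by disparity and reliability
#'
#' Model-free summary of the unity-judgment task: the proportion of
#' trials on which a common cause was reported, for each signed
#' disparity (\eqn{s_{vest} - s_{vis}}) and visual reliability level.
#'
#' @param data Trial table containing unity-task trials.
#' @return Data frame with columns \code{disparity}, \code{c_vis},
#'   \code{n}, \code{prop_unity}; empty cells are absent (counts are
#'   reported so callers can flag them).
#' @export
summarize_unity <- function(data) {
  d <- data[data$task == "unity", , drop = FALSE]
  if (!nrow(d)) stop("no unity-task trials present")
  disparity <- d$s_vest - d$s_vis
  agg <- stats::aggregate(
    list(n = rep(1L, nrow(d)),
         n_unity = as.integer(d$response == "unity")),
    by = list(disparity = disparity, c_vis = d$c_vis), FUN = sum)
  agg$prop_unity <- agg$n_unity / agg$n
  agg[order(agg$c_vis, agg$disparity),
      c("disparity", "c_vis", "n", "prop_unity")]
}

# The visual-heading bins used for the bias summary (degrees); chosen to
# equalize trial counts under the design's nonuniform s_vis distribution.
.bias_bins <- function() {
  list(c(-45, -30), c(-27.5, -22.5), c(-20, -15), c(-12.5, -7.5),
       c(-5, -2.5), c(0, 0), c(2.5, 5), c(7.5, 12.5), c(15, 20),
       c(22.5, 27.5), c(30, 45))
}

.bias_bin_label <- function(b)
  if (b[1] == b[2]) "0" else sprintf("[%g,%g]", b[1], b[2])

# ML fit of a cumulative Gaussian with fixed lapse:
# P(right | s) = lapse/2 + (1 - lapse) * pnorm((s - mu)/sigma)
.fit_psychometric <- function(s, r_right, lapse = 0) {
  nll <- function(par) {
    p <- lapse / 2 + (1 - lapse) * stats::pnorm((s - par[1]) / exp(par[2]))
    p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
    -sum(r_right * log(p) + (1 - r_right) * log(1 - p))
  }
  init <- tryCatch({
    co <- stats::coef(suppressWarnings(
      stats::glm(r_right ~ s, family = stats::binomial("probit"))))
    if (!all(is.finite(co)) || co[2] <= 0) stop("probit init failed")
    c(-co[1] / co[2], log(1 / co[2]))
  }, error = function(e) c(0, log(max(stats::sd(s), 1))))
  fit <- stats::optim(init, nll, method = "Nelder-Mead",
                      control = list(maxit = 500))
  list(pse = fit$par[1], sigma = exp(fit$par[2]),
       converged = fit$convergence == 0)
}

#' Vestibular bias by visual-heading bin and reliability
#'
#' Model-free summary of the inertial-discrimination task: within each
#' visual-heading bin and reliability level, the proportion of rightward
#' responses as a function of \eqn{s_{vest}} is fitted with a cumulative
#' Gaussian, and the bias is defined as minus the point of subjective
#' equality (PSE). A bias near zero means the co-presented visual
#' heading did not distort perceived inertial heading.
#'
#' @param data Trial table containing inertial-task trials.
#' @param lapse Fixed lapse rate of the psychometric function (e.g. the
#'   simulated observer's lambda); default 0.
#' @param min_trials Bins with fewer trials are skipped (flagged
#'   \code{NA}).
#' @return Data frame with columns \code{bin}, \code{bin_lo},
#'   \code{bin_hi}, \code{c_vis}, \code{n}, \code{pse}, \code{bias},
#'   \code{converged}.
#' @export
summarize_bias <- function(data, lapse = 0, min_trials = 20) {
  d <- data[data$task == "inertial", , drop = FALSE]
  if (!nrow(d)) stop("no inertial-task trials present")
  bins <- .bias_bins()
  out <- list()
  for (b in bins) {
    inb <- if (b[1] == b[2]) d$s_vis == b[1]
    else d$s_vis >= b[1] & d$s_vis <= b[2]
    for (cv in unique(d$c_vis)) {
      sel <- inb & d$c_vis == cv
      n <- sum(sel)
      row <- data.frame(bin = .bias_bin_label(b), bin_lo = b[1],
                        bin_hi = b[2], c_vis = cv, n = n,
                        pse = NA_real_, bias = NA_real_,
                        converged = NA, stringsAsFactors = FALSE)
      if (n >= min_trials && length(unique(d$s_vest[sel])) >= 3) {
        fit <- .fit_psychometric(d$s_vest[sel],
                                 as.integer(d$response[sel] == "right"),
                                 lapse)
        row$pse <- fit$pse
        row$bias <- -fit$pse
        row$converged <- fit$converged
      }
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
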