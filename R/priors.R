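#' Prior parameter bundle
#'
#' Parameters of the observer's prior over heading directions.
#' \code{sigma_prior} is the SD of the (central, zero-mean) prior over a
#' single heading for the independent prior, or over the mean heading for
#' the empirical prior; \code{delta_prior} is the SD of the empirical
#' prior over signed disparity (unused for independent priors).
#'
#' @param sigma_prior SD in degrees, in [1, 120].
#' @param delta_prior SD in degrees, in [1, 120]; ignored for
#'   \code{kind = "I"}.
#' @param kind \code{"E"} (empirical) or \code{"I"} (independent).
#' @return Object of class \code{"prior_params"}.
#' @export
prior_params <- function(sigma_prior, delta_prior = NA, kind = c("E", "I")) {
  kind <- match.arg(kind)
  stopifnot(sigma_prior >= 1, sigma_prior <= 120)
  if (kind == "E") {
    stopifnot(!is.na(delta_prior), delta_prior >= 1, delta_prior <= 120)
  } else delta_prior <- NA
  structure(list(sigma_prior = sigma_prior, delta_prior = delta_prior,
                 kind = kind), class = "prior_params")
}

# Design constants: the stimulus schedule the empirical prior mirrors.
.design_means <- function() seq(-25, 25, by = 5)
.design_disparities <- function() c(-40, -20, -10, -5, 5, 10, 20, 40)

# Internal: discrete support of the empirical prior.
# C = 1: the 11 mean headings, weights ~ N(s | 0, sigma_prior).
# C = 2: 11 means x 8 nonzero signed disparities, weights
#        ~ N(mean | 0, sigma_prior) * N(disparity | 0, delta_prior);
#        s_vis = mean - disparity/2, s_vest = mean + disparity/2.
.empirical_support <- function(pp, C) {
  m <- .design_means()
  if (C == 1L) {
    w <- stats::dnorm(m, 0, pp$sigma_prior)
    return(list(s = m, w = w / sum(w)))
  }
  d <- .design_disparities()
  g <- expand.grid(m = m, d = d)
  w <- stats::dnorm(g$m, 0, pp$sigma_prior) *
    stats::dnorm(g$d, 0, pp$delta_prior)
  list(s_vis = g$m - g$d / 2, s_vest = g$m + g$d / 2, w = w / sum(w))
}

#' Prior density or mass over heading pairs
#'
#' Evaluates the observer's prior over headings conditional on the causal
#' scenario. For the independent prior this is a density: under
#' \eqn{C = 1} both arguments must coincide (\code{s_vis == s_vest}) and
#' the density of the common heading is returned; under \eqn{C = 2} the
#' product of two independent Gaussian densities. For the empirical prior
#' it is a probability mass on the discrete design support (zero off the
#' support); the \eqn{C = 2} support excludes zero disparity, since the
#' design's "different" trials always have nonzero disparity.
#'
#' @param s_vis,s_vest Headings, degrees (vectors of equal length).
#' @param C Causal scenario, 1 or 2.
#' @param pp \code{\link{prior_params}}.
#' @return Density (kind \code{"I"}) or mass (kind \code{"E"}) values.
#' @export
prior_density <- function(s_vis, s_vest, C, pp) {
  stopifnot(C %in% c(1L, 2L), length(s_vis) == length(s_vest))
  if (pp$kind == "I") {
    if (C == 1L) {
      if (any(abs(s_vis - s_vest) > 1e-12))
        stop("C = 1 requires s_vis == s_vest for a density evaluation")
      return(stats::dnorm(s_vis, 0, pp$sigma_prior))
    }
    return(stats::dnorm(s_vis, 0, pp$sigma_prior) *
             stats::dnorm(s_vest, 0, pp$sigma_prior))
  }
  sup <- .empirical_support(pp, C)
  out <- numeric(length(s_vis))
  if (C == 1L) {
    for (i in seq_along(s_vis)) {
      if (abs(s_vis[i] - s_vest[i]) > 1e-9) next
      j <- which(abs(sup$s - s_vis[i]) < 1e-9)
      if (length(j)) out[i] <- sup$w[j]
    }
  } else {
    for (i in seq_along(s_vis)) {
      j <- which(abs(sup$s_vis - s_vis[i]) < 1e-9 &
                   abs(sup$s_vest - s_vest[i]) < 1e-9)
      if (length(j)) out[i] <- sup$w[j]
    }
  }
  out
}
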