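#' Sensory noise standard deviation
#'
#' Standard deviation of the sensory measurement noise for a heading
#' stimulus. Under constant noise (\code{shape = "C"}) the SD equals the
#' base magnitude for the modality (and, for vision, the reliability
#' level). Under eccentricity-dependent noise (\code{shape = "X"}) the SD
#' grows with distance from straight ahead as
#' \deqn{\sigma(s) = \sigma_0 \sqrt{1 + w^2 s^2},}
#' which is approximately quadratic in \eqn{s} for small headings. With
#' \eqn{w = 0} the eccentric form reduces exactly to the constant form.
#'
#' @param s Heading angle(s) in degrees (rightward positive).
#' @param modality \code{"vis"} or \code{"vest"}.
#' @param c_vis Visual reliability level (\code{"high"}, \code{"med"},
#'   \code{"low"}); required for \code{modality = "vis"}, ignored
#'   otherwise.
#' @param np Noise parameters as returned by \code{\link{noise_params}}.
#' @return Numeric vector of SDs (degrees), same length as \code{s}.
#' @examples
#' np <- noise_params(sigma0_vest = 6.49, sigma0_vis = c(4, 6, 11),
#'                    w_vest = 0.04, w_vis = 0.07, shape = "X")
#' noise_sd(0, "vest", np = np)    # eccentricity term vanishes at 0
#' noise_sd(20, "vest", np = np)
#' @export
noise_sd <- function(s, modality = c("vest", "vis"), c_vis = NULL, np) {
  modality <- match.arg(modality)
  if (modality == "vis") {
    if (is.null(c_vis) || !c_vis %in% c("high", "med", "low"))
      stop("visual modality requires a reliability level ('high','med','low')")
    sigma0 <- np$sigma0_vis[[c_vis]]
    w <- if (np$shape == "X") np$w_vis else 0
  } else {
    sigma0 <- np$sigma0_vest
    w <- if (np$shape == "X") np$w_vest else 0
  }
  sigma0 * sqrt(1 + w^2 * s^2)
}

#' Noise parameter bundle
#'
#' @param sigma0_vest Vestibular base SD (deg), in [0.5, 80].
#' @param sigma0_vis Visual base SDs (deg), length-3 vector or named
#'   vector/list with entries \code{high}, \code{med}, \code{low}.
#' @param w_vest,w_vis Eccentricity coefficients in [0, 1]; ignored when
#'   \code{shape = "C"}.
#' @param shape \code{"C"} (constant) or \code{"X"} (eccentricity-
#'   dependent).
#' @return Object of class \code{"noise_params"}.
#' @export
noise_params <- function(sigma0_vest, sigma0_vis, w_vest = 0, w_vis = 0,
                         shape = c("C", "X")) {
  shape <- match.arg(shape)
  if (is.null(names(sigma0_vis)))
    names(sigma0_vis) <- c("high", "med", "low")
  sigma0_vis <- as.list(sigma0_vis)[c("high", "med", "low")]
  stopifnot(sigma0_vest >= 0.5, sigma0_vest <= 80,
            all(unlist(sigma0_vis) >= 0.5), all(unlist(sigma0_vis) <= 80),
            w_vest >= 0, w_vest <= 1, w_vis >= 0, w_vis <= 1)
  if (shape == "C") w_vest <- w_vis <- 0
  structure(list(sigma0_vest = sigma0_vest, sigma0_vis = sigma0_vis,
                 w_vest = w_vest, w_vis = w_vis, shape = shape),
            class = "noise_params")
}

#' Measurement noise density
#'
#' Density of the noisy internal measurement \eqn{x} given a presented
#' heading \eqn{s}: a normal centered on \eqn{s} with SD
#' \code{\link{noise_sd}(s, ...)}. Optionally a wrapped normal with period
#' 360 degrees; for the heading ranges used here the two are numerically
#' indistinguishable.
#'
#' @param x Measurement value(s), degrees.
#' @param s Presented heading, degrees (scalar).
#' @param modality,c_vis,np As in \code{\link{noise_sd}}.
#' @param wrap Logical; use the wrapped-normal variant.
#' @return Density values at \code{x}.
#' @export
measurement_density <- function(x, s, modality = c("vest", "vis"),
                                c_vis = NULL, np, wrap = FALSE) {
  modality <- match.arg(modality)
  sd <- noise_sd(s, modality, c_vis, np)
  if (!wrap) return(stats::dnorm(x, mean = s, sd = sd))
  # wraps beyond +/-3 are < 1e-300 for sd <= 80
  d <- 0
  for (k in -3:3) d <- d + stats::dnorm(x + 360 * k, mean = s, sd = sd)
  d
}

# Internal: matrix of measurement likelihoods over a stimulus grid.
# L[i, j] = p(x_j | s_i) with SD evaluated at s_i (the observer knows the
# eccentricity dependence of its own noise).
.lik_matrix <- function(x, s, sigma0, w, wrap = FALSE) {
  sd <- sigma0 * sqrt(1 + w^2 * s^2)
  if (!wrap) {
    L <- stats::dnorm(outer(s, x, "-") / sd) / sd
  } else {
    L <- 0
    for (k in -3:3) L <- L + stats::dnorm((outer(s, x, "-") + 360 * k) / sd) / sd
  }
  L
}

# Internal: (sigma0, w) for a modality under a theta vector/model.
.noise_of <- function(theta, modality, c_vis = NULL, noise_shape = "C") {
  if (modality == "vest") {
    sigma0 <- theta[["sigma0_vest"]]
    w <- if (noise_shape == "X") theta[["w_vest"]] else 0
  } else {
    sigma0 <- theta[[paste0("sigma0_vis_", c_vis)]]
    w <- if (noise_shape == "X") theta[["w_vis"]] else 0
  }
  list(sigma0 = sigma0, w = w)
}
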