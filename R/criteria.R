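#' Information criteria
#'
#' Sample-size-corrected Akaike information criterion and Bayesian
#' information criterion from a maximum log likelihood:
#' \deqn{AICc = -2 LL^* + 2k + \frac{2k(k+1)}{N - k - 1}, \qquad
#'       BIC = -2 LL^* + k \log N.}
#'
#' @param logLik Maximum log likelihood \eqn{LL^*}.
#' @param k Number of free parameters.
#' @param n Number of trials; must exceed \eqn{k + 1} for AICc.
#' @return Named list with \code{AICc} and \code{BIC}.
#' @examples
#' info_criteria(-100, 5, 500)   # AICc = 210 + 60/494
#' @export
info_criteria <- function(logLik, k, n) {
  stopifnot(is.finite(logLik), k >= 0)
  if (n <= k + 1)
    stop("AICc undefined: need n > k + 1 (n = ", n, ", k = ", k, ")")
  aic <- -2 * logLik + 2 * k
  list(AICc = aic + 2 * k * (k + 1) / (n - k - 1),
       BIC = -2 * logLik + k * log(n))
}

# Generalized-Pareto fit (profile-posterior point estimate of Zhang &
# Stephens 2009, as used for Pareto smoothing). x: positive exceedances.
.gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior_b <- 3
  m <- 30 + floor(sqrt(n))
  q1 <- x[max(1, floor(n / 4 + 0.5))]
  bs <- 1 / x[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) / (prior_b * q1)
  ks <- vapply(bs, function(b) -mean(log1p(-b * x)), 0)
  L <- n * (log(bs / ks) + ks - 1)
  wts <- exp(L - max(L)); wts <- wts / sum(wts)
  b <- sum(bs * wts)
  k <- -mean(log1p(-b * x))
  list(k = k, sigma = k / b)
}

.gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma / k * ((1 - p)^(-k) - 1)
}

#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' Estimates the Bayesian leave-one-out score from posterior draws: for
#' each trial the leave-one-out posterior is approximated by importance
#' reweighting of the full posterior with weights proportional to the
#' inverse trial likelihood; the weight tails are stabilized by replacing
#' the largest weights with quantiles of a fitted generalized Pareto
#' distribution, whose shape exponent \eqn{k_i} is reported as a
#' reliability diagnostic (\eqn{k_i > 0.7} flagged; \eqn{k_i > 1} means
#' the weight-distribution moments do not exist and triggers a warning).
#'
#' @param log_lik Matrix of per-draw, per-trial log likelihoods
#'   (draws \eqn{S} by trials \eqn{N}).
#' @param k_warn,k_bad Pareto-shape flag and warning thresholds.
#' @return Object of class \code{"psis_result"}: \code{loo} (total),
#'   \code{pointwise} (per-trial contributions), \code{pareto_k}
#'   (per-trial shape exponents, \code{NA} when the tail is too short to
#'   fit), and \code{flagged} (indices with \eqn{k_i} above the flag
#'   threshold).
#' @export
psis_loo <- function(log_lik, k_warn = 0.7, k_bad = 1.0) {
  log_lik <- as.matrix(log_lik)
  if (any(!is.finite(log_lik)))
    stop("log-likelihood matrix must be finite")
  S <- nrow(log_lik); N <- ncol(log_lik)
  if (S == 1) {
    pw <- drop(log_lik)
    return(structure(list(loo = sum(pw), pointwise = pw,
                          pareto_k = rep(NA_real_, N),
                          flagged = integer(0)),
                     class = "psis_result"))
  }
  pointwise <- numeric(N)
  pareto_k <- rep(NA_real_, N)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  for (i in seq_len(N)) {
    lr <- -log_lik[, i]          # log raw importance ratios
    lr <- lr - max(lr)
    if (M >= 5 && S - M >= 1) {
      ord <- order(lr)
      tail_idx <- ord[(S - M + 1):S]
      cutoff <- lr[ord[S - M]]
      exceed <- exp(lr[tail_idx]) - exp(cutoff)
      if (stats::sd(exceed) > 0) {
        fit <- .gpd_fit(exceed)
        pareto_k[i] <- fit$k
        q <- .gpd_quantile((seq_len(M) - 0.5) / M, fit$k, fit$sigma)
        smoothed <- log(exp(cutoff) + q)
        # keep order, cap at the largest raw weight
        smoothed <- pmin(sort(smoothed), max(lr))
        lr[tail_idx[order(lr[tail_idx])]] <- smoothed
      }
    }
    # log [ sum_s w_s p_i(theta_s) / sum_s w_s ]
    pointwise[i] <- .logsumexp(lr + log_lik[, i]) - .logsumexp(lr)
  }
  if (any(pareto_k > k_bad, na.rm = TRUE))
    warning(sum(pareto_k > k_bad, na.rm = TRUE),
            " trial(s) with Pareto k > ", k_bad,
            "; PSIS-LOO estimate may be unreliable")
  structure(list(loo = sum(pointwise), pointwise = pointwise,
                 pareto_k = pareto_k,
                 flagged = which(pareto_k > k_warn)),
            class = "psis_result")
}

#' @export
print.psis_result <- function(x, ...) {
  cat("<psis_result> LOO =", format(x$loo), "over",
      length(x$pointwise), "trials;",
      length(x$flagged), "flagged (k > 0.7)\n")
  invisible(x)
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Marginal likelihood by weighted harmonic mean
#'
#' Estimates the log marginal likelihood from posterior draws via the
#' weighted harmonic mean identity
#' \deqn{LML = -\log \frac{1}{S} \sum_s
#'   \frac{\varphi(\theta^{(s)})}{p(\theta^{(s)})\, L(\theta^{(s)})},}
#' where \eqn{\varphi} is a weight density with support confined to a
#' high-posterior-density region so the summand's variance stays finite.
#' Here \eqn{\varphi} is a mixture of uniform ellipsoids: a Gaussian
#' mixture is fitted to the draws and each component is replaced by a
#' uniform distribution on an ellipsoid proportional to its covariance;
#' the common proportionality (Mahalanobis radius) is chosen by
#' minimizing the empirical variance of the summands.
#'
#' @param draws Matrix of posterior draws (rows) in natural space.
#' @param log_prior Vector of log prior densities at the draws.
#' @param log_lik Vector of total log likelihoods at the draws.
#' @param max_components Maximum number of mixture components tried.
#' @param radii Candidate Mahalanobis radii for the ellipsoids.
#' @return List with \code{lml}, the chosen \code{radius}, the number of
#'   mixture \code{components}, and the fraction of draws inside the
#'   weight support.
#' @importFrom mclust Mclust mclustBIC
#' @export
marginal_likelihood_whm <- function(draws, log_prior, log_lik,
                                    max_components = 3,
                                    radii = seq(0.6, 2.4, by = 0.2)) {
  draws <- as.matrix(draws)
  S <- nrow(draws); d <- ncol(draws)
  stopifnot(length(log_prior) == S, length(log_lik) == S, S >= 100)

  mix <- tryCatch({
    # the mixture initialization subsamples for large S; pin it so the
    # estimator is a deterministic function of its inputs
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(20240601)
    fit <- Mclust(draws, G = seq_len(max_components), verbose = FALSE)
    if (is.null(fit)) stop("mclust failed")
    G <- fit$G
    means <- matrix(fit$parameters$mean, nrow = d)
    covs <- lapply(seq_len(G), function(g) {
      S_g <- if (d == 1) matrix(fit$parameters$variance$sigmasq[
        min(g, length(fit$parameters$variance$sigmasq))], 1, 1)
      else fit$parameters$variance$sigma[, , g]
      S_g
    })
    list(pi = fit$parameters$pro, means = means, covs = covs, G = G)
  }, error = function(e) {
    warning("mixture fit degenerate; falling back to a single ellipsoid")
    list(pi = 1, means = matrix(colMeans(draws), nrow = d),
         covs = list(stats::cov(draws) + diag(1e-12, d)), G = 1L)
  })

  # Mahalanobis distance of every draw to every component
  maha <- matrix(NA_real_, S, mix$G)
  logdet <- numeric(mix$G)
  for (g in seq_len(mix$G)) {
    Sg <- as.matrix(mix$covs[[g]])
    ch <- tryCatch(chol(Sg), error = function(e)
      chol(Sg + diag(1e-10 * mean(diag(Sg)) + 1e-300, d)))
    logdet[g] <- 2 * sum(log(diag(ch)))
    z <- backsolve(ch, t(draws) - mix$means[, g], transpose = TRUE)
    maha[, g] <- colSums(z^2)
  }
  log_unit_ball <- (d / 2) * log(pi) - lgamma(d / 2 + 1)

  score <- function(r) {
    # log phi at each draw for radius r
    lphi_g <- vapply(seq_len(mix$G), function(g) {
      lvol <- log_unit_ball + d * log(r) + 0.5 * logdet[g]
      ifelse(maha[, g] <= r^2, log(mix$pi[g]) - lvol, -Inf)
    }, numeric(S))
    lphi <- apply(as.matrix(lphi_g), 1, .logsumexp)
    lt <- lphi - log_prior - log_lik
    keep <- is.finite(lt)
    if (sum(keep) < 10) return(NULL)
    # variance of the summands on a common scale
    m <- max(lt[keep])
    t_s <- exp(lt - m)
    t_s[!keep] <- 0
    list(var = stats::var(t_s),
         lml = -(.logsumexp(lt[keep]) - log(S)))
  }
  results <- lapply(radii, score)
  ok <- !vapply(results, is.null, TRUE)
  if (!any(ok)) stop("no candidate radius yields a usable weight density")
  vars <- vapply(results[ok], `[[`, 0, "var")
  best <- which(ok)[which.min(vars)]
  inside <- mean(apply(maha, 1, min) <= radii[best]^2)
  list(lml = results[[best]]$lml, radius = radii[best],
       components = mix$G, inside_fraction = inside)
}
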