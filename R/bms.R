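#' Hierarchical (group) Bayesian model selection
#'
#' Random-effects model selection across subjects: model identities are
#' treated as draws from an unknown population frequency vector with a
#' Dirichlet prior. The Dirichlet posterior is obtained with the standard
#' variational scheme; summary statistics are the posterior model
#' frequencies, the exceedance probability \eqn{\varphi} (probability
#' that a model is the most frequent), the Bayesian omnibus risk BOR
#' (posterior probability that the evidence differences arose under equal
#' frequencies), and the protected exceedance probability
#' \deqn{\tilde\varphi_i = (1 - BOR)\,\varphi_i + BOR / K.}
#'
#' @param evidence Subjects-by-models matrix of log model evidence
#'   (e.g. LOO scores, \eqn{-AICc/2}, \eqn{-BIC/2}, or LML), on a scale
#'   comparable across models.
#' @param alpha0 Prior Dirichlet concentrations: scalar \eqn{\alpha_0}
#'   (weights all 1) or a vector \eqn{\alpha_0 w} of per-model prior
#'   concentrations.
#' @param n_draws Monte-Carlo draws for the exceedance probabilities.
#' @param seed Seed for the exceedance Monte Carlo.
#' @param tol,max_iter Variational convergence controls.
#' @return Object of class \code{"bms_result"}: \code{alpha} (posterior
#'   concentrations), \code{alpha0}, \code{freq_mean}, \code{freq_sd},
#'   \code{attribution} (subjects-by-models posterior model
#'   probabilities), \code{xp} (\eqn{\varphi}), \code{pxp}
#'   (\eqn{\tilde\varphi}), \code{bor}, and the free energies \code{F1},
#'   \code{F0}.
#' @export
group_bms <- function(evidence, alpha0 = 1, n_draws = 1e6, seed = 1,
                      tol = 1e-8, max_iter = 500) {
  evidence <- as.matrix(evidence)
  if (any(!is.finite(evidence))) stop("evidence must be finite")
  n <- nrow(evidence); K <- ncol(evidence)
  if (K < 2) stop("need at least two models")
  if (length(alpha0) == 1) alpha0 <- rep(alpha0, K)
  stopifnot(length(alpha0) == K, all(alpha0 > 0))

  alpha <- alpha0 + n / K
  u <- matrix(1 / K, n, K)
  for (it in seq_len(max_iter)) {
    lu <- sweep(evidence, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    u <- exp(lu - apply(lu, 1, .logsumexp))
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }

  asum <- sum(alpha)
  freq_mean <- alpha / asum
  freq_sd <- sqrt(alpha * (asum - alpha) / (asum^2 * (asum + 1)))
  xp <- .dirichlet_exceedance(alpha, n_draws, seed)

  F1 <- .bms_free_energy(evidence, u, alpha, alpha0)
  F0 <- .bms_null_energy(evidence, alpha0)
  bor <- 1 / (1 + exp(F1 - F0))
  pxp <- (1 - bor) * xp + bor / K

  structure(list(alpha = alpha, alpha0 = alpha0, freq_mean = freq_mean,
                 freq_sd = freq_sd, attribution = u, xp = xp, pxp = pxp,
                 bor = bor, F1 = F1, F0 = F0, n_subjects = n,
                 models = colnames(evidence)),
            class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  df <- data.frame(model = if (is.null(x$models))
    paste0("M", seq_along(x$alpha)) else x$models,
    alpha = round(x$alpha, 3), freq = round(x$freq_mean, 3),
    xp = round(x$xp, 3), pxp = round(x$pxp, 3))
  print(df, row.names = FALSE)
  cat("BOR =", signif(x$bor, 3), "\n")
  invisible(x)
}

# Variational free energy of the random-effects model (H1).
.bms_free_energy <- function(evidence, u, alpha, alpha0) {
  Eq_lnr <- digamma(alpha) - digamma(sum(alpha))
  ent_u <- -sum(u * log(pmax(u, 1e-300)))
  sum(u * evidence) + sum(u %*% Eq_lnr) + ent_u +
    lgamma(sum(alpha0)) - sum(lgamma(alpha0)) +
    sum((alpha0 - 1) * Eq_lnr) -
    (lgamma(sum(alpha)) - sum(lgamma(alpha)) +
       sum((alpha - 1) * Eq_lnr))
}

# Evidence of the null (equal, fixed frequencies given by the normalized
# prior weights).
.bms_null_energy <- function(evidence, alpha0) {
  r0 <- alpha0 / sum(alpha0)
  sum(apply(sweep(evidence, 2, log(r0), "+"), 1, .logsumexp))
}

.dirichlet_exceedance <- function(alpha, n_draws = 1e6, seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  K <- length(alpha)
  counts <- numeric(K)
  block <- 1e5
  done <- 0
  while (done < n_draws) {
    m <- min(block, n_draws - done)
    g <- matrix(stats::rgamma(m * K, shape = rep(alpha, each = m)), m, K)
    w <- max.col(g, ties.method = "first")   # ties are measure-zero
    counts <- counts + tabulate(w, K)
    done <- done + m
  }
  counts / n_draws
}

#' Factor-level Bayesian model selection
#'
#' Aggregates a model-level group BMS to the components of a model
#' factor, exploiting the agglomerative property of the Dirichlet
#' distribution (concentrations of models in the same component add).
#' The prior is re-weighted so that every component of every factor gets
#' equal prior mass (models in smaller components get proportionally
#' larger weights), with overall scale \eqn{\alpha_0} defaulting to the
#' mean number of components per factor divided by the number of models,
#' which keeps the aggregated concentrations of order one. The
#' factor-level BOR repeats the null-versus-random-effects comparison on
#' the factor partition with the factor-balanced prior.
#'
#' @param evidence Subjects-by-models log-evidence matrix with column
#'   names matching \code{names(models)}.
#' @param models Named list of \code{\link{model_spec}} objects.
#' @param factors Factor names to analyze.
#' @param alpha0 Overall prior scale; \code{NULL} for the factor-balanced
#'   default.
#' @param n_draws,seed Exceedance Monte-Carlo controls.
#' @return Named list (one per factor) of lists with the aggregated
#'   \code{alpha}, \code{freq_mean}, \code{xp}, \code{pxp}, \code{bor}
#'   and the component \code{partition}; plus attribute
#'   \code{"model_bms"}, the underlying model-level \code{bms_result}.
#' @export
factor_level_bms <- function(evidence, models,
                             factors = c("strategy", "noise", "prior"),
                             alpha0 = NULL, n_draws = 1e6, seed = 1) {
  evidence <- as.matrix(evidence)
  stopifnot(!is.null(colnames(evidence)),
            setequal(colnames(evidence), names(models)))
  evidence <- evidence[, names(models), drop = FALSE]
  K <- length(models)

  partitions <- lapply(factors, function(f)
    model_factor_partition(models, f))
  names(partitions) <- factors

  # prior weights: equal mass per component within each factor, combined
  # multiplicatively across factors, then scaled
  w <- rep(1, K); names(w) <- names(models)
  for (part in partitions) {
    covered <- unlist(part)
    for (comp in part)
      w[comp] <- w[comp] * (length(covered) / length(part)) / length(comp)
  }
  w <- w * K / sum(w)
  if (is.null(alpha0)) {
    mean_comp <- mean(vapply(partitions, length, 0))
    alpha0 <- mean_comp / K
  }
  prior <- alpha0 * w

  model_bms <- group_bms(evidence, alpha0 = prior, n_draws = n_draws,
                         seed = seed)

  out <- list()
  for (f in factors) {
    part <- partitions[[f]]
    if (length(part) < 2) next
    covered <- unlist(part)
    agg <- vapply(part, function(comp)
      sum(model_bms$alpha[match(comp, names(models))]), 0)
    agg0 <- vapply(part, function(comp)
      sum(prior[match(comp, names(models))]), 0)
    xp <- .dirichlet_exceedance(agg, n_draws, seed)
    # factor-level BOR: repeat the null-vs-random-effects comparison on
    # the factor partition, with component evidence marginalized over the
    # member models at their within-component prior weights
    ev_f <- vapply(part, function(comp) {
      wc <- prior[comp] / sum(prior[comp])
      apply(sweep(evidence[, comp, drop = FALSE], 2, log(wc), "+"),
            1, .logsumexp)
    }, numeric(nrow(evidence)))
    ev_f <- matrix(ev_f, nrow = nrow(evidence))
    bms_f <- group_bms(ev_f, alpha0 = agg0, n_draws = 1e3, seed = seed)
    bor <- bms_f$bor
    pxp <- (1 - bor) * xp + bor / length(part)
    out[[f]] <- list(alpha = agg, alpha0 = agg0,
                     freq_mean = agg / sum(agg), xp = xp, pxp = pxp,
                     bor = bor, partition = part)
  }
  attr(out, "model_bms") <- model_bms
  out
}
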