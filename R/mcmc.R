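#' Ensemble slice sampler
#'
#' Markov chain Monte Carlo over a box-bounded target density, combining
#' slice sampling with adaptive direction sampling: an ensemble of
#' dependent walkers is updated in turn, each by slice sampling along a
#' line through the current walker — either a coordinate axis or the
#' difference vector of two other walkers, which adapts the proposal
#' geometry to the target's correlation structure. Slice sampling needs
#' no step-size tuning; the box bounds delimit the slice interval.
#'
#' @param logf Log target density taking a parameter vector; \code{-Inf}
#'   outside the support is tolerated.
#' @param lower,upper Box bounds (numeric vectors).
#' @param n_walkers Number of ensemble walkers (>= 4 recommended;
#'   default 2*(dim+1)).
#' @param n_sweeps Number of post-burn-in sweeps to record (each sweep
#'   updates every walker once, so the total number of recorded draws is
#'   \code{n_sweeps * n_walkers}).
#' @param burn_in Number of discarded initial sweeps (default: equal to
#'   \code{n_sweeps}, i.e. half the run).
#' @param seed Integer seed.
#' @param init Optional matrix (\code{n_walkers x dim}) of starting
#'   positions inside the box.
#' @param p_ads Probability of proposing along a walker-difference
#'   direction instead of a coordinate axis.
#' @return List with \code{draws} (matrix, rows are recorded positions),
#'   \code{logp}, \code{walker} (walker index per row), \code{rhat} and
#'   \code{ess} per dimension, and \code{n_evals}.
#' @export
eis_sample <- function(logf, lower, upper, n_walkers = NULL,
                       n_sweeps = 500, burn_in = NULL, seed = 1,
                       init = NULL, p_ads = 0.66) {
  k <- length(lower)
  stopifnot(length(upper) == k, all(upper > lower))
  if (is.null(n_walkers)) n_walkers <- 2L * (k + 1L)
  n_walkers <- max(4L, as.integer(n_walkers))
  if (is.null(burn_in)) burn_in <- n_sweeps
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  X <- if (!is.null(init)) {
    stopifnot(nrow(init) == n_walkers, ncol(init) == k)
    as.matrix(init)
  } else {
    u <- matrix(stats::runif(n_walkers * k, 0.1, 0.9), n_walkers, k)
    sweep(sweep(u, 2, upper - lower, "*"), 2, lower, "+")
  }
  lp <- apply(X, 1, logf)
  if (any(!is.finite(lp)))
    stop("initial walker positions have non-finite log density")
  n_evals <- n_walkers

  slice_line <- function(x0, lp0, dir) {
    # t-range keeping x0 + t*dir inside the box
    tlo <- -Inf; thi <- Inf
    for (j in seq_len(k)) {
      if (dir[j] == 0) next
      r <- sort(c((lower[j] - x0[j]) / dir[j], (upper[j] - x0[j]) / dir[j]))
      tlo <- max(tlo, r[1]); thi <- min(thi, r[2])
    }
    y <- lp0 - stats::rexp(1)
    lo <- tlo; hi <- thi
    repeat {
      t1 <- stats::runif(1, lo, hi)
      x1 <- x0 + t1 * dir
      lp1 <- logf(x1)
      n_evals <<- n_evals + 1
      if (is.finite(lp1) && lp1 >= y) return(list(x = x1, lp = lp1))
      if (t1 < 0) lo <- t1 else hi <- t1
      if (hi - lo < 1e-12) return(list(x = x0, lp = lp0))
    }
  }

  total <- burn_in + n_sweeps
  draws <- matrix(NA_real_, n_sweeps * n_walkers, k)
  logp <- numeric(n_sweeps * n_walkers)
  walker <- integer(n_sweeps * n_walkers)
  row <- 0L
  for (sweep_i in seq_len(total)) {
    for (w in seq_len(n_walkers)) {
      if (stats::runif(1) < p_ads && n_walkers >= 3) {
        ab <- sample(setdiff(seq_len(n_walkers), w), 2)
        dir <- X[ab[1], ] - X[ab[2], ]
        if (all(abs(dir) < 1e-12)) dir <- .coord_dir(k, lower, upper)
      } else {
        dir <- .coord_dir(k, lower, upper)
      }
      res <- slice_line(X[w, ], lp[w], dir)
      X[w, ] <- res$x
      lp[w] <- res$lp
      if (sweep_i > burn_in) {
        row <- row + 1L
        draws[row, ] <- res$x
        logp[row] <- res$lp
        walker[row] <- w
      }
    }
  }

  ch <- .chain_array(draws, walker, n_walkers)
  list(draws = draws, logp = logp, walker = walker,
       rhat = apply(ch, 3, .split_rhat), ess = apply(ch, 3, .ess),
       n_evals = n_evals, seed = seed)
}

.coord_dir <- function(k, lower, upper) {
  j <- sample.int(k, 1)
  d <- numeric(k)
  d[j] <- (upper[j] - lower[j]) / 10
  d
}

# draws (rows in walker-sweep order) -> array [sweep, walker, dim]
.chain_array <- function(draws, walker, n_walkers) {
  k <- ncol(draws)
  n_sweeps <- nrow(draws) / n_walkers
  a <- array(NA_real_, c(n_sweeps, n_walkers, k))
  for (w in seq_len(n_walkers)) {
    rows <- which(walker == w)
    a[, w, ] <- draws[rows, , drop = FALSE]
  }
  a
}

# Split-Rhat (Gelman et al.): each walker chain split in half.
.split_rhat <- function(ch) {
  n <- nrow(ch)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  sub <- cbind(ch[seq_len(half), , drop = FALSE],
               ch[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# Effective sample size via initial-positive-sequence autocorrelation sums.
.ess <- function(ch) {
  n <- nrow(ch); m <- ncol(ch)
  if (n < 4) return(NA_real_)
  rho_sum <- 0
  for (j in seq_len(m)) {
    x <- ch[, j]
    v <- stats::var(x)
    if (v <= 0) next
    ac <- stats::acf(x, lag.max = min(n - 2, 200), plot = FALSE)$acf[-1]
    pos <- which(ac < 0.05)
    cutoff <- if (length(pos)) pos[1] - 1 else length(ac)
    rho_sum <- rho_sum + max(0, sum(ac[seq_len(cutoff)]))
  }
  rho <- rho_sum / m
  n * m / (1 + 2 * rho)
}

#' Posterior sampling for an observer model
#'
#' Samples the parameter posterior \eqn{p(\theta \mid data) \propto
#' p(data \mid \theta)\, p(\theta)} with \code{\link{eis_sample}}, under
#' a non-informative uniform prior over each parameter's allowed range
#' (uniform in log space for scale parameters). Also stores the
#' per-draw, per-trial log-likelihood matrix needed by
#' \code{\link{psis_loo}} and \code{\link{marginal_likelihood_whm}}.
#'
#' @param data Trial table data frame.
#' @param model \code{\link{model_spec}}.
#' @param n_walkers Ensemble size (default 2*(k+1)).
#' @param n_samples Target number of recorded posterior draws.
#' @param burn_in Burn-in sweeps (default: half the run).
#' @param seed Integer seed.
#' @param opts \code{\link{ci_opts}}.
#' @param init Optional named parameter vector (e.g. an MLE) around which
#'   walkers are initialized.
#' @param store_trial_ll Store the draws-by-trials log-likelihood matrix
#'   (recomputed for each recorded draw).
#' @param rhat_warn Split-Rhat threshold above which a convergence
#'   warning is raised.
#' @return Object of class \code{"posterior_samples"}: \code{draws}
#'   (natural-space matrix with named columns), \code{logp} (log
#'   posterior up to a constant), \code{log_lik} (draws x trials, or
#'   \code{NULL}), \code{rhat}, \code{ess}, \code{param_space},
#'   \code{walker}, \code{seed}.
#' @export
sample_posterior <- function(data, model, n_walkers = NULL,
                             n_samples = 5000, burn_in = NULL, seed = 1,
                             opts = ci_opts(), init = NULL,
                             store_trial_ll = TRUE, rhat_warn = 1.1) {
  ps <- build_parameter_space(model, tasks = intersect(
    model$tasks, unique(data$task)))
  b <- ps_bounds_z(ps)
  k <- nrow(ps)
  if (is.null(n_walkers)) n_walkers <- 2L * (k + 1L)
  n_sweeps <- max(2L, ceiling(n_samples / n_walkers))

  logf <- function(z)
    tryCatch(dataset_log_likelihood(data, model,
                                    ps_untransform(z, ps), opts)$total,
             error = function(e) -Inf)

  init_mat <- NULL
  if (!is.null(init)) {
    z0 <- ps_transform(init, ps)
    old <- .Random.seed_save()
    set.seed(seed + 1L)
    span <- (b$upper - b$lower)
    init_mat <- t(replicate(n_walkers, pmin(pmax(
      z0 + stats::rnorm(k, 0, 0.02) * span, b$lower + 1e-6 * span),
      b$upper - 1e-6 * span)))
    .Random.seed_restore(old)
  }

  res <- eis_sample(logf, b$lower, b$upper, n_walkers = n_walkers,
                    n_sweeps = n_sweeps, burn_in = burn_in, seed = seed,
                    init = init_mat)
  if (any(res$rhat > rhat_warn, na.rm = TRUE))
    warning("split-Rhat above ", rhat_warn, " for parameter(s): ",
            paste(ps$name[which(res$rhat > rhat_warn)], collapse = ", "))

  draws <- t(apply(res$draws, 1, ps_untransform, ps = ps))
  colnames(draws) <- ps$name
  log_lik <- NULL
  if (store_trial_ll) {
    log_lik <- matrix(NA_real_, nrow(draws), nrow(data))
    for (s in seq_len(nrow(draws)))
      log_lik[s, ] <- dataset_log_likelihood(
        data, model, draws[s, ], opts)$per_trial
  }
  structure(list(draws = draws, logp = res$logp, log_lik = log_lik,
                 rhat = stats::setNames(res$rhat, ps$name),
                 ess = stats::setNames(res$ess, ps$name),
                 param_space = ps, walker = res$walker, seed = seed,
                 model = model),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("<posterior_samples>", nrow(x$draws), "draws,",
      ncol(x$draws), "parameters\n")
  cat("  max split-Rhat:", round(max(x$rhat, na.rm = TRUE), 3),
      " min ESS:", round(min(x$ess, na.rm = TRUE)), "\n")
  invisible(x)
}
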