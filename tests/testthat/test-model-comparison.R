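test_that("information criteria match their closed forms", {
  ic <- info_criteria(-100, 5, 500)
  expect_equal(ic$AICc, 210 + 60 / 494)
  expect_equal(info_criteria(0, 2, 100)$BIC, 2 * log(100))
  # AICc approaches AIC as N grows
  aic <- -2 * (-100) + 2 * 5
  expect_lt(info_criteria(-100, 5, 1e7)$AICc - aic, 1e-4)
  expect_gt(ic$AICc, aic)
  expect_error(info_criteria(-100, 5, 6), "AICc undefined")
})

test_that("PSIS-LOO degenerates to the plug-in sum for one draw and to a
           log-mean for equal weights", {
  ll <- matrix(log(c(0.7, 0.2, 0.9)), nrow = 1)
  r1 <- psis_loo(ll)
  expect_equal(r1$loo, sum(ll))
  # equal per-draw likelihoods for each trial -> contribution is
  # log(mean_s p_i)
  S <- 50
  p <- c(0.3, 0.6)
  ll2 <- cbind(rep(log(p[1]), S), rep(log(p[2]), S))
  r2 <- psis_loo(ll2)
  expect_equal(r2$pointwise, log(p))
  expect_error(psis_loo(matrix(c(1, -Inf), 1)), "finite")
})

test_that("PSIS-LOO tracks the exact leave-one-out score on a conjugate
           toy and never beats the in-sample fit", {
  toy <- beta_bernoulli_toy(n = 20, p_true = 0.7, S = 4000, seed = 21)
  res <- psis_loo(toy$log_lik)
  expect_lt(abs(res$loo - toy$loo_exact), 0.1)
  expect_true(all(is.finite(res$pareto_k)))
  # penalization is non-negative: LOO <= sum of log mean likelihoods
  insample <- sum(apply(toy$log_lik, 2, function(l)
    log(mean(exp(l)))))
  expect_lte(res$loo, insample + 1e-10)
})

test_that("the weighted-harmonic-mean estimator recovers analytic
           evidence on conjugate toys and shifts exactly", {
  toy <- beta_bernoulli_toy(n = 25, p_true = 0.6, S = 4000, seed = 8)
  res <- marginal_likelihood_whm(matrix(toy$draws, ncol = 1),
                                 toy$log_prior, toy$log_lik_total)
  expect_lt(abs(res$lml - toy$lml_exact), 0.1)
  # adding a constant to every log likelihood shifts the estimate by it
  # (holding the weight density fixed at the chosen radius)
  resa <- marginal_likelihood_whm(matrix(toy$draws, ncol = 1),
                                  toy$log_prior, toy$log_lik_total,
                                  radii = res$radius)
  res2 <- marginal_likelihood_whm(matrix(toy$draws, ncol = 1),
                                  toy$log_prior,
                                  toy$log_lik_total + 3.2,
                                  radii = res$radius)
  expect_equal(res2$lml, resa$lml + 3.2, tolerance = 1e-9)

  # 1-D Gaussian likelihood x uniform prior on [-10, 10]:
  # evidence = (1/20) * N(y | mu0, sigma^2 + tau^2) integrated form;
  # with a single observation y and flat prior the evidence is
  # (1/20) * integral N(y | theta, 1) dtheta ~= 1/20
  set.seed(99)
  y <- 0.4
  draws <- rnorm(4000, y, 1)          # posterior under flat prior
  draws <- draws[abs(draws) < 10]
  lp <- rep(log(1 / 20), length(draws))
  llv <- dnorm(y, draws, 1, log = TRUE)
  res3 <- marginal_likelihood_whm(matrix(draws, ncol = 1), lp, llv)
  exact <- log(1 / 20)                # mass inside the box ~= 1
  expect_lt(abs(res3$lml - exact), 0.1)
})

test_that("group model selection reaches its analytic limits", {
  # identical evidence: null hypothesis wins (BOR grows toward 1 with
  # the number of subjects), protected exceedance is uniform
  ev <- matrix(-100, 8, 3)
  r <- group_bms(ev, alpha0 = 1, n_draws = 1e5, seed = 2)
  expect_gt(r$bor, 0.75)
  r60 <- group_bms(matrix(-100, 60, 3), alpha0 = 1, n_draws = 1e5,
                   seed = 2)
  expect_gt(r60$bor, 0.95)
  expect_gt(r60$bor, r$bor)
  expect_equal(r$pxp, rep(1 / 3, 3), tolerance = 0.02)
  expect_equal(sum(r$pxp), 1, tolerance = 1e-9)
  # dominant model: protected exceedance concentrates, BOR vanishes
  ev2 <- matrix(0, 11, 4)
  ev2[, 2] <- 100
  r2 <- group_bms(ev2, alpha0 = 1, n_draws = 1e5, seed = 2)
  expect_gt(r2$pxp[2], 0.99)
  expect_lt(r2$bor, 0.01)
  # Dirichlet count update
  expect_equal(sum(r2$alpha) - sum(r2$alpha0), 11)
  expect_error(group_bms(matrix(c(1, NA, 2, 3), 2)), "finite")
})

test_that("posterior frequencies converge to the generating frequencies
           with many subjects", {
  set.seed(31)
  true_freq <- c(0.6, 0.3, 0.1)
  n <- 200
  assign <- sample(1:3, n, replace = TRUE, prob = true_freq)
  ev <- matrix(0, n, 3)
  for (i in seq_len(n)) ev[i, assign[i]] <- 8   # clear per-subject winner
  r <- group_bms(ev, alpha0 = 1, n_draws = 1e5, seed = 5)
  expect_lt(max(abs(r$freq_mean - true_freq)), 0.08)
})

test_that("factor aggregation adds concentrations and balances prior
           weights as documented", {
  models <- explicit_model_space()
  set.seed(12)
  ev <- matrix(rnorm(6 * 7, sd = 2), 6, 7,
               dimnames = list(NULL, names(models)))
  fr <- factor_level_bms(ev, models, n_draws = 1e4, seed = 3)
  mb <- attr(fr, "model_bms")
  # agglomeration: factor alpha are sums of member-model alpha
  part <- fr$strategy$partition
  for (comp in names(part))
    expect_equal(fr$strategy$alpha[[comp]],
                 sum(mb$alpha[match(part[[comp]], names(models))]))
  # the factor-balanced prior gives Fix models 2x and SFu 4x the weight
  # of Bay models
  pw <- mb$alpha0
  expect_equal(pw[["Fix-C"]] / pw[["Bay-C-E"]], 2)
  expect_equal(pw[["SFu"]] / pw[["Bay-C-E"]], 4)
  # overall scale: mean components per factor / number of models
  expect_equal(sum(pw), (3 + 2 + 2) / 3, tolerance = 1e-9)
  # protected exceedance vectors are probability vectors interpolating
  # to uniform with the omnibus risk
  for (f in names(fr)) {
    expect_equal(sum(fr[[f]]$xp), 1, tolerance = 1e-9)
    K <- length(fr[[f]]$alpha)
    expect_equal(fr[[f]]$pxp,
                 (1 - fr[[f]]$bor) * fr[[f]]$xp + fr[[f]]$bor / K,
                 tolerance = 1e-12)
  }
})

test_that("Dirichlet agglomeration commutes with count updates", {
  alpha0 <- c(0.3, 0.5, 0.2, 1.0)
  counts <- c(4, 1, 2, 3)
  part <- list(a = 1:2, b = 3:4)
  agg_then_update <- vapply(part, function(i) sum(alpha0[i]), 0) +
    vapply(part, function(i) sum(counts[i]), 0)
  update_then_agg <- vapply(part, function(i) sum(alpha0[i] + counts[i]), 0)
  expect_equal(agg_then_update, update_then_agg)
  # spot check of the stated aggregation example
  expect_equal(vapply(list(1:2, 3:4), function(i) sum(c(1, 2, 3, 4)[i]), 0),
               c(3, 7))
})

test_that("compatibility probability favors shared parameters for
           overlapping posteriors and distinct ones otherwise", {
  set.seed(17)
  # single task: both hypotheses reduce to the same integral
  one <- compatibility_probability(list(list(rnorm(2000, 0, 1))))
  expect_equal(one$logml_h0, one$logml_h1, tolerance = 1e-9)
  # identical, sharply peaked task posteriors: H0 preferred
  subs <- lapply(1:6, function(i)
    lapply(1:3, function(t) rnorm(1500, 0.5, 0.05)))
  same <- compatibility_probability(subs, seed = 2)
  expect_true(all(same$logml_h0 > same$logml_h1))
  expect_gt(same$cp, 0.5)
  # well-separated posteriors: H1 preferred
  subs2 <- lapply(1:6, function(i)
    lapply(1:3, function(t) rnorm(1500, c(-2, 0, 2)[t], 0.08)))
  diff <- compatibility_probability(subs2, seed = 2)
  expect_true(all(diff$logml_h1 > diff$logml_h0))
  expect_lt(diff$cp, 0.5)
})

test_that("absolute goodness of fit anchors at chance and at the data
           entropy", {
  des <- generate_design(design_spec(0, 400, 0), seed = 3)
  m <- model_spec(explicit = "SFu", tasks = "unity")
  data <- simulate_observer(des, m, c(eta_low = 0.8, eta_med = 0.5,
                                      eta_high = 0.3), seed = 3,
                            opts = fast_opts())
  N <- nrow(data)
  g0 <- absolute_goodness_of_fit(data, -N * log(2))
  expect_equal(g0$g, 0)
  g1 <- absolute_goodness_of_fit(data, -g0$entropy)
  expect_equal(g1$g, 1)
  # linear in LOO
  gm <- absolute_goodness_of_fit(data, (-N * log(2) - g0$entropy) / 2)
  expect_equal(gm$g, 0.5)
})

test_that("the bias-corrected entropy approaches the plug-in entropy for
           balanced counts", {
  for (n in c(50, 500)) {
    d <- data.frame(task = "unity", s_vis = 0, s_vest = 0,
                    c_vis = "high",
                    response = rep(c("unity", "separate"), each = n))
    h <- grassberger_entropy(d)$entropy
    expect_equal(h, 2 * n * log(2), tolerance = if (n == 50) 0.01 else 1e-3)
  }
  # bias correction shrinks with counts
  err <- vapply(c(10, 40, 160), function(n) {
    d <- data.frame(task = "unity", s_vis = 0, s_vest = 0,
                    c_vis = "high",
                    response = rep(c("unity", "separate"), each = n))
    abs(grassberger_entropy(d)$entropy - 2 * n * log(2)) / (2 * n)
  }, 0)
  expect_true(all(diff(err) < 0))
})
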