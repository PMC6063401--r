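# Shared fixtures: coarse quadrature settings and parameter vectors near
# the study's joint-fit posterior means, built in code.

test_opts <- function(n_x1 = 201, n_x2 = 101, n_s = 201)
  ci_opts(n_x1 = n_x1, n_x2 = n_x2, n_s = n_s)

# quick settings for expensive fitting/sampling checks
fast_opts <- function() ci_opts(n_x1 = 101, n_x2 = 61, n_s = 101)

theta_ref <- function(...) {
  th <- c(sigma0_vest = 6.49, sigma0_vis_high = 4.08,
          sigma0_vis_med = 6.32, sigma0_vis_low = 11.57,
          w_vest = 0.04, w_vis = 0.07, lambda = 0.02,
          p_c = 0.56, kappa_c = 26.5, sigma_prior = 49.8,
          delta_prior = 23.5)
  over <- c(...)
  th[names(over)] <- over
  th
}

theta_for <- function(model, tasks = model$tasks, ...) {
  ps <- build_parameter_space(model, tasks)
  th <- theta_ref(...)
  extra <- c(eta_low = 0.8, eta_med = 0.55, eta_high = 0.35)
  th <- c(th, extra)
  over <- c(...)
  th[names(over)] <- over
  th[ps$name]
}

# Conjugate Beta-Bernoulli toy: y binary vector, uniform prior on the
# success probability. Used as an analytic oracle for LOO and LML.
beta_bernoulli_toy <- function(n = 20, p_true = 0.7, S = 4000, seed = 1) {
  set.seed(seed)
  y <- as.integer(runif(n) < p_true)
  h <- sum(y); t <- n - h
  draws <- rbeta(S, h + 1, t + 1)
  log_lik <- sapply(y, function(yi)
    if (yi == 1) log(draws) else log(1 - draws))
  # exact leave-one-out predictive: posterior without trial i is
  # Beta(h - y_i + 1, t - (1 - y_i) + 1)
  loo_exact <- sum(vapply(seq_len(n), function(i) {
    a <- h - y[i] + 1; b <- t - (1 - y[i]) + 1
    if (y[i] == 1) log(a / (a + b)) else log(b / (a + b))
  }, 0))
  list(y = y, draws = draws, log_lik = log_lik, loo_exact = loo_exact,
       lml_exact = lbeta(h + 1, t + 1),
       log_prior = rep(0, S),
       log_lik_total = rowSums(log_lik))
}
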