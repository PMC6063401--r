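test_that("noise SD follows the eccentricity law and reduces to constant", {
  np <- noise_params(6.49, c(4.08, 6.32, 11.57), w_vest = 0.04,
                     w_vis = 0.07, shape = "X")
  expect_equal(noise_sd(0, "vest", np = np), 6.49)
  expect_equal(noise_sd(20, "vest",
                        np = noise_params(5, c(5, 5, 5), w_vest = 0.05,
                                          shape = "X")),
               5 * sqrt(2), tolerance = 1e-10)
  # even and non-decreasing in |s|
  s <- seq(-45, 45, by = 5)
  sd_x <- noise_sd(s, "vis", "low", np)
  expect_equal(sd_x, rev(sd_x))
  expect_true(all(diff(sd_x[s >= 0]) >= 0))
  # w = 0 reproduces the constant model bitwise
  np0 <- noise_params(6.49, c(4.08, 6.32, 11.57), w_vest = 0, w_vis = 0,
                      shape = "X")
  npc <- noise_params(6.49, c(4.08, 6.32, 11.57), shape = "C")
  expect_identical(noise_sd(s, "vest", np = np0),
                   noise_sd(s, "vest", np = npc))
  expect_error(noise_sd(0, "vis", np = np), "reliability")
})

test_that("measurement density normalizes, peaks at the stimulus, and the
           wrapped variant is indistinguishable at this range", {
  np <- noise_params(6, c(6, 6, 6), shape = "C")
  x <- seq(-180, 180, length.out = 20001)
  h <- diff(x[1:2])
  d <- measurement_density(x, 10, "vest", np = np)
  expect_true(all(d >= 0))
  expect_equal(sum(d) * h, 1, tolerance = 1e-6)
  expect_equal(x[which.max(d)], 10, tolerance = h)
  dw <- measurement_density(x, 0, "vest", np = np, wrap = TRUE)
  dp <- measurement_density(x, 0, "vest", np = np)
  expect_lt(max(abs(dw - dp)), 1e-10)
})

test_that("priors factorize, are sign-symmetric, and the empirical prior
           lives on the design support", {
  ppI <- prior_params(40, kind = "I")
  s1 <- c(5, -10, 22); s2 <- c(-3, 14, 22)
  expect_equal(prior_density(s1, s2, 2, ppI),
               dnorm(s1, 0, 40) * dnorm(s2, 0, 40))
  ppE <- prior_params(50, 24, kind = "E")
  # sign-flip symmetry for both kinds and both scenarios
  expect_equal(prior_density(s1, s2, 2, ppI),
               prior_density(-s1, -s2, 2, ppI))
  expect_equal(prior_density(c(10, -15), c(-10, 5), 2, ppE),
               prior_density(c(-10, 15), c(10, -5), 2, ppE))
  # empirical C = 2 mass normalizes over its support and excludes zero
  # disparity
  sup <- headingci:::.empirical_support(ppE, 2L)
  expect_equal(sum(sup$w), 1)
  expect_true(all(abs(sup$s_vest - sup$s_vis) >= 5))
  expect_equal(prior_density(10, 10, 2, ppE), 0)
  # a narrow disparity prior concentrates mass on the |disparity| = 5 pairs
  ppN <- prior_params(50, 1, kind = "E")
  supN <- headingci:::.empirical_support(ppN, 2L)
  m5 <- sum(supN$w[abs(supN$s_vest - supN$s_vis) == 5])
  expect_gt(m5, 0.999)
})

test_that("posterior of a common cause respects degenerate priors and
           monotonicity, and matches a brute-force quadrature oracle", {
  m <- model_spec(explicit = "Bay", noise = "C", prior = "I",
                  tasks = "unity")
  opts <- test_opts()
  th <- theta_for(m)
  xv <- c(0, 5, -12, 30); xw <- c(0, -5, -10, -28)
  expect_equal(posterior_common_cause(xv, xw, "med", m,
                                      theta_ref(p_c = 1)[names(th)], opts),
               rep(1, 4))
  expect_equal(posterior_common_cause(xv, xw, "med", m,
                                      theta_ref(p_c = 0)[names(th)], opts),
               rep(0, 4))
  pcs <- seq(0.1, 0.9, by = 0.2)
  vals <- sapply(pcs, function(pc)
    posterior_common_cause(5, -5, "high", m,
                           theta_ref(p_c = pc)[names(th)], opts))
  expect_true(all(diff(vals) > 0))
  expect_error(posterior_common_cause(5, -5, "high", m,
                                      theta_ref(p_c = 1.5)[names(th)],
                                      opts), "p_c")

  # brute-force oracle: scenario likelihoods by direct quadrature on a
  # 10x finer stimulus grid
  oracle_pc1 <- function(xv, xw, pc, sigma_v, sigma_w, sp) {
    s <- seq(-90, 90, length.out = 10 * opts$n_s)
    h <- diff(s[1:2])
    trap <- rep(h, length(s)); trap[c(1, length(s))] <- h / 2
    p0 <- dnorm(s, 0, sp)
    L1 <- sum(dnorm(xv, s, sigma_v) * dnorm(xw, s, sigma_w) * p0 * trap)
    L2 <- sum(dnorm(xv, s, sigma_v) * p0 * trap) *
      sum(dnorm(xw, s, sigma_w) * p0 * trap)
    L1 * pc / (L1 * pc + L2 * (1 - pc))
  }
  for (pair in list(c(3, -4), c(15, 20), c(-30, 10))) {
    got <- posterior_common_cause(pair[1], pair[2], "med", m, th, opts)
    want <- oracle_pc1(pair[1], pair[2], th[["p_c"]],
                       th[["sigma0_vis_med"]], th[["sigma0_vest"]],
                       th[["sigma_prior"]])
    expect_equal(got, want, tolerance = 1e-4)
  }
})

test_that("unity choice rules: fixed criterion, lapse envelope, and
           stochastic fusion", {
  opts <- test_opts()
  mF <- model_spec(explicit = "Fix", noise = "C", tasks = "unity")
  thF <- c(theta_ref(lambda = 0)[c("sigma0_vest", "sigma0_vis_high",
                                   "sigma0_vis_med", "sigma0_vis_low")],
           lambda = 0, kappa_c = 25)
  expect_equal(choice_prob_unity(5, 15, "med", mF, thF, opts), 1)
  expect_equal(choice_prob_unity(5, 40, "med", mF, thF, opts), 0)
  # full lapse gives chance for Bay and Fix
  thF1 <- thF; thF1[["lambda"]] <- 1
  expect_equal(choice_prob_unity(c(5, -60), c(15, 60), "med", mF, thF1,
                                 opts), c(0.5, 0.5))
  mB <- model_spec(explicit = "Bay", noise = "C", prior = "I",
                   tasks = "unity")
  thB <- theta_for(mB, lambda = 1)
  expect_equal(choice_prob_unity(c(0, 30), c(0, -30), "high", mB, thB,
                                 opts), c(0.5, 0.5))
  # stochastic fusion ignores the measurements entirely, and rejects a
  # lapse parameter
  mS <- model_spec(explicit = "SFu", tasks = "unity")
  thS <- c(eta_low = 0.8, eta_med = 0.55, eta_high = 0.35)
  expect_equal(choice_prob_unity(c(-50, 0, 50), c(50, 0, -50), "high",
                                 mS, thS, opts), rep(0.35, 3))
  expect_error(choice_prob_unity(0, 0, "high", mS, c(thS, lambda = 0.1),
                                 opts), "lapse")
})

test_that("implicit causal weights match their strategy definitions", {
  opts <- test_opts()
  xv <- seq(-60, 60, by = 15); xw <- rev(xv)
  mFF <- model_spec(implicit = "FFu", noise = "C", prior = "I",
                    tasks = "inertial")
  expect_equal(implicit_causal_weight(xv, xw, "med", mFF,
                                      theta_for(mFF), opts),
               rep(1, length(xv)))
  mFx <- model_spec(implicit = "Fix", noise = "C", prior = "I",
                    tasks = "inertial")
  thFx <- theta_for(mFx, kappa_c = 180)
  expect_equal(implicit_causal_weight(xv, xw, "med", mFx, thFx, opts),
               rep(1, length(xv)))
  thFx2 <- theta_for(mFx, kappa_c = 10)
  expect_equal(implicit_causal_weight(c(0, 0), c(5, 20), "med", mFx,
                                      thFx2, opts), c(1, 0))
  mB <- model_spec(implicit = "Bay", noise = "C", prior = "I",
                   tasks = "inertial")
  expect_equal(implicit_causal_weight(xv, xw, "med", mB,
                                      theta_for(mB, p_c = 1), opts),
               rep(1, length(xv)))
})

test_that("left/right rules: lapse bounds, the unisensory sign rule, and
           forced fusion equals Bayes with certain common cause", {
  opts <- test_opts()
  mU <- model_spec(tasks = "unisensory", noise = "C", prior = "I")
  thU <- theta_for(mU, lambda = 0)
  expect_equal(choice_prob_right(x_vest = 10, model = mU, theta = thU,
                                 task = "unisensory", opts = opts), 1)
  expect_equal(choice_prob_right(x_vest = -10, model = mU, theta = thU,
                                 task = "unisensory", opts = opts), 0)
  thU1 <- theta_for(mU, lambda = 1)
  expect_equal(choice_prob_right(x_vest = c(-20, 3, 50), model = mU,
                                 theta = thU1, task = "unisensory",
                                 opts = opts), rep(0.5, 3))
  # FFu identical to Bay with p_c = 1 for any measurement pair
  xv <- runif(40, -60, 60); xw <- runif(40, -60, 60)
  mFF <- model_spec(implicit = "FFu", noise = "C", prior = "I",
                    tasks = "inertial")
  mB <- model_spec(implicit = "Bay", noise = "C", prior = "I",
                   tasks = "inertial")
  pF <- choice_prob_right(xv, xw, "low", mFF, theta_for(mFF, lambda = 0.1),
                          task = "inertial", opts = opts)
  pB <- choice_prob_right(xv, xw, "low", mB,
                          theta_for(mB, lambda = 0.1, p_c = 1),
                          task = "inertial", opts = opts)
  expect_lt(max(abs(pF - pB)), 1e-10)
  # lapse envelope over a measurement grid
  thB <- theta_for(mB, lambda = 0.1)
  p <- choice_prob_right(xv, xw, "med", mB, thB, task = "inertial",
                         opts = opts)
  expect_true(all(p >= 0.05 - 1e-12 & p <= 0.95 + 1e-12))
})

test_that("sign-flip antisymmetry and symmetry hold under symmetric
           priors", {
  opts <- test_opts()
  set.seed(7)
  xv <- runif(30, -60, 60); xw <- runif(30, -60, 60)
  for (pr in c("I", "E")) {
    mB <- model_spec(explicit = "Bay", implicit = "Bay", noise = "X",
                     prior = pr)
    th <- theta_for(mB)
    pr_r <- choice_prob_right(xv, xw, "med", mB, th, task = "inertial",
                              opts = opts)
    pr_l <- choice_prob_right(-xv, -xw, "med", mB, th, task = "inertial",
                              opts = opts)
    expect_lt(max(abs(pr_r + pr_l - 1)), 1e-10)
    pu1 <- choice_prob_unity(xv, xw, "med", mB, th, opts)
    pu2 <- choice_prob_unity(-xv, -xw, "med", mB, th, opts)
    expect_lt(max(abs(pu1 - pu2)), 1e-10)
  }
})

test_that("eccentric noise with w = 0 reproduces the constant-noise
           observer", {
  opts <- test_opts()
  mX <- model_spec(explicit = "Bay", implicit = "Bay", noise = "X",
                   prior = "I")
  mC <- model_spec(explicit = "Bay", implicit = "Bay", noise = "C",
                   prior = "I")
  thX <- theta_for(mX, w_vest = 0, w_vis = 0)
  thC <- theta_for(mC)
  xv <- seq(-50, 50, by = 10); xw <- rev(xv)
  expect_lt(max(abs(
    choice_prob_unity(xv, xw, "low", mX, thX, opts) -
      choice_prob_unity(xv, xw, "low", mC, thC, opts))), 1e-12)
  expect_lt(abs(
    response_prob_bisensory(10, 20, "med", "inertial", mX, thX, opts) -
      response_prob_bisensory(10, 20, "med", "inertial", mC, thC, opts)),
    1e-12)
})

test_that("the factorial model spaces enumerate the documented cells", {
  expect_length(explicit_model_space(), 7)
  expect_setequal(names(explicit_model_space()),
                  c("Bay-C-E", "Bay-C-I", "Bay-X-E", "Bay-X-I",
                    "Fix-C", "Fix-X", "SFu"))
  expect_length(implicit_model_space(), 12)
  js <- joint_model_space()
  expect_length(js, 16)
  strategies <- unique(vapply(js, headingci:::.strategy_label, ""))
  expect_setequal(strategies,
                  c("Bay/Bay", "Fix/Fix", "Bay/FFu", "Fix/FFu"))
  part <- model_factor_partition(explicit_model_space(), "strategy")
  expect_equal(lengths(part)[c("Bay", "Fix", "SFu")],
               c(Bay = 4L, Fix = 2L, SFu = 1L))
})
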