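test_that("the stimulus design enumerates 297 conditions and hits its
           marginal frequencies", {
  conds <- enumerate_conditions()
  expect_equal(nrow(conds), 297)
  expect_equal(nrow(unique(conds[, c("s_vis", "s_vest", "c_vis")])), 297)
  # headings reconstruct mean and disparity exactly
  expect_equal((conds$s_vis + conds$s_vest) / 2, conds$mean)
  expect_equal(conds$s_vest - conds$s_vis, conds$disparity)

  spec <- design_spec(0, 0, 12000)
  d <- generate_design(spec, seed = 2)
  expect_identical(d, generate_design(spec, seed = 2))
  disp <- d$s_vest - d$s_vis
  # zero disparity in 1/5 of trials (binomial tolerance)
  p0 <- mean(disp == 0)
  expect_lt(abs(p0 - 0.2), 3 * sqrt(0.2 * 0.8 / nrow(d)))
  # uniform marginals: mean headings, |disparity|, reliabilities
  expect_gt(chisq.test(table((d$s_vis + d$s_vest) / 2))$p.value, 1e-4)
  expect_gt(chisq.test(table(abs(disp)))$p.value, 1e-4)
  expect_gt(chisq.test(table(d$c_vis))$p.value, 1e-4)
  # nonzero disparities split evenly by sign
  expect_gt(chisq.test(table(sign(disp[disp != 0])))$p.value, 1e-4)
})

test_that("simulated observers match their own response probabilities", {
  opts <- fast_opts()
  m <- model_spec(explicit = "Fix", noise = "C", tasks = "unity")
  th <- c(sigma0_vest = 6.5, sigma0_vis_high = 4, sigma0_vis_med = 6.3,
          sigma0_vis_low = 11.6, lambda = 0.04, kappa_c = 22)
  cond <- data.frame(task = "unity", s_vis = 5, s_vest = 15,
                     c_vis = "med", response = NA_character_)
  design <- cond[rep(1, 600), ]
  data <- simulate_observer(design, m, th, seed = 4, opts = opts)
  expect_identical(data$response,
                   simulate_observer(design, m, th, seed = 4,
                                     opts = opts)$response)
  p_hat <- mean(data$response == "unity")
  p <- response_prob_bisensory(5, 15, "med", "unity", m, th, opts)
  expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / 600))
  # full lapse: chance responding everywhere
  th1 <- th; th1[["lambda"]] <- 1
  d1 <- simulate_observer(design, m, th1, seed = 9, opts = opts)
  expect_lt(abs(mean(d1$response == "unity") - 0.5),
            3 * sqrt(0.25 / 600))
})

test_that("unity summaries are flat for stochastic fusion and
           sign-symmetric for symmetric observers", {
  opts <- fast_opts()
  mS <- model_spec(explicit = "SFu", tasks = "unity")
  eta <- c(eta_low = 0.75, eta_med = 0.5, eta_high = 0.3)
  des <- generate_design(design_spec(0, 4000, 0), seed = 6)
  dS <- simulate_observer(des, mS, eta, seed = 6, opts = opts)
  su <- summarize_unity(dS)
  for (cv in c("low", "med", "high")) {
    rows <- su[su$c_vis == cv, ]
    e <- eta[[paste0("eta_", cv)]]
    expect_true(all(abs(rows$prop_unity - e) <
                      4 * sqrt(e * (1 - e) / rows$n)))
  }
  # all-unity responses give proportions of exactly one
  dA <- dS; dA$response <- "unity"
  expect_true(all(summarize_unity(dA)$prop_unity == 1))
  # sign symmetry within binomial error for a symmetric observer
  mB <- model_spec(explicit = "Bay", noise = "C", prior = "I",
                   tasks = "unity")
  dB <- simulate_observer(des, mB, theta_for(mB), seed = 7, opts = opts)
  sb <- summarize_unity(dB)
  for (cv in unique(sb$c_vis)) {
    s1 <- sb[sb$c_vis == cv & sb$disparity > 0, ]
    s2 <- sb[sb$c_vis == cv & sb$disparity < 0, ]
    s2 <- s2[match(-s1$disparity, s2$disparity), ]
    se <- sqrt(s1$prop_unity * (1 - s1$prop_unity) / s1$n +
                 s2$prop_unity * (1 - s2$prop_unity) / s2$n)
    expect_true(all(abs(s1$prop_unity - s2$prop_unity) < 4 * se + 0.05))
  }
})

test_that("vestibular bias vanishes for a segregating observer, tracks
           the visual heading under forced fusion, and shifts with the
           PSE by construction", {
  opts <- fast_opts()
  des <- generate_design(design_spec(0, 0, 9000), seed = 11)
  # near-degenerate fixed criterion: vision is almost always discarded,
  # so per-bin biases are pure PSE sampling noise around zero
  mFx <- model_spec(implicit = "Fix", noise = "C", prior = "I",
                    tasks = "inertial")
  thFx <- theta_for(mFx, kappa_c = 0.25, lambda = 0)
  dFx <- simulate_observer(des, mFx, thFx, seed = 11, opts = opts)
  bFx <- summarize_bias(dFx)
  expect_true(all(abs(bFx$bias) < 3.5, na.rm = TRUE))
  expect_lt(abs(mean(bFx$bias, na.rm = TRUE)), 1)
  pos_b <- bFx$bias[bFx$bin_lo >= 2.5 & !is.na(bFx$bias)]
  neg_b <- bFx$bias[bFx$bin_hi <= -2.5 & !is.na(bFx$bias)]
  expect_lt(abs(mean(pos_b) - mean(neg_b)), 2)
  # forced fusion with precise vision: bias follows s_vis
  mFF <- model_spec(implicit = "FFu", noise = "C", prior = "I",
                    tasks = "inertial")
  thFF <- theta_for(mFF, sigma0_vis_high = 0.5, sigma0_vis_med = 0.5,
                    sigma0_vis_low = 0.5, sigma0_vest = 8, lambda = 0)
  dFF <- simulate_observer(des, mFF, thFF, seed = 12, opts = opts)
  bFF <- summarize_bias(dFF)
  pos <- bFF$bias[bFF$bin_lo >= 2.5 & !is.na(bFF$bias)]
  neg <- bFF$bias[bFF$bin_hi <= -2.5 & !is.na(bFF$bias)]
  expect_true(mean(pos > 1) > 0.8)
  expect_true(mean(neg < -1) > 0.8)
  # shifting the vestibular axis shifts the PSE, so the bias moves
  # opposite by the same amount
  shifted <- dFx
  shifted$s_vest <- shifted$s_vest + 5
  b0 <- summarize_bias(dFx)
  b5 <- summarize_bias(shifted)
  ok <- !is.na(b0$bias) & !is.na(b5$bias)
  expect_equal(b5$bias[ok], b0$bias[ok] - 5, tolerance = 0.15)
})

test_that("model recovery tallies winners with rows summing to the
           dataset count", {
  opts <- fast_opts()
  models <- list(
    `Fix-C` = model_spec(explicit = "Fix", noise = "C", tasks = "unity"),
    SFu = model_spec(explicit = "SFu", tasks = "unity"))
  thetas <- list(
    `Fix-C` = c(sigma0_vest = 6.5, sigma0_vis_high = 4,
                sigma0_vis_med = 6.3, sigma0_vis_low = 11.6,
                lambda = 0.03, kappa_c = 22),
    SFu = c(eta_low = 0.75, eta_med = 0.5, eta_high = 0.3))
  rep <- suppressWarnings(model_recovery(
    models, thetas, n_datasets = 2, spec = design_spec(0, 400, 0),
    n_starts = 2, maxit = 400, seed = 3, opts = opts))
  expect_equal(unname(rowSums(rep$selection)), c(2L, 2L))
  expect_equal(rep$fit_errors, 0L)
  # the fixed-criterion data are strongly disparity-dependent, so the
  # generating model wins; fusion data are flat, so fusion wins
  expect_equal(unname(rep$selection["Fix-C", "Fix-C"]), 2L)
  expect_equal(unname(rep$selection["SFu", "SFu"]), 2L)
})
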