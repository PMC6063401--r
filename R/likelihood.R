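#' Numerical-integration options
#'
#' Controls the quadrature used to marginalize trial response
#' probabilities over unseen noisy measurements, and the stimulus grids
#' used for the observer's internal posteriors. All grids are equispaced
#' with trapezoidal weights on a fixed domain; noise densities are
#' renormalized on the grid, which truncates negligible tail mass outside
#' the integration domain.
#'
#' @param n_x1 Measurement-grid nodes for one-dimensional (unisensory)
#'   marginalization.
#' @param n_x2 Measurement-grid nodes per dimension for bisensory
#'   marginalization (decision surfaces are \code{n_x2 x n_x2}).
#' @param n_s Stimulus-grid nodes for internal posteriors over headings.
#' @param domain Integration domain in degrees.
#' @param wrap Use wrapped-normal measurement noise (period 360).
#' @param p_floor Per-trial probability floor applied before taking logs.
#' @return List of class \code{"ci_opts"}.
#' @export
ci_opts <- function(n_x1 = 401, n_x2 = 201, n_s = 401,
                    domain = c(-90, 90), wrap = FALSE, p_floor = 1e-10) {
  stopifnot(n_x1 >= 21, n_x2 >= 21, n_s >= 21, domain[2] > domain[1])
  structure(list(n_x1 = n_x1, n_x2 = n_x2, n_s = n_s, domain = domain,
                 wrap = wrap, p_floor = p_floor), class = "ci_opts")
}

#' Trapezoidal integration grid
#'
#' @param n Number of nodes.
#' @param domain Interval endpoints (degrees).
#' @return List with equispaced \code{nodes} and trapezoidal
#'   \code{weights} (positive, summing to the domain length).
#' @export
integration_grid <- function(n = 401, domain = c(-90, 90)) {
  nodes <- seq(domain[1], domain[2], length.out = n)
  h <- diff(domain) / (n - 1)
  nodes[abs(nodes) < 1e-9] <- 0   # keep straight-ahead exactly on-grid
  weights <- rep(h, n)
  weights[c(1, n)] <- h / 2
  list(nodes = nodes, weights = weights)
}

# Decision step with ties at 0.5 resolved as probability 0.5 each way
# (tolerance absorbs rounding in symmetric configurations).
.step <- function(p) (p > 0.5 + 1e-9) + 0.5 * (abs(p - 0.5) <= 1e-9)

# "Mass to the right of 0" mask with half weight at exactly 0.
.mask_pos <- function(s) (s > 0) + 0.5 * (s == 0)

.theta_get <- function(theta, name, default = NA_real_) {
  if (name %in% names(theta)) unname(theta[[name]]) else default
}

# Posteriors where both scenario likelihoods underflow carry essentially
# no measurement-density mass; indifference (0.5) is the safe value.
.guard_prob <- function(p) {
  p[!is.finite(p)] <- 0.5
  p
}

# ---------------------------------------------------------------------------
# Internal field engine.
#
# Computes, for measurement pairs (x_vis, x_vest), the observer-internal
# quantities the decision rules need:
#   pc1 : Pr(C = 1 | x_vis, x_vest)          (Bayesian strategies)
#   pr1 : Pr(s_vest > 0 | x, C = 1)
#   pr2 : Pr(s_vest > 0 | x, C = 2)
# mode "outer" treats xv, xw as grid axes and returns matrices indexed
# [xv, xw]; mode "paired" treats them as paired vectors.
# ---------------------------------------------------------------------------
.fields_bisensory <- function(xv, xw, model, theta, c_vis, opts,
                              mode = c("outer", "paired"),
                              needs = c("pc1", "pr")) {
  mode <- match.arg(mode)
  need_pc1 <- "pc1" %in% needs
  need_pr <- "pr" %in% needs
  nv <- .noise_of(theta, "vis", c_vis, model$noise)
  nw <- .noise_of(theta, "vest", NULL, model$noise)
  sp <- .theta_get(theta, "sigma_prior")
  out <- list()

  comb <- function(A, B) if (mode == "outer") crossprod(A, B) else colSums(A * B)
  bcast <- function(v_xw) {
    # lift a function of x_vest alone to the pair layout
    if (mode == "outer") matrix(v_xw, nrow = length(xv), ncol = length(xw),
                                byrow = TRUE) else v_xw
  }

  if (model$prior == "I") {
    g <- integration_grid(opts$n_s, opts$domain)
    p0w <- stats::dnorm(g$nodes, 0, sp) * g$weights
    mp <- .mask_pos(g$nodes)
    Lv <- .lik_matrix(xv, g$nodes, nv$sigma0, nv$w, opts$wrap)
    Lw <- .lik_matrix(xw, g$nodes, nw$sigma0, nw$w, opts$wrap)
    A <- Lv * p0w
    pxC1 <- comb(A, Lw)
    if (need_pr) {
      out$pr1 <- .guard_prob(comb(A * mp, Lw) / pxC1)
      mw <- colSums(Lw * p0w)
      out$pr2 <- bcast(.guard_prob(colSums(Lw * (p0w * mp)) / mw))
    }
    if (need_pc1) {
      mv <- colSums(A)
      if (!exists("mw", inherits = FALSE)) mw <- colSums(Lw * p0w)
      pxC2 <- if (mode == "outer") outer(mv, mw) else mv * mw
    }
  } else {
    dp <- .theta_get(theta, "delta_prior")
    pp <- prior_params(sp, dp, kind = "E")
    s1 <- .empirical_support(pp, 1L)
    s2 <- .empirical_support(pp, 2L)
    Dv1 <- .lik_matrix(xv, s1$s, nv$sigma0, nv$w, opts$wrap)
    Dw1 <- .lik_matrix(xw, s1$s, nw$sigma0, nw$w, opts$wrap)
    A1 <- Dv1 * s1$w
    pxC1 <- comb(A1, Dw1)
    Dv2 <- .lik_matrix(xv, s2$s_vis, nv$sigma0, nv$w, opts$wrap)
    Dw2 <- .lik_matrix(xw, s2$s_vest, nw$sigma0, nw$w, opts$wrap)
    A2 <- Dv2 * s2$w
    if (need_pr) {
      out$pr1 <- .guard_prob(comb(A1 * .mask_pos(s1$s), Dw1) / pxC1)
      pxC2 <- comb(A2, Dw2)
      out$pr2 <- .guard_prob(comb(A2 * .mask_pos(s2$s_vest), Dw2) / pxC2)
    }
    if (need_pc1 && !exists("pxC2", inherits = FALSE)) pxC2 <- comb(A2, Dw2)
  }

  if (need_pc1) {
    pc <- .theta_get(theta, "p_c")
    if (is.na(pc) || pc < 0 || pc > 1)
      stop("p_c must lie in [0, 1]")
    num <- pxC1 * pc
    den <- num + pxC2 * (1 - pc)
    pc1 <- num / den
    pc1[den == 0] <- pc   # both scenario likelihoods underflow
    out$pc1 <- pc1
  }
  out
}

# Pr(s > 0 | x) for a unisensory measurement vector x.
.unisensory_prpos <- function(x, modality, c_vis, model, theta, opts) {
  np <- .noise_of(theta, modality, c_vis, model$noise)
  sp <- .theta_get(theta, "sigma_prior")
  if (model$prior == "E" && !is.na(sp)) {
    m <- .design_means()
    w <- stats::dnorm(m, 0, sp)
    L <- .lik_matrix(x, m, np$sigma0, np$w, opts$wrap)
    .guard_prob(colSums(L * (w * .mask_pos(m))) / colSums(L * w))
  } else {
    g <- integration_grid(opts$n_s, opts$domain)
    w <- if (is.na(sp)) g$weights else stats::dnorm(g$nodes, 0, sp) * g$weights
    L <- .lik_matrix(x, g$nodes, np$sigma0, np$w, opts$wrap)
    .guard_prob(colSums(L * (w * .mask_pos(g$nodes))) / colSums(L * w))
  }
}

# ---------------------------------------------------------------------------
# Decision rules given measurements (choice probabilities conditional on x).
# ---------------------------------------------------------------------------

# Explicit (unity) rule, including lapse/eta; mode as in .fields_bisensory.
.unity_choice <- function(xv, xw, c_vis, model, theta, opts,
                          mode = "paired") {
  st <- model$explicit
  if (st == "SFu") {
    if ("lambda" %in% names(theta) && !is.na(theta[["lambda"]]))
      stop("the stochastic fusion observer has no lapse parameter")
    eta <- .theta_get(theta, paste0("eta_", c_vis))
    d <- eta
    if (mode == "outer")
      return(matrix(d, length(xv), length(xw)))
    return(rep(d, length(xv)))
  }
  lambda <- .theta_get(theta, "lambda", 0)
  D <- switch(st,
    Bay = .step(.fields_bisensory(xv, xw, model, theta, c_vis, opts,
                                  mode, needs = "pc1")$pc1),
    BayPM = .fields_bisensory(xv, xw, model, theta, c_vis, opts,
                              mode, needs = "pc1")$pc1,
    Fix = {
      kc <- .theta_get(theta, "kappa_c")
      if (mode == "outer") outer(xv, xw, function(a, b) (abs(a - b) < kc) * 1)
      else (abs(xv - xw) < kc) * 1
    })
  lambda / 2 + (1 - lambda) * D
}

# Implicit (inertial left/right) rule, including lapse.
.inertial_choice <- function(xv, xw, c_vis, model, theta, opts,
                             mode = "paired") {
  st <- model$implicit
  lambda <- .theta_get(theta, "lambda", 0)
  needs <- if (st %in% c("Bay", "BayPM")) c("pc1", "pr") else "pr"
  f <- .fields_bisensory(xv, xw, model, theta, c_vis, opts, mode, needs)
  D <- switch(st,
    Bay = .step(f$pc1 * f$pr1 + (1 - f$pc1) * f$pr2),
    BayPM = f$pc1 * .step(f$pr1) + (1 - f$pc1) * .step(f$pr2),
    Fix = {
      kc <- .theta_get(theta, "kappa_c")
      ind <- if (mode == "outer")
        outer(xv, xw, function(a, b) (abs(a - b) < kc) * 1)
      else (abs(xv - xw) < kc) * 1
      ind * .step(f$pr1) + (1 - ind) * .step(f$pr2)
    },
    FFu = .step(f$pr1))
  lambda / 2 + (1 - lambda) * D
}

#' Posterior probability of a common cause
#'
#' \eqn{\Pr(C = 1 \mid x_{vis}, x_{vest})} for given noisy measurements,
#' combining the scenario likelihoods with the prior probability of a
#' common cause \code{p_c} (a free model parameter in \code{theta}).
#'
#' @param x_vis,x_vest Paired measurement vectors (degrees).
#' @param c_vis Visual reliability level.
#' @param model \code{\link{model_spec}} (noise shape and prior type are
#'   used; the strategy is irrelevant here).
#' @param theta Named parameter vector (see
#'   \code{\link{build_parameter_space}}).
#' @param opts \code{\link{ci_opts}}.
#' @return Probabilities in [0, 1].
#' @export
posterior_common_cause <- function(x_vis, x_vest, c_vis, model, theta,
                                   opts = ci_opts()) {
  .fields_bisensory(x_vis, x_vest, model, theta, c_vis, opts,
                    mode = "paired", needs = "pc1")$pc1
}

#' Probability of reporting 'unity' given measurements
#'
#' Choice probability of the explicit causal-inference (unity-judgment)
#' rule conditional on the internal measurements, including lapses. The
#' Bayesian observer reports unity when the posterior probability of a
#' common cause exceeds 0.5; the probability-matching variant reports
#' unity with that posterior probability; the fixed-criterion observer
#' reports unity when \eqn{|x_{vis} - x_{vest}| < \kappa_c}; stochastic
#' fusion reports unity with probability \eqn{\eta(c_{vis})} regardless of
#' the measurements (and carries no lapse parameter).
#'
#' @inheritParams posterior_common_cause
#' @return Probabilities in [0, 1].
#' @export
choice_prob_unity <- function(x_vis, x_vest, c_vis, model, theta,
                              opts = ci_opts()) {
  if (is.na(model$explicit)) stop("model has no explicit strategy")
  .unity_choice(x_vis, x_vest, c_vis, model, theta, opts, mode = "paired")
}

#' Implicit causal weight
#'
#' Weight \eqn{v_1 \in [0,1]} given to the common-cause posterior over the
#' vestibular heading when combining the two causal scenarios. Bayesian:
#' \eqn{v_1 = \Pr(C=1|x)}; probability matching: a Bernoulli draw with
#' that expectation (the expectation is returned; response probabilities
#' marginalize the draw analytically); fixed criterion: the indicator
#' \eqn{[|x_{vis}-x_{vest}| < \kappa_c]}; forced fusion: 1.
#'
#' @inheritParams posterior_common_cause
#' @return Weights in [0, 1].
#' @export
implicit_causal_weight <- function(x_vis, x_vest, c_vis, model, theta,
                                   opts = ci_opts()) {
  st <- model$implicit
  if (is.na(st)) stop("model has no implicit strategy")
  switch(st,
    FFu = rep(1, length(x_vis)),
    Fix = {
      kc <- .theta_get(theta, "kappa_c")
      (abs(x_vis - x_vest) < kc) * 1
    },
    posterior_common_cause(x_vis, x_vest, c_vis, model, theta, opts))
}

#' Probability of responding 'right' given measurements
#'
#' Choice probability of the left/right rule conditional on internal
#' measurements, including lapses. For unisensory trials supply exactly
#' one of \code{x_vis}/\code{x_vest}; for bisensory inertial trials supply
#' both.
#'
#' @inheritParams posterior_common_cause
#' @param x_vis,x_vest Measurement vectors; one may be \code{NULL} for the
#'   unisensory task.
#' @param task \code{"unisensory"} or \code{"inertial"}.
#' @return Probabilities in \eqn{[\lambda/2, 1 - \lambda/2]}.
#' @export
choice_prob_right <- function(x_vis = NULL, x_vest = NULL, c_vis = NULL,
                              model, theta, task = c("unisensory", "inertial"),
                              opts = ci_opts()) {
  task <- match.arg(task)
  lambda <- .theta_get(theta, "lambda", 0)
  if (task == "unisensory") {
    if (!xor(is.null(x_vis), is.null(x_vest)))
      stop("unisensory task takes exactly one measurement vector")
    if (is.null(x_vis))
      p <- .unisensory_prpos(x_vest, "vest", NULL, model, theta, opts)
    else
      p <- .unisensory_prpos(x_vis, "vis", c_vis, model, theta, opts)
    return(lambda / 2 + (1 - lambda) * .step(p))
  }
  if (is.null(x_vis) || is.null(x_vest))
    stop("inertial task requires both measurement vectors")
  .inertial_choice(x_vis, x_vest, c_vis, model, theta, opts, mode = "paired")
}

# ---------------------------------------------------------------------------
# Marginalized (trial) response probabilities.
# ---------------------------------------------------------------------------

# Renormalized measurement-density quadrature weights for stimulus s.
.meas_weights <- function(xg, s, sigma0, w, wrap) {
  d <- .lik_matrix(xg$nodes, s, sigma0, w, wrap)[1, ] * xg$weights
  tot <- sum(d)
  if (!is.finite(tot) || tot <= 0)
    stop("measurement density does not normalize on the grid ",
         "(s = ", s, ", sigma0 = ", sigma0, ")")
  d / tot
}

# Column-wise weights for a vector of stimuli (nodes x conditions).
.meas_weights_batch <- function(xg, s, sigma0, w, wrap) {
  sd <- sigma0 * sqrt(1 + w^2 * s^2)
  W <- if (!wrap) {
    t(stats::dnorm(outer(s, xg$nodes, "-") / sd) / sd)
  } else {
    acc <- 0
    for (k in -3:3)
      acc <- acc + stats::dnorm((outer(s, xg$nodes, "-") + 360 * k) / sd) / sd
    t(acc)
  }
  W <- W * xg$weights
  tot <- colSums(W)
  if (any(!is.finite(tot)) || any(tot <= 0))
    stop("measurement density does not normalize on the grid")
  sweep(W, 2, tot, "/")
}

#' Unisensory trial response probability
#'
#' Probability of a 'right' response for a unisensory trial, obtained by
#' marginalizing the choice rule over the unseen noisy measurement.
#'
#' @param s Presented heading (deg).
#' @param modality \code{"vis"} or \code{"vest"}.
#' @param c_vis Reliability level (visual trials).
#' @param model,theta,opts As elsewhere.
#' @return Scalar probability of responding 'right'.
#' @export
response_prob_unisensory <- function(s, modality = c("vest", "vis"),
                                     c_vis = NULL, model, theta,
                                     opts = ci_opts()) {
  modality <- match.arg(modality)
  lambda <- .theta_get(theta, "lambda", 0)
  xg <- integration_grid(opts$n_x1, opts$domain)
  d <- .step(.unisensory_prpos(xg$nodes, modality, c_vis, model, theta, opts))
  np <- .noise_of(theta, modality, c_vis, model$noise)
  wts <- .meas_weights(xg, s, np$sigma0, np$w, opts$wrap)
  lambda / 2 + (1 - lambda) * sum(d * wts)
}

#' Bisensory trial response probability
#'
#' Probability of the designated response for a bisensory trial (the
#' 'unity' response for the unity-judgment task, the 'right' response for
#' the inertial-discrimination task), marginalized over both unseen noisy
#' measurements. The visual measurement is handled by quadrature; along
#' the vestibular measurement axis the decision region of the (binary)
#' rule is extracted as intervals — crossings of the smooth decision
#' field located by linear interpolation on the grid — and integrated in
#' closed form against the truncated-normal measurement density, which
#' keeps the marginalization second-order accurate despite the
#' discontinuous decision rules.
#'
#' @param s_vis,s_vest Presented headings (deg).
#' @param c_vis Reliability level.
#' @param task \code{"unity"} or \code{"inertial"}.
#' @param model,theta,opts As elsewhere.
#' @return Scalar probability.
#' @export
response_prob_bisensory <- function(s_vis, s_vest, c_vis,
                                    task = c("unity", "inertial"),
                                    model, theta, opts = ci_opts()) {
  task <- match.arg(task)
  rule <- .response_rule(task, c_vis, model, theta, opts)
  .rule_prob(rule, s_vis, s_vest, c_vis, model, theta, opts)
}

# --- interval helpers -------------------------------------------------------

# Decision-region intervals {F > 0.5} along one grid row, crossings by
# linear interpolation. Returns a 2-column matrix of (a, b) pairs.
.iv_from_row <- function(F_row, nodes) {
  v <- F_row - 0.5
  pos <- v > 0
  n <- length(v)
  if (!any(pos)) return(matrix(numeric(0), 0, 2))
  idx <- which(pos[-n] != pos[-1])
  cross <- nodes[idx] + (nodes[idx + 1] - nodes[idx]) *
    v[idx] / (v[idx] - v[idx + 1])
  pts <- c(if (pos[1]) nodes[1], cross, if (pos[n]) nodes[n])
  matrix(pts, ncol = 2, byrow = TRUE)
}

# Clip an interval set to [lo, hi].
.iv_clip <- function(iv, lo, hi) {
  if (!nrow(iv) || lo >= hi) return(matrix(numeric(0), 0, 2))
  a <- pmax(iv[, 1], lo); b <- pmin(iv[, 2], hi)
  keep <- b > a
  cbind(a[keep], b[keep])
}

# --- response rules ---------------------------------------------------------

# Precomputed decision rule for one (task, c_vis) class at parameters
# theta: for each visual-measurement node, the decision region along the
# vestibular axis (list of intervals), or a constant/smooth fallback.
# Built once per class and reused across all trials sharing it.
.response_rule <- function(task, c_vis, model, theta, opts) {
  xg <- integration_grid(opts$n_x2, opts$domain)
  x <- xg$nodes
  nx <- length(x)
  lo <- opts$domain[1]; hi <- opts$domain[2]
  strategy <- if (task == "unity") model$explicit else model$implicit

  if (task == "unity" && strategy == "SFu") {
    if ("lambda" %in% names(theta) && !is.na(theta[["lambda"]]))
      stop("the stochastic fusion observer has no lapse parameter")
    return(list(type = "const", value = .theta_get(theta,
                                                   paste0("eta_", c_vis)),
                xg = xg))
  }
  if (task == "unity" && strategy == "Fix") {
    kc <- .theta_get(theta, "kappa_c")
    iv <- lapply(seq_len(nx), function(i)
      .iv_clip(matrix(c(x[i] - kc, x[i] + kc), 1, 2), lo, hi))
    return(.flatten_rule(iv, xg))
  }
  if (strategy == "BayPM") {
    if (task == "unity") {
      D <- .fields_bisensory(x, x, model, theta, c_vis, opts, "outer",
                             needs = "pc1")$pc1
      return(list(type = "smooth", D = D, xg = xg))
    }
    f <- .fields_bisensory(x, x, model, theta, c_vis, opts, "outer",
                           needs = c("pc1", "pr"))
    iv1 <- lapply(seq_len(nx), function(i) .iv_from_row(f$pr1[i, ], x))
    iv2 <- lapply(seq_len(nx), function(i) .iv_from_row(f$pr2[i, ], x))
    return(list(type = "region_g", iv1 = iv1, iv2 = iv2, G = f$pc1,
                xg = xg))
  }

  if (task == "unity") {            # Bay
    F <- .fields_bisensory(x, x, model, theta, c_vis, opts, "outer",
                           needs = "pc1")$pc1
    iv <- lapply(seq_len(nx), function(i) .iv_from_row(F[i, ], x))
    return(.flatten_rule(iv, xg))
  }
  # inertial task
  if (strategy == "Bay") {
    f <- .fields_bisensory(x, x, model, theta, c_vis, opts, "outer",
                           needs = c("pc1", "pr"))
    F <- f$pc1 * f$pr1 + (1 - f$pc1) * f$pr2
    iv <- lapply(seq_len(nx), function(i) .iv_from_row(F[i, ], x))
    return(.flatten_rule(iv, xg))
  }
  if (strategy == "FFu") {
    F <- .fields_bisensory(x, x, model, theta, c_vis, opts, "outer",
                           needs = "pr")$pr1
    iv <- lapply(seq_len(nx), function(i) .iv_from_row(F[i, ], x))
    return(.flatten_rule(iv, xg))
  }
  # Fix: inside the criterion band use the C=1 posterior, outside C=2
  kc <- .theta_get(theta, "kappa_c")
  f <- .fields_bisensory(x, x, model, theta, c_vis, opts, "outer",
                         needs = "pr")
  iv <- lapply(seq_len(nx), function(i) {
    r1 <- .iv_clip(.iv_from_row(f$pr1[i, ], x), x[i] - kc, x[i] + kc)
    r2 <- .iv_from_row(f$pr2[i, ], x)
    rbind(r1, .iv_clip(r2, lo, x[i] - kc), .iv_clip(r2, x[i] + kc, hi))
  })
  .flatten_rule(iv, xg)
}

# Flatten per-row interval lists for vectorized CDF evaluation.
.flatten_rule <- function(iv, xg) {
  counts <- vapply(iv, nrow, 0L)
  all_iv <- do.call(rbind, iv)
  list(type = "region", a = all_iv[, 1], b = all_iv[, 2],
       row = rep(seq_along(iv), counts), xg = xg)
}

# Truncated-normal CDF on the integration domain.
.ptrunc <- function(q, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  (stats::pnorm(q, mean, sd) - plo) /
    (stats::pnorm(hi, mean, sd) - plo)
}

# Trial response probability from a precomputed rule.
.rule_prob <- function(rule, s_vis, s_vest, c_vis, model, theta, opts) {
  if (rule$type == "const") return(rule$value)
  lambda <- .theta_get(theta, "lambda", 0)
  nv <- .noise_of(theta, "vis", c_vis, model$noise)
  nw <- .noise_of(theta, "vest", NULL, model$noise)
  wv <- .meas_weights(rule$xg, s_vis, nv$sigma0, nv$w, opts$wrap)
  lo <- opts$domain[1]; hi <- opts$domain[2]
  sdw <- nw$sigma0 * sqrt(1 + nw$w^2 * s_vest^2)
  nx <- length(rule$xg$nodes)

  if (rule$type == "smooth") {
    ww <- .meas_weights(rule$xg, s_vest, nw$sigma0, nw$w, opts$wrap)
    p_pre <- drop(rule$D %*% ww)
  } else if (rule$type == "region") {
    contrib <- .ptrunc(rule$b, s_vest, sdw, lo, hi) -
      .ptrunc(rule$a, s_vest, sdw, lo, hi)
    p_pre <- numeric(nx)
    if (length(contrib)) {
      sums <- rowsum(contrib, rule$row)
      p_pre[as.integer(rownames(sums))] <- sums[, 1]
    }
  } else {  # region_g: indicator regions weighted by a smooth field
    x <- rule$xg$nodes
    Zw <- stats::pnorm(hi, s_vest, sdw) - stats::pnorm(lo, s_vest, sdw)
    dens <- function(q) stats::dnorm(q, s_vest, sdw) / Zw
    seg_int <- function(iv, Grow, flip = FALSE) {
      if (!nrow(iv)) return(0)
      tot <- 0
      for (k in seq_len(nrow(iv))) {
        qs <- x[x > iv[k, 1] & x < iv[k, 2]]
        qs <- c(iv[k, 1], qs, iv[k, 2])
        g <- stats::approx(x, Grow, xout = qs, rule = 2)$y
        if (flip) g <- 1 - g
        f <- g * dens(qs)
        tot <- tot + sum(diff(qs) * (f[-1] + f[-length(f)]) / 2)
      }
      tot
    }
    p_pre <- vapply(seq_len(nx), function(i)
      seg_int(rule$iv1[[i]], rule$G[i, ]) +
        seg_int(rule$iv2[[i]], rule$G[i, ], flip = TRUE), 0)
  }
  sum(wv * (lambda / 2 + (1 - lambda) * p_pre))
}

# Vectorized version of .rule_prob over a batch of conditions sharing the
# same rule (task, c_vis): returns one probability per condition.
.rule_prob_batch <- function(rule, s_vis, s_vest, c_vis, model, theta,
                             opts) {
  nc <- length(s_vis)
  if (rule$type == "const") return(rep(rule$value, nc))
  if (rule$type %in% c("smooth", "region_g"))
    return(vapply(seq_len(nc), function(j)
      .rule_prob(rule, s_vis[j], s_vest[j], c_vis, model, theta, opts), 0))
  lambda <- .theta_get(theta, "lambda", 0)
  nv <- .noise_of(theta, "vis", c_vis, model$noise)
  nw <- .noise_of(theta, "vest", NULL, model$noise)
  Wv <- .meas_weights_batch(rule$xg, s_vis, nv$sigma0, nv$w, opts$wrap)
  lo <- opts$domain[1]; hi <- opts$domain[2]
  sdw <- nw$sigma0 * sqrt(1 + nw$w^2 * s_vest^2)
  nx <- length(rule$xg$nodes)
  # interval-end CDFs for every condition at once
  Plo <- stats::pnorm(lo, s_vest, sdw)
  Z <- stats::pnorm(hi, s_vest, sdw) - Plo
  cdf <- function(q)       # (K intervals) x (nc conditions)
    (stats::pnorm(outer(q, s_vest, "-") / rep(sdw, each = length(q))) -
       rep(Plo, each = length(q))) / rep(Z, each = length(q))
  P_pre <- matrix(0, nx, nc)
  if (length(rule$a)) {
    contrib <- cdf(rule$b) - cdf(rule$a)
    sums <- rowsum(contrib, rule$row)
    P_pre[as.integer(rownames(sums)), ] <- sums
  }
  colSums(Wv * (lambda / 2 + (1 - lambda) * P_pre))
}

#' Monte-Carlo oracle for trial response probabilities
#'
#' Estimates a trial response probability by forward sampling of the
#' unseen measurements (the approach commonly used in the causal-inference
#' literature), rather than by quadrature. Intended as an independent
#' check of the marginalization; the estimator is unbiased with standard
#' error \eqn{\sqrt{\hat p (1 - \hat p) / M}} (a conservative envelope,
#' since the averaged quantities are probabilities rather than draws).
#'
#' @param task \code{"unisensory"}, \code{"unity"} or \code{"inertial"}.
#' @param s_vis,s_vest Presented headings (either may be \code{NA} for
#'   unisensory trials).
#' @param c_vis Reliability level (or \code{NULL}).
#' @param model,theta,opts As elsewhere.
#' @param M Number of measurement draws (>= 1000).
#' @param seed Integer seed; same seed gives identical estimates.
#' @return List with \code{estimate}, \code{se} and \code{M}.
#' @export
mc_response_prob_oracle <- function(task, s_vis = NA, s_vest = NA,
                                    c_vis = NULL, model, theta,
                                    M = 1e4, seed = 1, opts = ci_opts()) {
  stopifnot(M >= 1000)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lo <- opts$domain[1]; hi <- opts$domain[2]
  draw <- function(s, modality, cv) {
    np <- .noise_of(theta, modality, cv, model$noise)
    sd <- np$sigma0 * sqrt(1 + np$w^2 * s^2)
    .rtruncnorm(M, s, sd, lo, hi)
  }
  if (task == "unisensory") {
    if (is.na(s_vis)) {
      x <- draw(s_vest, "vest", NULL)
      p <- choice_prob_right(x_vest = x, model = model, theta = theta,
                             task = "unisensory", opts = opts)
    } else {
      x <- draw(s_vis, "vis", c_vis)
      p <- choice_prob_right(x_vis = x, c_vis = c_vis, model = model,
                             theta = theta, task = "unisensory", opts = opts)
    }
  } else if (task == "unity" && identical(model$explicit, "SFu")) {
    # measurement-independent rule: no noisy measurements to draw
    p <- rep(.theta_get(theta, paste0("eta_", c_vis)), M)
  } else {
    xv <- draw(s_vis, "vis", c_vis)
    xw <- draw(s_vest, "vest", NULL)
    p <- if (task == "unity")
      choice_prob_unity(xv, xw, c_vis, model, theta, opts)
    else
      choice_prob_right(xv, xw, c_vis, model, theta, task = "inertial",
                        opts = opts)
  }
  est <- mean(p)
  list(estimate = est, se = sqrt(max(est * (1 - est), 1e-12) / M), M = M)
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Dataset log likelihood
#'
#' Total and per-trial log likelihood of a trial table under an observer
#' model, assuming conditional independence between trials. Decision
#' surfaces are computed once per (task, reliability) class and reused
#' across trials; per-trial probabilities are clamped at a small floor
#' before taking logs, and the number of clamped trials is reported.
#'
#' @param data Trial table data frame (see \code{\link{read_trials}}).
#' @param model,theta,opts As elsewhere.
#' @return List with \code{total}, \code{per_trial} (length
#'   \code{nrow(data)}) and \code{n_clamped}.
#' @export
dataset_log_likelihood <- function(data, model, theta, opts = ci_opts()) {
  stopifnot(nrow(data) >= 1)
  if (!all(unique(data$task) %in% model$tasks))
    stop("data contain tasks not covered by the model: ",
         paste(setdiff(unique(data$task), model$tasks), collapse = ", "))
  p <- numeric(nrow(data))

  uni <- which(data$task == "unisensory")
  if (length(uni)) {
    sub <- data[uni, , drop = FALSE]
    modality <- ifelse(is.na(sub$s_vis), "vest", "vis")
    lambda <- .theta_get(theta, "lambda", 0)
    xg <- integration_grid(opts$n_x1, opts$domain)
    cls <- paste(modality, ifelse(is.na(sub$c_vis), "", sub$c_vis))
    for (k in unique(cls)) {
      i <- which(cls == k)
      mod <- modality[i[1]]
      cv <- if (mod == "vis") sub$c_vis[i[1]] else NULL
      d <- .step(.unisensory_prpos(xg$nodes, mod, cv, model, theta, opts))
      np <- .noise_of(theta, mod, cv, model$noise)
      s_all <- if (mod == "vest") sub$s_vest[i] else sub$s_vis[i]
      s_u <- unique(s_all)
      W <- .meas_weights_batch(xg, s_u, np$sigma0, np$w, opts$wrap)
      pr <- lambda / 2 + (1 - lambda) * colSums(d * W)
      pr_all <- pr[match(s_all, s_u)]
      p[uni[i]] <- ifelse(sub$response[i] == "right", pr_all, 1 - pr_all)
    }
  }

  for (task in intersect(c("unity", "inertial"), unique(data$task))) {
    rows <- which(data$task == task)
    sub <- data[rows, , drop = FALSE]
    yes <- if (task == "unity") "unity" else "right"
    for (cv in unique(sub$c_vis)) {
      i <- which(sub$c_vis == cv)
      rule <- .response_rule(task, cv, model, theta, opts)
      key <- paste(sub$s_vis[i], sub$s_vest[i])
      uk <- !duplicated(key)
      pr_u <- .rule_prob_batch(rule, sub$s_vis[i][uk], sub$s_vest[i][uk],
                               cv, model, theta, opts)
      pr_all <- pr_u[match(key, key[uk])]
      p[rows[i]] <- ifelse(sub$response[i] == yes, pr_all, 1 - pr_all)
    }
  }

  clamped <- p < opts$p_floor | p > 1 - opts$p_floor
  p <- pmin(pmax(p, opts$p_floor), 1 - opts$p_floor)
  ll <- log(p)
  list(total = sum(ll), per_trial = ll, n_clamped = sum(clamped))
}
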