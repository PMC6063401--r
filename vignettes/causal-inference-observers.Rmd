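---
title: "Causal-inference observer models for visuo-vestibular heading:
  models, fitting, and comparison"
author: "headingci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal-inference observer models for visuo-vestibular heading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(headingci)
```

## The scientific problem

When an observer simultaneously receives a visual heading cue (optic
flow) and a vestibular (inertial) heading cue, the two may or may not
originate from the same physical motion. Before combining the cues, the
observer must — explicitly or implicitly — solve a *causal inference*
problem: decide whether a single cause ($C = 1$) or two separate causes
($C = 2$) produced the noisy sensory measurements $x_\mathrm{vis}$ and
$x_\mathrm{vest}$. `headingci` implements a factorial family of observer
models for three binary-response psychophysical tasks:

* **unisensory discrimination** — left/right of straight ahead, one cue;
* **unity judgment** (explicit causal inference) — same or different
  causes;
* **bisensory inertial discrimination** (implicit causal inference) —
  left/right of the *vestibular* heading while a visual distractor is
  present.

Each model is one cell of a three-factor space:

1. **Causal-inference strategy.** *Bayesian* (`Bay`): compute
   $\Pr(C=1 \mid x_\mathrm{vis}, x_\mathrm{vest})$ from the scenario
   likelihoods and the free prior probability of a common cause $p_c$,
   report "unity" when it exceeds 0.5, and model-average the two
   scenario posteriors in the implicit task. A *probability matching*
   variant (`BayPM`) samples the scenario instead of averaging.
   *Fixed criterion* (`Fix`): declare a common cause whenever
   $|x_\mathrm{vis} - x_\mathrm{vest}| < \kappa_c$, ignoring
   reliability. *Fusion*: never infer separate causes — *stochastic
   fusion* (`SFu`) in the unity task (report "unity" with
   reliability-specific probabilities $\eta_{low}, \eta_{med},
   \eta_{high}$, its only parameters) and *forced fusion* (`FFu`,
   $C \equiv 1$) in the inertial task.
2. **Sensory noise shape.** Measurements are Gaussian around the true
   heading with SD either constant (`C`) per modality/reliability, or
   eccentricity-dependent (`X`),
   $\sigma(s) = \sigma_0\sqrt{1 + w^2 s^2}$, which grows approximately
   quadratically near straight ahead. With $w = 0$ the eccentric model
   reduces exactly to the constant one. The same noise model governs
   both the generative side and the observer's beliefs.
3. **Prior over headings.** *Empirical* (`E`): a discrete prior on the
   experiment's design grid (11 mean headings $\times$ 8 nonzero signed
   disparities for $C=2$), with Gaussian weights of widths
   $\sigma_{prior}$ (over the mean heading) and $\Delta_{prior}$ (over
   the disparity). *Independent* (`I`): a single zero-mean Gaussian per
   heading with SD $\sigma_{prior}$.

`explicit_model_space()` (7 distinguishable unity-task models),
`implicit_model_space()` (12) and `joint_model_space()` (16, with
strategy pairs restricted to Bay/Bay, Fix/Fix, Bay/FFu, Fix/FFu)
enumerate the spaces used in the analyses.

## Trial response probabilities

Given measurements, every decision rule is deterministic or an explicit
probability; lapses mix in a coin flip with rate $\lambda$, so all choice
probabilities live in $[\lambda/2,\, 1-\lambda/2]$. The experimenter
never observes the measurements, so a trial's response probability
marginalizes the rule over the measurement noise, e.g. for bisensory
trials
$$\Pr(r \mid s_\mathrm{vis}, s_\mathrm{vest}, c_\mathrm{vis}) =
\iint \Pr(r \mid x_\mathrm{vis}, x_\mathrm{vest}, c_\mathrm{vis})\,
p(x_\mathrm{vis} \mid s_\mathrm{vis})\, p(x_\mathrm{vest} \mid
s_\mathrm{vest})\, dx_\mathrm{vis}\, dx_\mathrm{vest}.$$

### Numerical scheme

We evaluate these integrals by numerical quadrature rather than Monte
Carlo. Design choices, all testable and exposed through
`ci_opts()`:

* **Fixed domain grids.** All measurement and stimulus grids are
  equispaced with trapezoidal weights on $[-90^\circ, 90^\circ]$, and
  per-trial measurement densities are renormalized on the grid
  (equivalently, the noise is truncated at the integration bounds; the
  simulator and the Monte-Carlo oracle draw from the same truncated
  densities). A fixed grid lets one decision evaluation be reused by
  every trial that shares a (task, reliability) class, which dominates
  the per-parameter-vector cost.
* **Semi-analytic marginalization over the vestibular axis.** The
  binary rules are indicators of smooth internal fields (e.g.
  $\Pr(C=1\mid x) - 0.5$), and naive 2-D quadrature of an indicator
  converges only first order. Instead, for each visual-measurement node
  the package finds the rule's decision region along the vestibular
  axis — crossings of the field located by linear interpolation between
  grid nodes — and integrates the truncated-normal density over those
  intervals in closed form. This restores second-order convergence:
  doubling the default grids (`n_x2 = 201`, `n_s = 401`) moves response
  probabilities by less than $10^{-4}$ (tested).
* **Ties.** A posterior exactly at 0.5 contributes probability 0.5 to
  each response (within a $10^{-9}$ tolerance that absorbs floating
  rounding in symmetric configurations). Boundary points carry no
  quadrature mass in the interval scheme, so ties only matter for the
  1-D unisensory rule, where the straight-ahead node is kept exactly on
  the grid.
* **Degenerate corners.** Where both scenario likelihoods underflow
  (essentially zero measurement-density mass), internal posteriors are
  set to indifference (0.5); per-trial probabilities are floored at
  $10^{-10}$ before logging and the number of clamped trials is
  reported.
* A wrapped-normal noise variant (period $360^\circ$) is available;
  at this stimulus range it is numerically identical to the plain
  normal (tested to $10^{-10}$), so the plain normal is the default.

`mc_response_prob_oracle()` re-estimates any response probability by
forward sampling of the measurements and serves as an independent check;
the suite verifies 3-SE agreement in every strategy family.

## Fitting

`fit_mle()` maximizes the trial log likelihood (conditional independence
across trials; joint fits sum the per-task log likelihoods) by
multistart Nelder-Mead through a smooth bounded reparameterization, with
Latin-hypercube starts in the parameter box. Scale parameters
($\sigma_0$, $\kappa_c$, $\sigma_{prior}$, $\Delta_{prior}$) are handled
in log space; all bounds follow the published allowed ranges (e.g.
$\sigma_0 \in [0.5^\circ, 80^\circ]$, $\kappa_c \in [0.25^\circ,
180^\circ]$). The contract is multistart dominance — the returned
optimum is at least as good as every start — not certified global
optimality.

`sample_posterior()` draws from the parameter posterior under a
non-informative uniform prior over each bounded range (uniform in log
space for scale parameters) using `eis_sample()`, an ensemble slice
sampler: each of $2(k+1)$ walkers is updated by slice sampling along
either a coordinate axis or the difference vector of two other walkers
(adaptive direction sampling), which requires no step-size tuning and
adapts to posterior correlations. Burn-in defaults to half the run;
split-$\hat R$ (warning threshold 1.1) and effective sample sizes are
always computed, and the per-draw per-trial log-likelihood matrix is
stored for the comparison metrics below.

## Model comparison

* `info_criteria()` — AICc and BIC from the ML fit.
* `psis_loo()` — Bayesian leave-one-out cross-validation estimated from
  posterior draws by Pareto-smoothed importance sampling. The largest
  $M = \min(0.2S, 3\sqrt S)$ weights per trial are replaced by quantiles
  of a generalized Pareto distribution fitted to the tail
  (Zhang-Stephens estimator); the shape exponent $k_i$ is reported per
  trial, flagged above 0.7 and escalated to a warning above 1, where the
  weight moments cease to exist.
* `marginal_likelihood_whm()` — the log marginal likelihood by the
  weighted harmonic mean identity, with the weight density $\varphi$
  confined to a high-posterior-density region: a Gaussian mixture is
  fitted to the draws (via mclust; a moment-matched single ellipsoid is
  the fallback), each component is replaced by a uniform ellipsoid
  proportional to its covariance, and the common radius is chosen by
  minimizing the empirical variance of the estimator's summands. The
  mixture initialization is internally seeded so the estimator is a
  deterministic function of its inputs.
* `group_bms()` — hierarchical (random-effects) model selection across
  subjects: a variational Dirichlet posterior over population model
  frequencies, exceedance probabilities $\varphi$ by Monte Carlo over
  that posterior, the Bayesian omnibus risk (BOR) from the free-energy
  comparison against the equal-frequency null, and the protected
  exceedance probability
  $\tilde\varphi_i = (1-\mathrm{BOR})\varphi_i + \mathrm{BOR}/K$.
  Under identical evidence the BOR rises toward 1 with the number of
  subjects (it is the posterior probability of the null, not a hard
  indicator), and $\tilde\varphi$ becomes uniform; both limits are
  tested.
* `factor_level_bms()` — factor-level results by Dirichlet
  agglomeration (concentrations of models in a factor component add).
  The prior is re-weighted so every component of every factor carries
  equal prior mass (for the 7-model explicit space: Fix models
  $\times 2$, SFu $\times 4$), with overall scale
  $\alpha_0 = $ (mean components per factor)/(number of models) so that
  aggregated concentrations are of order one. The factor-level BOR —
  for which no single canonical construction exists — is
  computed here by repeating the null-versus-random-effects comparison
  on the factor partition, with each component's evidence marginalized
  over its member models at their within-component prior weights. This
  is the most direct extension of the model-level definition; it reduces
  to it when every component has one model.
* `compatibility_probability()` — whether a parameter is the same
  across tasks: per subject, kernel-density estimates
  ($\mathrm{SJ}$ plug-in bandwidth, Silverman fallback) of the
  model-averaged marginal posteriors are scored under a shared-value
  hypothesis ($H_0$: one integral of the product) versus a
  distinct-values hypothesis ($H_1$: product of integrals), against a
  truncated-Cauchy prior matched to the pooled average posterior's
  median and half interquartile range and truncated to the pooled
  sample range; $C_p$ is the protected exceedance probability of $H_0$
  across subjects.
* `absolute_goodness_of_fit()` — the fraction of information gain above
  chance, $g = 1 - (\hat H_G + \mathrm{LOO})/(\hat H_G - N\log 2)$,
  anchored by a bias-corrected entropy estimate $\hat H_G$ of the data
  grouped by unique (task, $s_\mathrm{vis}$, $s_\mathrm{vest}$,
  $c_\mathrm{vis}$) condition, using the alternating-digamma correction
  $G(n) = \psi(n) + \tfrac12(-1)^n[\psi(\tfrac{n+1}{2}) -
  \psi(\tfrac n2)]$. The anchor needs repeated conditions: with only a
  couple of trials per condition the entropy estimate is flagged
  high-variance and $g$ can exceed 1; for the generating model evaluated
  at the generating parameters $g \to 1$ from above as per-condition
  counts grow (tested).

## The synthetic experiment

`generate_design()` reproduces the study's stimulus schedule: mean
heading uniform on $\{-25^\circ, \dots, 25^\circ\}$ in $5^\circ$ steps;
disparity magnitude uniform on $\{0, 5, 10, 20, 40\}^\circ$ — so exactly
20% of trials have identical headings — with random sign when nonzero;
three equiprobable visual reliability levels; headings placed
symmetrically, $s_\mathrm{vis} = \bar s - \Delta/2$,
$s_\mathrm{vest} = \bar s + \Delta/2$ (297 distinct bisensory
conditions). Default per-task trial counts (550 unisensory, 950 unity,
2550 inertial) sit mid-range of the study's per-subject totals (350-750,
700-1200, 2100-3000). Trials are drawn i.i.d. with target totals; the
study's minimum-repeat scheduling ("each condition at least 20/70
times") is emulated only in expectation. Subject-specific coherence
staircasing is abstracted into the three $\sigma_{0vis}$ parameters.

`simulate_observer()` forward-samples responses through actual noisy
measurements and the decision rules (not by thinning precomputed
response probabilities), so simulator and likelihood can disagree if
either is wrong — the self-consistency tests exploit this.
`summarize_unity()` and `summarize_bias()` compute the model-free
summaries (proportion of unity reports by disparity and reliability;
vestibular bias $= -$PSE from cumulative-Gaussian psychometric fits of
rightward responses against $s_\mathrm{vest}$, within the study's eleven
verbatim $s_\mathrm{vis}$ bins, with the lapse fixed at the simulated
observer's $\lambda$). `model_recovery()` runs the simulate-fit-tally
confusion analysis.

What the simulator does *not* emulate: platform kinematics, session and
block structure, sequential effects, learning or fatigue, and
subject-specific coherence calibration. Passing recovery tests therefore
show that the pipeline is self-consistent under the model family's own
assumptions — not that those assumptions hold for any real observer.

## Worked example

A small end-to-end run (scaled grids for speed):

```{r example, eval = FALSE}
opts <- ci_opts(n_x1 = 201, n_x2 = 101, n_s = 201)
m <- model_spec(explicit = "Bay", noise = "C", prior = "I",
                tasks = "unity")
theta <- c(sigma0_vest = 6.5, sigma0_vis_high = 4, sigma0_vis_med = 6.3,
           sigma0_vis_low = 11.6, lambda = 0.02, p_c = 0.56,
           sigma_prior = 50)
design <- generate_design(design_spec(0, 950, 0), seed = 1)
data <- simulate_observer(design, m, theta, seed = 1, opts = opts)
fit <- fit_mle(data, m, n_starts = 5, seed = 1, opts = opts)
fit$logLik
info_criteria(fit$logLik, nrow(fit$param_space), nrow(data))
```

## Problem sizes and tunables

The defaults aim at study-scale analyses: quadrature grids `n_x1 = 401`,
`n_x2 = 201`, `n_s = 401` (a joint-fit likelihood evaluation is a few
tens of milliseconds); `fit_mle()` with 10 starts; MCMC with $2(k+1)$
walkers and 5000 recorded draws. The shipped test-suite and acceptance
checks run the same code at reduced sizes chosen to keep each check in
seconds-to-minutes: grids of 101-201 nodes (61-101 for fitting loops),
800-trial unity datasets, 800-draw posteriors, $2\times 10^4$-draw
Monte-Carlo oracles, and two datasets per cell in recovery runs. These
reductions were validated against the convergence criteria above (grid
doubling $< 10^{-4}$; oracle agreement within 3 SE) rather than assumed.

## Known limitations

* The eccentricity law `σ0·√(1 + w²s²)` and the discrete empirical-prior
  approximation are this package's concrete choices among a family of
  plausible forms with the same small-angle behavior; both sit behind
  stable interfaces (`noise_sd()`, `prior_density()`) and can be swapped
  without touching the rest.
* The likelihood is piecewise-constant along directions that move a
  decision boundary between grid nodes only at the resolution of the
  crossing interpolation; derivative-free optimization is used for this
  reason.
* Probability-matching response probabilities fall back to dense
  trapezoid integration weighted by the smooth posterior field, which is
  slower and slightly less accurate than the interval scheme used for
  the indicator rules.
* No hierarchical (shared-across-subject) parameter priors; group
  structure enters only through the model-frequency level.
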