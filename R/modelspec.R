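#' Observer model specification
#'
#' One cell of the factorial observer-model space: a causal-inference
#' strategy for the explicit (unity-judgment) task and/or the implicit
#' (inertial-discrimination) task, a sensory-noise shape, and a type of
#' prior over headings.
#'
#' Strategies: \code{"Bay"} (Bayesian model averaging), \code{"BayPM"}
#' (probability-matching Bayesian), \code{"Fix"} (fixed criterion on the
#' measurement disparity), \code{"SFu"} (stochastic fusion; explicit task
#' only), \code{"FFu"} (forced fusion; implicit task only). Noise shape:
#' \code{"C"} constant, \code{"X"} eccentricity-dependent. Prior:
#' \code{"E"} empirical (discrete, correlated design distribution),
#' \code{"I"} independent Gaussian.
#'
#' @param explicit Explicit-task strategy, or \code{NA} if the model does
#'   not cover the unity-judgment task.
#' @param implicit Implicit-task strategy, or \code{NA}.
#' @param noise Noise shape, \code{"C"} or \code{"X"}.
#' @param prior Prior type, \code{"E"} or \code{"I"}.
#' @param tasks Character vector of tasks covered; subset of
#'   \code{c("unisensory", "unity", "inertial")}.
#' @return Object of class \code{"model_spec"}.
#' @examples
#' model_spec(explicit = "Bay", noise = "X", prior = "E", tasks = "unity")
#' model_spec(explicit = "Fix", implicit = "Fix", noise = "C", prior = "E")
#' @export
model_spec <- function(explicit = NA, implicit = NA, noise = c("C", "X"),
                       prior = c("E", "I"),
                       tasks = NULL) {
  noise <- match.arg(noise)
  prior <- match.arg(prior)
  if (!is.na(explicit) &&
      !explicit %in% c("Bay", "BayPM", "Fix", "SFu"))
    stop("unknown explicit strategy: ", explicit)
  if (!is.na(implicit) &&
      !implicit %in% c("Bay", "BayPM", "Fix", "FFu"))
    stop("unknown implicit strategy: ", implicit)
  if (is.na(explicit) && is.na(implicit) && is.null(tasks))
    tasks <- "unisensory"
  if (is.null(tasks)) {
    tasks <- c(if (!is.na(explicit)) "unity",
               if (!is.na(implicit)) "inertial")
    if (!is.na(explicit) && !is.na(implicit))
      tasks <- c("unisensory", tasks)   # joint fits include unisensory
  }
  stopifnot(all(tasks %in% c("unisensory", "unity", "inertial")))
  if ("unity" %in% tasks && is.na(explicit))
    stop("unity task requires an explicit strategy")
  if ("inertial" %in% tasks && is.na(implicit))
    stop("inertial task requires an implicit strategy")
  structure(list(explicit = explicit, implicit = implicit,
                 noise = noise, prior = prior, tasks = tasks),
            class = "model_spec")
}

#' @export
format.model_spec <- function(x, ...) {
  strat <- if (!is.na(x$explicit) && !is.na(x$implicit))
    paste0(x$explicit, "/", x$implicit)
  else if (!is.na(x$explicit)) x$explicit
  else if (!is.na(x$implicit)) x$implicit
  else "Uni"
  # SFu uses neither noise shape nor prior; explicit Fix uses no prior
  if (identical(strat, "SFu")) return("SFu")
  uses_prior <- !(identical(x$tasks, "unity") && x$explicit == "Fix") &&
    any(c("unity", "inertial") %in% x$tasks)
  if (uses_prior) paste(strat, x$noise, x$prior, sep = "-")
  else paste(strat, x$noise, sep = "-")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", format(x), "| tasks:", paste(x$tasks, collapse = ", "),
      "\n")
  invisible(x)
}

#' Enumerate the explicit-task model space
#'
#' The seven distinguishable models of the unity-judgment task: four
#' Bayesian models (noise shape crossed with prior type), two
#' fixed-criterion models (the prior factor does not influence the
#' fixed-criterion rule), and one stochastic-fusion model (influenced by
#' neither noise nor prior).
#'
#' @param bayes Bayesian variant, \code{"Bay"} or \code{"BayPM"}.
#' @return Named list of \code{\link{model_spec}} objects.
#' @export
explicit_model_space <- function(bayes = "Bay") {
  ms <- list()
  for (nz in c("C", "X")) for (pr in c("E", "I"))
    ms[[length(ms) + 1L]] <- model_spec(explicit = bayes, noise = nz,
                                        prior = pr, tasks = "unity")
  for (nz in c("C", "X"))
    ms[[length(ms) + 1L]] <- model_spec(explicit = "Fix", noise = nz,
                                        prior = "E", tasks = "unity")
  ms[[length(ms) + 1L]] <- model_spec(explicit = "SFu", tasks = "unity")
  names(ms) <- vapply(ms, format, "")
  ms
}

#' Enumerate the implicit-task model space
#'
#' Full factorial space for the inertial-discrimination task: strategies
#' \{Bay, Fix, FFu\} crossed with noise \{C, X\} and prior \{E, I\}
#' (twelve models).
#'
#' @param bayes Bayesian variant, \code{"Bay"} or \code{"BayPM"}.
#' @return Named list of \code{\link{model_spec}} objects.
#' @export
implicit_model_space <- function(bayes = "Bay") {
  ms <- list()
  for (st in c(bayes, "Fix", "FFu"))
    for (nz in c("C", "X")) for (pr in c("E", "I"))
      ms[[length(ms) + 1L]] <- model_spec(implicit = st, noise = nz,
                                          prior = pr, tasks = "inertial")
  names(ms) <- vapply(ms, format, "")
  ms
}

#' Enumerate the joint-fit model space
#'
#' Sixteen models for joint fits across all three tasks: strategy pairs
#' (explicit/implicit) restricted to \{Bay/Bay, Fix/Fix, Bay/FFu,
#' Fix/FFu\}, crossed with noise \{C, X\} and prior \{E, I\}.
#'
#' @param bayes Bayesian variant, \code{"Bay"} or \code{"BayPM"}.
#' @return Named list of \code{\link{model_spec}} objects.
#' @export
joint_model_space <- function(bayes = "Bay") {
  pairs <- list(c(bayes, bayes), c("Fix", "Fix"),
                c(bayes, "FFu"), c("Fix", "FFu"))
  ms <- list()
  for (p in pairs) for (nz in c("C", "X")) for (pr in c("E", "I"))
    ms[[length(ms) + 1L]] <- model_spec(explicit = p[1], implicit = p[2],
                                        noise = nz, prior = pr)
  names(ms) <- vapply(ms, format, "")
  ms
}

# Internal: strategy factor label of a model (used for factor-level BMS).
.strategy_label <- function(m) {
  if (!is.na(m$explicit) && !is.na(m$implicit))
    paste0(m$explicit, "/", m$implicit)
  else if (!is.na(m$explicit)) m$explicit else m$implicit
}

#' Factor partition of a model space
#'
#' Groups the models of a space by one of the three model factors. Models
#' on which a factor has no effect (e.g. the prior for explicit-task
#' fixed-criterion models, everything for stochastic fusion) are dropped
#' from that factor's partition.
#'
#' @param models Named list of \code{\link{model_spec}} objects.
#' @param factor One of \code{"strategy"}, \code{"noise"}, \code{"prior"}.
#' @return Named list mapping factor component to model names.
#' @export
model_factor_partition <- function(models,
                                   factor = c("strategy", "noise", "prior")) {
  factor <- match.arg(factor)
  lab <- switch(factor,
    strategy = vapply(models, .strategy_label, ""),
    noise = vapply(models, function(m)
      if (identical(.strategy_label(m), "SFu")) NA_character_ else m$noise, ""),
    prior = vapply(models, function(m) {
      s <- .strategy_label(m)
      if (s %in% c("SFu") ||
          (identical(m$tasks, "unity") && identical(m$explicit, "Fix")))
        NA_character_
      else m$prior
    }, ""))
  keep <- !is.na(lab)
  split(names(models)[keep], lab[keep])
}
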