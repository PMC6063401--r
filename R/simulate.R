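#' Simulate an observer on a stimulus schedule
#'
#' Forward-samples responses: for each trial, noisy measurements are
#' drawn from the model's noise distributions, the model's decision rule
#' is evaluated at those measurements (including any rule stochasticity
#' and lapses), and a binary response is drawn.
#'
#' @param design Trial table of stimuli (responses ignored), e.g. from
#'   \code{\link{generate_design}}.
#' @param model \code{\link{model_spec}} covering the design's tasks.
#' @param theta Named parameter vector.
#' @param seed Integer seed.
#' @param opts \code{\link{ci_opts}} (controls the internal posterior
#'   grids of the decision rules and the measurement truncation domain).
#' @return The design with the \code{response} column filled
#'   (\code{"right"}/\code{"left"} or \code{"unity"}/\code{"separate"}).
#' @export
simulate_observer <- function(design, model, theta, seed = 1,
                              opts = ci_opts()) {
  if (!all(unique(design$task) %in% model$tasks))
    stop("design contains tasks not covered by the model")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lo <- opts$domain[1]; hi <- opts$domain[2]
  n <- nrow(design)
  resp <- character(n)

  draw_meas <- function(s, modality, cv) {
    np <- .noise_of(theta, modality, cv, model$noise)
    sd <- np$sigma0 * sqrt(1 + np$w^2 * s^2)
    .rtruncnorm(length(s), s, sd, lo, hi)
  }

  uni <- which(design$task == "unisensory")
  if (length(uni)) {
    vest <- uni[is.na(design$s_vis[uni])]
    if (length(vest)) {
      x <- draw_meas(design$s_vest[vest], "vest", NULL)
      p <- choice_prob_right(x_vest = x, model = model, theta = theta,
                             task = "unisensory", opts = opts)
      resp[vest] <- ifelse(stats::runif(length(p)) < p, "right", "left")
    }
    for (cv in unique(stats::na.omit(design$c_vis[uni]))) {
      i <- uni[!is.na(design$c_vis[uni]) & design$c_vis[uni] == cv]
      x <- draw_meas(design$s_vis[i], "vis", cv)
      p <- choice_prob_right(x_vis = x, c_vis = cv, model = model,
                             theta = theta, task = "unisensory",
                             opts = opts)
      resp[i] <- ifelse(stats::runif(length(p)) < p, "right", "left")
    }
  }

  for (task in intersect(c("unity", "inertial"), unique(design$task))) {
    rows <- which(design$task == task)
    for (cv in unique(design$c_vis[rows])) {
      i <- rows[design$c_vis[rows] == cv]
      if (task == "unity" && identical(model$explicit, "SFu")) {
        # stochastic fusion ignores the measurements entirely
        p <- .theta_get(theta, paste0("eta_", cv))
        resp[i] <- ifelse(stats::runif(length(i)) < p, "unity", "separate")
        next
      }
      xv <- draw_meas(design$s_vis[i], "vis", cv)
      xw <- draw_meas(design$s_vest[i], "vest", NULL)
      if (task == "unity") {
        p <- choice_prob_unity(xv, xw, cv, model, theta, opts)
        resp[i] <- ifelse(stats::runif(length(p)) < p, "unity", "separate")
      } else {
        p <- choice_prob_right(xv, xw, cv, model, theta,
                               task = "inertial", opts = opts)
        resp[i] <- ifelse(stats::runif(length(p)) < p, "right", "left")
      }
    }
  }
  design$response <- resp
  design
}
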