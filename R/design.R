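#' Stimulus design specification
#'
#' The interleaved visuo-vestibular heading design: on each bisensory
#' trial a mean heading is drawn uniformly from \{-25, -20, ..., 25\}
#' degrees, a disparity magnitude uniformly from \{0, 5, 10, 20, 40\}
#' degrees (so zero disparity occurs with probability exactly 1/5) with a
#' random sign when nonzero, and a visual reliability level uniformly
#' from \{high, med, low\}. Headings are placed symmetrically about the
#' mean: \eqn{s_{vis} = \bar s - \Delta/2},
#' \eqn{s_{vest} = \bar s + \Delta/2}. Unisensory trials draw headings
#' from the same mean-heading set, split across one vestibular and three
#' visual reliability conditions.
#'
#' @param n_unisensory,n_unity,n_inertial Per-task trial counts; the
#'   defaults sit inside the per-subject ranges of the study design
#'   (350-750, 700-1200, 2100-3000).
#' @return List of class \code{"design_spec"}.
#' @export
design_spec <- function(n_unisensory = 550, n_unity = 950,
                        n_inertial = 2550) {
  stopifnot(n_unisensory >= 1 || n_unity >= 1 || n_inertial >= 1,
            n_unisensory >= 0, n_unity >= 0, n_inertial >= 0)
  structure(list(means = .design_means(),
                 disparity_magnitudes = c(0, 5, 10, 20, 40),
                 reliabilities = c("high", "med", "low"),
                 n_unisensory = n_unisensory, n_unity = n_unity,
                 n_inertial = n_inertial),
            class = "design_spec")
}

#' Enumerate the bisensory stimulus conditions
#'
#' @param spec \code{\link{design_spec}}.
#' @return Data frame of the unique bisensory (s_vis, s_vest, c_vis)
#'   conditions: 9 signed disparities x 11 mean headings x 3
#'   reliabilities = 297 rows.
#' @export
enumerate_conditions <- function(spec = design_spec()) {
  disp <- sort(unique(c(-spec$disparity_magnitudes,
                        spec$disparity_magnitudes)))
  g <- expand.grid(mean = spec$means, disparity = disp,
                   c_vis = spec$reliabilities,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$s_vis <- g$mean - g$disparity / 2
  g$s_vest <- g$mean + g$disparity / 2
  g[, c("s_vis", "s_vest", "c_vis", "mean", "disparity")]
}

#' Generate a stimulus schedule
#'
#' Draws the trial-by-trial stimuli (no responses) for the three tasks
#' under a design specification.
#'
#' @param spec \code{\link{design_spec}}.
#' @param seed Integer seed; the schedule is reproducible.
#' @return Trial table data frame with columns \code{task}, \code{s_vis},
#'   \code{s_vest}, \code{c_vis}, \code{response} (all \code{NA}).
#' @export
generate_design <- function(spec = design_spec(), seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- list()

  draw_bisensory <- function(n, task) {
    if (n == 0) return(NULL)
    mag <- sample(spec$disparity_magnitudes, n, replace = TRUE)
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    disp <- mag * ifelse(mag == 0, 1, sgn)
    m <- sample(spec$means, n, replace = TRUE)
    data.frame(task = task, s_vis = m - disp / 2, s_vest = m + disp / 2,
               c_vis = sample(spec$reliabilities, n, replace = TRUE),
               response = NA_character_, stringsAsFactors = FALSE)
  }

  if (spec$n_unisensory > 0) {
    n <- spec$n_unisensory
    kind <- sample(c("vest", "vis_high", "vis_med", "vis_low"), n,
                   replace = TRUE)
    s <- sample(spec$means, n, replace = TRUE)
    out$uni <- data.frame(
      task = "unisensory",
      s_vis = ifelse(kind == "vest", NA_real_, s),
      s_vest = ifelse(kind == "vest", s, NA_real_),
      c_vis = ifelse(kind == "vest", NA_character_, sub("vis_", "", kind)),
      response = NA_character_, stringsAsFactors = FALSE)
  }
  out$unity <- draw_bisensory(spec$n_unity, "unity")
  out$inertial <- draw_bisensory(spec$n_inertial, "inertial")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
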