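#' Bias-corrected entropy of grouped binary responses
#'
#' Estimates the total response entropy (nats) of a trial table whose
#' trials can be grouped into repeated identical stimulus conditions,
#' using the bias-corrected estimator with the alternating-digamma
#' correction
#' \deqn{G(n) = \psi(n) + \tfrac12 (-1)^n
#'   \big[\psi(\tfrac{n+1}{2}) - \psi(\tfrac{n}{2})\big],}
#' so that a condition with counts \eqn{n_1, n_2} (total \eqn{N_c})
#' contributes \eqn{N_c \log N_c - \sum_j n_j G(n_j)}.
#'
#' @param data Trial table; trials are grouped by unique
#'   (task, s_vis, s_vest, c_vis).
#' @param min_repeats Conditions with fewer trials are counted but the
#'   estimate is flagged as high-variance.
#' @return List with \code{entropy} (total, nats), \code{n_conditions},
#'   and \code{high_variance} (logical flag).
#' @export
grassberger_entropy <- function(data, min_repeats = 2) {
  key <- paste(data$task,
               ifelse(is.na(data$s_vis), ".", data$s_vis),
               ifelse(is.na(data$s_vest), ".", data$s_vest),
               ifelse(is.na(data$c_vis), ".", data$c_vis))
  G <- function(n) {
    out <- numeric(length(n))
    pos <- n > 0
    np <- n[pos]
    out[pos] <- digamma(np) +
      0.5 * (-1)^np * (digamma((np + 1) / 2) - digamma(np / 2))
    out
  }
  H <- 0
  sizes <- integer(0)
  for (k in unique(key)) {
    r <- data$response[key == k]
    counts <- as.numeric(table(r))
    N <- sum(counts)
    sizes <- c(sizes, N)
    H <- H + N * log(N) - sum(counts * G(counts))
  }
  list(entropy = H, n_conditions = length(sizes),
       high_variance = mean(sizes < min_repeats) > 0.5)
}

#' Absolute goodness of fit
#'
#' Fraction of information gain above chance achieved by a model:
#' \deqn{g = 1 - \frac{\hat H_G + LOO}{\hat H_G - N \log 2},}
#' where \eqn{\hat H_G} is the bias-corrected entropy estimate of the
#' (binary-response) data and LOO is the model's leave-one-out score.
#' \eqn{g = 0} at chance performance and \eqn{g = 1} when the model
#' predicts as well as the data's intrinsic variability allows.
#'
#' @param data Trial table with binary responses.
#' @param loo LOO score of the model on these data (nats).
#' @return Object of class \code{"goodness_of_fit"}: \code{g},
#'   \code{entropy}, \code{loo}, \code{n_trials},
#'   \code{high_variance}.
#' @export
absolute_goodness_of_fit <- function(data, loo) {
  ent <- grassberger_entropy(data)
  N <- nrow(data)
  g <- 1 - (ent$entropy + loo) / (ent$entropy - N * log(2))
  structure(list(g = g, entropy = ent$entropy, loo = loo, n_trials = N,
                 high_variance = ent$high_variance),
            class = "goodness_of_fit")
}

#' @export
print.goodness_of_fit <- function(x, ...) {
  cat("<goodness_of_fit> g =", round(x$g, 4),
      sprintf("(entropy %.1f nats, LOO %.1f, N %d)\n",
              x$entropy, x$loo, x$n_trials))
  if (x$high_variance)
    cat("  note: many single-trial conditions; entropy estimate is",
        "high-variance\n")
  invisible(x)
}
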