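# Test-phase validation of the observer model: end-of-round uncertainty
# versus accuracy and confidence.

#' Validate the observer model against simulated test performance
#'
#' Bins test records by end-of-round posterior entropy (equal-count bins)
#' and summarizes per-bin accuracy with standard errors and mean confidence
#' split by correctness, together with a logistic regression of accuracy on
#' entropy. Under the observer model, accuracy should fall from near 1 at
#' low entropy to chance (0.5) at maximal entropy, and confidence on
#' correct answers should fall with entropy.
#'
#' @param tests A test-record data frame (from an `"explore_sim"`), or the
#'   `"explore_sim"` itself. Practice rounds are excluded.
#' @param n_bins Number of entropy bins (default 10).
#' @return An object of class `"observer_validation"`: the bin table, the
#'   accuracy-on-entropy logistic slope with SE, and confidence summaries.
#' @export
validate_observer <- function(tests, n_bins = 10L) {
  if (inherits(tests, "explore_sim")) tests <- tests$tests
  tests <- tests[tests$is_practice == 0, , drop = FALSE]
  if (!nrow(tests)) stop("no experimental test records")

  edges <- unique(stats::quantile(tests$entropy,
                                  probs = seq(0, 1, length.out = n_bins + 1),
                                  type = 7))
  if (length(edges) < 3) {
    edges <- unique(c(min(tests$entropy), stats::median(tests$entropy),
                      max(tests$entropy)))
  }
  edges[1] <- -Inf; edges[length(edges)] <- Inf
  bin <- cut(tests$entropy, breaks = edges, labels = FALSE)
  dropped <- n_bins - length(unique(bin))
  if (dropped > 0) {
    message(dropped, " empty entropy bin(s) dropped")
  }

  agg <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    sub <- tests[bin == b, , drop = FALSE]
    acc <- mean(sub$correct)
    data.frame(bin = b, n = nrow(sub),
               entropy_mean = mean(sub$entropy),
               accuracy = acc,
               accuracy_se = sqrt(acc * (1 - acc) / nrow(sub)),
               confidence_correct = if (any(sub$correct == 1))
                 mean(sub$confidence[sub$correct == 1]) else NA_real_,
               confidence_error = if (any(sub$correct == 0))
                 mean(sub$confidence[sub$correct == 0]) else NA_real_)
  }))

  glm_fit <- stats::glm(correct ~ entropy, data = tests,
                        family = stats::binomial())
  sl <- summary(glm_fit)$coefficients["entropy", ]

  structure(list(bins = agg,
                 slope = unname(sl["Estimate"]),
                 slope_se = unname(sl["Std. Error"]),
                 n_records = nrow(tests),
                 glm = glm_fit),
            class = "observer_validation")
}

#' @export
print.observer_validation <- function(x, ...) {
  cat(sprintf("Observer validation over %d test records\n", x$n_records))
  cat(sprintf("  accuracy ~ entropy logistic slope: %.3f (SE %.3f)\n",
              x$slope, x$slope_se))
  print(round(x$bins, 3), row.names = FALSE)
  invisible(x)
}

#' @export
plot.observer_validation <- function(x, ...) {
  b <- x$bins
  graphics::plot(b$entropy_mean, b$accuracy, type = "b", pch = 19,
                 ylim = c(0.4, 1),
                 xlab = "end-of-round entropy (nats)",
                 ylab = "test accuracy",
                 main = "Accuracy falls with observer uncertainty")
  graphics::arrows(b$entropy_mean, b$accuracy - b$accuracy_se,
                   b$entropy_mean, b$accuracy + b$accuracy_se,
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(h = 0.5, lty = 2, col = "grey")
  invisible(x)
}

#' Was a table's test question unsolvable?
#'
#' A test question is unsolvable when at least one of the table's decks was
#' never sampled during exploration, since the color proportions of the two
#' decks are independent.
#'
#' @param trials Trial-level data frame for the round(s) of interest.
#' @param participant,round,table Identify the round-table to check.
#' @return `TRUE` if any deck of the table has zero observations.
#' @export
unsolvable_flag <- function(trials, participant, round, table) {
  sub <- trials[trials$participant == participant & trials$round == round &
                trials$chosen_table == table, , drop = FALSE]
  length(unique(sub$chosen_deck)) < 2
}
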