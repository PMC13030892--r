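# Strategy-driven agents: parameter containers and the logistic choice rule.

.strategies <- c("eig", "uncertainty", "exposure", "random")

# Calibration constants: standard deviations of the raw trial-level decision
# variables under the default task configuration (measured once from a large
# random-exploration simulation; see the methods vignette). Generation
# divides raw DVs by these so that beta_dv is a slope per calibrated SD unit,
# and each simulated dataset stores them so fitting can share the scale.
.dv_scale_default <- c(eig = 0.0161, uncertainty = 0.273, exposure = 3.99)

#' Agent parameters for the choice simulator
#'
#' Describes one simulated participant: which decision variable drives table
#' choice (`strategy`), the slope on that scaled variable (`beta_dv`), a
#' right-side bias (`beta_side`), a repeat-option bias (`beta_rep`), an
#' optional overall-uncertainty threshold `tau` (nats) above which the slope
#' changes by `beta_int` per nat (negative values produce uncertainty
#' avoidance), and a lapse probability of uniformly random choice.
#'
#' @param strategy One of `"eig"`, `"uncertainty"`, `"exposure"`, `"random"`.
#'   Random explorers have no decision variable; `beta_dv` is forced to 0.
#' @param beta_dv Slope on the scaled decision-variable difference.
#' @param beta_side Right-side intercept bias.
#' @param beta_rep Repeat-option bias (applied to +1 right / -1 left / 0 none).
#' @param tau Overall-uncertainty threshold in nats, in `(0, 2 log 2]`, or
#'   `NA` for no threshold.
#' @param beta_int Change of the decision-variable slope per nat of overall
#'   uncertainty above `tau` (typically negative); ignored when `tau` is `NA`.
#' @param lapse Probability of an attention-free 50/50 choice, in `[0, 1]`.
#' @param deck_policy How the agent picks a deck on the chosen table:
#'   `"least"` (least-sampled deck, the balanced default), `"max"`
#'   (deck with the higher expected information gain) or `"mean"` (random).
#' @param eig_policy Deck aggregation for the table-level EIG decision
#'   variable; see [expected_information_gain()].
#' @return An object of class `"agent_params"`.
#' @export
agent_params <- function(strategy = c("uncertainty", "eig", "exposure", "random"),
                         beta_dv = 1, beta_side = 0, beta_rep = 0.5,
                         tau = NA_real_, beta_int = NA_real_, lapse = 0.05,
                         deck_policy = c("least", "max", "mean"),
                         eig_policy = c("max", "mean", "least")) {
  strategy <- match.arg(strategy)
  deck_policy <- match.arg(deck_policy)
  eig_policy <- match.arg(eig_policy)
  if (lapse < 0 || lapse > 1) stop("'lapse' must lie in [0, 1]")
  if (!is.na(tau) && (tau <= 0 || tau > 2 * log(2))) {
    stop("'tau' must lie in (0, 2 log 2] nats")
  }
  if (strategy == "random") beta_dv <- 0
  if (is.na(tau)) beta_int <- NA_real_
  if (!is.na(tau) && is.na(beta_int)) beta_int <- 0
  structure(list(strategy = strategy, beta_dv = beta_dv,
                 beta_side = beta_side, beta_rep = beta_rep,
                 tau = tau, beta_int = beta_int, lapse = lapse,
                 deck_policy = deck_policy, eig_policy = eig_policy),
            class = "agent_params")
}

#' @export
print.agent_params <- function(x, ...) {
  cat(sprintf("Agent: %s strategy, beta_dv = %g, side = %g, repeat = %g, lapse = %g\n",
              x$strategy, x$beta_dv, x$beta_side, x$beta_rep, x$lapse))
  if (!is.na(x$tau)) {
    cat(sprintf("  threshold tau = %g nats, slope change %g per nat above\n",
                x$tau, x$beta_int))
  }
  invisible(x)
}

#' Draw a population of agents
#'
#' Samples per-participant agent parameters from independent normal
#' population distributions (strategy, threshold and lapse are shared).
#' A correlation `cor_dv_int` between the approach slope `beta_dv` and the
#' avoidance magnitude `|beta_int|` can be requested to emulate the coupling
#' between approaching and avoiding uncertainty across individuals.
#'
#' @param n Number of participants.
#' @param strategy Shared strategy label.
#' @param beta_dv_mean,beta_dv_sd Population mean and sd of the slope.
#' @param beta_side_sd Population sd of the side bias (mean 0).
#' @param beta_rep_mean,beta_rep_sd Population mean and sd of the repeat bias.
#' @param tau Shared overall-uncertainty threshold (nats) or `NA`.
#' @param beta_int_mean,beta_int_sd Population mean and sd of the
#'   above-threshold slope change.
#' @param cor_dv_int Correlation between `beta_dv` and `|beta_int|` draws.
#' @param lapse Shared lapse probability.
#' @param deck_policy,eig_policy Shared policies; see [agent_params()].
#' @return A data frame with one row per participant, class
#'   `"agent_population"`.
#' @export
agent_population <- function(n, strategy = "uncertainty",
                             beta_dv_mean = 1, beta_dv_sd = 0.25,
                             beta_side_sd = 0.1,
                             beta_rep_mean = 0.5, beta_rep_sd = 0.2,
                             tau = NA_real_, beta_int_mean = NA_real_,
                             beta_int_sd = 0, cor_dv_int = 0,
                             lapse = 0.05,
                             deck_policy = "least", eig_policy = "max") {
  stopifnot(n >= 1)
  z1 <- stats::rnorm(n)
  beta_dv <- beta_dv_mean + beta_dv_sd * z1
  if (strategy == "random") beta_dv <- rep(0, n)
  if (!is.na(tau) && !is.na(beta_int_mean)) {
    z2 <- cor_dv_int * z1 + sqrt(1 - cor_dv_int^2) * stats::rnorm(n)
    mag <- abs(beta_int_mean) + beta_int_sd * z2
    mag[mag < 0] <- 0
    beta_int <- sign(beta_int_mean) * mag
  } else {
    beta_int <- rep(NA_real_, n)
  }
  out <- data.frame(
    participant = seq_len(n),
    strategy = strategy,
    beta_dv = beta_dv,
    beta_side = stats::rnorm(n, 0, beta_side_sd),
    beta_rep = stats::rnorm(n, beta_rep_mean, beta_rep_sd),
    tau = rep(tau, n),
    beta_int = beta_int,
    lapse = rep(lapse, n),
    deck_policy = deck_policy,
    eig_policy = eig_policy,
    stringsAsFactors = FALSE
  )
  class(out) <- c("agent_population", "data.frame")
  out
}

#' Probability of choosing the right-hand table
#'
#' The generative logistic choice rule. The linear predictor is
#' `beta_side + beta_rep * r + s(U) * delta`, where `r` is +1 when the right
#' table is the repeat option, -1 when the left is, 0 otherwise, and the
#' decision-variable slope `s(U)` equals `beta_dv` at or below the
#' overall-uncertainty threshold and `beta_dv + beta_int * (U - tau)` above
#' it (a continuous hinge). Lapses mix in a uniform choice:
#' `P = (1 - lapse) * logistic(eta) + lapse / 2`.
#'
#' @param agent An [agent_params()] object (or anything with the same fields).
#' @param delta_dv_scaled Decision-variable difference (right minus left),
#'   already on the calibrated scale.
#' @param overall_uncertainty Overall uncertainty of the pair, in nats.
#' @param repeat_side +1, -1 or 0 (right / left / no repeat option).
#' @return Probability of choosing the right table. Vectorized over the
#'   trial-level inputs.
#' @export
choice_probability <- function(agent, delta_dv_scaled,
                               overall_uncertainty = NA_real_,
                               repeat_side = 0) {
  s <- rep(agent$beta_dv, length.out = max(length(delta_dv_scaled),
                                           length(overall_uncertainty)))
  if (!is.null(agent$tau) && !is.na(agent$tau)) {
    above <- !is.na(overall_uncertainty) & overall_uncertainty > agent$tau
    s[above] <- agent$beta_dv +
      agent$beta_int * (overall_uncertainty[above] - agent$tau)
  }
  eta <- agent$beta_side + agent$beta_rep * repeat_side + s * delta_dv_scaled
  (1 - agent$lapse) * stats::plogis(eta) + agent$lapse / 2
}
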