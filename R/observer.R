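# Bayesian observer over a two-deck table: conjugate Beta-Bernoulli beliefs,
# posterior over theta = sgn(pi1 - pi2), entropy, expected information gain.

# Memoised P(pi1 > pi2) for integer-ish hyperparameters. The quadrature itself
# (adaptive Gauss-Kronrod via stats::integrate, abs.tol 1e-8) is the
# implementation; the cache only avoids recomputing identical belief states
# during long simulations. States with many observations are not cached to
# bound memory.
.ptheta_cache <- new.env(parent = emptyenv())
.ptheta_cache_max_obs <- 80L

.ptheta_raw <- function(a1, b1, a2, b2) {
  v <- stats::integrate(
    function(z) stats::dbeta(z, a1, b1) * stats::pbeta(z, a2, b2),
    lower = 0, upper = 1,
    abs.tol = 1e-8, rel.tol = 1e-10, subdivisions = 200L
  )$value
  if (v < 0) 0 else if (v > 1) 1 else v
}

.ptheta <- function(a1, b1, a2, b2) {
  if (a1 + b1 + a2 + b2 - 4 > .ptheta_cache_max_obs) {
    return(.ptheta_raw(a1, b1, a2, b2))
  }
  key <- paste(a1, b1, a2, b2)
  v <- .ptheta_cache[[key]]
  if (is.null(v)) {
    v <- .ptheta_raw(a1, b1, a2, b2)
    assign(key, v, envir = .ptheta_cache)
  }
  v
}

# Binary entropy in nats with the 0*log(0) := 0 convention.
.h2 <- function(p, base = exp(1)) {
  s <- 0
  if (p > 0 && p < 1) {
    q <- 1 - p
    s <- -(p * log(p, base = base) + q * log(q, base = base))
  }
  s
}

# Per-table summary used by the simulator: P(theta = 1), entropy H, and the
# two decks' expected information gains, all from raw counts (o = orange,
# n = total observed on that deck).
.table_stats <- function(o1, n1, o2, n2, with_eig = TRUE) {
  a1 <- o1 + 1; b1 <- n1 - o1 + 1
  a2 <- o2 + 1; b2 <- n2 - o2 + 1
  p <- .ptheta(a1, b1, a2, b2)
  h <- .h2(p)
  if (!with_eig) {
    return(c(p = p, h = h, eig1 = NA_real_, eig2 = NA_real_))
  }
  # deck 1: predictive P(orange) = a1 / (a1 + b1)
  p1 <- a1 / (a1 + b1)
  e1 <- h - (p1 * .h2(.ptheta(a1 + 1, b1, a2, b2)) +
             (1 - p1) * .h2(.ptheta(a1, b1 + 1, a2, b2)))
  p2 <- a2 / (a2 + b2)
  e2 <- h - (p2 * .h2(.ptheta(a1, b1, a2 + 1, b2)) +
             (1 - p2) * .h2(.ptheta(a1, b1, a2, b2 + 1)))
  # EIG is a mutual information, hence >= 0; clip quadrature jitter.
  if (e1 < 0) e1 <- 0
  if (e2 < 0) e2 <- 0
  c(p = p, h = h, eig1 = e1, eig2 = e2)
}

.aggregate_eig <- function(eig1, eig2, n1, n2, deck_policy) {
  switch(deck_policy,
    max   = max(eig1, eig2),
    mean  = (eig1 + eig2) / 2,
    least = if (n1 < n2) eig1 else if (n2 < n1) eig2 else (eig1 + eig2) / 2,
    stop("unknown deck policy: ", deck_policy)
  )
}

#' Belief about a single deck's orange-card proportion
#'
#' A conjugate Beta belief over the proportion of orange cards in one deck.
#' The flat `Beta(1, 1)` prior corresponds to a fresh, unobserved deck; after
#' observing `c` orange and `t - c` blue cards the posterior is
#' `Beta(1 + c, 1 + t - c)`.
#'
#' @param alpha,beta Beta pseudo-counts; both must be `>= 1` so that the
#'   observed card counts `alpha + beta - 2` are non-negative.
#' @return An object of class `"deck_belief"`.
#' @examples
#' b <- deck_belief()            # flat prior
#' update_belief(b, 1)           # one orange card -> Beta(2, 1)
#' @export
deck_belief <- function(alpha = 1, beta = 1) {
  if (!is.numeric(alpha) || !is.numeric(beta) || length(alpha) != 1L ||
      length(beta) != 1L || alpha < 1 || beta < 1) {
    stop("'alpha' and 'beta' must be scalar pseudo-counts >= 1")
  }
  structure(list(alpha = alpha, beta = beta), class = "deck_belief")
}

#' @export
print.deck_belief <- function(x, ...) {
  cat(sprintf("Deck belief: Beta(%g, %g), %g cards observed\n",
              x$alpha, x$beta, x$alpha + x$beta - 2))
  invisible(x)
}

#' Update a deck belief with one observed card
#'
#' Conjugate Beta-Bernoulli update: an orange card (coded 1) increments
#' `alpha`, a blue card (coded 0) increments `beta`. The input belief is not
#' modified (value semantics).
#'
#' @param belief A [deck_belief()].
#' @param color Observed card color, `1` (orange) or `0` (blue).
#' @return The updated `"deck_belief"`.
#' @export
update_belief <- function(belief, color) {
  stopifnot(inherits(belief, "deck_belief"))
  if (!length(color) == 1L || !color %in% c(0, 1)) {
    stop("'color' must be 0 (blue) or 1 (orange)")
  }
  if (color == 1) deck_belief(belief$alpha + 1, belief$beta) else
    deck_belief(belief$alpha, belief$beta + 1)
}

#' Belief state for one table (a pair of decks)
#'
#' Bundles the two decks' Beta beliefs. All table-level decision variables --
#' the posterior over `theta = sgn(pi1 - pi2)`, its entropy, expected
#' information gain and exposure -- are derived from this object.
#'
#' @param deck1,deck2 [deck_belief()] objects (default: flat priors).
#' @return An object of class `"table_belief"`.
#' @export
table_belief <- function(deck1 = deck_belief(), deck2 = deck_belief()) {
  stopifnot(inherits(deck1, "deck_belief"), inherits(deck2, "deck_belief"))
  structure(list(deck1 = deck1, deck2 = deck2), class = "table_belief")
}

#' @export
print.table_belief <- function(x, ...) {
  cat(sprintf(
    "Table belief: Beta(%g, %g) / Beta(%g, %g); P(theta = 1) = %.4f, H = %.4f nats\n",
    x$deck1$alpha, x$deck1$beta, x$deck2$alpha, x$deck2$beta,
    prob_theta_positive(x), entropy_theta(x)))
  invisible(x)
}

.tb_pars <- function(tb) {
  stopifnot(inherits(tb, "table_belief"))
  c(tb$deck1$alpha, tb$deck1$beta, tb$deck2$alpha, tb$deck2$beta)
}

#' Posterior probability that deck 1 is richer in orange
#'
#' Computes `P(theta = 1 | x) = P(pi1 > pi2)` by numerical integration of the
#' Beta density of deck 1 against the Beta distribution function of deck 2 on
#' the unit interval (adaptive Gauss-Kronrod quadrature, absolute tolerance
#' 1e-8). `P(theta = -1) = 1 - P(theta = 1)` since ties have measure zero.
#'
#' @param tb A [table_belief()].
#' @return Probability in `(0, 1)`.
#' @examples
#' prob_theta_positive(table_belief())                           # 0.5
#' prob_theta_positive(table_belief(deck_belief(2, 1)))          # 2/3
#' @export
prob_theta_positive <- function(tb) {
  p <- .tb_pars(tb)
  .ptheta(p[1], p[2], p[3], p[4])
}

#' Posterior uncertainty about theta (entropy)
#'
#' The entropy `H(theta | x) = -sum P log P` of the two-point posterior over
#' `theta`, in nats by default. It ranges from 0 (certainty about which deck
#' is richer) to `log(2)` (about 0.69 nats, i.e. one bit) for a table about
#' which nothing is known.
#'
#' @param tb A [table_belief()].
#' @param base Logarithm base; `exp(1)` gives nats (default), `2` gives bits.
#' @return Entropy, `>= 0`.
#' @export
entropy_theta <- function(tb, base = exp(1)) {
  .h2(prob_theta_positive(tb), base = base)
}

#' Expected information gain for a table
#'
#' The expected reduction in `theta`-uncertainty from observing one more card
#' on this table. For a given deck with predictive orange probability `p`,
#' `EIG = H(current) - [p * H(after orange) + (1 - p) * H(after blue)]`; this
#' is the mutual information between theta and the next card, hence
#' non-negative. The per-deck gains are aggregated into a table-level value
#' according to `deck_policy`: the deck the agent expects to learn most from
#' (`"max"`, default), the average deck (`"mean"`), or the deck sampled least
#' so far (`"least"`).
#'
#' @param tb A [table_belief()].
#' @param deck_policy One of `"max"`, `"mean"`, `"least"`.
#' @return Expected information gain in nats.
#' @examples
#' expected_information_gain(table_belief())  # log(2) - H(2/3), about 0.0566
#' @export
expected_information_gain <- function(tb, deck_policy = c("max", "mean", "least")) {
  deck_policy <- match.arg(deck_policy)
  p <- .tb_pars(tb)
  # .table_stats takes counts (orange, total observed) per deck
  st <- .table_stats(p[1] - 1, p[1] + p[2] - 2, p[3] - 1, p[3] + p[4] - 2)
  .aggregate_eig(st[["eig1"]], st[["eig2"]],
                 p[1] + p[2] - 2, p[3] + p[4] - 2, deck_policy)
}

#' Exposure: number of cards observed on a table
#'
#' @param tb A [table_belief()].
#' @return Total observed card count across the table's two decks.
#' @export
exposure <- function(tb) {
  p <- .tb_pars(tb)
  (p[1] + p[2] - 2) + (p[3] + p[4] - 2)
}

#' Signed decision-variable difference between two presented tables
#'
#' Returns `DV(right) - DV(left)` for the requested strategy's decision
#' variable: posterior entropy (`"uncertainty"`), expected information gain
#' (`"eig"`), or the novelty variable `-exposure` (`"exposure"`; higher for
#' the table with fewer previous observations, so that the least-exposure
#' heuristic predicts a positive effect on choice).
#'
#' @param left,right [table_belief()] objects for the left and right option.
#' @param kind One of `"eig"`, `"uncertainty"`, `"exposure"`.
#' @param deck_policy Passed to [expected_information_gain()] for `kind = "eig"`.
#' @return Signed scalar (nats for the entropy-based kinds, counts for exposure).
#' @export
delta_dv <- function(left, right, kind = c("uncertainty", "eig", "exposure"),
                     deck_policy = "max") {
  kind <- match.arg(kind)
  switch(kind,
    uncertainty = entropy_theta(right) - entropy_theta(left),
    eig = expected_information_gain(right, deck_policy) -
          expected_information_gain(left, deck_policy),
    exposure = -(exposure(right) - exposure(left))
  )
}

#' Overall uncertainty of a presented pair
#'
#' The sum of the two tables' posterior entropies, the trial-level measure of
#' decision difficulty. Ranges from 0 to `2 * log(2)` (about 1.386 nats).
#'
#' @param left,right [table_belief()] objects.
#' @return Overall uncertainty in nats.
#' @export
overall_uncertainty <- function(left, right) {
  entropy_theta(left) + entropy_theta(right)
}
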