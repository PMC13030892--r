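# Independent oracles used across the suite. These deliberately avoid the
# package's own quadrature/enumeration code paths.

# Closed-form P(X > Y) for X ~ Beta(a1, b1), Y ~ Beta(a2, b2) with integer
# parameters, via the finite sum
#   sum_{i=0}^{a1-1} B(a2 + i, b1 + b2) / [(b1 + i) B(1 + i, b1) B(a2, b2)]
# evaluated on the log scale.
oracle_pgt <- function(a1, b1, a2, b2) {
  i <- seq_len(a1) - 1
  sum(exp(lbeta(a2 + i, b1 + b2) - log(b1 + i) -
          lbeta(1 + i, b1) - lbeta(a2, b2)))
}

# Dense-grid midpoint (Riemann) evaluation of the defining integral.
oracle_riemann <- function(a1, b1, a2, b2, n = 1e5) {
  z <- (seq_len(n) - 0.5) / n
  mean(dbeta(z, a1, b1) * pbeta(z, a2, b2))
}

# Monte-Carlo estimate from paired Beta draws, with its standard error.
oracle_mc <- function(a1, b1, a2, b2, n = 1e6) {
  hit <- rbeta(n, a1, b1) > rbeta(n, a2, b2)
  p <- mean(hit)
  list(p = p, se = sqrt(p * (1 - p) / n))
}

# Binary entropy in nats, written independently of the package's guard.
oracle_h <- function(p) {
  terms <- c(p, 1 - p)
  terms <- terms[terms > 0]
  -sum(terms * log(terms))
}

# Two-outcome enumeration of a table's expected information gain for the
# deck given by (a, b) against the other deck (ao, bo), using the
# closed-form posterior probabilities.
oracle_eig_deck <- function(a, b, ao, bo) {
  h0 <- oracle_h(oracle_pgt(a, b, ao, bo))
  p_orange <- a / (a + b)
  h_orange <- oracle_h(oracle_pgt(a + 1, b, ao, bo))
  h_blue <- oracle_h(oracle_pgt(a, b + 1, ao, bo))
  h0 - (p_orange * h_orange + (1 - p_orange) * h_blue)
}

# Small-study task configuration used by the recovery-style tests:
# two sessions of one practice round plus three experimental rounds.
small_config <- function() {
  task_config(session_schedule = list(c(1L, 3L), c(1L, 3L)))
}
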