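# Bayesian observer: conjugate updating, the posterior over theta, entropy,
# expected information gain, exposure and the paired decision variables.

test_that("belief updates are conjugate and exchangeable", {
  b <- deck_belief()
  bo <- update_belief(b, 1)
  expect_equal(c(bo$alpha, bo$beta), c(2, 1))
  bb <- update_belief(b, 0)
  expect_equal(c(bb$alpha, bb$beta), c(1, 2))
  # value semantics: the prior is untouched
  expect_equal(c(b$alpha, b$beta), c(1, 1))
  # orange-then-blue equals blue-then-orange
  ob <- update_belief(update_belief(b, 1), 0)
  bo2 <- update_belief(update_belief(b, 0), 1)
  expect_equal(unclass(ob), unclass(bo2))
  expect_error(update_belief(b, 2), "color")
  expect_error(deck_belief(0.5, 1), "alpha")
})

test_that("posterior over theta matches closed forms and the sum oracle", {
  expect_equal(prob_theta_positive(table_belief()), 0.5, tolerance = 1e-8)
  expect_equal(prob_theta_positive(table_belief(deck_belief(2, 1))),
               2 / 3, tolerance = 1e-7)
  expect_equal(prob_theta_positive(
    table_belief(deck_belief(2, 1), deck_belief(1, 2))),
    5 / 6, tolerance = 1e-7)
  # seeded sweep against the independent finite-sum oracle
  set.seed(201)
  for (i in 1:100) {
    pars <- sample.int(15, 4, replace = TRUE)
    tb <- table_belief(deck_belief(pars[1], pars[2]),
                       deck_belief(pars[3], pars[4]))
    expect_equal(prob_theta_positive(tb), do.call(oracle_pgt, as.list(pars)),
                 tolerance = 1e-7)
  }
})

test_that("posterior respects deck-exchange and color-relabel symmetries", {
  set.seed(202)
  for (i in 1:25) {
    pars <- sample.int(20, 4, replace = TRUE)
    d1 <- deck_belief(pars[1], pars[2]); d2 <- deck_belief(pars[3], pars[4])
    p <- prob_theta_positive(table_belief(d1, d2))
    # swapping the decks flips theta
    expect_equal(prob_theta_positive(table_belief(d2, d1)), 1 - p,
                 tolerance = 1e-7)
    # relabeling colors on both decks flips theta too
    flip <- table_belief(deck_belief(pars[2], pars[1]),
                         deck_belief(pars[4], pars[3]))
    expect_equal(prob_theta_positive(flip), 1 - p, tolerance = 1e-7)
    # entropy is invariant under both
    expect_equal(entropy_theta(table_belief(d2, d1)),
                 entropy_theta(table_belief(d1, d2)), tolerance = 1e-7)
  }
})

test_that("entropy attains 0.69 nats (one bit) on a fresh table", {
  tb <- table_belief()
  expect_equal(round(entropy_theta(tb), 2), 0.69)
  expect_equal(entropy_theta(tb, base = 2), 1, tolerance = 1e-8)
  tb21 <- table_belief(deck_belief(2, 1))
  expect_equal(entropy_theta(tb21), oracle_h(2 / 3), tolerance = 1e-7)
  expect_equal(entropy_theta(tb21), 0.6365, tolerance = 1e-4)
  # bounds
  near <- table_belief(deck_belief(100, 1), deck_belief(1, 100))
  expect_gte(entropy_theta(near), 0)
  expect_lte(entropy_theta(tb), log(2) + 1e-12)
})

test_that("expected information gain matches enumeration and is non-negative", {
  tb <- table_belief()
  expect_equal(expected_information_gain(tb), log(2) - oracle_h(2 / 3),
               tolerance = 1e-7)
  near <- table_belief(deck_belief(100, 1), deck_belief(1, 100))
  expect_lt(expected_information_gain(near), 1e-3)
  # seeded sweep: per-deck EIG equals the two-outcome enumeration oracle
  set.seed(203)
  for (i in 1:40) {
    pars <- sample.int(20, 4, replace = TRUE)
    tb_i <- table_belief(deck_belief(pars[1], pars[2]),
                         deck_belief(pars[3], pars[4]))
    st <- cardexplore:::.table_stats(pars[1] - 1, pars[1] + pars[2] - 2,
                                     pars[3] - 1, pars[3] + pars[4] - 2)
    expect_gte(st[["eig1"]], 0)
    expect_gte(st[["eig2"]], 0)
    expect_equal(st[["eig1"]],
                 oracle_eig_deck(pars[1], pars[2], pars[3], pars[4]),
                 tolerance = 1e-6)
    expect_equal(st[["eig2"]],
                 oracle_eig_deck(pars[3], pars[4], pars[1], pars[2]),
                 tolerance = 1e-6)
  }
  # deck policies aggregate the per-deck gains as documented
  lop <- table_belief(deck_belief(5, 2), deck_belief(1, 1))
  e_max <- expected_information_gain(lop, "max")
  e_mean <- expected_information_gain(lop, "mean")
  e_least <- expected_information_gain(lop, "least")
  expect_gte(e_max, e_mean)
  st <- cardexplore:::.table_stats(4, 5, 0, 0)
  expect_equal(e_least, st[["eig2"]], tolerance = 1e-9)
})

test_that("exposure counts observed cards", {
  expect_equal(exposure(table_belief()), 0)
  expect_equal(exposure(table_belief(deck_belief(2, 1))), 1)
  b <- table_belief()
  set.seed(204)
  for (i in 1:17) {
    d <- sample(1:2, 1)
    if (d == 1) b$deck1 <- update_belief(b$deck1, rbinom(1, 1, 0.5))
    else b$deck2 <- update_belief(b$deck2, rbinom(1, 1, 0.5))
  }
  expect_equal(exposure(b), 17)
})

test_that("delta decision variables are antisymmetric and correctly signed", {
  fresh <- table_belief()
  seen <- table_belief(deck_belief(2, 1))
  for (kind in c("uncertainty", "eig", "exposure")) {
    expect_equal(delta_dv(fresh, fresh, kind), 0)
    expect_equal(delta_dv(fresh, seen, kind), -delta_dv(seen, fresh, kind),
                 tolerance = 1e-9)
  }
  expect_equal(delta_dv(fresh, seen, "uncertainty"),
               oracle_h(2 / 3) - log(2), tolerance = 1e-6)
  expect_equal(delta_dv(fresh, seen, "uncertainty"), -0.0566,
               tolerance = 1e-3)
  # novelty convention: the more-exposed right table has a negative delta
  expect_equal(delta_dv(fresh, seen, "exposure"), -1)
})

test_that("overall uncertainty sums the pair's entropies", {
  fresh <- table_belief()
  expect_equal(overall_uncertainty(fresh, fresh), 2 * log(2),
               tolerance = 1e-8)
  near <- table_belief(deck_belief(200, 1), deck_belief(1, 200))
  expect_lt(overall_uncertainty(near, near), 1e-3)
  seen <- table_belief(deck_belief(3, 2))
  expect_equal(overall_uncertainty(fresh, seen),
               overall_uncertainty(seen, fresh))
})

test_that("long observation of a lopsided table drives certainty", {
  # alternating-deck schedule, 200 cards per deck from pi1 = 0.8, pi2 = 0.2
  set.seed(205)
  c1 <- rbinom(200, 1, 0.8)
  c2 <- rbinom(200, 1, 0.2)
  d1 <- deck_belief(); d2 <- deck_belief()
  for (i in 1:200) {
    d1 <- update_belief(d1, c1[i])
    d2 <- update_belief(d2, c2[i])
  }
  tb <- table_belief(d1, d2)
  expect_gt(prob_theta_positive(tb), 0.999)
  expect_lt(entropy_theta(tb), 0.01)
})
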