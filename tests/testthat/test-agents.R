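# Agents and the dataset simulator: choice rule, round simulation,
# test phase, bookkeeping and reproducibility.

test_that("the choice rule evaluates the stated logistic form", {
  pure_random <- agent_params("random", lapse = 1, beta_rep = 0)
  expect_equal(choice_probability(pure_random, 3, 1.2, 1), 0.5)
  indiff <- agent_params("uncertainty", beta_dv = 1, beta_side = 0,
                         beta_rep = 0, lapse = 0)
  expect_equal(choice_probability(indiff, 0, 0.5, 0), 0.5)
  # hinge interaction worked example: logistic((1 - 40 * 0.1) * 0.5)
  hinged <- agent_params("uncertainty", beta_dv = 1, beta_side = 0,
                         beta_rep = 0, tau = 1.0, beta_int = -40, lapse = 0)
  expect_equal(choice_probability(hinged, 0.5, 1.1, 0), plogis(-1.5),
               tolerance = 1e-12)
  # below the threshold the slope is unchanged
  expect_equal(choice_probability(hinged, 0.5, 0.9, 0), plogis(0.5))
  # repeat bias and side bias enter additively
  biased <- agent_params("uncertainty", beta_dv = 0, beta_side = 0.3,
                         beta_rep = 0.5, lapse = 0)
  expect_equal(choice_probability(biased, 0, 1, -1), plogis(0.3 - 0.5))
})

test_that("agent parameter validation enforces the invariants", {
  expect_error(agent_params("uncertainty", lapse = 1.2), "lapse")
  expect_error(agent_params("uncertainty", tau = 2), "tau")
  expect_error(agent_params("uncertainty", tau = 0), "tau")
  expect_equal(agent_params("random", beta_dv = 3)$beta_dv, 0)
})

test_that("a near-greedy uncertainty agent picks the more uncertain table", {
  greedy <- agent_params("uncertainty", beta_dv = 200, beta_side = 0,
                         beta_rep = 0, lapse = 0)
  cfg <- task_config()
  set.seed(301)
  rd <- make_rounds(cfg, rep(60L, n_experimental_rounds(cfg)))[[2]]
  out <- simulate_round(greedy, rd, cfg)
  tr <- out$trials
  informative <- abs(tr$delta_uncertainty) > 1e-9
  chose_more_uncertain <- (tr$choice_right == 1) == (tr$delta_uncertainty > 0)
  expect_gte(mean(chose_more_uncertain[informative]), 0.99)
})

test_that("a full-lapse agent chooses sides at random", {
  rand <- agent_params("random", lapse = 1, beta_rep = 0)
  sim <- simulate_dataset(rand, config = task_config(
    session_schedule = list(c(0L, 4L))), n_participants = 50,
    seed = 302, dvs = "none")
  n <- nrow(sim$trials)
  expect_gt(n, 4000)
  expect_lt(abs(mean(sim$trials$choice_right) - 0.5), 4 * 0.5 / sqrt(n))
})

test_that("exposure is conserved and row counts match round lengths", {
  sim <- simulate_dataset(agent_params("uncertainty"), config = small_config(),
                          n_participants = 4, seed = 303, dvs = "all")
  tr <- sim$trials
  for (pid in unique(tr$participant)) {
    for (rid in unique(tr$round[tr$participant == pid])) {
      sub <- tr[tr$participant == pid & tr$round == rid, ]
      counts <- table(factor(sub$chosen_table, levels = 1:4))
      expect_equal(sum(counts), nrow(sub))
      # the recorded exposure delta on the last trial is consistent with
      # the running counts (novelty = minus the count difference)
      last <- sub[nrow(sub), ]
      prior <- sub[-nrow(sub), ]
      n_right <- sum(prior$chosen_table == last$right_table)
      n_left <- sum(prior$chosen_table == last$left_table)
      expect_equal(last$delta_exposure, -(n_right - n_left))
    }
  }
  # one test record per table per round
  expect_equal(nrow(sim$tests),
               4 * nrow(unique(tr[, c("participant", "round")])))
})

test_that("repeat-side coding marks the more recently chosen table", {
  sim <- simulate_dataset(agent_params("uncertainty", beta_rep = 1),
                          config = small_config(), n_participants = 2,
                          seed = 304, dvs = "uncertainty")
  tr <- sim$trials
  sub <- tr[tr$participant == 1 & tr$round == 2, ]
  last_seen <- integer(4)
  for (i in seq_len(nrow(sub))) {
    lt <- sub$left_table[i]; rt <- sub$right_table[i]
    expected_r <- if (last_seen[lt] == last_seen[rt]) 0 else
      if (last_seen[rt] > last_seen[lt]) 1 else -1
    expect_equal(sub$repeat_side[i], expected_r)
    last_seen[sub$chosen_table[i]] <- i
  }
})

test_that("datasets are reproducible and round-trip through CSV byte-identically", {
  cfg <- small_config()
  a <- simulate_dataset(agent_params("uncertainty"), config = cfg,
                        n_participants = 3, seed = 305)
  b <- simulate_dataset(agent_params("uncertainty"), config = cfg,
                        n_participants = 3, seed = 305)
  expect_identical(a$trials, b$trials)
  expect_identical(a$tests, b$tests)
  d1 <- file.path(tempdir(), "sim-a"); d2 <- file.path(tempdir(), "sim-b")
  write_sim(a, d1); write_sim(b, d2)
  for (f in c("trials.csv", "tests.csv", "agents.csv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  back <- read_sim(d1)
  expect_equal(back$trials, a$trials, tolerance = 1e-12)
  expect_equal(back$scaling, a$scaling)
  expect_identical(n_experimental_rounds(back$config),
                   n_experimental_rounds(cfg))
})

test_that("test phase: fresh tables sit at chance with minimal confidence", {
  fresh <- replicate(4, table_belief(), simplify = FALSE)
  set.seed(306)
  recs <- do.call(rbind, replicate(300, simulate_test_phase(
    fresh, theta_true = c(1, -1, 1, -1)), simplify = FALSE))
  expect_true(all(recs$confidence == 1))
  expect_true(all(recs$unsolvable == 1))
  expect_equal(unique(recs$p_max), 0.5)
  acc <- mean(recs$correct)
  expect_lt(abs(acc - 0.5), 4 * 0.5 / sqrt(nrow(recs)))
  # a decisive belief matching the truth is (almost) always correct
  sure <- list(table_belief(deck_belief(60, 5), deck_belief(5, 60)))
  rec <- simulate_test_phase(sure, theta_true = 1)
  expect_equal(rec$correct, 1L)
  expect_equal(rec$confidence, 5L)
  expect_equal(rec$unsolvable, 0L)
})

test_that("simulated accuracy is calibrated to the posterior", {
  # MAP choice under a calibrated posterior is correct with probability
  # equal to the maximum posterior probability; check in aggregate
  sim <- simulate_dataset(agent_params("uncertainty"), config = small_config(),
                          n_participants = 25, seed = 307, dvs = "uncertainty")
  te <- sim$tests[sim$tests$is_practice == 0, ]
  expect_gt(nrow(te), 500)
  dev <- mean(te$correct) - mean(te$p_max)
  se <- sd(te$correct - te$p_max) / sqrt(nrow(te))
  expect_lt(abs(dev), 4 * se)
})

test_that("invalid simulator configurations are rejected", {
  expect_error(simulate_dataset(agent_params("uncertainty"),
                                config = small_config(), n_participants = 1,
                                seed = 1, dvs = "none"), "random")
  expect_error(simulate_dataset(agent_params("eig"),
                                config = small_config(), n_participants = 1,
                                seed = 1, dvs = "uncertainty"), "EIG")
  expect_error(simulate_dataset(agent_params("uncertainty"),
                                config = small_config()), "n_participants")
})
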