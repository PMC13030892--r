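# Piecewise threshold model: profile search, avoidance score, individual
# differences.

test_that("the avoidance score evaluates the triangular area", {
  f0 <- list(tau_hat = 1.0, beta_int = 0)
  expect_equal(avoidance_score(f0)$area, 0)
  f1 <- list(tau_hat = 1.0, beta_int = -40)
  expect_equal(avoidance_score(f1)$area, 0.5 * 40 * (2 * log(2) - 1)^2,
               tolerance = 1e-12)
  expect_equal(avoidance_score(f1)$area, 2.984, tolerance = 1e-3)
  f2 <- list(tau_hat = 1.0, beta_int = -80)
  expect_equal(avoidance_score(f2)$area, 2 * avoidance_score(f1)$area)
  # positive interaction or threshold beyond the bound give zero area
  expect_equal(avoidance_score(list(tau_hat = 1.0, beta_int = 5))$area, 0)
  expect_equal(avoidance_score(list(tau_hat = 1.5, beta_int = -40),
                               u_max = 1.2)$area, 0)
})

test_that("fraction above threshold respects the entropy bounds", {
  sim <- simulate_dataset(agent_params("uncertainty"), config = small_config(),
                          n_participants = 6, seed = 501, dvs = "uncertainty")
  des <- prepare_predictors(sim)
  expect_equal(fraction_above_threshold(des, 0), 1.0)
  expect_equal(fraction_above_threshold(des, 2 * log(2)), 0.0)
  q80 <- quantile(des$u, 0.8, names = FALSE)
  expect_equal(fraction_above_threshold(des, q80), 0.2, tolerance = 0.01)
})

test_that("threshold and interaction sign are recovered from hinge data", {
  ag <- agent_population(40, "uncertainty", beta_dv_mean = 1, beta_dv_sd = 0.2,
                         tau = 1.0, beta_int_mean = -40)
  sim <- simulate_dataset(ag, config = task_config(
    session_schedule = list(c(1L, 5L), c(1L, 5L))), seed = 502,
    dvs = "uncertainty")
  des <- prepare_predictors(sim)
  pw <- fit_piecewise(des)
  expect_lt(abs(pw$tau_hat - 1.0), pw$grid_step + 2 * pw$tau_se + 0.02)
  expect_lt(pw$beta_int, 0)
  expect_gt(abs(pw$beta_int) , 2 * pw$se[["beta_int"]])
  expect_gt(pw$beta_low, 0)
  # the profile maximum is attained at tau_hat
  expect_equal(pw$profile$tau[which.max(pw$profile$ploglik)], pw$tau_hat)
  # binned empirical slopes flip sign across the threshold, as the fit says
  below <- des$u <= pw$tau_hat
  slope_emp <- function(sub) {
    coef(glm(y ~ du + r, data = sub, family = binomial()))[["du"]]
  }
  expect_gt(slope_emp(des[below, ]), 0)
  expect_lt(slope_emp(des[des$u > quantile(des$u, 0.85), ]), 0)
})

test_that("thresholdless data yield a null interaction (nested model check)", {
  ag <- agent_population(25, "uncertainty", beta_dv_mean = 1, beta_dv_sd = 0.2)
  sim <- simulate_dataset(ag, config = small_config(), seed = 503,
                          dvs = "uncertainty")
  des <- prepare_predictors(sim)
  pw <- fit_piecewise(des)
  expect_lt(abs(pw$beta_int), 3 * pw$se[["beta_int"]])
  # nesting: the profiled model cannot do worse than the no-threshold model
  X3 <- cbind(1, des$r, des$du)
  f3 <- cardexplore:::.ridge_logit(X3, des$y, lambda = 1)
  expect_gte(max(pw$profile$ploglik), f3$ploglik - 1e-8)
})

test_that("the fit and avoidance score are invariant to a left/right flip", {
  ag <- agent_population(20, "uncertainty", beta_dv_mean = 1,
                         tau = 0.9, beta_int_mean = -30)
  sim <- simulate_dataset(ag, config = small_config(), seed = 504,
                          dvs = "uncertainty")
  des <- prepare_predictors(sim)
  flipped <- des
  flipped$du <- -des$du
  flipped$r <- -des$r
  flipped$y <- 1L - des$y
  grid <- seq(0.5, 1.3, by = 0.01)
  a <- fit_piecewise(des, tau_grid = grid)
  b <- fit_piecewise(flipped, tau_grid = grid)
  expect_equal(a$tau_hat, b$tau_hat)
  expect_equal(a$beta_low, b$beta_low, tolerance = 1e-6)
  expect_equal(a$beta_int, b$beta_int, tolerance = 1e-4)
  expect_equal(a$beta_side, -b$beta_side, tolerance = 1e-6)
  expect_equal(avoidance_score(a)$area, avoidance_score(b)$area,
               tolerance = 1e-4)
})

test_that("piecewise fit methods behave like a classed model object", {
  ag <- agent_population(10, "uncertainty", beta_dv_mean = 1,
                         tau = 1.0, beta_int_mean = -30)
  sim <- simulate_dataset(ag, config = small_config(), seed = 505,
                          dvs = "uncertainty")
  des <- prepare_predictors(sim)
  pw <- fit_piecewise(des, tau_grid = seq(0.6, 1.3, by = 0.02))
  expect_s3_class(pw, "piecewise_fit")
  co <- coef(pw)
  expect_named(co, c("side", "repeat_option", "beta_low", "beta_int", "tau"))
  p <- predict(pw)
  expect_true(all(p > 0 & p < 1))
  # predictions discriminate: higher predicted probability for chosen-right
  expect_gt(mean(p[pw$data$y == 1]), mean(p[pw$data$y == 0]))
  r <- residuals(pw)
  expect_equal(length(r), pw$n_trials)
  s <- simulate(pw, nsim = 2, seed = 1)
  expect_equal(dim(s), c(pw$n_trials, 2L))
  expect_true(all(unlist(s) %in% 0:1))
  expect_output(print(pw), "threshold tau")
  expect_output(print(summary(pw)), "avoidance")
  ll <- logLik(pw)
  expect_lte(as.numeric(ll), 0)
})

test_that("correlated approach and avoidance tendencies are recovered", {
  ag <- agent_population(60, "uncertainty", beta_dv_mean = 1.2,
                         beta_dv_sd = 0.4, tau = 0.9,
                         beta_int_mean = -35, beta_int_sd = 15,
                         cor_dv_int = 0.5, lapse = 0.02)
  sim <- simulate_dataset(ag, config = task_config(
    session_schedule = list(c(0L, 4L), c(0L, 4L))), seed = 506,
    dvs = "uncertainty")
  des <- prepare_predictors(sim)
  aa <- approach_avoid_individuals(des, tau_grid = seq(0.5, 1.3, by = 0.02),
                                   n_perm = 499, seed = 506)
  expect_gt(aa$correlation, 0)
  expect_lt(abs(aa$correlation - 0.5), 0.25)
  expect_lt(aa$p_value, 0.05)
  expect_true(all(aa$participants$avoidance >= 0))
  aa2 <- approach_avoid_individuals(des, tau_grid = seq(0.5, 1.3, by = 0.02),
                                    n_perm = 499, seed = 506)
  expect_identical(aa$participants, aa2$participants)
  # an uncorrelated population stays inside the permutation null band
  ag0 <- agent_population(40, "uncertainty", beta_dv_mean = 1.2,
                          beta_dv_sd = 0.4, tau = 0.9,
                          beta_int_mean = -35, beta_int_sd = 15,
                          cor_dv_int = 0, lapse = 0.02)
  sim0 <- simulate_dataset(ag0, config = task_config(
    session_schedule = list(c(0L, 4L))), seed = 507, dvs = "uncertainty")
  aa0 <- approach_avoid_individuals(prepare_predictors(sim0),
                                    tau_grid = seq(0.5, 1.3, by = 0.02),
                                    n_perm = 499, seed = 507)
  expect_gt(aa0$p_value, 0.05)
})
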