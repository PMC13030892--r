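# Simulation of complete task datasets: exploration trials driven by the
# Bayesian observer plus the agent's choice rule, and the end-of-round test
# phase.

.trial_cols <- c("participant", "session", "round", "trial", "is_practice",
                 "left_table", "right_table", "delta_eig", "delta_uncertainty",
                 "delta_exposure", "overall_uncertainty", "repeat_side",
                 "choice_right", "chosen_table", "chosen_deck",
                 "observed_color")

.test_cols <- c("participant", "session", "round", "is_practice", "table",
                "entropy", "p_max", "chosen_deck", "correct", "confidence",
                "unsolvable", "theta_true")

.dv_levels <- c(none = 0L, uncertainty = 1L, all = 2L)

# Workhorse: one exploration round for one agent. `ag` is a plain list with
# numeric fields (strategy_code 1 eig / 2 uncertainty / 3 exposure /
# 4 random). Returns the trial matrix and the final per-deck counts.
.sim_round <- function(ag, round, config, scaling, dv_level, participant_id) {
  nt <- config$n_tables
  L <- round$length
  truth <- round$truth
  with_h <- dv_level >= 1L
  with_eig <- dv_level >= 2L

  oc1 <- integer(nt); oc2 <- integer(nt)   # orange counts per deck
  nn1 <- integer(nt); nn2 <- integer(nt)   # total counts per deck
  nx <- integer(nt)
  last <- integer(nt)                      # trial of last choice (0 = never)

  ln2 <- log(2)
  eig_fresh <- ln2 - .h2(2 / 3)
  H <- rep(ln2, nt)
  E1 <- rep(eig_fresh, nt); E2 <- rep(eig_fresh, nt)
  EIGt <- rep(eig_fresh, nt)

  has_tau <- !is.na(ag$tau)
  scode <- ag$strategy_code
  dv_scale <- switch(scode, scaling[["eig"]], scaling[["uncertainty"]],
                     scaling[["exposure"]], 1)
  one_m_lapse <- 1 - ag$lapse
  half_lapse <- ag$lapse / 2
  policy <- ag$deck_policy
  eigpol <- ag$eig_policy

  M <- matrix(NA_real_, L, length(.trial_cols))

  for (t in seq_len(L)) {
    pr <- sample.int(nt, 2L)
    lt <- pr[1]; rt <- pr[2]

    dx <- -(nx[rt] - nx[lt])
    if (with_h) {
      du <- H[rt] - H[lt]
      U <- H[rt] + H[lt]
    } else {
      du <- NA_real_; U <- NA_real_
    }
    de <- if (with_eig) EIGt[rt] - EIGt[lt] else NA_real_
    rs <- if (last[rt] == last[lt]) 0 else if (last[rt] > last[lt]) 1 else -1

    dv <- switch(scode, de, du, dx, 0) / dv_scale
    s_dv <- ag$beta_dv
    if (has_tau && U > ag$tau) s_dv <- s_dv + ag$beta_int * (U - ag$tau)
    eta <- ag$beta_side + ag$beta_rep * rs + s_dv * dv
    p_right <- one_m_lapse / (1 + exp(-eta)) + half_lapse
    right <- stats::runif(1) < p_right
    ct <- if (right) rt else lt

    # deck choice on the chosen table
    deck <- switch(policy,
      least = if (nn1[ct] < nn2[ct]) 1L else if (nn2[ct] < nn1[ct]) 2L
              else sample.int(2L, 1L),
      max = if (!with_eig || E1[ct] == E2[ct]) sample.int(2L, 1L)
            else if (E1[ct] > E2[ct]) 1L else 2L,
      mean = sample.int(2L, 1L)
    )

    col <- if (stats::runif(1) < truth[ct, deck]) 1L else 0L
    if (deck == 1L) {
      oc1[ct] <- oc1[ct] + col; nn1[ct] <- nn1[ct] + 1L
    } else {
      oc2[ct] <- oc2[ct] + col; nn2[ct] <- nn2[ct] + 1L
    }
    nx[ct] <- nx[ct] + 1L
    last[ct] <- t

    if (with_h) {
      st <- .table_stats(oc1[ct], nn1[ct], oc2[ct], nn2[ct],
                         with_eig = with_eig)
      H[ct] <- st[[2]]
      if (with_eig) {
        E1[ct] <- st[[3]]; E2[ct] <- st[[4]]
        EIGt[ct] <- .aggregate_eig(st[[3]], st[[4]], nn1[ct], nn2[ct], eigpol)
      }
    }

    M[t, ] <- c(participant_id, round$session, round$round,
                t, round$is_practice, lt, rt, de, du, dx, U, rs,
                right, ct, deck, col)
  }

  list(trials = M, oc1 = oc1, nn1 = nn1, oc2 = oc2, nn2 = nn2)
}

# End-of-round test phase from final deck counts. MAP deck choice under the
# observer's posterior (random tie-break at P = 0.5): with a calibrated
# posterior this makes the probability of a correct answer equal to the
# maximum posterior probability, reproducing chance-level accuracy at
# maximal uncertainty. Confidence is the equal-width bin of the maximum
# posterior probability on [0.5, 1] into 1..5.
.sim_test <- function(state, round, participant_id) {
  nt <- length(state$nx <- state$nn1 + state$nn2)
  out <- matrix(NA_real_, nt, length(.test_cols))
  for (tb in seq_len(nt)) {
    p <- .ptheta(state$oc1[tb] + 1, state$nn1[tb] - state$oc1[tb] + 1,
                 state$oc2[tb] + 1, state$nn2[tb] - state$oc2[tb] + 1)
    pmax <- max(p, 1 - p)
    map <- if (p > 0.5) 1 else if (p < 0.5) -1 else
      (if (stats::runif(1) < 0.5) 1 else -1)
    chosen_deck <- if (map == 1) 1L else 2L
    correct <- as.integer(map == round$theta[tb])
    conf <- min(5L, 1L + floor((pmax - 0.5) * 10))
    unsolv <- as.integer(state$nn1[tb] == 0L || state$nn2[tb] == 0L)
    out[tb, ] <- c(participant_id, round$session, round$round,
                   round$is_practice, tb, .h2(p), pmax, chosen_deck,
                   correct, conf, unsolv, round$theta[tb])
  }
  out
}

#' Simulate the test phase from end-of-round beliefs
#'
#' For every table, the simulated participant picks the deck favored by the
#' maximum-a-posteriori belief about `theta` (random tie-break when the
#' posterior is flat). Because the observer's posterior is calibrated, the
#' probability of a correct answer equals the maximum posterior probability,
#' so accuracy falls to chance as end-of-round entropy approaches its
#' maximum without any extra noise parameter. Confidence is the equal-width
#' bin of the maximum posterior probability on `[0.5, 1]` into
#' `1:conf_levels`.
#'
#' @param beliefs List of [table_belief()] objects, one per table.
#' @param theta_true Integer vector in {-1, +1}: the true sign of
#'   `pi1 - pi2` per table.
#' @param conf_levels Number of confidence levels (default 5).
#' @return A data frame with one row per table: `table`, `entropy`,
#'   `p_max`, `chosen_deck`, `correct`, `confidence`, `unsolvable`.
#' @export
simulate_test_phase <- function(beliefs, theta_true, conf_levels = 5L) {
  stopifnot(length(beliefs) == length(theta_true),
            all(theta_true %in% c(-1, 1)))
  out <- do.call(rbind, lapply(seq_along(beliefs), function(tb) {
    b <- beliefs[[tb]]
    stopifnot(inherits(b, "table_belief"))
    p <- prob_theta_positive(b)
    pmax_ <- max(p, 1 - p)
    map <- if (p > 0.5) 1 else if (p < 0.5) -1 else
      (if (stats::runif(1) < 0.5) 1 else -1)
    data.frame(
      table = tb, entropy = .h2(p), p_max = pmax_,
      chosen_deck = if (map == 1) 1L else 2L,
      correct = as.integer(map == theta_true[tb]),
      confidence = min(conf_levels,
                       1L + floor((pmax_ - 0.5) * 2 * conf_levels)),
      unsolvable = as.integer(b$deck1$alpha + b$deck1$beta == 2 ||
                              b$deck2$alpha + b$deck2$beta == 2))
  }))
  out
}

.agent_row_to_list <- function(row) {
  list(strategy = row$strategy,
       strategy_code = match(row$strategy, .strategies),
       beta_dv = row$beta_dv, beta_side = row$beta_side,
       beta_rep = row$beta_rep, tau = row$tau, beta_int = row$beta_int,
       lapse = row$lapse, deck_policy = row$deck_policy,
       eig_policy = row$eig_policy)
}

#' Simulate one exploration round
#'
#' Runs a single agent through one round: on every trial a random pair of
#' tables is presented, the decision variables are computed from the current
#' Bayesian-observer beliefs, the choice is drawn from the logistic choice
#' rule, a deck is picked, a card is drawn from the true proportion and the
#' chosen deck's belief is updated.
#'
#' @param agent An [agent_params()] object.
#' @param round A round descriptor from [make_rounds()].
#' @param config A [task_config()].
#' @param scaling Named vector of decision-variable calibration constants.
#' @param dvs Which decision variables to record: `"all"`, `"uncertainty"`
#'   (entropy-based only, skipping expected information gain) or `"none"`.
#' @return A list with `trials` (data frame of the round's trials) and
#'   `tests` (data frame of the end-of-round test records).
#' @export
simulate_round <- function(agent, round, config = task_config(),
                           scaling = .dv_scale_default,
                           dvs = c("all", "uncertainty", "none")) {
  dvs <- match.arg(dvs)
  stopifnot(inherits(agent, "agent_params"))
  if (nrow(round$truth) != config$n_tables) {
    stop("round truth does not match the configured number of tables")
  }
  ag <- agent
  ag$strategy_code <- match(ag$strategy, .strategies)
  res <- .sim_round(ag, round, config, scaling, .dv_levels[[dvs]], 1L)
  trials <- as.data.frame(res$trials)
  names(trials) <- .trial_cols
  tests <- as.data.frame(.sim_test(res, round, 1L))
  names(tests) <- .test_cols
  list(trials = trials, tests = tests)
}

#' Simulate a complete multi-participant dataset
#'
#' Generates the full study structure for a population of agents: for every
#' participant, practice and experimental rounds per the session schedule,
#' with the same list of experimental round lengths used for all
#' participants in per-participant random order, followed by a test phase
#' after each round. Practice rounds are simulated and flagged so analyses
#' can exclude them.
#'
#' @param agents An `agent_population` data frame (one row per participant),
#'   or a single [agent_params()] plus `n_participants`.
#' @param config A [task_config()]. Use the `session_schedule` to control
#'   the number of rounds (default: the four-session study schedule).
#' @param n_participants Number of participants when `agents` is a single
#'   [agent_params()].
#' @param seed Integer seed for full reproducibility.
#' @param dvs Decision variables to record; `"uncertainty"` skips the
#'   expensive expected-information-gain bookkeeping, `"none"` records no
#'   belief-based variables (random agents only).
#' @param scaling Decision-variable calibration constants stored with the
#'   dataset and shared between generation and fitting.
#' @return An object of class `"explore_sim"`: a list with data frames
#'   `trials`, `tests`, `agents`, plus `scaling`, `config` and `seed`.
#' @examples
#' sim <- simulate_dataset(agent_params("uncertainty"),
#'                         config = task_config(session_schedule = list(c(1, 2))),
#'                         n_participants = 3, seed = 1)
#' sim
#' @export
simulate_dataset <- function(agents, config = task_config(),
                             n_participants = NULL, seed = NULL,
                             dvs = c("all", "uncertainty", "none"),
                             scaling = .dv_scale_default) {
  dvs <- match.arg(dvs)
  dv_level <- .dv_levels[[dvs]]
  if (inherits(agents, "agent_params")) {
    if (is.null(n_participants)) {
      stop("give 'n_participants' when 'agents' is a single agent_params")
    }
    agents <- do.call(rbind, lapply(seq_len(n_participants), function(i) {
      d <- as.data.frame(unclass(agents), stringsAsFactors = FALSE)
      d$participant <- i
      d
    }))
  }
  if (!nrow(agents)) stop("empty agent specification")
  if (is.null(agents$participant)) agents$participant <- seq_len(nrow(agents))
  if (!is.null(seed)) set.seed(seed)

  if (dv_level == 0L &&
      (any(agents$strategy != "random") || any(!is.na(agents$tau)))) {
    stop("dvs = \"none\" is only valid for threshold-free random agents")
  }
  if (dv_level == 1L && any(agents$strategy == "eig")) {
    stop("dvs = \"uncertainty\" cannot drive EIG-strategy agents")
  }

  n_exp <- n_experimental_rounds(config)
  shared_lengths <- sample_round_length(n_exp, config$geometric_rate,
                                        config$geometric_shift)

  tr_list <- vector("list", nrow(agents))
  te_list <- vector("list", nrow(agents))
  for (i in seq_len(nrow(agents))) {
    ag <- .agent_row_to_list(agents[i, ])
    rounds <- make_rounds(config, shared_lengths)
    pid <- agents$participant[i]
    tm <- vector("list", length(rounds))
    sm <- vector("list", length(rounds))
    for (k in seq_along(rounds)) {
      res <- .sim_round(ag, rounds[[k]], config, scaling, dv_level, pid)
      tm[[k]] <- res$trials
      sm[[k]] <- .sim_test(res, rounds[[k]], pid)
    }
    tr_list[[i]] <- do.call(rbind, tm)
    te_list[[i]] <- do.call(rbind, sm)
  }
  trials <- as.data.frame(do.call(rbind, tr_list))
  names(trials) <- .trial_cols
  tests <- as.data.frame(do.call(rbind, te_list))
  names(tests) <- .test_cols

  structure(list(trials = trials, tests = tests,
                 agents = as.data.frame(agents), scaling = scaling,
                 config = config, seed = seed, dvs = dvs),
            class = "explore_sim")
}

#' @export
print.explore_sim <- function(x, ...) {
  cat("Simulated exploration dataset\n")
  cat(sprintf("  %d participants, %d rounds, %d exploration trials (%d practice)\n",
              length(unique(x$trials$participant)),
              nrow(unique(x$trials[, c("participant", "round")])),
              nrow(x$trials), sum(x$trials$is_practice)))
  cat(sprintf("  %d test records; strategies: %s\n", nrow(x$tests),
              paste(unique(x$agents$strategy), collapse = ", ")))
  invisible(x)
}

#' Write / read a simulated dataset as plain CSV + YAML
#'
#' Persists the tidy trial-level and test-level tables with a stable column
#' order, the agent table, and a small YAML metadata file carrying the
#' scaling constants and the task configuration.
#'
#' @param sim An `"explore_sim"` object.
#' @param dir Output directory (created if missing).
#' @return `write_sim` returns `dir` invisibly; `read_sim` returns the
#'   reassembled `"explore_sim"` object.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "explore_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  utils::write.csv(sim$tests, file.path(dir, "tests.csv"), row.names = FALSE)
  utils::write.csv(sim$agents, file.path(dir, "agents.csv"), row.names = FALSE)
  cfg <- sim$config
  meta <- list(scaling = as.list(sim$scaling),
               seed = sim$seed, dvs = sim$dvs,
               config = list(
                 n_tables = cfg$n_tables,
                 n_decks_per_table = cfg$n_decks_per_table,
                 geometric_rate = cfg$geometric_rate,
                 geometric_shift = cfg$geometric_shift,
                 session_schedule = lapply(cfg$session_schedule, as.integer),
                 reward_per_correct = cfg$reward_per_correct,
                 proportion_grid = cfg$proportion_grid,
                 practice_length_range = cfg$practice_length_range))
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname write_sim
#' @export
read_sim <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  cfg <- do.call(task_config, meta$config)
  structure(list(
    trials = utils::read.csv(file.path(dir, "trials.csv")),
    tests = utils::read.csv(file.path(dir, "tests.csv")),
    agents = utils::read.csv(file.path(dir, "agents.csv"),
                             stringsAsFactors = FALSE),
    scaling = unlist(meta$scaling),
    config = cfg, seed = meta$seed, dvs = meta$dvs
  ), class = "explore_sim")
}
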