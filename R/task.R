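# Task environment: configuration, round structure, pair presentation and
# card draws for the two-deck exploration task.

#' Task configuration
#'
#' Parameters of the card-exploration environment: four tables of two decks
#' each, exploration-phase lengths drawn from a geometric distribution with
#' rate 1/44 shifted by 10 trials (so a test is equally likely after any
#' trial past the tenth), and a session schedule of one practice round plus
#' 3/5/5/5 experimental rounds across four sessions (18 experimental rounds,
#' 22 rounds in total). True deck proportions live on a grid of tenths so
#' that they can be revealed as ten open cards at feedback.
#'
#' @param n_tables Number of tables (at least 2).
#' @param n_decks_per_table Number of decks per table (the analysis assumes 2).
#' @param geometric_rate Per-trial stopping hazard after the shift, in (0, 1).
#' @param geometric_shift Number of initial trials with no stopping hazard.
#' @param session_schedule List of `c(practice, experimental)` round counts
#'   per session.
#' @param reward_per_correct Payout per correct test choice, in dollars.
#' @param proportion_grid Admissible true orange proportions.
#' @param practice_length_range Range of practice-round lengths (trials).
#' @return An object of class `"task_config"`.
#' @examples
#' cfg <- task_config()
#' n_experimental_rounds(cfg)  # 18
#' @export
task_config <- function(n_tables = 4L,
                        n_decks_per_table = 2L,
                        geometric_rate = 1 / 44,
                        geometric_shift = 10L,
                        session_schedule = list(c(1L, 3L), c(1L, 5L),
                                                c(1L, 5L), c(1L, 5L)),
                        reward_per_correct = 0.25,
                        proportion_grid = seq(0.1, 0.9, by = 0.1),
                        practice_length_range = c(12L, 19L)) {
  if (!is.numeric(geometric_rate) || geometric_rate <= 0 || geometric_rate >= 1) {
    stop("'geometric_rate' must lie strictly between 0 and 1")
  }
  if (geometric_shift < 0) stop("'geometric_shift' must be >= 0")
  if (n_tables < 2) stop("'n_tables' must be >= 2")
  if (!length(proportion_grid) || any(proportion_grid <= 0 | proportion_grid >= 1)) {
    stop("'proportion_grid' values must lie strictly between 0 and 1")
  }
  if (!is.list(session_schedule) ||
      !all(vapply(session_schedule, length, 1L) == 2L)) {
    stop("'session_schedule' must be a list of c(practice, experimental) pairs")
  }
  structure(list(
    n_tables = as.integer(n_tables),
    n_decks_per_table = as.integer(n_decks_per_table),
    geometric_rate = geometric_rate,
    geometric_shift = as.integer(geometric_shift),
    session_schedule = lapply(session_schedule, as.integer),
    reward_per_correct = reward_per_correct,
    proportion_grid = proportion_grid,
    practice_length_range = as.integer(practice_length_range)
  ), class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat("Task configuration\n")
  cat(sprintf("  tables: %d x %d decks\n", x$n_tables, x$n_decks_per_table))
  cat(sprintf("  round length: %d + Geometric(%.4g) trials (mean %.1f)\n",
              x$geometric_shift, x$geometric_rate,
              x$geometric_shift + 1 / x$geometric_rate))
  cat(sprintf("  sessions: %s (%d experimental rounds)\n",
              paste(vapply(x$session_schedule,
                           function(s) sprintf("%d+%d", s[1], s[2]), ""),
                    collapse = ", "),
              n_experimental_rounds(x)))
  cat(sprintf("  true proportions on {%s}\n",
              paste(format(x$proportion_grid), collapse = ", ")))
  invisible(x)
}

#' Number of experimental (non-practice) rounds in a schedule
#'
#' @param config A [task_config()].
#' @return Integer count of experimental rounds across all sessions.
#' @export
n_experimental_rounds <- function(config = task_config()) {
  sum(vapply(config$session_schedule, function(s) s[2], 1L))
}

#' Sample exploration-phase lengths
#'
#' Draws round lengths `L = shift + G`, with `G` geometric on {1, 2, ...}
#' with success probability `rate`: the test is impossible during the first
#' `shift` trials and equally likely to follow any trial after them
#' (constant hazard). The minimum length is `shift + 1` and the mean is
#' `shift + 1 / rate` (54 trials under the defaults).
#'
#' @param n Number of lengths to draw.
#' @param rate Geometric success probability in (0, 1).
#' @param shift Hazard-free initial trial count, `>= 0`.
#' @return Integer vector of `n` round lengths.
#' @export
sample_round_length <- function(n = 1L, rate = 1 / 44, shift = 10L) {
  if (!is.numeric(rate) || rate <= 0 || rate >= 1) {
    stop("'rate' must lie strictly between 0 and 1")
  }
  if (shift < 0) stop("'shift' must be >= 0")
  as.integer(shift) + 1L + stats::rgeom(n, prob = rate)
}

#' Sample true deck proportions for every table
#'
#' Each deck's true orange proportion is drawn uniformly from the
#' configuration's proportion grid, resampling within a table until the two
#' decks differ (so that `theta = sgn(pi1 - pi2)` is defined).
#'
#' @param config A [task_config()].
#' @return A matrix with one row per table and columns `pi1`, `pi2`.
#' @export
sample_true_proportions <- function(config = task_config()) {
  grid <- config$proportion_grid
  if (length(unique(grid)) < 2L) {
    stop("'proportion_grid' needs at least two distinct values to keep pi1 != pi2")
  }
  k <- length(grid)
  nt <- config$n_tables
  p1 <- grid[sample.int(k, nt, replace = TRUE)]
  p2 <- grid[sample.int(k, nt, replace = TRUE)]
  while (any(tie <- p1 == p2)) {
    p2[tie] <- grid[sample.int(k, sum(tie), replace = TRUE)]
  }
  cbind(pi1 = p1, pi2 = p2)
}

#' Present a random pair of tables
#'
#' Draws an unordered pair uniformly from all `choose(n_tables, 2)` pairs and
#' assigns the left/right sides uniformly at random.
#'
#' @param n_tables Number of tables, `>= 2`.
#' @return Integer vector `c(left, right)` with distinct table ids.
#' @export
present_pair <- function(n_tables = 4L) {
  if (n_tables < 2) stop("'n_tables' must be >= 2")
  pr <- sample.int(n_tables, 2L)
  c(left = pr[1], right = pr[2])
}

#' Draw one card from a deck
#'
#' Bernoulli draw of a card color with orange coded 1 and blue coded 0.
#'
#' @param pi True orange proportion, strictly between 0 and 1.
#' @param n Number of cards to draw.
#' @return Integer vector of colors in {0, 1}.
#' @export
draw_card <- function(pi, n = 1L) {
  if (!is.numeric(pi) || length(pi) != 1L || pi <= 0 || pi >= 1) {
    stop("'pi' must lie strictly between 0 and 1")
  }
  as.integer(stats::runif(n) < pi)
}

# Color-pair labels for rounds (cosmetic plumbing; unique pair per round).
.color_palette <- c("orange", "blue", "red", "green", "purple", "yellow",
                    "teal", "pink", "brown", "navy", "olive", "maroon")

.color_pair <- function(i) {
  k <- length(.color_palette)
  a <- ((i - 1L) %% k) + 1L
  b <- (a %% k) + 1L
  paste(.color_palette[a], .color_palette[b], sep = "-")
}

#' Build the round structure for one simulated participant
#'
#' Generates the per-round ground truth (true proportions, theta, color pair,
#' exploration length) for every round of the session schedule. Experimental
#' lengths are taken from `exp_lengths` -- the shared list of round lengths
#' used for all participants -- in a randomly permuted order, mirroring the
#' task's design; practice lengths are drawn uniformly from the practice
#' range.
#'
#' @param config A [task_config()].
#' @param exp_lengths Integer vector with one exploration length per
#'   experimental round (see [sample_round_length()]).
#' @return A list of round descriptors (fields: `session`, `round`,
#'   `is_practice`, `length`, `truth`, `theta`, `color_pair`).
#' @export
make_rounds <- function(config = task_config(),
                        exp_lengths = sample_round_length(
                          n_experimental_rounds(config),
                          config$geometric_rate, config$geometric_shift)) {
  n_exp <- n_experimental_rounds(config)
  stopifnot(length(exp_lengths) == n_exp)
  if (any(exp_lengths < config$geometric_shift + 1L)) {
    stop("every experimental length must be >= geometric_shift + 1")
  }
  exp_lengths <- exp_lengths[sample.int(n_exp)]
  rounds <- list()
  rid <- 0L
  eid <- 0L
  for (s in seq_along(config$session_schedule)) {
    sched <- config$session_schedule[[s]]
    for (kind in c("practice", "experimental")) {
      n_k <- if (kind == "practice") sched[1] else sched[2]
      for (j in seq_len(n_k)) {
        rid <- rid + 1L
        if (kind == "practice") {
          len <- sample.int(diff(config$practice_length_range) + 1L, 1L) +
            config$practice_length_range[1] - 1L
        } else {
          eid <- eid + 1L
          len <- exp_lengths[eid]
        }
        truth <- sample_true_proportions(config)
        rounds[[rid]] <- list(
          session = s, round = rid,
          is_practice = (kind == "practice"),
          length = as.integer(len),
          truth = truth,
          theta = sign(truth[, 1] - truth[, 2]),
          color_pair = .color_pair(rid)
        )
      }
    }
  }
  rounds
}
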