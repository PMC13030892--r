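# Piecewise logistic model of approach vs. avoidance: the slope of
# delta-uncertainty on choice is allowed to change above a free
# overall-uncertainty threshold, estimated by profile likelihood on a grid.

.default_tau_grid <- function() seq(0.30, 2 * log(2), by = 0.005)

# Fit the 4-parameter model at a fixed threshold. The hinge regressor
# max(0, U - tau) * du is standardized internally so the ridge penalty acts
# on a unit-variance predictor; the reported interaction is back-transformed
# to per-nat units. `form = "step"` uses an indicator instead of the hinge.
.fit_at_tau <- function(X3, du, u, y, tau, lambda, form, beta0 = NULL,
                        min_above = 1L, min_range = 0) {
  h_raw <- if (form == "hinge") pmax(0, u - tau) * du else (u > tau) * du
  sh <- stats::sd(h_raw)
  if (sum(u > tau) < min_above || max(u) - tau < min_range) sh <- 0
  if (!is.finite(sh) || sh == 0) {
    f <- .ridge_logit(X3, y, lambda = lambda, beta0 = beta0[1:3])
    return(list(fit = f, sh = NA_real_, identifiable = FALSE))
  }
  X <- cbind(X3, h = h_raw / sh)
  f <- .ridge_logit(X, y, lambda = lambda, beta0 = beta0)
  list(fit = f, sh = sh, identifiable = TRUE)
}

#' Fit the piecewise logistic threshold model
#'
#' Models the probability of choosing the right-hand table as a logistic
#' function of a side intercept, the repeat indicator and the scaled
#' delta-uncertainty, whose slope changes continuously above a free
#' overall-uncertainty threshold `tau`:
#' `s(U) = beta_low + beta_int * max(0, U - tau)` (hinge interaction;
#' a discrete slope switch is available via `form = "step"`). The threshold
#' is estimated by maximizing the ridge-penalized profile log-likelihood
#' over a grid of candidate values; by default the search evaluates a coarse
#' pass over the grid range and then refines around the optimum down to the
#' grid resolution (0.005 nats), which keeps the estimate reproducible on
#' the non-smooth profile. Slope standard errors are conditional on the
#' estimated threshold; the threshold's own standard error is obtained from
#' the local curvature of the profile.
#'
#' @param design An `"explore_design"` table from [prepare_predictors()].
#' @param tau_grid Candidate thresholds in nats (default: 0.30 to
#'   `2 log 2` at resolution 0.005, searched coarse-to-fine).
#' @param lambda Ridge penalty weight.
#' @param form `"hinge"` (continuous, default) or `"step"`.
#' @param refine Use the coarse-to-fine profile search (default); set to
#'   `FALSE` to evaluate every grid point.
#' @param keep_data Store the design columns needed by `predict`,
#'   `residuals` and `simulate` (default `TRUE`).
#' @param min_above Minimum number of trials above a candidate threshold
#'   for the interaction to be estimable there (default: 1% of trials, at
#'   least 20). Candidate thresholds with fewer trials above are profiled
#'   without the interaction; if the optimum falls on one, the interaction
#'   is fixed at 0 and flagged.
#' @param min_range Minimum moderation window in nats between a candidate
#'   threshold and the maximum observed overall uncertainty (default 0.02).
#'   Overall uncertainty is bounded by `2 log 2`, so a per-nat slope change
#'   cannot be resolved on a vanishing window above the threshold; such
#'   candidates are profiled without the interaction.
#' @return An object of class `"piecewise_fit"` with the estimated
#'   threshold `tau_hat`, below-threshold slope `beta_low`, per-nat slope
#'   change `beta_int`, side and repeat coefficients, standard errors, the
#'   evaluated profile, and the fraction of trials above the threshold.
#' @export
fit_piecewise <- function(design, tau_grid = NULL, lambda = 1,
                          form = c("hinge", "step"), refine = TRUE,
                          keep_data = TRUE, min_above = NULL,
                          min_range = 0.02) {
  form <- match.arg(form)
  user_grid <- !is.null(tau_grid)
  if (!user_grid) tau_grid <- .default_tau_grid()
  if (any(tau_grid <= 0 | tau_grid >= 2 * log(2) + 1e-9)) {
    stop("'tau_grid' must lie inside (0, 2 log 2)")
  }
  tau_grid <- sort(unique(tau_grid))
  du <- design$du
  u <- design$u
  if (all(is.na(du)) || all(is.na(u))) {
    stop("design must carry delta-uncertainty and overall uncertainty")
  }
  y <- design$y
  if (is.null(min_above)) min_above <- max(20L, ceiling(0.01 * length(y)))
  X3 <- cbind(side = 1, repeat_option = design$r, du = du)

  eval_grid <- function(taus, beta0 = NULL) {
    out <- vector("list", length(taus))
    for (i in seq_along(taus)) {
      res <- .fit_at_tau(X3, du, u, y, taus[i], lambda, form, beta0 = beta0,
                         min_above = min_above, min_range = min_range)
      if (res$identifiable) beta0 <- res$fit$coef
      out[[i]] <- list(tau = taus[i], pll = res$fit$ploglik, res = res)
    }
    out
  }

  if (refine && !user_grid && length(tau_grid) > 40L) {
    step <- min(diff(tau_grid))
    coarse <- tau_grid[seq(1L, length(tau_grid), by = 10L)]
    if (coarse[length(coarse)] != tau_grid[length(tau_grid)]) {
      coarse <- c(coarse, tau_grid[length(tau_grid)])
    }
    ev1 <- eval_grid(coarse)
    pll1 <- vapply(ev1, `[[`, 0, "pll")
    best <- coarse[which.max(pll1)]
    fine <- tau_grid[tau_grid >= best - 10.5 * step &
                     tau_grid <= best + 10.5 * step]
    ev2 <- eval_grid(fine, beta0 = ev1[[which.max(pll1)]]$res$fit$coef)
    evals <- c(ev1, ev2)
  } else {
    evals <- eval_grid(tau_grid)
  }

  taus <- vapply(evals, `[[`, 0, "tau")
  plls <- vapply(evals, `[[`, 0, "pll")
  ord <- order(taus)
  keep <- !duplicated(taus[ord])
  profile <- data.frame(tau = taus[ord][keep], ploglik = plls[ord][keep])

  ibest <- which.max(plls)
  best <- evals[[ibest]]
  fit <- best$res$fit
  identifiable <- best$res$identifiable
  if (!identifiable) {
    warning("too few trials above the profiled threshold; ",
            "interaction fixed at 0")
  }
  co <- fit$coef
  se <- fit$se
  sh <- best$res$sh
  beta_int <- if (identifiable) co[4] / sh else 0
  se_int <- if (identifiable) se[4] / sh else NA_real_

  # threshold SE from the profile curvature at the optimum
  tau_hat <- best$tau
  pr <- profile
  j <- which(pr$tau == tau_hat)
  tau_se <- NA_real_
  if (length(j) == 1 && j > 1 && j < nrow(pr)) {
    d1 <- pr$tau[j] - pr$tau[j - 1]
    d2 <- pr$tau[j + 1] - pr$tau[j]
    if (abs(d1 - d2) < 1e-9) {
      curv <- (pr$ploglik[j + 1] - 2 * pr$ploglik[j] + pr$ploglik[j - 1]) / d1^2
      if (is.finite(curv) && curv < 0) tau_se <- sqrt(-1 / curv)
    }
  }

  frac_above <- mean(u > tau_hat)

  structure(list(
    tau_hat = tau_hat, tau_se = tau_se,
    beta_low = unname(co[3]), beta_int = unname(beta_int),
    beta_side = unname(co[1]), beta_rep = unname(co[2]),
    se = c(side = unname(se[1]), repeat_option = unname(se[2]),
           beta_low = unname(se[3]), beta_int = unname(se_int)),
    profile = profile, loglik = fit$loglik, ploglik = fit$ploglik,
    fraction_above = frac_above, identifiable = identifiable,
    form = form, lambda = lambda, n_trials = nrow(design),
    grid_step = min(diff(tau_grid)),
    scales = attr(design, "scales"),
    data = if (keep_data) design[, c("participant", "y", "du", "u", "r")]
           else NULL
  ), class = "piecewise_fit")
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat(sprintf("Piecewise logistic threshold model (%s form, %d trials)\n",
              x$form, x$n_trials))
  cat(sprintf("  threshold tau  = %.3f nats (SE %.4f); %.1f%% of trials above\n",
              x$tau_hat, x$tau_se, 100 * x$fraction_above))
  cat(sprintf("  slope below    = %.3f (SE %.3f)\n", x$beta_low,
              x$se[["beta_low"]]))
  cat(sprintf("  slope change   = %.2f per nat above (SE %.2f)%s\n",
              x$beta_int, x$se[["beta_int"]],
              if (!x$identifiable) " [fixed: unidentifiable]" else ""))
  cat(sprintf("  side = %.3f, repeat = %.3f\n", x$beta_side, x$beta_rep))
  invisible(x)
}

#' @export
summary.piecewise_fit <- function(object, ...) {
  object$avoidance <- avoidance_score(object)
  class(object) <- c("summary.piecewise_fit", class(object))
  object
}

#' @export
print.summary.piecewise_fit <- function(x, ...) {
  NextMethod()
  cat(sprintf("  avoidance score = %.3f (triangular area above the fitted line)\n",
              x$avoidance$area))
  invisible(x)
}

#' @export
coef.piecewise_fit <- function(object, ...) {
  c(side = object$beta_side, repeat_option = object$beta_rep,
    beta_low = object$beta_low, beta_int = object$beta_int,
    tau = object$tau_hat)
}

#' @export
logLik.piecewise_fit <- function(object, ...) {
  structure(object$loglik, df = 5L, nobs = object$n_trials, class = "logLik")
}

# effective delta-uncertainty slope at overall uncertainty U
.pw_slope <- function(object, u) {
  if (object$form == "hinge") {
    object$beta_low + ifelse(u > object$tau_hat,
                             object$beta_int * (u - object$tau_hat), 0)
  } else {
    object$beta_low + ifelse(u > object$tau_hat, object$beta_int, 0)
  }
}

.pw_eta <- function(object, newdata) {
  object$beta_side + object$beta_rep * newdata$r +
    .pw_slope(object, newdata$u) * newdata$du
}

#' @export
predict.piecewise_fit <- function(object, newdata = object$data,
                                  type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) stop("no data stored; supply 'newdata'")
  eta <- .pw_eta(object, newdata)
  if (type == "response") stats::plogis(eta) else eta
}

#' @export
residuals.piecewise_fit <- function(object, type = c("pearson", "deviance"),
                                    ...) {
  type <- match.arg(type)
  if (is.null(object$data)) stop("refit with keep_data = TRUE")
  y <- object$data$y
  p <- predict(object)
  if (type == "pearson") {
    (y - p) / sqrt(p * (1 - p))
  } else {
    sign(y - p) * sqrt(-2 * (y * log(p) + (1 - y) * log(1 - p)))
  }
}

#' @export
simulate.piecewise_fit <- function(object, nsim = 1, seed = NULL,
                                   newdata = object$data, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(newdata)) stop("no data stored; supply 'newdata'")
  p <- predict(object, newdata)
  out <- as.data.frame(replicate(nsim,
    as.integer(stats::runif(length(p)) < p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.piecewise_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  uu <- seq(0, 2 * log(2), length.out = 200)
  graphics::plot(uu, .pw_slope(x, uu), type = "l", lwd = 2,
                 xlab = "overall uncertainty (nats)",
                 ylab = "delta-uncertainty slope",
                 main = "Effective approach/avoid slope")
  graphics::abline(v = x$tau_hat, lty = 2)
  graphics::abline(h = 0, col = "grey")
  graphics::plot(x$profile$tau, x$profile$ploglik, type = "l",
                 xlab = "threshold tau (nats)",
                 ylab = "penalized log-likelihood",
                 main = "Profile likelihood")
  graphics::abline(v = x$tau_hat, lty = 2)
  invisible(x)
}

#' Uncertainty-avoidance score of a piecewise fit
#'
#' The triangular area enclosed between the below-threshold slope and the
#' declining above-threshold segment of the fitted effect line, integrated
#' up to `u_max`: `0.5 * |beta_int| * (u_max - tau)^2` when the interaction
#' is negative, and 0 otherwise. Larger areas mean stronger uncertainty
#' avoidance when overall uncertainty is high.
#'
#' @param fit A `"piecewise_fit"` (or any list with `tau_hat` and
#'   `beta_int`).
#' @param u_max Upper integration bound in nats (default `2 log 2`, the
#'   maximum possible overall uncertainty).
#' @return A list with `area` and its `components`.
#' @export
avoidance_score <- function(fit, u_max = 2 * log(2)) {
  tau <- fit$tau_hat
  bint <- fit$beta_int
  area <- if (!is.na(bint) && bint < 0 && tau < u_max) {
    0.5 * abs(bint) * (u_max - tau)^2
  } else 0
  list(area = area,
       components = c(tau_hat = tau, beta_int = bint, u_max = u_max))
}

#' Fraction of trials above a threshold of overall uncertainty
#'
#' @param design An `"explore_design"` table (or any data frame with a raw
#'   overall-uncertainty column `u`).
#' @param tau Threshold in nats.
#' @return Proportion of trials with overall uncertainty strictly above
#'   `tau`.
#' @export
fraction_above_threshold <- function(design, tau) {
  if (!nrow(design)) stop("empty design")
  mean(design$u > tau)
}

#' Per-participant approach and avoidance with their correlation
#'
#' Fits the piecewise model separately to every participant with at least
#' `min_trials` trials. Participant profiles share the group grid and are
#' shrunk toward the group optimum by adding the group profile, weighted by
#' the participant's share of trials, as a log-prior (this stabilizes
#' individuals with few high-uncertainty trials). Returns the
#' per-participant approach slope (`beta_low`) and avoidance score, their
#' Pearson correlation, and a permutation p-value.
#'
#' @param design An `"explore_design"` table.
#' @param tau_grid Shared threshold grid (default: 0.30 to `2 log 2` at
#'   0.01-nat resolution; full sweep, no refinement, so that group and
#'   individual profiles align).
#' @param lambda Ridge penalty.
#' @param min_trials Minimum trials per participant (default 100).
#' @param n_perm Number of permutations for the correlation p-value.
#' @param seed Seed for the permutation draw.
#' @return An object of class `"approach_avoid"`: per-participant table,
#'   `correlation`, `p_value`, and the group fit.
#' @export
approach_avoid_individuals <- function(design, tau_grid = NULL, lambda = 1,
                                       min_trials = 100L, n_perm = 999L,
                                       seed = NULL) {
  if (is.null(tau_grid)) tau_grid <- seq(0.30, 2 * log(2), by = 0.01)
  if (!is.null(seed)) set.seed(seed)
  group <- fit_piecewise(design, tau_grid = tau_grid, lambda = lambda,
                         keep_data = FALSE)
  gp <- group$profile
  gprior <- gp$ploglik - max(gp$ploglik)
  n_total <- nrow(design)

  idx <- split(seq_len(nrow(design)), design$participant)
  rows <- list()
  excluded <- character()
  for (id in names(idx)) {
    ii <- idx[[id]]
    if (length(ii) < min_trials) { excluded <- c(excluded, id); next }
    di <- design[ii, , drop = FALSE]
    du <- di$du; u <- di$u; y <- di$y
    X3 <- cbind(1, di$r, du)
    w <- length(ii) / n_total
    pll <- rep(NA_real_, nrow(gp))
    fits <- vector("list", nrow(gp))
    beta0 <- NULL
    ok <- TRUE
    min_above_i <- max(5L, ceiling(0.01 * length(y)))
    for (k in seq_len(nrow(gp))) {
      res <- tryCatch(
        .fit_at_tau(X3, du, u, y, gp$tau[k], lambda, "hinge", beta0 = beta0,
                    min_above = min_above_i, min_range = 0.02),
        error = function(e) NULL)
      if (is.null(res)) { ok <- FALSE; break }
      if (res$identifiable) beta0 <- res$fit$coef
      pll[k] <- res$fit$ploglik + w * gprior[k]
      fits[[k]] <- res
    }
    if (!ok || all(is.na(pll))) { excluded <- c(excluded, id); next }
    kbest <- which.max(pll)
    best <- fits[[kbest]]
    if (!best$identifiable) { excluded <- c(excluded, id); next }
    b_low <- best$fit$coef[3]
    b_int <- best$fit$coef[4] / best$sh
    sc <- avoidance_score(list(tau_hat = gp$tau[kbest], beta_int = b_int))
    rows[[id]] <- data.frame(
      participant = as.numeric(id), n_trials = length(ii),
      tau = gp$tau[kbest], beta_low = unname(b_low),
      beta_int = unname(b_int), avoidance = sc$area)
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) < 3) {
    stop("fewer than 3 participants with identifiable individual fits")
  }
  r_obs <- stats::cor(tab$beta_low, tab$avoidance)
  perms <- vapply(seq_len(n_perm), function(i)
    stats::cor(tab$beta_low, sample(tab$avoidance)), 0)
  p_val <- (1 + sum(abs(perms) >= abs(r_obs))) / (n_perm + 1)

  structure(list(participants = tab, correlation = r_obs, p_value = p_val,
                 group = group, excluded = excluded, n_perm = n_perm),
            class = "approach_avoid")
}

#' @export
print.approach_avoid <- function(x, ...) {
  cat(sprintf("Approach vs. avoidance across %d participants\n",
              nrow(x$participants)))
  cat(sprintf("  cor(approach slope, avoidance score) = %.3f (permutation p = %.4f)\n",
              x$correlation, x$p_value))
  if (length(x$excluded)) {
    cat(sprintf("  excluded (too few trials or unidentifiable): %s\n",
                paste(x$excluded, collapse = ", ")))
  }
  invisible(x)
}
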