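# Per-strategy logistic choice models: penalized maximum likelihood with a
# two-stage population summary (per-participant fits pooled by inverse
# variance), plus a pooled fit for prediction.

#' Fit a logistic choice model for one candidate strategy
#'
#' Models the probability of choosing the right-hand table as a logistic
#' function of the side intercept, the repeat-option indicator and the
#' scaled decision-variable difference of the requested strategy. Estimation
#' is ridge-penalized maximum likelihood (penalty `0.5 * lambda * sum(b^2)`,
#' the deterministic analogue of standard-normal coefficient priors).
#' Individual differences are handled by a two-stage summary: the model is
#' fit separately to each participant with at least `min_trials` trials and
#' the population coefficient is the inverse-variance-weighted mean of the
#' per-participant estimates, with matching standard error. A pooled
#' (all-trials) fit is also retained and used by `predict`.
#'
#' @param design An `"explore_design"` table from [prepare_predictors()].
#' @param dv_kind Which decision variable drives the model: `"uncertainty"`,
#'   `"eig"` or `"exposure"`.
#' @param lambda Ridge penalty weight (default 1).
#' @param min_trials Minimum trials for a per-participant fit (default 20;
#'   participants below it contribute to the pooled fit only).
#' @return An object of class `"choice_fit"`.
#' @export
fit_choice_model <- function(design, dv_kind = c("uncertainty", "eig", "exposure"),
                             lambda = 1, min_trials = 20L) {
  dv_kind <- match.arg(dv_kind)
  col <- .design_dv_col(dv_kind)
  dv <- design[[col]]
  if (all(is.na(dv))) {
    stop("decision variable '", dv_kind, "' was not recorded in this design")
  }
  X <- cbind(side = 1, repeat_option = design$r, dv = dv)
  colnames(X)[3] <- paste0("delta_", dv_kind)
  y <- design$y

  pooled <- .ridge_logit(X, y, lambda = lambda)

  ids <- unique(design$participant)
  idx <- split(seq_len(nrow(design)), design$participant)
  rows <- lapply(names(idx), function(id) {
    ii <- idx[[id]]
    if (length(ii) < min_trials) return(NULL)
    f <- .ridge_logit(X[ii, , drop = FALSE], y[ii], lambda = lambda)
    data.frame(participant = as.numeric(id), n_trials = length(ii),
               side = f$coef[1], repeat_option = f$coef[2], dv = f$coef[3],
               se_side = f$se[1], se_repeat = f$se[2], se_dv = f$se[3])
  })
  per <- do.call(rbind, rows)

  if (!is.null(per) && nrow(per) > 0) {
    se_col <- c(side = "se_side", repeat_option = "se_repeat", dv = "se_dv")
    pop <- t(vapply(c("side", "repeat_option", "dv"), function(nm) {
      b <- per[[nm]]
      w <- 1 / per[[se_col[[nm]]]]^2
      c(estimate = sum(w * b) / sum(w), se = sqrt(1 / sum(w)))
    }, c(estimate = 0, se = 0)))
  } else {
    pop <- cbind(estimate = pooled$coef, se = pooled$se)
    rownames(pop) <- c("side", "repeat_option", "dv")
  }

  structure(list(
    dv_kind = dv_kind, lambda = lambda,
    population = pop,
    pooled = list(coef = stats::setNames(pooled$coef, colnames(X)),
                  se = pooled$se, vcov = pooled$vcov,
                  loglik = pooled$loglik),
    participants = per,
    n_trials = nrow(design),
    n_participants = length(ids),
    scales = attr(design, "scales")
  ), class = "choice_fit")
}

#' @export
print.choice_fit <- function(x, ...) {
  cat(sprintf("Logistic choice model (%s strategy), %d trials, %d participants\n",
              x$dv_kind, x$n_trials, x$n_participants))
  cat("Population coefficients (two-stage, inverse-variance weighted):\n")
  tab <- cbind(x$population, z = x$population[, 1] / x$population[, 2])
  print(round(tab, 4))
  invisible(x)
}

#' @export
summary.choice_fit <- function(object, ...) {
  tab <- cbind(object$population,
               z = object$population[, 1] / object$population[, 2])
  out <- list(dv_kind = object$dv_kind, population = tab,
              pooled = object$pooled,
              n_participants_fit = if (is.null(object$participants)) 0L
                                   else nrow(object$participants),
              n_trials = object$n_trials)
  class(out) <- "summary.choice_fit"
  out
}

#' @export
print.summary.choice_fit <- function(x, ...) {
  cat(sprintf("Choice model: %s decision variable\n", x$dv_kind))
  print(round(x$population, 4))
  cat(sprintf("Pooled log-likelihood: %.2f over %d trials (%d per-participant fits)\n",
              x$pooled$loglik, x$n_trials, x$n_participants_fit))
  invisible(x)
}

#' @export
coef.choice_fit <- function(object, which = c("population", "pooled"), ...) {
  which <- match.arg(which)
  if (which == "population") {
    stats::setNames(object$population[, "estimate"], rownames(object$population))
  } else {
    object$pooled$coef
  }
}

#' @export
vcov.choice_fit <- function(object, ...) object$pooled$vcov

#' @export
logLik.choice_fit <- function(object, ...) {
  structure(object$pooled$loglik, df = 3L, nobs = object$n_trials,
            class = "logLik")
}

#' @export
predict.choice_fit <- function(object, newdata,
                               type = c("response", "link"), ...) {
  type <- match.arg(type)
  dv <- newdata[[.design_dv_col(object$dv_kind)]]
  eta <- object$pooled$coef[1] + object$pooled$coef[2] * newdata$r +
    object$pooled$coef[3] * dv
  if (type == "response") stats::plogis(eta) else eta
}

#' @export
residuals.choice_fit <- function(object, design, ...) {
  p <- predict(object, design)
  (design$y - p) / sqrt(p * (1 - p))
}
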