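# Design-table preparation for the choice models.

#' Prepare the trial-level design table for model fitting
#'
#' Drops practice rounds and assembles, per trial, the scaled decision
#' variables (`delta_eig`, `delta_uncertainty`, `delta_exposure`), the raw
#' overall uncertainty in nats, the repeat-option indicator (+1 right
#' repeat, -1 left repeat, 0 none) and the chose-right response.
#'
#' Two scalings are available. `"stored"` (default when the dataset carries
#' calibration constants) divides each decision variable by the same
#' constants the generator used, so fitted slopes are directly comparable to
#' generating slopes. `"zscore"` centers and scales every decision variable
#' and overall uncertainty within the dataset; the constants used are
#' attached as attributes either way. Zero-variance predictors are flagged
#' with a warning and left unscaled.
#'
#' @param sim An `"explore_sim"` object, or a trials data frame.
#' @param scale `"stored"` or `"zscore"`.
#' @return A data frame of class `"explore_design"` with columns
#'   `participant`, `y`, `deig`, `du`, `dexp`, `u` (raw nats), `uz`, `r`;
#'   attributes `centers` and `scales` record the scaling constants.
#' @export
prepare_predictors <- function(sim, scale = c("stored", "zscore")) {
  scale <- match.arg(scale)
  if (inherits(sim, "explore_sim")) {
    trials <- sim$trials
    stored <- sim$scaling
  } else {
    trials <- sim
    stored <- attr(sim, "scaling")
  }
  if (!nrow(trials)) stop("empty dataset")
  trials <- trials[trials$is_practice == 0, , drop = FALSE]
  if (!nrow(trials)) stop("no experimental trials after excluding practice")
  if (scale == "stored" && is.null(stored)) {
    warning("no stored scaling constants; falling back to z-scoring")
    scale <- "zscore"
  }

  raw <- list(deig = trials$delta_eig,
              du = trials$delta_uncertainty,
              dexp = trials$delta_exposure)
  centers <- c(deig = 0, du = 0, dexp = 0, u = 0)
  scales <- c(deig = 1, du = 1, dexp = 1, u = 1)
  key <- c(deig = "eig", du = "uncertainty", dexp = "exposure")

  out <- data.frame(participant = trials$participant, y = trials$choice_right)
  for (nm in names(raw)) {
    v <- raw[[nm]]
    if (all(is.na(v))) {
      out[[nm]] <- v
      next
    }
    if (scale == "stored") {
      sc <- stored[[key[[nm]]]]
      ctr <- 0
    } else {
      sc <- stats::sd(v)
      ctr <- mean(v)
      if (!is.finite(sc) || sc == 0) {
        warning("zero-variance predictor '", nm, "' left unscaled")
        sc <- 1; ctr <- 0
      }
    }
    centers[[nm]] <- ctr
    scales[[nm]] <- sc
    out[[nm]] <- (v - ctr) / sc
  }
  out$u <- trials$overall_uncertainty
  if (!all(is.na(out$u))) {
    if (scale == "zscore") {
      centers[["u"]] <- mean(out$u)
      scales[["u"]] <- stats::sd(out$u)
      if (!is.finite(scales[["u"]]) || scales[["u"]] == 0) {
        warning("zero-variance predictor 'u' left unscaled")
        centers[["u"]] <- 0; scales[["u"]] <- 1
      }
    }
    out$uz <- (out$u - centers[["u"]]) / scales[["u"]]
  } else {
    out$uz <- out$u
  }
  out$r <- trials$repeat_side
  attr(out, "centers") <- centers
  attr(out, "scales") <- scales
  attr(out, "scale_mode") <- scale
  class(out) <- c("explore_design", "data.frame")
  out
}

.design_dv_col <- function(dv_kind) {
  switch(dv_kind,
    eig = "deig", uncertainty = "du", exposure = "dexp",
    stop("unknown decision-variable kind: ", dv_kind))
}
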