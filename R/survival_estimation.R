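#' Kaplan-Meier curve object
#'
#' A right-continuous step-function estimate of a survival probability
#' over time from diagnosis, with S(0) = 1.  Only times at which the
#' curve drops (event times) are stored; between stored times the last
#' value is carried forward, and beyond the last stored time the final
#' value is carried forward.
#'
#' @param time Strictly increasing event times (months).
#' @param surv Survival probability immediately after each event time;
#'   non-increasing, in `[0, 1]`.
#' @param n_risk Number at risk just before each event time (optional).
#' @return An object of class `km_curve`.
#' @export
km_curve <- function(time, surv, n_risk = rep(NA_integer_, length(time))) {
  time <- as.numeric(time); surv <- as.numeric(surv)
  if (length(time) != length(surv))
    stop("time and surv must have equal length", call. = FALSE)
  if (is.unsorted(time, strictly = TRUE))
    stop("event times must be strictly increasing", call. = FALSE)
  if (any(surv < -1e-12 | surv > 1 + 1e-12))
    stop("survival probabilities must lie in [0, 1]", call. = FALSE)
  surv <- pmin(pmax(surv, 0), 1)
  if (any(diff(surv) > 1e-12))
    stop("survival must be non-increasing", call. = FALSE)
  structure(list(time = time, surv = surv, n_risk = n_risk),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve: %d event times, S(last) = %.4f>\n",
              length(x$time), utils::tail(x$surv, 1)))
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve
#'
#' Right-continuous step-function evaluation: `S(t)` is the survival
#' value at the largest stored event time `<= t`, 1 before the first
#' event, and the last value carried forward beyond the last event.
#'
#' @param curve A [km_curve()].
#' @param t Times (months) at which to evaluate; vectorized.
#' @return Survival probabilities.
#' @export
km_surv_at <- function(curve, t) {
  idx <- findInterval(t, curve$time)
  ifelse(idx == 0, 1, curve$surv[pmax(idx, 1)])
}

#' Kaplan-Meier estimate from survival records
#'
#' Standard product-limit estimate; at tied times events are processed
#' before censorings (the usual convention).
#'
#' @param records A survival-record data frame (see
#'   [read_survival_records()]); the `stage` column is ignored here.
#' @return A [km_curve()] whose stored times are the distinct event
#'   (death) times.
#' @export
km_estimate <- function(records) {
  if (nrow(records) == 0)
    stop("cannot estimate a survival curve from zero records",
         call. = FALSE)
  if (!any(records$event))
    stop("all records censored: no events to estimate from",
         call. = FALSE)
  fit <- survival::survfit(
    survival::Surv(time_months, event) ~ 1,
    data = records, conf.type = "none")
  keep <- fit$n.event > 0
  km_curve(fit$time[keep], fit$surv[keep], fit$n.risk[keep])
}

#' Stage-weighted overall survival curve
#'
#' Combines stage-specific Kaplan-Meier curves into one overall curve as
#' the mixture `S(t) = sum_s w_s S_s(t)` using an external stage
#' distribution, evaluated on the union of the stage event-time grids
#' with each stage curve carried right-continuously.  Re-weighting to a
#' registry stage mix removes referral bias in the stage composition of
#' the source case series.
#'
#' @param curves Named list of [km_curve()] objects, one per stage
#'   `I,II,III,IV`.
#' @param weights A [stage_weights()] object.
#' @return A [km_curve()] on the union time grid.
#' @export
weighted_overall_curve <- function(curves, weights) {
  weights <- stage_weights(weights)
  missing_stage <- setdiff(STAGE_LEVELS, names(curves))
  if (length(missing_stage))
    stop("missing stage curve(s): ", paste(missing_stage, collapse = ", "),
         call. = FALSE)
  grid <- sort(unique(unlist(lapply(curves[STAGE_LEVELS],
                                    function(cv) cv$time))))
  surv <- rowSums(vapply(
    STAGE_LEVELS,
    function(s) weights[[s]] * km_surv_at(curves[[s]], grid),
    numeric(length(grid))))
  n_risk <- rowSums(vapply(
    STAGE_LEVELS,
    function(s) {
      idx <- findInterval(grid, curves[[s]]$time)
      nr <- as.numeric(curves[[s]]$n_risk)
      ifelse(idx == 0, if (length(nr)) max(nr, na.rm = TRUE) else NA_real_,
             nr[pmax(idx, 1)])
    },
    numeric(length(grid))))
  km_curve(grid, surv, n_risk)
}

#' Median survival time of a Kaplan-Meier curve
#'
#' Standard convention: the smallest stored event time `t` with
#' `S(t) <= 0.5`, without interpolation.
#'
#' @param curve A [km_curve()].
#' @return Median survival time (months).
#' @export
km_median <- function(curve) {
  idx <- which(curve$surv <= 0.5)
  if (!length(idx))
    stop("median undefined: survival curve never reaches 0.5 (minimum ",
         if (length(curve$surv)) format(min(curve$surv), digits = 4)
         else "empty curve", ")", call. = FALSE)
  curve$time[idx[1]]
}

#' Exponential approximation of a survival distribution from its median
#'
#' Converts a median survival time in months to the mean of the
#' exponential distribution with that median:
#' `mean (years) = (median / 12) / ln 2`.
#'
#' @param median_months Median survival time in months (> 0).
#' @return An object of class `exponential_interval` with fields
#'   `mean_years` and `median_months`.
#' @examples
#' exponential_from_median(17)  # mean 2.04 years
#' exponential_from_median(11)  # mean 1.32 years
#' @export
exponential_from_median <- function(median_months) {
  if (!is.finite(median_months) || median_months <= 0)
    stop("median must be a positive number of months", call. = FALSE)
  structure(list(mean_years = (median_months / 12) / log(2),
                 median_months = median_months),
            class = "exponential_interval")
}

#' Exponential diagnosis-to-death interval from its mean
#'
#' @param mean_years Mean of the exponential interval (years, > 0).
#' @return An `exponential_interval` object.
#' @export
exponential_interval <- function(mean_years) {
  if (!is.finite(mean_years) || mean_years <= 0)
    stop("mean must be a positive number of years", call. = FALSE)
  structure(list(mean_years = mean_years,
                 median_months = mean_years * log(2) * 12),
            class = "exponential_interval")
}

#' @export
print.exponential_interval <- function(x, ...) {
  cat(sprintf(
    "<exponential_interval: mean %.4g years (median %.4g months)>\n",
    x$mean_years, x$median_months))
  invisible(x)
}

#' Estimate the diagnosis-to-death interval from survival records
#'
#' The full estimation pipeline: Kaplan-Meier curves per AJCC stage, a
#' stage-weighted overall curve using an external stage distribution,
#' the Kaplan-Meier median of the overall curve, and the exponential
#' distribution with that median.
#'
#' @param records Survival-record data frame with events in every stage
#'   that carries positive weight.
#' @param weights A [stage_weights()] object (default: the SEER-17
#'   stage distribution for cases diagnosed in 2000).
#' @return An `exponential_interval`, with attributes
#'   `overall_curve` (the weighted [km_curve()]) and `stage_medians`
#'   (named vector, `NA` where a stage curve does not reach 0.5).
#' @export
estimate_interval <- function(records, weights = seer_stage_weights_2000()) {
  weights <- stage_weights(weights)
  curves <- lapply(STAGE_LEVELS, function(s) {
    sub <- records[records$stage == s, , drop = FALSE]
    if (nrow(sub) == 0 || !any(sub$event)) {
      if (weights[[s]] > 0)
        stop("stage ", s, " has no events but carries weight ",
             format(weights[[s]]), call. = FALSE)
      return(km_curve(numeric(0), numeric(0)))
    }
    km_estimate(sub)
  })
  names(curves) <- STAGE_LEVELS
  overall <- weighted_overall_curve(curves, weights)
  med <- km_median(overall)
  out <- exponential_from_median(med)
  attr(out, "overall_curve") <- overall
  attr(out, "stage_medians") <- vapply(curves, function(cv) {
    tryCatch(km_median(cv), error = function(e) NA_real_)
  }, numeric(1))
  out
}
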