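#' Run configuration for the full prediction workflow
#'
#' Bundles and validates everything [run_pipeline()] needs: the cohort,
#' the survival model, exactly one source for the diagnosis-to-death
#' interval (a fixed mean, estimation from survival-record files, or no
#' adjustment), the replicate count and the seed.
#'
#' @param cohort A cohort data frame or a path to a cohort CSV.
#' @param model `"tsce"` (default) or `"toy-exponential"`.
#' @param model_params A [tsce_params()] object for the TSCE model
#'   (default [default_tsce_params()]).
#' @param rate Hazard for the toy exponential model.
#' @param interval_mean Fixed interval mean in years.
#' @param survival_file,weights_file Paths to survival-record and
#'   stage-weight CSVs for estimating the interval; `weights_file`
#'   defaults to the SEER-17 year-2000 stage distribution.
#' @param no_adjustment If `TRUE`, simulate without the eligibility
#'   adjustment only.
#' @param n_reps Replicate trials (default 5000).
#' @param seed Integer seed.
#' @param out_prefix Path prefix for written artifacts, or `NULL` to
#'   write nothing.
#' @param quiet Suppress progress messages.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort, model = c("tsce", "toy-exponential"),
                       model_params = NULL, rate = NULL,
                       interval_mean = NULL, survival_file = NULL,
                       weights_file = NULL, no_adjustment = FALSE,
                       n_reps = 5000, seed = 1L, out_prefix = NULL,
                       quiet = TRUE) {
  model <- match.arg(model)
  sources <- c(!is.null(interval_mean), !is.null(survival_file),
               isTRUE(no_adjustment))
  if (sum(sources) != 1)
    stop("exactly one interval source required: interval_mean, ",
         "survival_file, or no_adjustment", call. = FALSE)
  if (n_reps < 2) stop("n_reps must be >= 2", call. = FALSE)
  if (model == "toy-exponential" && is.null(rate))
    stop("toy-exponential model requires rate", call. = FALSE)
  structure(list(cohort = cohort, model = model,
                 model_params = model_params, rate = rate,
                 interval_mean = interval_mean,
                 survival_file = survival_file,
                 weights_file = weights_file,
                 no_adjustment = isTRUE(no_adjustment),
                 n_reps = n_reps, seed = as.integer(seed),
                 out_prefix = out_prefix, quiet = isTRUE(quiet)),
            class = "run_config")
}

#' Estimate the diagnosis-to-death interval from files
#'
#' File-level wrapper around [estimate_interval()]: reads survival
#' records (and optionally stage weights) from CSV and, if requested,
#' writes the estimate as JSON.
#'
#' @param survival_file Path to a survival-record CSV.
#' @param weights_file Path to a stage-weight CSV, or `NULL` for the
#'   SEER-17 year-2000 distribution.
#' @param out Optional path for a JSON report (`median_months`,
#'   `mean_years`, per-stage medians).
#' @return The `exponential_interval` (invisibly if `out` is given).
#' @export
estimate_interval_files <- function(survival_file, weights_file = NULL,
                                    out = NULL) {
  records <- read_survival_records(survival_file)
  weights <- if (is.null(weights_file)) seer_stage_weights_2000()
             else read_stage_weights(weights_file)
  est <- estimate_interval(records, weights)
  if (!is.null(out)) {
    jsonlite::write_json(list(
      median_months = est$median_months,
      mean_years = est$mean_years,
      stage_medians_months = as.list(attr(est, "stage_medians"))),
      out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(est))
  }
  est
}

#' Run the full prediction workflow
#'
#' Ties the modules into the complete analysis: resolve the
#' diagnosis-to-death interval (fixed, estimated from files, or none),
#' simulate replicate trials with and (for reference) without the
#' eligibility adjustment, and assemble observed-versus-predicted
#' tables when the cohort carries observed outcomes.  With an
#' `out_prefix`, writes `<prefix>_annual.csv`,
#' `<prefix>_cumulative.csv`, `<prefix>_summary.json` (totals
#' overall/male/female plus rejection-rate statistics) and
#' `<prefix>_manifest.json` (the configuration needed to reproduce the
#' run exactly).
#'
#' @param config A [run_config()].
#' @return A list with elements `interval` (or `NULL`), `adjusted`
#'   (a [run_trials()] summary, `NULL` in no-adjustment mode),
#'   `unadjusted`, `comparison` (observed-vs-predicted, or `NULL`),
#'   and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config"))
    stop("config must come from run_config()", call. = FALSE)
  say <- function(...) if (!config$quiet) message("[eligsim] ", ...)

  cohort <- if (is.character(config$cohort)) {
    say("reading cohort from ", config$cohort)
    read_cohort(config$cohort)
  } else validate_cohort(config$cohort)

  model <- switch(config$model,
    "tsce" = tsce_model(config$model_params %||% default_tsce_params()),
    "toy-exponential" = toy_exponential_model(config$rate))

  interval <- NULL
  if (!is.null(config$interval_mean)) {
    interval <- exponential_interval(config$interval_mean)
  } else if (!is.null(config$survival_file)) {
    say("estimating interval from ", config$survival_file)
    interval <- estimate_interval_files(config$survival_file,
                                        config$weights_file)
  }
  if (!is.null(interval))
    say(sprintf("interval mean %.3f years", interval$mean_years))

  say("simulating ", config$n_reps, " unadjusted replicate trials")
  unadjusted <- run_trials(cohort, model, interval = NULL,
                           n_reps = config$n_reps, seed = config$seed,
                           progress = !config$quiet)
  adjusted <- NULL
  if (!is.null(interval)) {
    say("simulating ", config$n_reps, " adjusted replicate trials")
    adjusted <- run_trials(cohort, model, interval = interval,
                           n_reps = config$n_reps, seed = config$seed,
                           progress = !config$quiet)
  }
  main <- adjusted %||% unadjusted

  comparison <- NULL
  if (any(!is.na(cohort$observed_lc_death)))
    comparison <- compare_observed(cohort, main)

  manifest <- list(
    package = "eligsim",
    version = as.character(utils::packageVersion("eligsim")),
    model = config$model,
    model_params = config$model_params %||%
      (if (config$model == "tsce") unclass(default_tsce_params())),
    rate = config$rate,
    interval_mean_years = if (!is.null(interval)) interval$mean_years,
    interval_source = if (!is.null(config$interval_mean)) "fixed"
                      else if (!is.null(config$survival_file)) "estimated"
                      else "none",
    n_reps = config$n_reps,
    seed = config$seed,
    n_subjects = nrow(cohort))

  if (!is.null(config$out_prefix)) {
    px <- config$out_prefix
    annual <- main$annual
    cumulative <- main$cumulative
    if (!is.null(comparison)) {
      annual <- comparison$annual
      cumulative <- comparison$cumulative
    }
    utils::write.csv(annual, paste0(px, "_annual.csv"),
                     row.names = FALSE)
    utils::write.csv(cumulative, paste0(px, "_cumulative.csv"),
                     row.names = FALSE)
    summary_out <- list(
      totals = list(
        adjusted = if (!is.null(adjusted)) adjusted$total,
        unadjusted = unadjusted$total,
        observed = if (!is.null(comparison))
          comparison$totals[, c("group", "observed")]),
      mean_rejections_per_trial =
        if (!is.null(adjusted)) adjusted$mean_rejections else 0)
    jsonlite::write_json(summary_out, paste0(px, "_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    jsonlite::write_json(manifest, paste0(px, "_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("artifacts written under prefix ", px)
  }

  list(interval = interval, adjusted = adjusted,
       unadjusted = unadjusted, comparison = comparison,
       manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
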