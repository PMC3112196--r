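#' @keywords internal
#' @importFrom stats runif rexp quantile integrate uniroot
"_PACKAGE"

STAGE_LEVELS <- c("I", "II", "III", "IV")

#' Smoking history of one subject
#'
#' A smoking history is the covariate vector driving the age-specific
#' lung-cancer mortality tail function: age at initiation, age at
#' cessation, and smoking intensity in cigarettes per day.  A
#' never-smoker has `cigs_per_day = 0` and no start/quit ages.  A current
#' smoker (still smoking at end of observation) has `age_quit = NA`.
#'
#' @param age_start Age at initiation of smoking (years, continuous), or
#'   `NA` for a never-smoker.
#' @param age_quit Age at cessation (years), `NA` if still smoking (or a
#'   never-smoker).
#' @param cigs_per_day Cigarettes smoked per day (>= 0; 0 if and only if
#'   never-smoker).
#'
#' @return An object of class `smoking_history`.
#' @examples
#' smoking_history(18, 55, 30)   # former smoker
#' smoking_history(20, NA, 20)   # current smoker
#' never_smoker()
#' @export
smoking_history <- function(age_start, age_quit = NA_real_, cigs_per_day) {
  age_start <- as.numeric(age_start)
  age_quit <- as.numeric(age_quit)
  cigs_per_day <- as.numeric(cigs_per_day)
  if (is.na(cigs_per_day) || cigs_per_day < 0)
    stop("cigs_per_day must be a non-negative number", call. = FALSE)
  if (cigs_per_day == 0) {
    if (!is.na(age_start) || !is.na(age_quit))
      stop("never-smokers (cigs_per_day = 0) must have no start/quit ages",
           call. = FALSE)
  } else {
    if (is.na(age_start) || age_start < 0)
      stop("smokers require age_start >= 0", call. = FALSE)
    if (!is.na(age_quit) && age_quit < age_start)
      stop("age_quit must be >= age_start", call. = FALSE)
  }
  structure(list(age_start = age_start, age_quit = age_quit,
                 cigs_per_day = cigs_per_day),
            class = "smoking_history")
}

#' @rdname smoking_history
#' @export
never_smoker <- function() smoking_history(NA, NA, 0)

#' @export
print.smoking_history <- function(x, ...) {
  if (x$cigs_per_day == 0) {
    cat("<smoking_history: never-smoker>\n")
  } else {
    cat(sprintf("<smoking_history: %.3g cigs/day from age %.4g to %s>\n",
                x$cigs_per_day, x$age_start,
                if (is.na(x$age_quit)) "end of observation"
                else sprintf("%.4g", x$age_quit)))
  }
  invisible(x)
}

#' Pack-years implied by a smoking history
#'
#' Pack-years accumulated by age `at_age` (default: end of smoking):
#' duration of smoking times packs per day (20 cigarettes per pack).
#'
#' @param history A [smoking_history()].
#' @param at_age Age at which exposure is evaluated; smoking after
#'   `min(age_quit, at_age)` does not count.
#' @return Pack-years (numeric scalar).
#' @export
pack_years <- function(history, at_age = Inf) {
  if (history$cigs_per_day == 0) return(0)
  quit_eff <- min(if (is.na(history$age_quit)) Inf else history$age_quit,
                  at_age)
  max(quit_eff - history$age_start, 0) * history$cigs_per_day / 20
}

cohort_columns <- c("id", "gender", "t0", "t1", "age_start", "age_quit",
                    "cigs_per_day", "observed_lc_death",
                    "observed_death_age")

#' Validate a cohort data frame
#'
#' Checks the invariants of a cohort table: one row per subject with
#' gender, enrollment age `t0`, end-of-follow-up age `t1`, smoking
#' history columns, and (optionally) observed lung-cancer death outcome.
#'
#' @param cohort A data frame with the columns documented in
#'   [read_cohort()].
#' @return The validated cohort (invisibly), with normalized column
#'   types.
#' @export
validate_cohort <- function(cohort) {
  missing_cols <- setdiff(cohort_columns, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  cohort$id <- as.character(cohort$id)
  cohort$gender <- as.character(cohort$gender)
  for (col in c("t0", "t1", "age_start", "age_quit", "cigs_per_day",
                "observed_death_age"))
    cohort[[col]] <- as.numeric(cohort[[col]])
  cohort$observed_lc_death <- as.logical(cohort$observed_lc_death)

  bad <- which(!cohort$gender %in% c("male", "female"))
  if (length(bad))
    stop("row ", bad[1], ": gender must be 'male' or 'female', got '",
         cohort$gender[bad[1]], "'", call. = FALSE)
  bad <- which(!(cohort$t0 > 0))
  if (length(bad))
    stop("row ", bad[1], ": enrollment age t0 must be > 0", call. = FALSE)
  bad <- which(!(cohort$t1 > cohort$t0))
  if (length(bad))
    stop("row ", bad[1], ": end of follow-up t1 must exceed t0 (t0 = ",
         cohort$t0[bad[1]], ", t1 = ", cohort$t1[bad[1]], ")",
         call. = FALSE)
  smoker <- cohort$cigs_per_day > 0
  bad <- which(smoker & is.na(cohort$age_start))
  if (length(bad))
    stop("row ", bad[1], ": smokers require age_start", call. = FALSE)
  bad <- which(!smoker & (!is.na(cohort$age_start) | !is.na(cohort$age_quit)))
  if (length(bad))
    stop("row ", bad[1],
         ": never-smokers must have empty age_start/age_quit",
         call. = FALSE)
  bad <- which(smoker & !is.na(cohort$age_quit) &
                 cohort$age_quit < cohort$age_start)
  if (length(bad))
    stop("row ", bad[1], ": age_quit before age_start", call. = FALSE)
  bad <- which(!is.na(cohort$observed_death_age) &
                 !(cohort$observed_death_age > cohort$t0 &
                     cohort$observed_death_age <= cohort$t1))
  if (length(bad))
    stop("row ", bad[1], ": observed_death_age must lie in (t0, t1]",
         call. = FALSE)
  invisible(cohort)
}

#' Read a cohort CSV file
#'
#' Columns: `id,gender,t0,t1,age_start,age_quit,cigs_per_day,
#' observed_lc_death,observed_death_age`.  Ages are decimal years; empty
#' `age_quit` on a smoker row means "still smoking"; never-smoker rows
#' leave `age_start`/`age_quit` empty and have `cigs_per_day = 0`.  When
#' the `id` column is absent, row numbers are used as ids.
#'
#' @param path Path to a UTF-8 CSV file with header.
#' @return A validated cohort `data.frame`.
#' @seealso [write_cohort()], [validate_cohort()]
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if (!"id" %in% names(df)) df$id <- as.character(seq_len(nrow(df)))
  missing_cols <- setdiff(setdiff(cohort_columns, "id"), names(df))
  if (length(missing_cols))
    stop("cohort file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- validate_cohort(df[, cohort_columns])
  df
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: the write/read round trip is the identity
#' up to floating-point formatting (10 significant digits).
#'
#' @param cohort A cohort data frame (validated on write).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  out <- cohort[, cohort_columns]
  for (col in c("t0", "t1", "age_start", "age_quit", "observed_death_age"))
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         formatC(out[[col]], digits = 10, format = "g"))
  out$observed_lc_death <- ifelse(is.na(cohort$observed_lc_death), "",
                                  ifelse(cohort$observed_lc_death,
                                         "TRUE", "FALSE"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read patient-level survival records
#'
#' Columns: `time_months,event,stage`.  `time_months` is time from
#' diagnosis (months, >= 0); `event` is 1/TRUE for death, 0/FALSE for
#' censoring; `stage` accepts the AJCC labels `I`--`IV` or `1`--`4`.
#'
#' @param path Path to a CSV file.
#' @return A `data.frame` with columns `time_months` (numeric), `event`
#'   (logical) and `stage` (factor with levels I, II, III, IV), in file
#'   order.
#' @export
read_survival_records <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(stage = "character"))
  missing_cols <- setdiff(c("time_months", "event", "stage"), names(df))
  if (length(missing_cols))
    stop("survival file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  survival_records(time_months = as.numeric(df$time_months),
                   event = df$event, stage = df$stage)
}

#' Construct survival records from vectors
#'
#' @param time_months Time from diagnosis in months (>= 0).
#' @param event Death indicator (logical or 0/1); censored rows are
#'   `FALSE`.
#' @param stage AJCC stage labels (`"I"`--`"IV"` or `"1"`--`"4"`).
#' @return A validated survival-record `data.frame`.
#' @export
survival_records <- function(time_months, event, stage) {
  stage <- as.character(stage)
  arabic <- match(stage, c("1", "2", "3", "4"))
  stage[!is.na(arabic)] <- STAGE_LEVELS[arabic[!is.na(arabic)]]
  bad <- which(!stage %in% STAGE_LEVELS)
  if (length(bad))
    stop("unknown stage label '", stage[bad[1]], "' (row ", bad[1],
         "); expected I-IV or 1-4", call. = FALSE)
  time_months <- as.numeric(time_months)
  bad <- which(!is.finite(time_months) | time_months < 0)
  if (length(bad))
    stop("row ", bad[1], ": time_months must be finite and >= 0",
         call. = FALSE)
  data.frame(time_months = time_months,
             event = as.logical(as.integer(as.logical(event))),
             stage = factor(stage, levels = STAGE_LEVELS))
}

#' @rdname read_survival_records
#' @param records A survival-record data frame.
#' @export
write_survival_records <- function(records, path) {
  out <- data.frame(
    time_months = formatC(records$time_months, digits = 10, format = "g"),
    event = as.integer(records$event),
    stage = as.character(records$stage))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Stage weights for external re-weighting
#'
#' A set of mixture weights over the four AJCC stages, used to combine
#' stage-specific survival curves into an overall curve representative of
#' a reference population (e.g. a registry stage distribution at
#' diagnosis).  Inputs may be percentages or proportions; sums near 100
#' are auto-detected as percentages and normalized.
#'
#' @param weights Named numeric vector with names among `I,II,III,IV`
#'   (or `1`--`4`), or an unnamed length-4 vector taken in stage order.
#' @return A normalized named numeric vector of class `stage_weights`
#'   summing to 1.
#' @examples
#' stage_weights(c(I = 16.22, II = 2.91, III = 32.64, IV = 48.23))
#' @export
stage_weights <- function(weights) {
  w <- as.numeric(weights)
  nm <- names(weights)
  if (is.null(nm)) {
    if (length(w) != 4)
      stop("unnamed stage weights must have length 4 (stages I-IV)",
           call. = FALSE)
    nm <- STAGE_LEVELS
  } else {
    arabic <- match(nm, c("1", "2", "3", "4"))
    nm[!is.na(arabic)] <- STAGE_LEVELS[arabic[!is.na(arabic)]]
  }
  if (!setequal(nm, STAGE_LEVELS) || anyDuplicated(nm))
    stop("stage weights must cover exactly the stages I, II, III, IV",
         call. = FALSE)
  w <- w[match(STAGE_LEVELS, nm)]
  names(w) <- STAGE_LEVELS
  if (any(!is.finite(w) | w < 0))
    stop("stage weights must be finite and non-negative", call. = FALSE)
  s <- sum(w)
  if (abs(s - 100) < 1) w <- w / 100 else if (s <= 0)
    stop("stage weights sum to zero", call. = FALSE)
  w <- w / sum(w)
  if (abs(sum(w) - 1) > 1e-6)
    stop("stage weights failed to normalize", call. = FALSE)
  structure(w, class = "stage_weights")
}

#' @rdname stage_weights
#' @param path Path to a CSV file with columns `stage,weight`.
#' @export
read_stage_weights <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(stage = "character"))
  missing_cols <- setdiff(c("stage", "weight"), names(df))
  if (length(missing_cols))
    stop("stage-weight file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  stage_weights(stats::setNames(df$weight, df$stage))
}

#' @rdname stage_weights
#' @param x A `stage_weights` object.
#' @export
write_stage_weights <- function(x, path) {
  utils::write.csv(data.frame(stage = names(x),
                              weight = formatC(as.numeric(x), digits = 10,
                                               format = "g")),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' SEER-17 stage distribution of lung cancers diagnosed in 2000
#'
#' The registry stage distribution used by default to re-weight
#' stage-specific survival curves to the general diagnosed population:
#' I 16.22%, II 2.91%, III 32.64%, IV 48.23%.
#'
#' @return A [stage_weights()] object (proportions).
#' @export
seer_stage_weights_2000 <- function() {
  stage_weights(c(I = 16.22, II = 2.91, III = 32.64, IV = 48.23))
}

#' Extract one subject's smoking history from a cohort row
#'
#' @param cohort A cohort data frame.
#' @param i Row index.
#' @return A [smoking_history()].
#' @export
subject_history <- function(cohort, i) {
  if (cohort$cigs_per_day[i] == 0) return(never_smoker())
  smoking_history(cohort$age_start[i], cohort$age_quit[i],
                  cohort$cigs_per_day[i])
}
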