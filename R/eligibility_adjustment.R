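# Deterministic per-(replicate, subject) stream seed: a multiplicative
# congruential mix in the Lehmer modulus, kept in exact double
# arithmetic (48271 * (2^31 - 1) < 2^53).  Gives every subject in every
# replicate its own reproducible substream independent of iteration
# order.
stream_seed <- function(seed, rep, i) {
  m <- 2147483647
  x <- seed %% m
  x <- (x * 48271 + rep) %% m
  x <- (x * 48271 + i) %% m
  as.integer(x + 1)
}

# Follow-up-year bin of a death age: year k covers (t0 + k - 1, t0 + k],
# so a death exactly at a year boundary belongs to the earlier year and
# a death exactly at t1 is in follow-up.
followup_year <- function(death_age, t0) {
  k <- ceiling(death_age - t0)
  pmax(k, 1L)
}

#' Simulate one subject's lung-cancer death with eligibility adjustment
#'
#' The individual-level rejection-sampling routine.  A tail probability
#' `u ~ Uniform(0, S(t0; d))` is drawn; if `u <= S(t1; d)` the subject
#' survives follow-up and the simulation is retired.  Otherwise the
#' subject dies at `t* = S^{-1}(u)` within follow-up; when an
#' `interval` is supplied, a diagnosis-to-death interval
#' `w ~ Exponential(mean)` is drawn and the diagnosis age is
#' `t* - w`.  A diagnosis age at or after enrollment is accepted; a
#' diagnosis before enrollment means the subject would have been
#' ineligible to volunteer, so the whole draw (fresh `u` *and* fresh
#' `w`) is rejected and restarted.  With `interval = NULL` (unadjusted
#' mode) every death is accepted.
#'
#' Uses the current RNG state; callers that need reproducible per-subject
#' streams should seed before calling (see [run_trials()]).
#'
#' @param subject A subject list (see [as_subject()]).
#' @param model A [survival_model()].
#' @param interval An `exponential_interval`, or `NULL` for no
#'   adjustment.
#' @param max_rejections Cap on restarts before erroring (default
#'   10000); hitting it signals a subject whose death is near-certain
#'   before enrollment.
#' @param s0,s1 Optional precomputed `S(t0; d)` and `S(t1; d)`.
#' @return A list with `died` (logical), `death_age`, `diagnosis_age`
#'   (`NA` unless died), and `rejections` (restart count).
#' @export
simulate_subject <- function(subject, model, interval = NULL,
                             max_rejections = 10000,
                             s0 = NULL, s1 = NULL) {
  if (is.null(s0)) s0 <- model$evaluate(subject$t0, subject$history,
                                        subject$gender)
  if (is.null(s1)) s1 <- model$evaluate(subject$t1, subject$history,
                                        subject$gender)
  rejections <- 0L
  mean_w <- if (is.null(interval)) NULL else interval$mean_years
  repeat {
    u <- stats::runif(1, 0, s0)
    if (u <= s1)
      return(list(died = FALSE, death_age = NA_real_,
                  diagnosis_age = NA_real_, rejections = rejections))
    t_star <- invert_tail(u, subject, model)
    if (is.null(mean_w))
      return(list(died = TRUE, death_age = t_star,
                  diagnosis_age = t_star, rejections = rejections))
    w <- stats::rexp(1, rate = 1 / mean_w)
    diag_age <- t_star - w
    if (diag_age >= subject$t0)
      return(list(died = TRUE, death_age = t_star,
                  diagnosis_age = diag_age, rejections = rejections))
    rejections <- rejections + 1L
    if (rejections > max_rejections)
      stop("subject ", subject$id, ": rejection cap (", max_rejections,
           ") exceeded; S(t0) may put death before enrollment almost ",
           "surely", call. = FALSE)
  }
}

#' Batch draws of one subject's outcome
#'
#' Draws `n` independent accepted outcomes of the rejection-sampling
#' routine for a single subject, vectorizing the rejection loop and the
#' tail inversion.  Distributionally identical to `n` calls of
#' [simulate_subject()]; used for oracle comparisons and calibration
#' studies.
#'
#' @inheritParams simulate_subject
#' @param n Number of accepted draws.
#' @return A data frame with columns `died`, `death_age`,
#'   `diagnosis_age` (one row per draw).
#' @export
simulate_subject_draws <- function(subject, model, interval = NULL, n,
                                   max_rejections = 10000) {
  s0 <- model$evaluate(subject$t0, subject$history, subject$gender)
  s1 <- model$evaluate(subject$t1, subject$history, subject$gender)
  mean_w <- if (is.null(interval)) NULL else interval$mean_years
  died <- logical(n)
  death_age <- rep(NA_real_, n)
  diagnosis_age <- rep(NA_real_, n)
  active <- seq_len(n)
  rounds <- 0L
  while (length(active)) {
    u <- stats::runif(length(active), 0, s0)
    no_death <- u <= s1
    death_age[active[no_death]] <- NA_real_
    died[active[no_death]] <- FALSE
    dying <- active[!no_death]
    if (length(dying)) {
      t_star <- invert_tail_vec(u[!no_death], subject, model)
      if (is.null(mean_w)) {
        died[dying] <- TRUE
        death_age[dying] <- t_star
        diagnosis_age[dying] <- t_star
        active <- integer(0)
      } else {
        w <- stats::rexp(length(dying), rate = 1 / mean_w)
        diag_age <- t_star - w
        ok <- diag_age >= subject$t0
        acc <- dying[ok]
        died[acc] <- TRUE
        death_age[acc] <- t_star[ok]
        diagnosis_age[acc] <- diag_age[ok]
        active <- dying[!ok]
      }
    } else {
      active <- integer(0)
    }
    rounds <- rounds + 1L
    if (rounds > max_rejections)
      stop("subject ", subject$id, ": rejection cap (", max_rejections,
           ") exceeded", call. = FALSE)
  }
  data.frame(died = died, death_age = death_age,
             diagnosis_age = diagnosis_age)
}

# Precompute S(t0) and S(t1) for every cohort row.
precompute_tails <- function(cohort, model) {
  n <- nrow(cohort)
  s0 <- numeric(n); s1 <- numeric(n)
  for (i in seq_len(n)) {
    subj <- as_subject(cohort, i)
    s0[i] <- model$evaluate(subj$t0, subj$history, subj$gender)
    s1[i] <- model$evaluate(subj$t1, subj$history, subj$gender)
  }
  list(s0 = s0, s1 = s1)
}

#' Simulate a single cohort trial
#'
#' Runs the rejection-sampling routine for every cohort subject, with a
#' reproducible per-subject random substream derived from `(seed, rep,
#' subject index)`, and bins deaths into follow-up years.
#'
#' @inheritParams simulate_subject
#' @param cohort A validated cohort data frame.
#' @param seed Integer base seed.
#' @param rep Replicate index (distinct replicates get distinct
#'   substreams).
#' @param K Number of follow-up years; defaults to
#'   `ceiling(max(t1 - t0))`.
#' @param .precomp Optional result of an internal tail precomputation
#'   (used by [run_trials()] to avoid recomputing `S(t0)`, `S(t1)`).
#' @return A list with integer vectors `annual`, `annual_male`,
#'   `annual_female` (length `K`) and `rejections` (total restarts).
#' @export
simulate_trial <- function(cohort, model, interval = NULL, seed = 1L,
                           rep = 1L, K = NULL, max_rejections = 10000,
                           .precomp = NULL) {
  n <- nrow(cohort)
  if (n == 0) stop("empty cohort", call. = FALSE)
  if (is.null(K)) K <- as.integer(ceiling(max(cohort$t1 - cohort$t0)))
  if (is.null(.precomp)) .precomp <- precompute_tails(cohort, model)
  annual <- integer(K); annual_m <- integer(K); annual_f <- integer(K)
  rejections <- 0L
  male <- cohort$gender == "male"
  for (i in seq_len(n)) {
    subj <- as_subject(cohort, i)
    set.seed(stream_seed(seed, rep, i))
    out <- simulate_subject(subj, model, interval, max_rejections,
                            s0 = .precomp$s0[i], s1 = .precomp$s1[i])
    rejections <- rejections + out$rejections
    if (out$died) {
      k <- followup_year(out$death_age, subj$t0)
      if (k <= K) {
        annual[k] <- annual[k] + 1L
        if (male[i]) annual_m[k] <- annual_m[k] + 1L
        else annual_f[k] <- annual_f[k] + 1L
      }
    }
  }
  list(annual = annual, annual_male = annual_m, annual_female = annual_f,
       rejections = rejections)
}

#' Replicate-trial simulation with percentile confidence bands
#'
#' Simulates `n_reps` independent trials of the whole cohort and
#' summarizes annual, cumulative, and total lung-cancer deaths per
#' follow-up year as the replicate mean with empirical 2.5% and 97.5%
#' percentile bands.  The default of 5000 replicates matches the usual
#' protocol for this adjustment.  Fully reproducible from `(seed,
#' n_reps, cohort order)`.
#'
#' @inheritParams simulate_trial
#' @param n_reps Number of replicate trials (>= 2; default 5000).
#' @param progress Print a progress line every 500 replicates.
#' @return An object of class `trial_summary`: a list with data frames
#'   `annual` and `cumulative` (columns `year, mean, lo, hi`), a `total`
#'   data frame (rows overall/male/female), replicate count, seed,
#'   follow-up length `K`, mean rejection count per trial, and the raw
#'   replicate count matrices (`counts`, `counts_male`,
#'   `counts_female`).
#' @export
run_trials <- function(cohort, model, interval = NULL, n_reps = 5000,
                       seed = 1L, max_rejections = 10000,
                       progress = FALSE) {
  if (n_reps < 2) stop("n_reps must be >= 2", call. = FALSE)
  cohort <- validate_cohort(cohort)
  K <- as.integer(ceiling(max(cohort$t1 - cohort$t0)))
  precomp <- precompute_tails(cohort, model)
  counts <- matrix(0L, n_reps, K)
  counts_m <- matrix(0L, n_reps, K)
  counts_f <- matrix(0L, n_reps, K)
  rejections <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    tr <- simulate_trial(cohort, model, interval, seed = seed, rep = r,
                         K = K, max_rejections = max_rejections,
                         .precomp = precomp)
    counts[r, ] <- tr$annual
    counts_m[r, ] <- tr$annual_male
    counts_f[r, ] <- tr$annual_female
    rejections[r] <- tr$rejections
    if (progress && r %% 500 == 0)
      message("replicate ", r, "/", n_reps)
  }
  pct <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE,
                                     type = 7)
  band_frame <- function(mat) {
    qs <- apply(mat, 2, pct)
    data.frame(year = seq_len(ncol(mat)), mean = colMeans(mat),
               lo = qs[1, ], hi = qs[2, ])
  }
  row_cumsum <- function(mat)
    if (ncol(mat) == 1) mat else t(apply(mat, 1, cumsum))
  cum <- row_cumsum(counts)
  cum_m <- row_cumsum(counts_m)
  cum_f <- row_cumsum(counts_f)
  totals <- data.frame(
    group = c("overall", "male", "female"),
    mean = c(mean(cum[, K]), mean(cum_m[, K]), mean(cum_f[, K])),
    lo = c(pct(cum[, K])[1], pct(cum_m[, K])[1], pct(cum_f[, K])[1]),
    hi = c(pct(cum[, K])[2], pct(cum_m[, K])[2], pct(cum_f[, K])[2]))
  structure(list(annual = band_frame(counts),
                 cumulative = band_frame(cum),
                 total = totals,
                 n_reps = n_reps, seed = seed, K = K,
                 mean_rejections = mean(rejections),
                 counts = counts, counts_male = counts_m,
                 counts_female = counts_f),
            class = "trial_summary")
}

#' @export
print.trial_summary <- function(x, ...) {
  tot <- x$total[x$total$group == "overall", ]
  cat(sprintf(paste0(
    "<trial_summary: %d replicates, %d follow-up years>\n",
    "  total deaths: %.1f (95%% band %.0f, %.0f)\n",
    "  mean rejections per trial: %.2f\n"),
    x$n_reps, x$K, tot$mean, tot$lo, tot$hi, x$mean_rejections))
  invisible(x)
}

#' Compare predicted with observed lung-cancer deaths
#'
#' Bins the cohort's observed lung-cancer deaths into follow-up years
#' with the same rule as the simulator and lays them beside the
#' predicted replicate mean and 95% percentile band, annually,
#' cumulatively, and as totals overall and by gender.
#'
#' @param cohort A cohort with `observed_lc_death`/`observed_death_age`
#'   populated.
#' @param summary A [run_trials()] result for the same cohort.
#' @return A list of class `observed_comparison` with data frames
#'   `annual` (year, observed, predicted mean/lo/hi), `cumulative`, and
#'   `totals` (overall/male/female).
#' @export
compare_observed <- function(cohort, summary) {
  cohort <- validate_cohort(cohort)
  if (all(is.na(cohort$observed_lc_death)))
    stop("cohort carries no observed outcomes", call. = FALSE)
  if (!inherits(summary, "trial_summary"))
    stop("summary must come from run_trials()", call. = FALSE)
  K <- summary$K
  obs_year <- function(rows) {
    d <- rows[!is.na(rows$observed_lc_death) & rows$observed_lc_death, ]
    tabulate(pmin(followup_year(d$observed_death_age, d$t0), K), nbins = K)
  }
  obs <- obs_year(cohort)
  obs_m <- obs_year(cohort[cohort$gender == "male", ])
  obs_f <- obs_year(cohort[cohort$gender == "female", ])
  annual <- cbind(data.frame(year = seq_len(K), observed = obs),
                  summary$annual[, c("mean", "lo", "hi")])
  cumulative <- cbind(data.frame(year = seq_len(K),
                                 observed = cumsum(obs)),
                      summary$cumulative[, c("mean", "lo", "hi")])
  totals <- cbind(
    data.frame(group = c("overall", "male", "female"),
               observed = c(sum(obs), sum(obs_m), sum(obs_f))),
    summary$total[, c("mean", "lo", "hi")])
  structure(list(annual = annual, cumulative = cumulative,
                 totals = totals),
            class = "observed_comparison")
}

#' @export
print.observed_comparison <- function(x, ...) {
  cat("Observed vs predicted lung-cancer deaths\n")
  print(x$totals, row.names = FALSE)
  invisible(x)
}
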