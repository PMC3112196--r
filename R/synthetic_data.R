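# Truncated-normal draws by inverse-CDF; location calibrated elsewhere
# so the *truncated* mean hits a requested target.
rtrunc_norm <- function(n, mu, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mu, sd)
  phi <- stats::pnorm(upper, mu, sd)
  stats::qnorm(stats::runif(n, plo, phi), mu, sd)
}

trunc_norm_mean <- function(mu, sd, lower = -Inf, upper = Inf) {
  a <- (lower - mu) / sd; b <- (upper - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# Location parameter such that the truncated-normal mean equals target.
calibrate_trunc_mu <- function(target, sd, lower = -Inf, upper = Inf) {
  if (is.finite(lower) && is.finite(upper) &&
      (target <= lower || target >= upper))
    stop("target mean ", target, " outside truncation bounds [", lower,
         ", ", upper, "]", call. = FALSE)
  stats::uniroot(function(mu) trunc_norm_mean(mu, sd, lower, upper) - target,
                 interval = target + c(-6, 6) * sd, extendInt = "yes",
                 tol = 1e-10)$root
}

# E[ min(X, cap) ] for X ~ N(mu, sd) truncated to [lower, Inf); used to
# pre-compensate the pack-year mean for the start-age floor.
trunc_norm_capped_mean <- function(mu, sd, lower, cap) {
  a <- (lower - mu) / sd; b <- (cap - mu) / sd
  pa <- stats::pnorm(a); pb <- stats::pnorm(b)
  if (pb <= pa) return(cap)
  num <- mu * (pb - pa) - sd * (stats::dnorm(b) - stats::dnorm(a)) +
    cap * (1 - pb)
  num / (1 - pa)
}

#' Specification of a synthetic heavy-smoker cohort
#'
#' Marginal moments and eligibility bounds for the synthetic cohort
#' generator.  The default reproduces the placebo control arm of a
#' chemoprevention trial of heavy smokers: 3797 males (age 58.4 (5.5),
#' pack-years 53 (21.5), follow-up 11.2 (3.4) years) and 3080 females
#' (age 58.2 (5.4), pack-years 44.4 (18.0), follow-up 11.8 (3.1)),
#' with eligibility requiring age 50-69 at enrollment, at least 20
#' pack-years, and current smoking or cessation within the previous 6
#' years; the longest follow-up is capped at 19.5 years.
#'
#' @param male,female Named lists with `n`, `age_mean`, `age_sd`,
#'   `packyears_mean`, `packyears_sd`, `followup_mean`, `followup_sd`.
#' @param age_range Eligible enrollment-age interval (years).
#' @param min_packyears Minimum pack-years at enrollment.
#' @param max_quit_lag Maximum years since cessation at enrollment.
#' @param max_followup Cap on follow-up (years).
#' @param min_start_age Floor on age at smoking initiation.
#' @param p_current Probability of being a current (vs former) smoker.
#' @param cigs_levels,cigs_probs Cigarettes/day mixture; per subject the
#'   mixture is renormalized over the levels compatible with the drawn
#'   pack-years and the start-age floor.
#' @return A list of class `cohort_spec`.
#' @export
caret_cohort_spec <- function(
    male = list(n = 3797, age_mean = 58.4, age_sd = 5.5,
                packyears_mean = 53, packyears_sd = 21.5,
                followup_mean = 11.2, followup_sd = 3.4),
    female = list(n = 3080, age_mean = 58.2, age_sd = 5.4,
                  packyears_mean = 44.4, packyears_sd = 18.0,
                  followup_mean = 11.8, followup_sd = 3.1),
    age_range = c(50, 69), min_packyears = 20, max_quit_lag = 6,
    max_followup = 19.5, min_start_age = 12, p_current = 0.6,
    cigs_levels = c(10, 20, 30, 40),
    cigs_probs = c(0.10, 0.30, 0.35, 0.25)) {
  spec <- list(male = male, female = female, age_range = age_range,
               min_packyears = min_packyears, max_quit_lag = max_quit_lag,
               max_followup = max_followup, min_start_age = min_start_age,
               p_current = p_current, cigs_levels = cigs_levels,
               cigs_probs = cigs_probs / sum(cigs_probs))
  for (g in c("male", "female")) {
    p <- spec[[g]]
    if (p$n <= 0) stop(g, ": n must be positive", call. = FALSE)
    if (p$age_mean - 4 * p$age_sd > age_range[2] ||
        p$age_mean + 4 * p$age_sd < age_range[1])
      stop(g, ": age bounds exclude mean +/- 4 sd", call. = FALSE)
    if (p$packyears_mean + 4 * p$packyears_sd < min_packyears)
      stop(g, ": pack-year bound excludes mean +/- 4 sd", call. = FALSE)
  }
  class(spec) <- "cohort_spec"
  spec
}

#' Generate a synthetic heavy-smoker cohort
#'
#' Draws subjects satisfying the eligibility bounds of the spec:
#' enrollment ages and pack-years are truncated-normal with the location
#' calibrated so the truncated means equal the spec targets; smoking
#' intensity is drawn from the cigarettes/day mixture restricted to
#' levels under which the implied start age (initiation such that the
#' drawn pack-years are accumulated by end of smoking) stays above the
#' start-age floor; current smokers (probability `p_current`) smoke
#' through follow-up, former smokers quit uniformly within
#' `max_quit_lag` years before enrollment; follow-up is truncated-normal
#' capped at `max_followup`.  The pack-year location is additionally
#' pre-compensated for the rare start-age-floor rescaling so the
#' realized pack-year mean stays on target.
#'
#' @param spec A [caret_cohort_spec()].
#' @param seed Integer seed.
#' @return A validated cohort data frame (no observed outcomes).
#' @export
generate_cohort <- function(spec = caret_cohort_spec(), seed = 1L) {
  set.seed(seed)
  one_gender <- function(g) {
    p <- spec[[g]]
    n <- p$n
    mu_age <- calibrate_trunc_mu(p$age_mean, p$age_sd,
                                 spec$age_range[1], spec$age_range[2])
    t0 <- rtrunc_norm(n, mu_age, p$age_sd,
                      spec$age_range[1], spec$age_range[2])
    current <- stats::runif(n) < spec$p_current
    quit_age <- ifelse(current, NA_real_,
                       t0 - stats::runif(n, 0, spec$max_quit_lag))
    quit_eff <- ifelse(current, t0, quit_age)
    # pack-year cap implied by the start-age floor at the heaviest level
    cap <- (quit_eff - spec$min_start_age) *
      max(spec$cigs_levels) / 20
    mu_py <- stats::uniroot(function(mu) {
      mean(vapply(cap, function(cp)
        trunc_norm_capped_mean(mu, p$packyears_sd, spec$min_packyears, cp),
        numeric(1))) - p$packyears_mean
    }, interval = p$packyears_mean + c(-6, 6) * p$packyears_sd,
    extendInt = "yes", tol = 1e-8)$root
    py <- rtrunc_norm(n, mu_py, p$packyears_sd, spec$min_packyears, Inf)
    cigs <- numeric(n); start <- numeric(n)
    for (i in seq_len(n)) {
      min_cigs <- 20 * py[i] / (quit_eff[i] - spec$min_start_age)
      feasible <- spec$cigs_levels >= min_cigs
      if (any(feasible)) {
        pr <- spec$cigs_probs[feasible]
        cigs[i] <- spec$cigs_levels[feasible][
          sample.int(sum(feasible), 1, prob = pr / sum(pr))]
        start[i] <- quit_eff[i] - py[i] * 20 / cigs[i]
      } else {
        cigs[i] <- max(spec$cigs_levels)
        start[i] <- spec$min_start_age   # pack-years rescaled to the cap
        py[i] <- (quit_eff[i] - start[i]) * cigs[i] / 20
      }
    }
    mu_fu <- calibrate_trunc_mu(p$followup_mean, p$followup_sd,
                                0.5, spec$max_followup)
    fu <- rtrunc_norm(n, mu_fu, p$followup_sd, 0.5, spec$max_followup)
    data.frame(
      id = sprintf("%s%04d", toupper(substr(g, 1, 1)), seq_len(n)),
      gender = g, t0 = t0, t1 = t0 + fu, age_start = start,
      age_quit = quit_age, cigs_per_day = cigs,
      observed_lc_death = NA, observed_death_age = NA_real_)
  }
  cohort <- rbind(one_gender("male"), one_gender("female"))
  validate_cohort(cohort)
  cohort
}

#' Specification of synthetic stage-stratified survival records
#'
#' @param n Number of diagnosed patients (default 1190).
#' @param stage_medians Named vector of per-stage median survival
#'   (months).
#' @param weights Stage mix at diagnosis (a [stage_weights()]; default
#'   the SEER-17 year-2000 distribution).
#' @param censor_frac Fraction of records censored (in `[0, 1)`).
#' @return A list of class `survival_spec`.
#' @export
survival_spec <- function(n = 1190,
                          stage_medians = c(I = 60, II = 35, III = 14,
                                            IV = 6),
                          weights = seer_stage_weights_2000(),
                          censor_frac = 0.1) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (any(stage_medians <= 0))
    stop("stage medians must be positive", call. = FALSE)
  if (censor_frac < 0 || censor_frac >= 1)
    stop("censor_frac must be in [0, 1)", call. = FALSE)
  if (!setequal(names(stage_medians), STAGE_LEVELS))
    stop("stage_medians must be named I-IV", call. = FALSE)
  structure(list(n = n,
                 stage_medians = stage_medians[STAGE_LEVELS],
                 weights = stage_weights(weights),
                 censor_frac = censor_frac),
            class = "survival_spec")
}

#' Scale stage medians to hit a target overall mixture median
#'
#' Finds the common scale factor `k` such that the stage-weighted
#' exponential mixture `sum_s w_s 2^(-t / (k m_s))` has median exactly
#' `target_median` months, and returns the scaled medians.  Used to
#' construct synthetic survival data whose weighted overall curve has a
#' known median.
#'
#' @param target_median Desired overall median (months).
#' @param base_medians Named per-stage medians setting the relative
#'   profile.
#' @param weights A [stage_weights()].
#' @return Named vector of scaled stage medians (months).
#' @export
calibrate_stage_medians <- function(target_median,
                                    base_medians = c(I = 60, II = 35,
                                                     III = 14, IV = 6),
                                    weights = seer_stage_weights_2000()) {
  w <- stage_weights(weights)
  base_medians <- base_medians[STAGE_LEVELS]
  mix_surv <- function(k)
    sum(as.numeric(w) * 2^(-target_median / (k * base_medians)))
  k <- stats::uniroot(function(k) mix_surv(k) - 0.5,
                      interval = c(1e-3, 1e3), tol = 1e-12)$root
  k * base_medians
}

#' Synthetic analogue of a tertiary-referral survival series
#'
#' A [survival_spec()] whose stage medians are calibrated so the
#' SEER-weighted overall mixture median is exactly `target_median`
#' months (default 17, the longer median typical of a tertiary cancer
#' center), with the default sample size of 1190 patients.
#'
#' @param target_median Overall mixture median (months).
#' @param n Number of patients.
#' @param censor_frac Fraction censored.
#' @return A `survival_spec`.
#' @export
mda_survival_spec <- function(target_median = 17, n = 1190,
                              censor_frac = 0.1) {
  survival_spec(n = n,
                stage_medians = calibrate_stage_medians(target_median),
                censor_frac = censor_frac)
}

#' Generate synthetic stage-stratified survival records
#'
#' Assigns each patient a stage from the spec's stage mix, draws an
#' exponential survival time with the stage-specific median, and
#' censors the requested fraction of records at an independent uniform
#' time before their event.
#'
#' @param spec A [survival_spec()].
#' @param seed Integer seed.
#' @return A survival-record data frame (see [survival_records()]).
#' @export
generate_survival <- function(spec = mda_survival_spec(), seed = 1L) {
  set.seed(seed)
  stage <- sample(STAGE_LEVELS, spec$n, replace = TRUE,
                  prob = as.numeric(spec$weights))
  time <- stats::rexp(spec$n,
                      rate = log(2) / spec$stage_medians[stage])
  event <- rep(TRUE, spec$n)
  if (spec$censor_frac > 0) {
    # independent U(0, c_max) censoring times, with c_max calibrated so
    # the expected censored fraction P(C < T) equals censor_frac;
    # independence keeps the Kaplan-Meier estimate consistent
    w <- as.numeric(spec$weights)
    m <- spec$stage_medians
    frac <- function(cmax)
      sum(w * (m / log(2)) * (1 - 2^(-cmax / m))) / cmax
    cmax <- stats::uniroot(function(cm) frac(cm) - spec$censor_frac,
                           interval = c(1e-6, 1e6), tol = 1e-10)$root
    cens <- stats::runif(spec$n, 0, cmax)
    censored <- cens < time
    time[censored] <- cens[censored]
    event[censored] <- FALSE
  }
  survival_records(time, event, stage)
}
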