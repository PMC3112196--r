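#' Survival-model interface
#'
#' A survival model supplies the tail function `S(t; d)`: the
#' probability that a subject with smoking history `d` and given gender
#' has not died of lung cancer by age `t` (with `t = 0` at birth).  It
#' must satisfy `S(0) = 1`, be non-increasing in `t`, and depend on the
#' history only through its portion before `t` (so never-smokers and
#' smokers prior to initiation are identical).
#'
#' @param name Short model label.
#' @param evaluate `function(t, history, gender)` returning `S(t; d)`;
#'   vectorized over `t`.
#' @param density Optional `function(t, history, gender)` giving the
#'   exact age-at-death density `-dS/dt`; when absent, consumers fall
#'   back to numerical differentiation.
#' @return An object of class `survival_model`.
#' @seealso [tsce_model()], [toy_exponential_model()]
#' @export
survival_model <- function(name, evaluate, density = NULL) {
  stopifnot(is.function(evaluate))
  structure(list(name = name, evaluate = evaluate, density = density),
            class = "survival_model")
}

#' @export
print.survival_model <- function(x, ...) {
  cat(sprintf("<survival_model: %s%s>\n", x$name,
              if (is.null(x$density)) "" else ", analytic density"))
  invisible(x)
}

#' Closed-form exponential test model
#'
#' `S(t) = exp(-rate * t)` regardless of smoking history and gender: a
#' constant-hazard model with exact density and exact tail inverse, used
#' for oracle checks and toy cohorts.
#'
#' @param rate Constant hazard (per year, > 0).
#' @return A [survival_model()] exposing an analytic `density`.
#' @export
toy_exponential_model <- function(rate) {
  stopifnot(is.finite(rate), rate > 0)
  survival_model(
    name = sprintf("toy-exponential(rate=%g)", rate),
    evaluate = function(t, history, gender) exp(-rate * t),
    density = function(t, history, gender) rate * exp(-rate * t))
}

#' TSCE model parameters
#'
#' Parameters of the two-stage clonal expansion (TSCE) carcinogenesis
#' model: normal cells acquire a first (initiation) event at rate `nu`
#' (initiated cells per year, the product of the per-cell rate and the
#' number of normal cells); initiated cells divide at rate `alpha`, die
#' or differentiate at rate `beta`, and acquire the malignant
#' transformation at rate `mu` (all per cell-year); malignancy leads to
#' lung-cancer death after a fixed `lag` (years).  During active smoking
#' the initiation and division rates are multiplied by dose-response
#' factors `1 + coef * dose^exponent` of the intensity in cigarettes/day.
#'
#' @param male,female Named lists with elements `nu`, `alpha`, `beta`,
#'   `mu`, `lag` (all `>= 0`).
#' @param dose_response Named list with elements `nu` and `alpha`, each
#'   `c(coef, exponent)` for the multiplicative factor active between
#'   initiation and cessation of smoking.
#' @return An object of class `tsce_params`.
#' @details `alpha > beta` (supercritical clonal growth) is the expected
#'   regime; a subcritical parameterization is accepted with a warning.
#' @export
tsce_params <- function(male, female = male,
                        dose_response = list(nu = c(coef = 0.15, exponent = 1),
                                             alpha = c(coef = 6.5e-4, exponent = 0.8))) {
  check_one <- function(p, label) {
    need <- c("nu", "alpha", "beta", "mu", "lag")
    missing_par <- setdiff(need, names(p))
    if (length(missing_par))
      stop(label, " parameters missing: ",
           paste(missing_par, collapse = ", "), call. = FALSE)
    p <- lapply(p[need], as.numeric)
    if (any(!vapply(p, is.finite, logical(1))) ||
        any(unlist(p) < 0))
      stop(label, " parameters must be finite and >= 0", call. = FALSE)
    if (p$alpha <= p$beta)
      warning(label,
              ": alpha <= beta (subcritical clonal growth); the usual ",
              "TSCE regime has alpha > beta", call. = FALSE)
    p
  }
  dr <- lapply(dose_response[c("nu", "alpha")], function(v) {
    v <- as.numeric(v)
    if (length(v) != 2 || any(!is.finite(v)) || v[1] < 0)
      stop("dose_response entries must be c(coef >= 0, exponent)",
           call. = FALSE)
    c(coef = v[1], exponent = v[2])
  })
  structure(list(male = check_one(male, "male"),
                 female = check_one(female, "female"),
                 dose_response = dr),
            class = "tsce_params")
}

#' Synthetic default TSCE parameter set
#'
#' A placeholder parameterization for testing and demonstration: it is
#' *not* a fit to epidemiological data, but is tuned once to realistic
#' lifetime lung-cancer mortality magnitudes (of order 1% by age 80 for
#' never-smokers and over tenfold higher for lifelong heavy smokers).
#' Substantive applications should supply their own fitted parameters
#' via [tsce_params()] (e.g. from a model-fitting study) through the
#' model-configuration interface.
#'
#' @return A [tsce_params()] object.
#' @export
default_tsce_params <- function() {
  tsce_params(
    male = list(nu = 1.2, alpha = 9, beta = 8.87, mu = 1e-8, lag = 5),
    female = list(nu = 1.08, alpha = 9, beta = 8.87, mu = 1e-8, lag = 5),
    dose_response = list(nu = c(coef = 0.15, exponent = 1),
                         alpha = c(coef = 6.5e-4, exponent = 0.8)))
}

# Piecewise-constant parameter segments on the age axis induced by a
# smoking history: [0, start), [start, quit_eff), [quit_eff, Inf), with
# the smoking multipliers active only on the middle segment.  A missing
# quit age means still smoking (quit_eff = Inf).
tsce_segments <- function(history, gender, params) {
  base <- params[[gender]]
  if (is.null(base)) stop("unknown gender '", gender, "'", call. = FALSE)
  dose <- history$cigs_per_day
  if (dose == 0)
    return(list(list(a = 0, b = Inf, nu = base$nu, alpha = base$alpha,
                     beta = base$beta, mu = base$mu)))
  dr <- params$dose_response
  mult_nu <- 1 + dr$nu[["coef"]] * dose^dr$nu[["exponent"]]
  mult_alpha <- 1 + dr$alpha[["coef"]] * dose^dr$alpha[["exponent"]]
  quit_eff <- if (is.na(history$age_quit)) Inf else history$age_quit
  segs <- list(
    list(a = 0, b = history$age_start, nu = base$nu, alpha = base$alpha,
         beta = base$beta, mu = base$mu),
    list(a = history$age_start, b = quit_eff, nu = base$nu * mult_nu,
         alpha = base$alpha * mult_alpha, beta = base$beta, mu = base$mu),
    list(a = quit_eff, b = Inf, nu = base$nu, alpha = base$alpha,
         beta = base$beta, mu = base$mu))
  Filter(function(s) s$b > s$a, segs)
}

# Backward Riccati propagation over one constant-parameter segment.
#
# Gamma(s) = P(a clone seeded by one initiated cell at time s contains
# no malignant cell by the horizon), satisfying (backward in s)
#   dGamma/ds = (alpha+beta+mu) Gamma - alpha Gamma^2 - beta
#             = -alpha (Gamma - rp)(Gamma - rm),  rm < 1 <= rp,
# with terminal value Gb at s = b.  Returns Gamma(a) and the integral of
# Gamma over [a, b].  The ratio R(s) = (Gamma-rp)/(Gamma-rm) satisfies
# R(s) = R(b) exp(D (b - s)) with D = alpha (rp - rm) > 0, and is <= 0
# for Gamma in (rm, 1], so backward propagation drives Gamma from Gb
# down toward the extinction fixed point rm.  Logs of (1 - R) are
# computed in softplus form since |R(a)| can overflow for long segments.
riccati_propagate <- function(Gb, a, b, alpha, beta, mu) {
  delta <- b - a
  g <- alpha + beta + mu
  disc <- g^2 - 4 * alpha * beta
  if (alpha < 1e-12 || disc <= 1e-14 * g^2)
    return(riccati_propagate_ode(Gb, a, b, alpha, beta, mu))
  D <- sqrt(disc)
  rp <- (g + D) / (2 * alpha)
  rm <- (g - D) / (2 * alpha)
  if (abs(Gb - rm) < 1e-14)           # terminal value at the fixed point
    return(list(Ga = Gb, int_gamma = Gb * delta))
  if (abs(Gb - rp) < 1e-12 * max(1, rp)) {  # at the upper fixed point
    return(list(Ga = Gb, int_gamma = Gb * delta))
  }
  Rb <- (Gb - rp) / (Gb - rm)
  # R(s) keeps its sign along the segment: R < 0 for Gamma in (rm, rp),
  # R > 1 for Gamma < rm (reachable when a preceding segment has a lower
  # fixed point).  |1 - R| never vanishes, so log|1 - R| is computed from
  # the log-magnitude of R, which is overflow-safe for long segments.
  softplus <- function(x) if (x > 30) x + log1p(exp(-x)) else log1p(exp(x))
  log_abs_1mR <- function(l) {
    # l = log|R|; sign of R taken from Rb
    if (Rb < 0) softplus(l)                       # log(1 + |R|)
    else if (l > 30) l else l + log1p(-exp(-l))   # log(|R| - 1), |R| > 1
  }
  lRb <- log(abs(Rb))
  lRa <- lRb + D * delta
  la_b <- log_abs_1mR(lRb)
  la_a <- log_abs_1mR(lRa)
  Ga <- if (Rb < 0) rm + (rp - rm) * exp(-la_a)
        else        rm - (rp - rm) * exp(-la_a)
  int_gamma <- rm * delta + (rp - rm) * (delta + (la_b - la_a) / D)
  list(Ga = Ga, int_gamma = int_gamma)
}

# Numerical fallback for degenerate segments (alpha ~ 0 or repeated
# Riccati roots): integrate Gamma and its running integral with an
# adaptive ODE solver in the reversed time tau = b - s.
riccati_propagate_ode <- function(Gb, a, b, alpha, beta, mu) {
  delta <- b - a
  rhs <- function(tau, y, parms) {
    g <- alpha + beta + mu
    list(c(alpha * y[1]^2 - g * y[1] + beta, y[1]))
  }
  sol <- deSolve::ode(y = c(Gb, 0), times = c(0, delta), func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-11, atol = 1e-12)
  list(Ga = sol[2, 2], int_gamma = sol[2, 3])
}

# log S_mal(t): minus the integrated rate of malignancy-producing
# initiations, sum over segments of nu * integral of (1 - Gamma).
tsce_log_survival_raw <- function(t, segs) {
  if (t <= 0) return(0)
  G <- 1
  H <- 0
  for (i in rev(seq_along(segs))) {
    a <- max(segs[[i]]$a, 0)
    b <- min(segs[[i]]$b, t)
    if (b <= a) next
    res <- riccati_propagate(G, a, b, segs[[i]]$alpha, segs[[i]]$beta,
                             segs[[i]]$mu)
    if (!is.finite(res$Ga) || !is.finite(res$int_gamma))
      stop("non-finite TSCE propagation on segment [", format(a), ", ",
           format(b), "] (alpha = ", segs[[i]]$alpha, ", beta = ",
           segs[[i]]$beta, ", mu = ", segs[[i]]$mu, ")", call. = FALSE)
    H <- H + segs[[i]]$nu * ((b - a) - res$int_gamma)
    G <- res$Ga
  }
  -H
}

#' TSCE tail function
#'
#' Probability of no lung-cancer death by age `t` under the two-stage
#' clonal expansion model with smoking-history-dependent
#' piecewise-constant parameters.  The no-malignancy probability is
#' propagated backward across the history-induced parameter segments via
#' the closed-form solution of the clone-extinction Riccati equation
#' (with an adaptive ODE fallback for degenerate segments), and death is
#' the malignancy time shifted by the fixed lag:
#' `S_death(t) = S_malignancy(max(t - lag, 0))`.
#'
#' @param t Ages in years (>= 0); vectorized.
#' @param history A [smoking_history()].
#' @param gender `"male"` or `"female"`.
#' @param params A [tsce_params()] object.
#' @return Survival probabilities in `(0, 1]`.
#' @examples
#' p <- default_tsce_params()
#' tsce_survival(70, never_smoker(), "male", p)
#' tsce_survival(70, smoking_history(18, NA, 30), "male", p)
#' @export
tsce_survival <- function(t, history, gender, params) {
  if (any(!is.finite(t) | t < 0))
    stop("ages must be finite and >= 0", call. = FALSE)
  segs <- tsce_segments(history, gender, params)
  lag <- params[[gender]]$lag
  vapply(t, function(ti) {
    exp(tsce_log_survival_raw(max(ti - lag, 0), segs))
  }, numeric(1))
}

#' TSCE model as a pluggable survival model
#'
#' Wraps [tsce_survival()] with a fixed parameter set into the
#' [survival_model()] interface used by the simulator and oracle.
#'
#' @param params A [tsce_params()] object
#'   (default [default_tsce_params()]).
#' @return A [survival_model()].
#' @export
tsce_model <- function(params = default_tsce_params()) {
  force(params)
  survival_model(
    name = "tsce",
    evaluate = function(t, history, gender)
      tsce_survival(t, history, gender, params))
}

#' Invert the tail function of the age-at-death distribution
#'
#' Solves `S(t*; d) = u` for `t*` in the subject's follow-up window
#' `(t0, t1)` by bisection on the monotone tail function.
#'
#' @param u Tail probability, strictly between `S(t1; d)` and
#'   `S(t0; d)`.
#' @param subject A list with elements `t0`, `t1`, `gender`, `history`
#'   (see [as_subject()]).
#' @param model A [survival_model()].
#' @param tol Tolerance on `|S(t*) - u|` (default `1e-9`).
#' @return The age at death `t*` (years).
#' @export
invert_tail <- function(u, subject, model, tol = 1e-9) {
  h <- subject$history; g <- subject$gender
  s0 <- model$evaluate(subject$t0, h, g)
  s1 <- model$evaluate(subject$t1, h, g)
  if (!(u > s1 && u < s0))
    stop("u = ", format(u), " outside (S(t1), S(t0)) = (", format(s1),
         ", ", format(s0), ")", call. = FALSE)
  lo <- subject$t0; hi <- subject$t1
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    sm <- model$evaluate(mid, h, g)
    if (abs(sm - u) <= tol || (hi - lo) < 1e-13 * max(1, subject$t1))
      return(mid)
    if (sm > u) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Vectorized bisection for many u values for one subject; used by the
# single-subject batch simulator.  Same contract as invert_tail.
invert_tail_vec <- function(u, subject, model, tol = 1e-9) {
  if (!length(u)) return(numeric(0))
  h <- subject$history; g <- subject$gender
  lo <- rep(subject$t0, length(u)); hi <- rep(subject$t1, length(u))
  done <- rep(FALSE, length(u)); out <- numeric(length(u))
  for (iter in 1:100) {
    mid <- (lo + hi) / 2
    sm <- model$evaluate(mid, h, g)
    hit <- !done & (abs(sm - u) <= tol | (hi - lo) < 1e-13)
    out[hit] <- mid[hit]; done <- done | hit
    if (all(done)) break
    up <- !done & sm > u
    lo[up] <- mid[up]; hi[!done & !up] <- mid[!done & !up]
  }
  out[!done] <- (lo[!done] + hi[!done]) / 2
  out
}

#' Subject view of one cohort row
#'
#' @param cohort A cohort data frame.
#' @param i Row index.
#' @return A list with `id`, `gender`, `t0`, `t1`, `history`,
#'   `observed_lc_death`, `observed_death_age`.
#' @export
as_subject <- function(cohort, i) {
  list(id = cohort$id[i], gender = cohort$gender[i],
       t0 = cohort$t0[i], t1 = cohort$t1[i],
       history = subject_history(cohort, i),
       observed_lc_death = cohort$observed_lc_death[i],
       observed_death_age = cohort$observed_death_age[i])
}
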