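# Independent numerical oracle for the TSCE tail function: direct
# adaptive ODE integration of the clone-extinction Riccati system and
# the cumulative initiation integral, in reversed time tau = t - s,
# with its own piecewise-parameter lookup (shares no propagation code
# with the package implementation).
ode_tsce_survival <- function(t_age, history, gender, params) {
  base <- params[[gender]]
  dr <- params$dose_response
  t <- max(t_age - base$lag, 0)
  if (t == 0) return(1)
  dose <- history$cigs_per_day
  quit <- if (is.na(history$age_quit)) Inf else history$age_quit
  smoking_at <- function(s) {
    dose > 0 && s >= history$age_start && s < quit
  }
  # integrate piece by piece, restarting at the parameter
  # discontinuities (smoking initiation/cessation), where a single-pass
  # adaptive step would lose accuracy; each piece has constant
  # parameters chosen by its midpoint
  breaks <- sort(unique(pmin(pmax(c(0, t - quit, t - history$age_start,
                                    t), 0), t)))
  breaks <- breaks[!is.na(breaks)]
  y <- c(1, 0)
  for (j in seq_len(length(breaks) - 1)) {
    if (breaks[j + 1] - breaks[j] < 1e-12) next
    s_mid <- t - (breaks[j] + breaks[j + 1]) / 2
    if (smoking_at(s_mid)) {
      nu <- base$nu * (1 + dr$nu[["coef"]] * dose^dr$nu[["exponent"]])
      al <- base$alpha *
        (1 + dr$alpha[["coef"]] * dose^dr$alpha[["exponent"]])
    } else {
      nu <- base$nu
      al <- base$alpha
    }
    g <- al + base$beta + base$mu
    rhs <- function(tau, y, parms)
      list(c(al * y[1]^2 - g * y[1] + base$beta, nu * (1 - y[1])))
    sol <- deSolve::ode(y, times = c(breaks[j], breaks[j + 1]), rhs,
                        NULL, method = "ode45", rtol = 1e-13,
                        atol = 1e-15, hmax = 0.1)
    y <- unname(sol[nrow(sol), 2:3])
  }
  unname(exp(-y[2]))
}

# Flat toy cohort of never-smokers for simulator tests: identical
# follow-up windows, gender split for the by-gender bookkeeping.
make_toy_cohort <- function(n, t0 = 55, followup = 10) {
  data.frame(
    id = as.character(seq_len(n)),
    gender = rep(c("male", "female"), length.out = n),
    t0 = rep(t0, n), t1 = rep(t0 + followup, n),
    age_start = NA_real_, age_quit = NA_real_, cigs_per_day = 0,
    observed_lc_death = NA, observed_death_age = NA_real_)
}

toy_subject <- function(t0 = 55, t1 = 65, gender = "male") {
  list(id = "toy", gender = gender, t0 = t0, t1 = t1,
       history = never_smoker())
}

# Independent per-subject seed mix for regenerating "observed" outcomes.
stream_seed_for_test <- function(seed, i) {
  as.integer((seed * 7919 + i * 104729) %% 2147483647 + 1)
}

# Random toy configuration for oracle-equivalence checks.
random_toy_config <- function() {
  t0 <- runif(1, 50, 62)
  list(rate = 1 / runif(1, 30, 80),
       t0 = t0,
       t1 = t0 + runif(1, 2, 4),
       mean = runif(1, 0.5, 3))
}
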