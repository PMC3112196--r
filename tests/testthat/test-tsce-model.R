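test_that("TSCE tail function satisfies its boundary and degeneracy laws", {
  p <- default_tsce_params()
  h <- smoking_history(18, 50, 30)
  expect_equal(tsce_survival(0, h, "male", p), 1)
  expect_equal(tsce_survival(3, h, "male", p), 1)  # within the lag

  # no malignant transformation => no lung-cancer death, ever
  p0 <- suppressWarnings(tsce_params(
    male = list(nu = 1.2, alpha = 9, beta = 8.87, mu = 0, lag = 5)))
  for (t in c(10, 50, 90))
    expect_equal(tsce_survival(t, h, "male", p0), 1, tolerance = 1e-12)

  expect_error(tsce_survival(-1, h, "male", p), "ages")
})

test_that("TSCE survival is monotone and history-consistent", {
  p <- default_tsce_params()
  grid <- seq(0, 90, by = 2.5)
  for (h in list(never_smoker(), smoking_history(16, NA, 40),
                 smoking_history(22, 45, 10))) {
    s <- tsce_survival(grid, h, "female", p)
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s > 0 & s <= 1))
  }

  ns <- tsce_survival(grid, never_smoker(), "male", p)
  # vanishing dose coincides with never smoking
  eps <- tsce_survival(grid, smoking_history(18, 55, 1e-9), "male", p)
  expect_equal(eps, ns, tolerance = 1e-8)
  # prior to initiation, smokers and never-smokers are identical
  sm <- tsce_survival(c(5, 10, 20), smoking_history(20, NA, 30),
                      "male", p)
  expect_equal(sm, tsce_survival(c(5, 10, 20), never_smoker(), "male", p),
               tolerance = 1e-12)

  # heavier exposure never increases survival
  light <- tsce_survival(grid, smoking_history(22, 45, 10), "male", p)
  heavy <- tsce_survival(grid, smoking_history(18, 60, 40), "male", p)
  expect_true(all(heavy <= light + 1e-12))
})

test_that("piecewise closed form agrees with independent ODE integration", {
  set.seed(61)
  for (i in 1:8) {
    alpha <- runif(1, 5, 12)
    beta <- alpha * runif(1, 0.9, 0.999)
    p <- tsce_params(
      male = list(nu = runif(1, 0.5, 3), alpha = alpha, beta = beta,
                  mu = 10^runif(1, -8, -5), lag = runif(1, 0, 6)),
      dose_response = list(nu = c(coef = runif(1, 0, 0.3), exponent = 1),
                           alpha = c(coef = runif(1, 0, 1e-3),
                                     exponent = 0.8)))
    h <- switch(sample.int(3, 1),
                never_smoker(),
                smoking_history(runif(1, 12, 25), NA, runif(1, 5, 40)),
                smoking_history(runif(1, 12, 25), runif(1, 40, 60),
                                runif(1, 5, 40)))
    for (t in c(35, 60, 85)) {
      a <- tsce_survival(t, h, "male", p)
      b <- ode_tsce_survival(t, h, "male", p)
      expect_equal(a, b, tolerance = 1e-8)
    }
  }
})

test_that("tail inversion solves S(t*) = u on the follow-up window", {
  # closed-form check: S(t) = exp(-t/50), u = exp(-1) inverts to t* = 50
  mod <- toy_exponential_model(1 / 50)
  subj <- toy_subject(t0 = 40, t1 = 60)
  expect_equal(invert_tail(exp(-1), subj, mod), 50, tolerance = 1e-6)

  # boundary continuity: u just below S(t0) maps just above t0
  s0 <- mod$evaluate(40, subj$history, subj$gender)
  expect_lt(invert_tail(s0 * (1 - 1e-9), subj, mod) - 40, 1e-4)

  expect_error(invert_tail(0.99, subj, mod), "outside")

  # round-trip property under the TSCE model
  p <- default_tsce_params()
  tm <- tsce_model(p)
  subj <- list(id = "x", gender = "male", t0 = 55, t1 = 70,
               history = smoking_history(17, NA, 30))
  s0 <- tm$evaluate(55, subj$history, "male")
  s1 <- tm$evaluate(70, subj$history, "male")
  set.seed(8)
  for (u in runif(6, s1, s0)) {
    t_star <- invert_tail(u, subj, tm)
    expect_true(t_star > 55 && t_star < 70)
    expect_equal(tm$evaluate(t_star, subj$history, "male"), u,
                 tolerance = 1e-9)
  }
})

test_that("parameter validation flags bad and subcritical inputs", {
  expect_error(tsce_params(male = list(nu = 1, alpha = 2, beta = 1)),
               "missing")
  expect_error(tsce_params(male = list(nu = -1, alpha = 2, beta = 1,
                                       mu = 1e-7, lag = 5)), ">= 0")
  expect_warning(tsce_params(male = list(nu = 1, alpha = 1, beta = 2,
                                         mu = 1e-7, lag = 5),
                             female = list(nu = 1, alpha = 2, beta = 1,
                                           mu = 1e-7, lag = 5)),
                 "subcritical")
})
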