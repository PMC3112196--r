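test_that("product-limit estimate matches hand computation", {
  # uncensored: KM is the empirical survival function
  recs <- survival_records(c(1, 2, 3, 4), rep(TRUE, 4), rep("I", 4))
  cv <- km_estimate(recs)
  expect_equal(cv$time, 1:4)
  expect_equal(cv$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km_median(cv), 2)   # S(2) = 0.5 exactly

  # censoring: S(1) = 2/3; at t = 3 one subject at risk dies, so S(3) =
  # 2/3 * (1 - 1/1) = 0 (hand product-limit computation)
  recs <- survival_records(c(1, 2, 3), c(TRUE, FALSE, TRUE),
                           rep("II", 3))
  cv <- km_estimate(recs)
  expect_equal(cv$time, c(1, 3))
  expect_equal(cv$surv, c(2 / 3, 0), tolerance = 1e-12)

  expect_error(km_estimate(survival_records(numeric(0), logical(0),
                                            character(0))), "zero")
  expect_error(km_estimate(survival_records(c(1, 2), c(FALSE, FALSE),
                                            c("I", "I"))), "censored")
})

test_that("KM median is consistent for exponential survival", {
  set.seed(101)
  m <- 17
  recs <- survival_records(rexp(10000, rate = log(2) / m),
                           rep(TRUE, 10000), rep("III", 10000))
  expect_lt(abs(km_median(km_estimate(recs)) - m), 0.5)
})

test_that("stage-weighted overall curve is the survival mixture", {
  set.seed(77)
  medians <- c(I = 60, II = 35, III = 14, IV = 6)
  curves <- lapply(medians, function(m) {
    km_estimate(survival_records(rexp(20000, log(2) / m),
                                 rep(TRUE, 20000), rep("I", 20000)))
  })
  names(curves) <- names(medians)
  w <- seer_stage_weights_2000()
  mix <- weighted_overall_curve(curves, w)

  # degenerate mixture reproduces the stage-I curve
  only1 <- weighted_overall_curve(curves,
                                  stage_weights(c(I = 1, II = 0, III = 0,
                                                  IV = 0)))
  expect_equal(km_surv_at(only1, c(5, 20, 61)),
               km_surv_at(curves$I, c(5, 20, 61)), tolerance = 1e-12)

  # mixture of identical curves is that curve
  same <- weighted_overall_curve(list(I = curves$I, II = curves$I,
                                      III = curves$I, IV = curves$I), w)
  expect_equal(km_surv_at(same, c(3, 30)), km_surv_at(curves$I, c(3, 30)),
               tolerance = 1e-12)

  # closed-form mixture oracle: sum_s w_s 2^(-t/m_s)
  grid <- c(3, 6, 12, 17, 24, 36)
  oracle <- vapply(grid, function(t)
    sum(as.numeric(w) * 2^(-t / medians)), numeric(1))
  expect_equal(km_surv_at(mix, grid), oracle, tolerance = 0.015)

  # monotone non-increasing for any valid weights
  expect_true(all(diff(mix$surv) <= 1e-12))

  expect_error(weighted_overall_curve(curves[c("I", "II")], w),
               "III")
})

test_that("median extraction uses the first-crossing convention", {
  flat <- km_curve(c(1, 5, 10), c(0.8, 0.7, 0.6))
  expect_error(km_median(flat), "median undefined")
  stepped <- km_curve(c(2, 4, 9), c(0.7, 0.5, 0.2))
  expect_equal(km_median(stepped), 4)  # first time S <= 0.5
})

test_that("median-to-exponential-mean conversion is exact", {
  expect_equal(round(exponential_from_median(17)$mean_years, 1), 2.0)
  expect_equal(round(exponential_from_median(11)$mean_years, 1), 1.3)
  expect_equal(exponential_from_median(12 * log(2))$mean_years, 1,
               tolerance = 1e-12)
  # round trip: mean -> implied median -> mean
  iv <- exponential_interval(2.5)
  expect_equal(exponential_from_median(iv$median_months)$mean_years, 2.5,
               tolerance = 1e-12)
  expect_error(exponential_from_median(0), "positive")
  expect_error(exponential_interval(-1), "positive")
})

test_that("interval estimation composes the pipeline correctly", {
  set.seed(13)
  # degenerate weights on one stage equal the unstratified pipeline
  recs <- survival_records(rexp(4000, log(2) / 9), rep(TRUE, 4000),
                           rep("IV", 4000))
  est <- estimate_interval(recs, stage_weights(c(I = 0, II = 0, III = 0,
                                                 IV = 1)))
  direct <- exponential_from_median(km_median(km_estimate(recs)))
  expect_equal(est$mean_years, direct$mean_years, tolerance = 1e-12)

  # KM (hence the estimate) is invariant under duplicating every record
  recs2 <- generate_survival(mda_survival_spec(n = 800), seed = 4)
  est1 <- estimate_interval(recs2)
  est2 <- estimate_interval(rbind(recs2, recs2))
  expect_equal(est2$mean_years, est1$mean_years, tolerance = 1e-12)

  # a stage with positive weight but no events is an error
  bad <- recs2[recs2$stage != "II", ]
  expect_error(estimate_interval(bad), "stage II")
})
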