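test_that("zero hazard in follow-up retires every simulation", {
  flat_model <- survival_model("flat-after-50",
    evaluate = function(t, h, g) exp(-0.02 * pmin(t, 50)))
  subj <- toy_subject(55, 65)
  set.seed(1)
  out <- simulate_subject(subj, flat_model, exponential_interval(2))
  expect_false(out$died)
  expect_equal(out$rejections, 0L)

  co <- make_toy_cohort(50, t0 = 55, followup = 10)
  tr <- simulate_trial(co, flat_model, NULL, seed = 1)
  expect_equal(sum(tr$annual), 0L)
})

test_that("accepted outcomes satisfy the subject-level invariants", {
  mod <- toy_exponential_model(1 / 40)
  subj <- toy_subject(55, 63)
  set.seed(3)
  dr <- simulate_subject_draws(subj, mod, exponential_interval(1.5),
                               n = 5000)
  died <- dr[dr$died, ]
  expect_gt(nrow(died), 0)
  expect_true(all(died$death_age > 55 & died$death_age <= 63))
  expect_true(all(died$diagnosis_age <= died$death_age))
  expect_true(all(died$diagnosis_age >= 55))
})

test_that("deaths are binned into half-open follow-up years", {
  co <- make_toy_cohort(3, t0 = 55, followup = 10)
  co$observed_lc_death <- c(TRUE, TRUE, TRUE)
  co$observed_death_age <- c(55.5, 56.0, 56.0001)  # boundary at year 1
  mod <- toy_exponential_model(1 / 40)
  sm <- run_trials(co, mod, NULL, n_reps = 2, seed = 1)
  cmp <- compare_observed(co, sm)
  expect_equal(cmp$annual$observed[1:2], c(2, 1))
  expect_equal(sum(cmp$annual$observed), 3)
})

test_that("unadjusted replicate means match the conditional death law", {
  co <- make_toy_cohort(400, t0 = 55, followup = 10)
  mod <- toy_exponential_model(1 / 40)
  sm <- run_trials(co, mod, NULL, n_reps = 150, seed = 2)
  p <- 1 - exp(-10 / 40)          # per-subject death probability
  expected <- 400 * p
  se <- sqrt(400 * p * (1 - p) / 150)
  tot <- sm$total$mean[sm$total$group == "overall"]
  expect_lt(abs(tot - expected), 3 * se)
  # gender split adds up
  expect_equal(sm$total$mean[2] + sm$total$mean[3], tot,
               tolerance = 1e-9)
  # cumulative is the running sum of annual means
  expect_equal(sm$cumulative$mean, cumsum(sm$annual$mean),
               tolerance = 1e-9)
})

test_that("identical seeds reproduce trials bit for bit", {
  co <- make_toy_cohort(60, t0 = 56, followup = 8)
  mod <- toy_exponential_model(1 / 35)
  iv <- exponential_interval(1.3)
  a <- run_trials(co, mod, iv, n_reps = 30, seed = 7)
  b <- run_trials(co, mod, iv, n_reps = 30, seed = 7)
  expect_identical(a$counts, b$counts)
  expect_identical(a$total, b$total)
  c2 <- run_trials(co, mod, iv, n_reps = 30, seed = 8)
  expect_false(identical(a$counts, c2$counts))
})

test_that("a vanishing interval reproduces the unadjusted simulation", {
  co <- make_toy_cohort(200, t0 = 55, followup = 10)
  mod <- toy_exponential_model(1 / 40)
  un <- run_trials(co, mod, NULL, n_reps = 80, seed = 5)
  ad <- run_trials(co, mod, exponential_interval(1e-6), n_reps = 80,
                   seed = 5)
  # shared substreams: the same uniforms drive both runs and w ~ 0
  expect_equal(ad$counts, un$counts)
})

test_that("the adjustment only ever removes deaths", {
  co <- make_toy_cohort(200, t0 = 55, followup = 10)
  mod <- toy_exponential_model(1 / 40)
  un <- run_trials(co, mod, NULL, n_reps = 60, seed = 4)
  ad <- run_trials(co, mod, exponential_interval(2), n_reps = 60,
                   seed = 4)
  expect_lt(ad$total$mean[1], un$total$mean[1])
})

test_that("the rejection cap trips on pathological subjects", {
  # death during follow-up is near-certain and the interval is enormous,
  # so diagnosis falls before enrollment in essentially every draw
  mod <- toy_exponential_model(10)
  subj <- toy_subject(55, 60)
  set.seed(9)
  expect_error(
    simulate_subject(subj, mod, exponential_interval(1e6),
                     max_rejections = 20),
    "rejection cap")
})

test_that("observed-vs-predicted comparison is additive and calibrated", {
  mod <- toy_exponential_model(1 / 45)
  iv <- exponential_interval(1.0)
  co <- make_toy_cohort(300, t0 = 55, followup = 10)

  # no observed deaths: observed column is all zero
  co0 <- co; co0$observed_lc_death <- FALSE
  sm <- run_trials(co0, mod, iv, n_reps = 40, seed = 3)
  cmp <- compare_observed(co0, sm)
  expect_true(all(cmp$annual$observed == 0))

  # observed outcomes generated by the model itself fall inside the 95%
  # band in most regenerations (calibration by construction)
  inside <- 0L
  for (rep in 1:8) {
    obs <- co
    obs$observed_lc_death <- FALSE
    # regenerate observed outcomes subject by subject from the same law
    for (i in seq_len(nrow(obs))) {
      set.seed(stream_seed_for_test(3000 + rep, i))
      o <- simulate_subject(as_subject(obs, i), mod, iv)
      if (o$died) {
        obs$observed_lc_death[i] <- TRUE
        obs$observed_death_age[i] <- o$death_age
      }
    }
    cmp <- compare_observed(obs, sm)
    tot <- cmp$totals[cmp$totals$group == "overall", ]
    if (tot$observed >= tot$lo && tot$observed <= tot$hi)
      inside <- inside + 1L
    # gender additivity holds in every regeneration
    expect_equal(sum(cmp$totals$observed[2:3]), cmp$totals$observed[1])
  }
  expect_gte(inside, 6)

  expect_error(compare_observed(make_toy_cohort(5), sm), "no observed")
})
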