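test_that("smoking histories enforce their invariants", {
  expect_s3_class(smoking_history(18, 55, 30), "smoking_history")
  expect_s3_class(smoking_history(20, NA, 20), "smoking_history")
  expect_equal(never_smoker()$cigs_per_day, 0)
  expect_error(smoking_history(NA, NA, 0.5), "age_start")
  expect_error(smoking_history(50, 40, 20), "age_quit")
  expect_error(smoking_history(18, 55, 0), "never-smokers")
  expect_error(smoking_history(18, 55, -1), "non-negative")
})

test_that("pack-years accrue only while smoking", {
  expect_equal(pack_years(smoking_history(20, 60, 20), at_age = 70), 40)
  expect_equal(pack_years(smoking_history(20, 60, 20), at_age = 50), 30)
  expect_equal(pack_years(smoking_history(20, NA, 40), at_age = 45), 50)
  expect_equal(pack_years(never_smoker(), 70), 0)
})

test_that("cohort files parse, validate and report row-level errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "gender,t0,t1,age_start,age_quit,cigs_per_day,observed_lc_death,observed_death_age",
    "male,55,65,18,,30,FALSE,",
    "female,58.5,70,20,50,20,TRUE,63.2",
    "male,60,72,,,0,FALSE,"), path)
  co <- read_cohort(path)
  expect_equal(nrow(co), 3)
  expect_equal(co$id, c("1", "2", "3"))          # ids from row numbers
  expect_true(is.na(co$age_quit[1]))             # still smoking
  expect_equal(subject_history(co, 3)$cigs_per_day, 0)

  writeLines(c(
    "gender,t0,t1,age_start,age_quit,cigs_per_day,observed_lc_death,observed_death_age",
    "male,58,58,18,,30,FALSE,"), path)
  expect_error(read_cohort(path), "row 1.*t1 must exceed t0")

  writeLines(c("gender,t0,age_start,age_quit,cigs_per_day",
               "male,55,18,,30"), path)
  expect_error(read_cohort(path), "t1")
})

test_that("survival records parse stage labels in both notations", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_months,event,stage", "17,1,IV", "12,0,2"), path)
  recs <- read_survival_records(path)
  expect_equal(recs$time_months, c(17, 12))
  expect_equal(recs$event, c(TRUE, FALSE))
  expect_equal(as.character(recs$stage), c("IV", "II"))

  expect_error(survival_records(-1, TRUE, "I"), "time_months")
  expect_error(survival_records(5, TRUE, "V"), "stage")
})

test_that("stage weights normalize percentages and proportions alike", {
  w <- seer_stage_weights_2000()
  expect_equal(sum(w), 1, tolerance = 1e-9)
  expect_equal(as.numeric(w),
               c(16.22, 2.91, 32.64, 48.23) / 100, tolerance = 1e-12)
  w2 <- stage_weights(c(I = 0.25, II = 0.25, III = 0.25, IV = 0.25))
  expect_equal(as.numeric(w2), rep(0.25, 4))
  w3 <- stage_weights(c("1" = 10, "2" = 20, "3" = 30, "4" = 40))
  expect_equal(as.numeric(w3), c(0.1, 0.2, 0.3, 0.4))
  expect_error(stage_weights(c(I = 1, II = 1, III = 1)), "exactly")
})

test_that("write-then-read round-trips are the identity on all file kinds", {
  co <- generate_cohort(caret_cohort_spec(), seed = 11)
  expect_equal(nrow(co), 6877)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(back$id, co$id)
  expect_equal(back$gender, co$gender)
  for (col in c("t0", "t1", "age_start", "age_quit", "cigs_per_day",
                "observed_death_age"))
    expect_equal(back[[col]], co[[col]], tolerance = 1e-8)

  recs <- generate_survival(mda_survival_spec(), seed = 2)
  expect_equal(nrow(recs), 1190)
  write_survival_records(recs, path)
  back <- read_survival_records(path)
  expect_equal(back$time_months, recs$time_months, tolerance = 1e-8)
  expect_equal(back$event, recs$event)
  expect_equal(back$stage, recs$stage)

  w <- seer_stage_weights_2000()
  write_stage_weights(w, path)
  expect_equal(as.numeric(read_stage_weights(path)), as.numeric(w),
               tolerance = 1e-9)
})
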