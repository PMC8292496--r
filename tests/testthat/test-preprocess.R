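test_that("Mosteller BSA matches direct evaluation and rejects bad input", {
  expect_equal(compute_bsa(180, 80), 2)
  expect_equal(compute_bsa(160, 56.25), 1.58114, tolerance = 1e-5)
  expect_equal(compute_bsa(130, 35), 1.12423, tolerance = 1e-5)
  expect_equal(compute_bsa(c(180, 160), c(80, 56.25)),
               c(2, sqrt(160 * 56.25 / 3600)))
  expect_error(compute_bsa(0, 80), "positive")
  expect_error(compute_bsa(170, -1), "positive")
  expect_error(compute_bsa("a", 80), "numeric")
})

test_that("same-day measurements consolidate by policy and administered flag", {
  raw <- make_patient_records(days = c(1, 1, 2), inr = c(2.1, 2.4, 2.2),
                              dose = c(3, 0, 3))
  raw$administered <- c(1, 0, 1)
  last <- consolidate_daily(raw, inr_policy = "last")
  expect_equal(nrow(last), 2)
  expect_equal(last$inr[last$day == 1], 2.4)
  expect_equal(last$dose_mg[last$day == 1], 3)  # non-administered row ignored
  mean_pol <- consolidate_daily(raw, inr_policy = "mean")
  expect_equal(mean_pol$inr[mean_pol$day == 1], mean(c(2.1, 2.4)))

  # single record per day is the identity
  one <- make_patient_records(days = 1:3)
  expect_equal(consolidate_daily(one)[names(one)], one)

  # dose rows marked not-administered contribute 0
  skipped <- make_patient_records(days = 1, dose = 5)
  skipped$administered <- 0
  expect_equal(consolidate_daily(skipped)$dose_mg, 0)

  # conflicting static covariates are an error naming the patient-day
  conf <- make_patient_records(days = c(1, 1))
  conf$weight_kg <- c(70, 75)
  expect_error(consolidate_daily(conf), "P1 day 1")
})

test_that("exclusion filters use strict boundaries and log attrition", {
  mk <- function(id, ...) make_patient_records(id = id, days = 1:5, ...)
  records <- rbind(
    mk("keep"),
    mk("light", weight = 34.9),
    mk("tall", height = 220.5),
    mk("child", age = 17),
    mk("bid", doses_per_day = 2)
  )
  res <- apply_exclusion_filters(records)
  expect_setequal(unique(res$records$patient_id), "keep")
  log <- res$log
  expect_equal(log$n_excluded[log$rule == "weight_out_of_range"], 1)
  expect_equal(log$n_excluded[log$rule == "under_18"], 1)
  expect_equal(log$n_excluded[log$rule == "multiple_daily_doses"], 1)

  # record-level rules drop only the offending day
  rec <- mk("p")
  rec$inr[3] <- 10.1
  rec$dose_mg[4] <- 20.5
  res2 <- apply_exclusion_filters(rec)
  expect_equal(nrow(res2$records), 3)
  expect_false(3 %in% res2$records$day)
  expect_false(4 %in% res2$records$day)
  expect_equal(res2$log$n_excluded[res2$log$rule == "inr_above_10"], 1)

  # schema violations name the field
  bad <- mk("p")
  bad$dose_mg <- NULL
  expect_error(apply_exclusion_filters(bad), "dose_mg")
})

test_that("window extraction counts runs of eligible consecutive days", {
  # 5 consecutive eligible days -> exactly 1 sample
  w <- extract_windows(make_patient_records(days = 1:5))
  expect_equal(nrow(w), 1)
  expect_equal(w$start_day, 1)
  expect_equal(w$bsa, compute_bsa(170, 70))

  # 8 consecutive days -> n - 4 = 4 overlapping samples
  w8 <- extract_windows(make_patient_records(days = 1:8, inr = seq(1, 2.4, 0.2)))
  expect_equal(nrow(w8), 4)
  expect_equal(w8$start_day, 1:4)
  expect_equal(w8$target_inr, w8$inr1 + 0.8, tolerance = 1e-12)

  # a gap breaks the run
  expect_equal(nrow(extract_windows(make_patient_records(days = c(1, 2, 3, 5, 6)))), 0)

  # a zero-dose day breaks the run
  z <- make_patient_records(days = 1:6, dose = c(3, 3, 0, 3, 3, 3))
  expect_equal(nrow(extract_windows(z)), 0)

  # non-overlapping mode takes disjoint runs greedily
  long <- make_patient_records(days = 1:12)
  expect_equal(nrow(extract_windows(long, overlapping = FALSE)), 2)
})

test_that("window extraction matches brute-force enumeration on random cohorts", {
  set.seed(404)
  for (rep in 1:3) {
    cohort <- do.call(rbind, lapply(1:50, function(i) {
      n <- sample(4:12, 1)
      days <- sort(sample(1:14, n))
      dose <- sample(c(0, seq(1, 8, 0.5)), n, replace = TRUE,
                     prob = c(0.2, rep(0.8 / 15, 15)))
      make_patient_records(id = sprintf("R%02d", i), days = days,
                           inr = runif(n, 1, 4), dose = dose)
    }))
    # shuffled multi-patient input: windows must never span patients
    cohort <- cohort[sample(nrow(cohort)), ]
    got <- extract_windows(cohort)
    want <- brute_force_windows(cohort)
    expect_equal(nrow(got), nrow(want))
    expect_setequal(paste(got$patient_id, got$start_day),
                    paste(want$patient_id, want$start_day))
    if (nrow(got) > 0) {
      statics <- cohort[match(got$patient_id, cohort$patient_id), ]
      expect_equal(got$age, statics$age)  # each window carries its own patient
    }
  }
})

test_that("chain-evaluation cases require 8 days with fixed day-4..7 doses", {
  eligible <- make_patient_records(days = 1:8,
                                   dose = c(2, 2.5, 3, 3, 3, 3, 3, 3))
  cases <- select_chain_eval_cases(eligible)
  expect_equal(nrow(cases), 1)
  expect_equal(cases$fixed_dose, 3)
  expect_equal(cases$actual_day8_inr, eligible$inr[8])

  varying <- make_patient_records(days = 1:8,
                                  dose = c(2, 2.5, 3, 3, 3, 3.5, 3, 3))
  expect_null(select_chain_eval_cases(varying))

  short <- make_patient_records(days = 1:7)
  expect_null(select_chain_eval_cases(short))

  # constant dosing over 10 days yields all three overlapping runs
  steady <- make_patient_records(days = 1:10)
  expect_equal(nrow(select_chain_eval_cases(steady)), 3)
})
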