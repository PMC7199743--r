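test_that("built-in designs encode the two study layouts", {
  d1 <- study_design("study1")
  expect_equal(d1$n_subjects, 5L)
  expect_equal(nrow(d1$periods), 5L)
  expect_equal(d1$periods$excluded_from_fit[d1$periods$dose_mgkg == 0.8], 1L)
  expect_equal(d1$dosing_days, 1:14)
  d2 <- study_design("study2")
  expect_equal(d2$n_subjects, 12L)
  expect_equal(d2$dosing_days, c(1L, 5:14))
  expect_equal(d2$periods$dose_mgkg[d2$periods$drug == "torasemide"],
               c(0.1, 0.2, 0.3, 0.4))
  # furosemide periods are placeholders without simulated records
  expect_false(any(d2$periods$simulate[d2$periods$drug == "furosemide"]))
  expect_error(study_design("study3"))
})

test_that("generation is deterministic under the seed contract", {
  a <- generate_trial(study_design("study2"), seed = 42, n_subjects = 2)
  b <- generate_trial(study_design("study2"), seed = 42, n_subjects = 2)
  expect_identical(a$value, b$value)
  c3 <- generate_trial(study_design("study2"), seed = 43, n_subjects = 2)
  expect_false(identical(a$value, c3$value))
  # placebo period carries zero dose amounts
  expect_true(all(a$amount_mg[a$record_type == "dose" &
                                a$period == "placebo"] == 0))
  # no observations for furosemide placeholder periods
  expect_false(any(grepl("^F", unique(a$period))))
})

test_that("zero CV puts every subject at the typical values", {
  ind <- sample_individual_parameters(noise_free_true(), 4, seed = 9)
  expect_true(all(ind$CL == 0.077))
  expect_true(all(ind$ka == 1.66))
  expect_true(all(ind$EmaxNa == 4.67))
})

test_that("sampled variability reproduces the requested CV at large n", {
  ind <- sample_individual_parameters(true_parameters(), 10000, seed = 1)
  emp_cv <- 100 * sd(ind$CL) / mean(ind$CL)
  expect_lt(abs(emp_cv / 64.3 - 1), 0.02)
  emp_fu <- 100 * sd(ind$Fu) / mean(ind$Fu)
  expect_lt(abs(emp_fu / 8.6 - 1), 0.05)
})

test_that("noise-free generation equals the forward models exactly", {
  tr <- noise_free_true()
  dat <- generate_trial(study_design("study2"), tr, seed = 3, n_subjects = 1)
  sub <- dat[dat$subject_id == "study2-01" & dat$period == "T0.2", ]
  doses <- sub[sub$record_type == "dose", ]
  pla <- sub[sub$record_type == "plasma", ]
  want <- simulate_plasma(pk_params(), data.frame(time = doses$time_h,
                                                  amount = doses$amount_mg),
                          pla$time_h)
  expect_equal(pla$value, want, tolerance = 1e-12)
  vol <- sub[sub$record_type == "urine_volume", ]
  qd <- simulate_urine_excretion(pk_params(),
                                 data.frame(time = doses$time_h,
                                            amount = doses$amount_mg),
                                 cbind(vol$interval_start_h, vol$interval_end_h))
  expect_equal(vol$value, predict_daily_diuresis(diuresis_params(), qd),
               tolerance = 1e-9)
})

test_that("placebo observations scatter around the drug-free baselines", {
  dat <- generate_trial(study_design("study2"), seed = 17)
  pla <- dat[dat$period == "placebo", ]
  vol <- pla$value[pla$record_type == "urine_volume"]
  expect_equal(mean(vol), 221, tolerance = 0.12)
  na <- pla$value[pla$record_type == "urine_sodium"]
  # arithmetic means sit above the log-normal typical by exp(omega^2/2),
  # plus 12-subject sampling scatter
  expect_equal(mean(na), 24 * 3.67 / 4.99, tolerance = 0.2)
})

test_that("plasma below the quantification limit is flagged", {
  dat <- generate_trial(study_design("study2"), seed = 2, n_subjects = 3)
  pla <- dat[dat$record_type == "plasma", ]
  expect_true(all(pla$blq_flag[pla$value < 5] == 1))
  expect_true(all(pla$blq_flag[pla$value >= 5] == 0))
  expect_gt(sum(pla$blq_flag), 0) # late washout samples do fall below 5 ug/L
})

test_that("empirical residual scatter matches the configured magnitudes", {
  tr_quiet <- true_parameters(residuals = list(
    plasma_prop = 0, urine_prop = 0, urine_add = 0, diuresis_prop = 0,
    natriuresis_prop = 0))
  noisy <- generate_trial(study_design("study2"), seed = 8)
  clean <- generate_trial(study_design("study2"), tr_quiet, seed = 8)
  sel <- noisy$record_type == "urine_sodium" & clean$value > 0.5
  ratio <- noisy$value[sel] / clean$value[sel]
  expect_equal(sd(ratio), 0.305, tolerance = 0.05)
  sel2 <- noisy$record_type == "urine_volume"
  expect_equal(sd(noisy$value[sel2] / clean$value[sel2]), 0.432,
               tolerance = 0.05)
})

test_that("below-quantification rules: leading zeroed, interior and trailing dropped", {
  mk <- function(values, flags) data.frame(
    study_id = "s", subject_id = "x", period = "p", treatment = "torasemide",
    body_weight_kg = 10, record_type = "plasma",
    time_h = seq_along(values), interval_start_h = NA_real_,
    interval_end_h = NA_real_, amount_mg = NA_real_, value = values,
    blq_flag = flags, excluded_from_fit = 0L, stringsAsFactors = FALSE)
  out <- apply_blq_rules(mk(c(2, 10, 8, 3, 1), c(1L, 0L, 0L, 1L, 1L)))
  expect_equal(out$value, c(0, 10, 8))
  expect_equal(out$blq_flag, c(1L, 0L, 0L))
  # interior below-limit record removed
  out2 <- apply_blq_rules(mk(c(10, 2, 8), c(0L, 1L, 0L)))
  expect_equal(out2$value, c(10, 8))
  # fully censored profile retained as zeros
  out3 <- apply_blq_rules(mk(c(1, 2), c(1L, 1L)))
  expect_equal(out3$value, c(0, 0))
  # untouched profile passes through
  clean <- mk(c(10, 8), c(0L, 0L))
  expect_equal(apply_blq_rules(clean), clean)
})
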