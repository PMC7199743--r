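test_that("trapezoidal AUC geometry", {
  tt <- 0:10
  expect_equal(auc_trapezoid(tt, rep(3, 11)), 30)
  expect_equal(auc_trapezoid(c(0, 1, 2), c(0, 5, 0)), 5)
  # endpoint interpolation and sub-interval additivity
  tt <- c(0, 2, 5, 9, 12)
  cc <- c(0, 8, 5, 2, 1)
  expect_equal(auc_trapezoid(tt, cc, 1, 11),
               auc_trapezoid(tt, cc, 1, 4) + auc_trapezoid(tt, cc, 4, 11),
               tolerance = 1e-12)
  expect_error(auc_trapezoid(tt, cc, 0, 20), "outside")
})

test_that("AUC to infinity recovers dose over clearance", {
  p <- pk_params()
  tt <- c(seq(0.02, 24, by = 0.02), seq(24.5, 400, by = 0.5))
  cc <- simulate_plasma(p, data.frame(time = 0, amount = 2), tt)
  auc <- auc_trapezoid(c(0, tt), c(0, cc))
  expect_equal(auc, 0.98 * 2 * 1000 / 0.077, tolerance = 0.01)
})

test_that("accumulation ratio closed forms", {
  tt <- seq(0, 24, by = 0.05)
  prof <- exp(-0.1 * tt)
  expect_equal(accumulation_ratio(tt, prof, tt, prof), 1)
  # one-compartment theory: R = 1 / (1 - exp(-k tau))
  k <- 0.1; tau <- 24
  ss <- prof / (1 - exp(-k * tau))
  expect_equal(accumulation_ratio(tt, prof, tt, ss),
               1 / (1 - exp(-k * tau)), tolerance = 1e-10)
  expect_error(accumulation_ratio(tt, 0 * prof, tt, prof), "zero")
})

test_that("noiseless repeated dosing accumulates moderately above unity", {
  p <- pk_params()
  doses <- data.frame(time = 24 * (0:13), amount = 2)
  tt <- seq(0, 24, by = 0.1)
  c1 <- simulate_plasma(p, doses, tt)
  css <- simulate_plasma(p, doses, 24 * 13 + tt)
  r <- accumulation_ratio(tt, c1, tt, css)
  expect_gt(r, 1)
  expect_lt(r, 3)
})

test_that("dose-proportionality power fit identities", {
  d <- c(1, 2, 3, 5)
  fit1 <- dose_proportionality_power_fit(d, 7 * d)
  expect_equal(fit1$beta, 1, tolerance = 1e-12)
  expect_equal(diff(fit1$ci), 0, tolerance = 1e-9)
  fit2 <- dose_proportionality_power_fit(d, 2 * d^2)
  expect_equal(fit2$beta, 2, tolerance = 1e-12)
  # scale invariance of the exponent
  set.seed(1)
  auc <- 3 * d^1.3 * exp(rnorm(4, 0, 0.05))
  b1 <- dose_proportionality_power_fit(d, auc)$beta
  b2 <- dose_proportionality_power_fit(10 * d, auc)$beta
  expect_equal(b1, b2, tolerance = 1e-12)
  expect_error(dose_proportionality_power_fit(c(1, 2), c(1, 2)), "3 distinct")
})

test_that("the implemented linear PK is exactly dose-proportional", {
  p <- pk_params()
  doses_mgkg <- c(0.1, 0.2, 0.3, 0.4)
  tt <- c(seq(0.05, 24, by = 0.05), seq(25, 300, by = 1))
  aucs <- vapply(doses_mgkg, function(d) {
    cc <- simulate_plasma(p, data.frame(time = 0, amount = d * 10), tt)
    auc_trapezoid(c(0, tt), c(0, cc))
  }, numeric(1))
  fit <- dose_proportionality_power_fit(doses_mgkg, aucs)
  expect_equal(fit$beta, 1, tolerance = 1e-6)
})

test_that("between-subject diuresis variability per dose", {
  expect_equal(diuresis_variability_summary(
    c("a", "b"), c(1, 1), c(100, 100))$cv_percent, 0)
  got <- diuresis_variability_summary(
    c("a", "b", "c", "d"), rep(0.1, 4), c(100, 100, 200, 200))
  expect_equal(got$cv_percent, 100 * sd(c(100, 100, 200, 200)) / 150,
               tolerance = 1e-12)
  expect_equal(round(got$cv_percent, 1), 38.5)
  expect_error(diuresis_variability_summary("a", 1, 100), "fewer than 2")
})

test_that("the power model amplifies slope variability with dose", {
  tr <- true_parameters(residuals = list(plasma_prop = 0, urine_prop = 0,
                                         urine_add = 0, diuresis_prop = 0,
                                         natriuresis_prop = 0))
  dat <- generate_trial(study_design("study2"), tr, seed = 21)
  vol <- dat[dat$record_type == "urine_volume" & dat$period != "placebo" &
               dat$interval_end_h > 24 * 7, ]
  dose <- as.numeric(sub("T", "", vol$period))
  cv <- diuresis_variability_summary(vol$subject_id, dose, vol$value)
  expect_gt(cv$cv_percent[cv$dose == 0.4], cv$cv_percent[cv$dose == 0.1])
})
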