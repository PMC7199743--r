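test_that("log-normal CV conversion closed forms", {
  expect_equal(cv_percent(0), 0)
  expect_equal(cv_percent(log(2)), 100)
  # first-order limit CV% -> 100 * omega
  expect_equal(cv_percent(1e-6), 100 * sqrt(1e-6), tolerance = 1e-3)
  expect_equal(cv_to_omega2(cv_percent(0.37)), 0.37, tolerance = 1e-12)
  expect_error(cv_percent(-1), "non-negative")
})

test_that("shrinkage closed forms", {
  ebes <- c(-0.1, 0, 0.1)
  expect_equal(shrinkage_fraction(ebes, 0.2), 0.5)
  expect_equal(shrinkage_fraction(ebes, sd(ebes)), 0)
  expect_equal(shrinkage_fraction(c(0.3, 0.3, 0.3), 0.5), 1)
  expect_error(shrinkage_fraction(ebes, 0), "omega")
  expect_error(shrinkage_fraction(0.1, 0.2), "two subjects")
})

test_that("likelihood-ratio criterion matches the chi-square quantiles", {
  expect_true(lrt(100, 110.83, df = 1)$significant)
  expect_false(lrt(100, 100, df = 1)$significant)
  expect_false(lrt(100, 110.5, df = 1)$significant)
  expect_true(lrt(100, 113.82, df = 2)$significant)
  expect_equal(lrt(100, 110, df = 1)$critical, qchisq(0.999, 1))
  expect_warning(lrt(110, 100, df = 1), "lower OFV")
})

test_that("Gaussian OFV without random effects is the exact closed form", {
  y <- c(4.1, 5.2, 3.9, 4.8)
  f <- c(4.0, 5.0, 4.0, 5.0)
  sig <- 0.3
  blob <- list(y = y, chan = rep(1L, 4), pred = function(th) f)
  g <- torapkpd:::.make_gfun(blob, c(dummy = 1), character(0),
                             numeric(0), rep(0, 4), rep(sig^2, 4))
  got <- torapkpd:::.laplace_subject(g, 0L)$n2ll
  expect_equal(got, sum((y - f)^2 / sig^2 + log(2 * pi * sig^2)),
               tolerance = 1e-12)
})

test_that("Laplace equals the analytic marginal likelihood on a linear-Gaussian model", {
  set.seed(42)
  n <- 8; a <- 2.5; sig <- 0.4; omega <- 0.7
  y <- a + 0.55 + rnorm(n, 0, sig)   # one subject, random intercept eta
  gfun <- function(eta)
    0.5 * sum((y - a - eta)^2 / sig^2 + log(2 * pi * sig^2)) +
    0.5 * (eta^2 / omega^2 + log(2 * pi * omega^2))
  lap <- torapkpd:::.laplace_subject(gfun, 1L)$n2ll
  # exact: y ~ N(a 1, sig^2 I + omega^2 J)
  V <- diag(sig^2, n) + omega^2
  r <- y - a
  exact <- n * log(2 * pi) + determinant(V)$modulus[1] +
    drop(r %*% solve(V, r))
  expect_equal(lap, exact, tolerance = 1e-8)
})

test_that("Laplace is close to 64-point adaptive quadrature on a nonlinear model", {
  set.seed(7)
  x <- seq(0.5, 4, length.out = 10)
  f0 <- function(eta) 3 * exp(eta) * exp(-0.8 * exp(0.5 * eta) * x)
  y <- f0(0.3) * (1 + rnorm(10, 0, 0.1))
  sig <- 0.25; omega <- 0.5
  gfun <- function(eta) {
    f <- f0(eta)
    0.5 * sum((y - f)^2 / sig^2 + log(2 * pi * sig^2)) +
      0.5 * (eta^2 / omega^2 + log(2 * pi * omega^2))
  }
  lap <- torapkpd:::.laplace_subject(gfun, 1L)$n2ll
  quad <- agh_neg2ll(gfun, n = 64)
  expect_lt(abs(lap - quad), 0.5)
})

test_that("empirical Bayes mode behaves at the degenerate limits", {
  # no observations: the prior mode, eta = 0
  omega <- 0.5
  g_prior <- function(eta) 0.5 * (eta^2 / omega^2 + log(2 * pi * omega^2))
  expect_equal(torapkpd:::.laplace_subject(g_prior, 1L)$eta, 0,
               tolerance = 1e-8)
  # rich noiseless data at a known eta: the mode recovers it
  q <- c(200, 500, 900, 1500, 2300)
  eta_true <- 0.37
  y <- 221 * exp(eta_true) + 7.76e-5 * q^2.05
  blob <- list(y = y, chan = rep(1L, 5),
               pred = function(th) th[["baseline"]] + 7.76e-5 * q^2.05)
  g <- torapkpd:::.make_gfun(blob, c(baseline = 221), "baseline",
                             c(baseline = 0.25), rep(0.005, 5), rep(0, 5))
  est <- torapkpd:::.laplace_subject(g, 1L)$eta
  expect_equal(est, eta_true, tolerance = 0.01)
})

test_that("noise-free data are recovered to better than 0.1 percent", {
  dat <- generate_trial(study_design("study2"), noise_free_true(), seed = 5,
                        n_subjects = 3)
  dat <- apply_blq_rules(dat)
  init <- list(
    theta = unclass(pk_params())[-1] * c(1.1, 0.9, 1.05, 0.9, 1.1, 0.95),
    omega2 = setNames(numeric(0), character(0)),
    sigma = c(plasma_prop = 0.005, urine_prop = 0.005, urine_add = 0.05))
  fit <- popfit(dat, stage = "pk", init = init,
                fix = c("plasma_prop", "urine_prop", "urine_add"),
                control = list(outer.rel.tol = 1e-12, grad.step = 1e-5))
  truth <- unclass(pk_params())[-1]
  expect_lt(max(abs(fit$theta / truth - 1)), 0.001)
})

test_that("diuresis fit is stable under a perturbed start", {
  dat <- apply_blq_rules(generate_pooled_trial(seed = 11))
  dat <- dat[dat$record_type %in% c("dose", "urine_volume"), ]
  f1 <- popfit(dat, stage = "diuresis")
  f2 <- popfit(dat, stage = "diuresis",
               init = list(theta = f1$init$theta * c(1.2, 0.8, 1.1)))
  expect_lt(abs(f2$ofv - f1$ofv), 0.5)
  expect_lt(abs(f2$theta[["baseline"]] / f1$theta[["baseline"]] - 1), 0.02)
  # slope and exponent trade off along a near-flat ridge; the fits agree on
  # what they jointly predict
  p1 <- predict(f1, level = "population")$predicted
  p2 <- predict(f2, level = "population")$predicted
  expect_lt(max(abs(p2 / p1 - 1)), 0.02)
})

test_that("the power form is not preferred on linear-simulated data", {
  # rebuild the diuresis channel from the nested (linear) truth and check the
  # likelihood-ratio criterion does not pick the superset model
  dat <- generate_trial(study_design("study2"), noise_free_true(), seed = 13,
                        n_subjects = 6)
  dat <- dat[dat$record_type %in% c("dose", "urine_volume"), ]
  set.seed(99)
  for (id in unique(dat$subject_id)) for (pr in unique(dat$period)) {
    sel <- dat$subject_id == id & dat$period == pr
    vol <- sel & dat$record_type == "urine_volume"
    if (!any(vol)) next
    dd <- dat[sel & dat$record_type == "dose" & dat$amount_mg > 0, ]
    qd <- if (nrow(dd)) simulate_urine_excretion(
      pk_params(), data.frame(time = dd$time_h, amount = dd$amount_mg),
      cbind(dat$interval_start_h[vol], dat$interval_end_h[vol])) else 0
    dat$value[vol] <- (221 + 0.12 * qd) * (1 + rnorm(sum(vol), 0, 0.15))
  }
  om <- cv_to_omega2(c(baseline = 10, slope = 20))
  f_lin <- popfit(dat, stage = "diuresis", form = "linear",
                  init = list(omega2 = om, sigma = c(diuresis_prop = 0.15)))
  f_pow <- popfit(dat, stage = "diuresis", form = "power",
                  init = list(theta = c(baseline = 221, slope = 0.1,
                                        alpha = 1.05),
                              omega2 = om, sigma = c(diuresis_prop = 0.15)))
  expect_false(lrt(f_pow, f_lin, df = 1)$significant)
})

test_that("rival diuresis forms self-select on power-simulated data", {
  dat <- apply_blq_rules(generate_pooled_trial(seed = 3))
  dat <- dat[dat$record_type %in% c("dose", "urine_volume"), ]
  tab <- compare_pd_models(dat, forms = c("linear", "power"))
  expect_true(tab$selected[tab$form == "power"])
  expect_gt(tab$ofv[tab$form == "linear"] - tab$ofv[tab$form == "power"],
            qchisq(0.999, 2))
  # determinism: identical data and model give identical OFV
  f1 <- popfit(dat, stage = "diuresis")
  f2 <- popfit(dat, stage = "diuresis")
  expect_identical(f1$ofv, f2$ofv)
})
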