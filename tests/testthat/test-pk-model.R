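test_that("parameter and input validation reject invalid values", {
  expect_error(pk_params(CL = -1), "CL")
  expect_error(pk_params(Fu = 1.2), "Fu")
  expect_error(pk_params(F = 0), "F")
  p <- pk_params()
  expect_error(simulate_plasma(p, data.frame(time = 0, amount = 1),
                               c(2, 1)), "sorted")
  expect_error(simulate_plasma(p, data.frame(time = 0, amount = 1),
                               c(-1, 1)), "non-negative")
  expect_error(simulate_urine_excretion(p, data.frame(time = 0, amount = 1),
                                        rbind(c(0, 24), c(12, 36))),
               "non-overlapping")
})

test_that("no drug in means no drug anywhere", {
  p <- pk_params()
  expect_equal(simulate_plasma(p, NULL, c(0, 1, 10)), c(0, 0, 0))
  expect_equal(simulate_urine_excretion(p, NULL, cbind(0, 24)), 0)
  # interval entirely before the first dose
  expect_equal(simulate_urine_excretion(p, data.frame(time = 48, amount = 2),
                                        cbind(0, 24)), 0)
})

test_that("mass balance holds at every output time under repeated dosing", {
  p <- pk_params()
  doses <- data.frame(time = 24 * (0:13), amount = 2)
  tt <- seq(0.5, 400, by = 0.5)
  st <- pk_state(p, doses, tt)
  given <- 0.98 * vapply(tt, function(t) sum(doses$amount[doses$time <= t]),
                         numeric(1))
  total <- st$gut + st$central + st$peripheral + st$urine + st$nonrenal
  expect_lt(max(abs(total - given) / given), 1e-6)
})

test_that("closed-form solution matches a generic ODE integrator", {
  p <- pk_params()
  pv <- unclass(p)
  doses <- data.frame(time = c(0, 24, 48), amount = c(2, 2, 2))
  tt <- c(0.25, 1, 6, 12, 23.9, 30, 47.9, 60, 96)
  sol <- pk_lsoda_oracle(pv, doses$time, doses$amount, tt)
  cc <- simulate_plasma(p, doses, tt)
  expect_lt(max(abs(cc - sol[, "c"] / pv[["Vc"]] * 1000) /
                  (sol[, "c"] / pv[["Vc"]] * 1000)), 1e-6)
  cum <- pk_state(p, doses, tt)$urine
  expect_lt(max(abs(cum - sol[, "u"]) / pmax(sol[, "u"], 1e-9)), 1e-6)
})

test_that("instantaneous-absorption limit matches the bi-exponential bolus solution", {
  pv <- pk_params(ka = 1e7)
  tt <- c(0.1, 0.5, 1, 2, 6, 12, 24, 48)
  got <- simulate_plasma(pv, data.frame(time = 0, amount = 2), tt)
  want <- iv_bolus_conc_oracle(0.98 * 2, 0.077, 0.145, 0.262, 0.935, tt)
  expect_lt(max(abs(got - want) / want), 1e-6)
})

test_that("dose superposition holds exactly (linear system)", {
  p <- pk_params()
  tt <- seq(0.5, 72, by = 0.5)
  one <- simulate_plasma(p, data.frame(time = 0, amount = 1.5), tt)
  two_shift <- simulate_plasma(p, data.frame(time = 24, amount = 3), tt)
  both <- simulate_plasma(p, data.frame(time = c(0, 24), amount = c(1.5, 3)), tt)
  expect_lt(max(abs(both - (one + two_shift)) / pmax(both, 1e-12)), 1e-6)
})

test_that("urinary excretion obeys the mass-balance limit and interval additivity", {
  p <- pk_params()
  d <- data.frame(time = 0, amount = 2.6)
  # whole-profile collection recovers F * Fu * dose
  tot <- simulate_urine_excretion(p, d, cbind(0, 5000))
  expect_equal(tot, 0.98 * 0.611 * 2.6 * 1000, tolerance = 1e-6)
  # contiguous intervals sum to the union
  parts <- simulate_urine_excretion(p, d, rbind(c(0, 6), c(6, 24), c(24, 72)))
  whole <- simulate_urine_excretion(p, d, cbind(0, 72))
  expect_equal(sum(parts), whole, tolerance = 1e-12)
})

test_that("once-daily dosing reaches a periodic steady state in daily urine output", {
  p <- pk_params()
  doses <- data.frame(time = 24 * (0:59), amount = 2)
  days <- simulate_urine_excretion(p, doses, cbind(24 * (50:59), 24 * (51:60)))
  expect_lt(max(abs(days / (0.98 * 0.611 * 2 * 1000) - 1)), 0.001)
})

test_that("steady-state daily urinary quantity is the mass-balance shortcut", {
  p <- pk_params()
  expect_equal(steady_state_daily_urine_quantity(p, 0), 0)
  expect_equal(steady_state_daily_urine_quantity(p, 2.6), 1556.8,
               tolerance = 1e-4)
  expect_equal(steady_state_daily_urine_quantity(p, 0.1 * 10.5), 628.7,
               tolerance = 1e-4)
  expect_error(steady_state_daily_urine_quantity(p, -1), "non-negative")
})

test_that("clearances scale to the published per-kg values", {
  sc <- scaled_clearances(pk_params(), 10)
  expect_equal(unname(sc["total"]), 7.7)
  expect_equal(unname(round(sc["urinary"], 1)), 4.7)
  sc1 <- scaled_clearances(pk_params(Fu = 1), 10)
  expect_equal(unname(sc1["total"]), unname(sc1["urinary"]))
})

test_that("half-life report exposes the slow/fast eigenvalue discrepancy", {
  hl <- pk_half_lives(pk_params())
  expect_true(hl[["distribution"]] < hl[["effective"]])
  expect_true(hl[["effective"]] < hl[["terminal"]])
  # terminal phase implied by the published parameters is about 12 h
  expect_equal(hl[["terminal"]], 11.92, tolerance = 0.01)
})
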