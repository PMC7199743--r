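# Independent oracles used across the suite.  Each deliberately avoids the
# package's production code paths: the PK oracle integrates the ODE system
# numerically (deSolve), the natriuresis oracle is a naive fixed-step RK4
# with the literal on/off switching rule, the quadrature oracle builds
# Gauss-Hermite nodes from the Jacobi matrix, and the bolus oracle is the
# textbook bi-exponential disposition solution.

# numeric ODE solution of the two-compartment oral model with urine output
pk_lsoda_oracle <- function(pv, dose_t, dose_a, times, rtol = 1e-10) {
  rhs <- function(t, y, p) {
    ka <- p[["ka"]]; ke <- p[["CL"]] / p[["Vc"]]
    k12 <- p[["Q"]] / p[["Vc"]]; k21 <- p[["Q"]] / p[["Vp"]]
    list(c(-ka * y[1],
           ka * y[1] - (ke + k12) * y[2] + k21 * y[3],
           k12 * y[2] - k21 * y[3],
           p[["Fu"]] * ke * y[2]))
  }
  evt <- data.frame(var = "g", time = dose_t, value = pv[["F"]] * dose_a,
                    method = "add")
  grid <- sort(unique(c(0, times, dose_t)))
  sol <- deSolve::lsoda(c(g = 0, c = 0, p = 0, u = 0), grid, rhs, pv,
                        events = list(data = evt), rtol = rtol, atol = 1e-12)
  sol[match(times, grid), , drop = FALSE]
}

# textbook bi-exponential solution for an IV bolus into the central
# compartment of a two-compartment model
iv_bolus_conc_oracle <- function(dose, CL, Vc, Q, Vp, times) {
  ke <- CL / Vc; k12 <- Q / Vc; k21 <- Q / Vp
  s <- ke + k12 + k21
  disc <- sqrt(s^2 - 4 * ke * k21)
  a <- (s + disc) / 2; b <- (s - disc) / 2
  dose / Vc * ((a - k21) / (a - b) * exp(-a * times) +
                 (k21 - b) / (a - b) * exp(-b * times)) * 1000
}

# naive fixed-step RK4 for the natriuresis turnover/resistance system with
# the literal threshold rule evaluated at every derivative call
rk4_natriuresis_oracle <- function(p, q_daily, t_end, h = 0.01) {
  p <- unclass(p)
  deriv <- function(t, s) {
    day <- floor(t / 24) + 1
    q <- if (day <= length(q_daily)) q_daily[day] else 0
    qh <- if (q > 0) (q / p[["EC50Na"]])^p[["hillNa"]] else 0
    S <- p[["EmaxNa"]] * (1 - s[2]) * qh / (1 + qh)
    kon <- if (S > p[["threshold"]]) p[["kResON"]] else 0
    c(p[["kforNa"]] * (1 + S) - p[["kabsNa"]] * s[1],
      kon - p[["kResOFF"]] * s[2],
      s[1])
  }
  nstep <- round(t_end / h)
  s <- c(p[["kforNa"]] / p[["kabsNa"]], 0, 0)
  out <- matrix(NA_real_, nstep + 1, 4)
  out[1, ] <- c(0, s)
  for (i in seq_len(nstep)) {
    t <- (i - 1) * h
    k1 <- deriv(t, s); k2 <- deriv(t + h / 2, s + h / 2 * k1)
    k3 <- deriv(t + h / 2, s + h / 2 * k2); k4 <- deriv(t + h, s + h * k3)
    s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i + 1, ] <- c(i * h, s)
  }
  colnames(out) <- c("t", "E", "R", "Q")
  out
}

# Gauss-Hermite nodes/weights (weight exp(-x^2)) via the symmetric Jacobi
# matrix (Golub-Welsch)
gauss_hermite_rule <- function(n) {
  i <- seq_len(n - 1)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b; J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# adaptive Gauss-Hermite value of -2 log integral exp(-g(eta)) d eta,
# centred at the mode with the curvature scale
agh_neg2ll <- function(gfun, n = 64) {
  opt <- nlminb(0, gfun, control = list(rel.tol = 1e-14))
  m <- opt$par
  h <- 1e-4
  H <- (gfun(m + h) - 2 * gfun(m) + gfun(m - h)) / h^2
  s <- 1 / sqrt(H)
  gh <- gauss_hermite_rule(n)
  eta <- m + sqrt(2) * s * gh$nodes
  vals <- vapply(eta, gfun, numeric(1))
  # factor exp(z^2) undoes the GH weight; log-sum-exp for stability
  le <- log(gh$weights) + gh$nodes^2 - vals
  -2 * (log(sum(exp(le - max(le)))) + max(le) + log(sqrt(2) * s))
}

# minimal two-record dataset in the trial dialect (for io tests)
tiny_trial_rows <- function() {
  data.frame(
    study_id = "study2", subject_id = "study2-01", period = "T0.1",
    treatment = "torasemide", body_weight_kg = 10.5,
    record_type = c("dose", "plasma"),
    time_h = c(0, 1), interval_start_h = NA_real_, interval_end_h = NA_real_,
    amount_mg = c(1.05, NA), value = c(NA, 250), blq_flag = 0L,
    excluded_from_fit = 0L, stringsAsFactors = FALSE)
}

# noise-free true-parameter set (degenerate-variability simulations)
noise_free_true <- function() {
  true_parameters(
    pk_cv = c(ka = 0, CL = 0, Fu = 0),
    diuresis_cv = c(baseline = 0, slope = 0, alpha = 0),
    natriuresis_cv = c(kforNa = 0, EmaxNa = 0),
    residuals = list(plasma_prop = 0, urine_prop = 0, urine_add = 0,
                     diuresis_prop = 0, natriuresis_prop = 0))
}
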