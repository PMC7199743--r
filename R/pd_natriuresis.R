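#' Natriuresis turnover-model parameters
#'
#' Indirect-response model of daily sodium excretion.  Sodium output rate
#' `E_Na` (mEq/h) turns over with zero-order production `kforNa` and
#' first-order dissipation `kabsNa`; the daily urinary torasemide amount
#' stimulates production through a sigmoid-Emax term.  A reversible resistance
#' state `R_Na` in \[0, 1\] fractionally reduces the maximal stimulus
#' (`Emax_apparent = EmaxNa * (1 - R_Na)`) and builds up (zero-order `kResON`,
#' first-order loss `kResOFF`) only while the stimulus exceeds `threshold`;
#' otherwise the activation rate is zero and resistance decays.
#'
#' @param kforNa zero-order natriuresis production constant (mEq/h^2).
#' @param kabsNa first-order dissipation constant (1/h).
#' @param EmaxNa maximal fractional stimulus (unitless).
#' @param EC50Na daily urinary torasemide amount at half-maximal stimulus (ug).
#' @param hillNa sigmoidicity factor (unitless).
#' @param kResON zero-order resistance activation constant (1/h).
#' @param kResOFF first-order resistance decay constant (1/h);
#'   `kResON/kResOFF <= 1` keeps the resistance fraction within \[0, 1\].
#' @param threshold stimulus level above which resistance activates (unitless).
#' @return object of class `natriuresis_params`.
#' @examples
#' p <- natriuresis_params()
#' baseline_natriuresis_rate(p) * 24 # drug-free daily sodium, ~17.65 mEq
#' @export
natriuresis_params <- function(kforNa = 3.67, kabsNa = 4.99, EmaxNa = 4.67,
                               EC50Na = 1080, hillNa = 2.57, kResON = 0.0811,
                               kResOFF = 0.0894, threshold = 0.0547) {
  for (nm in c("kforNa", "kabsNa", "EmaxNa", "EC50Na", "hillNa", "kResON",
               "kResOFF", "threshold"))
    .check_positive(get(nm), nm)
  if (kResON / kResOFF > 1 + 1e-12)
    .stopf("kResON/kResOFF must not exceed 1 (resistance fraction bounded by 1)")
  structure(c(kforNa = kforNa, kabsNa = kabsNa, EmaxNa = EmaxNa,
              EC50Na = EC50Na, hillNa = hillNa, kResON = kResON,
              kResOFF = kResOFF, threshold = threshold),
            class = "natriuresis_params")
}

.nat_vec <- function(params) {
  if (inherits(params, "natriuresis_params")) return(unclass(params))
  params <- unlist(params)
  nm <- c("kforNa", "kabsNa", "EmaxNa", "EC50Na", "hillNa", "kResON",
          "kResOFF", "threshold")
  if (!all(nm %in% names(params))) .stopf("natriuresis parameters must contain %s",
                                          paste(nm, collapse = ", "))
  params[nm]
}

#' Drug stimulus on sodium production
#'
#' `S = EmaxNa * (1 - r_na) * Q^h / (EC50Na^h + Q^h)`, bounded in
#' \[0, EmaxNa\].
#'
#' @param params a [natriuresis_params()] object.
#' @param q_urine_daily daily urinary torasemide amount(s) (ug/day, >= 0).
#' @param r_na resistance fraction in \[0, 1\] (default 0).
#' @return unitless stimulus value(s).
#' @export
natriuresis_stimulus <- function(params, q_urine_daily, r_na = 0) {
  p <- .nat_vec(params)
  if (any(q_urine_daily < 0)) .stopf("'q_urine_daily' must be non-negative")
  if (any(r_na < 0 | r_na > 1)) .stopf("'r_na' must lie in [0, 1]")
  qh <- (q_urine_daily / p[["EC50Na"]])^p[["hillNa"]]
  p[["EmaxNa"]] * (1 - r_na) * qh / (1 + qh)
}

#' Drug-free natriuresis rate
#'
#' The fixed point of the turnover equation without drug:
#' `kforNa / kabsNa` (mEq/h).
#'
#' @param params a [natriuresis_params()] object.
#' @return baseline sodium output rate (mEq/h).
#' @export
baseline_natriuresis_rate <- function(params) {
  p <- .nat_vec(params)
  p[["kforNa"]] / p[["kabsNa"]]
}

#' Simulate per-collection urinary sodium amounts
#'
#' Integrates the coupled turnover/resistance system with a piecewise-constant
#' daily drive and differences the cumulative sodium at the collection
#' boundaries (the bladder is emptied at each collection).  Integration is
#' piecewise analytic with threshold crossings located exactly; the state
#' starts at the drug-free fixed point (`E = kforNa/kabsNa`, `R = 0`) unless
#' overridden.
#'
#' @param params a [natriuresis_params()] object.
#' @param q_urine_daily_series daily urinary torasemide amounts (ug/day), one
#'   per study day starting at day 1; days beyond the series carry 0.
#' @param collections two-column matrix/data frame of collection intervals
#'   `(start_h, end_h)`, sorted, non-overlapping.
#' @param state0 optional `c(E, R)` initial state.
#' @return numeric vector of sodium amounts per collection (mEq).
#' @examples
#' p <- natriuresis_params()
#' simulate_natriuresis(p, 0, cbind(0, 24)) # 24 * kforNa/kabsNa
#' @export
simulate_natriuresis <- function(params, q_urine_daily_series, collections,
                                 state0 = NULL) {
  p <- .nat_vec(params)
  if (any(q_urine_daily_series < 0)) .stopf("daily drive must be non-negative")
  collections <- .check_intervals(collections, "collections")
  if (is.null(state0)) state0 <- c(p[["kforNa"]] / p[["kabsNa"]], 0)
  bounds <- sort(unique(as.numeric(collections)))
  st <- .nat_sim_cpp(p, as.numeric(q_urine_daily_series), bounds,
                     state0[1], state0[2])
  cum <- st[, 1]
  cum[match(collections[, 2], bounds)] - cum[match(collections[, 1], bounds)]
}

#' Natriuresis state trajectory
#'
#' Full state (cumulative sodium, output rate, resistance fraction) at
#' requested times; diagnostic companion to [simulate_natriuresis()].
#'
#' @inheritParams simulate_natriuresis
#' @param times sorted non-negative times (h).
#' @return data frame with columns `time`, `Qcum`, `E`, `R`.
#' @export
natriuresis_trajectory <- function(params, q_urine_daily_series, times,
                                   state0 = NULL) {
  p <- .nat_vec(params)
  .check_sorted_times(times)
  if (is.null(state0)) state0 <- c(p[["kforNa"]] / p[["kabsNa"]], 0)
  st <- .nat_sim_cpp(p, as.numeric(q_urine_daily_series), as.numeric(times),
                     state0[1], state0[2])
  data.frame(time = as.numeric(times), Qcum = st[, 1], E = st[, 2], R = st[, 3])
}
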