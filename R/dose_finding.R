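# Dose determination: steady-state dose -> diuresis curve from the fitted
# model and closed-form inversion to the dose achieving a target daily
# diuresis.  At periodic steady state of the linear PK model the daily
# urinary drug amount is exactly F * Fu * dose (mass balance), so the
# pharmacodynamic power model can be evaluated and inverted analytically.

#' Steady-state dose-response curve for daily diuresis
#'
#' For each dose, the steady-state daily urinary torasemide amount
#' `Q = F * Fu * dose * BW` (ug) is fed through the diuresis power model.
#' Optionally a population band is simulated by Monte-Carlo over the
#' between-subject variabilities (urinary fraction, baseline, slope,
#' exponent), reported as 5th-95th percentiles.
#'
#' @param dose_grid doses to evaluate (mg/kg/day).
#' @param body_weight_kg body weight (kg), default 10.
#' @param pk a [pk_params()] object.
#' @param diuresis a [diuresis_params()] object.
#' @param n_sim Monte-Carlo samples for the population band (0 = typical
#'   values only).
#' @param true a [true_parameters()] object supplying the CV% used for the
#'   band.
#' @param seed seed for the band simulation.
#' @return data frame with `dose`, `q_urine` (ug/day), `diuresis` (mL/day)
#'   and, when `n_sim > 0`, `lower`/`upper` percentile columns.
#' @examples
#' dose_response_curve(c(0, 0.1, 0.2, 0.26, 0.4))
#' @export
dose_response_curve <- function(dose_grid, body_weight_kg = 10,
                                pk = pk_params(), diuresis = diuresis_params(),
                                n_sim = 0, true = true_parameters(),
                                seed = 1L) {
  if (any(dose_grid < 0)) .stopf("doses must be non-negative")
  .check_positive(body_weight_kg, "body_weight_kg")
  q <- steady_state_daily_urine_quantity(pk, dose_grid * body_weight_kg)
  out <- data.frame(dose = dose_grid, q_urine = q,
                    diuresis = predict_daily_diuresis(diuresis, q))
  if (n_sim > 0) {
    set.seed(seed)
    pkv <- unclass(pk); dv <- unclass(diuresis)
    draw <- function(typ, cv) typ * exp(rnorm(n_sim, 0, sqrt(cv_to_omega2(cv))))
    Fu_i <- pmin(draw(pkv[["Fu"]], true$pk_cv[["Fu"]]), 1)
    b_i <- draw(dv[["baseline"]], true$diuresis_cv[["baseline"]])
    s_i <- draw(10^dv[["slope_log10"]], true$diuresis_cv[["slope"]])
    a_i <- draw(dv[["alpha"]], true$diuresis_cv[["alpha"]])
    bands <- vapply(seq_along(dose_grid), function(j) {
      qi <- pkv[["F"]] * Fu_i * dose_grid[j] * body_weight_kg * 1000
      quantile(b_i + s_i * qi^a_i, c(0.05, 0.95))
    }, numeric(2))
    out$lower <- bands[1, ]; out$upper <- bands[2, ]
  }
  out
}

#' Dose achieving a target daily diuresis at steady state
#'
#' Closed-form inversion of the diuresis power model followed by the
#' steady-state mass balance:
#' `dose = ((target - baseline) / 10^slope_log10)^(1/alpha) / (F * Fu * BW * 1000)`.
#' Round-trips with [dose_response_curve()] to numerical precision.
#'
#' @param target_diuresis target daily urine volume (mL/day); must exceed the
#'   model baseline (otherwise no diuretic is needed and an error is raised).
#' @inheritParams dose_response_curve
#' @return dose in mg/kg/day.
#' @examples
#' solve_dose_for_target(460) # about 0.24 mg/kg/day for a 10 kg dog
#' @export
solve_dose_for_target <- function(target_diuresis, body_weight_kg = 10,
                                  pk = pk_params(),
                                  diuresis = diuresis_params()) {
  .check_positive(target_diuresis, "target_diuresis")
  .check_positive(body_weight_kg, "body_weight_kg")
  dv <- unclass(diuresis); pkv <- unclass(pk)
  if (target_diuresis <= dv[["baseline"]])
    .stopf(paste("target (%.0f mL/day) does not exceed the baseline diuresis",
                 "(%.0f mL/day): no diuretic needed"),
           target_diuresis, dv[["baseline"]])
  q <- ((target_diuresis - dv[["baseline"]]) /
          10^dv[["slope_log10"]])^(1 / dv[["alpha"]])
  unname(q / (pkv[["F"]] * pkv[["Fu"]] * body_weight_kg * 1000))
}

#' Furosemide/torasemide equivalence table
#'
#' Loads the observed day-9 diuresis equivalence between twice-daily
#' furosemide and once-daily torasemide (shipped as a plain-text fixture) and
#' appends the model-predicted steady-state diuresis at the torasemide doses
#' plus the implied torasemide:furosemide dose ratio.
#'
#' @inheritParams dose_response_curve
#' @return data frame with the observed reference rows, the model prediction
#'   and the dose-ratio column.
#' @export
abacus_report <- function(pk = pk_params(), diuresis = diuresis_params(),
                          body_weight_kg = 10) {
  path <- system.file("extdata", "furosemide_torasemide_day9_diuresis.csv",
                      package = "torapkpd")
  ref <- read.csv(path, stringsAsFactors = FALSE)
  pred <- dose_response_curve(ref$torasemide_dose_mgkg, body_weight_kg,
                              pk, diuresis)
  ref$torasemide_predicted_mL <- pred$diuresis
  ref$dose_ratio <- ifelse(ref$furosemide_dose_mgkg > 0,
                           ref$torasemide_dose_mgkg / ref$furosemide_dose_mgkg,
                           NA_real_)
  ref
}
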