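#' Diuresis power-model parameters
#'
#' Daily urine volume responds directly to the daily quantity of torasemide
#' excreted in urine (`Q_urine`, ug/day):
#' `E = baseline + 10^slope_log10 * Q_urine^alpha`.
#' Defaults are the published population typical values.
#'
#' @param baseline urine volume over 24 h without treatment (mL/day).
#' @param slope_log10 log10 of the proportionality factor (log10 mL/ug);
#'   -4.11 corresponds to 7.76e-5 mL/ug on the linear scale.
#' @param alpha power exponent (unitless, > 0).
#' @return object of class `diuresis_params`.
#' @examples
#' predict_daily_diuresis(diuresis_params(), 1556.8) # about 492.7 mL/day
#' @export
diuresis_params <- function(baseline = 221, slope_log10 = -4.11, alpha = 2.05) {
  .check_positive(baseline, "baseline")
  .check_positive(alpha, "alpha")
  if (!is.finite(slope_log10)) .stopf("'slope_log10' must be finite")
  structure(c(baseline = baseline, slope_log10 = slope_log10, alpha = alpha),
            class = "diuresis_params")
}

#' Predict daily diuresis from daily urinary torasemide
#'
#' @param params a [diuresis_params()] object.
#' @param q_urine_daily daily urinary torasemide amount(s) (ug/day, >= 0).
#' @return predicted daily urine volume(s) (mL/day).
#' @export
predict_daily_diuresis <- function(params, q_urine_daily) {
  if (any(q_urine_daily < 0)) .stopf("'q_urine_daily' must be non-negative")
  p <- unclass(params)
  p[["baseline"]] + 10^p[["slope_log10"]] * q_urine_daily^p[["alpha"]]
}

#' Rival direct-response effect models
#'
#' The candidate forms considered for the drug effect on daily diuresis:
#' linear, power, Emax and sigmoid-Emax, each on top of a baseline.  The power
#' form with `alpha = 1` reduces to the linear form, and the sigmoid-Emax form
#' with `hill = 1` reduces to the simple Emax form; these nesting identities
#' underpin likelihood-ratio model selection.
#'
#' @param form one of `"linear"`, `"power"`, `"emax"`, `"sigmoid_emax"`.
#' @param baseline baseline response (mL/day).
#' @param slope linear-scale slope (mL/ug), for linear/power forms.
#' @param alpha power exponent, for the power form.
#' @param emax maximal drug effect (mL/day), for (sigmoid-)Emax forms.
#' @param ec50 daily urinary amount at half-maximal effect (ug).
#' @param hill sigmoidicity coefficient, for the sigmoid-Emax form.
#' @return object of class `direct_effect_spec`.
#' @export
direct_effect_spec <- function(form = c("linear", "power", "emax", "sigmoid_emax"),
                               baseline, slope = NULL, alpha = NULL,
                               emax = NULL, ec50 = NULL, hill = NULL) {
  form <- match.arg(form)
  .check_positive(baseline, "baseline")
  pars <- switch(form,
    linear = {
      .check_positive(slope, "slope")
      c(baseline = baseline, slope = slope)
    },
    power = {
      .check_positive(slope, "slope"); .check_positive(alpha, "alpha")
      c(baseline = baseline, slope = slope, alpha = alpha)
    },
    emax = {
      .check_positive(emax, "emax"); .check_positive(ec50, "ec50")
      c(baseline = baseline, emax = emax, ec50 = ec50)
    },
    sigmoid_emax = {
      .check_positive(emax, "emax"); .check_positive(ec50, "ec50")
      .check_positive(hill, "hill")
      c(baseline = baseline, emax = emax, ec50 = ec50, hill = hill)
    })
  structure(list(form = form, pars = pars), class = "direct_effect_spec")
}

#' Evaluate a rival direct-response form
#'
#' @param spec a [direct_effect_spec()] object.
#' @param q_urine_daily daily urinary torasemide amount(s) (ug/day, >= 0).
#' @return predicted response(s) (mL/day).
#' @export
predict_direct_effect <- function(spec, q_urine_daily) {
  if (!inherits(spec, "direct_effect_spec")) .stopf("'spec' must be a direct_effect_spec")
  if (any(q_urine_daily < 0)) .stopf("'q_urine_daily' must be non-negative")
  q <- q_urine_daily
  p <- spec$pars
  switch(spec$form,
    linear = p[["baseline"]] + p[["slope"]] * q,
    power = p[["baseline"]] + p[["slope"]] * q^p[["alpha"]],
    emax = p[["baseline"]] + p[["emax"]] * q / (p[["ec50"]] + q),
    sigmoid_emax = {
      qh <- q^p[["hill"]]
      p[["baseline"]] + p[["emax"]] * qh / (p[["ec50"]]^p[["hill"]] + qh)
    },
    .stopf("unknown direct-effect form '%s'", spec$form))
}
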