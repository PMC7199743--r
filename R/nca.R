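# Model-independent (non-compartmental) summaries: linear-trapezoidal AUC,
# accumulation ratio, dose-proportionality power fit and between-subject
# variability of daily diuresis.

#' Linear-trapezoidal area under the curve
#'
#' Integrates a concentration-time profile over a closed interval by the
#' linear trapezoidal rule, interpolating linearly at the interval endpoints
#' when they fall between samples.  The requested interval must be covered by
#' the sampled range.
#'
#' @param times sorted sampling times (h).
#' @param conc concentrations (ug/L), same length.
#' @param start_h,end_h integration bounds (default: full sampled range).
#' @return AUC in ug.h/L.
#' @export
auc_trapezoid <- function(times, conc, start_h = min(times),
                          end_h = max(times)) {
  .check_sorted_times(times)
  if (length(conc) != length(times)) .stopf("'times' and 'conc' lengths differ")
  if (any(conc < 0)) .stopf("concentrations must be non-negative")
  if (start_h < min(times) - 1e-9 || end_h > max(times) + 1e-9)
    .stopf("interval [%g, %g] outside the sampled range [%g, %g]",
           start_h, end_h, min(times), max(times))
  if (end_h <= start_h) .stopf("end must exceed start")
  grid <- sort(unique(c(start_h, end_h, times[times > start_h & times < end_h])))
  cc <- stats::approx(times, conc, xout = grid, ties = "ordered")$y
  sum(diff(grid) * (cc[-1] + cc[-length(cc)]) / 2)
}

#' Accumulation ratio over a dosing interval
#'
#' Ratio of the steady-state to the first-dose exposure over one dosing
#' interval, `AUC_ss(0-tau) / AUC_day1(0-tau)`, each profile on its own
#' time-since-dose axis.
#'
#' @param times_day1,conc_day1 first-dose profile.
#' @param times_ss,conc_ss steady-state profile (time since last dose).
#' @param tau dosing interval (h), default 24.
#' @return the accumulation ratio (dimensionless).
#' @export
accumulation_ratio <- function(times_day1, conc_day1, times_ss, conc_ss,
                               tau = 24) {
  a1 <- auc_trapezoid(times_day1, conc_day1, 0, tau)
  if (a1 <= 0) .stopf("day-1 AUC is zero; ratio undefined")
  auc_trapezoid(times_ss, conc_ss, 0, tau) / a1
}

#' Dose-proportionality power fit
#'
#' Ordinary least squares on the log-log scale,
#' `log(AUC) = log(alpha) + beta * log(dose)`; dose-proportional exposure
#' corresponds to `beta = 1`.  The confidence interval for `beta` uses the
#' t distribution (degenerate at the point estimate when the fit is exact).
#'
#' @param dose dose levels (> 0), at least 3 distinct values.
#' @param auc corresponding exposures (> 0).
#' @param level confidence level (default 0.90).
#' @return list with `beta`, `ci` (length 2), `alpha`, and the underlying
#'   `lm` fit.
#' @export
dose_proportionality_power_fit <- function(dose, auc, level = 0.90) {
  if (length(dose) != length(auc)) .stopf("'dose' and 'auc' lengths differ")
  if (any(dose <= 0) || any(auc <= 0)) .stopf("doses and AUCs must be positive")
  if (length(unique(dose)) < 3L) .stopf("need at least 3 distinct dose levels")
  fit <- lm(log(auc) ~ log(dose))
  beta <- unname(coef(fit)[2])
  # slope SE computed directly (an exact fit is a legitimate degenerate case)
  ld <- log(dose)
  se <- sqrt(sum(fit$residuals^2) / fit$df.residual / sum((ld - mean(ld))^2))
  tq <- qt(1 - (1 - level) / 2, fit$df.residual)
  list(beta = beta, ci = c(beta - tq * se, beta + tq * se),
       alpha = exp(unname(coef(fit)[1])), fit = fit)
}

#' Between-subject variability of daily diuresis, per dose
#'
#' For each dose group, averages each subject's daily urine volumes over the
#' observation window and reports the coefficient of variation across
#' subjects (sample, n-1, standard deviation).
#'
#' @param subject subject identifiers.
#' @param dose dose group of each record.
#' @param volume daily urine volume of each record (mL).
#' @return data frame with `dose`, `n_subjects`, `cv_percent`.
#' @export
diuresis_variability_summary <- function(subject, dose, volume) {
  if (length(subject) != length(dose) || length(dose) != length(volume))
    .stopf("inputs must have equal length")
  out <- lapply(sort(unique(dose)), function(d) {
    sel <- dose == d
    means <- tapply(volume[sel], subject[sel], mean)
    if (length(means) < 2L)
      .stopf("dose %g has fewer than 2 subjects", d)
    data.frame(dose = d, n_subjects = length(means),
               cv_percent = 100 * sd(means) / mean(means))
  })
  do.call(rbind, out)
}

#' Extract a plasma profile from a trial dataset
#'
#' Convenience accessor returning the quantifiable plasma records of one
#' subject/period as a time-concentration data frame (times in hours since
#' the period's first dose; optionally shifted to time since a reference
#' dose).
#'
#' @param data trial dataset.
#' @param subject_id,period selectors.
#' @param since_h reference time subtracted from the sample times (e.g. the
#'   last dose time); samples before it are dropped.
#' @return data frame with `time_h` and `conc`.
#' @export
plasma_profile <- function(data, subject_id, period, since_h = 0) {
  d <- data[data$record_type == "plasma" & data$subject_id == subject_id &
              data$period == period & data$blq_flag == 0, ]
  d <- d[d$time_h >= since_h, ]
  d <- d[order(d$time_h), ]
  data.frame(time_h = d$time_h - since_h, conc = d$value)
}
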