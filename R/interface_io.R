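# File formats: the trial-dataset CSV dialect and the YAML run configuration.
# Times are hours from the first administration of each period; urine
# intervals are half-open [start, end) with day boundaries at multiples of
# 24 h.  Files are comma-separated, decimal point, UTF-8.

.trial_columns <- c("study_id", "subject_id", "period", "treatment",
                    "body_weight_kg", "record_type", "time_h",
                    "interval_start_h", "interval_end_h", "amount_mg",
                    "value", "blq_flag", "excluded_from_fit")

.record_types <- c("dose", "plasma", "urine_drug", "urine_volume",
                   "urine_sodium")

#' Validate a trial dataset against the dialect
#'
#' Checks the column set, record types, flag domains and the rule that every
#' record carries exactly one of a time point (dose, plasma) or a collection
#' interval (urine records).  Errors name the offending rows.
#'
#' @param data data frame to validate.
#' @return the data (invisibly) if valid; otherwise an error.
#' @export
validate_trial_dataset <- function(data) {
  miss <- setdiff(.trial_columns, names(data))
  if (length(miss)) .stopf("missing column(s): %s", paste(miss, collapse = ", "))
  bad <- which(!data$record_type %in% .record_types)
  if (length(bad)) .stopf("unknown record_type in row(s): %s",
                          paste(utils::head(bad, 5), collapse = ", "))
  timed <- data$record_type %in% c("dose", "plasma")
  has_t <- !is.na(data$time_h)
  has_i <- !is.na(data$interval_start_h) & !is.na(data$interval_end_h)
  bad <- which((timed & (!has_t | has_i)) | (!timed & (has_t | !has_i)))
  if (length(bad))
    .stopf("row(s) %s must carry exactly one of time_h or an interval",
           paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!data$blq_flag %in% c(0L, 1L) |
                 !data$excluded_from_fit %in% c(0L, 1L))
  if (length(bad)) .stopf("flags must be 0/1; offending row(s): %s",
                          paste(utils::head(bad, 5), collapse = ", "))
  num_ok <- is.numeric(data$value) && is.numeric(data$body_weight_kg)
  if (!num_ok) .stopf("'value' and 'body_weight_kg' must be numeric")
  obs <- data$record_type != "dose"
  bad <- which(obs & (is.na(data$value) | data$value < 0))
  if (length(bad)) .stopf("observation values must be non-negative; row(s): %s",
                          paste(utils::head(bad, 5), collapse = ", "))
  invisible(data)
}

#' Read / write a trial dataset
#'
#' CSV with a mandatory header in the package dialect; [write_trial_dataset()]
#' emits records in the canonical order (subject, period, record type, time)
#' so that write-then-read round-trips byte-stably.
#'
#' @param path file path.
#' @return [read_trial_dataset()]: the validated data frame.
#' @export
read_trial_dataset <- function(path) {
  data <- read.csv(path, stringsAsFactors = FALSE)
  validate_trial_dataset(data)
  data
}

#' @rdname read_trial_dataset
#' @param data trial dataset to write.
#' @export
write_trial_dataset <- function(data, path) {
  validate_trial_dataset(data)
  ord <- order(data$subject_id, data$period, data$record_type,
               ifelse(is.na(data$time_h), data$interval_start_h, data$time_h))
  write.csv(data[ord, .trial_columns], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.config_keys <- c("design", "seed", "n_subjects", "true_parameters", "init",
                  "stages", "output", "lloq", "tolerances")

#' Read a run configuration
#'
#' YAML key-value document controlling a simulation/estimation run: `design`
#' (built-in name or dataset path), `seed`, optional `n_subjects`,
#' `true_parameters` / `init` overrides (named exactly as the model
#' parameters), `stages` (subset of pk/diuresis/natriuresis), `output`,
#' `lloq`, `tolerances`.  Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown)) .stopf("unknown configuration key(s): %s",
                              paste(unknown, collapse = ", "))
  if (!is.null(cfg$stages)) {
    bad <- setdiff(cfg$stages, c("pk", "diuresis", "natriuresis"))
    if (length(bad)) .stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  }
  cfg
}

#' Write the provenance manifest of a generated dataset
#'
#' Records design name, seed, subject count and the full true-parameter set of
#' a [generate_trial()] output as YAML, sufficient to regenerate the file
#' exactly.
#'
#' @param data a dataset produced by [generate_trial()].
#' @param path output YAML path.
#' @export
write_trial_manifest <- function(data, path) {
  true <- attr(data, "true")
  man <- list(
    design = attr(data, "design"),
    seed = attr(data, "seed"),
    n_subjects = length(unique(data$subject_id)),
    package_version = as.character(utils::packageVersion("torapkpd")),
    true_parameters = list(
      pk = as.list(unclass(true$pk)), pk_cv = as.list(true$pk_cv),
      diuresis = as.list(unclass(true$diuresis)),
      diuresis_cv = as.list(true$diuresis_cv),
      natriuresis = as.list(unclass(true$natriuresis)),
      natriuresis_cv = as.list(true$natriuresis_cv),
      residuals = true$residuals, lloq = as.list(true$lloq)))
  yaml::write_yaml(man, path)
  invisible(path)
}

#' Serialise a fit report
#'
#' Writes the estimates, relative standard errors, OFV and shrinkage of a
#' [popfit()] object as structured JSON, mirroring the layout of a population
#' parameter table.
#'
#' @param fit a [popfit()] object.
#' @param path output JSON path.
#' @export
write_fit_report <- function(fit, path) {
  if (!inherits(fit, "popfit")) .stopf("'fit' must be a popfit object")
  rep <- list(
    stage = fit$stage,
    ofv = fit$ofv,
    converged = fit$convergence$converged,
    typical_values = as.list(fit$theta),
    iiv_cv_percent = as.list(cv_percent(fit$omega2)),
    residual_error = as.list(fit$sigma),
    shrinkage = as.list(fit$shrinkage),
    n_subjects = fit$n_subjects, n_obs = fit$n_obs)
  if (!is.null(fit$se))
    rep$rse_percent <- as.list(setNames(fit$se$rse_pct, fit$se$parameter))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
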