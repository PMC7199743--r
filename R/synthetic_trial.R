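# Synthetic crossover-trial generator: stands in for the proprietary study
# data.  Emulates the two preclinical designs (rich day-1/day-14 plasma
# sampling, daily troughs, interval urine collections), log-normal
# between-subject variability, proportional(+additive) residual error and
# below-quantification censoring at the published magnitudes.

#' Built-in crossover study designs
#'
#' * `study1`: 5 dogs, 5 periods (placebo and 0.1/0.2/0.4/0.8 mg/kg
#'   torasemide once daily for 14 days), rich plasma sampling on days 1 and 14
#'   (to 72 h) with daily trough + 2 h samples between, 2-hourly urine
#'   collections on days 1 and 14 and 24 h collections otherwise.  The
#'   0.8 mg/kg period is generated but flagged `excluded_from_fit`.
#' * `study2`: 12 dogs, placebo and 0.1/0.2/0.3/0.4 mg/kg torasemide dosed on
#'   day 1 and on days 5-14 (no treatment days 2-4), rich day-1 plasma to
#'   24 h, troughs on days 12-13, rich day-14 sampling to 96 h, daily 24 h
#'   urine collections to day 16.  Twice-daily furosemide periods exist in
#'   the design as placeholders but carry no simulated observations (no
#'   furosemide model is part of the package).
#'
#' @param name `"study1"` or `"study2"`.
#' @return object of class `study_design`.
#' @export
study_design <- function(name = c("study1", "study2")) {
  name <- match.arg(name)
  if (name == "study1") {
    rich <- c(0.25, 0.5, 0.75, 1, 1.5, 2, 4, 6, 8, 10, 24)
    last <- 24 * 13
    plasma <- sort(unique(c(0, rich,
                            24 * (1:12), 24 * (1:12) + 2,
                            last, last + c(rich[1:10], 24, 36, 48, 72))))
    sub_breaks <- c(0, 2, 4, 6, 8, 10, 12, 24)
    ui <- rbind(cbind(sub_breaks[-8], sub_breaks[-1]),
                cbind(24 * (1:12), 24 * (2:13)),
                cbind(last + sub_breaks[-8], last + sub_breaks[-1]))
    vol <- cbind(24 * (0:13), 24 * (1:14))
    design <- list(
      study_id = "study1", n_subjects = 5L,
      body_weight_range = c(9.3, 11.6), washout_days = 14L,
      periods = data.frame(
        label = c("placebo", "T0.1", "T0.2", "T0.4", "T0.8"),
        drug = c("placebo", rep("torasemide", 4)),
        dose_mgkg = c(0, 0.1, 0.2, 0.4, 0.8),
        excluded_from_fit = c(0L, 0L, 0L, 0L, 1L),
        simulate = TRUE, stringsAsFactors = FALSE),
      dosing_days = 1:14,
      plasma_times = plasma, urine_intervals = ui, volume_intervals = vol)
  } else {
    rich <- c(0.25, 0.5, 0.75, 1, 1.5, 2, 4, 6, 8, 12, 24)
    last <- 24 * 13
    plasma <- sort(unique(c(0, rich, 24 * 11, 24 * 12,
                            last, last + c(rich, 48, 72, 96))))
    daily <- cbind(24 * (0:15), 24 * (1:16))
    design <- list(
      study_id = "study2", n_subjects = 12L,
      body_weight_range = c(9.9, 11.2), washout_days = 14L,
      periods = data.frame(
        label = c("placebo", "T0.1", "T0.2", "T0.3", "T0.4",
                  "F1", "F2", "F5", "F8"),
        drug = c("placebo", rep("torasemide", 4), rep("furosemide", 4)),
        dose_mgkg = c(0, 0.1, 0.2, 0.3, 0.4, 1, 2, 5, 8),
        excluded_from_fit = 0L,
        simulate = c(rep(TRUE, 5), rep(FALSE, 4)), stringsAsFactors = FALSE),
      dosing_days = c(1L, 5:14),
      plasma_times = plasma, urine_intervals = daily, volume_intervals = daily)
  }
  structure(design, class = "study_design")
}

#' True parameter set for trial simulation
#'
#' Bundles the structural typical values, between-subject CV%, residual error
#' magnitudes and quantification limits used by [generate_trial()].  Defaults
#' are the published population estimates.
#'
#' @param pk a [pk_params()] object of typical values.
#' @param pk_cv named CV% vector for the PK parameters with variability.
#' @param diuresis a [diuresis_params()] object.
#' @param diuresis_cv named CV% vector (the slope CV applies to the
#'   linear-scale factor `10^slope_log10`).
#' @param natriuresis a [natriuresis_params()] object.
#' @param natriuresis_cv named CV% vector.
#' @param residuals named list of residual error magnitudes (SD scale):
#'   `plasma_prop`, `urine_prop`, `urine_add` (ug), `diuresis_prop`,
#'   `natriuresis_prop`.
#' @param lloq quantification limits: plasma (ug/L) and urine drug
#'   concentration (ug/mL).
#' @return object of class `true_parameters`.
#' @export
true_parameters <- function(pk = pk_params(),
                            pk_cv = c(ka = 126.1, CL = 64.3, Fu = 8.6),
                            diuresis = diuresis_params(),
                            diuresis_cv = c(baseline = 13.4, slope = 45.8,
                                            alpha = 3.9),
                            natriuresis = natriuresis_params(),
                            natriuresis_cv = c(kforNa = 19.4, EmaxNa = 62.4),
                            residuals = list(plasma_prop = 0.184,
                                             urine_prop = 0.225,
                                             urine_add = 3.68,
                                             diuresis_prop = 0.432,
                                             natriuresis_prop = 0.305),
                            lloq = c(plasma_ug_L = 5, urine_ug_mL = 0.02)) {
  if (any(c(pk_cv, diuresis_cv, natriuresis_cv) < 0))
    .stopf("CV%% values must be non-negative")
  structure(list(pk = pk, pk_cv = pk_cv, diuresis = diuresis,
                 diuresis_cv = diuresis_cv, natriuresis = natriuresis,
                 natriuresis_cv = natriuresis_cv, residuals = residuals,
                 lloq = lloq), class = "true_parameters")
}

.subseed <- function(seed, i) as.integer((as.numeric(seed) * 1009 + 7919 * i)
                                         %% 2147483647)

.ln_draw <- function(typ, cv) {
  if (cv <= 0) return(typ)
  typ * exp(rnorm(1, 0, sqrt(cv_to_omega2(cv))))
}

#' Sample individual parameters from the population model
#'
#' Each parameter with between-subject variability is drawn as
#' `theta * exp(eta)` with `eta ~ N(0, omega2)` and
#' `omega2 = log(1 + (CV/100)^2)`; parameters without variability stay at the
#' typical value.  Body weights are drawn uniformly within the design range.
#' Subjects use distinct deterministic sub-seeds, so the draw is reproducible
#' and subjects are independent.
#'
#' @param true a [true_parameters()] object.
#' @param n number of subjects.
#' @param seed integer seed.
#' @param body_weight_range `c(min, max)` body weight (kg).
#' @param stream_offset integer offset applied to the per-subject sub-seeds
#'   (used to give different studies independent streams under one seed).
#' @return data frame, one row per subject, with body weight and all
#'   individual structural parameters.
#' @export
sample_individual_parameters <- function(true, n, seed,
                                         body_weight_range = c(9.9, 11.2),
                                         stream_offset = 0L) {
  if (!inherits(true, "true_parameters")) .stopf("'true' must be true_parameters")
  rows <- lapply(seq_len(n), function(i) {
    set.seed(.subseed(seed, i + stream_offset))
    bw <- runif(1, body_weight_range[1], body_weight_range[2])
    pk <- unclass(true$pk)
    for (nm in names(true$pk_cv)) pk[[nm]] <- .ln_draw(pk[[nm]], true$pk_cv[[nm]])
    di <- unclass(true$diuresis)
    slope_lin <- 10^di[["slope_log10"]]
    di_out <- c(baseline = .ln_draw(di[["baseline"]], true$diuresis_cv[["baseline"]]),
                slope = .ln_draw(slope_lin, true$diuresis_cv[["slope"]]),
                alpha = .ln_draw(di[["alpha"]], true$diuresis_cv[["alpha"]]))
    na <- unclass(true$natriuresis)
    for (nm in names(true$natriuresis_cv))
      na[[nm]] <- .ln_draw(na[[nm]], true$natriuresis_cv[[nm]])
    c(body_weight_kg = bw, pk, di_out, na)
  })
  out <- as.data.frame(do.call(rbind, rows))
  cbind(subject_index = seq_len(n), out)
}

.empty_trial_row <- function() data.frame(
  study_id = character(0), subject_id = character(0), period = character(0),
  treatment = character(0), body_weight_kg = numeric(0),
  record_type = character(0), time_h = numeric(0),
  interval_start_h = numeric(0), interval_end_h = numeric(0),
  amount_mg = numeric(0), value = numeric(0), blq_flag = integer(0),
  excluded_from_fit = integer(0), stringsAsFactors = FALSE)

#' Generate a synthetic crossover trial dataset
#'
#' Simulates every subject and period of a [study_design()] through the PK,
#' diuresis and natriuresis models at individually sampled parameters, then
#' applies channel-specific residual error and flags records below the
#' quantification limits.  With all CV% and residual magnitudes set to zero
#' the observations equal the noiseless model predictions exactly.
#'
#' Channels and units: plasma concentration (ug/L, proportional error),
#' urinary drug amount per collection (ug, proportional + additive error),
#' daily urine volume (mL, proportional), urinary sodium per collection (mEq,
#' proportional).  Negative noised values are truncated at zero (count in
#' `attr(x, "n_truncated")`).  Urinary drug records are flagged below
#' quantification when the implied concentration (amount over the collected
#' volume, pro-rated for sub-daily intervals) falls below the urine assay
#' limit.
#'
#' @param design a [study_design()] object.
#' @param true a [true_parameters()] object.
#' @param seed integer seed (reproducibility contract: same seed, same data).
#' @param n_subjects optional override of the design's subject count.
#' @return trial dataset (data frame in the package dialect) with attributes
#'   `seed`, `design`, `true`, `n_truncated`.
#' @export
generate_trial <- function(design, true = true_parameters(), seed,
                           n_subjects = NULL) {
  if (!inherits(design, "study_design")) .stopf("'design' must be a study_design")
  n <- if (is.null(n_subjects)) design$n_subjects else as.integer(n_subjects)
  # distinct random streams per study so the two designs can share one seed
  soff <- if (design$study_id == "study2") 300000L else 0L
  ind <- sample_individual_parameters(true, n, seed,
                                      design$body_weight_range,
                                      stream_offset = soff)
  res <- true$residuals
  lloq <- true$lloq
  n_trunc <- 0L
  out <- vector("list", n * nrow(design$periods)); k <- 0L

  for (i in seq_len(n)) {
    id <- sprintf("%s-%02d", design$study_id, i)
    bw <- ind$body_weight_kg[i]
    pkv <- c(F = unname(unclass(true$pk)[["F"]]), ka = ind$ka[i],
             CL = ind$CL[i], Fu = ind$Fu[i], Vc = ind$Vc[i], Q = ind$Q[i],
             Vp = ind$Vp[i])
    set.seed(.subseed(seed, 100000L + i + soff)) # residual-noise stream
    for (p in seq_len(nrow(design$periods))) {
      per <- design$periods[p, ]
      if (!per$simulate) next
      dose_t <- 24 * (design$dosing_days - 1)
      dose_a <- rep(per$dose_mgkg * bw, length(dose_t))
      is_tora <- per$drug == "torasemide"
      base_row <- function(type) data.frame(
        study_id = design$study_id, subject_id = id, period = per$label,
        treatment = per$drug, body_weight_kg = bw, record_type = type,
        time_h = NA_real_, interval_start_h = NA_real_,
        interval_end_h = NA_real_, amount_mg = NA_real_, value = NA_real_,
        blq_flag = 0L, excluded_from_fit = per$excluded_from_fit,
        stringsAsFactors = FALSE)

      # dose events
      dr <- base_row("dose")[rep(1, length(dose_t)), ]
      dr$time_h <- dose_t; dr$amount_mg <- dose_a; dr$value <- NA_real_
      k <- k + 1L; out[[k]] <- dr

      vol_int <- design$volume_intervals
      n_days <- max(ceiling(vol_int[, 2] / 24))
      qd <- if (is_tora)
        .daily_driver(pkv, dose_t, dose_a, n_days) else numeric(n_days)

      # daily urine volume (diuresis channel)
      day <- floor(vol_int[, 1] / 24) + 1L
      f_vol <- ind$baseline[i] + ind$slope[i] * qd[day]^ind$alpha[i]
      y_vol <- f_vol * (1 + rnorm(length(f_vol), 0, res$diuresis_prop))
      n_trunc <- n_trunc + sum(y_vol < 0); y_vol <- pmax(y_vol, 0)
      vr <- base_row("urine_volume")[rep(1, nrow(vol_int)), ]
      vr$interval_start_h <- vol_int[, 1]; vr$interval_end_h <- vol_int[, 2]
      vr$value <- y_vol
      k <- k + 1L; out[[k]] <- vr

      # urinary sodium per collection
      nav <- c(kforNa = ind$kforNa[i], kabsNa = ind$kabsNa[i],
               EmaxNa = ind$EmaxNa[i], EC50Na = ind$EC50Na[i],
               hillNa = ind$hillNa[i], kResON = ind$kResON[i],
               kResOFF = ind$kResOFF[i], threshold = ind$threshold[i])
      ui <- design$urine_intervals
      f_na <- simulate_natriuresis(nav, qd, ui)
      y_na <- f_na * (1 + rnorm(length(f_na), 0, res$natriuresis_prop))
      n_trunc <- n_trunc + sum(y_na < 0); y_na <- pmax(y_na, 0)
      nr <- base_row("urine_sodium")[rep(1, nrow(ui)), ]
      nr$interval_start_h <- ui[, 1]; nr$interval_end_h <- ui[, 2]
      nr$value <- y_na
      k <- k + 1L; out[[k]] <- nr

      if (is_tora) {
        # plasma concentrations
        tt <- design$plasma_times
        f_pl <- simulate_plasma(pkv, data.frame(time = dose_t, amount = dose_a),
                                tt)
        y_pl <- f_pl * (1 + rnorm(length(f_pl), 0, res$plasma_prop))
        n_trunc <- n_trunc + sum(y_pl < 0); y_pl <- pmax(y_pl, 0)
        pr <- base_row("plasma")[rep(1, length(tt)), ]
        pr$time_h <- tt; pr$value <- y_pl
        pr$blq_flag <- as.integer(y_pl < lloq[["plasma_ug_L"]])
        k <- k + 1L; out[[k]] <- pr

        # urinary drug amounts per collection
        f_ud <- simulate_urine_excretion(pkv,
                                         data.frame(time = dose_t,
                                                    amount = dose_a), ui)
        y_ud <- f_ud * (1 + rnorm(length(f_ud), 0, res$urine_prop)) +
          rnorm(length(f_ud), 0, res$urine_add)
        n_trunc <- n_trunc + sum(y_ud < 0); y_ud <- pmax(y_ud, 0)
        # implied concentration against the urine assay limit, pro-rating the
        # day's simulated volume for sub-daily collections
        ud_day <- floor(ui[, 1] / 24) + 1L
        vol_of_day <- y_vol[match(ud_day, day)]
        frac <- (ui[, 2] - ui[, 1]) / 24
        conc <- ifelse(vol_of_day * frac > 0, y_ud / (vol_of_day * frac), Inf)
        ur <- base_row("urine_drug")[rep(1, nrow(ui)), ]
        ur$interval_start_h <- ui[, 1]; ur$interval_end_h <- ui[, 2]
        ur$value <- y_ud
        ur$blq_flag <- as.integer(conc < lloq[["urine_ug_mL"]])
        k <- k + 1L; out[[k]] <- ur
      }
    }
  }
  dat <- do.call(rbind, out[seq_len(k)])
  ord <- order(dat$subject_id, dat$period, dat$record_type,
               ifelse(is.na(dat$time_h), dat$interval_start_h, dat$time_h))
  dat <- dat[ord, ]
  rownames(dat) <- NULL
  attr(dat, "seed") <- seed
  attr(dat, "design") <- design$study_id
  attr(dat, "true") <- true
  attr(dat, "n_truncated") <- n_trunc
  dat
}

#' Generate the pooled two-study torasemide dataset
#'
#' Convenience wrapper producing the estimation dataset of the package's
#' recovery analyses: both crossover designs generated under one seed (with
#' independent random streams per study) and concatenated.  The 0.8 mg/kg
#' period of study 1 remains flagged `excluded_from_fit`.
#'
#' @inheritParams generate_trial
#' @return pooled trial dataset.
#' @export
generate_pooled_trial <- function(seed, true = true_parameters()) {
  d1 <- generate_trial(study_design("study1"), true, seed)
  d2 <- generate_trial(study_design("study2"), true, seed)
  out <- rbind(d1, d2)
  attr(out, "seed") <- seed
  attr(out, "design") <- "study1+study2"
  attr(out, "true") <- true
  attr(out, "n_truncated") <- attr(d1, "n_truncated") + attr(d2, "n_truncated")
  out
}

#' Apply below-quantification handling rules to plasma profiles
#'
#' Within each subject/period plasma profile (sorted by time): records below
#' the limit of quantification before the first quantifiable concentration
#' are set to zero and retained; those after the last quantifiable
#' concentration are removed, as are isolated below-limit records in between.
#' Profiles that never reach the limit are retained entirely as zeros.  Other
#' record types are returned unchanged.
#'
#' @param data trial dataset.
#' @return the dataset with the rules applied.
#' @export
apply_blq_rules <- function(data) {
  is_pl <- data$record_type == "plasma"
  if (!any(is_pl)) return(data)
  keep <- rep(TRUE, nrow(data))
  idx_all <- which(is_pl)
  key <- paste(data$subject_id[idx_all], data$period[idx_all])
  for (kk in unique(key)) {
    idx <- idx_all[key == kk]
    idx <- idx[order(data$time_h[idx])]
    q <- which(data$blq_flag[idx] == 0)
    if (!length(q)) { data$value[idx] <- 0; next } # all leading, kept as zeros
    pos_blq <- which(data$blq_flag[idx] == 1)
    data$value[idx[pos_blq[pos_blq < q[1]]]] <- 0      # leading: zeroed, kept
    keep[idx[pos_blq[pos_blq > q[1]]]] <- FALSE        # intermediate/trailing
  }
  out <- data[keep, ]
  rownames(out) <- NULL
  out
}
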