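# Stage builders: translate a trial dataset (the package CSV dialect) into the
# per-subject prediction closures consumed by the Laplace machinery.  Records
# flagged excluded_from_fit or below the limit of quantification do not enter
# the likelihood (leading below-quantification zeros are degenerate under a
# proportional-only residual model and carry no information).

.fit_records <- function(data, type, drop_blq = TRUE) {
  d <- data[data$record_type == type & data$excluded_from_fit == 0, ]
  if (drop_blq && nrow(d)) d <- d[d$blq_flag == 0, ]
  d
}

.subject_doses <- function(data) {
  d <- data[data$record_type == "dose" & data$amount_mg > 0, ]
  split(d[, c("period", "time_h", "amount_mg")],
        d$subject_id, drop = TRUE)
}

.period_doses <- function(dose_tab, period) {
  if (is.null(dose_tab)) return(list(t = numeric(0), a = numeric(0)))
  d <- dose_tab[dose_tab$period == period, ]
  list(t = d$time_h, a = d$amount_mg)
}

## ---- PK stage ------------------------------------------------------------

.build_stage_pk <- function(data) {
  pla <- .fit_records(data, "plasma")
  uri <- .fit_records(data, "urine_drug")
  if (!nrow(pla) && !nrow(uri))
    .stopf("no quantifiable plasma or urinary drug observations to fit")
  doses <- .subject_doses(data)
  ids <- sort(unique(c(pla$subject_id, uri$subject_id)))
  Fconst <- 0.98

  subjects <- lapply(ids, function(id) {
    sp <- pla[pla$subject_id == id, ]
    su <- uri[uri$subject_id == id, ]
    pers <- sort(unique(c(sp$period, su$period)))
    y <- numeric(0); chan <- integer(0); periods <- list()
    for (pr in pers) {
      dd <- .period_doses(doses[[id]], pr)
      pi <- sp[sp$period == pr, ]; pi <- pi[order(pi$time_h), ]
      ui <- su[su$period == pr, ]; ui <- ui[order(ui$interval_start_h), ]
      ub <- sort(unique(c(ui$interval_start_h, ui$interval_end_h)))
      periods[[length(periods) + 1L]] <- list(
        dose_t = dd$t, dose_a = dd$a, pt = pi$time_h, ub = ub,
        ui0 = match(ui$interval_start_h, ub), ui1 = match(ui$interval_end_h, ub))
      y <- c(y, pi$value, ui$value)
      chan <- c(chan, rep.int(1L, nrow(pi)), rep.int(2L, nrow(ui)))
    }
    pred <- local({
      periods <- periods; Fc <- Fconst
      function(th) {
        pv <- c(Fc, th[["ka"]], th[["CL"]], th[["Fu"]], th[["Vc"]],
                th[["Q"]], th[["Vp"]])
        out <- vector("list", 2L * length(periods)); k <- 0L
        for (p in periods) {
          if (length(p$pt)) {
            k <- k + 1L
            out[[k]] <- .pk_conc_cpp(pv, p$dose_t, p$dose_a, p$pt)
          }
          if (length(p$ub)) {
            k <- k + 1L
            cum <- .pk_urine_cum_cpp(pv, p$dose_t, p$dose_a, p$ub)
            out[[k]] <- (cum[p$ui1] - cum[p$ui0]) * 1000
          }
        }
        unlist(out[seq_len(k)], use.names = FALSE)
      }
    })
    list(id = id, y = y, chan = chan, pred = pred)
  })

  list(stage = "pk",
       subjects = subjects,
       channels = c("plasma", "urine"),
       sigma_map = data.frame(
         name = c("plasma_prop", "urine_prop", "urine_add"),
         channel = c("plasma", "urine", "urine"),
         type = c("prop", "prop", "add"), stringsAsFactors = FALSE),
       theta0 = unclass(pk_params())[-1],  # F excluded (fixed constant)
       const = c(F = Fconst),
       omega2_0 = cv_to_omega2(c(ka = 126.1, CL = 64.3, Fu = 8.6)),
       sigma0 = c(plasma_prop = 0.184, urine_prop = 0.225, urine_add = 3.68))
}

## ---- individual PK parameters for the PD drivers -------------------------

# per-subject structural PK parameter lookup from a fitted PK stage;
# population typicals for subjects without a PK fit
.pk_lookup <- function(pk_fit) {
  typ <- unclass(pk_params())
  if (is.null(pk_fit)) return(function(id) typ)
  if (!inherits(pk_fit, "popfit") || pk_fit$stage != "pk")
    .stopf("'pk_fit' must be a fitted stage = \"pk\" popfit object")
  ind <- pk_fit$individual
  function(id) {
    i <- match(id, ind$subject_id)
    if (is.na(i)) return(typ)
    c(F = unname(pk_fit$const[["F"]]), ka = ind$ka[i], CL = ind$CL[i],
      Fu = ind$Fu[i], Vc = ind$Vc[i], Q = ind$Q[i], Vp = ind$Vp[i])
  }
}

# daily urinary torasemide amounts (ug) per subject/period, the PD driver
.daily_driver <- function(pv, dose_t, dose_a, n_days) {
  if (!length(dose_t)) return(numeric(n_days))
  cum <- .pk_urine_cum_cpp(pv, dose_t, dose_a, 24 * (0:n_days))
  diff(cum) * 1000
}

## ---- diuresis stage ------------------------------------------------------

.build_stage_diuresis <- function(data, pk_fit, form = "power") {
  form <- match.arg(form, c("power", "linear", "emax", "sigmoid_emax"))
  vol <- .fit_records(data, "urine_volume")
  if (!nrow(vol)) .stopf("no daily urine volume observations to fit")
  doses <- .subject_doses(data)
  lookup <- .pk_lookup(pk_fit)
  ids <- sort(unique(vol$subject_id))

  subjects <- lapply(ids, function(id) {
    sv <- vol[vol$subject_id == id, ]
    pv <- lookup(id)
    q <- numeric(nrow(sv)); k <- 0L
    for (pr in unique(sv$period)) {
      si <- sv[sv$period == pr, ]
      dd <- .period_doses(doses[[id]], pr)
      nd <- max(ceiling(si$interval_end_h / 24))
      qd <- .daily_driver(pv, dd$t, dd$a, nd)
      day <- floor(si$interval_start_h / 24) + 1L
      q[k + seq_len(nrow(si))] <- qd[day]
      k <- k + nrow(si)
    }
    y <- unlist(lapply(unique(sv$period),
                       function(pr) sv$value[sv$period == pr]))
    pred <- .make_direct_pred(form, q)
    list(id = id, y = y, chan = rep.int(1L, length(y)), pred = pred, q = q)
  })

  yall <- unlist(lapply(subjects, `[[`, "y"))
  qall <- unlist(lapply(subjects, `[[`, "q"))
  init <- .direct_form_init(form, yall, qall)

  list(stage = "diuresis", form = form,
       subjects = subjects,
       channels = "diuresis",
       sigma_map = data.frame(name = "diuresis_prop", channel = "diuresis",
                              type = "prop", stringsAsFactors = FALSE),
       theta0 = init$theta0, const = NULL,
       omega2_0 = init$omega2_0,
       sigma0 = c(diuresis_prop = 0.432))
}

.make_direct_pred <- function(form, q) {
  force(q)
  switch(form,
    power = function(th) th[["baseline"]] + th[["slope"]] * q^th[["alpha"]],
    linear = function(th) th[["baseline"]] + th[["slope"]] * q,
    emax = function(th) th[["baseline"]] +
      th[["emax"]] * q / (th[["ec50"]] + q),
    sigmoid_emax = function(th) {
      qh <- q^th[["hill"]]
      th[["baseline"]] + th[["emax"]] * qh / (th[["ec50"]]^th[["hill"]] + qh)
    })
}

.direct_form_init <- function(form, y, q) {
  b0 <- 221
  iiv_b <- cv_to_omega2(13.4); iiv_s <- cv_to_omega2(45.8)
  qpos <- q[q > 0]
  top <- max(quantile(y, 0.95) - b0, 50)
  switch(form,
    power = list(theta0 = c(baseline = 221, slope = 10^-4.11, alpha = 2.05),
                 omega2_0 = c(baseline = iiv_b, slope = iiv_s,
                              alpha = cv_to_omega2(3.9))),
    linear = list(theta0 = c(baseline = b0,
                             slope = unname(top / max(qpos, 1))),
                  omega2_0 = c(baseline = iiv_b, slope = iiv_s)),
    emax = list(theta0 = c(baseline = b0, emax = unname(2 * top),
                           ec50 = unname(stats::median(qpos))),
                omega2_0 = c(baseline = iiv_b, emax = iiv_s)),
    sigmoid_emax = list(theta0 = c(baseline = b0, emax = unname(2 * top),
                                   ec50 = unname(stats::median(qpos)),
                                   hill = 1.5),
                        omega2_0 = c(baseline = iiv_b, emax = iiv_s)))
}

## ---- natriuresis stage ---------------------------------------------------

.build_stage_natriuresis <- function(data, pk_fit) {
  na <- .fit_records(data, "urine_sodium")
  if (!nrow(na)) .stopf("no urinary sodium observations to fit")
  doses <- .subject_doses(data)
  lookup <- .pk_lookup(pk_fit)
  ids <- sort(unique(na$subject_id))

  subjects <- lapply(ids, function(id) {
    sn <- na[na$subject_id == id, ]
    pv <- lookup(id)
    periods <- list(); y <- numeric(0)
    for (pr in sort(unique(sn$period))) {
      si <- sn[sn$period == pr, ]; si <- si[order(si$interval_start_h), ]
      dd <- .period_doses(doses[[id]], pr)
      nd <- max(ceiling(si$interval_end_h / 24))
      qd <- .daily_driver(pv, dd$t, dd$a, nd)
      ub <- sort(unique(c(si$interval_start_h, si$interval_end_h)))
      periods[[length(periods) + 1L]] <- list(
        q = qd, ub = ub, i0 = match(si$interval_start_h, ub),
        i1 = match(si$interval_end_h, ub))
      y <- c(y, si$value)
    }
    pred <- local({
      periods <- periods
      function(th) {
        pars <- c(th[["kforNa"]], th[["kabsNa"]], th[["EmaxNa"]],
                  th[["EC50Na"]], th[["hillNa"]], th[["kResON"]],
                  th[["kResOFF"]], th[["threshold"]])
        out <- vector("list", length(periods))
        for (k in seq_along(periods)) {
          p <- periods[[k]]
          st <- .nat_sim_cpp(pars, p$q, p$ub, pars[1] / pars[2], 0)
          out[[k]] <- st[p$i1, 1] - st[p$i0, 1]
        }
        unlist(out, use.names = FALSE)
      }
    })
    list(id = id, y = y, chan = rep.int(1L, length(y)), pred = pred)
  })

  list(stage = "natriuresis",
       subjects = subjects,
       channels = "natriuresis",
       sigma_map = data.frame(name = "natriuresis_prop",
                              channel = "natriuresis", type = "prop",
                              stringsAsFactors = FALSE),
       theta0 = unclass(natriuresis_params()), const = NULL,
       omega2_0 = cv_to_omega2(c(kforNa = 19.4, EmaxNa = 62.4)),
       sigma0 = c(natriuresis_prop = 0.305))
}
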