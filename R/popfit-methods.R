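# S3 methods for fitted population models

#' @export
print.popfit <- function(x, ...) {
  cat("Population", switch(x$stage, pk = "pharmacokinetic",
                           diuresis = "diuresis", natriuresis = "natriuresis"),
      "model fit (Laplace marginal likelihood)\n")
  if (!is.null(x$form)) cat("Direct-effect form:", x$form, "\n")
  cat(sprintf("  %d subjects, %d observations\n", x$n_subjects, x$n_obs))
  cat(sprintf("  OFV (-2LL): %.3f   converged: %s\n", x$ofv,
              x$convergence$converged))
  cat("Typical values:\n")
  print(signif(x$theta, 4))
  if (length(x$omega2)) {
    cat("Between-subject variability (CV%):\n")
    print(round(cv_percent(x$omega2), 1))
  }
  cat("Residual error:\n")
  print(signif(x$sigma, 4))
  invisible(x)
}

#' @export
coef.popfit <- function(object, type = c("theta", "all"), ...) {
  type <- match.arg(type)
  if (type == "theta") return(object$theta)
  c(object$theta,
    setNames(object$omega2, paste0("omega2.", names(object$omega2))),
    setNames(object$sigma, paste0("sigma.", names(object$sigma))))
}

#' @export
logLik.popfit <- function(object, ...) {
  val <- -object$ofv / 2
  attr(val, "df") <- length(object$theta) - length(object$fixed) +
    length(object$omega2) + length(object$sigma)
  attr(val, "nobs") <- object$n_obs
  class(val) <- "logLik"
  val
}

#' @export
summary.popfit <- function(object, ...) {
  tab <- data.frame(parameter = names(object$theta),
                    estimate = unname(object$theta))
  if (!is.null(object$se)) {
    m <- match(paste0("theta.", tab$parameter), object$se$parameter)
    tab$rse_pct <- object$se$rse_pct[m]
  }
  iiv <- if (length(object$omega2))
    data.frame(parameter = names(object$omega2),
               omega2 = unname(object$omega2),
               cv_percent = unname(cv_percent(object$omega2)),
               shrinkage_pct = unname(100 * object$shrinkage))
  out <- list(stage = object$stage, form = object$form, ofv = object$ofv,
              typical = tab, iiv = iiv, sigma = object$sigma,
              n_subjects = object$n_subjects, n_obs = object$n_obs,
              convergence = object$convergence)
  class(out) <- "summary.popfit"
  out
}

#' @export
print.summary.popfit <- function(x, ...) {
  cat("Stage:", x$stage, if (!is.null(x$form)) paste0("(", x$form, ")"), "\n")
  cat(sprintf("OFV: %.3f over %d observations from %d subjects\n",
              x$ofv, x$n_obs, x$n_subjects))
  cat("\nTypical values:\n"); print(x$typical, row.names = FALSE, digits = 4)
  if (!is.null(x$iiv)) {
    cat("\nBetween-subject variability:\n")
    print(x$iiv, row.names = FALSE, digits = 3)
  }
  cat("\nResidual error:\n"); print(signif(x$sigma, 4))
  cat(sprintf("\nConvergence: %s (%d outer iterations, %d evaluations)\n",
              x$convergence$converged, x$convergence$iterations,
              x$convergence$evaluations))
  invisible(x)
}

# fitted values per observation, at population or individual parameters
.popfit_fitted <- function(object, level) {
  ss <- object$stage_spec
  out <- lapply(ss$subjects, function(blob) {
    th <- object$theta
    if (level == "individual" && length(object$omega2)) {
      eta <- object$ebes[blob$id, ]
      th[names(object$omega2)] <- th[names(object$omega2)] * exp(eta)
    }
    data.frame(subject_id = blob$id, channel = ss$channels[blob$chan],
               observed = blob$y, predicted = blob$pred(th),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Predicted observations from a fitted population model
#'
#' @param object a [popfit()] object.
#' @param level `"individual"` (empirical Bayes parameters, default) or
#'   `"population"` (typical values).
#' @param ... unused.
#' @return data frame with `subject_id`, `channel`, `observed`, `predicted`,
#'   one row per observation entering the fit.
#' @export
predict.popfit <- function(object, level = c("individual", "population"),
                           ...) {
  level <- match.arg(level)
  .popfit_fitted(object, level)
}

#' @export
fitted.popfit <- function(object, ...) {
  .popfit_fitted(object, "individual")$predicted
}

#' Residuals of a fitted population model
#'
#' @param object a [popfit()] object.
#' @param type `"pearson"` (residuals scaled by the residual-error standard
#'   deviation at the individual prediction, default) or `"response"`.
#' @param ... unused.
#' @return numeric vector aligned with the observations entering the fit.
#' @export
residuals.popfit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  pr <- .popfit_fitted(object, "individual")
  res <- pr$observed - pr$predicted
  if (type == "response") return(res)
  ss <- object$stage_spec
  sp <- sa <- setNames(numeric(length(ss$channels)), ss$channels)
  for (k in seq_len(nrow(ss$sigma_map))) {
    row <- ss$sigma_map[k, ]
    if (row$type == "prop") sp[[row$channel]] <- object$sigma[[row$name]]
    else sa[[row$channel]] <- object$sigma[[row$name]]
  }
  v <- (sp[pr$channel] * pr$predicted)^2 + sa[pr$channel]^2
  res / sqrt(v)
}

#' Observed-versus-predicted diagnostic plot
#'
#' @param x a [popfit()] object.
#' @param level passed to [predict.popfit()].
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.popfit <- function(x, level = "individual", ...) {
  pr <- .popfit_fitted(x, level)
  graphics::plot(pr$predicted, pr$observed,
                 xlab = paste(level, "prediction"), ylab = "observation",
                 main = paste("torasemide", x$stage, "fit"),
                 col = as.integer(factor(pr$channel)), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(pr)
}
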