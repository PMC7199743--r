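# input-checking helpers shared across modules

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    .stopf("'%s' must be a single finite positive number", name)
  invisible(x)
}

.check_fraction <- function(x, name) {
  .check_positive(x, name)
  if (x > 1) .stopf("'%s' must lie in (0, 1]", name)
  invisible(x)
}

.check_sorted_times <- function(times, name = "times") {
  if (!is.numeric(times)) .stopf("'%s' must be numeric", name)
  if (any(!is.finite(times)) || any(times < 0))
    .stopf("'%s' must be finite and non-negative", name)
  if (is.unsorted(times)) .stopf("'%s' must be sorted increasingly", name)
  invisible(times)
}

# intervals: 2-column object (start, end); must be sorted and non-overlapping
.check_intervals <- function(intervals, name = "intervals") {
  intervals <- as.matrix(intervals)
  if (ncol(intervals) != 2L) .stopf("'%s' must have two columns (start, end)", name)
  if (any(!is.finite(intervals)) || any(intervals < 0))
    .stopf("'%s' must be finite and non-negative", name)
  if (any(intervals[, 2] <= intervals[, 1]))
    .stopf("'%s' must have end > start in every row", name)
  if (nrow(intervals) > 1L &&
      any(intervals[-1L, 1] < intervals[-nrow(intervals), 2] - 1e-9))
    .stopf("'%s' must be non-overlapping and sorted", name)
  invisible(intervals)
}

.as_dose_frame <- function(doses) {
  if (is.null(doses) || (is.data.frame(doses) && nrow(doses) == 0L))
    return(data.frame(time = numeric(0), amount = numeric(0)))
  doses <- as.data.frame(doses)
  if (!all(c("time", "amount") %in% names(doses)))
    .stopf("'doses' needs columns 'time' and 'amount'")
  if (any(doses$time < 0) || any(doses$amount < 0))
    .stopf("dose times and amounts must be non-negative")
  doses[order(doses$time), c("time", "amount"), drop = FALSE]
}
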