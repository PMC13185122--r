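# Scalar time-series utilities shared by the analyses.

#' Block-average a scalar time series
#'
#' Non-overlapping blocks of fixed duration starting at the first sample
#' time; each block reports the mean of its samples at the block-center
#' time. A trailing partial block is averaged over the samples it
#' contains and reported at the center of the span it covers.
#'
#' @param times numeric, strictly increasing sample times (ns).
#' @param values numeric, same length.
#' @param window block duration in ns (default 15, the standard smoothing
#'   window for these observables).
#' @return data.frame with columns `time` and `value`.
#' @export
block_average <- function(times, values, window = 15) {
  stopifnot(length(times) == length(values), window > 0)
  if (length(times) == 0) stop("empty series")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  idx <- floor((times - times[1]) / window)
  ublk <- sort(unique(idx))
  t_end <- times[length(times)]
  out_t <- vapply(ublk, function(b) {
    lo <- times[1] + b * window
    hi <- min(lo + window, t_end)
    (lo + hi) / 2
  }, numeric(1))
  out_v <- vapply(ublk, function(b) mean(values[idx == b]), numeric(1))
  data.frame(time = out_t, value = out_v)
}

#' Mean of a time series over an analysis interval
#'
#' Time-averaged quantities conventionally exclude an initial
#' equilibration span; by default the first quarter of the trajectory is
#' skipped when no absolute start time is given.
#'
#' @param times sample times (ns).
#' @param values sample values.
#' @param start absolute start time (ns); samples at `time >= start` are
#'   averaged. If `NULL`, start = first time + 25% of the span.
#' @param end optional absolute end time (default: last sample).
#' @return the interval mean (scalar).
#' @export
interval_mean <- function(times, values, start = NULL, end = NULL) {
  if (is.null(start)) start <- times[1] + 0.25 * (times[length(times)] - times[1])
  if (is.null(end)) end <- times[length(times)]
  keep <- times >= start & times <= end
  if (!any(keep)) stop("analysis interval contains no samples")
  mean(values[keep])
}
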