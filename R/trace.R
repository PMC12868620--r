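#' Construct a fluorescence (or area) time course
#'
#' The unit of kinetic analysis: one time-stamped series of dye-uptake
#' fluorescence (arbitrary units) or projected area (um^2) for a sub-region,
#' cell group, or spheroid, together with the time at which the pulse train
#' was delivered.
#'
#' @param times Sample times in seconds, strictly increasing.
#' @param values Fluorescence (a.u.) or area (um^2), same length as `times`.
#' @param exposure_time Time of pulse delivery in seconds. At least 3 samples
#'   must precede it and at least 10 follow it.
#' @param kind `"uptake"` or `"area"`.
#' @param meta Named list of metadata (trace_id, cell_line, ca_mM,
#'   field_level, replicate_id, ...).
#' @return An object of class `"fluorescence_trace"`.
#' @export
fluorescence_trace <- function(times, values, exposure_time,
                               kind = c("uptake", "area"), meta = list()) {
  kind <- match.arg(kind)
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("'times' and 'values' must have equal length")
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    stop("'times' must be finite and strictly increasing")
  if (any(!is.finite(values))) stop("'values' must be finite")
  if (sum(times < exposure_time) < 3L)
    stop("need at least 3 samples before the exposure time")
  if (sum(times >= exposure_time) < 10L)
    stop("need at least 10 samples after the exposure time")
  structure(list(times = times, values = values,
                 exposure_time = exposure_time, kind = kind, meta = meta),
            class = "fluorescence_trace")
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  id <- x$meta$trace_id %||% "<unnamed>"
  cat(sprintf("Fluorescence trace '%s' (%s): %d samples, t = [%g, %g] s, exposure at %g s\n",
              id, x$kind, length(x$times), min(x$times), max(x$times),
              x$exposure_time))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.pre_mask <- function(trace) trace$times < trace$exposure_time

#' Subtract the pre-exposure baseline from a trace
#'
#' Subtracts the mean of all samples recorded before the exposure time from
#' every value, so the pre-exposure portion has zero mean. Idempotent.
#'
#' @param trace A [fluorescence_trace()].
#' @return The trace with baseline-corrected values; the subtracted baseline
#'   is stored in `attr(, "baseline")`.
#' @export
subtract_baseline <- function(trace) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  pre <- .pre_mask(trace)
  if (!any(pre)) stop("no pre-exposure samples to estimate a baseline from")
  b <- mean(trace$values[pre])
  trace$values <- trace$values - b
  attr(trace, "baseline") <- b
  trace
}

#' Trapezoidal area under a baseline-subtracted trace
#'
#' Integrates the baseline-subtracted values over `[t_start, t_end]` with the
#' trapezoidal rule (interval endpoints interpolated linearly when they fall
#' between samples). Additive over adjacent intervals.
#'
#' @param trace A [fluorescence_trace()].
#' @param t_start,t_end Integration limits in seconds, within the trace span.
#'   Defaults: exposure time to the last sample.
#' @param baseline_subtract Subtract the pre-exposure baseline first
#'   (default TRUE).
#' @return Integral in a.u. x s (or um^2 x s for area traces).
#' @export
trace_auc <- function(trace, t_start = trace$exposure_time,
                      t_end = max(trace$times), baseline_subtract = TRUE) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  if (t_start >= t_end) stop("'t_start' must be strictly less than 't_end'")
  if (t_start < min(trace$times) || t_end > max(trace$times))
    stop("integration limits must lie within the trace time span")
  if (baseline_subtract) trace <- subtract_baseline(trace)
  t <- trace$times; v <- trace$values
  # clip to [t_start, t_end] with linear interpolation at the cut points
  keep <- t > t_start & t < t_end
  tt <- c(t_start, t[keep], t_end)
  vv <- c(stats::approx(t, v, xout = t_start)$y, v[keep],
          stats::approx(t, v, xout = t_end)$y)
  sum(diff(tt) * (utils::head(vv, -1) + utils::tail(vv, -1)) / 2)
}

.value_at <- function(trace, t_eval) {
  t <- trace$times
  dt <- stats::median(diff(t))
  i <- which.min(abs(t - t_eval))
  if (abs(t[i] - t_eval) > dt)
    stop(sprintf("'t_eval' = %g s is more than one sampling interval from any sample", t_eval))
  trace$values[i]
}

#' Baseline-subtracted uptake at a fixed time point
#'
#' Looks up the baseline-subtracted value at the sample nearest `t_eval`
#' (tolerance: one sampling interval). Conventionally evaluated 180 s after
#' the start of a monolayer acquisition, or 10 min post-exposure for
#' spheroids.
#'
#' @param trace A [fluorescence_trace()].
#' @param t_eval Evaluation time in seconds.
#' @return Baseline-subtracted value (a.u.).
#' @export
final_uptake <- function(trace, t_eval = max(trace$times)) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  .value_at(subtract_baseline(trace), t_eval)
}

#' Fold change of mean final uptake between two trace groups
#'
#' Ratio of group means of baseline-subtracted uptake at `t_eval`
#' (`mean(group_a) / mean(group_b)`).
#'
#' @param group_a,group_b Lists of [fluorescence_trace()] objects.
#' @param t_eval Evaluation time in seconds.
#' @return List with `fold_change`, the two group means, and `defined`
#'   (FALSE when the denominator mean is not positive, in which case
#'   `fold_change` is NA).
#' @export
group_fold_change <- function(group_a, group_b, t_eval) {
  ma <- mean(vapply(group_a, final_uptake, numeric(1), t_eval = t_eval))
  mb <- mean(vapply(group_b, final_uptake, numeric(1), t_eval = t_eval))
  if (mb <= 0) {
    warning("denominator group mean is not positive; fold change undefined")
    return(list(fold_change = NA_real_, mean_a = ma, mean_b = mb, defined = FALSE))
  }
  list(fold_change = ma / mb, mean_a = ma, mean_b = mb, defined = TRUE)
}

#' Percent change of projected area relative to the pre-exposure mean
#'
#' For spheroid swelling traces: `100 * (value(t_eval) - pre) / pre`, where
#' `pre` is the mean projected area before exposure.
#'
#' @param trace A [fluorescence_trace()] of kind `"area"`.
#' @param t_eval Evaluation time in seconds (default: last sample, i.e. 10
#'   min post-exposure for the standard spheroid acquisition).
#' @return Percent change.
#' @export
percent_area_change <- function(trace, t_eval = max(trace$times)) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  if (trace$kind != "area") stop("'trace' must be an area trace (kind = \"area\")")
  pre <- mean(trace$values[.pre_mask(trace)])
  if (pre <= 0) stop("pre-exposure mean area must be positive")
  100 * (.value_at(trace, t_eval) - pre) / pre
}
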