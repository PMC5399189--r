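#' Stimulus-evoked ROS accumulation as area under the curve
#'
#' HEt oxidation is cumulative, so even resting cells show a rising signal.
#' The pre-stimulus segment is therefore summarized by a linear trend
#' (default) or its mean, and the stimulus effect is the trapezoidal
#' integral of the fluorescence *above the extrapolated pre-stimulus trend*
#' over the stimulus window — the cumulative extra oxidation evoked by the
#' challenge.
#'
#' @param time time vector (s).
#' @param values fluorescence vector.
#' @param stim_start_s,stim_end_s stimulus window (s), inside the trace.
#' @param baseline_mode `"linear"` (trend extrapolation) or `"mean"`.
#' @param roi_id label carried into the summary.
#' @return an object of class `ros_summary`: `roi_id`, `baseline_f` (mean
#'   pre-stimulus fluorescence), `auc` (fluorescence x s above trend), and
#'   `window`.
#' @examples
#' t <- 0:600
#' f <- 1000 + 0.2 * t + 0.05 * pmax(0, pmin(t, 360) - 60)  # extra slope in 60..360
#' ros_auc(t, f, 60, 360)$auc  # 0.05 * 300^2 / 2 = 2250
#' @export
ros_auc <- function(time, values, stim_start_s, stim_end_s,
                    baseline_mode = c("linear", "mean"), roi_id = NA) {
  baseline_mode <- match.arg(baseline_mode)
  if (length(time) != length(values)) stop_param("time/values length mismatch")
  if (stim_start_s < min(time) || stim_end_s > max(time) ||
      stim_end_s <= stim_start_s)
    stop_param("stimulus window must lie inside the trace")
  pre <- time < stim_start_s
  if (sum(pre) < 10) stop_param("need >= 10 pre-stimulus samples")

  trend <- if (baseline_mode == "linear") {
    fit <- stats::lm(values[pre] ~ time[pre])
    stats::coef(fit)[1] + stats::coef(fit)[2] * time
  } else {
    rep(mean(values[pre]), length(time))
  }

  win <- time >= stim_start_s & time <= stim_end_s
  auc <- trapz(time[win], (values - trend)[win])
  structure(list(
    roi_id = roi_id,
    baseline_f = mean(values[pre]),
    auc = auc,
    window = c(stim_start_s, stim_end_s),
    baseline_mode = baseline_mode
  ), class = "ros_summary")
}

#' AUC analysis of every ROI in a trace set
#'
#' @param traces a `fluor_trace_set` (e.g. from [generate_het()]).
#' @param stim_start_s,stim_end_s stimulus window (s).
#' @param baseline_mode passed to [ros_auc()].
#' @return data frame with one row per ROI: `roi`, `baseline_f`, `auc`.
#' @export
ros_auc_set <- function(traces, stim_start_s, stim_end_s,
                        baseline_mode = "linear") {
  stopifnot(inherits(traces, "fluor_trace_set"))
  rows <- lapply(seq_len(ncol(traces$values)), function(r) {
    s <- ros_auc(traces$time, traces$values[, r], stim_start_s, stim_end_s,
                 baseline_mode, roi_id = colnames(traces$values)[r])
    data.frame(roi = as.character(s$roi_id), baseline_f = s$baseline_f,
               auc = s$auc)
  })
  do.call(rbind, rows)
}

#' Baseline (resting) HEt fluorescence per ROI and per group
#'
#' The mean pre-stimulus fluorescence per ROI indexes the oxidation
#' accumulated before the session, i.e. resting ROS production. SEM is `NA`
#' for a single ROI.
#'
#' @param traces a `fluor_trace_set`.
#' @param stim_start_s end of the pre-stimulus segment (s); the full trace
#'   is used when it exceeds the trace.
#' @return list with `per_roi` (data frame `roi`, `baseline_f`) and `mean`,
#'   `sem`, `n`.
#' @export
baseline_ros <- function(traces, stim_start_s = Inf) {
  stopifnot(inherits(traces, "fluor_trace_set"))
  pre <- traces$time < stim_start_s
  if (!any(pre)) stop_param("no samples before stim_start_s")
  b <- colMeans(traces$values[pre, , drop = FALSE])
  list(
    per_roi = data.frame(roi = colnames(traces$values), baseline_f = unname(b)),
    mean = mean(b),
    sem = sem(b),
    n = length(b)
  )
}

#' @export
print.ros_summary <- function(x, ...) {
  cat(sprintf("ROI %s: baseline F %.1f, AUC %.1f (window %g..%g s, %s trend)\n",
              as.character(x$roi_id), x$baseline_f, x$auc,
              x$window[1], x$window[2], x$baseline_mode))
  invisible(x)
}
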