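#' Rolling-percentile baseline of a fluorescence trace
#'
#' Estimates the slowly varying baseline F0(t) as a centered rolling lower
#' percentile (default: 10th percentile over a 30 s window), which tracks
#' drift while ignoring sparse positive transients. Edges use the partial
#' window. If the window exceeds the trace length the global percentile is
#' used with a warning.
#'
#' @param values fluorescence vector.
#' @param frame_interval s between samples.
#' @param window_s rolling window (s); must be >= 3 frames.
#' @param percentile lower percentile in (0, 100).
#' @return baseline vector, same length as `values`.
#' @export
estimate_baseline <- function(values, frame_interval, window_s = 30,
                              percentile = 10) {
  if (window_s < 3 * frame_interval)
    stop_param("window_s must be at least 3 frames")
  n <- length(values)
  w <- round(window_s / frame_interval)
  if (w > n) {
    warning("baseline window longer than trace; using global percentile",
            call. = FALSE)
    return(rep(stats::quantile(values, percentile / 100, names = FALSE), n))
  }
  if (w %% 2 == 0) w <- w + 1
  as.numeric(zoo::rollapply(
    zoo::zoo(values), width = w,
    FUN = function(x) stats::quantile(x, percentile / 100, names = FALSE),
    align = "center", partial = TRUE))
}

#' Normalize a trace to percent of baseline fluorescence
#'
#' `value(t) = 100 * (F(t) - F0(t)) / F0(t)`, the dF/F0 x 100 convention:
#' a sample 25% above baseline maps to 25.
#'
#' @param values raw fluorescence vector.
#' @param baseline baseline estimate, strictly positive, same length.
#' @return normalized trace (% of basal fluorescence).
#' @export
normalize_dff <- function(values, baseline) {
  if (length(baseline) == 1L) baseline <- rep(baseline, length(values))
  if (length(baseline) != length(values))
    stop_param("baseline and values must have equal length")
  if (any(baseline <= 0)) stop_param("baseline must be strictly positive")
  100 * (values - baseline) / baseline
}

# indices of strict-then-plateau local maxima of x
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(diff(sign(diff(x))) < 0) + 1L
}

# topographic prominence of each peak: height above the higher of the two
# minima separating it from the nearest higher terrain (or the trace edge)
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    l <- p
    while (l > 1 && x[l - 1] <= h) l <- l - 1
    left_min <- min(x[l:p])
    r <- p
    n <- length(x)
    while (r < n && x[r + 1] <= h) r <- r + 1
    right_min <- min(x[p:r])
    h - max(left_min, right_min)
  }, numeric(1))
}

#' Detect calcium spikes in a normalized trace
#'
#' Spikes are local maxima of the percent-of-baseline trace whose amplitude
#' exceeds `threshold_pct` (default 25, i.e. events at least 25% above
#' baseline are counted). Maxima closer together than `min_separation_s`
#' (default two frames) are merged, keeping the larger peak. Frequency is
#' reported per minute over the whole trace. `rate_est` additionally
#' corrects the raw count for pulse pile-up: with ~1.5 s transients sampled
#' at 1 s, events closer than the merge window register as one peak, so the
#' observed rate `r_obs = r * exp(-r * tau)` (paralyzable dead-time model)
#' is inverted for the underlying Poisson rate. The dead time follows from
#' the detector geometry: peaks are quantized to frames, so the merge
#' half-window blocks separations up to `(half + 1/2)` frames.
#'
#' @param norm_values normalized trace (% of baseline).
#' @param frame_interval s between samples.
#' @param threshold_pct detection threshold (% above baseline).
#' @param min_separation_s merge window for nearby maxima (s); default two
#'   frames.
#' @param min_prominence_pct minimum topographic prominence of a counted
#'   peak (% of baseline); rejects noise ripples on sustained activity.
#'   Default half the detection threshold; 0 disables.
#' @param kernel_rise_s,kernel_decay_s transient rise time and decay
#'   constant (s) assumed by the detection-efficiency model (see
#'   [detection_weight()]); defaults match the canonical calcium transient.
#' @param roi_id label carried into the summary.
#' @return an object of class `spike_summary`: `n_spikes`, `frequency`
#'   (min^-1, raw count based), `rate_est` (pile-up-corrected min^-1),
#'   `mean_amplitude` (% of baseline; `NA` when no spikes), `spike_times`
#'   (s), `spike_amplitudes`, `duration_s`, `roi_id`.
#' @export
detect_spikes <- function(norm_values, frame_interval, threshold_pct = 25,
                          min_separation_s = 2 * frame_interval,
                          min_prominence_pct = threshold_pct / 2,
                          kernel_rise_s = 0.2, kernel_decay_s = 1.5,
                          roi_id = NA) {
  n <- length(norm_values)
  if (n == 0) stop_param("empty trace")
  duration <- (n - 1) * frame_interval
  if (duration <= 0) stop_param("trace must span more than one frame")

  peaks <- local_maxima(norm_values)
  peaks <- peaks[norm_values[peaks] > threshold_pct]
  # a counted peak must also stand out from the surrounding trace, so that
  # noise ripples riding on sustained suprathreshold activity (frequent at
  # high event rates) are not counted as events
  if (length(peaks) && min_prominence_pct > 0) {
    peaks <- peaks[peak_prominence(norm_values, peaks) >= min_prominence_pct]
  }

  # merge maxima closer than min_separation_s, keeping the larger
  if (length(peaks) > 1) {
    keep <- logical(length(peaks))
    ord <- order(norm_values[peaks], decreasing = TRUE)
    taken <- rep(FALSE, n)
    half <- max(1L, round(min_separation_s / frame_interval))
    for (j in ord) {
      p <- peaks[j]
      lo <- max(1L, p - half); hi <- min(n, p + half)
      if (!any(taken[lo:hi])) {
        keep[j] <- TRUE
        taken[p] <- TRUE
      }
    }
    peaks <- sort(peaks[keep])
  }

  n_spk <- length(peaks)
  freq <- n_spk / (duration / 60)
  # effective dead time of the detector: peaks are quantized to frames, so
  # the merge half-window blocks separations up to (half + 1/2) frames
  dead <- (max(1L, round(min_separation_s / frame_interval)) + 0.5) *
    frame_interval
  # detection-efficiency weights: an event whose true amplitude sits near
  # the threshold is only caught when a frame lands early on its decay, so
  # each detected near-threshold event stands for 1/pi of them (inverse-
  # probability weighting over the sampling phase)
  amps <- norm_values[peaks]
  w <- detection_weight(amps, threshold_pct, frame_interval,
                        kernel_rise_s, kernel_decay_s)
  n_eff <- sum(w)
  structure(list(
    roi_id = roi_id,
    n_spikes = n_spk,
    frequency = freq,
    frequency_eff = n_eff / (duration / 60),
    rate_est = correct_pileup(n_eff / (duration / 60), dead),
    mean_amplitude = if (n_spk > 0) mean(norm_values[peaks]) else NA_real_,
    spike_times = (peaks - 1) * frame_interval,
    spike_amplitudes = norm_values[peaks],
    duration_s = duration,
    threshold_pct = threshold_pct,
    dead_time_s = dead
  ), class = "spike_summary")
}

#' Inverse detection probability of a spike given its sampled amplitude
#'
#' A transient of true amplitude A rising over `rise_s` and decaying with
#' `decay_s`, sampled every `dt_s`, shows a peak sample of
#' `A * exp(-max(0, u - rise_s)/decay_s)` with sampling phase
#' `u ~ U(0, dt_s)`; it clears an amplitude threshold with probability
#' `pi(A) = min(1, (rise_s + decay_s * log(A / thr)) / dt_s)`. Each
#' detected event therefore stands for `1/pi` events of its amplitude
#' (Horvitz-Thompson weighting). The true amplitude is approximated from
#' the sampled one through the mean attenuation factor; weights are capped
#' at 5 to bound the variance contributed by barely-detectable events.
#'
#' @param amps sampled peak amplitudes (% of baseline) of detected events.
#' @param threshold_pct detection threshold.
#' @param dt_s frame interval (s).
#' @param rise_s,decay_s kernel rise time and decay constant (s).
#' @return per-event weights >= 1.
#' @export
detection_weight <- function(amps, threshold_pct, dt_s,
                             rise_s = 0.2, decay_s = 1.5) {
  if (length(amps) == 0) return(numeric(0))
  # mean sampled-peak attenuation over the sampling phase
  f_bar <- (min(rise_s, dt_s) +
              decay_s * (1 - exp(-max(dt_s - rise_s, 0) / decay_s))) / dt_s
  a_true <- pmax(amps / f_bar, threshold_pct * 1.0001)
  pi_det <- pmin(1, (rise_s + decay_s * log(a_true / threshold_pct)) / dt_s)
  pmin(1 / pmax(pi_det, 1e-6), 5)
}

#' Pile-up (dead-time) correction of an observed spike rate
#'
#' For a Poisson process whose events are unresolvable when closer than
#' `dead_time_s` (paralyzable model), the observed rate is
#' `r_obs = r * exp(-r * tau)`. This inverts that relation on the lower
#' branch (`r < 1/tau`). Rates at or beyond the foldover point are returned
#' as `1/tau` (the maximum resolvable rate).
#'
#' @param freq_per_min observed rate (min^-1).
#' @param dead_time_s dead time (s).
#' @return estimated underlying rate (min^-1).
#' @export
correct_pileup <- function(freq_per_min, dead_time_s) {
  if (dead_time_s <= 0 || freq_per_min == 0) return(freq_per_min)
  tau <- dead_time_s / 60                      # min
  r_obs <- freq_per_min
  r_max <- 1 / tau
  if (r_obs >= r_max * exp(-1)) return(r_max)  # at/above foldover
  f <- function(r) r * exp(-r * tau) - r_obs
  stats::uniroot(f, c(r_obs, r_max), tol = 1e-10)$root
}

#' Analyze every ROI of a trace set
#'
#' Per-ROI chain: rolling-percentile baseline, percent-of-baseline
#' normalization, spike detection. Optionally applies the activity screen
#' used for session selection: keep only ROIs with at least one spike in
#' the first 60 s.
#'
#' @param traces a `fluor_trace_set`.
#' @param threshold_pct,min_separation_s passed to [detect_spikes()].
#' @param window_s,percentile passed to [estimate_baseline()].
#' @param first_minute_filter drop ROIs silent during the first minute.
#' @return list of `spike_summary`, one per (retained) ROI.
#' @export
analyze_traces <- function(traces, threshold_pct = 25,
                           min_separation_s = 2 * traces$frame_interval,
                           window_s = 30, percentile = 10,
                           first_minute_filter = FALSE) {
  stopifnot(inherits(traces, "fluor_trace_set"))
  out <- lapply(seq_len(ncol(traces$values)), function(r) {
    f <- traces$values[, r]
    b <- estimate_baseline(f, traces$frame_interval, window_s, percentile)
    d <- normalize_dff(f, b)
    detect_spikes(d, traces$frame_interval, threshold_pct,
                  min_separation_s, roi_id = colnames(traces$values)[r])
  })
  if (first_minute_filter) {
    out <- Filter(function(s) any(s$spike_times <= 60), out)
  }
  out
}

#' Group summary of spike statistics
#'
#' Mean +/- SEM of spike frequency and mean amplitude across ROIs, the
#' per-condition summary used for strain/treatment comparisons. Amplitude
#' averages skip ROIs with no detected spikes.
#'
#' @param summaries list of `spike_summary`.
#' @param label condition label.
#' @return an object of class `group_spike_stats`: per-metric mean, SEM, n,
#'   plus the vectors of per-ROI frequencies, pile-up-corrected rates and
#'   amplitudes.
#' @export
summarize_group <- function(summaries, label = "group") {
  if (length(summaries) < 2) stop_param("need >= 2 ROIs to summarize")
  freq <- vapply(summaries, function(s) s$frequency, numeric(1))
  freq_eff <- vapply(summaries, function(s) s$frequency_eff %||% s$frequency,
                     numeric(1))
  rate <- vapply(summaries, function(s) s$rate_est, numeric(1))
  amp <- vapply(summaries, function(s) s$mean_amplitude, numeric(1))
  # group rate estimate: pile-up-correct the mean efficiency-weighted
  # frequency (the correction is convex, so correcting per ROI and
  # averaging biases up); SEM by the delta method through the inverse
  # dead-time map
  dead <- summaries[[1]]$dead_time_s %||% 0
  r_hat <- correct_pileup(mean(freq_eff), dead)
  tau <- dead / 60
  deriv <- if (dead > 0 && r_hat * tau < 1)
    exp(r_hat * tau) / (1 - r_hat * tau) else 1
  structure(list(
    label = label,
    n = length(summaries),
    frequency_mean = mean(freq), frequency_sem = sem(freq),
    rate_est_mean = r_hat, rate_est_sem = sem(freq_eff) * deriv,
    amplitude_mean = mean(amp, na.rm = TRUE), amplitude_sem = sem(amp),
    frequencies = freq, rate_ests = rate, amplitudes = amp
  ), class = "group_spike_stats")
}

#' @export
print.spike_summary <- function(x, ...) {
  cat(sprintf("ROI %s: %d spikes, %.3f min^-1 (pile-up corrected %.3f), mean amplitude %s%%\n",
              as.character(x$roi_id), x$n_spikes, x$frequency, x$rate_est,
              if (is.na(x$mean_amplitude)) "NA" else sprintf("%.1f", x$mean_amplitude)))
  invisible(x)
}

#' @export
print.group_spike_stats <- function(x, ...) {
  cat(sprintf("%s (n = %d ROIs): frequency %.3f +/- %.3f min^-1; amplitude %.1f +/- %.1f %%\n",
              x$label, x$n, x$frequency_mean, x$frequency_sem,
              x$amplitude_mean, x$amplitude_sem))
  invisible(x)
}
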