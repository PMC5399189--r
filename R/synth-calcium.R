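#' Simulation parameters for spontaneous calcium-spike traces
#'
#' Somatic Fluo-4 traces are modelled as a drifting baseline plus transients
#' fired by a homogeneous Poisson process. Each transient rises linearly over
#' `rise_time` and decays exponentially with `decay_tau`; its amplitude is
#' drawn from a normal distribution, truncated below at `amp_min`, expressed
#' as a percent of the local baseline (the field's dF/F0 x 100 convention).
#' The truncation default equals the standard 25% detection threshold
#' because scenario presets encode *detected-event* statistics: reported
#' spike rates and amplitudes are post-threshold quantities, so the emulated
#' event population must be detectable by the same rule.
#' Default rate/amplitude correspond to the non-transgenic scenario
#' (~2 spikes/min, ~131% of basal fluorescence).
#'
#' @param rate_per_min mean spike rate (min^-1), >= 0.
#' @param amp_mean,amp_sd transient amplitude mean and SD (% of baseline).
#' @param amp_min lower truncation of the amplitude distribution (%).
#' @param decay_tau exponential decay time constant (s).
#' @param rise_time linear rise time (s).
#' @param f0 baseline fluorescence (arbitrary units), > 0.
#' @param drift_slope baseline drift (fluorescence units per s).
#' @param noise_sd additive Gaussian noise (fluorescence units).
#' @param duration trace duration (s).
#' @param frame_interval acquisition interval (s); 1.0 for standard imaging,
#'   0.5 for the fast (toxin-challenge) protocol.
#' @param n_rois number of regions of interest.
#' @param seed integer seed.
#' @return an object of class `calcium_sim_params`.
#' @export
calcium_sim_params <- function(rate_per_min = 1.958,
                               amp_mean = 131.4,
                               amp_sd = 30,
                               amp_min = 25,
                               decay_tau = 1.5,
                               rise_time = 0.2,
                               f0 = 1000,
                               drift_slope = 0.1,
                               noise_sd = 15,
                               duration = 300,
                               frame_interval = 1.0,
                               n_rois = 50,
                               seed = 1L) {
  if (rate_per_min < 0) stop_param("rate_per_min must be >= 0")
  if (duration <= 0) stop_param("duration must be > 0")
  if (frame_interval <= 0) stop_param("frame_interval must be > 0")
  if (duration < 2 * frame_interval) stop_param("duration must cover at least 2 frames")
  if (f0 <= 0) stop_param("f0 must be > 0")
  if (n_rois < 1) stop_param("n_rois must be >= 1")
  if (amp_min < 0 || amp_min >= amp_mean + 5 * max(amp_sd, 1))
    stop_param("amp_min must be non-negative and below the amplitude range")
  structure(list(
    rate_per_min = rate_per_min, amp_mean = amp_mean, amp_sd = amp_sd,
    amp_min = amp_min,
    decay_tau = decay_tau, rise_time = rise_time, f0 = f0,
    drift_slope = drift_slope, noise_sd = noise_sd, duration = duration,
    frame_interval = frame_interval, n_rois = as.integer(n_rois),
    seed = as.integer(seed)
  ), class = "calcium_sim_params")
}

# transient kernel: linear rise over rise_time, then exponential decay;
# evaluated at times dt (s) since spike onset
ca_kernel <- function(dt, rise_time, decay_tau) {
  out <- numeric(length(dt))
  up <- dt >= 0 & dt < rise_time
  dn <- dt >= rise_time
  if (rise_time > 0) out[up] <- dt[up] / rise_time
  out[dn] <- exp(-(dt[dn] - rise_time) / decay_tau)
  out
}

#' Generate synthetic per-ROI calcium fluorescence traces
#'
#' Spike times are drawn per ROI from a homogeneous Poisson process at
#' `rate_per_min`; each spike adds `amp/100 * baseline(t_spike)` times the
#' rise/decay kernel to the raw fluorescence. Ground-truth spike times and
#' amplitudes are returned per ROI so downstream detection can be scored.
#'
#' @param params a [calcium_sim_params()].
#' @return object of class `fluor_trace_set`: `time` (s), `values`
#'   (frames x ROIs matrix, columns `roi_0001`...), `frame_interval`, and
#'   `ground_truth` (per-ROI list with `spike_times`, `spike_amplitudes`,
#'   plus the generating params).
#' @examples
#' ts <- generate_calcium(calcium_sim_params(n_rois = 2, duration = 60))
#' dim(ts$values)
#' @export
generate_calcium <- function(params) {
  stopifnot(inherits(params, "calcium_sim_params"))
  tm <- seq(0, params$duration, by = params$frame_interval)
  n <- length(tm)
  vals <- matrix(0, nrow = n, ncol = params$n_rois)
  gt <- vector("list", params$n_rois)
  base <- params$f0 + params$drift_slope * tm

  for (r in seq_len(params$n_rois)) {
    set.seed(substream_seed(params$seed, paste0("roi", r)))
    n_spk <- stats::rpois(1, params$rate_per_min / 60 * params$duration)
    spk_t <- sort(stats::runif(n_spk, 0, params$duration))
    # truncated normal via inverse CDF: detectable-event amplitudes
    lo <- stats::pnorm(params$amp_min, params$amp_mean, params$amp_sd)
    spk_a <- stats::qnorm(lo + stats::runif(n_spk) * (1 - lo),
                          params$amp_mean, params$amp_sd)
    f <- base
    for (k in seq_len(n_spk)) {
      b_at <- params$f0 + params$drift_slope * spk_t[k]
      f <- f + spk_a[k] / 100 * b_at *
        ca_kernel(tm - spk_t[k], params$rise_time, params$decay_tau)
    }
    if (params$noise_sd > 0) f <- f + stats::rnorm(n, 0, params$noise_sd)
    vals[, r] <- f
    gt[[r]] <- list(spike_times = spk_t, spike_amplitudes = spk_a)
  }
  colnames(vals) <- sprintf("roi_%04d", seq_len(params$n_rois))

  structure(list(
    time = tm,
    values = vals,
    frame_interval = params$frame_interval,
    ground_truth = list(params = unclass(params), rois = gt)
  ), class = "fluor_trace_set")
}

#' @export
print.fluor_trace_set <- function(x, ...) {
  cat(sprintf("Fluorescence trace set: %d ROIs, %d frames at %g s (%.0f s total)\n",
              ncol(x$values), nrow(x$values), x$frame_interval,
              max(x$time)))
  invisible(x)
}
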