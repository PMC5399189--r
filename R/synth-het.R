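#' Simulation parameters for cumulative HEt (ROS) fluorescence
#'
#' Hydroethidine oxidation is irreversible, so the expected signal is a
#' monotone cumulative trace: it grows at `basal_rate` before the stimulus,
#' at `stim_rate` during the stimulus window, and returns to `basal_rate`
#' afterwards (the accumulated offset persists). Defaults emulate a 5-minute
#' NMDA challenge after a 3-minute resting baseline in a 780 s session; the
#' baseline must be long enough for the pre-stimulus trend fit, since trend
#' extrapolation error grows quadratically over the stimulus window.
#'
#' @param basal_rate fluorescence increase per s before/after stimulus, >= 0.
#' @param stim_rate fluorescence increase per s during the stimulus, >= 0.
#' @param stim_start,stim_duration stimulus onset and length (s).
#' @param f0 initial fluorescence (arbitrary units).
#' @param noise_sd additive Gaussian noise (fluorescence units).
#' @param duration trace duration (s).
#' @param frame_interval acquisition interval (s).
#' @param n_rois number of regions of interest.
#' @param rate_cv between-ROI lognormal coefficient of variation applied to
#'   both rates (cell-to-cell variability in ROS production).
#' @param seed integer seed.
#' @return an object of class `het_sim_params`.
#' @export
het_sim_params <- function(basal_rate = 0.2,
                           stim_rate = 0.25,
                           stim_start = 180,
                           stim_duration = 300,
                           f0 = 2389,
                           noise_sd = 20,
                           duration = 780,
                           frame_interval = 1,
                           n_rois = 1,
                           rate_cv = 0,
                           seed = 1L) {
  if (basal_rate < 0 || stim_rate < 0) stop_param("rates must be >= 0 (HEt oxidation is cumulative)")
  if (stim_start + stim_duration > duration)
    stop_param("stimulus window must end within the trace")
  if (frame_interval <= 0 || duration <= 0) stop_param("duration and frame_interval must be > 0")
  if (rate_cv < 0) stop_param("rate_cv must be >= 0")
  structure(list(
    basal_rate = basal_rate, stim_rate = stim_rate, stim_start = stim_start,
    stim_duration = stim_duration, f0 = f0, noise_sd = noise_sd,
    duration = duration, frame_interval = frame_interval,
    n_rois = as.integer(n_rois), rate_cv = rate_cv, seed = as.integer(seed)
  ), class = "het_sim_params")
}

#' Generate synthetic cumulative HEt fluorescence traces
#'
#' The expectation of each trace is piecewise linear: slope `basal_rate`
#' outside the stimulus window and `stim_rate` inside it. With `rate_cv > 0`
#' each ROI's two rates are scaled by a shared lognormal factor (mean 1),
#' emulating cell-to-cell variability in ROS production. True slopes are
#' stored per ROI in the ground truth.
#'
#' @param params a [het_sim_params()].
#' @return a `fluor_trace_set` whose `ground_truth` holds the generating
#'   params and per-ROI realized `basal_rate`/`stim_rate`.
#' @examples
#' tr <- generate_het(het_sim_params(noise_sd = 0))
#' tail(tr$values[, 1], 1)  # f0 + basal*480 + stim*300
#' @export
generate_het <- function(params) {
  stopifnot(inherits(params, "het_sim_params"))
  tm <- seq(0, params$duration, by = params$frame_interval)
  n <- length(tm)
  vals <- matrix(0, n, params$n_rois)
  gt <- vector("list", params$n_rois)
  t0 <- params$stim_start
  t1 <- params$stim_start + params$stim_duration

  for (r in seq_len(params$n_rois)) {
    set.seed(substream_seed(params$seed, paste0("het", r)))
    fac <- if (params$rate_cv > 0) {
      sdl <- sqrt(log(1 + params$rate_cv^2))
      stats::rlnorm(1, meanlog = -sdl^2 / 2, sdlog = sdl)
    } else 1
    br <- params$basal_rate * fac
    sr <- params$stim_rate * fac
    # cumulative expectation: integral of the piecewise-constant rate
    mu <- params$f0 + br * pmin(tm, t0) +
      sr * pmax(0, pmin(tm, t1) - t0) +
      br * pmax(0, tm - t1)
    f <- mu
    if (params$noise_sd > 0) f <- f + stats::rnorm(n, 0, params$noise_sd)
    vals[, r] <- f
    gt[[r]] <- list(basal_rate = br, stim_rate = sr)
  }
  colnames(vals) <- sprintf("roi_%04d", seq_len(params$n_rois))

  structure(list(
    time = tm,
    values = vals,
    frame_interval = params$frame_interval,
    ground_truth = list(params = unclass(params), rois = gt)
  ), class = "fluor_trace_set")
}
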