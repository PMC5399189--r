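#' Simulation parameters for whole-cell delayed-rectifier recordings
#'
#' The synthetic cell is a single-compartment voltage-clamped membrane with
#' three current components: a Boltzmann-gated delayed-rectifier conductance
#' with first-order (single-exponential) activation, an ohmic leak, and a
#' capacitive transient at every voltage transition whose integral equals
#' `c_m * dV`. Defaults are calibrated so that the non-transgenic scenario
#' yields a steady-state current of about 3.1 nA at +60 mV at ~60 pF,
#' i.e. ~51 pA/pF, typical of cultured hippocampal neurons.
#'
#' @param g_max maximal Kv conductance (nS).
#' @param v_half half-activation voltage (mV).
#' @param slope_k activation slope factor (mV), > 0.
#' @param e_k K+ reversal potential (mV); -79.4 mV for the standard
#'   5 mM external / 117 mM internal solutions (see [nernst_potential()]).
#' @param tau_act activation time constant (ms), voltage independent.
#' @param g_leak linear leak conductance (nS).
#' @param e_leak leak reversal potential (mV).
#' @param c_m membrane capacitance (pF), > 0.
#' @param cap_tau capacitive transient decay constant (ms).
#' @param noise_sd additive Gaussian current noise (pA).
#' @param sample_interval sampling interval (s/point); 25e-6 matches a
#'   25 us/point acquisition.
#' @param seed integer seed; the recording is a pure function of
#'   (params, protocol).
#' @return an object of class `vclamp_sim_params` (validated list).
#' @export
vclamp_sim_params <- function(g_max = 22.46,
                              v_half = 8,
                              slope_k = 12,
                              e_k = -79.4,
                              tau_act = 20,
                              g_leak = 1.5,
                              e_leak = -65,
                              c_m = 60,
                              cap_tau = 1,
                              noise_sd = 20,
                              sample_interval = 25e-6,
                              seed = 1L) {
  if (g_max < 0) stop_param("g_max must be >= 0")
  if (slope_k <= 0) stop_param("slope_k must be > 0")
  if (c_m <= 0) stop_param("c_m must be > 0")
  if (sample_interval <= 0) stop_param("sample_interval must be > 0")
  if (tau_act <= 0 || cap_tau <= 0) stop_param("time constants must be > 0")
  if (noise_sd < 0) stop_param("noise_sd must be >= 0")
  structure(list(
    g_max = g_max, v_half = v_half, slope_k = slope_k, e_k = e_k,
    tau_act = tau_act, g_leak = g_leak, e_leak = e_leak, c_m = c_m,
    cap_tau = cap_tau, noise_sd = noise_sd,
    sample_interval = sample_interval, seed = as.integer(seed)
  ), class = "vclamp_sim_params")
}

# Boltzmann activation gate
boltzmann_gate <- function(V, v_half, slope_k) {
  1 / (1 + exp(-(V - v_half) / slope_k))
}

# model currents (pA) for one constant-voltage segment of duration covered by
# time vector tt (s, from segment onset, uniform spacing dt); gate starts at
# m0 and relaxes to its steady state at V; capacitive transient for the
# entering step dV. Each capacitive sample is the average of the continuous
# transient over its sampling bin, so the discrete sum times dt equals the
# transient charge c_m*dV/1000 (pA*s) at any sampling rate.
segment_current <- function(tt, dt, V, dV, m0, p) {
  tau <- p$tau_act / 1000
  m_inf <- boltzmann_gate(V, p$v_half, p$slope_k)
  m <- m_inf + (m0 - m_inf) * exp(-tt / tau)
  i_kv <- p$g_max * m * (V - p$e_k)              # nS * mV = pA
  i_leak <- p$g_leak * (V - p$e_leak)
  tc <- p$cap_tau / 1000
  i_cap <- (p$c_m * dV / 1000) * (exp(-tt / tc) - exp(-(tt + dt) / tc)) / dt
  list(i = i_kv + i_leak + i_cap, m_end = m[length(m)])
}

# noiseless model sweep for a test potential; returns current vector over
# baseline + test + tail segments and the sample index ranges of each segment
model_sweep <- function(V, p, protocol, baseline_duration_s) {
  dt <- p$sample_interval
  n_base <- round(baseline_duration_s / dt)
  n_test <- round(protocol$pulse_duration_s / dt)
  n_tail <- round(protocol$tail_duration_s / dt)
  hold <- protocol$holding_mV

  # holding: gate assumed fully deactivated (closed) before the pulse
  i_base <- rep(p$g_leak * (hold - p$e_leak) +
                  p$g_max * 0 * (hold - p$e_k), n_base)
  tt_test <- (seq_len(n_test) - 1) * dt
  seg_test <- segment_current(tt_test, dt, V, V - hold, m0 = 0, p)
  tt_tail <- (seq_len(n_tail) - 1) * dt
  seg_tail <- segment_current(tt_tail, dt, protocol$tail_mV,
                              protocol$tail_mV - V, m0 = seg_test$m_end, p)
  list(
    i = c(i_base, seg_test$i, seg_tail$i),
    idx_test = n_base + seq_len(n_test),
    idx_tail = n_base + n_test + seq_len(n_tail)
  )
}

#' Generate a synthetic whole-cell delayed-rectifier recording
#'
#' Produces one current sweep per test potential of `protocol`, each the sum
#' of a capacitive transient (area `c_m * dV`), ohmic leak and the
#' Boltzmann-gated Kv current
#' `g_max * B(V) * (1 - exp(-t/tau_act)) * (V - e_k)`, plus additive
#' Gaussian noise. Hyperpolarizing P/-N leak sub-sweeps (amplitude `-dV/N`
#' from holding, averaged over `pn` repetitions) are generated alongside so
#' that [pn_leak_subtract()] can cancel the linear components; the
#' hyperpolarizing direction keeps the gate shut in the sub-sweeps.
#' The generating parameters are embedded as ground truth in the metadata.
#'
#' @param params a [vclamp_sim_params()].
#' @param protocol a [voltage_protocol()].
#' @param pn number of leak sub-sweeps averaged per test potential
#'   (0 disables sub-sweep generation).
#' @param baseline_duration_s pre-pulse segment at holding potential (s).
#' @return an object of class `vclamp_recording`: fields `time` (s),
#'   `sweeps` (named list, pA, one per test mV), `pn_sweeps` (averaged
#'   sub-sweeps), `sample_interval`, `c_m`, `protocol`,
#'   `baseline_duration_s`, `metadata$ground_truth`.
#' @examples
#' rec <- generate_vclamp(vclamp_sim_params(noise_sd = 0, sample_interval = 1e-3))
#' range(rec$sweeps[["60"]])
#' @export
generate_vclamp <- function(params,
                            protocol = voltage_protocol(),
                            pn = 4,
                            baseline_duration_s = 0.1) {
  stopifnot(inherits(params, "vclamp_sim_params"),
            inherits(protocol, "voltage_protocol"))
  volts <- protocol_voltages(protocol)
  if (any(abs(volts) > 200)) stop_param("protocol voltages must lie within +/-200 mV")
  dt <- params$sample_interval
  hold <- protocol$holding_mV

  sweeps <- vector("list", length(volts))
  pn_sweeps <- if (pn > 0) vector("list", length(volts)) else NULL
  names(sweeps) <- as.character(volts)
  if (!is.null(pn_sweeps)) names(pn_sweeps) <- as.character(volts)
  idx_test <- NULL

  for (j in seq_along(volts)) {
    V <- volts[j]
    ms <- model_sweep(V, params, protocol, baseline_duration_s)
    idx_test <- ms$idx_test
    set.seed(substream_seed(params$seed, paste0("sweep", V)))
    noise <- if (params$noise_sd > 0)
      stats::rnorm(length(ms$i), 0, params$noise_sd) else 0
    sweeps[[j]] <- ms$i + noise

    if (pn > 0) {
      # sub-pulse always hyperpolarizing: the waveform is scaled by
      # -sign(dV)/N about holding, so the gate stays shut whatever the test
      # polarity and the linear response is exactly -sign(dV)/N of the test
      # sweep's leak + capacitance ([pn_leak_subtract()] applies the
      # matching sign(dV)*N scale)
      s_dir <- if (V >= hold) 1 else -1
      V_sub <- hold - abs(V - hold) / pn
      sub_protocol <- protocol
      sub_protocol$tail_mV <- hold - s_dir * (protocol$tail_mV - hold) / pn
      ms_sub <- model_sweep(V_sub, params, sub_protocol, baseline_duration_s)
      set.seed(substream_seed(params$seed, paste0("pn", V)))
      noise_sub <- if (params$noise_sd > 0)
        stats::rnorm(length(ms_sub$i), 0, params$noise_sd / sqrt(pn)) else 0
      pn_sweeps[[j]] <- ms_sub$i + noise_sub
    }
  }

  structure(list(
    time = (seq_along(sweeps[[1]]) - 1) * dt,
    sweeps = sweeps,
    pn_sweeps = pn_sweeps,
    pn_n = if (pn > 0) as.integer(pn) else NULL,
    sample_interval = dt,
    c_m = params$c_m,
    protocol = protocol,
    baseline_duration_s = baseline_duration_s,
    idx_test = idx_test,
    metadata = list(ground_truth = unclass(params), leak_subtracted = FALSE)
  ), class = "vclamp_recording")
}

#' Noiseless steady-state Kv current of the simulated cell
#'
#' Closed-form mean of the generator's Kv component over the last-500-ms
#' analysis window, used as the analytic oracle for the I-V stage:
#' `g_max * B(V) * (1 - mean(exp(-t/tau))) * (V - e_k)`.
#'
#' @param params a [vclamp_sim_params()].
#' @param V test potentials (mV).
#' @param window_s averaging window (start, end) within the pulse (s).
#' @return expected window-averaged Kv current (pA) at each `V`.
#' @export
expected_kv_ss <- function(params, V, window_s = c(0.5, 1.0)) {
  tau <- params$tau_act / 1000
  # mean of (1 - exp(-t/tau)) over the window, analytic
  mean_act <- 1 - tau * (exp(-window_s[1] / tau) - exp(-window_s[2] / tau)) /
    (window_s[2] - window_s[1])
  params$g_max * boltzmann_gate(V, params$v_half, params$slope_k) *
    mean_act * (V - params$e_k)
}

#' @export
print.vclamp_recording <- function(x, ...) {
  cat(sprintf(
    "Whole-cell recording: %d sweeps (%s mV), %d points each at %.3g s/pt, c_m %.3g pF%s\n",
    length(x$sweeps),
    paste(range(as.numeric(names(x$sweeps))), collapse = ".."),
    length(x$time), x$sample_interval, x$c_m,
    if (isTRUE(x$metadata$leak_subtracted)) " (leak-subtracted)" else ""))
  invisible(x)
}
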