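#' P/N subtraction of leak and capacitive currents
#'
#' Cancels the linear components of each sweep using the averaged leak
#' sub-sweeps stored in the recording: the sub-sweep response (elicited by a
#' step of `-dV/n_sub` from holding) is scaled by `-n_sub` and subtracted,
#' which removes ohmic leak and capacitive transients exactly in the
#' noiseless linear limit. When no sub-sweeps are present, an optional
#' fallback fits a line to the steady-state currents at sub-threshold
#' potentials (<= -70 mV), where the delayed rectifier is shut, and
#' subtracts the fitted `g * (V - e)` leak current segment by segment
#' (capacitive transients then remain).
#'
#' @param rec a `vclamp_recording`.
#' @param n_sub number of sub-sweeps the stored average represents; defaults
#'   to the count recorded at generation time.
#' @param fallback if `TRUE`, use the linear-leak fit when `pn_sweeps` are
#'   absent; if `FALSE` (default), their absence is an error.
#' @return the recording with leak-subtracted sweeps (`pn_sweeps` dropped,
#'   `metadata$leak_subtracted` set).
#' @export
pn_leak_subtract <- function(rec, n_sub = rec$pn_n, fallback = FALSE) {
  stopifnot(inherits(rec, "vclamp_recording"))
  if (!is.null(rec$pn_sweeps)) {
    n_sub <- n_sub %||% 4L
    volts <- names(rec$sweeps)
    n_base <- max(1L, round(rec$baseline_duration_s / rec$sample_interval))
    hold <- rec$protocol$holding_mV
    for (v in volts) {
      sub <- rec$pn_sweeps[[v]]
      if (is.null(sub)) stop_param("no sub-sweep stored for ", v, " mV")
      if (length(sub) != length(rec$sweeps[[v]]))
        stop_param("sub-sweep length mismatch at ", v, " mV")
      # sub-pulses are always hyperpolarizing (amplitude -|dV|/N), so the
      # scale carries the test-step sign; the shared holding-level current
      # cancels via the (1 + scale) baseline term
      scale <- if (as.numeric(v) >= hold) n_sub else -n_sub
      rec$sweeps[[v]] <- rec$sweeps[[v]] + scale * sub -
        (1 + scale) * mean(sub[seq_len(n_base)])
    }
    rec$pn_sweeps <- NULL
  } else if (fallback) {
    iv <- steady_state_iv(rec, check_subtracted = FALSE)
    sub_idx <- iv$voltage_mV <= -70
    if (sum(sub_idx) < 2)
      stop_param("fallback needs >= 2 sub-threshold (<= -70 mV) sweeps")
    fit <- stats::lm(i_ss_nA * 1000 ~ voltage_mV, data = iv[sub_idx, ])
    g_fit <- stats::coef(fit)[2]          # nS
    b_fit <- stats::coef(fit)[1]          # pA at 0 mV
    prot <- rec$protocol
    n <- length(rec$time)
    idx_test <- rec$idx_test
    for (v in names(rec$sweeps)) {
      V <- as.numeric(v)
      leak <- numeric(n)
      leak[] <- g_fit * prot$holding_mV + b_fit
      leak[idx_test] <- g_fit * V + b_fit
      if (max(idx_test) < n)
        leak[(max(idx_test) + 1):n] <- g_fit * prot$tail_mV + b_fit
      rec$sweeps[[v]] <- rec$sweeps[[v]] - leak
    }
  } else {
    stop_param("recording has no P/N sub-sweeps and fallback is disabled")
  }
  rec$metadata$leak_subtracted <- TRUE
  rec
}

#' Steady-state I-V relation
#'
#' Evaluates each sweep at steady state by averaging the current over the
#' last 500 ms of the test pulse (window end inclusive), then reports the
#' steady-state current in nA per test potential. The +60 mV point, the
#' conventional peak-current summary, is exposed as an attribute; if the
#' +60 mV sweep is absent it is `NA` rather than an error.
#'
#' @param rec a `vclamp_recording` (normally leak-subtracted).
#' @param window_s width of the steady-state window (s).
#' @param check_subtracted warn when the recording has not been
#'   leak-subtracted.
#' @return an `iv_result` data frame with columns `voltage_mV`, `i_ss_nA`
#'   and attributes `peak_60` (nA), `c_m` (pF).
#' @export
steady_state_iv <- function(rec, window_s = 0.5, check_subtracted = TRUE) {
  stopifnot(inherits(rec, "vclamp_recording"))
  if (rec$protocol$pulse_duration_s < window_s)
    stop_param("test pulse shorter than the steady-state window")
  if (check_subtracted && !isTRUE(rec$metadata$leak_subtracted))
    warning("recording does not appear to be leak-subtracted", call. = FALSE)
  idx_test <- rec$idx_test
  n_win <- round(window_s / rec$sample_interval)
  win <- idx_test[(length(idx_test) - n_win + 1):length(idx_test)]
  volts <- as.numeric(names(rec$sweeps))
  i_ss <- vapply(rec$sweeps, function(s) mean(s[win]), numeric(1)) / 1000  # pA -> nA
  iv <- data.frame(voltage_mV = volts, i_ss_nA = unname(i_ss))
  class(iv) <- c("iv_result", "data.frame")
  attr(iv, "peak_60") <- if (any(volts == 60)) unname(i_ss[volts == 60]) else NA_real_
  attr(iv, "c_m") <- rec$c_m
  iv
}

#' Current density (pA/pF)
#'
#' Normalizes the steady-state current by membrane capacitance, the standard
#' cell-size-independent expression of macroscopic current.
#'
#' @param iv an `iv_result` with `i_ss_nA`.
#' @param c_m membrane capacitance (pF); defaults to the recording's value
#'   carried on the `iv_result`.
#' @return the `iv_result` with a `density_pA_pF` column added.
#' @examples
#' iv <- structure(data.frame(voltage_mV = 60, i_ss_nA = 2.4),
#'                 class = c("iv_result", "data.frame"))
#' current_density(iv, c_m = 100)$density_pA_pF  # 24
#' @export
current_density <- function(iv, c_m = attr(iv, "c_m")) {
  stopifnot(inherits(iv, "iv_result"))
  if (is.null(c_m) || is.na(c_m) || c_m <= 0) stop_param("c_m must be > 0")
  iv$density_pA_pF <- iv$i_ss_nA * 1000 / c_m
  attr(iv, "c_m") <- c_m
  iv
}

#' Estimate membrane capacitance from a capacitive transient
#'
#' Integrates the baseline- and plateau-corrected current transient that
#' follows a small sub-threshold voltage step: `C_m = Q / dV`, with `Q` the
#' transient charge. Requires a recording that still carries its capacitive
#' transients (i.e. not P/N subtracted). The most negative test potential is
#' used by default, where the delayed rectifier contributes nothing.
#'
#' @param rec a `vclamp_recording` with unsubtracted transients.
#' @param sweep_mV which sweep to use; default the most negative one.
#' @param window_s integration window after the step onset (s).
#' @return estimated capacitance (pF).
#' @export
estimate_capacitance <- function(rec, sweep_mV = NULL, window_s = 0.02) {
  stopifnot(inherits(rec, "vclamp_recording"))
  if (isTRUE(rec$metadata$leak_subtracted))
    stop_param("recording is leak-subtracted; transients no longer present")
  volts <- as.numeric(names(rec$sweeps))
  V <- sweep_mV %||% min(volts)
  if (!any(volts == V)) stop_param("no sweep at ", V, " mV")
  dV <- V - rec$protocol$holding_mV
  if (dV == 0) stop_param("step amplitude is zero; cannot estimate capacitance")
  s <- rec$sweeps[[as.character(V)]]
  dt <- rec$sample_interval
  idx_test <- rec$idx_test
  n_win <- round(window_s / dt)
  if (n_win < 4 || n_win > length(idx_test) / 2)
    stop_param("integration window does not fit the test pulse")
  trans <- idx_test[seq_len(n_win)]
  plateau <- mean(s[idx_test[(n_win + 1):min(3 * n_win, length(idx_test))]])
  q <- sum(s[trans] - plateau) * dt          # pA*s; leak step removed via plateau
  c_m <- 1000 * q / dV                       # pA*s/mV -> pF (Q[fC]=c_m*dV)
  unname(c_m)
}

#' Nernst equilibrium potential
#'
#' `E = S(T) * log10(out/in)` for a monovalent cation, with the slope
#' `S(T) = ln(10) R T / F` in mV. A fixed-slope mode (58 mV/decade, the
#' round-number convention near 20 C) is selected by supplying `slope_mV`.
#' The standard potassium solutions (5 mM external, 117 mM internal) give
#' E_K = -79.4 mV in fixed-slope mode.
#'
#' @param conc_out,conc_in external and internal concentrations (mM), > 0.
#' @param temperature_C temperature (C) for the thermodynamic slope.
#' @param slope_mV optional fixed slope (mV/decade); overrides temperature.
#' @return equilibrium potential (mV).
#' @examples
#' nernst_potential(5, 117, slope_mV = 58)   # -79.4
#' nernst_potential(10, 100, slope_mV = 58)  # -58
#' @export
nernst_potential <- function(conc_out, conc_in, temperature_C = 20,
                             slope_mV = NULL) {
  if (conc_out <= 0 || conc_in <= 0) stop_param("concentrations must be > 0")
  s <- if (!is.null(slope_mV)) slope_mV else {
    R <- 8.31446; Fd <- 96485.33
    log(10) * R * (temperature_C + 273.15) / Fd * 1000
  }
  s * log10(conc_out / conc_in)
}

#' Chord conductance and normalized activation curve
#'
#' `g_chord(V) = I_ss(V) / (V - E_K)` in nS; the normalized conductance
#' divides by the maximum chord conductance over depolarized potentials
#' (V >= 0 mV), so the activation curve tops out at 1 by construction.
#' Points where `V == E_K` are excluded with a warning (0/0).
#'
#' @param iv an `iv_result` with `i_ss_nA`.
#' @param e_k K+ reversal potential (mV); see [nernst_potential()].
#' @return the `iv_result` with `g_chord_nS` and `g_norm` columns.
#' @export
chord_conductance <- function(iv, e_k = -79.4) {
  stopifnot(inherits(iv, "iv_result"))
  at_ek <- iv$voltage_mV == e_k
  if (any(at_ek)) {
    warning("excluding point(s) at V == e_k", call. = FALSE)
    iv <- iv[!at_ek, , drop = FALSE]
    class(iv) <- c("iv_result", "data.frame")
  }
  iv$g_chord_nS <- iv$i_ss_nA * 1000 / (iv$voltage_mV - e_k)
  dep <- iv$voltage_mV >= 0
  if (!any(dep)) stop_param("need depolarized (V >= 0) points for normalization")
  iv$g_norm <- iv$g_chord_nS / max(iv$g_chord_nS[dep])
  attr(iv, "e_k") <- e_k
  iv
}

#' @export
print.iv_result <- function(x, ...) {
  cat("Steady-state I-V result\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  if (!is.na(attr(x, "peak_60") %||% NA))
    cat(sprintf("peak current at +60 mV: %.3f nA\n", attr(x, "peak_60")))
  invisible(x)
}
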