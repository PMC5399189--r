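#' Generator presets for the study conditions
#'
#' Named parameter presets emulating the experimental conditions of the
#' underlying study: non-transgenic (`non_tg`) and triple-transgenic AD
#' (`tg3x`) hippocampal cultures, antioxidant treatment (`tg3x_nac`),
#' Kv2.1 block by guangxitoxin (`non_tg_gxtx`, `tg3x_gxtx`, each with a
#' `*_pre` companion for the pre-drug condition), and activity blockade
#' (`blockade`, TTX / CNQX + MK-801 emulation). Calibration constants:
#' spike rates and amplitudes, +60 mV peak currents / densities, HEt AUC
#' and baseline levels, and cluster fractions are set to the corresponding
#' reported group means; `g_max` is back-computed from the +60 mV steady
#' state (`g_max = I60 / (B(60) * (60 - E_K))`) and `c_m` from the current
#' density.
#'
#' @param name preset name; see Details.
#' @param seed integer seed stored in every parameter object.
#' @return list with elements `calcium` (`calcium_sim_params`), `vclamp`
#'   (`vclamp_sim_params`), `het` (`het_sim_params`), `puncta`
#'   (`puncta_sim_params`), plus `label`.
#' @export
kv_scenario <- function(name = c("non_tg", "tg3x", "tg3x_nac",
                                 "non_tg_gxtx", "non_tg_gxtx_pre",
                                 "tg3x_gxtx", "tg3x_gxtx_pre", "blockade"),
                        seed = 1L) {
  name <- match.arg(name)
  # calcium: rate (min^-1), amplitude (% of basal); 0.5 s framing under GxTx
  ca <- switch(name,
    non_tg        = list(rate = 1.958, amp = 131.4, dt = 1.0),
    tg3x          = list(rate = 6.312, amp = 85.71, dt = 1.0),
    tg3x_nac      = list(rate = 4.682, amp = 69.04, dt = 1.0),
    non_tg_gxtx   = list(rate = 4.361, amp = 58.03, dt = 0.5),
    non_tg_gxtx_pre = list(rate = 2.506, amp = 118.6, dt = 0.5),
    tg3x_gxtx     = list(rate = 12.70, amp = 119.5, dt = 0.5),
    tg3x_gxtx_pre = list(rate = 12.03, amp = 105.0, dt = 0.5),
    blockade      = list(rate = 0, amp = 100, dt = 1.0))
  # vclamp: peak steady-state current at +60 mV (nA) and capacitance (pF)
  vc <- switch(name,
    non_tg        = list(i60 = 3.090, cm = 60.4),
    tg3x          = list(i60 = 2.266, cm = 63.4),
    tg3x_nac      = list(i60 = 2.970, cm = 60.4),
    non_tg_gxtx   = list(i60 = 1.940, cm = 60.4),
    non_tg_gxtx_pre = list(i60 = 3.090, cm = 60.4),
    tg3x_gxtx     = list(i60 = 2.266, cm = 63.4),
    tg3x_gxtx_pre = list(i60 = 2.266, cm = 63.4),
    blockade      = list(i60 = 3.090, cm = 60.4))
  # HEt: stimulus-evoked AUC (fluorescence x s) and resting baseline level
  het <- switch(name,
    tg3x          = list(auc = 3366, f0 = 3080),
    list(auc = 2146, f0 = 2389))
  # puncta: cluster/soma area fraction (%)
  pf <- switch(name, tg3x = 28.58, 18.82)

  # g_max from the +60 mV steady state of the generator model
  b60 <- boltzmann_gate(60, 8, 12)
  g_max <- vc$i60 * 1000 / (b60 * (60 - (-79.4)))
  stim_extra <- 2 * het$auc / 300^2           # AUC = s * T^2 / 2, T = 300 s

  list(
    label = name,
    calcium = calcium_sim_params(
      rate_per_min = ca$rate, amp_mean = ca$amp, amp_sd = 40,
      frame_interval = ca$dt, seed = seed),
    vclamp = vclamp_sim_params(
      g_max = g_max, c_m = vc$cm, seed = seed),
    het = het_sim_params(
      basal_rate = 0.2, stim_rate = 0.2 + stim_extra, f0 = het$f0,
      rate_cv = 0.6, seed = seed),
    puncta = puncta_sim_params(target_fraction = pf, seed = seed)
  )
}

#' Generate a cohort of voltage-clamp recordings with cell variability
#'
#' Draws per-cell `g_max` and `c_m` from lognormal distributions centred on
#' the scenario values (coefficients of variation `cv_gmax`, `cv_cm`,
#' matching the spread of reported per-cell current densities) and
#' simulates one recording per cell.
#'
#' @param params a `vclamp_sim_params` giving the cohort centre.
#' @param n_cells number of cells.
#' @param cv_gmax,cv_cm lognormal coefficients of variation.
#' @param protocol a [voltage_protocol()].
#' @param seed integer seed (cell substreams derived from it).
#' @return list of `vclamp_recording`.
#' @export
generate_vclamp_cohort <- function(params, n_cells, cv_gmax = 0.35,
                                   cv_cm = 0.12,
                                   protocol = voltage_protocol(),
                                   seed = params$seed) {
  rln <- function(mu, cv) {
    if (cv <= 0) return(mu)
    sdl <- sqrt(log(1 + cv^2))
    mu * stats::rlnorm(1, meanlog = -sdl^2 / 2, sdlog = sdl)
  }
  lapply(seq_len(n_cells), function(i) {
    set.seed(substream_seed(seed, paste0("cell", i)))
    p <- params
    p$g_max <- rln(params$g_max, cv_gmax)
    p$c_m <- rln(params$c_m, cv_cm)
    p$seed <- substream_seed(seed, paste0("cellrec", i))
    generate_vclamp(p, protocol)
  })
}
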