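# fast parameter sets used across tests: coarse sampling keeps recordings
# small; analyses only need the steady-state window statistics
fast_vc <- function(...) {
  vclamp_sim_params(sample_interval = 5e-4, ...)
}

# noiseless, fully deterministic recording for exactness checks
clean_rec <- function(..., pn = 4) {
  generate_vclamp(fast_vc(noise_sd = 0, ...), pn = pn)
}
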