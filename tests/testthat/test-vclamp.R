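test_that("Nernst potential reproduces the standard-solution value and limits", {
  # 5 mM external / 117 mM internal K+ at the 58 mV/decade slope
  expect_equal(nernst_potential(5, 117, slope_mV = 58), -79.4, tolerance = 0.02)
  expect_equal(nernst_potential(10, 100, slope_mV = 58), -58)
  expect_equal(nernst_potential(3.7, 3.7, temperature_C = 35), 0)
  # thermodynamic slope at 20 C agrees with the fixed 58 mV convention
  expect_equal(nernst_potential(5, 117, temperature_C = 20),
               nernst_potential(5, 117, slope_mV = 58), tolerance = 0.3)
  expect_error(nernst_potential(0, 117), "concentrations")
})

test_that("P/N subtraction removes a purely linear recording to machine precision", {
  rec <- clean_rec(g_max = 0)
  sub <- pn_leak_subtract(rec)
  for (v in names(sub$sweeps)) {
    expect_lt(max(abs(sub$sweeps[[v]])), 1e-9)
  }
})

test_that("P/N subtraction recovers the generator's Kv-only current", {
  p <- fast_vc(noise_sd = 0)
  rec <- generate_vclamp(p)
  sub <- pn_leak_subtract(rec)
  iv <- steady_state_iv(sub)
  # residual gate current in the -|dV|/4 sub-pulses is the only deviation
  # (a few pA at sub-threshold potentials, scaled by N)
  expect_lt(max(abs(iv$i_ss_nA * 1000 - expected_kv_ss(p, iv$voltage_mV))), 8)
  # noisy case: within a few noise standard errors of the window mean
  pn <- fast_vc(noise_sd = 20, seed = 8)
  ivn <- steady_state_iv(pn_leak_subtract(generate_vclamp(pn)))
  se <- 20 * sqrt(1 + 4) / sqrt(1000)   # P/4 noise penalty, 1000-sample window
  expect_true(all(abs(ivn$i_ss_nA * 1000 -
                        expected_kv_ss(pn, ivn$voltage_mV)) < 6 * se))
})

test_that("fallback leak subtraction works and is idempotent", {
  rec <- generate_vclamp(fast_vc(noise_sd = 0), pn = 0)
  expect_error(pn_leak_subtract(rec, fallback = FALSE), "fallback")
  sub1 <- pn_leak_subtract(rec, fallback = TRUE)
  iv1 <- steady_state_iv(sub1)
  # sub-threshold steady states ~ 0 after the linear fit is removed
  expect_lt(max(abs(iv1$i_ss_nA[iv1$voltage_mV <= -70])), 2e-3)
  # applying it twice changes nothing beyond numerical noise
  sub2 <- pn_leak_subtract(sub1, fallback = TRUE)
  iv2 <- steady_state_iv(sub2)
  expect_equal(iv2$i_ss_nA, iv1$i_ss_nA, tolerance = 1e-6)
})

test_that("steady-state window uses exactly the last 500 ms", {
  rec <- clean_rec()
  n_win <- round(0.5 / rec$sample_interval)
  win <- rec$idx_test[(length(rec$idx_test) - n_win + 1):length(rec$idx_test)]
  expect_length(win, n_win)
  expect_equal(max(win), max(rec$idx_test))  # inclusive of the last sample
  # constant sweep of 1000 pA reads as exactly 1 nA
  rec$sweeps[["60"]][] <- 1000
  rec$metadata$leak_subtracted <- TRUE
  iv <- steady_state_iv(rec)
  expect_equal(iv$i_ss_nA[iv$voltage_mV == 60], 1)
  expect_equal(attr(iv, "peak_60"), 1)
})

test_that("current density is i_ss scaled by capacitance", {
  iv <- structure(data.frame(voltage_mV = c(0, 60), i_ss_nA = c(0, 2.4)),
                  class = c("iv_result", "data.frame"))
  d <- current_density(iv, c_m = 100)
  expect_equal(d$density_pA_pF, c(0, 24))
  expect_error(current_density(iv, c_m = 0), "c_m")
  # density * c_m / 1000 reproduces i_ss exactly
  expect_equal(d$density_pA_pF * 100 / 1000, d$i_ss_nA)
  # doubling c_m in the generator halves density at identical currents
  iv2 <- current_density(iv, c_m = 200)
  expect_equal(iv2$density_pA_pF, d$density_pA_pF / 2)
})

test_that("capacitance is recovered from the transient and scales linearly", {
  rec <- clean_rec(c_m = 60)
  expect_equal(estimate_capacitance(rec), 60, tolerance = 0.02)
  rec2 <- clean_rec(c_m = 120)
  expect_equal(estimate_capacitance(rec2) / estimate_capacitance(rec), 2,
               tolerance = 0.01)
  # noisy recording still within a few percent
  recn <- generate_vclamp(vclamp_sim_params(seed = 3))
  expect_equal(estimate_capacitance(recn), 60, tolerance = 0.04)
  # zero-amplitude step is rejected
  prot0 <- voltage_protocol(step_start_mV = -60, step_stop_mV = -60)
  rec0 <- generate_vclamp(fast_vc(noise_sd = 0), protocol = prot0)
  expect_error(estimate_capacitance(rec0, sweep_mV = -60), "zero")
})

test_that("chord conductance and normalization contracts hold", {
  iv <- structure(data.frame(voltage_mV = 60, i_ss_nA = 2.788),
                  class = c("iv_result", "data.frame"))
  g <- chord_conductance(iv, e_k = -79.4)
  expect_equal(g$g_chord_nS, 2.788 / 139.4 * 1000, tolerance = 1e-6)

  p <- fast_vc(noise_sd = 0)
  iv2 <- chord_conductance(steady_state_iv(pn_leak_subtract(generate_vclamp(p))),
                           e_k = p$e_k)
  expect_equal(max(iv2$g_norm), 1)         # normalization contract
  # noiseless g_norm follows the generator's gate curve shape away from
  # E_K, where the chord denominator V - E_K is well conditioned (close to
  # the reversal potential, picoamp residuals are divided by < 1 mV)
  away <- iv2$voltage_mV >= -40
  shape <- expected_kv_ss(p, iv2$voltage_mV) / (iv2$voltage_mV - p$e_k)
  shape <- shape / max(shape[iv2$voltage_mV >= 0])
  expect_equal(iv2$g_norm[away], shape[away], tolerance = 0.01)
  # monotone non-decreasing on noiseless data away from the reversal
  expect_true(all(diff(iv2$g_norm[away]) > -1e-6))
  # and the fitted activation curve is monotone everywhere
  fit <- boltzmann_fit(iv2$voltage_mV, iv2$g_norm)
  expect_true(all(diff(predict(fit, seq(-100, 60, 1))) > 0))

  # a point at V == e_k is excluded with a warning
  iv3 <- structure(data.frame(voltage_mV = c(-79.4, 60),
                              i_ss_nA = c(0, 2)),
                   class = c("iv_result", "data.frame"))
  expect_warning(g3 <- chord_conductance(iv3, e_k = -79.4), "e_k")
  expect_equal(nrow(g3), 1)
})
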