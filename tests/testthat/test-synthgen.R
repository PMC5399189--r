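test_that("voltage-clamp generator is deterministic and parameter-validated", {
  p <- fast_vc(seed = 5)
  r1 <- generate_vclamp(p)
  r2 <- generate_vclamp(p)
  expect_identical(r1$sweeps, r2$sweeps)
  expect_identical(r1$pn_sweeps, r2$pn_sweeps)

  expect_error(vclamp_sim_params(sample_interval = 0), "sample_interval")
  expect_error(vclamp_sim_params(c_m = -1), "c_m")
  expect_error(vclamp_sim_params(slope_k = 0), "slope_k")
})

test_that("zero-conductance recordings contain only leak and capacitive current", {
  rec <- clean_rec(g_max = 0)
  p <- rec$metadata$ground_truth
  # during the late test pulse (transient decayed) the current is pure leak
  it <- rec$idx_test
  late_idx <- it[seq(round(length(it) * 0.75), length(it))]
  for (v in c("-100", "0", "60")) {
    late <- rec$sweeps[[v]][late_idx]
    expect_equal(mean(late), p$g_leak * (as.numeric(v) - p$e_leak),
                 tolerance = 1e-8)
  }
})

test_that("steady-state current at +60 mV matches the closed-form model", {
  rec <- clean_rec(g_leak = 0)
  p <- vclamp_sim_params(noise_sd = 0, g_leak = 0, sample_interval = 5e-4)
  iv <- steady_state_iv(rec, check_subtracted = FALSE)
  i60 <- iv$i_ss_nA[iv$voltage_mV == 60] * 1000
  expect_equal(i60, expected_kv_ss(p, 60), tolerance = 1e-3)
  # and across all depolarized potentials
  dep <- iv$voltage_mV >= 0
  expect_equal(iv$i_ss_nA[dep] * 1000,
               expected_kv_ss(p, iv$voltage_mV[dep]), tolerance = 1e-3)
})

test_that("capacitive transient area equals c_m * dV", {
  rec <- clean_rec(g_leak = 0, g_max = 0, c_m = 80)
  s <- rec$sweeps[["60"]]
  dt <- rec$sample_interval
  q <- sum(s[rec$idx_test[1:100]]) * dt          # pA*s over 50 ms
  expect_equal(1000 * q / 120, 80, tolerance = 0.01)  # dV = 120 mV
})

test_that("calcium generator: determinism, empty at rate 0, ground truth embedded", {
  p <- calcium_sim_params(n_rois = 3, duration = 120, seed = 9)
  t1 <- generate_calcium(p)
  t2 <- generate_calcium(p)
  expect_identical(t1$values, t2$values)

  p0 <- calcium_sim_params(rate_per_min = 0, n_rois = 3, duration = 120,
                           drift_slope = 0, seed = 9)
  t0 <- generate_calcium(p0)
  expect_true(all(lengths(lapply(t0$ground_truth$rois,
                                 `[[`, "spike_times")) == 0))
  # baseline + noise only
  expect_equal(mean(t0$values), p0$f0, tolerance = 0.01 * p0$f0)

  expect_error(calcium_sim_params(duration = 0.5, frame_interval = 1),
               "2 frames")
  expect_error(calcium_sim_params(rate_per_min = -1), "rate_per_min")
})

test_that("calcium spike counts over many ROIs follow the Poisson law", {
  # chi-square goodness of fit of per-ROI counts against Poisson(rate*T)
  p <- calcium_sim_params(rate_per_min = 3, duration = 300, n_rois = 400,
                          seed = 21)
  ts <- generate_calcium(p)
  counts <- lengths(lapply(ts$ground_truth$rois, `[[`, "spike_times"))
  lambda <- 3 / 60 * 300
  brk <- c(-Inf, 10:19, Inf)
  obs <- table(cut(counts, brk))
  pr <- diff(ppois(c(-Inf, 10:19, Inf), lambda))
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = pr))
  expect_gt(gof$p.value, 0.01)
})

test_that("HEt generator: analytic ramp area and flat-stimulus null", {
  # pure extra ramp: AUC over the stimulus window is s*T^2/2
  p <- het_sim_params(basal_rate = 0, stim_rate = 0.05, noise_sd = 0)
  tr <- generate_het(p)
  s <- ros_auc(tr$time, tr$values[, 1], 180, 480)
  expect_equal(s$auc, 0.05 * 300^2 / 2, tolerance = 1e-9)

  # basal == stim: no stimulus effect
  p2 <- het_sim_params(basal_rate = 0.1, stim_rate = 0.1, noise_sd = 0)
  tr2 <- generate_het(p2)
  s2 <- ros_auc(tr2$time, tr2$values[, 1], 180, 480)
  expect_equal(s2$auc, 0, tolerance = 1e-8)

  expect_error(het_sim_params(basal_rate = -1), "cumulative")
  expect_error(het_sim_params(stim_start = 600, stim_duration = 300,
                              duration = 780), "within the trace")
})

test_that("puncta generator reaches its target fraction and self-reports it", {
  p <- puncta_sim_params(target_fraction = 50, channel_noise_sd = 0, seed = 4)
  img <- generate_puncta_image(p)
  realized <- 100 * sum(img$cluster_mask) / sum(img$soma_mask)
  # metadata fraction is exactly the mask-derived fraction
  expect_equal(img$metadata$realized_fraction, realized)
  # realized >= target, overshoot bounded by one cluster's area
  max_cluster <- pi * (1.4 * p$cluster_radius_px_mean)^2
  expect_gte(realized, 50)
  expect_lt(realized, 50 + 100 * max_cluster / sum(img$soma_mask))
  # clusters live inside the soma
  expect_true(all(img$soma_mask[img$cluster_mask]))

  img0 <- generate_puncta_image(puncta_sim_params(target_fraction = 0,
                                                  channel_noise_sd = 0))
  expect_equal(sum(img0$cluster_mask), 0)
  expect_equal(max(img0$puncta_channel), 0)

  expect_error(
    generate_puncta_image(puncta_sim_params(target_fraction = 90,
                                            n_clusters = 5)),
    "unreachable")
})

test_that("generators are pure functions of (params, seed)", {
  h <- het_sim_params(n_rois = 2, rate_cv = 0.5, seed = 77)
  expect_identical(generate_het(h)$values, generate_het(h)$values)
  pp <- puncta_sim_params(seed = 77)
  expect_identical(generate_puncta_image(pp)$puncta_channel,
                   generate_puncta_image(pp)$puncta_channel)
  # different seeds give different data
  pp2 <- puncta_sim_params(seed = 78)
  expect_false(identical(generate_puncta_image(pp)$cluster_mask,
                         generate_puncta_image(pp2)$cluster_mask))
})
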