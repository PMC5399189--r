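test_that("baseline estimator tracks flat, drifting and transient-laden traces", {
  # constant trace: baseline is the constant
  expect_equal(estimate_baseline(rep(7, 100), 1), rep(7, 100))
  # median of symmetric noise on a flat signal ~ the signal mean
  set.seed(1)
  x <- 100 + rnorm(400)
  b <- estimate_baseline(x, 1, window_s = 60, percentile = 50)
  expect_equal(mean(b), 100, tolerance = 0.01)
  # drifting baseline with sparse transients is recovered within 5%
  p <- calcium_sim_params(rate_per_min = 3, amp_mean = 80, amp_sd = 10,
                          f0 = 1000, drift_slope = 0.5, noise_sd = 10,
                          duration = 300, n_rois = 4, seed = 31)
  ts <- generate_calcium(p)
  for (r in 1:4) {
    b <- estimate_baseline(ts$values[, r], 1)
    truth <- 1000 + 0.5 * ts$time
    expect_lt(max(abs(b - truth) / truth), 0.05)
  }
  # window longer than trace falls back to a global percentile
  expect_warning(bb <- estimate_baseline(1:10, 1, window_s = 50),
                 "global percentile")
  expect_length(bb, 10)
  expect_error(estimate_baseline(1:10, 1, window_s = 2), "3 frames")
})

test_that("percent-of-baseline normalization and its threshold boundary", {
  f0 <- rep(200, 5)
  expect_equal(normalize_dff(f0, f0), rep(0, 5))
  expect_equal(normalize_dff(1.25 * f0, f0), rep(25, 5))  # at the 25% rule
  expect_error(normalize_dff(f0, rep(0, 5)), "positive")
})

test_that("spike detection: counts, exclusion below 25%, flat traces", {
  # flat trace: nothing detected
  s <- detect_spikes(rep(0, 120), 1)
  expect_equal(s$n_spikes, 0)
  expect_equal(s$frequency, 0)
  expect_true(is.na(s$mean_amplitude))

  # five 60% transients in 60 s: frequency 5 min^-1
  tm <- seq(0, 60, 1)
  x <- numeric(length(tm))
  for (t0 in c(5, 17, 29, 41, 53)) {
    dt <- tm - t0
    x <- x + 60 * ifelse(dt >= 0, exp(-dt / 1.5), 0)
  }
  s5 <- detect_spikes(x, 1)
  expect_equal(s5$n_spikes, 5)
  expect_equal(s5$frequency, 5)
  expect_equal(s5$mean_amplitude, 60, tolerance = 0.01)

  # a transient peaking at 20% is excluded by the 25% rule
  x20 <- 20 * exp(-pmax(tm - 30, 0) / 1.5) * (tm >= 30)
  expect_equal(detect_spikes(x20, 1)$n_spikes, 0)

  expect_error(detect_spikes(numeric(0), 1), "empty")
})

test_that("raising the threshold never increases the spike count", {
  p <- calcium_sim_params(rate_per_min = 6, amp_mean = 90, amp_sd = 40,
                          n_rois = 6, duration = 300, seed = 17)
  ts <- generate_calcium(p)
  for (r in 1:6) {
    b <- estimate_baseline(ts$values[, r], 1)
    d <- normalize_dff(ts$values[, r], b)
    counts <- vapply(c(10, 25, 40, 60, 80),
                     function(th) detect_spikes(d, 1, threshold_pct = th)$n_spikes,
                     numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("group summary arithmetic matches hand computation", {
  mk <- function(f) structure(list(frequency = f, rate_est = f,
                                   mean_amplitude = 50, dead_time_s = 0),
                              class = "spike_summary")
  g <- summarize_group(list(mk(1), mk(2), mk(3)))
  expect_equal(g$frequency_mean, 2)
  expect_equal(g$frequency_sem, sd(c(1, 2, 3)) / sqrt(3))  # 0.577
  expect_equal(g$frequency_sem, 0.577, tolerance = 1e-3)
  g0 <- summarize_group(list(mk(2), mk(2), mk(2)))
  expect_equal(g0$frequency_sem, 0)
  expect_error(summarize_group(list(mk(1))), ">= 2")
})

test_that("detector recovers generator rates across the physiological range", {
  # |estimated - true| <= 2*sqrt(rate/duration_min) for >= 95% of ROIs;
  # high-rate conditions are imaged at the fast 0.5 s framing, as in the
  # toxin-challenge protocol (1 s framing cannot resolve ~4 s inter-event
  # intervals riding on 1.5 s transients)
  for (rate in c(0.5, 2, 6, 15)) {
    p <- calcium_sim_params(rate_per_min = rate, amp_mean = 60, amp_sd = 0,
                            noise_sd = 50, f0 = 1000,  # 5% of F0
                            frame_interval = if (rate >= 8) 0.5 else 1.0,
                            n_rois = 60, duration = 300, seed = 1234 + rate)
    ts <- generate_calcium(p)
    ss <- analyze_traces(ts)
    true_rate <- lengths(lapply(ts$ground_truth$rois, `[[`, "spike_times")) / 5
    est <- vapply(ss, function(s) s$rate_est, numeric(1))
    tol <- 2 * sqrt(rate / 5)
    expect_gte(mean(abs(est - true_rate) <= tol), 0.95)
  }
})

test_that("blockade (rate 0) cohorts are statistically silent", {
  p <- calcium_sim_params(rate_per_min = 0, n_rois = 50, duration = 300,
                          seed = 3)
  g <- summarize_group(analyze_traces(generate_calcium(p)))
  # mean indistinguishable from zero: within 3 SEM (and tiny absolutely)
  expect_lte(g$frequency_mean, max(3 * g$frequency_sem, 1e-12))
  expect_lt(g$frequency_mean, 0.05)
})

test_that("frequency estimates agree across 1 s and 0.5 s framings", {
  base <- list(rate_per_min = 6.312, amp_mean = 90, amp_sd = 30,
               n_rois = 150, duration = 300)
  g1 <- summarize_group(analyze_traces(generate_calcium(
    do.call(calcium_sim_params, c(base, frame_interval = 1.0, seed = 41)))))
  g2 <- summarize_group(analyze_traces(generate_calcium(
    do.call(calcium_sim_params, c(base, frame_interval = 0.5, seed = 42)))))
  se <- sqrt(g1$rate_est_sem^2 + g2$rate_est_sem^2)
  expect_lt(abs(g1$rate_est_mean - g2$rate_est_mean), 4 * se)
})

test_that("first-minute activity screen filters silent ROIs", {
  p <- calcium_sim_params(rate_per_min = 0.35, n_rois = 40, duration = 300,
                          seed = 6)
  ts <- generate_calcium(p)
  all_rois <- analyze_traces(ts)
  active <- analyze_traces(ts, first_minute_filter = TRUE)
  expect_lt(length(active), length(all_rois))
  expect_true(all(vapply(active, function(s) any(s$spike_times <= 60),
                         logical(1))))
})
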