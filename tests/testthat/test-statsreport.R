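test_that("two-group tests reproduce hand-computed values", {
  # identical groups: t = 0, p = 1
  same <- compare_two(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$effect_direction, "none")

  # pooled-variance t on {1,2,3} vs {4,5,6}
  cmp <- compare_two(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cmp$statistic, -3.674, tolerance = 1e-3)
  expect_equal(cmp$p_value, 0.0213, tolerance = 1e-2)
  expect_equal(cmp$effect_direction, "up")
  expect_equal(cmp$mean, c(2, 5))
  expect_equal(cmp$sem, c(1, 1) / sqrt(3))

  mw <- compare_two(c(1, 2, 3), c(4, 5, 6), "mann_whitney")
  expect_equal(mw$statistic, 0)           # all ranks separated
  expect_equal(mw$p_value, 0.1, tolerance = 1e-6)

  expect_error(compare_two(c(1, 1), c(2, 2)), "degenerate")
  expect_error(compare_two(1, c(2, 3)), ">= 2")
})

test_that("spike-frequency cohorts at study presets separate decisively", {
  g1 <- summarize_group(analyze_traces(generate_calcium(
    calcium_sim_params(rate_per_min = 1.958, n_rois = 150, seed = 1))))
  g2 <- summarize_group(analyze_traces(generate_calcium(
    calcium_sim_params(rate_per_min = 6.312, amp_mean = 85.71,
                       n_rois = 150, seed = 2))))
  cmp <- compare_two(g1$frequencies, g2$frequencies, "t_unpaired",
                     labels = c("non_tg", "tg3x"))
  expect_lt(cmp$p_value, 0.001)
  expect_equal(cmp$effect_direction, "up")
})

test_that("I-V comparison: identical groups null, degeneracy to one voltage", {
  mk_iv <- function(dens) {
    structure(data.frame(voltage_mV = seq(0, 60, 10),
                         density_pA_pF = dens),
              class = c("iv_result", "data.frame"))
  }
  set.seed(5)
  cells <- lapply(1:12, function(i) mk_iv(seq(10, 40, 5) * rlnorm(1, 0, 0.2)))
  same <- compare_iv(cells, rep(c("a", "b"), 6))
  expect_gt(same$main$p_value, 0.01)  # no group difference built in
  expect_equal(nrow(same$per_voltage), 7)
  expect_true(all(same$per_voltage$adjusted_p >= same$per_voltage$p_value,
                  na.rm = TRUE))

  # single shared voltage reduces to the unpaired comparison
  one <- lapply(cells, function(iv) iv[iv$voltage_mV == 30, ])
  r1 <- compare_iv(one, rep(c("a", "b"), 6))
  y <- vapply(one, function(iv) iv$density_pA_pF, numeric(1))
  ct <- compare_two(y[c(TRUE, FALSE)], y[c(FALSE, TRUE)])
  expect_equal(r1$main$p_value, ct$p_value, tolerance = 1e-10)
  expect_equal(r1$main$statistic, ct$statistic^2, tolerance = 1e-8)

  # friedman route runs and reports the blocked statistic
  fr <- compare_iv(cells, rep(c("a", "b"), 6), method = "friedman")
  expect_true(is.finite(fr$main$statistic))
})

test_that("strain I-V scenario yields a significant group main effect", {
  sc_nt <- kv_scenario("non_tg", seed = 3)
  sc_tg <- kv_scenario("tg3x", seed = 4)
  iv_of <- function(scn, n, seed) {
    p <- scn$vclamp; p$sample_interval <- 5e-4
    recs <- generate_vclamp_cohort(p, n, seed = seed)
    lapply(recs, function(r) {
      iv <- analyze_vclamp(r)$iv
      iv[iv$voltage_mV >= 0, ]
    })
  }
  tabs <- c(iv_of(sc_nt, 10, 31), iv_of(sc_tg, 17, 32))
  res <- compare_iv(tabs, rep(c("non_tg", "tg3x"), c(10, 17)))
  expect_lt(res$main$p_value, 0.05)
  expect_equal(res$main$effect_direction, "down")
})

test_that("ANOVA + Bonferroni arithmetic and degenerate inputs", {
  # all groups identical: F ~ 0, all adjusted p = 1
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  r <- anova_bonferroni(g)
  expect_equal(r$anova$F, 0, tolerance = 1e-10)
  expect_true(all(r$pairwise$adjusted_p == 1))

  # Bonferroni arithmetic: m = 3, raw 0.02 -> 0.06
  expect_equal(bonferroni_adjust(0.02, 3), 0.06)
  expect_equal(bonferroni_adjust(0.5, 3), 1)
  expect_true(all(r$pairwise$adjusted_p >= r$pairwise$p_value))

  expect_error(anova_bonferroni(list(a = 1:3, b = 1:3)), "compare_two")
})

test_that("six-condition antioxidant design flags only the treated transgenic contrasts", {
  # untreated / NAC / Trolox in both strains; treatment shifts only the
  # transgenic generator (rate 6.312 -> 4.682)
  hits <- c(tg = 0, nt = 0)
  n_rep <- 10
  for (rep in seq_len(n_rep)) {
    grp <- list()
    cfgs <- list(
      nt_untreated = 1.958, nt_nac = 1.958, nt_trolox = 1.958,
      tg_untreated = 6.312, tg_nac = 4.682, tg_trolox = 4.682)
    for (nm in names(cfgs)) {
      g <- summarize_group(analyze_traces(generate_calcium(
        calcium_sim_params(rate_per_min = cfgs[[nm]], n_rois = 40,
                           duration = 300,
                           seed = substream_seed(900 + rep, nm)))))
      grp[[nm]] <- g$frequencies
    }
    r <- anova_bonferroni(grp)
    pw <- r$pairwise
    sig <- function(a, b) {
      pw$adjusted_p[pw$group_a == a & pw$group_b == b] < 0.05
    }
    if (sig("tg_untreated", "tg_nac") && sig("tg_untreated", "tg_trolox"))
      hits["tg"] <- hits["tg"] + 1
    if (!sig("nt_untreated", "nt_nac") && !sig("nt_untreated", "nt_trolox"))
      hits["nt"] <- hits["nt"] + 1
  }
  expect_gte(hits[["tg"]] / n_rep, 0.9)
  expect_gte(hits[["nt"]] / n_rep, 0.9)
})
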