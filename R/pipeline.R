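#' Run the full multi-modality comparison pipeline
#'
#' Generates every study condition from its preset (see [kv_scenario()]),
#' runs each analysis stage, and assembles the group comparisons that
#' characterize the hyperexcitability phenotype: spike frequency and
#' amplitude, Kv current density and +60 mV peak current, NMDA-evoked ROS
#' AUC and resting ROS baseline, somatic clusterization index, plus the
#' pharmacology contrasts (Kv2.1 block on both strains, antioxidant
#' treatment on the transgenic strain). Each comparison carries the
#' qualitative direction expected under the Kv2.1-loss-of-function model,
#' and the report records whether the computed direction matches
#' (non-significance at alpha = 0.05 for the expected null).
#'
#' @param config named list (or path to a YAML file). Must name
#'   `preset = "study"`; optional overrides: `n_rois` (calcium ROIs per
#'   group), `n_rois_gxtx`, `n_cells` (named: `non_tg`, `tg3x`,
#'   `non_tg_gxtx`, `tg3x_gxtx`), `n_ros_rois` (length 2: non-tg, tg3x),
#'   `n_images` (length 2), `sample_interval` (s/point for simulated
#'   recordings), `calcium_duration` (s).
#' @param seed integer top-level seed; every generator substream derives
#'   from it.
#' @param out_dir optional directory; writes `report.json` and
#'   `comparisons.csv` there.
#' @return an object of class `kvquant_report`: `seed`, `config`,
#'   `comparisons` (named list, each with the `group_comparison`, expected
#'   and observed direction and `matches`), `directions_ok`.
#' @export
run_pipeline <- function(config, seed = 1L, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || length(config) == 0)
    stop_param("empty config: supply at least `preset: study` ",
               "(see ?run_pipeline for the recognized fields)")
  if (!identical(config$preset, "study"))
    stop_param("unknown preset; only `study` is defined")

  n_rois <- config$n_rois %||% 60L
  n_rois_gxtx <- config$n_rois_gxtx %||% 40L
  n_cells <- utils::modifyList(
    list(non_tg = 10L, tg3x = 17L, non_tg_gxtx = 6L, tg3x_gxtx = 5L),
    config$n_cells %||% list())
  n_ros <- config$n_ros_rois %||% c(108L, 145L)
  n_img <- config$n_images %||% c(36L, 26L)
  dt_rec <- config$sample_interval %||% 5e-4
  ca_dur <- config$calcium_duration %||% 300

  seed <- as.integer(seed)
  sc <- function(name, key) kv_scenario(name, seed = substream_seed(seed, key))

  # `fidelity` marks the qualitative direction set that defines phenotype
  # reproduction (strain frequency/amplitude/density/ROS/index and the
  # pharmacology contrasts); other comparisons are reported alongside but
  # do not enter `directions_ok`
  comparisons <- list()
  add <- function(name, cmp, expected, fidelity = TRUE) {
    matches <- if (expected == "none") cmp$p_value > 0.05
               else identical(cmp$effect_direction, expected)
    comparisons[[name]] <<- list(
      comparison = cmp, expected = expected,
      observed = cmp$effect_direction, matches = matches,
      fidelity = fidelity)
  }

  ## -- calcium spikes: strain comparison -------------------------------
  spikes_of <- function(scn, n, dur) {
    p <- scn$calcium; p$n_rois <- as.integer(n); p$duration <- dur
    analyze_traces(generate_calcium(p))
  }
  s_nt <- spikes_of(sc("non_tg", "ca_nt"), n_rois, ca_dur)
  s_tg <- spikes_of(sc("tg3x", "ca_tg"), n_rois, ca_dur)
  freq <- function(s) vapply(s, function(x) x$frequency, numeric(1))
  amp <- function(s) vapply(s, function(x) x$mean_amplitude, numeric(1))
  add("spike_frequency_tg3x_vs_non_tg",
      compare_two(freq(s_nt), freq(s_tg), "t_unpaired",
                  metric = "spike frequency (min^-1)",
                  labels = c("non_tg", "tg3x")), "up")
  add("spike_amplitude_tg3x_vs_non_tg",
      compare_two(amp(s_nt), amp(s_tg), "t_unpaired",
                  metric = "spike amplitude (% basal)",
                  labels = c("non_tg", "tg3x")), "down")

  ## -- voltage clamp: strain comparison --------------------------------
  iv_of <- function(scn, n, key) {
    p <- scn$vclamp; p$sample_interval <- dt_rec
    recs <- generate_vclamp_cohort(p, n, seed = substream_seed(seed, key))
    lapply(recs, function(r) analyze_vclamp(r)$iv)
  }
  iv_nt <- iv_of(sc("non_tg", "vc_nt"), n_cells$non_tg, "vc_nt_cells")
  iv_tg <- iv_of(sc("tg3x", "vc_tg"), n_cells$tg3x, "vc_tg_cells")
  dep <- function(iv) iv[iv$voltage_mV >= 0, , drop = FALSE]
  civ <- compare_iv(c(lapply(iv_nt, dep), lapply(iv_tg, dep)),
                    rep(c("non_tg", "tg3x"), c(length(iv_nt), length(iv_tg))))
  add("current_density_tg3x_vs_non_tg", civ$main, "down")
  peak <- function(ivs) vapply(ivs, function(iv) attr(iv, "peak_60"), numeric(1))
  add("peak_current_tg3x_vs_non_tg",
      compare_two(peak(iv_nt), peak(iv_tg), "t_unpaired",
                  metric = "peak current at +60 mV (nA)",
                  labels = c("non_tg", "tg3x")), "down", fidelity = FALSE)

  ## -- ROS -------------------------------------------------------------
  het_of <- function(scn, n, key) {
    p <- scn$het; p$n_rois <- as.integer(n)
    p$seed <- substream_seed(seed, key)
    generate_het(p)
  }
  het_nt <- het_of(sc("non_tg", "ros_nt"), n_ros[1], "ros_nt_rois")
  het_tg <- het_of(sc("tg3x", "ros_tg"), n_ros[2], "ros_tg_rois")
  stim <- c(het_nt$ground_truth$params$stim_start,
            het_nt$ground_truth$params$stim_start +
              het_nt$ground_truth$params$stim_duration)
  auc_nt <- ros_auc_set(het_nt, stim[1], stim[2])
  auc_tg <- ros_auc_set(het_tg, stim[1], stim[2])
  add("ros_auc_tg3x_vs_non_tg",
      compare_two(auc_nt$auc, auc_tg$auc, "t_unpaired",
                  metric = "NMDA-evoked HEt AUC",
                  labels = c("non_tg", "tg3x")), "up")
  add("ros_baseline_tg3x_vs_non_tg",
      compare_two(auc_nt$baseline_f, auc_tg$baseline_f, "t_unpaired",
                  metric = "baseline HEt fluorescence",
                  labels = c("non_tg", "tg3x")), "up")

  ## -- clusterization --------------------------------------------------
  index_of <- function(scn, n, key) {
    vapply(seq_len(n), function(i) {
      p <- scn$puncta
      p$seed <- substream_seed(seed, paste0(key, i))
      segment_clusters(generate_puncta_image(p))$index_pct
    }, numeric(1))
  }
  ci_nt <- index_of(sc("non_tg", "cl_nt"), n_img[1], "cl_nt_img")
  ci_tg <- index_of(sc("tg3x", "cl_tg"), n_img[2], "cl_tg_img")
  add("cluster_index_tg3x_vs_non_tg",
      compare_two(ci_nt, ci_tg, "mann_whitney",
                  metric = "clusterization index (%)",
                  labels = c("non_tg", "tg3x")), "up")

  ## -- pharmacology ----------------------------------------------------
  s_gx_pre <- spikes_of(sc("non_tg_gxtx_pre", "ca_gx0"), n_rois_gxtx, ca_dur)
  s_gx <- spikes_of(sc("non_tg_gxtx", "ca_gx1"), n_rois_gxtx, ca_dur)
  add("gxtx_non_tg_spike_frequency",
      compare_two(freq(s_gx_pre), freq(s_gx), "t_unpaired",
                  metric = "spike frequency under GxTx (min^-1)",
                  labels = c("pre", "gxtx")), "up")
  iv_gx <- iv_of(sc("non_tg_gxtx", "vc_gx"), n_cells$non_tg_gxtx, "vc_gx_cells")
  civ_gx <- compare_iv(c(lapply(iv_nt, dep), lapply(iv_gx, dep)),
                       rep(c("untreated", "gxtx"),
                           c(length(iv_nt), length(iv_gx))))
  add("gxtx_non_tg_current_density", civ_gx$main, "down")
  iv_tggx <- iv_of(sc("tg3x_gxtx", "vc_tggx"), n_cells$tg3x_gxtx, "vc_tggx_cells")
  civ_tggx <- compare_iv(c(lapply(iv_tg, dep), lapply(iv_tggx, dep)),
                         rep(c("untreated", "gxtx"),
                             c(length(iv_tg), length(iv_tggx))))
  add("gxtx_tg3x_current_density", civ_tggx$main, "none")
  s_nac <- spikes_of(sc("tg3x_nac", "ca_nac"), n_rois, ca_dur)
  add("nac_tg3x_spike_frequency",
      compare_two(freq(s_tg), freq(s_nac), "t_unpaired",
                  metric = "spike frequency under NAC (min^-1)",
                  labels = c("tg3x", "tg3x_nac")), "down")

  report <- structure(list(
    seed = seed,
    config = config,
    comparisons = comparisons,
    directions_ok = all(vapply(
      Filter(function(x) x$fidelity, comparisons),
      function(x) x$matches, logical(1)))
  ), class = "kvquant_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.kvquant_report <- function(x, ...) {
  cat(sprintf("kvquant pipeline report (seed %d)\n", x$seed))
  for (nm in names(x$comparisons)) {
    c0 <- x$comparisons[[nm]]
    cat(sprintf("  %-36s expected %-5s observed %-5s p=%.3g  %s\n",
                nm, c0$expected, c0$observed, c0$comparison$p_value,
                if (c0$matches) "ok" else "MISMATCH"))
  }
  cat(sprintf("all effect directions as expected: %s\n", x$directions_ok))
  invisible(x)
}

#' Tabular view of a pipeline report
#'
#' @param report a `kvquant_report`.
#' @return data frame, one row per comparison.
#' @export
report_table <- function(report) {
  do.call(rbind, lapply(names(report$comparisons), function(nm) {
    c0 <- report$comparisons[[nm]]
    cmp <- c0$comparison
    data.frame(
      comparison = nm, metric = cmp$metric,
      group_a = cmp$groups[1], group_b = cmp$groups[2],
      n_a = cmp$n[1], n_b = cmp$n[2],
      mean_a = cmp$mean[1], mean_b = cmp$mean[2],
      sem_a = cmp$sem[1], sem_b = cmp$sem[2],
      test = cmp$test, statistic = cmp$statistic, p_value = cmp$p_value,
      expected = c0$expected, observed = c0$observed, matches = c0$matches)
  }))
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(seed = report$seed,
         directions_ok = report$directions_ok,
         comparisons = lapply(report$comparisons, function(c0) {
           cmp <- c0$comparison
           list(metric = cmp$metric, groups = cmp$groups, n = cmp$n,
                mean = cmp$mean, sem = cmp$sem, test = cmp$test,
                statistic = cmp$statistic, p_value = cmp$p_value,
                expected = c0$expected, observed = c0$observed,
                matches = c0$matches)
         })),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  utils::write.csv(report_table(report),
                   file.path(out_dir, "comparisons.csv"), row.names = FALSE)
  invisible(file.path(out_dir, "report.json"))
}
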