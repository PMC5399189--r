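#' Write / read fluorescence trace sets as CSV
#'
#' Layout: column `time_s`, then one column per ROI (`roi_0001`, ...).
#' Ground truth, when present, goes to a JSON sidecar `<path>.json`.
#'
#' @param traces a `fluor_trace_set`.
#' @param path output CSV path.
#' @param ground_truth also write the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traces, path, ground_truth = TRUE) {
  stopifnot(inherits(traces, "fluor_trace_set"))
  df <- data.frame(time_s = traces$time)
  df <- cbind(df, as.data.frame(traces$values))
  utils::write.csv(df, path, row.names = FALSE)
  if (ground_truth && !is.null(traces$ground_truth)) {
    jsonlite::write_json(traces$ground_truth, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path)
  if (names(df)[1] != "time_s") stop_param("expected first column `time_s`")
  tm <- df$time_s
  vals <- as.matrix(df[, -1, drop = FALSE])
  gt <- NULL
  side <- paste0(path, ".json")
  if (file.exists(side)) gt <- jsonlite::read_json(side, simplifyVector = TRUE)
  structure(list(
    time = tm,
    values = vals,
    frame_interval = if (length(tm) > 1) tm[2] - tm[1] else NA_real_,
    ground_truth = gt
  ), class = "fluor_trace_set")
}

#' Write / read a voltage-clamp recording as CSV
#'
#' Layout: column `time_s`, one column per test potential (`sweep_-100` ...
#' `sweep_60`, pA) and, when present, the averaged P/N sub-sweeps
#' (`pn_-100` ...). Protocol and metadata (capacitance, sampling interval,
#' P/N count, ground truth) go to a JSON sidecar `<path>.json`.
#'
#' @param rec a `vclamp_recording`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "vclamp_recording"))
  df <- data.frame(time_s = rec$time)
  for (v in names(rec$sweeps)) df[[paste0("sweep_", v)]] <- rec$sweeps[[v]]
  for (v in names(rec$pn_sweeps)) df[[paste0("pn_", v)]] <- rec$pn_sweeps[[v]]
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(
    c_m_pF = rec$c_m,
    sample_interval_s = rec$sample_interval,
    pn_n = rec$pn_n,
    baseline_duration_s = rec$baseline_duration_s,
    protocol = unclass(rec$protocol),
    metadata = rec$metadata
  ), paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop_param("missing metadata sidecar ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  prot <- do.call(voltage_protocol, as.list(meta$protocol))
  sw_cols <- grep("^sweep_", names(df), value = TRUE)
  pn_cols <- grep("^pn_", names(df), value = TRUE)
  sweeps <- lapply(df[sw_cols], identity)
  names(sweeps) <- sub("^sweep_", "", sw_cols)
  pn_sweeps <- if (length(pn_cols)) {
    p <- lapply(df[pn_cols], identity)
    names(p) <- sub("^pn_", "", pn_cols)
    p
  } else NULL
  dt <- meta$sample_interval_s
  n_base <- round(meta$baseline_duration_s / dt)
  n_test <- round(prot$pulse_duration_s / dt)
  structure(list(
    time = df$time_s,
    sweeps = sweeps,
    pn_sweeps = pn_sweeps,
    pn_n = meta$pn_n,
    sample_interval = dt,
    c_m = meta$c_m_pF,
    protocol = prot,
    baseline_duration_s = meta$baseline_duration_s,
    idx_test = n_base + seq_len(n_test),
    metadata = as.list(meta$metadata)
  ), class = "vclamp_recording")
}

#' Write an I-V result as tidy CSV
#'
#' Columns `voltage_mV,i_ss_nA,density_pA_pF,g_chord_nS,g_norm` (whichever
#' are present); a companion JSON fit summary is written when a
#' `boltzmann_fit` is supplied.
#'
#' @param iv an `iv_result`.
#' @param path output CSV path.
#' @param fit optional `boltzmann_fit`, written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_iv_csv <- function(iv, path, fit = NULL) {
  stopifnot(inherits(iv, "iv_result"))
  utils::write.csv(as.data.frame(iv), path, row.names = FALSE)
  if (!is.null(fit)) {
    jsonlite::write_json(list(
      g_max = fit$coefficients[["g_max"]],
      v_half = fit$coefficients[["v_half"]],
      slope_k = fit$coefficients[["slope_k"]],
      residual_norm = fit$residual_norm,
      converged = fit$converged
    ), paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write / read a two-channel image pair as TIFF
#'
#' The image goes to a two-page float TIFF (page 1 puncta, page 2
#' structural); ground-truth masks, when present, to `<path>.masks.tif`
#' (page 1 soma, page 2 clusters). Intensities are clipped to `[0, 1]`
#' as required by the format.
#'
#' @param pair a `labeled_image_pair`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(pair, path) {
  stopifnot(inherits(pair, "labeled_image_pair"))
  clip <- function(m) pmax(pmin(m, 1), 0)
  tiff::writeTIFF(list(clip(pair$puncta_channel),
                       clip(pair$structural_channel %||%
                              matrix(0, nrow(pair$puncta_channel),
                                     ncol(pair$puncta_channel)))),
                  path, bits.per.sample = 32L)
  if (!is.null(pair$soma_mask)) {
    tiff::writeTIFF(list(pair$soma_mask * 1.0, pair$cluster_mask * 1.0),
                    sub("\\.tiff?$", ".masks.tif", path))
  }
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2) stop_param("expected a two-page (two-channel) TIFF")
  mask_path <- sub("\\.tiff?$", ".masks.tif", path)
  soma <- cluster <- NULL
  if (file.exists(mask_path) && mask_path != path) {
    masks <- tiff::readTIFF(mask_path, all = TRUE)
    soma <- masks[[1]] > 0.5
    cluster <- masks[[2]] > 0.5
  }
  structure(list(
    puncta_channel = pages[[1]],
    structural_channel = pages[[2]],
    soma_mask = soma,
    cluster_mask = cluster,
    pixel_size = NULL,
    provided_soma_mask = NULL,
    metadata = list()
  ), class = "labeled_image_pair")
}
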