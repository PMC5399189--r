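#' Simulation parameters for two-channel puncta/soma images
#'
#' Emulates single-plane two-channel immunofluorescence of a neuronal soma:
#' the structural channel (MAP-2-like) is a bright disk, the puncta channel
#' carries circular channel clusters placed inside the soma. Clusters are
#' added (overlap-merged) until their union first covers `target_fraction`
#' percent of the soma area, so the realized area fraction is known exactly
#' from the returned masks.
#'
#' @param image_shape image size in pixels, length-2 (rows, cols).
#' @param soma_radius_px soma disk radius (px); the disk must fit inside the
#'   image.
#' @param target_fraction intended cluster/soma area fraction (%), in
#'   `[0, 100]`.
#' @param n_clusters maximum number of clusters to place before declaring the
#'   target unreachable.
#' @param cluster_radius_px_mean mean cluster radius (px); radii vary
#'   +/- 40% uniformly around the mean.
#' @param channel_noise_sd additive Gaussian noise SD on both channels, as a
#'   fraction of the signal amplitude (which is 1).
#' @param seed integer seed.
#' @return an object of class `puncta_sim_params`.
#' @export
puncta_sim_params <- function(image_shape = c(192, 192),
                              soma_radius_px = 64,
                              target_fraction = 18.82,
                              n_clusters = 400,
                              cluster_radius_px_mean = 3,
                              channel_noise_sd = 0.05,
                              seed = 1L) {
  if (length(image_shape) != 2 || any(image_shape < 8))
    stop_param("image_shape must be two dimensions >= 8 px")
  if (target_fraction < 0 || target_fraction > 100)
    stop_param("target_fraction must be in [0, 100]")
  if (2 * soma_radius_px >= min(image_shape))
    stop_param("soma must fit inside the image")
  if (cluster_radius_px_mean <= 0) stop_param("cluster_radius_px_mean must be > 0")
  if (channel_noise_sd < 0) stop_param("channel_noise_sd must be >= 0")
  structure(list(
    image_shape = as.integer(image_shape),
    soma_radius_px = soma_radius_px,
    target_fraction = target_fraction,
    n_clusters = as.integer(n_clusters),
    cluster_radius_px_mean = cluster_radius_px_mean,
    channel_noise_sd = channel_noise_sd,
    seed = as.integer(seed)
  ), class = "puncta_sim_params")
}

disk_mask <- function(shape, cx, cy, r) {
  row <- matrix(seq_len(shape[1]), shape[1], shape[2])
  col <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  (row - cx)^2 + (col - cy)^2 <= r^2
}

# OR a disk into mask in place (bounding-box update; cheap for small disks)
stamp_disk <- function(mask, cx, cy, r) {
  ri <- max(1L, floor(cx - r)):min(nrow(mask), ceiling(cx + r))
  ci <- max(1L, floor(cy - r)):min(ncol(mask), ceiling(cy + r))
  sub <- outer((ri - cx)^2, (ci - cy)^2, `+`) <= r^2
  mask[ri, ci] <- mask[ri, ci] | sub
  mask
}

#' Generate a synthetic two-channel soma/puncta image
#'
#' Channel 1 carries the puncta (intensity 1 inside clusters), channel 2 the
#' structural soma marker (intensity 0.8 inside the soma); both get additive
#' Gaussian noise. Clusters are placed uniformly inside the soma and merged
#' by union until the covered fraction of the soma first reaches the target,
#' so the realized fraction overshoots by at most one cluster's area.
#'
#' @param params a [puncta_sim_params()].
#' @return an object of class `labeled_image_pair`: `puncta_channel`,
#'   `structural_channel` (matrices), `soma_mask`, `cluster_mask` (logical
#'   matrices, ground truth), and `metadata` with `realized_fraction` (%).
#' @examples
#' img <- generate_puncta_image(puncta_sim_params(target_fraction = 20))
#' img$metadata$realized_fraction
#' @export
generate_puncta_image <- function(params) {
  stopifnot(inherits(params, "puncta_sim_params"))
  shape <- params$image_shape
  cx <- (shape[1] + 1) / 2
  cy <- (shape[2] + 1) / 2
  soma <- disk_mask(shape, cx, cy, params$soma_radius_px)
  soma_area <- sum(soma)

  set.seed(substream_seed(params$seed, "puncta"))
  cluster <- matrix(FALSE, shape[1], shape[2])
  target_px <- params$target_fraction / 100 * soma_area
  placed <- 0L
  while (sum(cluster) < target_px) {
    if (placed >= params$n_clusters)
      stop_param("target_fraction unreachable with n_clusters clusters of this size")
    # uniform position within the soma disk
    repeat {
      px <- stats::runif(1, cx - params$soma_radius_px, cx + params$soma_radius_px)
      py <- stats::runif(1, cy - params$soma_radius_px, cy + params$soma_radius_px)
      if ((px - cx)^2 + (py - cy)^2 <= params$soma_radius_px^2) break
    }
    r <- params$cluster_radius_px_mean * stats::runif(1, 0.6, 1.4)
    cluster <- stamp_disk(cluster, px, py, r) & soma
    placed <- placed + 1L
  }

  puncta_ch <- cluster * 1.0
  struct_ch <- soma * 0.8
  if (params$channel_noise_sd > 0) {
    set.seed(substream_seed(params$seed, "puncta_noise"))
    puncta_ch <- puncta_ch + matrix(stats::rnorm(prod(shape), 0, params$channel_noise_sd),
                                    shape[1], shape[2])
    struct_ch <- struct_ch + matrix(stats::rnorm(prod(shape), 0, params$channel_noise_sd),
                                    shape[1], shape[2])
  }
  puncta_ch <- pmax(puncta_ch, 0)
  struct_ch <- pmax(struct_ch, 0)

  structure(list(
    puncta_channel = puncta_ch,
    structural_channel = struct_ch,
    soma_mask = soma,
    cluster_mask = cluster,
    pixel_size = NULL,
    provided_soma_mask = NULL,
    metadata = list(
      ground_truth = unclass(params),
      realized_fraction = 100 * sum(cluster) / soma_area,
      n_clusters_placed = placed
    )
  ), class = "labeled_image_pair")
}

#' Construct an image pair from raw channels
#'
#' Entry point for real (or externally generated) two-channel images.
#'
#' @param puncta_channel,structural_channel numeric matrices of equal shape;
#'   `structural_channel` may be `NULL` when a soma mask is supplied.
#' @param soma_mask optional logical matrix: a pre-drawn somatic region that
#'   bypasses structural-channel segmentation.
#' @param pixel_size optional pixel size (um/px), metadata only.
#' @return a `labeled_image_pair` (without ground-truth masks).
#' @export
image_pair <- function(puncta_channel, structural_channel = NULL,
                       soma_mask = NULL, pixel_size = NULL) {
  if (is.null(structural_channel) && is.null(soma_mask))
    stop_param("need a structural channel or a provided soma mask")
  if (!is.null(structural_channel) &&
      !identical(dim(puncta_channel), dim(structural_channel)))
    stop_param("channels must have the same shape")
  if (any(puncta_channel < 0, na.rm = TRUE))
    stop_param("intensities must be >= 0")
  structure(list(
    puncta_channel = puncta_channel,
    structural_channel = structural_channel,
    soma_mask = NULL,
    cluster_mask = NULL,
    pixel_size = pixel_size,
    provided_soma_mask = soma_mask,
    metadata = list()
  ), class = "labeled_image_pair")
}
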