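#' Somatic mask from the structural channel
#'
#' Returns the provided mask unchanged when one is attached to the pair;
#' otherwise thresholds the structural (MAP-2-like) channel by Otsu's
#' method, keeps the largest connected component and fills holes.
#'
#' @param pair a `labeled_image_pair`.
#' @return logical matrix, the somatic region.
#' @export
soma_mask <- function(pair) {
  stopifnot(inherits(pair, "labeled_image_pair"))
  if (!is.null(pair$provided_soma_mask)) {
    m <- pair$provided_soma_mask
    storage.mode(m) <- "logical"
    return(m)
  }
  ch <- pair$structural_channel
  if (is.null(ch)) stop_param("no structural channel and no provided mask")
  rng <- range(ch)
  if (diff(rng) == 0) stop_param("structural channel is constant; no soma found")
  img <- EBImage::Image((ch - rng[1]) / diff(rng))
  thr <- EBImage::otsu(img)
  bw <- img > thr
  if (sum(bw) == 0) stop_param("empty mask after thresholding")
  lab <- EBImage::bwlabel(bw)
  sizes <- tabulate(as.integer(lab[lab > 0]))
  biggest <- which.max(sizes)
  comp <- EBImage::fillHull(EBImage::Image(lab == biggest))
  matrix(as.logical(comp), nrow(ch), ncol(ch))
}

#' Segment channel clusters and compute the clusterization index
#'
#' Within the somatic mask, the puncta channel is thresholded by Otsu's
#' method restricted to somatic pixels (plus an optional offset for
#' sensitivity analysis); objects smaller than `min_size_px` are discarded
#' as shot noise, and connected components are labelled. The clusterization
#' index is the percentage of somatic area covered by suprathreshold
#' cluster pixels — the fraction of somatic membrane occupied by channel
#' clusters.
#'
#' @param pair a `labeled_image_pair`.
#' @param mask logical somatic mask (default [soma_mask()] of the pair).
#' @param offset additive threshold offset on the normalized intensity
#'   scale.
#' @param min_size_px minimum object size kept (px).
#' @return an object of class `cluster_result`: `soma_area_px`,
#'   `cluster_area_px`, `index_pct`, `cluster_count`, `label_mask`.
#' @export
segment_clusters <- function(pair, mask = soma_mask(pair), offset = 0,
                             min_size_px = 4) {
  stopifnot(inherits(pair, "labeled_image_pair"))
  storage.mode(mask) <- "logical"
  soma_area <- sum(mask)
  if (soma_area == 0) stop_param("empty soma mask")
  ch <- pair$puncta_channel
  vals <- ch[mask]
  rng <- range(vals)
  empty <- diff(rng) == 0
  if (!empty) {
    scaled <- (ch - rng[1]) / diff(rng)
    thr <- otsu_threshold(scaled[mask]) + offset
    bw <- scaled > thr & mask
  } else {
    bw <- matrix(FALSE, nrow(ch), ncol(ch))
  }
  lab <- EBImage::bwlabel(EBImage::Image(bw))
  if (max(lab) > 0 && min_size_px > 1) {
    sizes <- tabulate(as.integer(lab[lab > 0]), nbins = max(lab))
    drop <- which(sizes < min_size_px)
    if (length(drop)) lab <- EBImage::rmObjects(lab, drop, reenumerate = TRUE)
  }
  lab <- matrix(as.integer(lab), nrow(ch), ncol(ch))
  area <- sum(lab > 0)
  structure(list(
    soma_area_px = soma_area,
    cluster_area_px = area,
    index_pct = 100 * area / soma_area,
    cluster_count = max(lab),
    label_mask = lab
  ), class = "cluster_result")
}

# Otsu threshold of a sample of intensities in [0, 1]; histogram-based,
# same criterion EBImage::otsu uses but applicable to masked (non-image)
# pixel sets
otsu_threshold <- function(x, levels = 256) {
  h <- tabulate(pmin(levels, 1L + as.integer(x * (levels - 1))), nbins = levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(levels))
  mu_t <- mu[levels]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  (which.max(sigma_b) - 1) / (levels - 1)
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Clusterization: %d clusters, %d / %d px => index %.2f %%\n",
              x$cluster_count, x$cluster_area_px, x$soma_area_px, x$index_pct))
  invisible(x)
}

#' Clusterization index for a cohort of images
#'
#' @param pairs list of `labeled_image_pair`.
#' @param ... passed to [segment_clusters()].
#' @return data frame: `image`, `soma_area_px`, `cluster_area_px`,
#'   `index_pct`, `cluster_count`.
#' @export
clusterize_cohort <- function(pairs, ...) {
  rows <- lapply(seq_along(pairs), function(i) {
    r <- segment_clusters(pairs[[i]], ...)
    data.frame(image = i, soma_area_px = r$soma_area_px,
               cluster_area_px = r$cluster_area_px,
               index_pct = r$index_pct, cluster_count = r$cluster_count)
  })
  do.call(rbind, rows)
}
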