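#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible substream seed
#'
#' Generators draw every sweep, ROI or image from its own RNG substream so
#' that a single top-level seed fixes the whole dataset while individual
#' pieces stay independently reproducible. The substream seed is a small
#' integer hash of the top-level seed and a stream label, kept below 2^31.
#'
#' @param seed integer top-level seed.
#' @param key character or integer label of the substream.
#' @return integer seed suitable for [set.seed()].
#' @export
substream_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- as.double(seed %% 2147483629)
  for (c in utf8ToInt(paste0("s", key))) {
    h <- (h * 31 + c) %% 2147483629
  }
  as.integer(h)
}

# standard error of the mean; NA-dropping, NA for n < 2
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# trapezoidal integral of y(t) on an arbitrary grid
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(t))
}

stop_param <- function(...) stop(..., call. = FALSE)
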