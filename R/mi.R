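#' Mutual information between two grayscale images
#'
#' Computes Shannon mutual information, in bits, from the joint histogram of
#' the two images over `bins` equal-width bins per axis (each image binned
#' over its own value range).  Pixel pairs in which either value is missing
#' (e.g. outside the resampling overlap) are excluded, so the statistic is
#' taken over the overlap region only.
#'
#' @param fixed,moving `gray8` [raster_image]s (or plain numeric matrices) of
#'   identical size.
#' @param bins number of histogram bins per axis (>= 2).
#' @return mutual information in bits (non-negative, symmetric).
#' @export
mutual_information <- function(fixed, moving, bins = 50) {
  a <- if (is_raster_image(fixed)) fixed$pixels else fixed
  b <- if (is_raster_image(moving)) moving$pixels else moving
  if (!identical(dim(a), dim(b)))
    stop(sprintf("image size mismatch: %s vs %s",
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  if (bins < 2L) stop("`bins` must be >= 2")
  mi_from_values(as.numeric(a), as.numeric(b), as.integer(bins))
}

# MI (bits) for two numeric vectors; non-finite pairs dropped.
mi_from_values <- function(a, b, bins) {
  ok <- is.finite(a) & is.finite(b)
  if (!any(ok)) return(0)
  ar <- range(a[ok]); br <- range(b[ok])
  J <- cpp_joint_hist(a, b, bins, ar[1], ar[2], br[1], br[2])
  mi_from_joint(J)
}

# MI (bits) from a joint count matrix.
mi_from_joint <- function(J) {
  n <- sum(J)
  if (n == 0) return(0)
  p <- J / n
  px <- rowSums(p)
  py <- colSums(p)
  nz <- which(p > 0, arr.ind = TRUE)
  sum(p[nz] * log2(p[nz] / (px[nz[, 1]] * py[nz[, 2]])))
}

# Marginal entropy (bits) of one image under the same binning.
binned_entropy <- function(x, bins = 50) {
  v <- as.numeric(if (is_raster_image(x)) x$pixels else x)
  v <- v[is.finite(v)]
  if (!length(v)) return(0)
  r <- range(v)
  if (r[1] == r[2]) return(0)
  idx <- pmin(as.integer((v - r[1]) / (r[2] - r[1]) * bins), bins - 1L) + 1L
  p <- tabulate(idx, bins)
  p <- p[p > 0] / length(v)
  -sum(p * log2(p))
}
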