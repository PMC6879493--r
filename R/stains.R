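#' H-DAB stain matrix
#'
#' Ordered set of unit stain vectors in optical-density (R, G, B) space.
#' Defaults are the standard H-DAB colour-decomposition vectors:
#' `[0.650, 0.704, 0.286]` for Hematoxylin and `[0.072, 0.954, 0.283]` for
#' DAB, each renormalised to unit Euclidean length, with the residual (third)
#' vector completing the basis via [complete_residual()].
#'
#' @param h_vec length-3 optical-density vector for Hematoxylin.
#' @param dab_vec length-3 optical-density vector for DAB.
#' @param residual_vec optional length-3 residual vector; computed from the
#'   other two when `NULL`.
#' @return a `stain_matrix`: a 3x3 matrix whose columns are the unit vectors
#'   `h`, `dab`, `residual`, mapping stain densities to OD (`od = M %*% d`).
#' @export
stain_matrix <- function(h_vec = c(0.650, 0.704, 0.286),
                         dab_vec = c(0.072, 0.954, 0.283),
                         residual_vec = NULL) {
  unit <- function(v) {
    n <- sqrt(sum(v^2))
    if (n == 0) stop("stain vector must be nonzero")
    v / n
  }
  h <- unit(as.numeric(h_vec))
  d <- unit(as.numeric(dab_vec))
  r <- if (is.null(residual_vec)) complete_residual(h, d)
       else unit(as.numeric(residual_vec))
  M <- cbind(h = h, dab = d, residual = r)
  rownames(M) <- c("R", "G", "B")
  if (!is.finite(rcond(M)) || rcond(M) < 1e-12)
    stop("stain matrix is singular; the three stain vectors must be independent")
  structure(M, class = c("stain_matrix", "matrix"))
}

#' Complete a two-stain basis with a residual vector
#'
#' The residual is the normalised cross product of the two unit stain
#' vectors, so it is exactly orthogonal to both and the three-vector basis is
#' maximally well conditioned.  Its sign is chosen to make the component sum
#' positive, which puts all components in the non-negative OD octant
#' whenever the cross product is single-signed.
#'
#' @param h_vec,dab_vec length-3 stain vectors (nonzero, not parallel).
#' @return unit length-3 residual vector.
#' @export
complete_residual <- function(h_vec, dab_vec) {
  a <- as.numeric(h_vec); b <- as.numeric(dab_vec)
  cp <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  n <- sqrt(sum(cp^2))
  if (n < 1e-12) stop("stain vectors are parallel; no residual direction")
  cp <- cp / n
  if (sum(cp) < 0) cp <- -cp
  cp
}

#' Convert an RGB image to optical density
#'
#' Beer-Lambert conversion per channel: `OD_c = -log10(max(I_c, 1) /
#' background)`.  Intensities are clamped at 1 to avoid infinite densities,
#' and values above background map to OD 0.
#'
#' @param img an `rgb8` [raster_image].
#' @param background background (blank slide) intensity, default 255.
#' @return an `od_float` [raster_image] with 3 planes.
#' @export
rgb_to_od <- function(img, background = 255) {
  stopifnot_raster(img, "rgb8")
  stopifnot(background > 0)
  od <- -log10(pmax(img$pixels, 1) / background)
  od[od < 0] <- 0
  raster_image(od, "od_float")
}

#' Colour deconvolution into stain densities
#'
#' Per-pixel solve of the 3x3 linear system `densities = M^-1 od`, separating
#' Hematoxylin, DAB and residual densities.
#'
#' @param od an `od_float` [raster_image] with 3 planes (see [rgb_to_od()]).
#' @param m a [stain_matrix].
#' @return named list of three `od_float` [raster_image] planes: `h`, `dab`,
#'   `residual`.  Densities are returned unclipped; use [stain_channel_8bit()]
#'   for the thresholding-convention 8-bit pseudo-channels.
#' @export
deconvolve <- function(od, m) {
  stopifnot_raster(od, "od_float")
  stopifnot(inherits(m, "stain_matrix"))
  d <- dim(od$pixels)
  if (length(d) != 3L || d[3] != 3L) stop("`od` must have 3 planes")
  P <- matrix(od$pixels, ncol = 3L)          # N x 3, columns R,G,B
  Minv <- solve(unclass(m))
  D <- P %*% t(Minv)                         # N x 3, columns h,dab,residual
  mk <- function(k) {
    v <- matrix(D[, k], d[1], d[2])
    # densities may carry small negatives from noise; clipped downstream
    structure(list(pixels = v, channel_kind = "od_float"),
              class = "raster_image")
  }
  list(h = mk(1), dab = mk(2), residual = mk(3))
}

#' 8-bit pseudo-channel of a stain density plane
#'
#' ImageJ colour-deconvolution convention: `255 * 10^(-density)`, so 255
#' means no stain and darker values mean more stain.  Negative densities from
#' the linear solve are clipped to 0 first.
#'
#' @param plane an `od_float` density [raster_image] (one plane of
#'   [deconvolve()]).
#' @return a `gray8` [raster_image].
#' @export
stain_channel_8bit <- function(plane) {
  v <- pmax(plane$pixels, 0)
  g <- round(255 * 10^(-v))
  g[g < 0] <- 0; g[g > 255] <- 255
  raster_image(g, "gray8")
}

#' Threshold a DAB pseudo-channel into a binary positivity mask
#'
#' A pixel is DAB-positive when its 8-bit pseudo-channel value is strictly
#' below `threshold` (darker = more stain).
#'
#' @param dab_8bit a `gray8` [raster_image] (see [stain_channel_8bit()]).
#' @param threshold 8-bit threshold in `[0, 255]`.
#' @return a `binary` [raster_image].
#' @export
dab_mask <- function(dab_8bit, threshold) {
  stopifnot_raster(dab_8bit, "gray8")
  stopifnot(threshold >= 0, threshold <= 255)
  raster_image((dab_8bit$pixels < threshold) * 1, "binary")
}

#' Threshold an RGB image into a tissue mask
#'
#' The image is converted to 8-bit grayscale (Rec. 601 luminance) and pixels
#' strictly darker than `tissue_threshold` are marked as tissue.
#'
#' @param img an `rgb8` [raster_image].
#' @param tissue_threshold 8-bit threshold in `[0, 255]`.
#' @return a `binary` [raster_image].
#' @export
tissue_mask <- function(img, tissue_threshold) {
  stopifnot(tissue_threshold >= 0, tissue_threshold <= 255)
  g <- as_gray(img)
  raster_image((g$pixels < tissue_threshold) * 1, "binary")
}

#' Per-run threshold configuration
#'
#' The same marker's threshold must be identical across all samples in a run;
#' holding them in one validated object enforces that.
#'
#' @param dab_threshold named numeric vector of per-marker 8-bit DAB
#'   pseudo-channel thresholds.
#' @param hematoxylin_threshold 8-bit threshold for the hematoxylin channel.
#' @param tissue_threshold 8-bit grayscale threshold for the tissue mask.
#' @return an object of class `threshold_config`.
#' @export
threshold_config <- function(dab_threshold, hematoxylin_threshold = 160,
                             tissue_threshold = 200) {
  vals <- c(dab_threshold, hematoxylin_threshold, tissue_threshold)
  if (any(vals < 0 | vals > 255)) stop("all thresholds must lie in [0, 255]")
  structure(list(dab_threshold = dab_threshold,
                 hematoxylin_threshold = hematoxylin_threshold,
                 tissue_threshold = tissue_threshold),
            class = "threshold_config")
}
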