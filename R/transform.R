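#' Similarity transform (rotation + isotropic scale + translation)
#'
#' Maps moving-image coordinates into fixed-image coordinates:
#' `x_f = c + t + s * R(theta) * (x_m - c)` where `c` is the centre, `t` the
#' translation `(tx, ty)` in pixels, `s` the isotropic scale and `R` a
#' counter-clockwise rotation by `rotation_deg` degrees (in the x = column,
#' y = row, top-left-origin convention).
#'
#' @param rotation_deg rotation in degrees.
#' @param scale isotropic scale factor, strictly positive.
#' @param tx,ty translation in pixels.
#' @param center length-2 `(x, y)` centre about which rotation and scale act.
#' @return An object of class `similarity_transform`.
#' @export
similarity_transform <- function(rotation_deg = 0, scale = 1, tx = 0, ty = 0,
                                 center = c(0, 0)) {
  stopifnot(is.numeric(scale), length(scale) == 1L, is.finite(scale))
  if (scale <= 0) stop("`scale` must be > 0")
  stopifnot(length(center) == 2L, is.finite(rotation_deg),
            is.finite(tx), is.finite(ty))
  structure(list(rotation_deg = as.numeric(rotation_deg),
                 scale = as.numeric(scale),
                 tx = as.numeric(tx), ty = as.numeric(ty),
                 center = as.numeric(center)),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf(
    "<similarity_transform rot=%.4f deg  scale=%.5f  t=(%.3f, %.3f) px  centre=(%.1f, %.1f)>\n",
    x$rotation_deg, x$scale, x$tx, x$ty, x$center[1], x$center[2]))
  invisible(x)
}

#' Affine matrix of a similarity transform
#'
#' @param t a [similarity_transform].
#' @return 3x3 homogeneous matrix acting on column vectors `(x, y, 1)`.
#' @export
st_matrix <- function(t) {
  th <- t$rotation_deg * pi / 180
  A <- t$scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  b <- t$center + c(t$tx, t$ty) - A %*% t$center
  rbind(cbind(A, b), c(0, 0, 1))
}

#' Map points through a similarity transform
#'
#' @param t a [similarity_transform].
#' @param xy n x 2 matrix of `(x, y)` coordinates (moving frame).
#' @return n x 2 matrix of fixed-frame coordinates.
#' @export
transform_points <- function(t, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2L)
  M <- st_matrix(t)
  out <- cbind(xy, 1) %*% t(M)
  out[, 1:2, drop = FALSE]
}

#' Invert a similarity transform
#'
#' The inverse has the same centre; composing a transform with its inverse is
#' the identity map.
#'
#' @param t a [similarity_transform].
#' @return the inverse [similarity_transform].
#' @export
st_invert <- function(t) {
  th <- -t$rotation_deg * pi / 180
  s <- 1 / t$scale
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  tnew <- -s * as.numeric(R %*% c(t$tx, t$ty))
  similarity_transform(-t$rotation_deg, s, tnew[1], tnew[2], t$center)
}

#' Compose two similarity transforms
#'
#' Returns the transform equivalent to applying `t1` first, then `t2`; the
#' result uses `t2`'s centre.
#'
#' @param t2,t1 [similarity_transform]s.
#' @return a [similarity_transform].
#' @export
st_compose <- function(t2, t1) {
  M <- st_matrix(t2) %*% st_matrix(t1)
  s <- sqrt(M[1, 1]^2 + M[2, 1]^2)
  th <- atan2(M[2, 1], M[1, 1]) * 180 / pi
  c0 <- t2$center
  A <- M[1:2, 1:2]
  b <- M[1:2, 3]
  tt <- b - c0 + as.numeric(A %*% c0)
  similarity_transform(th, s, tt[1], tt[2], c0)
}

#' Resample an image through a similarity transform
#'
#' Inverse-mapped resampling of `img` (moving frame) onto a fixed-frame grid
#' of shape `out_shape`.  Intensity images (`rgb8`, `gray8`, `od_float`) use
#' bilinear interpolation with out-of-domain pixels filled with background
#' white (255, or 0 for `od_float`); `binary` masks use nearest-neighbour
#' with a 0 fill.
#'
#' @param img a [raster_image].
#' @param t a [similarity_transform] mapping `img` coordinates to the output
#'   frame.
#' @param out_shape `(h, w)` of the output grid; defaults to `dim(img)`.
#' @return a [raster_image] of the same channel kind.
#' @export
apply_transform <- function(img, t, out_shape = NULL) {
  stopifnot_raster(img)
  stopifnot(inherits(t, "similarity_transform"))
  if (is.null(out_shape)) out_shape <- dim(img$pixels)[1:2]
  stopifnot(length(out_shape) == 2L, all(out_shape >= 1))
  h_out <- as.integer(out_shape[1]); w_out <- as.integer(out_shape[2])
  th <- t$rotation_deg * pi / 180
  bilinear <- img$channel_kind != "binary"
  fill <- switch(img$channel_kind, rgb8 = 255, gray8 = 255, od_float = 0,
                 binary = 0)
  one_plane <- function(m) {
    out <- cpp_resample_similarity(m, h_out, w_out, th, t$scale, t$tx, t$ty,
                                   t$center[1], t$center[2], bilinear)
    out[is.na(out)] <- fill
    out
  }
  px <- img$pixels
  out <- if (length(dim(px)) == 3L) {
    planes <- lapply(seq_len(dim(px)[3]), function(k) one_plane(px[, , k]))
    array(unlist(planes), dim = c(h_out, w_out, dim(px)[3]))
  } else {
    one_plane(px)
  }
  raster_image(out, img$channel_kind)
}

# Resample a plain numeric matrix, keeping NA outside the moving domain.
# Internal workhorse for the MI metric (overlap-only statistics).
resample_overlap <- function(m, rotation_deg, scale, tx, ty, center, out_shape) {
  cpp_resample_similarity(m, as.integer(out_shape[1]), as.integer(out_shape[2]),
                          rotation_deg * pi / 180, scale, tx, ty,
                          center[1], center[2], TRUE)
}
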