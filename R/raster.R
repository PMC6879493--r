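#' Raster image container
#'
#' The universal pixel currency of the pipeline: a 2-D array of either RGB
#' triplets or scalar values, with an explicit channel kind.
#'
#' Coordinate convention, used everywhere in the package: `x` = column,
#' `y` = row, origin at the top-left corner, 0-based, with pixel centres at
#' integer coordinates.  Array storage is the usual R `[row, col]` layout, so
#' the pixel at `(x, y)` is `pixels[y + 1, x + 1]`.
#'
#' Channel kinds and their value ranges:
#' * `rgb8` — `h x w x 3` array, channels in `[0, 255]`.
#' * `gray8` — `h x w` matrix in `[0, 255]`.
#' * `od_float` — non-negative optical densities (matrix or 3-plane array).
#' * `binary` — `h x w` matrix in `{0, 1}`.
#'
#' @param pixels numeric matrix (`h x w`) or array (`h x w x 3`).
#' @param channel_kind one of `"rgb8"`, `"gray8"`, `"od_float"`, `"binary"`.
#' @return An object of class `raster_image`.
#' @export
raster_image <- function(pixels, channel_kind = c("rgb8", "gray8", "od_float", "binary")) {
  channel_kind <- match.arg(channel_kind)
  if (!is.numeric(pixels) && !is.logical(pixels))
    stop("`pixels` must be numeric")
  pixels <- if (is.logical(pixels)) {
    storage.mode(pixels) <- "double"
    pixels
  } else pixels
  d <- dim(pixels)
  if (is.null(d) || length(d) < 2L || d[1] < 1L || d[2] < 1L)
    stop("`pixels` must be a matrix or 3-channel array with positive dimensions")
  if (channel_kind == "rgb8") {
    if (length(d) != 3L || d[3] != 3L)
      stop("rgb8 images must be h x w x 3 arrays")
  } else if (channel_kind != "od_float" && length(d) != 2L) {
    stop(sprintf("%s images must be 2-D matrices", channel_kind))
  }
  rng <- range(pixels)
  if (channel_kind %in% c("rgb8", "gray8") && (rng[1] < 0 || rng[2] > 255))
    stop(sprintf("%s values must lie in [0, 255]", channel_kind))
  if (channel_kind == "binary" && !all(pixels %in% c(0, 1)))
    stop("binary values must lie in {0, 1}")
  if (channel_kind == "od_float" && rng[1] < 0)
    stop("od_float values must be >= 0")
  structure(list(pixels = pixels, channel_kind = channel_kind),
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image %dx%d %s>\n", ri_height(x), ri_width(x),
              x$channel_kind))
  invisible(x)
}

#' @export
dim.raster_image <- function(x) dim(x$pixels)

#' Image height / width in pixels
#' @param img a [raster_image].
#' @return integer count of rows (height) or columns (width).
#' @export
ri_height <- function(img) dim(img$pixels)[1]

#' @rdname ri_height
#' @export
ri_width <- function(img) dim(img$pixels)[2]

is_raster_image <- function(x) inherits(x, "raster_image")

stopifnot_raster <- function(img, kinds = NULL, arg = deparse(substitute(img))) {
  if (!is_raster_image(img))
    stop(sprintf("`%s` must be a raster_image", arg))
  if (!is.null(kinds) && !img$channel_kind %in% kinds)
    stop(sprintf("`%s` must have channel kind %s (got %s)", arg,
                 paste(kinds, collapse = "/"), img$channel_kind))
  invisible(img)
}

#' Convert an image to 8-bit grayscale
#'
#' RGB images are collapsed with Rec. 601 luminance
#' (0.299 R + 0.587 G + 0.114 B); grayscale and binary inputs are passed
#' through (binary is scaled to 0/255).
#'
#' @param img a [raster_image].
#' @return a `gray8` [raster_image].
#' @export
as_gray <- function(img) {
  stopifnot_raster(img)
  g <- switch(img$channel_kind,
    rgb8 = 0.299 * img$pixels[, , 1] + 0.587 * img$pixels[, , 2] +
           0.114 * img$pixels[, , 3],
    gray8 = img$pixels,
    binary = img$pixels * 255,
    od_float = stop("cannot convert od_float planes to gray8"))
  raster_image(g, "gray8")
}

#' Promote a grayscale image to rgb8
#' @param img a `gray8` or `binary` [raster_image].
#' @return an `rgb8` [raster_image] with three identical channels.
#' @export
as_rgb <- function(img) {
  stopifnot_raster(img)
  if (img$channel_kind == "rgb8") return(img)
  g <- if (img$channel_kind == "binary") img$pixels * 255 else img$pixels
  raster_image(array(rep(g, 3L), dim = c(dim(g), 3L)), "rgb8")
}

# Block-mean downsampling by a factor of 2 (odd trailing row/col dropped).
# Used to build the registration pyramid.
downsample_half <- function(m) {
  h <- nrow(m) %/% 2L
  w <- ncol(m) %/% 2L
  m <- m[seq_len(2L * h), seq_len(2L * w), drop = FALSE]
  0.25 * (m[seq(1, 2 * h, 2), seq(1, 2 * w, 2), drop = FALSE] +
          m[seq(2, 2 * h, 2), seq(1, 2 * w, 2), drop = FALSE] +
          m[seq(1, 2 * h, 2), seq(2, 2 * w, 2), drop = FALSE] +
          m[seq(2, 2 * h, 2), seq(2, 2 * w, 2), drop = FALSE])
}

# Separable box-ish Gaussian blur used by the synthetic generator; sigma in
# pixels.  stats::filter with a normalised Gaussian kernel, edges padded by
# replication.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  pad_apply <- function(mm) {
    top <- mm[rep(1L, r), , drop = FALSE]
    bot <- mm[rep(nrow(mm), r), , drop = FALSE]
    ext <- rbind(top, mm, bot)
    f <- stats::filter(ext, k, sides = 2)
    f[(r + 1L):(r + nrow(mm)), , drop = FALSE]
  }
  m2 <- pad_apply(m)
  t(pad_apply(t(m2)))
}
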