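# Shared fixture builders and independent oracles for the test suite.

# Textured grayscale test image: smooth blob + sinusoidal texture, values in
# [0, 255].  Deterministic in `seed`.
make_textured_gray <- function(h = 96, w = 96, seed = 1) {
  set.seed(seed)
  x <- matrix(rep(0:(w - 1), each = h), h, w)
  y <- matrix(rep(0:(h - 1), times = w), h, w)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  r <- sqrt((x - cx)^2 + (y - cy)^2)
  base <- 255 - 140 * (r < 0.35 * min(h, w))
  tex <- 25 * sin(x / 5 + stats::runif(1, 0, 6)) *
    cos(y / 7 + stats::runif(1, 0, 6))
  g <- pmin(pmax(round(base + tex), 0), 255)
  raster_image(g, "gray8")
}

make_textured_rgb <- function(h = 96, w = 96, seed = 1) {
  as_rgb(make_textured_gray(h, w, seed))
}

random_rgb8 <- function(h = 16, w = 16, seed = 1) {
  set.seed(seed)
  raster_image(array(sample(0:255, h * w * 3, replace = TRUE),
                     dim = c(h, w, 3)), "rgb8")
}

random_binary <- function(h = 64, w = 64, p = 0.5, seed = 1) {
  set.seed(seed)
  raster_image(matrix(as.numeric(stats::runif(h * w) < p), h, w), "binary")
}

# Independent MI oracle: explicit double loop over the joint histogram of
# pre-binned integer label vectors.  No shared code with the implementation.
mi_oracle_bits <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  n <- length(labels_a)
  ua <- sort(unique(labels_a)); ub <- sort(unique(labels_b))
  total <- 0
  for (a in ua) for (b in ub) {
    pab <- sum(labels_a == a & labels_b == b) / n
    if (pab > 0) {
      pa <- sum(labels_a == a) / n
      pb <- sum(labels_b == b) / n
      total <- total + pab * log2(pab / (pa * pb))
    }
  }
  total
}

# Independent point-in-polygon oracle: winding-angle summation per pixel
# centre (different formulation from the implementation's even-odd ray cast).
rasterize_oracle <- function(vertices, h, w) {
  m <- matrix(0, h, w)
  n <- nrow(vertices)
  for (row in seq_len(h)) for (col in seq_len(w)) {
    px <- col - 1; py <- row - 1
    ang <- 0
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      a1 <- atan2(vertices[i, 2] - py, vertices[i, 1] - px)
      a2 <- atan2(vertices[j, 2] - py, vertices[j, 1] - px)
      d <- a2 - a1
      if (d > pi) d <- d - 2 * pi
      if (d < -pi) d <- d + 2 * pi
      ang <- ang + d
    }
    if (abs(ang) > pi) m[row, col] <- 1
  }
  m
}

# Forward Beer-Lambert synthesis from density planes (continuous intensity
# unless quantise = TRUE), independent of the package's generator.
synthesize_rgb_from_densities <- function(h_plane, dab_plane, m = stain_matrix(),
                                          quantise = FALSE) {
  M <- unclass(m)
  d <- dim(h_plane)
  px <- array(0, dim = c(d, 3))
  for (c3 in 1:3) {
    od <- M[c3, 1] * h_plane + M[c3, 2] * dab_plane
    ic <- 255 * 10^(-od)
    if (quantise) ic <- pmin(pmax(round(ic), 0), 255)
    px[, , c3] <- ic
  }
  px
}
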