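test_that("optical-density conversion matches closed forms", {
  px <- array(255, c(2, 2, 3))
  expect_true(all(rgb_to_od(raster_image(px, "rgb8"))$pixels == 0))
  # I = 26 -> OD = -log10(26/255) = 0.99139...
  px26 <- array(26, c(1, 1, 3))
  expect_equal(as.numeric(rgb_to_od(raster_image(px26, "rgb8"))$pixels),
               rep(-log10(26 / 255), 3), tolerance = 1e-12)
  # I = 0 is clamped to 1 -> OD = log10(255)
  px0 <- array(0, c(1, 1, 3))
  expect_equal(as.numeric(rgb_to_od(raster_image(px0, "rgb8"))$pixels),
               rep(log10(255), 3), tolerance = 1e-12)
})

test_that("the residual vector completes the basis orthogonally", {
  expect_equal(complete_residual(c(1, 0, 0), c(0, 1, 0)), c(0, 0, 1))
  M <- stain_matrix()
  r <- M[, "residual"]
  expect_lt(abs(sum(r * M[, "h"])), 1e-12)
  expect_lt(abs(sum(r * M[, "dab"])), 1e-12)
  expect_equal(sqrt(sum(r^2)), 1, tolerance = 1e-12)
  # antisymmetry of the cross product is absorbed by the sign handling
  r_swapped <- complete_residual(M[, "dab"], M[, "h"])
  expect_equal(abs(r_swapped), abs(unname(r)), tolerance = 1e-12)
  expect_error(complete_residual(c(1, 1, 0), c(2, 2, 0)), "parallel")
})

test_that("the default stain matrix uses the H-DAB unit vectors", {
  M <- stain_matrix()
  expect_equal(M[, "h"], c(0.650, 0.704, 0.286) / sqrt(sum(c(0.650, 0.704, 0.286)^2)),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(M[, "dab"], c(0.072, 0.954, 0.283) / sqrt(sum(c(0.072, 0.954, 0.283)^2)),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("deconvolution inverts the forward stain model", {
  M <- stain_matrix()
  # single pixel with densities (H = 0.5, DAB = 0.3, residual = 0)
  od_vec <- unclass(M) %*% c(0.5, 0.3, 0)
  od <- raster_image(array(rep(od_vec, each = 1), c(1, 1, 3)), "od_float")
  d <- deconvolve(od, M)
  expect_equal(as.numeric(d$h$pixels), 0.5, tolerance = 1e-6)
  expect_equal(as.numeric(d$dab$pixels), 0.3, tolerance = 1e-6)
  expect_equal(as.numeric(d$residual$pixels), 0, tolerance = 1e-6)
  # white pixel: zero densities
  white <- rgb_to_od(raster_image(array(255, c(1, 1, 3)), "rgb8"))
  dw <- deconvolve(white, M)
  expect_equal(as.numeric(dw$h$pixels), 0)
  expect_equal(as.numeric(dw$dab$pixels), 0)
  # pure hematoxylin pixel separates cleanly
  od_h <- raster_image(array(unclass(M)[, "h"] * 1.0, c(1, 1, 3)), "od_float")
  dh <- deconvolve(od_h, M)
  expect_equal(as.numeric(dh$dab$pixels), 0, tolerance = 1e-6)
  expect_equal(as.numeric(dh$h$pixels), 1, tolerance = 1e-6)
})

test_that("continuous-intensity Beer-Lambert round trip is exact", {
  set.seed(10)
  h <- matrix(runif(400, 0, 1), 20, 20)
  dab <- matrix(runif(400, 0, 1), 20, 20)
  px <- synthesize_rgb_from_densities(h, dab, quantise = FALSE)
  od <- raster_image(-log10(pmax(px, 1e-300) / 255), "od_float")
  d <- deconvolve(od, stain_matrix())
  expect_lt(max(abs(d$h$pixels - h)), 5e-3)
  expect_lt(max(abs(d$dab$pixels - dab)), 5e-3)
})

test_that("8-bit quantised round-trip error stays within the quantisation budget", {
  set.seed(11)
  h <- matrix(runif(2500, 0, 0.8), 50, 50)
  dab <- matrix(runif(2500, 0, 0.8), 50, 50)
  px <- synthesize_rgb_from_densities(h, dab, quantise = TRUE)
  d <- deconvolve(rgb_to_od(raster_image(px, "rgb8")), stain_matrix())
  # rounding to the 8-bit grid perturbs each channel OD by at most
  # 0.5/(I ln 10); propagate the per-pixel bound through the matrix inverse
  Minv_norm <- norm(solve(unclass(stain_matrix())), type = "I")
  imin <- pmax(apply(px, c(1, 2), min), 1)
  budget <- Minv_norm * (0.5 / (imin * log(10)) + 1e-6)
  expect_true(all(abs(d$h$pixels - h) <= budget))
  expect_true(all(abs(d$dab$pixels - dab) <= budget))
})

test_that("DAB masks follow the below-threshold polarity and its boundaries", {
  g <- raster_image(matrix(c(0, 100, 200, 255), 2, 2), "gray8")
  expect_true(all(dab_mask(g, 0)$pixels == 0))          # nothing below 0
  m255 <- dab_mask(g, 255)
  expect_equal(m255$pixels, matrix(c(1, 1, 1, 0), 2, 2), ignore_attr = TRUE)
  m150 <- dab_mask(g, 150)
  expect_equal(sum(m150$pixels), 2)
})

test_that("masks are monotone in the threshold", {
  ch <- stain_channel_8bit(deconvolve(rgb_to_od(random_rgb8(32, 32, seed = 6)),
                                      stain_matrix())$dab)
  prev <- dab_mask(ch, 0)$pixels
  for (thr in seq(25, 255, by = 25)) {
    cur <- dab_mask(ch, thr)$pixels
    expect_true(all(cur >= prev))   # raising threshold never removes pixels
    prev <- cur
  }
})

test_that("the DAB pseudo-channel is invariant to hematoxylin density", {
  set.seed(13)
  dab <- matrix(runif(100, 0, 0.8), 10, 10)
  h1 <- matrix(runif(100, 0, 0.3), 10, 10)
  h2 <- h1 + 0.4
  ch1 <- stain_channel_8bit(deconvolve(rgb_to_od(raster_image(
    synthesize_rgb_from_densities(h1, dab, quantise = TRUE), "rgb8")),
    stain_matrix())$dab)
  ch2 <- stain_channel_8bit(deconvolve(rgb_to_od(raster_image(
    synthesize_rgb_from_densities(h2, dab, quantise = TRUE), "rgb8")),
    stain_matrix())$dab)
  # identical up to the 8-bit quantisation of the two syntheses
  expect_lte(max(abs(ch1$pixels - ch2$pixels)), 3)
})

test_that("tissue masks capture dark pixels of the grayscale image", {
  white <- raster_image(array(255, c(8, 8, 3)), "rgb8")
  expect_true(all(tissue_mask(white, 200)$pixels == 0))
  px <- array(255, c(8, 8, 3))
  px[, 1:4, ] <- 0
  half <- tissue_mask(raster_image(px, "rgb8"), 128)
  expect_equal(half$pixels[, 1:4], matrix(1, 8, 4), ignore_attr = TRUE)
  expect_equal(half$pixels[, 5:8], matrix(0, 8, 4), ignore_attr = TRUE)
})

test_that("threshold configuration validates its ranges", {
  expect_error(threshold_config(c(pERK = 300)), "\\[0, 255\\]")
  tc <- threshold_config(c(pERK = 101, p4EBP1 = 96))
  expect_equal(spaRQ:::marker_threshold(tc, "p4EBP1"), 96)
  expect_error(spaRQ:::marker_threshold(tc, "pAKT"), "no DAB threshold")
})
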