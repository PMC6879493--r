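test_that("an axis-aligned square rasterises to its exact pixel count", {
  roi <- roi_polygon("sq", rbind(c(-0.5, -0.5), c(9.5, -0.5),
                                 c(9.5, 9.5), c(-0.5, 9.5)))
  m <- rasterize_roi(roi, c(20, 20))
  expect_equal(sum(m$pixels), 100)
  expect_true(all(m$pixels[1:10, 1:10] == 1))
})

test_that("triangle area is within discretisation error of the analytic value", {
  roi <- roi_polygon("tri", rbind(c(0, 0), c(4, 0), c(0, 4)))
  m <- rasterize_roi(roi, c(10, 10))
  expect_lte(abs(sum(m$pixels) - 8), 2)
})

test_that("rasterisation agrees with a winding-angle oracle", {
  set.seed(33)
  for (rep in 1:5) {
    # star-shaped random polygon (simple by construction)
    k <- sample(5:9, 1)
    ang <- sort(runif(k, 0, 2 * pi))
    rad <- runif(k, 3, 11)
    v <- cbind(x = 12 + rad * cos(ang), y = 12 + rad * sin(ang))
    roi <- roi_polygon("rand", v)
    expect_equal(rasterize_roi(roi, c(24, 24))$pixels,
                 rasterize_oracle(v, 24, 24), ignore_attr = TRUE)
  }
})

test_that("sub-pixel slivers and out-of-frame polygons warn and are empty", {
  sliver <- roi_polygon("sliver", rbind(c(0.1, 0.2), c(5, 0.2), c(5, 0.4)))
  expect_warning(m <- rasterize_roi(sliver, c(10, 10)), "empty")
  expect_equal(sum(m$pixels), 0)
  outside <- roi_polygon("out", rbind(c(100, 100), c(110, 100), c(100, 110)))
  expect_warning(m2 <- rasterize_roi(outside, c(20, 20)), "empty")
  expect_equal(sum(m2$pixels), 0)
})

test_that("area percentages follow saturation and disjointness", {
  roi <- raster_image(matrix(1, 8, 8), "binary")
  tissue <- random_binary(8, 8, p = 0.7, seed = 2)
  expect_equal(area_pct(tissue, roi, tissue), 100)
  empty <- raster_image(matrix(0, 8, 8), "binary")
  expect_equal(area_pct(empty, roi, tissue), 0)
  expect_error(area_pct(tissue, empty, tissue), "no tissue")
})

test_that("area and overlap match a per-pixel counting oracle exactly", {
  for (seed in 1:10) {
    a <- random_binary(64, 64, p = 0.4, seed = seed)
    b <- random_binary(64, 64, p = 0.3, seed = seed + 500)
    roi <- random_binary(64, 64, p = 0.8, seed = seed + 1000)
    tis <- random_binary(64, 64, p = 0.9, seed = seed + 1500)
    if (sum(roi$pixels * tis$pixels) == 0) next
    # slow explicit loop oracle
    na <- 0; nb <- 0; nol <- 0; nd <- 0
    for (i in 1:64) for (j in 1:64) {
      if (roi$pixels[i, j] == 1 && tis$pixels[i, j] == 1) {
        nd <- nd + 1
        if (a$pixels[i, j] == 1) na <- na + 1
        if (b$pixels[i, j] == 1) nb <- nb + 1
        if (a$pixels[i, j] == 1 && b$pixels[i, j] == 1) nol <- nol + 1
      }
    }
    ol <- overlap_pct(a, b, roi, tis)
    expect_identical(ol$a_pct, 100 * na / nd)
    expect_identical(ol$b_pct, 100 * nb / nd)
    expect_identical(ol$ol_pct, 100 * nol / nd)
    expect_identical(area_pct(a, roi, tis), ol$a_pct)
    expect_lte(ol$ol_pct, min(ol$a_pct, ol$b_pct))
  }
})

test_that("the ROI-area denominator option rescales percentages", {
  a <- random_binary(20, 20, p = 0.5, seed = 11)
  roi <- raster_image(matrix(1, 20, 20), "binary")
  tis <- random_binary(20, 20, p = 0.5, seed = 12)
  by_tissue <- area_pct(a, roi, tis)
  by_roi <- area_pct(a, roi, tis, denominator = "roi")
  expect_equal(by_roi, by_tissue * sum(roi$pixels * tis$pixels) / 400)
  ol <- overlap_pct(a, a, roi, tis, denominator = "roi")
  expect_equal(ol$a_pct, by_roi)
})

test_that("overlap is symmetric and saturates for identical masks", {
  a <- random_binary(32, 32, p = 0.5, seed = 1)
  b <- random_binary(32, 32, p = 0.5, seed = 2)
  roi <- raster_image(matrix(1, 32, 32), "binary")
  tis <- raster_image(matrix(1, 32, 32), "binary")
  ab <- overlap_pct(a, b, roi, tis)
  ba <- overlap_pct(b, a, roi, tis)
  expect_equal(ab$ol_pct, ba$ol_pct)
  aa <- overlap_pct(a, a, roi, tis)
  expect_equal(aa$ol_pct, aa$a_pct)
  disj_b <- raster_image(1 - a$pixels, "binary")
  expect_equal(overlap_pct(a, disj_b, roi, tis)$ol_pct, 0)
})

test_that("signature classification follows the strict >15% rule", {
  expect_equal(classify_signature(20, 3), "MAPK_mTOR")
  expect_equal(classify_signature(3, 20), "AKT_mTOR")
  expect_equal(classify_signature(15, 15), "Null")      # boundary is strict
  expect_equal(classify_signature(0, 0), "Null")
  expect_warning(cls <- classify_signature(16, 16), "mutually exclusive")
  expect_equal(cls, "Dual")
})

test_that("signature classification is scale-free", {
  set.seed(9)
  for (rep in 1:20) {
    ol1 <- runif(1, 0, 50); ol2 <- runif(1, 0, 50); cut <- runif(1, 5, 30)
    f <- runif(1, 0.3, 2)
    c1 <- suppressWarnings(classify_signature(ol1, ol2, cut))
    c2 <- suppressWarnings(classify_signature(f * ol1, f * ol2, f * cut))
    expect_identical(c1, c2)
  }
})

test_that("landscape colours are exhaustive, exclusive and conserved", {
  a <- random_binary(48, 48, p = 0.35, seed = 3)
  b <- random_binary(48, 48, p = 0.35, seed = 4)
  roi <- random_binary(48, 48, p = 0.85, seed = 5)
  L <- render_landscape(a, b, roi)$pixels
  is_col <- function(r, g, bl)
    L[, , 1] == r & L[, , 2] == g & L[, , 3] == bl
  red <- is_col(255, 0, 0); yellow <- is_col(255, 255, 0)
  orange <- is_col(255, 165, 0); white <- is_col(255, 255, 255)
  expect_true(all(red | yellow | orange | white))
  ap <- a$pixels; bp <- b$pixels; rp <- roi$pixels
  expect_equal(sum(red), sum(ap * bp * rp))
  expect_equal(sum(yellow), sum(ap * (1 - bp) * rp))
  expect_equal(sum(orange), sum(bp * (1 - ap) * rp))
  expect_equal(sum(red) + sum(yellow) + sum(orange),
               sum(pmax(ap, bp) * rp))
  # disjoint masks produce no red; identical masks only red and white
  disj <- render_landscape(a, raster_image(1 - ap, "binary"), roi)$pixels
  expect_equal(sum(disj[, , 1] == 255 & disj[, , 2] == 0 & disj[, , 3] == 0), 0)
  same <- render_landscape(a, a, roi)$pixels
  expect_true(all((same[, , 2] == 0) == (same[, , 1] == 255 & same[, , 3] == 0)))
})

test_that("run_spaq composes the individual operations", {
  spec <- synthetic_slide_spec(size = c(160, 160), seed = 77,
                               noise = list(intensity_sd = 2,
                                            marker_jitter_px = 0),
                               section_transforms = list(
                                 similarity_transform(0, 1, 0, 0, c(79.5, 79.5)),
                                 similarity_transform(0, 1, 0, 0, c(79.5, 79.5))))
  gen <- generate_slide_series(spec)
  thr <- threshold_config(
    dab_threshold = c(pERK = gen$calibration$dab_threshold,
                      p4EBP1 = gen$calibration$dab_threshold),
    tissue_threshold = gen$calibration$tissue_threshold)
  res <- run_spaq(gen$images[[1]], gen$images[[2]], gen$rois, thr,
                  marker_names = c("pERK", "p4EBP1"))
  # manual composition of the same ops
  M <- stain_matrix()
  da <- dab_mask(stain_channel_8bit(deconvolve(rgb_to_od(gen$images[[1]]), M)$dab),
                 gen$calibration$dab_threshold)
  db <- dab_mask(stain_channel_8bit(deconvolve(rgb_to_od(gen$images[[2]]), M)$dab),
                 gen$calibration$dab_threshold)
  tm <- tissue_mask(gen$images[[1]], gen$calibration$tissue_threshold)
  rm <- rasterize_roi(gen$rois[[1]], c(160, 160))
  manual <- overlap_pct(da, db, rm, tm)
  expect_equal(res$records$pERK_pct[1], manual$a_pct)
  expect_equal(res$records$p4EBP1_pct[1], manual$b_pct)
  expect_equal(res$records$overlap_pct[1], manual$ol_pct)
  expect_equal(res$records$tissue_area_px[1], sum(rm$pixels * tm$pixels))
  # landscape agrees with direct rendering
  expect_equal(res$landscapes[[1]]$pixels,
               render_landscape(da, db, rm)$pixels)
})

test_that("a blank white pair quantifies to zeros with an empty landscape", {
  white <- raster_image(array(255, c(64, 64, 3)), "rgb8")
  roi <- roi_polygon("r1", rbind(c(10, 10), c(50, 10), c(50, 50), c(10, 50)))
  thr <- threshold_config(c(m1 = 100, m2 = 100), tissue_threshold = 200)
  res <- run_spaq(white, white, list(roi), thr, marker_names = c("m1", "m2"))
  expect_equal(res$records$m1_pct, 0)
  expect_equal(res$records$m2_pct, 0)
  expect_equal(res$records$overlap_pct, 0)
  expect_true(all(res$landscapes[[1]]$pixels == 255))
})

test_that("run_spaq writes masks, landscapes, results and a log", {
  spec <- synthetic_slide_spec(size = c(128, 128), seed = 6)
  gen <- generate_slide_series(spec)
  thr <- threshold_config(
    dab_threshold = c(pERK = gen$calibration$dab_threshold,
                      p4EBP1 = gen$calibration$dab_threshold))
  out <- tempfile("spaq_out_")
  res <- run_spaq(gen$images[[1]], gen$images[[2]], gen$rois, thr,
                  marker_names = c("pERK", "p4EBP1"),
                  signature_rule = list(class = "MAPK_mTOR", cutoff = 15),
                  out_dir = out)
  expect_true(file.exists(file.path(out, "results.csv")))
  expect_true(file.exists(file.path(out, "results.xlsx")))
  expect_true(file.exists(file.path(out, "mask_pERK.png")))
  expect_true(file.exists(file.path(out, "landscape_lesion_1.png")))
  log <- readLines(file.path(out, "run_log.txt"))
  expect_true(any(grepl("tissue_threshold", log)))
  expect_true(res$records$signature %in% c("MAPK_mTOR", "Null"))
  unlink(out, recursive = TRUE)
})
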