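test_that("TIFF and PNG round trips are pixel-lossless", {
  img <- random_rgb8(13, 17, seed = 3)
  for (ext in c("tif", "png")) {
    p <- tempfile(fileext = paste0(".", ext))
    write_image(img, p)
    back <- read_image(p)
    expect_identical(dim(back$pixels), dim(img$pixels))
    expect_equal(back$pixels, img$pixels, ignore_attr = TRUE)
    unlink(p)
  }
})

test_that("uniform and degenerate images read back correctly", {
  p <- tempfile(fileext = ".png")
  write_image(raster_image(array(255, c(64, 64, 3)), "rgb8"), p)
  white <- read_image(p)
  expect_equal(dim(white$pixels), c(64L, 64L, 3L))
  expect_true(all(white$pixels == 255))
  unlink(p)

  p1 <- tempfile(fileext = ".tif")
  write_image(raster_image(array(c(7, 8, 9), c(1, 1, 3)), "rgb8"), p1)
  one <- read_image(p1)
  expect_equal(as.numeric(one$pixels), c(7, 8, 9))
  unlink(p1)
})

test_that("grayscale sources are promoted to three identical channels", {
  p <- tempfile(fileext = ".png")
  g <- matrix(seq(0, 255, length.out = 30) / 255, 5, 6)
  png::writePNG(g, p)
  img <- read_image(p)
  expect_equal(dim(img$pixels)[3], 3L)
  expect_equal(img$pixels[, , 1], img$pixels[, , 2])
  expect_equal(img$pixels[, , 1], img$pixels[, , 3])
  unlink(p)
})

test_that("binary masks are written as two-level PNG", {
  m <- random_binary(9, 9, seed = 2)
  p <- tempfile(fileext = ".png")
  write_image(m, p)
  raw <- png::readPNG(p) * 255
  expect_true(all(raw %in% c(0, 255)))
  expect_equal((raw > 0) * 1, m$pixels, ignore_attr = TRUE)
  unlink(p)
})

test_that("unsupported or missing image files raise named errors", {
  expect_error(read_image("/nonexistent/x.png"), "not found")
  p <- tempfile(fileext = ".bmp")
  writeLines("junk", p)
  expect_error(read_image(p), "unsupported image format")
  unlink(p)
})

test_that("JSON ROI round trip preserves names and vertex order", {
  rois <- list(
    roi_polygon("IAC_1", rbind(c(0, 0), c(10, 0), c(0, 10))),
    roi_polygon("PAC_2", rbind(c(5, 5), c(20, 6), c(18, 19), c(4, 17))))
  p <- tempfile(fileext = ".json")
  write_rois(rois, p)
  back <- read_rois(p)
  expect_length(back, 2L)
  expect_equal(vapply(back, `[[`, "", "name"), c("IAC_1", "PAC_2"))
  expect_equal(back[[2]]$vertices, rois[[2]]$vertices)
  # idempotent: writing the parsed list again yields identical JSON
  p2 <- tempfile(fileext = ".json")
  write_rois(back, p2)
  expect_identical(readLines(p), readLines(p2))
  unlink(c(p, p2))
})

test_that("empty and malformed ROI files are handled per contract", {
  p <- tempfile(fileext = ".json")
  writeLines("[]", p)
  expect_identical(read_rois(p), list())
  jsonlite::write_json(list(list(name = "bad", vertices = list(c(0, 0), c(1, 1)))),
                       p, auto_unbox = TRUE)
  expect_error(read_rois(p), "entry 1")
  jsonlite::write_json(list(list(vertices = list(c(0, 0), c(1, 0), c(0, 1)))),
                       p, auto_unbox = TRUE)
  expect_error(read_rois(p), "entry 1")
  unlink(p)
})

test_that("roi_polygon rejects self-intersecting outlines", {
  expect_error(roi_polygon("bowtie",
                           rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))),
               "self-intersecting")
  expect_s3_class(roi_polygon("square",
                              rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))),
                  "roi_polygon")
})

# Build a minimal ImageJ .roi file (big-endian polygon record) in memory.
write_imagej_roi <- function(path, xs, ys, top = 0L, left = 0L) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("Iout", con, 4, eos = NULL)
  writeBin(c(227L, 0L), con, size = 2, endian = "big")   # version, type=0
  writeBin(as.integer(c(top, left, top + max(ys), left + max(xs),
                        length(xs))), con, size = 2, endian = "big")
  writeBin(raw(64 - 18), con)
  writeBin(as.integer(xs), con, size = 2, endian = "big")
  writeBin(as.integer(ys), con, size = 2, endian = "big")
}

test_that("ImageJ .roi polygon files parse (best-effort dialect)", {
  p <- tempfile(fileext = ".roi")
  write_imagej_roi(p, xs = c(2, 12, 2), ys = c(3, 3, 13), top = 5L, left = 7L)
  rois <- read_rois(p)
  expect_length(rois, 1L)
  expect_equal(rois[[1]]$vertices,
               cbind(x = c(9, 19, 9), y = c(8, 8, 18)), ignore_attr = TRUE)
  unlink(p)

  # zipped set of .roi files
  d <- tempfile(); dir.create(d)
  write_imagej_roi(file.path(d, "a_lesion.roi"), c(0, 8, 0), c(0, 0, 8))
  write_imagej_roi(file.path(d, "b_lesion.roi"), c(1, 9, 1), c(1, 1, 9))
  zp <- tempfile(fileext = ".zip")
  zip::zip(zp, c("a_lesion.roi", "b_lesion.roi"), root = d,
           mode = "cherry-pick")
  rois <- read_rois(zp)
  expect_equal(vapply(rois, `[[`, "", "name"), c("a_lesion", "b_lesion"))
  unlink(c(zp, d), recursive = TRUE)
})

test_that("export_results writes a CSV and xlsx twin with exact cells", {
  rec <- data.frame(roi_name = "lesion_1", tissue_area_px = 12345,
                    pERK_pct = 50.0, p4EBP1_pct = 20.0,
                    overlap_pct = 10.0, signature = "Null",
                    stringsAsFactors = FALSE)
  base <- tempfile()
  paths <- export_results(rec, paste0(base, ".csv"))
  back <- utils::read.csv(paths[["csv"]], stringsAsFactors = FALSE)
  expect_equal(back$overlap_pct, 10.0)
  expect_equal(back$roi_name, "lesion_1")
  # xlsx is a zip container whose sheet holds the same cells
  lst <- utils::unzip(paths[["xlsx"]], list = TRUE)
  expect_true("xl/worksheets/sheet1.xml" %in% lst$Name)
  d <- tempfile(); dir.create(d)
  utils::unzip(paths[["xlsx"]], exdir = d)
  sheet <- readLines(file.path(d, "xl", "worksheets", "sheet1.xml"), warn = FALSE)
  expect_match(sheet, "<t>lesion_1</t>")
  expect_match(sheet, "<v>12345</v>")
  unlink(c(paths, d), recursive = TRUE)
})

test_that("export_results with no records yields a header-only file", {
  rec <- data.frame(roi_name = character(), tissue_area_px = numeric(),
                    overlap_pct = numeric(), stringsAsFactors = FALSE)
  paths <- export_results(rec, tempfile(fileext = ".csv"))
  lines <- readLines(paths[["csv"]])
  expect_length(lines, 1L)
  expect_match(lines, "roi_name")
  unlink(paths)
})

test_that("full-precision numbers survive the CSV round trip", {
  rec <- data.frame(roi_name = "r", tissue_area_px = 1,
                    pct = 33.333333333333329, stringsAsFactors = FALSE)
  paths <- export_results(rec, tempfile(fileext = ".csv"))
  back <- utils::read.csv(paths[["csv"]])
  expect_equal(back$pct, rec$pct, tolerance = 1e-14)
  unlink(paths)
})
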