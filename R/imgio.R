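#' Read a brightfield image
#'
#' Reads TIFF, PNG or JPEG into an `rgb8` [raster_image].  Grayscale sources
#' are promoted to three identical channels; an alpha channel, if present, is
#' dropped.  Multi-page TIFFs yield their first page.
#'
#' @param path path to a `.tif`/`.tiff`, `.png`, `.jpg`/`.jpeg` file.
#' @return an `rgb8` [raster_image].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("image file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = , tiff = {
      x <- tiff::readTIFF(path)
      if (is.list(x)) x[[1]] else x
    },
    png = png::readPNG(path),
    jpg = , jpeg = jpeg::readJPEG(path),
    stop(sprintf("unsupported image format '%s' for: %s", ext, path)))
  if (is.null(dim(px))) stop(sprintf("could not decode image: %s", path))
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] >= 3L) px <- px[, , 1:3, drop = FALSE]
    else px <- px[, , 1L]
  }
  px <- round(px * 255)
  px[px < 0] <- 0; px[px > 255] <- 255
  if (length(dim(px)) == 2L)
    px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  raster_image(px, "rgb8")
}

#' Write an image to disk
#'
#' TIFF output is always uncompressed; PNG is used for masks and is lossless.
#' `binary` images are written as two-level 0/255 grayscale.
#'
#' @param img a [raster_image] (`rgb8`, `gray8` or `binary`).
#' @param path output path ending in `.tif`/`.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot_raster(img, c("rgb8", "gray8", "binary"))
  px <- img$pixels
  if (img$channel_kind == "binary") px <- px * 255
  px <- px / 255
  ext <- tolower(tools::file_ext(path))
  ok <- switch(ext,
    tif = , tiff = tiff::writeTIFF(px, path, compression = "none"),
    png = png::writePNG(px, path),
    stop(sprintf("unsupported output format '%s' for: %s", ext, path)))
  if (!file.exists(path)) stop(sprintf("failed to write image: %s", path))
  invisible(path)
}

#' ROI polygon
#'
#' A named, closed, simple polygon in fixed-image pixel coordinates
#' (x = column, y = row, 0-based).
#'
#' @param name text label, e.g. a lesion id plus histopathology class.
#' @param vertices n x 2 matrix (or list of pairs) of `(x, y)` vertices,
#'   n >= 3, in order; the polygon is closed implicitly.
#' @return an object of class `roi_polygon`.
#' @export
roi_polygon <- function(name, vertices) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("ROI `name` must be a non-empty string")
  if (is.list(vertices))
    vertices <- do.call(rbind, lapply(vertices, as.numeric))
  vertices <- matrix(as.numeric(vertices), ncol = 2L,
                     dimnames = list(NULL, c("x", "y")))
  if (nrow(vertices) < 3L)
    stop(sprintf("ROI '%s' needs >= 3 vertices, got %d", name, nrow(vertices)))
  if (anyNA(vertices)) stop(sprintf("ROI '%s' has non-numeric vertices", name))
  if (polygon_self_intersects(vertices))
    stop(sprintf("ROI '%s' is self-intersecting", name))
  structure(list(name = name, vertices = vertices, closed = TRUE),
            class = "roi_polygon")
}

#' @export
print.roi_polygon <- function(x, ...) {
  cat(sprintf("<roi_polygon '%s' with %d vertices>\n", x$name,
              nrow(x$vertices)))
  invisible(x)
}

# Proper-crossing test between all non-adjacent closed-polygon edges.
# Touching endpoints are tolerated; true crossings are not.
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  if (n < 4L) return(FALSE)
  p <- v
  q <- v[c(2:n, 1L), , drop = FALSE]
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]          # edge n is adjacent to edge 1
    if (!length(js)) next
    d1 <- cross(p[i, 1], p[i, 2], q[i, 1], q[i, 2], p[js, 1], p[js, 2])
    d2 <- cross(p[i, 1], p[i, 2], q[i, 1], q[i, 2], q[js, 1], q[js, 2])
    d3 <- cross(p[js, 1], p[js, 2], q[js, 1], q[js, 2],
                rep(p[i, 1], length(js)), rep(p[i, 2], length(js)))
    d4 <- cross(p[js, 1], p[js, 2], q[js, 1], q[js, 2],
                rep(q[i, 1], length(js)), rep(q[i, 2], length(js)))
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Read ROI polygons
#'
#' The native format is a JSON list of `{name, vertices}` objects with
#' `vertices` a list of `[x, y]` pixel coordinates.  As a best-effort
#' convenience, ImageJ `.roi` files (polygon and freehand types) and `.zip`
#' archives of them are also accepted; names default to the file stem.
#'
#' @param path path to a `.json`, `.roi`, or ImageJ ROI `.zip` file.
#' @return list of [roi_polygon]; may be empty.
#' @export
read_rois <- function(path) {
  if (!file.exists(path)) stop(sprintf("ROI file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    entries <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (length(entries) == 0L) return(list())
    out <- vector("list", length(entries))
    for (i in seq_along(entries)) {
      e <- entries[[i]]
      if (is.null(e$name) || is.null(e$vertices))
        stop(sprintf("ROI entry %d is malformed: needs 'name' and 'vertices'", i))
      out[[i]] <- tryCatch(roi_polygon(e$name, e$vertices),
        error = function(err)
          stop(sprintf("ROI entry %d ('%s'): %s", i,
                       as.character(e$name), conditionMessage(err))))
    }
    return(out)
  }
  if (ext == "roi") return(list(read_imagej_roi(path)))
  if (ext == "zip") {
    tmp <- tempfile("rois_")
    dir.create(tmp)
    on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
    files <- utils::unzip(path, exdir = tmp)
    files <- sort(files[grepl("\\.roi$", files, ignore.case = TRUE)])
    return(lapply(files, read_imagej_roi))
  }
  stop(sprintf("unsupported ROI format '%s' for: %s", ext, path))
}

# Minimal ImageJ .roi parser: polygon (type 0) and freehand (type 7) only.
# Big-endian header; vertex shorts are relative to the (left, top) corner.
read_imagej_roi <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 64L || rawToChar(raw[1:4]) != "Iout")
    stop(sprintf("not an ImageJ ROI file: %s", path))
  be_short <- function(off)     # 0-based offset of a signed big-endian short
    readBin(raw[(off + 1):(off + 2)], "integer", size = 2, endian = "big")
  type <- as.integer(raw[7])
  if (!type %in% c(0L, 7L))
    stop(sprintf("unsupported ImageJ ROI type %d in %s (only polygon/freehand)",
                 type, path))
  top <- be_short(8); left <- be_short(10)
  n <- be_short(16)
  if (n < 3L) stop(sprintf("ImageJ ROI %s has %d vertices (< 3)", path, n))
  xs <- vapply(seq_len(n) - 1L, function(k) be_short(64 + 2 * k), numeric(1))
  ys <- vapply(seq_len(n) - 1L, function(k) be_short(64 + 2 * n + 2 * k),
               numeric(1))
  roi_polygon(tools::file_path_sans_ext(basename(path)),
              cbind(x = xs + left, y = ys + top))
}

#' Write ROI polygons as JSON
#'
#' @param rois list of [roi_polygon].
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  entries <- lapply(rois, function(r)
    list(name = r$name,
         vertices = lapply(seq_len(nrow(r$vertices)),
                           function(i) as.numeric(r$vertices[i, ]))))
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export quantification results
#'
#' Writes one row per ROI to a CSV file and an `.xlsx` twin with identical
#' cells.  The CSV round-trips numbers at full precision and is the
#' authoritative output; the xlsx sheet is written with a minimal
#' single-sheet writer (inline strings, no styling).
#'
#' @param records data frame of per-ROI quantification rows (as produced by
#'   [run_spaq()]), or an empty data frame for a header-only file.
#' @param path output path; the `.csv` and `.xlsx` twins are derived from it
#'   by extension substitution.
#' @return named character vector with the `csv` and `xlsx` paths, invisibly.
#' @export
export_results <- function(records, path) {
  stopifnot(is.data.frame(records))
  base <- tools::file_path_sans_ext(path)
  csv_path <- paste0(base, ".csv")
  xlsx_path <- paste0(base, ".xlsx")
  utils::write.csv(records, csv_path, row.names = FALSE)
  write_minimal_xlsx(records, xlsx_path)
  invisible(c(csv = csv_path, xlsx = xlsx_path))
}

# Minimal single-sheet ECMA-376 xlsx writer: strings inline, numbers plain.
write_minimal_xlsx <- function(df, path, sheet = "results") {
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  cell <- function(v) {
    if (is.numeric(v) && !is.na(v))
      sprintf("<c><v>%s</v></c>", format(v, digits = 15, scientific = FALSE))
    else if (is.na(v)) "<c/>"
    else sprintf("<c t=\"inlineStr\"><is><t>%s</t></is></c>", esc(as.character(v)))
  }
  rows <- character(nrow(df) + 1L)
  rows[1] <- paste0("<row>", paste0(vapply(names(df), cell, character(1)),
                                    collapse = ""), "</row>")
  for (i in seq_len(nrow(df))) {
    vals <- lapply(seq_along(df), function(j) df[[j]][i])
    rows[i + 1L] <- paste0("<row>",
                           paste0(vapply(vals, cell, character(1)),
                                  collapse = ""), "</row>")
  }
  sheet_xml <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\" standalone=\"yes\"?>",
    "<worksheet xmlns=\"http://schemas.openxmlformats.org/spreadsheetml/2006/main\">",
    "<sheetData>", paste0(rows, collapse = ""), "</sheetData></worksheet>")
  wb_xml <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\" standalone=\"yes\"?>",
    "<workbook xmlns=\"http://schemas.openxmlformats.org/spreadsheetml/2006/main\" ",
    "xmlns:r=\"http://schemas.openxmlformats.org/officeDocument/2006/relationships\">",
    "<sheets><sheet name=\"", esc(sheet),
    "\" sheetId=\"1\" r:id=\"rId1\"/></sheets></workbook>")
  ct_xml <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\" standalone=\"yes\"?>",
    "<Types xmlns=\"http://schemas.openxmlformats.org/package/2006/content-types\">",
    "<Default Extension=\"rels\" ContentType=\"application/vnd.openxmlformats-package.relationships+xml\"/>",
    "<Default Extension=\"xml\" ContentType=\"application/xml\"/>",
    "<Override PartName=\"/xl/workbook.xml\" ContentType=\"application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml\"/>",
    "<Override PartName=\"/xl/worksheets/sheet1.xml\" ContentType=\"application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml\"/>",
    "</Types>")
  rels_xml <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\" standalone=\"yes\"?>",
    "<Relationships xmlns=\"http://schemas.openxmlformats.org/package/2006/relationships\">",
    "<Relationship Id=\"rId1\" Type=\"http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument\" Target=\"xl/workbook.xml\"/>",
    "</Relationships>")
  wb_rels_xml <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\" standalone=\"yes\"?>",
    "<Relationships xmlns=\"http://schemas.openxmlformats.org/package/2006/relationships\">",
    "<Relationship Id=\"rId1\" Type=\"http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet\" Target=\"worksheets/sheet1.xml\"/>",
    "</Relationships>")
  staging <- tempfile("xlsx_")
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)
  for (d in c("_rels", "xl/_rels", "xl/worksheets"))
    dir.create(file.path(staging, d), recursive = TRUE)
  wr <- function(rel, txt) writeLines(txt, file.path(staging, rel), sep = "")
  wr("[Content_Types].xml", ct_xml)
  wr("_rels/.rels", rels_xml)
  wr("xl/workbook.xml", wb_xml)
  wr("xl/_rels/workbook.xml.rels", wb_rels_xml)
  wr("xl/worksheets/sheet1.xml", sheet_xml)
  path <- normalizePath(path, mustWork = FALSE)
  zip::zip(path,
           c("[Content_Types].xml", "_rels/.rels", "xl/workbook.xml",
             "xl/_rels/workbook.xml.rels", "xl/worksheets/sheet1.xml"),
           root = staging, compression_level = 6, mode = "mirror")
  invisible(path)
}
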