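#' Rasterise an ROI polygon into a binary mask
#'
#' A pixel is inside the ROI iff its centre (integer `(x, y)` coordinate) is
#' inside the closed polygon under the even-odd rule; the polygon is clipped
#' to the image bounds.
#'
#' @param roi a [roi_polygon].
#' @param shape `(h, w)` of the target mask.
#' @return a `binary` [raster_image]; empty (with a warning) when the polygon
#'   lies fully outside the image or between pixel centres.
#' @export
rasterize_roi <- function(roi, shape) {
  stopifnot(inherits(roi, "roi_polygon"), length(shape) == 2L,
            all(shape >= 1))
  h <- as.integer(shape[1]); w <- as.integer(shape[2])
  v <- roi$vertices
  n <- nrow(v)
  px <- rep(0:(w - 1), each = h)        # x of every pixel centre, col-major
  py <- rep(0:(h - 1), times = w)
  inside <- rep(FALSE, h * w)
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]
    xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > py) != (yj > py))
    if (any(crosses)) {
      xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  m <- matrix(as.numeric(inside), h, w)
  if (!any(m == 1))
    warning(sprintf("ROI '%s' rasterises to an empty mask", roi$name))
  raster_image(m, "binary")
}

mask_px <- function(x) if (is_raster_image(x)) x$pixels else x

check_same_shape <- function(...) {
  ms <- list(...)
  d <- dim(ms[[1]])
  for (m in ms[-1])
    if (!identical(dim(m), d))
      stop("masks must all have the same shape")
  invisible(TRUE)
}

#' DAB-positive area as a percentage of ROI tissue area
#'
#' `100 * |marker & roi & tissue| / |roi & tissue|`: the denominator is the
#' ROI's tissue area (tumour area), not the full polygon area.
#'
#' @param marker_mask,roi_mask,tissue_mask `binary` [raster_image]s (or 0/1
#'   matrices) of identical shape.
#' @param roi_name label used in the error message when the ROI contains no
#'   tissue.
#' @param denominator `"tissue"` (default) divides by the ROI's tissue area;
#'   `"roi"` divides by the full ROI pixel count — useful for TMA spots
#'   classified by dominant phenotype, where a fixed tissue denominator is
#'   not meaningful.
#' @return percentage in `[0, 100]`.
#' @export
area_pct <- function(marker_mask, roi_mask, tissue_mask, roi_name = "ROI",
                     denominator = c("tissue", "roi")) {
  denominator <- match.arg(denominator)
  m <- mask_px(marker_mask); r <- mask_px(roi_mask); t <- mask_px(tissue_mask)
  check_same_shape(m, r, t)
  denom <- if (denominator == "tissue") sum(r * t) else sum(r)
  if (denom == 0)
    stop(sprintf("'%s' contains no tissue pixels; area %% undefined", roi_name))
  100 * sum(m * r * t) / denom
}

#' Pairwise overlap of two marker masks within an ROI
#'
#' Overlap (OL) is the area positive for both markers, as a percentage of the
#' ROI tissue area: `100 * |a & b & roi & tissue| / |roi & tissue|`.
#' Symmetric in the two markers.
#'
#' @param mask_a,mask_b `binary` marker masks (mask_b typically from a
#'   registered neighbouring section).
#' @param roi_mask,tissue_mask `binary` masks of the same shape.
#' @param marker_a_name,marker_b_name,roi_name labels carried into the result.
#' @param denominator `"tissue"` (default) or `"roi"`; see [area_pct()].
#' @return list of class `overlap_result` with `marker_a_name`,
#'   `marker_b_name`, `roi_name`, `a_pct`, `b_pct`, `ol_pct`; always
#'   `ol_pct <= min(a_pct, b_pct)`.
#' @export
overlap_pct <- function(mask_a, mask_b, roi_mask, tissue_mask,
                        marker_a_name = "marker_a",
                        marker_b_name = "marker_b",
                        roi_name = "ROI",
                        denominator = c("tissue", "roi")) {
  denominator <- match.arg(denominator)
  a <- mask_px(mask_a); b <- mask_px(mask_b)
  r <- mask_px(roi_mask); t <- mask_px(tissue_mask)
  check_same_shape(a, b, r, t)
  denom <- if (denominator == "tissue") sum(r * t) else sum(r)
  if (denom == 0)
    stop(sprintf("'%s' contains no tissue pixels; OL %% undefined", roi_name))
  rt <- r * t
  structure(list(marker_a_name = marker_a_name,
                 marker_b_name = marker_b_name,
                 roi_name = roi_name,
                 a_pct = 100 * sum(a * rt) / denom,
                 b_pct = 100 * sum(b * rt) / denom,
                 ol_pct = 100 * sum(a * b * rt) / denom),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<%s: %s %.2f%%, %s %.2f%%, OL %.2f%%>\n", x$roi_name,
              x$marker_a_name, x$a_pct, x$marker_b_name, x$b_pct, x$ol_pct))
  invisible(x)
}

#' Classify a lesion's signalling signature from two overlap values
#'
#' The subclassification rule: a lesion is `MAPK_mTOR` iff the pERK/p4EBP1
#' overlap strictly exceeds the cutoff while pAKT/p4EBP1 does not;
#' `AKT_mTOR` symmetrically; `Null` iff neither exceeds it.  When both exceed
#' the cutoff the (never-observed) `Dual` label is returned with a warning,
#' since the rule can mathematically produce it even though lesions were
#' found to carry the two signatures mutually exclusively.  The cutoff
#' comparison is strict (`> cutoff`), so exactly 15/15 is `Null`.
#'
#' @param ol_erk_4ebp1 pERK/p4EBP1 overlap percentage in `[0, 100]`.
#' @param ol_akt_4ebp1 pAKT/p4EBP1 overlap percentage in `[0, 100]`.
#' @param cutoff overlap cutoff percentage, default 15.
#' @return one of `"MAPK_mTOR"`, `"AKT_mTOR"`, `"Null"`, `"Dual"`.
#' @export
classify_signature <- function(ol_erk_4ebp1, ol_akt_4ebp1, cutoff = 15) {
  stopifnot(ol_erk_4ebp1 >= 0, ol_erk_4ebp1 <= 100,
            ol_akt_4ebp1 >= 0, ol_akt_4ebp1 <= 100, cutoff >= 0)
  a <- ol_erk_4ebp1 > cutoff
  b <- ol_akt_4ebp1 > cutoff
  if (a && b) {
    warning("both overlaps exceed the cutoff ('Dual'); the two signatures ",
            "were observed to be mutually exclusive in tumour lesions")
    return("Dual")
  }
  if (a) "MAPK_mTOR" else if (b) "AKT_mTOR" else "Null"
}

#' Render a pseudo-coloured overlap landscape
#'
#' Within the ROI, pixels positive only for marker A are yellow
#' `(255,255,0)`, only for marker B orange `(255,165,0)`, for both red
#' `(255,0,0)`; everything else (and everything outside the ROI) is white.
#' The colour assignment is exhaustive and mutually exclusive per pixel.
#'
#' @param mask_a,mask_b,roi_mask `binary` [raster_image]s of one shape.
#' @return an `rgb8` [raster_image].
#' @export
render_landscape <- function(mask_a, mask_b, roi_mask) {
  a <- mask_px(mask_a); b <- mask_px(mask_b); r <- mask_px(roi_mask)
  check_same_shape(a, b, r)
  both <- a * b * r
  a_only <- a * (1 - b) * r
  b_only <- b * (1 - a) * r
  d <- dim(a)
  out <- array(255, dim = c(d, 3L))
  out[, , 2] <- 255 - 90 * b_only - 255 * both   # orange G=165, red G=0
  out[, , 3] <- 255 - 255 * (a_only + b_only + both)
  raster_image(out, "rgb8")
}

#' Full Spa-Q quantification for one registered section pair
#'
#' Runs the complete per-pair pipeline: colour deconvolution of both images,
#' DAB thresholding, tissue masking (on the reference image `image_a`),
#' per-ROI area and overlap quantification, optional signature labelling,
#' landscape rendering, and (optionally) export of masks, landscapes and the
#' results spreadsheet.
#'
#' @param image_a reference-frame `rgb8` [raster_image] (marker A).
#' @param image_b `rgb8` [raster_image] already registered into `image_a`'s
#'   frame (marker B).
#' @param rois list of [roi_polygon] in the reference frame.
#' @param thresholds a [threshold_config]; `dab_threshold` must contain
#'   entries named after the two markers.
#' @param stains a [stain_matrix]; defaults to the H-DAB matrix.
#' @param marker_names length-2 character: names of markers A and B, used to
#'   look up thresholds and label outputs.
#' @param signature_rule optional list `(class =, cutoff = 15)`; when given,
#'   each record is labelled `class` if its OL strictly exceeds `cutoff`,
#'   otherwise `"Null"`.
#' @param out_dir optional output directory; when given, per-ROI landscape
#'   PNGs, per-marker mask PNGs, `results.csv`/`results.xlsx` and a
#'   `run_log.txt` (every threshold and parameter used) are written there.
#' @param denominator `"tissue"` (default) or `"roi"`; see [area_pct()].
#' @return list with `records` (data frame: `roi_name`, `tissue_area_px`,
#'   `<A>_pct`, `<B>_pct`, `overlap_pct`, `signature`), `landscapes` (named
#'   list of `rgb8` rasters), and `masks` (the binary marker/tissue masks).
#'   Per-ROI failures (e.g. no tissue in the ROI) are recorded as `NA` rows
#'   and do not abort the run.
#' @export
run_spaq <- function(image_a, image_b, rois, thresholds,
                     stains = stain_matrix(),
                     marker_names = c("marker_a", "marker_b"),
                     signature_rule = NULL, out_dir = NULL,
                     denominator = c("tissue", "roi")) {
  denominator <- match.arg(denominator)
  stopifnot_raster(image_a, "rgb8"); stopifnot_raster(image_b, "rgb8")
  stopifnot(inherits(thresholds, "threshold_config"),
            length(marker_names) == 2L)
  if (!identical(dim(image_a$pixels), dim(image_b$pixels)))
    stop("image_b must already be registered into image_a's frame (same size)")
  thr_a <- marker_threshold(thresholds, marker_names[1])
  thr_b <- marker_threshold(thresholds, marker_names[2])

  dab_a <- stain_channel_8bit(deconvolve(rgb_to_od(image_a), stains)$dab)
  dab_b <- stain_channel_8bit(deconvolve(rgb_to_od(image_b), stains)$dab)
  m_a <- dab_mask(dab_a, thr_a)
  m_b <- dab_mask(dab_b, thr_b)
  m_tissue <- tissue_mask(image_a, thresholds$tissue_threshold)
  shape <- dim(m_a$pixels)

  records <- vector("list", length(rois))
  landscapes <- list()
  for (i in seq_along(rois)) {
    roi <- rois[[i]]
    rec <- tryCatch({
      rm <- rasterize_roi(roi, shape)
      ol <- if (sum(rm$pixels * m_tissue$pixels) == 0) {
        # blank ROI (e.g. empty slide): report zeros rather than failing
        list(a_pct = 0, b_pct = 0, ol_pct = 0)
      } else {
        overlap_pct(m_a, m_b, rm, m_tissue,
                    marker_names[1], marker_names[2], roi$name,
                    denominator = denominator)
      }
      sig <- NA_character_
      if (!is.null(signature_rule)) {
        cutoff <- if (is.null(signature_rule$cutoff)) 15 else signature_rule$cutoff
        sig <- if (ol$ol_pct > cutoff) signature_rule$class else "Null"
      }
      landscapes[[roi$name]] <- render_landscape(m_a, m_b, rm)
      data.frame(roi_name = roi$name,
                 tissue_area_px = sum(rm$pixels * m_tissue$pixels),
                 a_pct = ol$a_pct, b_pct = ol$b_pct,
                 overlap_pct = ol$ol_pct, signature = sig,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warning(sprintf("ROI '%s' failed: %s", roi$name, conditionMessage(e)))
      data.frame(roi_name = roi$name, tissue_area_px = NA_real_,
                 a_pct = NA_real_, b_pct = NA_real_,
                 overlap_pct = NA_real_, signature = NA_character_,
                 stringsAsFactors = FALSE)
    })
    records[[i]] <- rec
  }
  records <- if (length(records))
    do.call(rbind, c(records, list(make.row.names = FALSE))) else NULL
  if (is.null(records)) {
    records <- data.frame(roi_name = character(), tissue_area_px = numeric(),
                          a_pct = numeric(), b_pct = numeric(),
                          overlap_pct = numeric(), signature = character(),
                          stringsAsFactors = FALSE)
  }
  names(records)[names(records) == "a_pct"] <- paste0(marker_names[1], "_pct")
  names(records)[names(records) == "b_pct"] <- paste0(marker_names[2], "_pct")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_image(m_a, file.path(out_dir, paste0("mask_", marker_names[1], ".png")))
    write_image(m_b, file.path(out_dir, paste0("mask_", marker_names[2], ".png")))
    write_image(m_tissue, file.path(out_dir, "mask_tissue.png"))
    for (nm in names(landscapes))
      write_image(landscapes[[nm]],
                  file.path(out_dir, paste0("landscape_", safe_name(nm), ".png")))
    export_results(records, file.path(out_dir, "results.csv"))
    log_lines <- c(
      sprintf("markers: %s, %s", marker_names[1], marker_names[2]),
      sprintf("dab_threshold[%s] = %s", marker_names, c(thr_a, thr_b)),
      sprintf("hematoxylin_threshold = %s", thresholds$hematoxylin_threshold),
      sprintf("tissue_threshold = %s", thresholds$tissue_threshold),
      sprintf("stain_matrix = %s",
              paste(signif(unclass(stains), 6), collapse = " ")),
      sprintf("rois = %s", paste(vapply(rois, `[[`, "", "name"),
                                 collapse = ", ")))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  list(records = records, landscapes = landscapes,
       masks = list(marker_a = m_a, marker_b = m_b, tissue = m_tissue))
}

marker_threshold <- function(thresholds, marker) {
  dt <- thresholds$dab_threshold
  if (!is.null(names(dt)) && marker %in% names(dt)) return(dt[[marker]])
  if (length(dt) == 1L) return(dt[[1L]])
  stop(sprintf("no DAB threshold configured for marker '%s'", marker))
}

safe_name <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)
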