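#' Load and validate a pipeline run configuration
#'
#' A run configuration is a YAML or JSON document with fields:
#' \preformatted{
#' version: 1
#' fixed:    {path: A.tif, marker: pERK}
#' movings:  [{path: B.tif, marker: p4EBP1}, ...]
#' rois:     rois.json
#' out_dir:  results/
#' seed:     1
#' registration: {max_iterations: 100, ...}   # registration_params fields
#' thresholds:
#'   dab_threshold: {pERK: 101, p4EBP1: 101}
#'   tissue_threshold: 200
#'   hematoxylin_threshold: 160
#' stain_matrix: {h: [0.650, 0.704, 0.286], dab: [0.072, 0.954, 0.283]}
#' pairs: [[pERK, p4EBP1], ...]               # marker pairs to quantify
#' signatures: {MAPK_mTOR: [pERK, p4EBP1], AKT_mTOR: [pAKT, p4EBP1]}
#' cutoff: 15
#' }
#' Marker-to-signature mapping is configuration, not hard-coded biology.
#'
#' @param path path to a `.yaml`/`.yml`/`.json` configuration file.
#' @return a validated `run_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::fromJSON(path, simplifyVector = TRUE,
                                                    simplifyDataFrame = FALSE)
         else stop(sprintf("unsupported config format '%s'", ext))
  as_run_config(cfg, dir = dirname(path))
}

as_run_config <- function(cfg, dir = ".") {
  need <- function(field) {
    if (is.null(cfg[[field]]))
      stop(sprintf("config is missing required field '%s'", field))
    cfg[[field]]
  }
  resolve <- function(p) if (file.exists(p)) p else file.path(dir, p)
  fixed <- need("fixed"); movings <- need("movings")
  rois <- resolve(need("rois")); out_dir <- need("out_dir")
  if (is.null(fixed$path) || is.null(fixed$marker))
    stop("config 'fixed' needs 'path' and 'marker'")
  for (m in movings)
    if (is.null(m$path) || is.null(m$marker))
      stop("config 'movings' entries need 'path' and 'marker'")
  paths <- c(resolve(fixed$path),
             vapply(movings, function(m) resolve(m$path), character(1)), rois)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop(sprintf("input file(s) not found: %s", paste(missing, collapse = ", ")))
  fixed$path <- resolve(fixed$path)
  movings <- lapply(movings, function(m) { m$path <- resolve(m$path); m })
  reg_args <- cfg$registration
  if (!is.null(cfg$seed) && is.null(reg_args$seed)) reg_args$seed <- cfg$seed
  params <- do.call(registration_params, as.list(reg_args))
  thr <- need("thresholds")
  thresholds <- threshold_config(
    dab_threshold = unlist(thr$dab_threshold),
    hematoxylin_threshold = thr$hematoxylin_threshold %||% 160,
    tissue_threshold = thr$tissue_threshold %||% 200)
  stains <- if (is.null(cfg$stain_matrix)) stain_matrix()
            else stain_matrix(cfg$stain_matrix$h, cfg$stain_matrix$dab)
  markers <- c(fixed$marker, vapply(movings, `[[`, "", "marker"))
  pairs <- cfg$pairs
  if (is.null(pairs))
    pairs <- lapply(markers[-1], function(m) c(markers[1], m))
  for (p in pairs)
    if (!all(unlist(p) %in% markers))
      stop(sprintf("pair (%s) references unknown markers",
                   paste(unlist(p), collapse = ", ")))
  structure(list(fixed = fixed, movings = movings, rois = rois,
                 out_dir = out_dir, params = params, thresholds = thresholds,
                 stains = stains, pairs = lapply(pairs, unlist),
                 signatures = cfg$signatures,
                 cutoff = cfg$cutoff %||% 15,
                 raw = cfg),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full registration-then-quantification pipeline
#'
#' Validates all inputs before any computation, registers every moving image
#' to the fixed reference, then quantifies each configured marker pair with
#' [run_spaq()].  Outputs written to `out_dir`: registered uncompressed
#' TIFFs (`<stem>_registered.tif`), `registration_log.csv` (transform
#' parameters, metric, iterations), per-pair mask and landscape images,
#' `results.csv`/`results.xlsx` (one row per ROI and pair, with a signature
#' column when two configured signature pairs are present),
#' `config_used.yaml`, and `run_log.txt`.  Re-running the same configuration
#' and seed reproduces the outputs.
#'
#' @param config a `run_config` (see [read_run_config()]), or a path to one.
#' @return the output directory, invisibly; the combined results table is
#'   attached as attribute `records`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- character()
  say <- function(...) {
    line <- sprintf(...)
    log <<- c(log, paste0(format(Sys.time(), "%H:%M:%S "), line))
    message(line)
  }

  fixed_img <- read_image(config$fixed$path)
  movings <- lapply(config$movings, function(m) read_image(m$path))
  rois <- read_rois(config$rois)
  say("loaded %d moving image(s), %d ROI(s)", length(movings), length(rois))

  fits <- register_batch(fixed_img, movings, config$params, verbose = FALSE)
  reg_log <- list()
  frame <- list(); frame[[config$fixed$marker]] <- fixed_img
  for (i in seq_along(fits)) {
    marker <- config$movings[[i]]$marker
    stem <- tools::file_path_sans_ext(basename(config$movings[[i]]$path))
    if (inherits(fits[[i]], "try-error")) {
      say("registration of '%s' FAILED: %s", marker, as.character(fits[[i]]))
      reg_log[[i]] <- data.frame(marker = marker, rotation_deg = NA,
                                 scale = NA, tx = NA, ty = NA,
                                 final_metric = NA, iterations = NA,
                                 converged = NA)
      next
    }
    fit <- fits[[i]]
    frame[[marker]] <- fit$registered
    write_image(fit$registered,
                file.path(out_dir, paste0(stem, "_registered.tif")))
    cf <- coef(fit)
    reg_log[[i]] <- data.frame(marker = marker,
                               rotation_deg = cf["rotation_deg"],
                               scale = cf["scale"], tx = cf["tx"],
                               ty = cf["ty"], final_metric = fit$final_metric,
                               iterations = fit$iterations_used,
                               converged = fit$converged)
    say("registered '%s': rot %.3f deg, scale %.4f, t (%.2f, %.2f), MI %.4f",
        marker, cf["rotation_deg"], cf["scale"], cf["tx"], cf["ty"],
        fit$final_metric)
  }
  utils::write.csv(do.call(rbind, reg_log),
                   file.path(out_dir, "registration_log.csv"),
                   row.names = FALSE)

  all_records <- list()
  for (p in config$pairs) {
    a <- p[1]; b <- p[2]
    if (is.null(frame[[a]]) || is.null(frame[[b]])) {
      say("skipping pair (%s, %s): image unavailable", a, b)
      next
    }
    pair_dir <- file.path(out_dir, paste0("pair_", safe_name(a), "_",
                                          safe_name(b)))
    res <- run_spaq(frame[[a]], frame[[b]], rois, config$thresholds,
                    stains = config$stains, marker_names = c(a, b),
                    out_dir = pair_dir)
    rec <- res$records
    names(rec)[names(rec) == paste0(a, "_pct")] <- "marker_a_pct"
    names(rec)[names(rec) == paste0(b, "_pct")] <- "marker_b_pct"
    rec <- data.frame(marker_a = a, marker_b = b, rec,
                      stringsAsFactors = FALSE)
    all_records[[paste(a, b, sep = "_")]] <- rec
    say("quantified pair (%s, %s): %d ROI(s)", a, b, nrow(rec))
  }
  records <- do.call(rbind, c(all_records, list(make.row.names = FALSE)))

  # signature classification when the two configured pairs are both present
  sig <- config$signatures
  if (!is.null(records) && !is.null(sig) && length(sig) == 2L) {
    keys <- vapply(sig, function(p) paste(sort(unlist(p)), collapse = "|"),
                   character(1))
    pair_key <- paste0(
      vapply(seq_len(nrow(records)), function(i)
        paste(sort(c(records$marker_a[i], records$marker_b[i])),
              collapse = "|"), character(1)))
    records$signature <- NA_character_
    for (roi in unique(records$roi_name)) {
      ol1 <- records$overlap_pct[records$roi_name == roi & pair_key == keys[1]]
      ol2 <- records$overlap_pct[records$roi_name == roi & pair_key == keys[2]]
      if (length(ol1) == 1L && length(ol2) == 1L &&
          !is.na(ol1) && !is.na(ol2)) {
        cls <- classify_signature(ol1, ol2, config$cutoff)
        records$signature[records$roi_name == roi &
                            pair_key %in% keys] <- cls
      }
    }
  }
  if (!is.null(records))
    export_results(records, file.path(out_dir, "results.csv"))
  yaml::write_yaml(config$raw, file.path(out_dir, "config_used.yaml"))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  structure(invisible(out_dir), records = records)
}
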