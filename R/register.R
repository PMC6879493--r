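#' Registration parameters
#'
#' Defaults follow the tool's recommended configuration: a maximum of 100
#' optimizer iterations per pyramid level, initial search radius 0.0018,
#' 3 pyramid levels, convergence tolerance (epsilon) 1.5e-06 on the search
#' radius, and radius growth factor 1.05 on each successful step.
#'
#' @param max_iterations optimizer iterations per pyramid level (>= 1).
#' @param initial_radius initial step radius of the one-plus-one evolutionary
#'   search, in normalised parameter units (> 0).
#' @param pyramid_levels number of coarse-to-fine resolution levels (>= 1).
#' @param epsilon convergence tolerance: the search stops when the step
#'   radius falls below it (> 0).
#' @param growth_factor radius multiplier after a successful step (> 1); the
#'   radius shrinks by `growth_factor^-0.25` after a failed step.
#' @param seed integer RNG seed for the stochastic search (reproducibility).
#' @param histogram_bins bins per axis of the mutual-information histogram.
#' @return an object of class `registration_params`.
#' @export
registration_params <- function(max_iterations = 100L,
                                initial_radius = 0.0018,
                                pyramid_levels = 3L,
                                epsilon = 1.5e-06,
                                growth_factor = 1.05,
                                seed = 1L,
                                histogram_bins = 50L) {
  stopifnot(max_iterations >= 1L, pyramid_levels >= 1L,
            growth_factor > 1, initial_radius > 0, epsilon > 0,
            histogram_bins >= 2L)
  structure(list(max_iterations = as.integer(max_iterations),
                 initial_radius = initial_radius,
                 pyramid_levels = as.integer(pyramid_levels),
                 epsilon = epsilon,
                 growth_factor = growth_factor,
                 seed = as.integer(seed),
                 histogram_bins = as.integer(histogram_bins)),
            class = "registration_params")
}

# Evaluate the MI metric (bits, fixed 0-255 binning) of moving resampled by
# parameter vector x = (theta_rad, log_scale, tx/W, ty/W) at one pyramid
# level.  Candidates whose overlap with the fixed frame drops below a quarter
# of the frame are rejected outright so background cannot drive the maximum.
mi_metric_level <- function(gf, gm, x, W_full, factor, bins) {
  h <- nrow(gf); w <- ncol(gf)
  ctr <- c((w - 1) / 2, (h - 1) / 2)
  reg <- cpp_resample_similarity(gm, h, w, x[1], exp(x[2]),
                                 x[3] * W_full / factor, x[4] * W_full / factor,
                                 ctr[1], ctr[2], TRUE)
  ok <- is.finite(reg)
  if (sum(ok) < 0.25 * length(reg)) return(-Inf)
  J <- cpp_joint_hist(as.numeric(gf), as.numeric(reg), bins, 0, 255, 0, 255)
  mi_from_joint(J)
}

# Initialisation of the similarity search: scan a grid of rotations and
# scales; for each candidate the best translation is read off the FFT
# cross-correlation of the background-subtracted "darkness" images, and the
# mutual information of the completed candidate decides the winner.  The
# identity transform always competes.  The scan runs one level above the
# coarsest so texture still carries orientation information; refinement below
# the grid pitch is deliberately left to the iterative search.
init_coarse <- function(gf, gm, W_full, factor, bins) {
  scan_similarity(gf, gm, W_full, factor, bins,
                  seq(-12, 12, by = 2) * pi / 180,
                  seq(0.90, 1.10, by = 0.02),
                  extra = list(c(0, 0, 0, 0)))
}

scan_similarity <- function(gf, gm, W_full, factor, bins,
                            rot_values, scale_values, extra = list()) {
  h <- nrow(gf); w <- ncol(gf)
  ctr <- c((w - 1) / 2, (h - 1) / 2)
  df <- 255 - gf
  df <- df - mean(df)
  Ff <- stats::fft(df)
  # rank candidates on a fixed central window so the comparison is over the
  # same pixel set: the overlap-only metric would otherwise favour larger
  # rotations simply because they exclude more background
  rows <- max(1L, round(0.15 * h)):min(h, round(0.85 * h))
  cols <- max(1L, round(0.15 * w)):min(w, round(0.85 * w))
  gf_win <- gf[rows, cols]
  mi_window <- function(x0) {
    reg <- cpp_resample_similarity(gm, h, w, x0[1], exp(x0[2]),
                                   x0[3] * W_full / factor,
                                   x0[4] * W_full / factor,
                                   ctr[1], ctr[2], TRUE)
    mi_from_values(as.numeric(gf_win), as.numeric(reg[rows, cols]), bins)
  }
  cands <- extra
  for (rot in rot_values) {
    for (sc in scale_values) {
      dm <- cpp_resample_similarity(gm, h, w, rot, sc, 0, 0, ctr[1], ctr[2],
                                    TRUE)
      dm[is.na(dm)] <- 255
      dm <- (255 - dm)
      dm <- dm - mean(dm)
      cc <- Re(stats::fft(Ff * Conj(stats::fft(dm)), inverse = TRUE))
      k <- which.max(cc)
      dy <- (k - 1) %% h
      dx <- (k - 1) %/% h
      if (dy > h / 2) dy <- dy - h
      if (dx > w / 2) dx <- dx - w
      cands[[length(cands) + 1L]] <-
        c(rot, log(sc), dx * factor / W_full, dy * factor / W_full)
    }
  }
  vals <- vapply(cands, mi_window, numeric(1))
  cands[[which.max(vals)]]
}

build_pyramid <- function(g, levels) {
  pyr <- vector("list", levels)
  pyr[[levels]] <- g
  if (levels > 1L)
    for (l in (levels - 1L):1L) pyr[[l]] <- downsample_half(pyr[[l + 1L]])
  pyr
}

#' Register a moving image to a fixed reference (Spa-R)
#'
#' Estimates the similarity transform (rotation, isotropic scale, 2-D
#' translation) aligning `moving` to `fixed` by maximising the mutual
#' information between the reference and the resampled moving image.  The
#' search is a seeded one-plus-one evolutionary strategy over a coarse-to-fine
#' image pyramid: at each level the step radius starts at `initial_radius`,
#' grows by `growth_factor` on each metric improvement and shrinks otherwise,
#' and the level stops when the radius falls below `epsilon` or after
#' `max_iterations` steps.  The search is initialised by a coarse
#' rotation-and-scale grid scan whose per-candidate translation comes from
#' FFT cross-correlation, and the returned transform is the best-metric
#' candidate seen (never worse than the identity transform).
#'
#' Both images are converted internally to Rec. 601 luminance for the metric;
#' the returned `registered` image is the original `moving` resampled into
#' the fixed frame.
#'
#' @param fixed reference [raster_image] (any intensity kind).
#' @param moving image to align, a [raster_image].
#' @param params a [registration_params] object.
#' @return An object of class `spa_registration` with elements `transform`
#'   (a [similarity_transform]), `final_metric` (mutual information, bits),
#'   `iterations_used`, `converged`, `registered` (the resampled moving
#'   image), and `params`.  `coef()`, `predict()`, `summary()` and `plot()`
#'   methods are available.
#' @export
register_pair <- function(fixed, moving, params = registration_params()) {
  stopifnot_raster(fixed); stopifnot_raster(moving)
  stopifnot(inherits(params, "registration_params"))
  gf_full <- as_gray(fixed)$pixels
  gm_full <- as_gray(moving)$pixels
  H <- nrow(gf_full); W <- ncol(gf_full)
  ctr <- c((W - 1) / 2, (H - 1) / 2)
  identity_t <- similarity_transform(0, 1, 0, 0, ctr)
  if (diff(range(gf_full)) == 0 || diff(range(gm_full)) == 0) {
    warning("degenerate (constant) image: returning identity transform")
    return(new_spa_registration(identity_t, 0, 0L, FALSE,
                                apply_transform(moving, identity_t, c(H, W)),
                                params, dim_fixed = c(H, W)))
  }

  levels <- params$pyramid_levels
  # never let the coarsest level collapse below ~32 px
  while (levels > 1L && min(H, W) / 2^(levels - 1L) < 32) levels <- levels - 1L
  pf <- build_pyramid(gf_full, levels)
  pm <- build_pyramid(gm_full, levels)
  factors <- 2^((levels - 1L):0L)
  bins <- params$histogram_bins

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()), add = TRUE)
  set.seed(params$seed)

  # --- initialisation: rotation/scale scan with correlation shift ----------
  # done one level above the coarsest, where texture still carries
  # orientation information
  sl <- max(1L, levels - 1L)
  x <- init_coarse(pf[[sl]], pm[[sl]], W, factors[sl], bins)

  # --- one-plus-one evolutionary search over the pyramid -------------------
  shrink <- params$growth_factor^(-0.25)
  # per-parameter step scales (rotation rad, log scale, tx/W, ty/W): after
  # the scan the translation is already near its conditional optimum, so its
  # steps are kept smaller than the rotation/scale steps
  step_scale <- c(1, 0.5, 0.25, 0.25)
  iterations_used <- 0L
  converged <- FALSE
  for (l in seq_len(levels)) {
    gf <- pf[[l]]; gm <- pm[[l]]; fac <- factors[l]
    m_cur <- mi_metric_level(gf, gm, x, W, fac, bins)
    radius <- params$initial_radius
    converged <- FALSE
    for (it in seq_len(params$max_iterations)) {
      iterations_used <- iterations_used + 1L
      cand <- x + radius * step_scale * stats::rnorm(4)
      # keep the search inside a sane similarity envelope
      if (abs(cand[1]) > pi / 2 || abs(cand[2]) > log(2)) {
        radius <- radius * shrink
      } else {
        m_c <- mi_metric_level(gf, gm, cand, W, fac, bins)
        if (m_c > m_cur) {
          x <- cand; m_cur <- m_c
          radius <- radius * params$growth_factor
        } else {
          radius <- radius * shrink
        }
      }
      if (radius < params$epsilon) { converged <- TRUE; break }
    }
  }

  # --- best-so-far policy: never return worse than the identity ------------
  m_final <- mi_metric_level(pf[[levels]], pm[[levels]], x, W, 1, bins)
  m_ident <- mi_metric_level(pf[[levels]], pm[[levels]], c(0, 0, 0, 0),
                             W, 1, bins)
  if (m_ident > m_final) { x <- c(0, 0, 0, 0); m_final <- m_ident }

  tr <- similarity_transform(x[1] * 180 / pi, exp(x[2]),
                             x[3] * W, x[4] * W, ctr)
  new_spa_registration(tr, m_final, iterations_used, converged,
                       apply_transform(moving, tr, c(H, W)),
                       params, dim_fixed = c(H, W))
}

new_spa_registration <- function(transform, final_metric, iterations_used,
                                 converged, registered, params, dim_fixed) {
  structure(list(transform = transform, final_metric = final_metric,
                 iterations_used = iterations_used, converged = converged,
                 registered = registered, params = params,
                 dim_fixed = dim_fixed),
            class = "spa_registration")
}

#' @export
print.spa_registration <- function(x, ...) {
  cat("Similarity-transform registration (mutual information)\n")
  print(x$transform)
  cat(sprintf("  final metric: %.4f bits   iterations: %d   converged: %s\n",
              x$final_metric, x$iterations_used, x$converged))
  invisible(x)
}

#' @export
summary.spa_registration <- function(object, ...) {
  print(object)
  p <- object$params
  cat(sprintf(
    "  params: max_iterations=%d, initial_radius=%g, pyramid_levels=%d,\n          epsilon=%g, growth_factor=%g, seed=%d, bins=%d\n",
    p$max_iterations, p$initial_radius, p$pyramid_levels, p$epsilon,
    p$growth_factor, p$seed, p$histogram_bins))
  invisible(object)
}

#' @export
coef.spa_registration <- function(object, ...) {
  t <- object$transform
  c(rotation_deg = t$rotation_deg, scale = t$scale, tx = t$tx, ty = t$ty)
}

#' Resample a new image with a fitted registration transform
#'
#' @param object a `spa_registration`.
#' @param newdata a [raster_image] in the moving frame (defaults to the
#'   moving image used for the fit, returning `object$registered`).
#' @param ... unused.
#' @return the resampled [raster_image] in the fixed frame.
#' @export
predict.spa_registration <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$registered)
  apply_transform(newdata, object$transform, object$dim_fixed)
}

#' Overlay plot of a fitted registration
#'
#' Renders the fixed image in the red channel and the registered moving image
#' in the green channel: aligned structure appears yellow, misalignment as
#' red/green fringes.
#'
#' @param x a `spa_registration`.
#' @param fixed the fixed [raster_image] used in the fit.
#' @param ... passed to [graphics::plot].
#' @export
plot.spa_registration <- function(x, fixed, ...) {
  gf <- as_gray(fixed)$pixels / 255
  gr <- as_gray(x$registered)$pixels / 255
  comp <- array(0, dim = c(dim(gf), 3L))
  comp[, , 1] <- 1 - gf
  comp[, , 2] <- 1 - gr
  graphics::plot(c(0, ncol(gf)), c(0, nrow(gf)), type = "n", asp = 1,
                 xlab = "x [px]", ylab = "y [px]", ...)
  graphics::rasterImage(grDevices::as.raster(comp), 0, 0, ncol(gf), nrow(gf))
  invisible(x)
}

#' Register a batch of moving images to one reference
#'
#' Each moving image is registered independently with the same parameters
#' (and the same seed, so identical inputs give identical transforms); a
#' failure on one image is recorded and does not abort the batch.
#'
#' @param fixed reference [raster_image].
#' @param movings non-empty list of [raster_image]s.
#' @param params a [registration_params].
#' @param verbose emit a per-image log line via [message()].
#' @return list of `spa_registration` (or `try-error` for failed items), in
#'   input order.
#' @export
register_batch <- function(fixed, movings, params = registration_params(),
                           verbose = TRUE) {
  stopifnot(is.list(movings), length(movings) >= 1L)
  out <- vector("list", length(movings))
  for (i in seq_along(movings)) {
    out[[i]] <- tryCatch(register_pair(fixed, movings[[i]], params),
                         error = function(e) {
                           if (verbose) message(sprintf(
                             "image %d: registration failed: %s", i,
                             conditionMessage(e)))
                           structure(conditionMessage(e), class = "try-error")
                         })
    if (verbose && inherits(out[[i]], "spa_registration"))
      message(sprintf("image %d: metric %.4f bits after %d iterations",
                      i, out[[i]]$final_metric, out[[i]]$iterations_used))
  }
  out
}

#' Mean corner displacement between two transforms
#'
#' Registration error measure: the four corners of the fixed frame are mapped
#' through both transforms and the mean Euclidean distance between the two
#' mappings is returned (pixels).
#'
#' @param est,truth [similarity_transform]s.
#' @param shape `(h, w)` of the frame whose corners are tracked.
#' @return mean corner displacement in pixels.
#' @export
corner_displacement <- function(est, truth, shape) {
  h <- shape[1]; w <- shape[2]
  corners <- rbind(c(0, 0), c(w - 1, 0), c(0, h - 1), c(w - 1, h - 1))
  d <- transform_points(est, corners) - transform_points(truth, corners)
  mean(sqrt(rowSums(d^2)))
}

#' Parameter sweep harness for the registration optimizer
#'
#' Runs [register_pair()] over the cross-product of the supplied parameter
#' values and reports the final metric (and, when a ground-truth transform is
#' known, the mean corner displacement error) per combination.
#'
#' @param fixed,moving [raster_image]s.
#' @param grid named list of value vectors for any of `max_iterations`,
#'   `initial_radius`, `pyramid_levels`, `epsilon`, `growth_factor`, `seed`.
#' @param truth optional ground-truth [similarity_transform]; adds an
#'   `error_px` column.
#' @param out_csv optional path; the sweep table is written there as CSV.
#' @return data frame with one row per combination: the parameter values,
#'   `final_metric`, `iterations_used`, `converged`, and `error_px` when
#'   `truth` is given.  Failed runs carry `NaN` metric.
#' @export
sweep_params <- function(fixed, moving, grid, truth = NULL, out_csv = NULL) {
  stopifnot(is.list(grid), length(grid) >= 1L)
  allowed <- c("max_iterations", "initial_radius", "pyramid_levels",
               "epsilon", "growth_factor", "seed")
  bad <- setdiff(names(grid), allowed)
  if (length(bad)) stop(sprintf("unknown sweep parameter(s): %s",
                                paste(bad, collapse = ", ")))
  tab <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$final_metric <- NA_real_
  tab$iterations_used <- NA_integer_
  tab$converged <- NA
  if (!is.null(truth)) tab$error_px <- NA_real_
  for (i in seq_len(nrow(tab))) {
    args <- as.list(tab[i, names(grid), drop = FALSE])
    p <- do.call(registration_params, args)
    fit <- tryCatch(register_pair(fixed, moving, p), error = function(e) NULL)
    if (is.null(fit)) { tab$final_metric[i] <- NaN; next }
    tab$final_metric[i] <- fit$final_metric
    tab$iterations_used[i] <- fit$iterations_used
    tab$converged[i] <- fit$converged
    if (!is.null(truth))
      tab$error_px[i] <- corner_displacement(fit$transform, truth,
                                             dim(fixed$pixels)[1:2])
  }
  if (!is.null(out_csv)) utils::write.csv(tab, out_csv, row.names = FALSE)
  tab
}
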