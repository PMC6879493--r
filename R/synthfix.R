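#' Specification for a synthetic serial-section slide series
#'
#' Describes a virtual tissue block from which serial sections are "cut":
#' one or more lesion blobs with rough boundaries, per-marker DAB density
#' regions with requested area fractions and pairwise overlap, a similarity
#' transform per section (the serial-section mounting offset), and brightfield
#' H-plus-DAB colour formation via the forward Beer-Lambert model with
#' per-section noise.  Ground truth (realised pixel-count fractions and the
#' true transforms) is emitted alongside the images.
#'
#' @param size `(h, w)` of every section image in pixels.
#' @param n_lesions number of lesion blobs (each gets its own ROI).
#' @param marker_names names of the markers; one section is generated per
#'   marker, the first in the reference frame.
#' @param fractions list with `a`, `b` (per-marker positive fractions of ROI
#'   tissue, in `[0, 1]`) and `ol` (their overlap fraction,
#'   `ol <= min(a, b)`); for a third marker its fraction defaults to `b`.
#' @param lesion_radius_frac blob radius as a fraction of the smaller image
#'   dimension.
#' @param roughness relative amplitude of the blob boundary's random polar
#'   perturbation (non-convex, realistic ROI shapes).
#' @param h_density hematoxylin optical density inside tissue.
#' @param dab_density DAB optical density inside a marker-positive region.
#' @param noise list: `intensity_sd` (additive 8-bit Gaussian noise),
#'   `texture_amp` (relative amplitude of the smooth hematoxylin texture
#'   field), `texture_scale` (its correlation length, px), and
#'   `marker_jitter_px` (per-section perturbation of marker-region geometry,
#'   emulating the decorrelation between sections a few microns apart).
#' @param section_transforms optional list of [similarity_transform] (one per
#'   marker); when `NULL`, the first is the identity and the others are drawn
#'   uniformly from the documented recovery envelope: rotation within +/- 10
#'   degrees, scale in `[0.9, 1.1]`, translation within 5 percent of width.
#' @param seed RNG seed; the whole series is a deterministic function of the
#'   spec.
#' @return an object of class `synthetic_slide_spec`.
#' @export
synthetic_slide_spec <- function(size = c(512, 512),
                                 n_lesions = 1L,
                                 marker_names = c("pERK", "p4EBP1"),
                                 fractions = list(a = 0.30, b = 0.25, ol = 0.10),
                                 lesion_radius_frac = 0.32,
                                 roughness = 0.06,
                                 h_density = 0.55,
                                 dab_density = 0.8,
                                 noise = list(intensity_sd = 5,
                                              texture_amp = 0.15,
                                              texture_scale = 25,
                                              marker_jitter_px = 1),
                                 section_transforms = NULL,
                                 seed = 1L) {
  stopifnot(length(size) == 2L, all(size >= 64), n_lesions >= 1L,
            length(marker_names) >= 2L)
  fr <- fractions
  stopifnot(fr$a >= 0, fr$a <= 1, fr$b >= 0, fr$b <= 1, fr$ol >= 0)
  if (fr$ol > min(fr$a, fr$b) + 1e-12)
    stop("infeasible fractions: requested OL exceeds min(a, b)")
  defaults <- list(intensity_sd = 5, texture_amp = 0.15, texture_scale = 25,
                   marker_jitter_px = 1)
  noise <- utils::modifyList(defaults, noise)
  if (!is.null(section_transforms)) {
    stopifnot(length(section_transforms) == length(marker_names))
    for (t in section_transforms) {
      stopifnot(inherits(t, "similarity_transform"))
      if (abs(t$rotation_deg) > 10 + 1e-9 || t$scale < 0.9 - 1e-9 ||
          t$scale > 1.1 + 1e-9 ||
          max(abs(c(t$tx, t$ty))) > 0.05 * size[2] + 1e-9)
        warning("section transform outside the documented recovery envelope")
    }
  }
  structure(list(size = as.integer(size), n_lesions = as.integer(n_lesions),
                 marker_names = marker_names, fractions = fr,
                 lesion_radius_frac = lesion_radius_frac,
                 roughness = roughness, h_density = h_density,
                 dab_density = dab_density, noise = noise,
                 section_transforms = section_transforms,
                 seed = as.integer(seed)),
            class = "synthetic_slide_spec")
}

# Area of the intersection lens of two discs with radii r1, r2 at distance d.
lens_area <- function(d, r1, r2) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  tri <- 0.5 * sqrt(pmax(0, (-d + r1 + r2) * (d + r1 - r2) *
                            (d - r1 + r2) * (d + r1 + r2)))
  a1 + a2 - tri
}

# Smooth unit-variance-ish noise field: white noise blurred at `scale` px.
smooth_field <- function(h, w, scale) {
  f <- gaussian_blur(matrix(stats::rnorm(h * w), h, w), scale)
  f / stats::sd(f)
}

#' Generate a synthetic serial-section slide series
#'
#' Builds the reference-frame density maps (tissue hematoxylin texture plus
#' per-marker DAB regions), applies each section's similarity transform,
#' synthesises brightfield RGB via `I_c = 255 * 10^(-(M d)_c)` with additive
#' noise, and returns the images together with ROI polygons (in section-1
#' coordinates) and a ground-truth table of realised fractions and
#' transforms.
#'
#' Marker regions are discs placed inside each lesion whose radii and
#' separation are solved so the realised pixel-count fractions match the
#' requested ones; each non-reference section's region geometry is jittered
#' by `noise$marker_jitter_px` and ground truth is recomputed from the
#' realised (jittered) regions, so the truth table is exact by construction.
#'
#' @param spec a [synthetic_slide_spec].
#' @return list with `images` (one `rgb8` [raster_image] per marker),
#'   `rois` (list of [roi_polygon]), `transforms` (list of
#'   [similarity_transform], the true moving-to-fixed transforms),
#'   `truth` (data frame per ROI: `roi_name`, `tissue_px`, per-marker
#'   `<m>_pct`, pairwise `ol_<i>_<j>_pct`), `truth_transforms` (data frame of
#'   transform parameters per section), and `calibration` (the thresholds
#'   matched to the generative densities: `dab_threshold`,
#'   `tissue_threshold`, `hematoxylin_threshold`).
#' @export
generate_slide_series <- function(spec) {
  stopifnot(inherits(spec, "synthetic_slide_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()), add = TRUE)
  set.seed(spec$seed)

  h <- spec$size[1]; w <- spec$size[2]
  nm <- length(spec$marker_names)
  ctr <- c((w - 1) / 2, (h - 1) / 2)
  X <- matrix(rep(0:(w - 1), each = h), h, w)
  Y <- matrix(rep(0:(h - 1), times = w), h, w)

  # --- section transforms --------------------------------------------------
  transforms <- spec$section_transforms
  if (is.null(transforms)) {
    transforms <- vector("list", nm)
    transforms[[1]] <- similarity_transform(0, 1, 0, 0, ctr)
    for (s in 2:nm)
      transforms[[s]] <- similarity_transform(
        stats::runif(1, -10, 10), stats::runif(1, 0.9, 1.1),
        stats::runif(1, -0.05, 0.05) * w, stats::runif(1, -0.05, 0.05) * w,
        ctr)
  }

  # --- lesions and ROIs ----------------------------------------------------
  R0 <- spec$lesion_radius_frac * min(h, w)
  lesion_centres <- if (spec$n_lesions == 1L) list(ctr) else {
    ang <- seq(0, 2 * pi, length.out = spec$n_lesions + 1L)[-1L]
    lapply(ang, function(a) ctr + 0.55 * min(h, w) / 2 * c(cos(a), sin(a)))
  }
  R0 <- R0 / sqrt(spec$n_lesions)
  lesions <- list(); rois <- list()
  for (k in seq_len(spec$n_lesions)) {
    ck <- lesion_centres[[k]]
    m_h <- 2:5
    amp <- spec$roughness * stats::rnorm(length(m_h)) / sqrt(m_h)
    ph <- stats::runif(length(m_h), 0, 2 * pi)
    radius_at <- function(phi) {
      r <- rep(R0, length(phi))
      for (i in seq_along(m_h)) r <- r + R0 * amp[i] * cos(m_h[i] * phi + ph[i])
      r
    }
    phi_px <- atan2(Y - ck[2], X - ck[1])
    rad_px <- sqrt((X - ck[1])^2 + (Y - ck[2])^2)
    lesions[[k]] <- (rad_px < radius_at(phi_px)) * 1
    phi_v <- seq(0, 2 * pi, length.out = 73L)[-73L]
    rv <- 1.04 * radius_at(phi_v) + 1.5
    rois[[k]] <- roi_polygon(sprintf("lesion_%d", k),
                             cbind(x = ck[1] + rv * cos(phi_v),
                                   y = ck[2] + rv * sin(phi_v)))
  }
  tissue <- Reduce(pmax, lesions)

  # --- marker regions (reference frame), per section with jitter ----------
  fr <- spec$fractions
  frac_of <- function(i) if (i == 1L) fr$a else fr$b
  jit <- spec$noise$marker_jitter_px
  region_for <- function(lesion_idx, marker_idx, jitter) {
    lesion <- lesions[[lesion_idx]]
    ck <- lesion_centres[[lesion_idx]]
    N <- sum(lesion)
    rA <- sqrt(frac_of(1L) * N / pi)
    rB <- sqrt(frac_of(2L) * N / pi)
    ol_target <- fr$ol * N
    d <- if (ol_target <= 0) rA + rB + 2
    else if (ol_target >= pi * min(rA, rB)^2 - 1e-9) abs(rA - rB)
    else stats::uniroot(function(x) lens_area(x, rA, rB) - ol_target,
                        c(abs(rA - rB) + 1e-6, rA + rB - 1e-6))$root
    # discs on the horizontal axis through the lesion centre
    centres <- list(ck + c(-d / 2, 0), ck + c(d / 2, 0))
    radii <- c(rA, rB)
    if (marker_idx > 2L) {                 # extra markers: offset vertically
      centres[[marker_idx]] <- ck + c(0, d / 2)
      radii[marker_idx] <- rB
    }
    cc <- centres[[min(marker_idx, length(centres))]]
    rr <- radii[min(marker_idx, length(radii))]
    if (jitter > 0) {
      cc <- cc + stats::rnorm(2, sd = jitter)
      rr <- rr * (1 + stats::rnorm(1, sd = jitter / (4 * rr)))
    }
    (((X - cc[1])^2 + (Y - cc[2])^2 < rr^2) & lesion == 1) * 1
  }
  # region list: regions[[marker]][[lesion]]; reference section unjittered
  regions <- lapply(seq_len(nm), function(mi)
    lapply(seq_len(spec$n_lesions), function(li)
      region_for(li, mi, if (mi == 1L) 0 else jit)))

  # --- ground truth by pixel counting in the reference frame ---------------
  truth <- list()
  for (li in seq_len(spec$n_lesions)) {
    rmask <- rasterize_roi(rois[[li]], c(h, w))$pixels
    rt <- rmask * tissue
    N <- sum(rt)
    row <- list(roi_name = rois[[li]]$name, tissue_px = N)
    for (mi in seq_len(nm))
      row[[paste0(spec$marker_names[mi], "_pct")]] <-
        100 * sum(regions[[mi]][[li]] * rt) / N
    for (i in seq_len(nm - 1L)) for (j in (i + 1L):nm)
      row[[paste0("ol_", spec$marker_names[i], "_",
                  spec$marker_names[j], "_pct")]] <-
        100 * sum(regions[[i]][[li]] * regions[[j]][[li]] * rt) / N
    truth[[li]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)

  # --- render each section -------------------------------------------------
  M <- unclass(stain_matrix())
  images <- vector("list", nm)
  for (s in seq_len(nm)) {
    tex <- 1 + spec$noise$texture_amp *
      smooth_field(h, w, spec$noise$texture_scale)
    tex[tex < 0.2] <- 0.2
    h_map <- spec$h_density * tissue * tex
    d_map <- spec$dab_density * Reduce(pmax, regions[[s]])
    dens <- list(h = raster_image(pmax(h_map, 0), "od_float"),
                 dab = raster_image(pmax(d_map, 0), "od_float"))
    inv <- st_invert(transforms[[s]])
    h_s <- apply_transform(dens$h, inv, c(h, w))$pixels
    d_s <- apply_transform(dens$dab, inv, c(h, w))$pixels
    px <- array(0, dim = c(h, w, 3L))
    for (c3 in 1:3) {
      od_c <- M[c3, 1] * h_s + M[c3, 2] * d_s
      ic <- 255 * 10^(-od_c)
      if (spec$noise$intensity_sd > 0)
        ic <- ic + stats::rnorm(h * w, sd = spec$noise$intensity_sd)
      px[, , c3] <- pmin(pmax(round(ic), 0), 255)
    }
    images[[s]] <- raster_image(px, "rgb8")
  }
  names(images) <- spec$marker_names

  truth_transforms <- do.call(rbind, lapply(seq_len(nm), function(s) {
    t <- transforms[[s]]
    data.frame(section = s, marker = spec$marker_names[s],
               rotation_deg = t$rotation_deg, scale = t$scale,
               tx = t$tx, ty = t$ty, stringsAsFactors = FALSE)
  }))

  list(images = images, rois = rois, transforms = transforms,
       truth = truth, truth_transforms = truth_transforms,
       calibration = list(
         dab_threshold = round(255 * 10^(-spec$dab_density / 2)),
         tissue_threshold = 200,
         hematoxylin_threshold = 160))
}

#' Construct two masks with exact requested area and overlap fractions
#'
#' Integer pixel-count construction used for exact-arithmetic tests of the
#' quantification module: the requested fractions are rounded to the nearest
#' pixel count and the masks are built from a seeded random permutation of
#' the pixels, so `|A| = round(fraction_a * N)` etc. hold exactly.
#'
#' @param fraction_a,fraction_b,fraction_ol fractions in `[0, 1]` with
#'   `fraction_ol <= min(fraction_a, fraction_b)` and
#'   `fraction_a + fraction_b - fraction_ol <= 1`.
#' @param size `(h, w)` of the masks; the ROI is the full frame.
#' @param seed RNG seed for the pixel permutation.
#' @return list with `mask_a`, `mask_b` (`binary` [raster_image]s), `roi`
#'   (a rectangular [roi_polygon] covering every pixel centre), and `counts`
#'   (`n_a`, `n_b`, `n_ol`, `n_total`).
#' @export
make_overlap_pair <- function(fraction_a, fraction_b, fraction_ol,
                              size = c(100, 100), seed = 1L) {
  stopifnot(length(size) == 2L, all(size >= 2))
  h <- as.integer(size[1]); w <- as.integer(size[2])
  N <- h * w
  if (fraction_ol > min(fraction_a, fraction_b) + 1e-12)
    stop("infeasible request: OL fraction exceeds min(fraction_a, fraction_b)")
  n_a <- round(fraction_a * N); n_b <- round(fraction_b * N)
  n_ol <- round(fraction_ol * N)
  n_ol <- min(n_ol, n_a, n_b)
  if (n_a + n_b - n_ol > N)
    stop("infeasible request: union exceeds the ROI pixel count")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()), add = TRUE)
  set.seed(seed)
  perm <- sample.int(N)
  a <- logical(N); b <- logical(N)
  if (n_ol > 0) { both <- perm[seq_len(n_ol)]; a[both] <- TRUE; b[both] <- TRUE }
  if (n_a > n_ol) a[perm[(n_ol + 1):n_a]] <- TRUE
  if (n_b > n_ol) b[perm[(n_a + 1):(n_a + n_b - n_ol)]] <- TRUE
  roi <- roi_polygon("full_frame",
                     rbind(c(-0.5, -0.5), c(w - 0.5, -0.5),
                           c(w - 0.5, h - 0.5), c(-0.5, h - 0.5)))
  list(mask_a = raster_image(matrix(as.numeric(a), h, w), "binary"),
       mask_b = raster_image(matrix(as.numeric(b), h, w), "binary"),
       roi = roi,
       counts = list(n_a = n_a, n_b = n_b, n_ol = n_ol, n_total = N))
}
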