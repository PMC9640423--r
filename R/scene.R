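# Seeded simulator of WorldView-2-like river scenes with ground truth.
# A meandering river crosses the scene west to east, flanked by riparian
# forest strips that are interrupted by crop/urban intrusions; the remaining
# background is a patch mosaic steered towards a target class mix.

#' Default class mean spectra (8 WV-2 bands, reflectance)
#'
#' Chosen so the land-cover classes are separable the way they are on real
#' scenes: forest has the strongest NIR/red-edge contrast (high RE-NDVI),
#' water the lowest NIR, urban is bright with a weak red-edge step, crops sit
#' between forest and urban, bare soil is bright with an almost flat
#' NIR/red-edge profile.
#'
#' @return 8 x 5 numeric matrix, rows in WV-2 band order, columns named by
#'   class.
#' @export
default_class_spectra <- function() {
  m <- cbind(
    water     = c(0.080, 0.070, 0.060, 0.050, 0.040, 0.035, 0.020, 0.015),
    forest    = c(0.040, 0.045, 0.070, 0.060, 0.050, 0.180, 0.450, 0.470),
    crops     = c(0.060, 0.070, 0.110, 0.120, 0.130, 0.220, 0.320, 0.330),
    urban     = c(0.300, 0.320, 0.340, 0.350, 0.360, 0.340, 0.400, 0.400),
    bare_soil = c(0.220, 0.240, 0.270, 0.290, 0.310, 0.330, 0.360, 0.370)
  )
  rownames(m) <- wv2_band_names()
  m
}

# fixed panchromatic response: weighted sum over blue..NIR1, the spectral
# window a WV-2-like panchromatic band integrates
PAN_WEIGHTS <- c(0, 0.20, 0.25, 0.15, 0.25, 0.10, 0.05, 0)

#' Specification of a synthetic scene
#'
#' @param width_px,height_px multispectral grid size in pixels; the default
#'   768 x 128 at 2 m gives a 1536 m stream reach, enough for 15 stations
#'   of 100 m.
#' @param ms_resolution multispectral pixel size, metres (default 2).
#' @param pan_ratio integer MS/PAN resolution ratio (default 4, i.e. 0.5 m).
#' @param class_spectra 8 x k matrix of per-class mean reflectances in
#'   `[0, 1]`, columns named with classes from
#'   water/forest/crops/urban/bare_soil.
#' @param noise_sd standard deviation of iid Gaussian sensor noise added to
#'   every band (reflectance units).
#' @param river_width_m,riparian_width_m river channel width and riparian
#'   strip width on each bank, metres.
#' @param class_mix named target area fractions (must sum to 1). Water is
#'   realised by the river geometry; the background mosaic tops up the other
#'   classes towards their targets.
#' @param intrusion_rate probability that a 50-m stretch of riparian strip on
#'   one bank is replaced by a crop or urban intrusion.
#' @param seed integer seed; identical spec + seed gives bit-identical scenes.
#' @return a validated `scene_spec` object.
#' @export
scene_spec <- function(width_px = 768, height_px = 128, ms_resolution = 2,
                       pan_ratio = 4,
                       class_spectra = default_class_spectra()[, c("water", "forest", "crops", "urban")],
                       noise_sd = 0.02,
                       river_width_m = 20, riparian_width_m = 30,
                       class_mix = c(water = 0.10, forest = 0.45,
                                     crops = 0.30, urban = 0.15),
                       intrusion_rate = 0.35, seed = 1) {
  spec <- list(width_px = as.integer(width_px), height_px = as.integer(height_px),
               ms_resolution = ms_resolution, pan_ratio = as.integer(pan_ratio),
               class_spectra = class_spectra, noise_sd = noise_sd,
               river_width_m = river_width_m, riparian_width_m = riparian_width_m,
               class_mix = class_mix, intrusion_rate = intrusion_rate,
               seed = as.integer(seed))
  validate_scene_spec(spec)
  structure(spec, class = "scene_spec")
}

validate_scene_spec <- function(spec) {
  if (spec$width_px <= 0 || spec$height_px <= 0) {
    abort("scene dimensions must be positive")
  }
  if (spec$pan_ratio < 1) abort("pan_ratio must be >= 1")
  if (spec$noise_sd < 0) abort("noise_sd must be >= 0")
  cs <- spec$class_spectra
  if (nrow(cs) != 8 || any(cs < 0) || any(cs > 1)) {
    abort("class_spectra must be 8 reflectances in [0,1] per class")
  }
  unknown <- setdiff(names(spec$class_mix), RIPAQ_CLASSES)
  if (length(unknown)) {
    abort(paste("unknown class in class_mix:", paste(unknown, collapse = ", ")))
  }
  if (abs(sum(spec$class_mix) - 1) > 1e-9) abort("class_mix must sum to 1")
  if (!all(setdiff(names(spec$class_mix), "water") %in% colnames(cs))) {
    abort("every class in class_mix needs a spectrum")
  }
  invisible(spec)
}

#' Generate a synthetic WorldView-2-like scene
#'
#' Produces a co-registered multispectral image (8 bands at the MS
#' resolution), a panchromatic image at `pan_ratio` times finer resolution
#' over the same extent, and the ground truth (label raster, river
#' centerline, per-class areas). Pixel values are the class mean spectrum
#' plus iid Gaussian noise, clipped to `[0, 1]`; the panchromatic value is a
#' fixed weighted sum of the visible + NIR1 bands of the class mean.
#'
#' @param spec a [scene_spec()].
#' @return list with elements `ms` ([ms_image()]), `pan` ([pan_image()]) and
#'   `truth` (class `ripaq_truth`: `labels` raster of integer class codes,
#'   `centerline` tibble, `class_areas` tibble with km^2, `classes`).
#' @export
generate_scene <- function(spec) {
  validate_scene_spec(spec)
  withr::with_seed(spec$seed, generate_scene_impl(spec))
}

generate_scene_impl <- function(spec) {
  H <- spec$height_px; W <- spec$width_px; res <- spec$ms_resolution
  origin <- c(0, H * res)            # top-left corner; y grows northwards
  grid <- ripaq_raster(matrix(0, H, W), res, origin = origin)

  # meandering centerline: smoothed random walk, clamped away from the edges
  margin <- min(spec$river_width_m / 2 + spec$riparian_width_m + 30,
                H * res / 2 - res)
  xs <- (seq_len(W) - 0.5) * res
  walk <- cumsum(rnorm(W, 0, res * 0.6))
  k <- min(21L, W - (W + 1L) %% 2L)  # odd window <= W
  if (k >= 3) {
    sm <- stats::filter(walk, rep(1 / k, k), sides = 2)
    sm[is.na(sm)] <- walk[is.na(sm)]
    walk <- as.numeric(sm)
  }
  ys <- H * res / 2 + (walk - mean(walk))
  ys <- pmin(pmax(ys, margin), H * res - margin)
  centerline <- tibble(x = xs, y = ys)

  field <- stream_field(centerline, grid)
  lab <- matrix(NA_integer_, H, W)
  water_mask <- field$dist <= spec$river_width_m / 2
  rip_mask <- !water_mask & field$dist <= spec$river_width_m / 2 + spec$riparian_width_m
  lab[water_mask] <- class_code("water")

  # riparian strips: forest, with per-(50 m block, bank) intrusions
  block_len <- 50
  n_blocks <- max(1L, ceiling(field$length / block_len))
  intr_draw <- matrix(runif(n_blocks * 2), n_blocks, 2)       # cols: right, left
  intr_class <- matrix(sample(class_code(c("crops", "urban")),
                              n_blocks * 2, replace = TRUE), n_blocks, 2)
  blk <- pmin(floor(field$chainage / block_len) + 1L, n_blocks)
  sd_col <- ifelse(field$side > 0, 2L, 1L)
  rip_idx <- which(rip_mask)
  rip_lab <- rep(class_code("forest"), length(rip_idx))
  bi <- blk[rip_idx]; si <- sd_col[rip_idx]
  hit <- intr_draw[cbind(bi, si)] < spec$intrusion_rate
  rip_lab[hit] <- intr_class[cbind(bi, si)][hit]
  lab[rip_idx] <- rip_lab

  # background mosaic steered towards the residual class quotas
  bg_idx <- which(is.na(lab))
  if (length(bg_idx)) {
    mix <- spec$class_mix
    n_px <- H * W
    bg_classes <- setdiff(names(mix), "water")
    assigned <- vapply(bg_classes, function(cl) sum(lab == class_code(cl), na.rm = TRUE), 0)
    quota <- pmax(mix[bg_classes] * n_px - assigned, 0)
    if (sum(quota) == 0) quota[] <- 1
    quota <- quota / sum(quota) * length(bg_idx)

    n_seeds <- max(24L, min(length(bg_idx), round(length(bg_idx) / 300)))
    seed_idx <- sample(bg_idx, n_seeds)
    sr <- (seed_idx - 1L) %% H + 1L; sc <- (seed_idx - 1L) %/% H + 1L
    pr <- (bg_idx - 1L) %% H + 1L; pc <- (bg_idx - 1L) %/% H + 1L
    best <- rep(Inf, length(bg_idx)); patch <- integer(length(bg_idx))
    for (s in seq_len(n_seeds)) {
      d2 <- (pr - sr[s])^2 + (pc - sc[s])^2
      upd <- d2 < best
      best[upd] <- d2[upd]; patch[upd] <- s
    }
    sizes <- tabulate(patch, n_seeds)
    remaining <- quota
    patch_class <- integer(n_seeds)
    for (s in order(sizes, decreasing = TRUE)) {
      cl <- bg_classes[which.max(remaining)]
      patch_class[s] <- class_code(cl)
      remaining[cl] <- remaining[cl] - sizes[s]
    }
    lab[bg_idx] <- patch_class[patch]
  }

  # multispectral + panchromatic values
  spectra <- matrix(0, 8, length(RIPAQ_CLASSES))
  spectra[, class_code(colnames(spec$class_spectra))] <- spec$class_spectra
  ms_v <- array(0, c(H, W, 8))
  for (b in 1:8) {
    ms_v[, , b] <- pmin(pmax(matrix(spectra[b, lab], H, W) +
                               rnorm(H * W, 0, spec$noise_sd), 0), 1)
  }
  r <- spec$pan_ratio
  lab_f <- block_replicate(lab, r)
  pan_mean <- as.numeric(PAN_WEIGHTS %*% spectra)
  pan_v <- pmin(pmax(matrix(pan_mean[lab_f], H * r, W * r) +
                       rnorm(length(lab_f), 0, spec$noise_sd), 0), 1)

  classes_present <- sort(unique(as.integer(lab)))
  areas <- tibble(
    class = class_label(classes_present),
    area_km2 = vapply(classes_present,
                      function(k) sum(lab == k) * res^2 / 1e6, 0)
  )
  truth <- structure(
    list(labels = ripaq_raster(lab + 0, res, origin = origin,
                               band_names = "class"),
         centerline = centerline, class_areas = areas,
         classes = class_label(classes_present)),
    class = "ripaq_truth"
  )
  list(ms = ms_image(ms_v, res, origin = origin),
       pan = pan_image(pan_v, res / r, origin = origin),
       truth = truth)
}

#' Per-station RSQI computed directly from ground-truth labels
#'
#' The recovery oracle: scores the stations against the true label raster,
#' bypassing segmentation and classification entirely.
#'
#' @param truth a `ripaq_truth` from [generate_scene()].
#' @param stations station tibble from [make_stations()].
#' @param weights a [class_weights()] table.
#' @param buffer_width_m buffer half-width, metres.
#' @return tibble of station scores as from [score_stations()].
#' @export
truth_station_scores <- function(truth, stations, weights = class_weights(),
                                 buffer_width_m = 50) {
  score_station_table(truth$labels, truth$centerline, stations,
                      weights = weights, buffer_width_m = buffer_width_m)
}

#' Write a generated scene to disk
#'
#' Multispectral and panchromatic rasters and the truth labels go to TIFF
#' (with world file + JSON sidecar), the centerline to GeoJSON, and the
#' per-class area summary to CSV.
#'
#' @param scene list from [generate_scene()].
#' @param dir output directory (created if missing).
#' @return named character vector of the five file paths, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(ms = file.path(dir, "ms.tif"),
             pan = file.path(dir, "pan.tif"),
             truth = file.path(dir, "truth.tif"),
             stream = file.path(dir, "stream.geojson"),
             summary = file.path(dir, "truth_summary.csv"))
  write_raster(scene$ms, paths["ms"])
  write_raster(scene$pan, paths["pan"])
  write_raster(scene$truth$labels, paths["truth"])
  write_centerline(scene$truth$centerline, paths["stream"])
  utils::write.csv(scene$truth$class_areas, paths["summary"], row.names = FALSE)
  invisible(paths)
}
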