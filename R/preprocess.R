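# From raw MS + PAN rasters to the 4-band analysis composite:
# pansharpening, red-edge NDVI, PCA band reduction, standardised stack.

#' Pansharpen a multispectral image
#'
#' Least-squares component substitution with additive detail injection. The
#' panchromatic image is block-averaged to the MS grid, per-band injection
#' gains are fitted by regressing each MS band on the low-resolution
#' panchromatic intensity, and the spatial detail
#' `PAN - upsample(blockaverage(PAN))` is added band-wise with those gains.
#' Block-averaging the output back to the MS grid reproduces the input
#' exactly (up to `[0,1]` clipping), a Wald-style spectral-consistency
#' property.
#'
#' @param ms an [ms_image()].
#' @param pan a [pan_image()] over the same extent, at an integer resolution
#'   ratio.
#' @param clip clip output reflectances to `[0, 1]` (default TRUE).
#' @return an [ms_image()] at the panchromatic resolution.
#' @export
pansharpen <- function(ms, pan, clip = TRUE) {
  ratio <- ms$resolution / pan$resolution
  if (abs(ratio - round(ratio)) > 1e-9) {
    abort("MS/PAN resolution ratio must be an integer")
  }
  r <- as.integer(round(ratio))
  if (!isTRUE(all.equal(raster_extent(ms), raster_extent(pan), tolerance = 1e-9))) {
    abort("MS and PAN extents do not match")
  }
  pv <- raster_band(pan, 1)
  pan_lr <- block_average(pv, r)
  detail <- pv - block_replicate(pan_lr, r)
  vd <- stats::var(as.vector(pan_lr))
  out <- array(0, c(dim(pv), 8L))
  for (b in 1:8) {
    mb <- raster_band(ms, b)
    g <- if (vd > 0) stats::cov(as.vector(mb), as.vector(pan_lr)) / vd else 0
    ob <- block_replicate(mb, r) + g * detail
    if (clip) ob <- pmin(pmax(ob, 0), 1)
    out[, , b] <- ob
  }
  ms_image(out, resolution = pan$resolution, origin = ms$origin, crs = ms$crs)
}

#' Red-edge NDVI
#'
#' Per-pixel `(NIR - RE) / (NIR + RE)` using the WV-2 NIR1 (band 7) and
#' red-edge (band 6) bands. Less saturation-prone over dense vegetation than
#' the classic red-band NDVI. Pixels where `NIR + RE == 0`, or where either
#' band is nodata, are nodata in the result.
#'
#' @param ms an [ms_image()].
#' @param nir_band,re_band band indices of NIR and red-edge (defaults 7, 6).
#' @return single-band `ripaq_raster` with values in `[-1, 1]` (or `NA`).
#' @export
re_ndvi <- function(ms, nir_band = 7L, re_band = 6L) {
  nir <- raster_band(ms, nir_band)
  re <- raster_band(ms, re_band)
  denom <- nir + re
  v <- (nir - re) / denom
  v[!is.na(denom) & denom == 0] <- NA_real_
  ripaq_raster(v, ms$resolution, ms$origin, ms$crs, band_names = "re_ndvi")
}

#' PCA reduction of the spectral bands
#'
#' Principal components of the band covariance matrix (reflectances centred,
#' not rescaled), fitted over valid (non-nodata) pixels only. Reduces and
#' synthesises the spectral variability of the 8 bands into a few components.
#'
#' @param ms an [ms_image()].
#' @param n_components number of component rasters to return (1-8).
#' @return list of class `ripaq_pca`: `components` (list of single-band
#'   rasters), `explained_variance` (all 8 fractions, descending), `rotation`,
#'   `center`.
#' @export
pca_reduce <- function(ms, n_components = 3L) {
  if (n_components < 1 || n_components > 8) abort("n_components must be in 1..8")
  d <- dim(ms$values)
  m <- matrix(ms$values, d[1] * d[2], d[3])
  valid <- stats::complete.cases(m)
  if (!any(valid)) abort("all pixels are nodata")
  fit <- prcomp(m[valid, , drop = FALSE], center = TRUE, scale. = FALSE)
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  comps <- lapply(seq_len(n_components), function(k) {
    v <- rep(NA_real_, d[1] * d[2])
    v[valid] <- fit$x[, k]
    ripaq_raster(matrix(v, d[1], d[2]), ms$resolution, ms$origin, ms$crs,
                 band_names = paste0("pc", k))
  })
  structure(list(components = comps, explained_variance = ev,
                 rotation = fit$rotation, center = fit$center),
            class = "ripaq_pca")
}

#' Assemble the 4-band analysis composite
#'
#' Stacks the leading principal components with the red-edge NDVI into the
#' raster that segmentation and classification operate on. Each band is
#' standardised to zero mean / unit variance over valid pixels so the equal
#' band weights of the segmentation criterion are meaningful; nodata in any
#' input band propagates to the composite pixel.
#'
#' @param pca a `ripaq_pca` from [pca_reduce()].
#' @param rendvi the red-edge NDVI raster from [re_ndvi()].
#' @param n_pcs number of principal components to include (default 3, giving
#'   the 4-band PC1-PC3 + RE-NDVI stack; 1 gives the PC1 + RE-NDVI variant).
#' @return `ripaq_raster` of class `composite_raster` with
#'   `explained_variance` attached.
#' @export
build_composite <- function(pca, rendvi, n_pcs = 3L) {
  if (n_pcs > length(pca$components)) abort("not enough fitted components")
  layers <- c(lapply(pca$components[seq_len(n_pcs)], raster_band, b = 1),
              list(raster_band(rendvi, 1)))
  d0 <- dim(layers[[1]])
  if (!all(vapply(layers, function(l) identical(dim(l), d0), TRUE))) {
    abort("composite inputs are not on the same grid")
  }
  mask <- Reduce(`|`, lapply(layers, is.na))
  v <- array(NA_real_, c(d0, length(layers)))
  for (b in seq_along(layers)) {
    l <- layers[[b]]
    l[mask] <- NA_real_
    mu <- mean(l, na.rm = TRUE)
    sg <- sd_pop(l[!is.na(l)])
    v[, , b] <- if (sg > 0) (l - mu) / sg else l - mu
  }
  out <- ripaq_raster(v, rendvi$resolution, rendvi$origin, rendvi$crs,
                      band_names = c(paste0("pc", seq_len(n_pcs)), "re_ndvi"))
  attr(out, "explained_variance") <- pca$explained_variance
  class(out) <- c("composite_raster", class(out))
  out
}

sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' One-call preprocessing: MS + PAN to composite
#'
#' Runs [pansharpen()] (optional), [re_ndvi()], [pca_reduce()] and
#' [build_composite()]. With a list of images from several acquisition
#' dates, each date is preprocessed separately and the composites are
#' unified by a band-wise mean.
#'
#' @param ms an [ms_image()] or list of them (multi-date).
#' @param pan matching [pan_image()] or list, or NULL to stay at MS
#'   resolution.
#' @param n_pcs principal components in the composite (default 3).
#' @return list with `composite` (composite_raster), `rendvi` (raw red-edge
#'   NDVI at analysis resolution), `ms` (analysis-resolution multispectral),
#'   `explained_variance`.
#' @export
preprocess_scene <- function(ms, pan = NULL, n_pcs = 3L) {
  if (inherits(ms, "ripaq_raster")) ms <- list(ms)
  if (inherits(pan, "ripaq_raster")) pan <- list(pan)
  runs <- purrr::map(seq_along(ms), function(i) {
    m <- if (!is.null(pan)) pansharpen(ms[[i]], pan[[i]]) else ms[[i]]
    nd <- re_ndvi(m)
    p <- pca_reduce(m, n_components = n_pcs)
    list(composite = build_composite(p, nd, n_pcs = n_pcs), rendvi = nd,
         ms = m, ev = p$explained_variance)
  })
  if (length(runs) == 1L) {
    r <- runs[[1]]
    return(list(composite = r$composite, rendvi = r$rendvi, ms = r$ms,
                explained_variance = r$ev))
  }
  mean_stack <- function(rasters) {
    v <- Reduce(`+`, lapply(rasters, function(r) r$values)) / length(rasters)
    out <- rasters[[1]]
    out$values <- v
    out
  }
  comp <- mean_stack(lapply(runs, `[[`, "composite"))
  attr(comp, "explained_variance") <-
    Reduce(`+`, lapply(runs, `[[`, "ev")) / length(runs)
  list(composite = comp,
       rendvi = mean_stack(lapply(runs, `[[`, "rendvi")),
       ms = mean_stack(lapply(runs, `[[`, "ms")),
       explained_variance = attr(comp, "explained_variance"))
}
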