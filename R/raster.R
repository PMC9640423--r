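#' Lightweight georeferenced raster
#'
#' An in-memory raster: an `H x W` matrix (one band) or `H x W x B` array
#' (multi-band) with a north-up affine georeference (top-left corner origin,
#' square pixels) and an optional nodata mask stored as `NA`.
#'
#' Rows run north to south, columns west to east, matching the usual
#' satellite-image layout. Map coordinates of the centre of pixel
#' `(row, col)` are `x = xmin + (col - 0.5) * res`,
#' `y = ymax - (row - 0.5) * res`.
#'
#' @param values matrix or 3-d array of band values; `NA` marks nodata.
#' @param resolution pixel size in metres.
#' @param origin numeric `c(xmin, ymax)`, the map coordinates of the
#'   top-left corner of the grid.
#' @param crs character CRS identifier kept as metadata (e.g. an EPSG code).
#' @param band_names optional character vector, one name per band.
#' @return a `ripaq_raster` object.
#' @export
ripaq_raster <- function(values, resolution, origin = c(0, 0),
                         crs = "EPSG:32629", band_names = NULL) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  if (length(dim(values)) != 3L) {
    abort("`values` must be a matrix or an H x W x B array.")
  }
  if (any(dim(values)[1:2] < 1L)) abort("raster dimensions must be positive")
  if (!is.null(band_names) && length(band_names) != dim(values)[3]) {
    abort("`band_names` length must equal the number of bands.")
  }
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0) {
    abort("`resolution` must be a single positive number.")
  }
  structure(
    list(values = values, resolution = as.numeric(resolution),
         origin = as.numeric(origin), crs = crs, band_names = band_names),
    class = "ripaq_raster"
  )
}

#' @export
print.ripaq_raster <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ripaq_raster> %d x %d px, %d band(s), %.3g m/px, origin (%g, %g), %s\n",
              d[1], d[2], d[3], x$resolution, x$origin[1], x$origin[2], x$crs))
  if (!is.null(x$band_names)) cat("bands:", paste(x$band_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ripaq_raster <- function(x) dim(x$values)

n_bands <- function(r) dim(r$values)[3]

raster_band <- function(r, b) r$values[, , b]

#' Map extent of a raster
#' @param r a `ripaq_raster`.
#' @return named numeric `c(xmin, xmax, ymin, ymax)`.
#' @export
raster_extent <- function(r) {
  d <- dim(r$values)
  c(xmin = r$origin[1], xmax = r$origin[1] + d[2] * r$resolution,
    ymin = r$origin[2] - d[1] * r$resolution, ymax = r$origin[2])
}

#' Pixel-centre coordinates
#' @param r a `ripaq_raster`.
#' @return list with vectors `x` (length W) and `y` (length H, north to south).
#' @export
pixel_centers <- function(r) {
  d <- dim(r$values)
  list(x = r$origin[1] + (seq_len(d[2]) - 0.5) * r$resolution,
       y = r$origin[2] - (seq_len(d[1]) - 0.5) * r$resolution)
}

#' Convert a raster to a long tibble
#'
#' One row per pixel and band, with map coordinates of pixel centres.
#'
#' @param x a `ripaq_raster`.
#' @param ... unused.
#' @return tibble with columns `row`, `col`, `x`, `y`, `band`, `value`.
#' @export
as_tibble.ripaq_raster <- function(x, ...) {
  r <- x
  d <- dim(r$values)
  cc <- pixel_centers(r)
  bn <- r$band_names %||% paste0("band", seq_len(d[3]))
  purrr::map_dfr(seq_len(d[3]), function(b) {
    tibble(row = rep(seq_len(d[1]), times = d[2]),
           col = rep(seq_len(d[2]), each = d[1]),
           x = rep(cc$x, each = d[1]),
           y = rep(cc$y, times = d[2]),
           band = bn[b],
           value = as.vector(r$values[, , b]))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' WorldView-2 band names, in sensor order
#' @return character vector of the 8 multispectral band names.
#' @export
wv2_band_names <- function() {
  c("coastal", "blue", "green", "yellow", "red", "rededge", "nir1", "nir2")
}

#' Construct a WorldView-2-like multispectral image
#'
#' Wraps an `H x W x 8` reflectance array with the fixed WV-2 band order
#' (coastal, blue, green, yellow, red, red-edge, NIR1, NIR2). The red-edge
#' band is band 6 and NIR1 is band 7, the pair used by the red-edge NDVI.
#'
#' @param values `H x W x 8` array of reflectances in `[0, 1]` (`NA` nodata).
#' @inheritParams ripaq_raster
#' @return a `ripaq_raster` with subclass `ms_image`.
#' @export
ms_image <- function(values, resolution = 2, origin = c(0, 0),
                     crs = "EPSG:32629") {
  if (length(dim(values)) != 3L || dim(values)[3] != 8L) {
    abort("a multispectral image needs exactly 8 bands in WV-2 order")
  }
  r <- ripaq_raster(values, resolution, origin, crs, wv2_band_names())
  class(r) <- c("ms_image", class(r))
  r
}

#' Construct a panchromatic image
#' @param values `H x W` matrix of panchromatic values.
#' @inheritParams ripaq_raster
#' @return a `ripaq_raster` with subclass `pan_image`.
#' @export
pan_image <- function(values, resolution = 0.5, origin = c(0, 0),
                      crs = "EPSG:32629") {
  r <- ripaq_raster(as.matrix(values), resolution, origin, crs, "pan")
  class(r) <- c("pan_image", class(r))
  r
}

# --- block resampling -------------------------------------------------------

#' Block-average a matrix by an integer factor
#' @param m numeric matrix with dimensions divisible by `f`.
#' @param f integer aggregation factor.
#' @return matrix of size `dim(m)/f`; each cell the mean of an `f x f` block.
#' @export
block_average <- function(m, f) {
  f <- as.integer(f)
  d <- dim(m)
  if (any(d %% f != 0L)) abort("matrix dimensions must be divisible by `f`")
  if (f == 1L) return(m)
  h <- d[1] %/% f; w <- d[2] %/% f
  # sum over f x f blocks via two reshapes
  a <- array(m, c(f, h, f, w))
  out <- apply(a, c(2, 4), mean)
  dim(out) <- c(h, w)
  out
}

#' Replicate each matrix cell into an f x f block
#' @param m numeric matrix.
#' @param f integer expansion factor.
#' @return matrix of size `dim(m)*f`.
#' @export
block_replicate <- function(m, f) {
  f <- as.integer(f)
  if (f == 1L) return(m)
  m[rep(seq_len(nrow(m)), each = f), rep(seq_len(ncol(m)), each = f)]
}

# --- file IO ----------------------------------------------------------------

#' Write a raster as TIFF with world file and metadata sidecar
#'
#' Bands are linearly rescaled into `[0, 1]` for 32-bit TIFF storage; the
#' per-band offset/scale, nodata encoding, CRS and band names go to a JSON
#' sidecar (`<path>.aux.json`) and the affine georeference to an ESRI world
#' file (`.tfw`), so the triplet is a plain-text-georeferenced TIFF.
#'
#' @param r a `ripaq_raster`.
#' @param path output path ending in `.tif`.
#' @return `path`, invisibly.
#' @export
write_raster <- function(r, path) {
  v <- r$values
  nb <- dim(v)[3]
  off <- sca <- numeric(nb)
  enc <- array(0, dim(v))
  has_na <- anyNA(v)
  for (b in seq_len(nb)) {
    x <- v[, , b]
    rng <- range(x, na.rm = TRUE)
    if (!all(is.finite(rng))) rng <- c(0, 1)          # all-nodata band
    if (rng[1] == rng[2]) rng[2] <- rng[1] + 1
    off[b] <- rng[1]; sca[b] <- rng[2] - rng[1]
    xe <- (x - off[b]) / sca[b]
    xe[is.na(xe)] <- 0
    enc[, , b] <- xe
  }
  # store the nodata mask as an extra band so NA patterns survive storage
  na_band <- array(0, dim(v)[1:2])
  if (has_na) {
    for (b in seq_len(nb)) na_band[is.na(v[, , b])] <- 1
  }
  pages <- c(lapply(seq_len(nb), function(b) enc[, , b]), list(na_band))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(offset = off, scale = sca, n_bands = nb, crs = r$crs,
               band_names = r$band_names, resolution = r$resolution,
               nodata_band = TRUE)
  jsonlite::write_json(meta, paste0(path, ".aux.json"), auto_unbox = TRUE,
                       digits = NA)
  tfw <- c(r$resolution, 0, 0, -r$resolution,
           r$origin[1] + r$resolution / 2, r$origin[2] - r$resolution / 2)
  writeLines(format(tfw, scientific = FALSE, trim = TRUE),
             sub("\\.tiff?$", ".tfw", path))
  invisible(path)
}

#' Read a raster written by [write_raster()]
#' @param path path to the `.tif` file.
#' @return a `ripaq_raster`.
#' @export
read_raster <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".aux.json"), simplifyVector = TRUE)
  pages <- suppressWarnings(tiff::readTIFF(path, all = TRUE))
  nb <- meta$n_bands
  v <- array(NA_real_, c(dim(pages[[1]])[1:2], nb))
  for (b in seq_len(nb)) v[, , b] <- pages[[b]] * meta$scale[b] + meta$offset[b]
  if (isTRUE(meta$nodata_band)) {
    mask <- pages[[nb + 1L]] > 0.5
    for (b in seq_len(nb)) {
      vb <- v[, , b]; vb[mask] <- NA_real_; v[, , b] <- vb
    }
  }
  tfw <- as.numeric(readLines(sub("\\.tiff?$", ".tfw", path)))
  res <- tfw[1]
  origin <- c(tfw[5] - res / 2, tfw[6] + res / 2)
  ripaq_raster(v, res, origin, crs = meta$crs,
               band_names = if (length(meta$band_names)) meta$band_names)
}

#' Write a polyline as GeoJSON LineString
#' @param line data frame or tibble with columns `x`, `y` (map coordinates).
#' @param path output `.geojson` path.
#' @param crs CRS identifier recorded as a foreign member.
#' @return `path`, invisibly.
#' @export
write_centerline <- function(line, path, crs = "EPSG:32629") {
  gj <- list(
    type = "Feature",
    properties = list(crs = crs),
    geometry = list(type = "LineString",
                    coordinates = unname(as.matrix(line[, c("x", "y")])))
  )
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GeoJSON LineString centerline
#' @param path path to a GeoJSON file holding a LineString feature.
#' @return tibble with columns `x`, `y`.
#' @export
read_centerline <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = TRUE)
  geom <- if (!is.null(gj$geometry)) gj$geometry else gj
  if (!identical(geom$type, "LineString")) abort("expected a GeoJSON LineString")
  m <- geom$coordinates
  tibble(x = m[, 1], y = m[, 2])
}
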