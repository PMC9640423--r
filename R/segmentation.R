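# R-side surface of the region-merging segmentation: parameter object,
# wrapper around the compiled core, per-segment statistics, sanity checks.

#' Segmentation parameters
#'
#' `scale` bounds the permitted heterogeneity increase of a merge (the
#' fusion cost must stay below `scale^2`), so larger scales give larger
#' objects. `shape_weight` balances shape vs colour heterogeneity and
#' `compactness_weight` balances compactness vs smoothness within the shape
#' term. Defaults follow common practice for riparian mapping with
#' VHR imagery: scale 25, shape 0.1, compactness 0.1.
#'
#' @param scale positive scale parameter.
#' @param shape_weight,compactness_weight weights in `[0, 1]`.
#' @return a `segmentation_params` object.
#' @export
segmentation_params <- function(scale = 25, shape_weight = 0.1,
                                compactness_weight = 0.1) {
  if (scale <= 0) abort("scale must be > 0")
  if (shape_weight < 0 || shape_weight > 1 ||
      compactness_weight < 0 || compactness_weight > 1) {
    abort("shape and compactness weights must be in [0, 1]")
  }
  structure(list(scale = scale, shape_weight = shape_weight,
                 compactness_weight = compactness_weight),
            class = "segmentation_params")
}

#' Multiresolution region-merging segmentation
#'
#' Bottom-up pairwise merging from single-pixel seeds under the combined
#' colour/shape heterogeneity criterion, with local mutual-best-fitting and
#' deterministic (lowest-id) tie-breaking; see [segmentation_params()] for
#' the meaning of the parameters. Band weights are equal. Segments are
#' 4-connected; diagonal neighbours are not adjacent.
#'
#' @param composite a multi-band `ripaq_raster` (typically the
#'   [build_composite()] output).
#' @param params a [segmentation_params()].
#' @param mask optional logical `H x W` matrix; pixels outside the mask (or
#'   nodata pixels) are left unsegmented (`NA` label).
#' @return object of class `ripaq_segmap`: list with `labels` (`H x W`
#'   integer matrix, ids `1..n_segments` gapless), `n_segments`, `params`,
#'   and the source grid georeference.
#' @export
multiresolution_segment <- function(composite, params = segmentation_params(),
                                    mask = NULL) {
  v <- composite$values
  d <- dim(v)
  valid <- !apply(is.na(v), c(1, 2), any)
  if (!is.null(mask)) {
    if (!identical(dim(mask), d[1:2])) abort("mask does not match the grid")
    valid <- valid & mask
  }
  if (!any(valid)) abort("empty mask: no valid pixels to segment")
  if (any(!is.finite(v[rep(valid, d[3])]))) {
    abort("non-finite composite values inside the mask")
  }
  vv <- v
  vv[is.na(vv)] <- 0  # invalid pixels never touched by the core
  lab <- .mrs_segment_cpp(as.numeric(vv), d[1], d[2], d[3],
                          as.logical(valid), params$scale,
                          params$shape_weight, params$compactness_weight)
  n_seg <- attr(lab, "n_segments")
  labels <- matrix(as.integer(lab), d[1], d[2])
  structure(list(labels = labels, n_segments = n_seg, params = params,
                 resolution = composite$resolution, origin = composite$origin,
                 crs = composite$crs),
            class = "ripaq_segmap")
}

#' @export
print.ripaq_segmap <- function(x, ...) {
  cat(sprintf("<ripaq_segmap> %d segments over %d x %d px (scale %.3g)\n",
              x$n_segments, nrow(x$labels), ncol(x$labels), x$params$scale))
  invisible(x)
}

#' Per-segment statistics
#'
#' Per-band mean and population standard deviation, pixel count, and
#' perimeter (in exposed pixel edges, counting image and mask borders) for
#' every segment.
#'
#' @param segmap a `ripaq_segmap`.
#' @param raster a `ripaq_raster` on the same grid.
#' @return tibble with one row per segment: `segment_id`, `area_px`,
#'   `perimeter_px`, then `mean_<band>` and `sd_<band>` columns.
#' @export
segment_stats <- function(segmap, raster) {
  v <- raster$values
  if (!identical(dim(v)[1:2], dim(segmap$labels))) {
    abort("raster grid does not match the segment map")
  }
  ids <- as.vector(segmap$labels)
  keep <- !is.na(ids)
  idk <- ids[keep]
  n <- segmap$n_segments
  area <- tabulate(idk, n)
  bn <- raster$band_names %||% paste0("band", seq_len(dim(v)[3]))
  out <- tibble(segment_id = seq_len(n), area_px = area,
                perimeter_px = segment_perimeters(segmap$labels))
  for (b in seq_len(dim(v)[3])) {
    x <- as.vector(v[, , b])[keep]
    s1 <- as.vector(tapply(x, idk, sum))
    s2 <- as.vector(tapply(x^2, idk, sum))
    mu <- s1 / area
    varb <- pmax(s2 / area - mu^2, 0)
    out[[paste0("mean_", bn[b])]] <- mu
    out[[paste0("sd_", bn[b])]] <- sqrt(varb)
  }
  out
}

# perimeter per segment: pixel edges facing a different segment, NA, or the
# image border
segment_perimeters <- function(labels) {
  H <- nrow(labels); W <- ncol(labels)
  n <- max(labels, na.rm = TRUE)
  p <- numeric(n)
  add_edges <- function(a, b) {
    # a, b: label matrices of adjacent pixels (same shape)
    diffm <- is.na(b) | (!is.na(a) & a != b)
    va <- a[!is.na(a) & diffm]
    if (length(va)) {
      t1 <- tabulate(va, n)
      p <<- p + t1
    }
  }
  # vertical neighbours
  add_edges(labels[-H, , drop = FALSE], labels[-1, , drop = FALSE])
  add_edges(labels[-1, , drop = FALSE], labels[-H, , drop = FALSE])
  # horizontal neighbours
  add_edges(labels[, -W, drop = FALSE], labels[, -1, drop = FALSE])
  add_edges(labels[, -1, drop = FALSE], labels[, -W, drop = FALSE])
  # image borders
  border <- c(labels[1, ], labels[H, ], labels[, 1], labels[, W])
  border <- border[!is.na(border)]
  p + tabulate(border, n)
}

#' Segment adjacency pairs
#' @param segmap a `ripaq_segmap`.
#' @return tibble with columns `a`, `b` (`a < b`), one row per 4-adjacent
#'   segment pair.
#' @export
segment_adjacency <- function(segmap) {
  l <- segmap$labels
  H <- nrow(l); W <- ncol(l)
  pairs <- rbind(cbind(as.vector(l[-H, ]), as.vector(l[-1, ])),
                 cbind(as.vector(l[, -W]), as.vector(l[, -1])))
  pairs <- pairs[!is.na(pairs[, 1]) & !is.na(pairs[, 2]) &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (!nrow(pairs)) return(tibble(a = integer(), b = integer()))
  ab <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  ab <- unique(ab)
  tibble(a = ab[, 1], b = ab[, 2]) %>% arrange(.data$a, .data$b)
}

#' Write a segment map to TIFF + per-segment stats to CSV
#' @param segmap a `ripaq_segmap`.
#' @param raster raster for the statistics.
#' @param tif_path,csv_path output paths.
#' @return invisibly, the two paths.
#' @export
write_segmentation <- function(segmap, raster, tif_path, csv_path) {
  r <- ripaq_raster(segmap$labels + 0, segmap$resolution, segmap$origin,
                    segmap$crs, band_names = "segment_id")
  write_raster(r, tif_path)
  utils::write.csv(segment_stats(segmap, raster), csv_path, row.names = FALSE)
  invisible(c(tif_path, csv_path))
}
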