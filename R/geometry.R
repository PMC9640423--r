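# Per-pixel geometry relative to a stream centerline. Everything downstream
# (buffers, banks, station footprints) derives from the three fields computed
# here: distance to the polyline, signed side, and chainage of the foot point.

#' Per-pixel stream geometry fields
#'
#' For every pixel centre of `grid`, finds the nearest point on the polyline
#' and records the distance to it, the signed side of the local flow
#' direction (+1 = left bank looking downstream, -1 = right bank), and the
#' chainage (arc length from the upstream end) of the foot point.
#'
#' @param centerline tibble with `x`, `y` vertices ordered upstream to
#'   downstream, at least 2 vertices.
#' @param grid a `ripaq_raster` defining the pixel grid (values unused).
#' @return object of class `ripaq_stream_field`: list with `H x W` matrices
#'   `dist`, `side`, `chainage`, the total centerline `length`, and the
#'   `centerline` itself.
#' @export
stream_field <- function(centerline, grid) {
  stopifnot(nrow(centerline) >= 2)
  seg_dx <- diff(centerline$x); seg_dy <- diff(centerline$y)
  seg_len <- sqrt(seg_dx^2 + seg_dy^2)
  if (sum(seg_len) <= 0) abort("degenerate (zero-length) centerline")
  keep <- seg_len > 0
  x0 <- centerline$x[-nrow(centerline)][keep]
  y0 <- centerline$y[-nrow(centerline)][keep]
  dx <- seg_dx[keep]; dy <- seg_dy[keep]; sl <- seg_len[keep]
  cum0 <- c(0, cumsum(sl))[seq_along(sl)]

  cc <- pixel_centers(grid)
  d <- dim(grid$values)
  px <- rep(cc$x, each = d[1])       # column-major over H x W
  py <- rep(cc$y, times = d[2])

  best_d2 <- rep(Inf, length(px))
  best_side <- numeric(length(px))
  best_chain <- numeric(length(px))
  for (i in seq_along(sl)) {
    t <- ((px - x0[i]) * dx[i] + (py - y0[i]) * dy[i]) / (sl[i]^2)
    t <- pmin(pmax(t, 0), 1)
    qx <- x0[i] + t * dx[i]; qy <- y0[i] + t * dy[i]
    d2 <- (px - qx)^2 + (py - qy)^2
    upd <- d2 < best_d2
    if (any(upd)) {
      best_d2[upd] <- d2[upd]
      cr <- dx[i] * (py[upd] - y0[i]) - dy[i] * (px[upd] - x0[i])
      best_side[upd] <- ifelse(cr >= 0, 1, -1)
      best_chain[upd] <- cum0[i] + t[upd] * sl[i]
    }
  }
  structure(
    list(dist = matrix(sqrt(best_d2), d[1], d[2]),
         side = matrix(best_side, d[1], d[2]),
         chainage = matrix(best_chain, d[1], d[2]),
         length = sum(sl),
         centerline = centerline,
         resolution = grid$resolution),
    class = "ripaq_stream_field"
  )
}

#' Arc length of a polyline
#' @param centerline tibble with `x`, `y`.
#' @return total length in map units.
#' @export
centerline_length <- function(centerline) {
  sum(sqrt(diff(centerline$x)^2 + diff(centerline$y)^2))
}
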