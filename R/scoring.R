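# Stream buffers, 100-m per-bank sampling stations, land-cover composition,
# the Riparian Strip Quality Index (RSQI), QBR totals, categorisation and
# restoration triage.

#' Land-cover class weights for the RSQI
#'
#' The standard weighting of riparian land covers: forest 10.0, crops 1.9,
#' bare soil 1.7, infrastructure 1.9. Urban areas map to the infrastructure
#' weight. With these weights the RSQI spans 17 (all bare soil) to 100
#' (all forest).
#'
#' @param forest,crops,bare_soil,urban class weights in `(0, 10]`.
#' @return named numeric vector of class weights.
#' @export
class_weights <- function(forest = 10.0, crops = 1.9, bare_soil = 1.7,
                          urban = 1.9) {
  w <- c(forest = forest, crops = crops, bare_soil = bare_soil, urban = urban)
  if (any(w <= 0) || any(w > 10)) abort("weights must be in (0, 10]")
  if (w["forest"] != max(w)) abort("forest must carry the maximum weight")
  w
}

#' Stream buffer mask
#'
#' All pixels whose centre lies within `width_m` of the centerline, split
#' into left/right banks by the signed side of the local flow direction.
#'
#' @param field a [stream_field()], or a `ripaq_raster` grid (then
#'   `centerline` must be given and the field is computed).
#' @param width_m buffer half-width in metres (default 50).
#' @param centerline needed when `field` is a raster grid.
#' @return list of class `ripaq_buffer`: logical matrices `mask`, `left`,
#'   `right`, plus the underlying `field` and `width_m`.
#' @export
buffer_stream <- function(field, width_m = 50, centerline = NULL) {
  if (inherits(field, "ripaq_raster")) {
    if (is.null(centerline)) abort("centerline required with a raster grid")
    field <- stream_field(centerline, field)
  }
  mask <- field$dist <= width_m + 1e-9   # guard against float round-off
  structure(list(mask = mask,
                 left = mask & field$side > 0,
                 right = mask & field$side < 0,
                 field = field, width_m = width_m),
            class = "ripaq_buffer")
}

#' Build sampling stations along a centerline
#'
#' Station centres are equally spaced in chainage; each centre yields one
#' evaluation unit per bank, whose footprint is the 100-m stretch (50 m
#' upstream and 50 m downstream of the centre) clipped to the bank-side
#' stream buffer.
#'
#' @param centerline tibble with `x`, `y` ordered upstream to downstream.
#' @param n_stations number of station centres; with both banks this yields
#'   `2 * n_stations` evaluation units.
#' @param station_length_m footprint length along the stream (default 100).
#' @param banks which banks to evaluate (default both).
#' @return tibble with columns `station_id`, `bank`, `chainage_m`,
#'   `chainage_from_m`, `chainage_to_m`; the centerline travels as an
#'   attribute.
#' @export
make_stations <- function(centerline, n_stations,
                          station_length_m = 100,
                          banks = c("left", "right")) {
  len <- centerline_length(centerline)
  if (len < n_stations * station_length_m) {
    abort(sprintf("centerline too short: %.0f m for %d stations of %.0f m",
                  len, n_stations, station_length_m))
  }
  centres <- (seq_len(n_stations) - 0.5) * len / n_stations
  out <- tidyr::expand_grid(station_id = seq_len(n_stations), bank = banks) %>%
    mutate(chainage_m = centres[.data$station_id],
           chainage_from_m = .data$chainage_m - station_length_m / 2,
           chainage_to_m = .data$chainage_m + station_length_m / 2)
  attr(out, "centerline") <- centerline
  out
}

# pixel indices of one station footprint within a buffer
station_cells <- function(buffer, bank, from_m, to_m) {
  side <- if (bank == "left") buffer$left else buffer$right
  ch <- buffer$field$chainage
  which(side & ch >= from_m & ch < to_m)
}

#' Land-cover composition of a set of pixels
#'
#' Percentage of each land-cover class over the station's pixels after
#' removing the excluded classes (water by default: the strip is the land
#' beside the channel), renormalised to sum to 100.
#'
#' @param class_raster single-band raster of integer class codes.
#' @param cells pixel indices (column-major) of the station footprint.
#' @param exclude classes removed before renormalisation.
#' @return tibble with `class`, `n_px`, `pct` (summing to 100).
#' @export
composition <- function(class_raster, cells, exclude = "water") {
  codes <- raster_band(class_raster, 1)[cells]
  codes <- codes[!is.na(codes)]
  codes <- codes[!class_label(codes) %in% exclude]
  if (!length(codes)) abort("station footprint has no scoreable pixels")
  tab <- table(codes)
  tibble(class = class_label(as.integer(names(tab))),
         n_px = as.integer(tab),
         pct = 100 * as.integer(tab) / sum(tab))
}

#' Riparian Strip Quality Index
#'
#' `RSQI = sum(%LU_i * W_i) / 10` over the land-cover percentages of the
#' strip. Under the default weight table the index spans 17 (all bare
#' soil) to 100 (all forest).
#'
#' @param comp a [composition()] tibble, or a named numeric vector of
#'   percentages summing to 100.
#' @param weights a [class_weights()] table.
#' @return the RSQI score (numeric scalar).
#' @export
rsqi <- function(comp, weights = class_weights()) {
  if (is.data.frame(comp)) comp <- setNames(comp$pct, comp$class)
  if (abs(sum(comp) - 100) > 1e-6) abort("composition must sum to 100%")
  missing_w <- setdiff(names(comp), names(weights))
  if (length(missing_w)) {
    abort(paste("no weight for class:", paste(missing_w, collapse = ", ")))
  }
  sum(comp * weights[names(comp)]) / 10
}

#' RSQI quality category
#'
#' Below 40 is very low, 40-60 low, 60-80 moderate, 80 and above high.
#'
#' @param score RSQI score(s), `>= 0`.
#' @return character vector of categories.
#' @export
rsqi_category <- function(score) {
  cut(score, c(-Inf, 40, 60, 80, Inf), right = FALSE,
      labels = c("very_low", "low", "moderate", "high")) %>% as.character()
}

#' QBR total from the four block scores
#'
#' The QBR field index scores four blocks (riparian cover, cover structure,
#' cover quality, channel alteration) from 0 to 25 in steps of 5; the total
#' is their sum, 0-100.
#'
#' @param blocks numeric vector (or matrix with 4 columns) of block scores.
#' @return integer total(s) in `[0, 100]`, multiples of 5.
#' @export
qbr_total <- function(blocks) {
  m <- if (is.matrix(blocks)) blocks else matrix(blocks, nrow = 1)
  if (ncol(m) != 4) abort("QBR needs exactly four block scores")
  ok <- m %in% seq(0, 25, by = 5)
  if (!all(ok)) abort("each QBR block must be one of 0, 5, 10, ..., 25")
  as.integer(rowSums(m))
}

#' QBR quality category
#'
#' 95 and above is very good, 75-90 good, 55-70 moderate, 30-50 poor, 25 and
#' below bad. QBR totals are multiples of 5, so the bands are exhaustive.
#'
#' @param total QBR total(s), multiples of 5 in `[0, 100]`.
#' @return character vector of categories.
#' @export
qbr_category <- function(total) {
  check_qbr_total(total)
  dplyr::case_when(
    total >= 95 ~ "very_good",
    total >= 75 ~ "good",
    total >= 55 ~ "moderate",
    total >= 30 ~ "poor",
    TRUE ~ "bad"
  )
}

check_qbr_total <- function(total) {
  bad <- is.na(total) | total < 0 | total > 100 | total %% 5 != 0
  if (any(bad)) abort("QBR totals must be multiples of 5 in [0, 100]")
  invisible(total)
}

#' Restoration triage from the QBR total
#'
#' Conservation above 90, recovery 55-90 (degraded but recoverable strip),
#' restoration below 50 (strip destroyed or unstructured).
#'
#' @param total QBR total(s), multiples of 5 in `[0, 100]`.
#' @return character vector: conservation / recovery / restoration.
#' @export
restoration_action <- function(total) {
  check_qbr_total(total)
  dplyr::case_when(
    total > 90 ~ "conservation",
    total >= 55 ~ "recovery",
    TRUE ~ "restoration"
  )
}

# shared scorer: stations tibble -> per-station composition + RSQI
score_station_table <- function(class_raster, centerline, stations,
                                weights = class_weights(),
                                buffer_width_m = 50, qbr = NULL) {
  buf <- buffer_stream(class_raster, width_m = buffer_width_m,
                       centerline = centerline)
  scored <- purrr::pmap_dfr(
    stations[, c("station_id", "bank", "chainage_m",
                 "chainage_from_m", "chainage_to_m")],
    function(station_id, bank, chainage_m, chainage_from_m, chainage_to_m) {
      cells <- station_cells(buf, bank, chainage_from_m, chainage_to_m)
      comp <- composition(class_raster, cells)
      s <- rsqi(comp, weights)
      tibble(station_id = station_id, bank = bank, chainage_m = chainage_m,
             n_px = sum(comp$n_px), rsqi = s,
             rsqi_category = rsqi_category(s))
    })
  if (!is.null(qbr)) {
    qb <- qbr %>%
      mutate(qbr_total = qbr_total(cbind(.data$block1, .data$block2,
                                         .data$block3, .data$block4)),
             qbr_category = qbr_category(.data$qbr_total),
             action = restoration_action(.data$qbr_total)) %>%
      select("station_id", "bank", "qbr_total", "qbr_category", "action")
    scored <- dplyr::left_join(scored, qb, by = c("station_id", "bank"))
  }
  class(scored) <- c("ripaq_scores", class(scored))
  scored
}

#' Score sampling stations from a classified raster
#'
#' Builds the stream buffer and the per-bank 100-m stations, computes each
#' station's land-cover composition (water excluded) and RSQI with its
#' category, and, when field QBR block scores are supplied, the QBR total,
#' category and restoration triage.
#'
#' @param class_raster single-band raster of integer class codes.
#' @param centerline tibble with `x`, `y` upstream to downstream.
#' @param n_stations number of station centres (units = `2 * n_stations`).
#' @param weights a [class_weights()] table.
#' @param buffer_width_m stream buffer half-width, metres (default 50).
#' @param qbr optional tibble of field scores with columns `station_id`,
#'   `bank`, `block1`..`block4`.
#' @return tibble of class `ripaq_scores`, one row per station x bank.
#' @export
score_stations <- function(class_raster, centerline, n_stations = 15,
                           weights = class_weights(), buffer_width_m = 50,
                           qbr = NULL) {
  stations <- make_stations(centerline, n_stations)
  score_station_table(class_raster, centerline, stations, weights,
                      buffer_width_m, qbr)
}

#' Read field QBR block scores from CSV
#' @param path CSV with columns `station_id`, `bank`, `block1`..`block4`.
#' @return tibble.
#' @export
read_qbr <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
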