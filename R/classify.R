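# Object-level land-cover classification (water / forest / crops / urban),
# stratified validation sampling, confusion matrix, overall accuracy and
# Cohen's kappa.

#' Hierarchical classifier thresholds
#'
#' The classifier is a transparent rule cascade on two physical object
#' features, mean red-edge NDVI and brightness (mean reflectance of the 8
#' bands): (1) RE-NDVI below `t_water` is water; (2) of the rest, bright
#' objects (`brightness > t_brightness`) with RE-NDVI below `t_urban_ndvi`
#' are urban; (3) RE-NDVI at or above `t_forest` is forest, else crops.
#'
#' @param t_water water rule threshold on RE-NDVI (default 0.05).
#' @param t_urban_ndvi urban rule RE-NDVI ceiling (default 0.12).
#' @param t_brightness urban rule brightness floor (default 0.25).
#' @param t_forest forest/crops split on RE-NDVI (default 0.30).
#' @param fallback class assigned when a feature is missing (default crops).
#' @return a `classifier_config` object.
#' @export
classifier_config <- function(t_water = 0.05, t_urban_ndvi = 0.12,
                              t_brightness = 0.25, t_forest = 0.30,
                              fallback = "crops") {
  if (!fallback %in% RIPAQ_CLASSES) abort("unknown fallback class")
  structure(list(t_water = t_water, t_urban_ndvi = t_urban_ndvi,
                 t_brightness = t_brightness, t_forest = t_forest,
                 fallback = fallback),
            class = "classifier_config")
}

#' Object feature table from a segment map
#'
#' Aggregates the classification features per image object: mean/sd of the
#' composite bands (when supplied), mean raw red-edge NDVI, brightness
#' (mean of the 8 multispectral bands), area, perimeter and compactness
#' (`perimeter / sqrt(area)`).
#'
#' @param segmap a `ripaq_segmap`.
#' @param ms multispectral image on the same grid (for brightness).
#' @param rendvi raw red-edge NDVI raster on the same grid.
#' @param composite optional composite raster; adds per-band mean/sd columns.
#' @return tibble with one row per object.
#' @export
object_features <- function(segmap, ms, rendvi, composite = NULL) {
  bright <- ripaq_raster(apply(ms$values, c(1, 2), mean), ms$resolution,
                         ms$origin, ms$crs, band_names = "brightness")
  st <- segment_stats(segmap, bright) %>%
    dplyr::rename(brightness = "mean_brightness") %>%
    select(-"sd_brightness")
  nd <- segment_stats(segmap, rendvi) %>%
    select("segment_id", re_ndvi = "mean_re_ndvi")
  out <- dplyr::left_join(st, nd, by = "segment_id") %>%
    mutate(compactness = .data$perimeter_px / sqrt(.data$area_px))
  if (!is.null(composite)) {
    cs <- segment_stats(segmap, composite) %>%
      select(-"area_px", -"perimeter_px")
    out <- dplyr::left_join(out, cs, by = "segment_id")
  }
  out
}

#' Classify image objects with the hierarchical rule cascade
#'
#' @param objects object tibble from [object_features()] (needs `re_ndvi`
#'   and `brightness`).
#' @param rules a [classifier_config()], or `NULL` to fit thresholds from
#'   labelled seed objects via [fit_thresholds()] (requires a
#'   `reference_class` column on a subset of rows).
#' @return the tibble with a `predicted_class` column appended; the number
#'   of objects that fell through to the fallback class is attached as
#'   attribute `n_fallback` (a warning is raised when it is positive).
#' @export
classify_objects <- function(objects, rules = classifier_config()) {
  if (is.null(rules)) rules <- fit_thresholds(objects)
  nd <- objects$re_ndvi
  br <- objects$brightness
  cls <- rep(NA_character_, nrow(objects))
  ok <- !is.na(nd) & !is.na(br)
  cls[ok & nd < rules$t_water] <- "water"
  rest <- ok & is.na(cls)
  cls[rest & br > rules$t_brightness & nd < rules$t_urban_ndvi] <- "urban"
  rest <- ok & is.na(cls)
  cls[rest] <- ifelse(nd[rest] >= rules$t_forest, "forest", "crops")
  n_fallback <- sum(is.na(cls))
  if (n_fallback > 0) {
    warn(sprintf("%d object(s) had missing features; assigned fallback class '%s'",
                 n_fallback, rules$fallback))
    cls[is.na(cls)] <- rules$fallback
  }
  out <- mutate(objects, predicted_class = cls)
  attr(out, "n_fallback") <- n_fallback
  out
}

#' Fit cascade thresholds from labelled seed objects
#'
#' Each threshold is the midpoint between the relevant class centroids of
#' the labelled objects: water/rest split on RE-NDVI, urban/crops split on
#' RE-NDVI, urban brightness floor against the brightest non-urban class,
#' and the forest/crops split on RE-NDVI.
#'
#' @param objects tibble with `re_ndvi`, `brightness` and a
#'   `reference_class` column (NA rows ignored).
#' @return a [classifier_config()].
#' @export
fit_thresholds <- function(objects) {
  lab <- objects %>%
    filter(!is.na(.data$reference_class)) %>%
    group_by(class = .data$reference_class) %>%
    summarise(nd = mean(.data$re_ndvi), br = mean(.data$brightness))
  need <- c("water", "forest", "crops", "urban")
  if (!all(need %in% lab$class)) {
    abort("labelled seed objects must cover water, forest, crops and urban")
  }
  g <- function(cl, col) lab[[col]][lab$class == cl]
  classifier_config(
    t_water = mean(c(g("water", "nd"), min(g("forest", "nd"), g("crops", "nd"), g("urban", "nd")))),
    t_urban_ndvi = mean(c(g("urban", "nd"), g("crops", "nd"))),
    t_brightness = mean(c(g("urban", "br"), max(g("forest", "br"), g("crops", "br")))),
    t_forest = mean(c(g("forest", "nd"), g("crops", "nd")))
  )
}

#' Majority ground-truth class per object
#'
#' Reference labels for validation: the modal truth-raster class within each
#' segment (ties broken towards the lowest class code).
#'
#' @param segmap a `ripaq_segmap`.
#' @param truth_labels truth label raster (integer class codes).
#' @return tibble with `segment_id`, `reference_class`, and `purity` (modal
#'   class share of the segment's pixels).
#' @export
majority_reference <- function(segmap, truth_labels) {
  ids <- as.vector(segmap$labels)
  tl <- as.vector(raster_band(truth_labels, 1))
  keep <- !is.na(ids) & !is.na(tl)
  tab <- table(segment_id = ids[keep], code = tl[keep])
  maj <- apply(tab, 1, which.max)             # ties -> first (lowest) code
  codes <- as.integer(colnames(tab))[maj]
  purity <- tab[cbind(seq_len(nrow(tab)), maj)] / rowSums(tab)
  tibble(segment_id = as.integer(rownames(tab)),
         reference_class = class_label(codes),
         purity = as.numeric(purity))
}

#' Stratified validation sample of objects
#'
#' Draws `n` objects with per-class allocation proportional to the
#' predicted-class object counts, integerised by largest-remainder rounding,
#' then samples without replacement within each class under the given seed.
#'
#' @param objects tibble with a `predicted_class` column.
#' @param n total sample size (at least the number of classes present,
#'   at most `nrow(objects)`).
#' @param seed integer seed; identical seed gives an identical sample.
#' @return the sampled subset tibble, ordered by class then `segment_id`.
#' @export
sample_validation_objects <- function(objects, n, seed = 1) {
  counts <- table(objects$predicted_class)
  k <- length(counts)
  if (n < k) abort("n must be at least the number of classes present")
  if (n > nrow(objects)) abort("n exceeds the number of objects")
  alloc <- largest_remainder(as.numeric(counts) / sum(counts) * n)
  # never allocate more than a class holds; redistribute any surplus
  over <- alloc - as.numeric(counts)
  while (any(over > 0)) {
    surplus <- sum(over[over > 0])
    alloc[over > 0] <- as.numeric(counts)[over > 0]
    room <- as.numeric(counts) - alloc
    give <- which(room > 0)
    give <- give[order(room[give], decreasing = TRUE)]
    for (i in give) {
      add <- min(room[i], surplus)
      alloc[i] <- alloc[i] + add
      surplus <- surplus - add
      if (surplus == 0) break
    }
    over <- alloc - as.numeric(counts)
  }
  withr::with_seed(seed, {
    picked <- purrr::map(seq_len(k), function(i) {
      pool <- which(objects$predicted_class == names(counts)[i])
      pool[sample.int(length(pool), alloc[i])]
    })
  })
  objects[sort(unlist(picked)), ]
}

#' Largest-remainder integer apportionment
#' @param x non-negative reals summing to an integer total (within 1e-9).
#' @return integer vector summing to `round(sum(x))`.
#' @export
largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- x - fl
  short <- round(sum(x)) - sum(fl)
  if (short > 0) {
    give <- order(rem, decreasing = TRUE)[seq_len(short)]
    fl[give] <- fl[give] + 1
  }
  as.integer(fl)
}

#' Confusion matrix (rows = predicted, columns = reference)
#'
#' @param pred,ref equal-length character vectors of class labels.
#' @param labels ordered class set; defaults to the union of observed
#'   labels in canonical class order.
#' @return object of class `ripaq_confusion`: a k x k integer matrix.
#' @export
confusion_matrix <- function(pred, ref, labels = NULL) {
  if (length(pred) != length(ref)) abort("pred and ref lengths differ")
  if (length(pred) == 0) abort("empty input")
  if (is.null(labels)) {
    obs <- union(pred, ref)
    labels <- c(intersect(RIPAQ_CLASSES, obs), sort(setdiff(obs, RIPAQ_CLASSES)))
  }
  bad <- setdiff(union(pred, ref), labels)
  if (length(bad)) abort(paste("label outside class set:", paste(bad, collapse = ", ")))
  m <- table(factor(pred, levels = labels), factor(ref, levels = labels))
  m <- matrix(as.integer(m), length(labels), length(labels),
              dimnames = list(predicted = labels, reference = labels))
  structure(m, class = c("ripaq_confusion", "matrix"))
}

#' Overall accuracy of a confusion matrix
#' @param cm a `ripaq_confusion` (or plain square count matrix).
#' @return fraction of agreeing pairs, `trace / total`.
#' @export
overall_accuracy <- function(cm) {
  n <- sum(cm)
  if (n <= 0) abort("confusion matrix total must be positive")
  sum(diag(unclass(cm))) / n
}

#' Cohen's kappa of a confusion matrix
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with expected
#' agreement `p_e = sum_i row_i * col_i / N^2`. Returns 1 for perfect
#' agreement even when `p_e = 1` (single-class degenerate case).
#'
#' @param cm a `ripaq_confusion` (or plain square count matrix).
#' @return kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(cm) {
  m <- unclass(cm)
  n <- sum(m)
  if (n <= 0) abort("confusion matrix total must be positive")
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (pe >= 1) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' @export
print.ripaq_confusion <- function(x, ...) {
  cat("<ripaq_confusion> rows = predicted, columns = reference\n")
  print(unclass(x))
  cat(sprintf("overall accuracy %.4f, kappa %.4f\n",
              overall_accuracy(x), cohens_kappa(x)))
  invisible(x)
}

#' Tidy a confusion matrix into a long tibble
#' @param x a `ripaq_confusion`.
#' @param ... unused.
#' @return tibble with `predicted`, `reference`, `n`.
#' @export
tidy.ripaq_confusion <- function(x, ...) {
  m <- unclass(x)
  tibble(predicted = rep(rownames(m), times = ncol(m)),
         reference = rep(colnames(m), each = nrow(m)),
         n = as.integer(m))
}

#' One-row accuracy summary of a confusion matrix
#' @param x a `ripaq_confusion`.
#' @param ... unused.
#' @return tibble with `n`, `n_classes`, `accuracy`, `kappa`.
#' @export
glance.ripaq_confusion <- function(x, ...) {
  tibble(n = sum(x), n_classes = nrow(x),
         accuracy = overall_accuracy(x), kappa = cohens_kappa(x))
}

#' Rasterise predicted object classes
#' @param segmap a `ripaq_segmap`.
#' @param objects classified object tibble (`segment_id`, `predicted_class`).
#' @return single-band `ripaq_raster` of integer class codes.
#' @export
class_raster <- function(segmap, objects) {
  codes <- rep(NA_integer_, segmap$n_segments)
  codes[objects$segment_id] <- class_code(objects$predicted_class)
  v <- matrix(codes[segmap$labels], nrow(segmap$labels), ncol(segmap$labels))
  ripaq_raster(v + 0, segmap$resolution, segmap$origin, segmap$crs,
               band_names = "class")
}
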