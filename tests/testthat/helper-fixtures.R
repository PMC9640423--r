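# Shared fixtures: small synthetic scenes and cached end-to-end recovery
# runs, so several test files can reuse one expensive computation.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

small_scene <- function(seed = 1, ...) {
  cached(paste0("scene_", seed, "_", paste(c(...), collapse = "_")),
         generate_scene(scene_spec(width_px = 96, height_px = 96,
                                   seed = seed, ...)))
}

# flat uniform 8-band image (one value per band), for degenerate cases
flat_ms <- function(spectrum, H = 8, W = 8, resolution = 2) {
  v <- array(rep(spectrum, each = H * W), c(H, W, 8))
  ms_image(v, resolution = resolution, origin = c(0, H * resolution))
}

# full recovery pipeline on a small seeded scene; returns object-level kappa
# vs ground truth and the per-station RSQI errors against the truth oracle
recovery_run <- function(seed) {
  cached(paste0("recovery_", seed), {
    sc <- small_scene(seed)
    prep <- preprocess_scene(sc$ms, sc$pan)
    buf <- buffer_stream(prep$composite, 50, sc$truth$centerline)
    seg <- multiresolution_segment(prep$composite, segmentation_params(),
                                   mask = buf$mask)
    obj <- object_features(seg, prep$ms, prep$rendvi)
    obj <- classify_objects(obj)
    truth_grid <- ripaq:::truth_at_resolution(sc$truth, prep$composite)
    refs <- majority_reference(seg, truth_grid)
    obj <- dplyr::left_join(obj, refs, by = "segment_id")
    cm <- confusion_matrix(obj$predicted_class, obj$reference_class)
    cr <- class_raster(seg, obj)
    stations <- make_stations(sc$truth$centerline, 1)
    got <- score_station_table(cr, sc$truth$centerline, stations)
    want <- truth_station_scores(sc$truth, stations)
    list(kappa = cohens_kappa(cm), objects = obj,
         rsqi_err = got$rsqi - want$rsqi,
         scores = got, truth_scores = want)
  })
}

# BFS flood fill: TRUE iff all pixels of `id` are 4-connected
flood_connected <- function(labels, id) {
  px <- which(labels == id)
  if (!length(px)) return(FALSE)
  H <- nrow(labels); W <- ncol(labels)
  inset <- seen <- rep(FALSE, length(labels))
  inset[px] <- TRUE
  queue <- px[1]; seen[px[1]] <- TRUE
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    r <- (p - 1) %% H + 1; c <- (p - 1) %/% H + 1
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 >= 1 && r2 <= H && c2 >= 1 && c2 <= W) {
        q <- (c2 - 1) * H + r2
        if (inset[q] && !seen[q]) {
          seen[q] <- TRUE
          queue <- c(queue, q)
        }
      }
    }
  }
  all(seen[px])
}

# the printed reference confusion matrix (rows = predicted class)
reference_confusion <- function() {
  m <- matrix(c(89, 3, 2, 1,
                2, 38, 1, 0,
                1, 1, 37, 5,
                0, 0, 1, 20),
              nrow = 4, byrow = TRUE,
              dimnames = list(predicted = c("forest", "crops", "water", "urban"),
                              reference = c("forest", "crops", "water", "urban")))
  structure(m, class = c("ripaq_confusion", "matrix"))
}
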