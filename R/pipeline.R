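# End-to-end orchestration: simulate (or load) -> preprocess -> segment ->
# classify -> validate -> score, persisting every intermediate artifact and
# a reproducibility manifest.

#' Pipeline configuration
#'
#' Defaults follow the reference workflow: segmentation scale 25 with shape
#' and compactness weights 0.1, a 50-m stream buffer, 15 station centres
#' (30 per-bank units), and a 200-object stratified validation sample.
#'
#' @param ms,pan,stream,qbr_csv input paths (TIFF / GeoJSON / CSV); leave
#'   `NULL` with `simulate = TRUE` to generate a synthetic scene instead.
#' @param simulate generate the input scene from `scene` (default TRUE when
#'   no `ms` path is given).
#' @param scene a [scene_spec()] for simulate mode.
#' @param segmentation a [segmentation_params()].
#' @param classifier a [classifier_config()].
#' @param weights a [class_weights()] table.
#' @param buffer_width_m stream buffer half-width (metres).
#' @param n_stations station centres along the stream.
#' @param n_pcs principal components in the composite.
#' @param pansharpen run analysis at the panchromatic resolution (default
#'   TRUE; FALSE stays on the multispectral grid).
#' @param validation_n stratified validation sample size.
#' @param seed seed for the validation sample (and the scene in simulate
#'   mode unless the scene spec carries its own).
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(ms = NULL, pan = NULL, stream = NULL,
                            qbr_csv = NULL, simulate = is.null(ms),
                            scene = scene_spec(),
                            segmentation = segmentation_params(),
                            classifier = classifier_config(),
                            weights = class_weights(),
                            buffer_width_m = 50, n_stations = 15,
                            n_pcs = 3, pansharpen = TRUE,
                            validation_n = 200, seed = 1) {
  if (buffer_width_m <= 0) abort("buffer_width_m must be positive")
  if (n_stations < 1) abort("n_stations must be at least 1")
  if (validation_n < 1) abort("validation_n must be at least 1")
  structure(list(ms = ms, pan = pan, stream = stream, qbr_csv = qbr_csv,
                 simulate = simulate, scene = scene,
                 segmentation = segmentation, classifier = classifier,
                 weights = weights, buffer_width_m = buffer_width_m,
                 n_stations = n_stations, n_pcs = as.integer(n_pcs),
                 pansharpen = pansharpen,
                 validation_n = as.integer(validation_n),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' An empty file yields the full defaults. Unknown keys and out-of-range
#' values are errors, not warnings.
#'
#' @param path YAML file. Recognised top-level keys: `ms`, `pan`, `stream`,
#'   `qbr_csv`, `simulate`, `scene` (sub-keys of [scene_spec()]),
#'   `segmentation` (`scale`, `shape_weight`, `compactness_weight`),
#'   `classifier` (threshold names), `weights`, `buffer_width_m`,
#'   `n_stations`, `n_pcs`, `pansharpen`, `validation_n`, `seed`.
#' @return a `pipeline_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("ms", "pan", "stream", "qbr_csv", "simulate", "scene",
             "segmentation", "classifier", "weights", "buffer_width_m",
             "n_stations", "n_pcs", "pansharpen", "validation_n", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  }
  sub <- function(x, ctor) {
    if (is.null(x)) ctor() else do.call(ctor, x)
  }
  args <- raw[setdiff(names(raw), c("scene", "segmentation", "classifier", "weights"))]
  args$scene <- sub(raw$scene, scene_spec)
  args$segmentation <- sub(raw$segmentation, segmentation_params)
  args$classifier <- sub(raw$classifier, classifier_config)
  args$weights <- sub(raw$weights, class_weights)
  do.call(pipeline_config, args)
}

#' Run the full assessment pipeline
#'
#' Executes simulate (or load) -> preprocess -> segment -> classify ->
#' validate -> score in order, writes every intermediate artifact under
#' `outdir`, and returns a manifest (parameters, seed, stage outputs with
#' MD5 hashes). Identical config + seed reproduces identical hashes. A
#' failure in any stage aborts with the stage name and cause.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @return list of class `ripaq_manifest`: `stages` (named list of stage
#'   artifact paths + hashes), `results` (scores tibble, accuracy metrics),
#'   `config_summary`, `seed`.
#' @export
run_pipeline <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  # -- simulate / load -------------------------------------------------
  sim <- run_stage("simulate", function() {
    if (config$simulate) {
      scene <- generate_scene(config$scene)
      paths <- write_scene(scene, outdir)
      list(ms = scene$ms, pan = scene$pan, truth = scene$truth,
           centerline = scene$truth$centerline, paths = paths)
    } else {
      if (is.null(config$ms)) abort("no multispectral input path")
      # the centerline is first consumed when stations are scored; a missing
      # stream file is reported there, and segmentation runs unmasked
      cl <- if (!is.null(config$stream) && file.exists(config$stream)) {
        read_centerline(config$stream)
      }
      list(ms = read_raster(config$ms),
           pan = if (!is.null(config$pan)) read_raster(config$pan),
           truth = NULL,
           centerline = cl,
           paths = c(ms = config$ms, pan = config$pan, stream = config$stream))
    }
  })
  stages$simulate <- sim$paths

  # -- preprocess ------------------------------------------------------
  prep <- run_stage("preprocess", function() {
    pan_in <- if (config$pansharpen) sim$pan
    preprocess_scene(sim$ms, pan_in, n_pcs = config$n_pcs)
  })
  comp_path <- file.path(outdir, "composite.tif")
  write_raster(prep$composite, comp_path)
  stages$preprocess <- c(composite = comp_path)

  # -- segment ---------------------------------------------------------
  segmap <- run_stage("segment", function() {
    mask <- if (!is.null(sim$centerline)) {
      buffer_stream(prep$composite, width_m = config$buffer_width_m,
                    centerline = sim$centerline)$mask
    }
    multiresolution_segment(prep$composite, config$segmentation, mask = mask)
  })
  seg_paths <- c(segments = file.path(outdir, "segments.tif"),
                 segment_stats = file.path(outdir, "segment_stats.csv"))
  write_segmentation(segmap, prep$composite, seg_paths[1], seg_paths[2])
  stages$segment <- seg_paths

  # -- classify --------------------------------------------------------
  cls <- run_stage("classify", function() {
    objects <- object_features(segmap, prep$ms, prep$rendvi, prep$composite)
    objects <- classify_objects(objects, config$classifier)
    list(objects = objects, raster = class_raster(segmap, objects))
  })
  cls_paths <- c(classes = file.path(outdir, "classes.tif"),
                 objects = file.path(outdir, "objects.csv"))
  write_raster(cls$raster, cls_paths[1])
  utils::write.csv(cls$objects, cls_paths[2], row.names = FALSE)
  stages$classify <- cls_paths

  # -- validate (needs ground truth) -----------------------------------
  metrics <- NULL
  val <- run_stage("validate", function() {
    if (is.null(sim$truth)) return(NULL)
    truth_grid <- truth_at_resolution(sim$truth, prep$composite)
    refs <- majority_reference(segmap, truth_grid)
    objects <- dplyr::left_join(cls$objects, refs, by = "segment_id")
    n <- min(config$validation_n, nrow(objects))
    sampled <- sample_validation_objects(objects, n, seed = config$seed)
    cm <- confusion_matrix(sampled$predicted_class, sampled$reference_class,
                           labels = intersect(RIPAQ_CLASSES,
                                              union(sampled$predicted_class,
                                                    sampled$reference_class)))
    list(cm = cm, metrics = glance(cm))
  })
  val_paths <- character()
  if (!is.null(val)) {
    val_paths <- c(confusion = file.path(outdir, "confusion.csv"),
                   metrics = file.path(outdir, "metrics.json"))
    utils::write.csv(tidy(val$cm), val_paths["confusion"], row.names = FALSE)
    jsonlite::write_json(as.list(val$metrics), val_paths["metrics"],
                         auto_unbox = TRUE, digits = NA)
    metrics <- val$metrics
  }
  stages$validate <- val_paths

  # -- score -----------------------------------------------------------
  scores <- run_stage("score", function() {
    if (is.null(sim$centerline)) abort("stream centerline file not found")
    qbr <- if (!is.null(config$qbr_csv)) read_qbr(config$qbr_csv)
    score_stations(cls$raster, sim$centerline,
                   n_stations = config$n_stations,
                   weights = config$weights,
                   buffer_width_m = config$buffer_width_m, qbr = qbr)
  })
  score_path <- file.path(outdir, "station_scores.csv")
  utils::write.csv(scores, score_path, row.names = FALSE)
  stages$score <- c(scores = score_path)

  manifest <- structure(
    list(stages = purrr::map(stages, function(p) {
           if (!length(p)) return(list())
           list(paths = as.list(p),
                md5 = as.list(unname(tools::md5sum(unlist(p)))))
         }),
         results = list(scores = scores, metrics = metrics),
         config_summary = list(
           simulate = config$simulate, seed = config$seed,
           scale = config$segmentation$scale,
           shape_weight = config$segmentation$shape_weight,
           compactness_weight = config$segmentation$compactness_weight,
           buffer_width_m = config$buffer_width_m,
           n_stations = config$n_stations,
           validation_n = config$validation_n),
         seed = config$seed),
    class = "ripaq_manifest")
  jsonlite::write_json(
    list(stages = manifest$stages, config = manifest$config_summary),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  manifest
}

# resample the MS-grid truth labels onto the analysis grid (replication)
truth_at_resolution <- function(truth, target) {
  f <- truth$labels$resolution / target$resolution
  if (abs(f - round(f)) > 1e-9) abort("non-integer truth/target grid ratio")
  f <- as.integer(round(f))
  v <- raster_band(truth$labels, 1)
  if (f > 1) v <- block_replicate(v, f)
  ripaq_raster(v, target$resolution, target$origin, target$crs,
               band_names = "class")
}
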