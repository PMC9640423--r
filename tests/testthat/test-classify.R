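toy_objects <- function(nd, br) {
  tibble::tibble(segment_id = seq_along(nd), re_ndvi = nd, brightness = br)
}

test_that("the rule cascade assigns each class from its feature signature", {
  obj <- toy_objects(nd = c(-0.2, 0.45, 0.18, 0.08),
                     br = c(0.05, 0.15, 0.17, 0.35))
  out <- classify_objects(obj)
  expect_equal(out$predicted_class, c("water", "forest", "crops", "urban"))
})

test_that("objects with missing features take the fallback class with a warning", {
  obj <- toy_objects(nd = c(0.4, NA), br = c(0.2, 0.3))
  expect_warning(out <- classify_objects(obj), "fallback")
  expect_equal(out$predicted_class, c("forest", "crops"))
  expect_equal(attr(out, "n_fallback"), 1L)
})

test_that("thresholds fitted from labelled seeds separate the class centroids", {
  obj <- toy_objects(nd = c(-0.25, -0.28, 0.42, 0.45, 0.17, 0.20, 0.07, 0.09),
                     br = c(0.05, 0.04, 0.16, 0.15, 0.18, 0.17, 0.36, 0.34))
  obj$reference_class <- rep(c("water", "forest", "crops", "urban"), each = 2)
  rules <- fit_thresholds(obj)
  out <- classify_objects(obj, rules)
  expect_equal(out$predicted_class, obj$reference_class)
  obj_missing <- obj[obj$reference_class != "urban", ]
  expect_error(fit_thresholds(obj_missing), "must cover")
})

test_that("on a noiseless scene every class-pure object is classified correctly", {
  sc <- cached("scene_noiseless_cls",
               generate_scene(scene_spec(width_px = 64, height_px = 64,
                                         noise_sd = 0, seed = 2)))
  prep <- preprocess_scene(sc$ms, NULL)
  buf <- buffer_stream(prep$composite, 50, sc$truth$centerline)
  seg <- multiresolution_segment(prep$composite, segmentation_params(),
                                 mask = buf$mask)
  obj <- classify_objects(object_features(seg, prep$ms, prep$rendvi))
  refs <- majority_reference(seg, sc$truth$labels)
  obj <- dplyr::left_join(obj, refs, by = "segment_id")
  pure <- obj[obj$purity == 1, ]
  expect_gt(nrow(pure), 0)
  expect_equal(pure$predicted_class, pure$reference_class)
})

test_that("object classification recovers ground truth with high kappa", {
  r <- recovery_run(1)
  expect_gte(r$kappa, 0.8)
})

test_that("stratified sampling allocates by largest remainder and is seeded", {
  counts <- c(forest = 475, water = 220, crops = 200, urban = 105)
  obj <- tibble::tibble(
    segment_id = seq_len(sum(counts)),
    predicted_class = rep(names(counts), counts))
  s <- sample_validation_objects(obj, 200, seed = 7)
  expect_equal(as.vector(table(s$predicted_class)[names(counts)]),
               c(95, 44, 40, 21))
  expect_identical(s, sample_validation_objects(obj, 200, seed = 7))
  expect_false(identical(s$segment_id,
                         sample_validation_objects(obj, 200, seed = 8)$segment_id))

  one <- tibble::tibble(segment_id = 1:10, predicted_class = rep("forest", 10))
  expect_equal(nrow(sample_validation_objects(one, 6, seed = 1)), 6L)
  expect_error(sample_validation_objects(obj, 3, seed = 1), "at least")
  expect_error(sample_validation_objects(one, 99, seed = 1), "exceeds")
})

test_that("largest-remainder apportionment keeps the target total", {
  expect_equal(largest_remainder(c(95, 44, 40, 21)), c(95L, 44L, 40L, 21L))
  expect_equal(sum(largest_remainder(c(33.4, 33.3, 33.3))), 100L)
  expect_equal(largest_remainder(c(1.6, 1.6, 0.8)), c(2L, 1L, 1L))
})

test_that("confusion matrices count predicted x reference pairs", {
  cm <- confusion_matrix(rep(c("water", "forest"), each = 5),
                         rep(c("water", "forest"), each = 5))
  expect_equal(sum(diag(unclass(cm))), 10)
  expect_equal(sum(cm) - sum(diag(unclass(cm))), 0)
  expect_error(confusion_matrix(character(), character()), "empty")
  expect_error(confusion_matrix("water", "lake", labels = c("water", "forest")),
               "outside")
  # reference matrix reproduces the printed row totals
  expect_equal(unname(rowSums(reference_confusion())), c(95, 41, 44, 21))
})

test_that("overall accuracy is the trace share", {
  ident <- structure(diag(50, 4), class = c("ripaq_confusion", "matrix"))
  expect_equal(overall_accuracy(ident), 1)
  expect_equal(overall_accuracy(reference_confusion()), 184 / 201)
  off <- structure(matrix(c(0, 5, 7, 0), 2, 2), class = c("ripaq_confusion", "matrix"))
  expect_equal(overall_accuracy(off), 0)
})

test_that("Cohen's kappa matches closed forms and the independent implementation", {
  ident <- structure(diag(50, 4), class = c("ripaq_confusion", "matrix"))
  expect_equal(cohens_kappa(ident), 1)
  chance <- matrix(c(50, 0, 50, 0), 2, 2)
  expect_equal(cohens_kappa(chance), 0)
  # degenerate single-class perfect agreement
  expect_equal(cohens_kappa(matrix(10)), 1)

  skip_if_not_installed("caret")
  for (s in 1:4) {
    set.seed(s)
    pred <- sample(c("a", "b", "c"), 60, replace = TRUE)
    ref <- ifelse(runif(60) < 0.6, pred, sample(c("a", "b", "c"), 60, TRUE))
    cm <- confusion_matrix(pred, ref, labels = c("a", "b", "c"))
    ind <- caret::confusionMatrix(table(factor(pred, c("a", "b", "c")),
                                        factor(ref, c("a", "b", "c"))))
    expect_equal(cohens_kappa(cm), unname(ind$overall["Kappa"]),
                 tolerance = 1e-10)
    expect_equal(overall_accuracy(cm), unname(ind$overall["Accuracy"]),
                 tolerance = 1e-10)
  }
})

test_that("kappa is invariant under simultaneous class permutation", {
  m <- unclass(reference_confusion())
  for (s in 1:3) {
    set.seed(s)
    p <- sample(4)
    expect_equal(cohens_kappa(m[p, p]), cohens_kappa(m))
  }
})

test_that("perfect accuracy and unit kappa coincide for non-degenerate matrices", {
  set.seed(2)
  for (i in 1:5) {
    d <- diag(sample(5:30, 3))
    expect_equal(overall_accuracy(d), 1)
    expect_equal(cohens_kappa(d), 1)
    d[1, 2] <- 1
    expect_lt(overall_accuracy(d), 1)
    expect_lt(cohens_kappa(d), 1)
  }
})
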