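test_that("red-edge NDVI evaluates the normalised difference with nodata rules", {
  spec <- c(0.1, 0.1, 0.1, 0.1, 0.1, 0.10, 0.30, 0.1)
  ms <- flat_ms(spec, H = 2, W = 2)
  expect_equal(unique(as.vector(raster_band(re_ndvi(ms), 1))), 0.5)

  ms$values[, , 6] <- 0.25; ms$values[, , 7] <- 0.25
  expect_equal(unique(as.vector(raster_band(re_ndvi(ms), 1))), 0)

  ms$values[1, 1, 6] <- 0; ms$values[1, 1, 7] <- 0
  ms$values[2, 2, 7] <- NA
  nd <- raster_band(re_ndvi(ms), 1)
  expect_true(is.na(nd[1, 1]))
  expect_true(is.na(nd[2, 2]))
})

test_that("red-edge NDVI is antisymmetric under swapping NIR and red-edge", {
  sc <- small_scene(1)
  swapped <- sc$ms
  swapped$values[, , c(6, 7)] <- swapped$values[, , c(7, 6)]
  a <- raster_band(re_ndvi(sc$ms), 1)
  b <- raster_band(re_ndvi(swapped), 1)
  expect_equal(a, -b)
})

test_that("pansharpening is the identity at ratio 1 and on flat images", {
  ms <- flat_ms(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.4, 0.3, 0.2), H = 4, W = 4)
  pan1 <- pan_image(matrix(0.35, 4, 4), resolution = 2, origin = ms$origin)
  out1 <- pansharpen(ms, pan1)
  expect_equal(out1$values, ms$values, tolerance = 1e-12)

  pan4 <- pan_image(matrix(0.35, 16, 16), resolution = 0.5, origin = ms$origin)
  out4 <- pansharpen(ms, pan4)
  expect_equal(dim(out4$values)[1:2], c(16L, 16L))
  for (b in 1:8) {
    expect_equal(unique(as.vector(out4$values[, , b])), ms$values[1, 1, b],
                 tolerance = 1e-12)
  }
  bad <- pan_image(matrix(0.3, 10, 10), resolution = 0.8, origin = ms$origin)
  expect_error(pansharpen(ms, bad), "integer")
})

test_that("block-averaging the pansharpened image recovers the multispectral input", {
  sc <- cached("scene_ps_7",
               generate_scene(scene_spec(width_px = 48, height_px = 48, seed = 7)))
  out <- pansharpen(sc$ms, sc$pan)
  for (b in 1:8) {
    lo <- block_average(raster_band(out, b), 4)
    rel <- abs(mean(lo) - mean(raster_band(sc$ms, b))) / mean(raster_band(sc$ms, b))
    expect_lt(rel, 0.01)
  }
  # Wald-style consistency on a noiseless scene: per-band RMSE under 1% of range
  scn <- cached("scene_ps_noiseless",
                generate_scene(scene_spec(width_px = 48, height_px = 48,
                                          noise_sd = 0, seed = 7)))
  outn <- pansharpen(scn$ms, scn$pan)
  for (b in 1:8) {
    dif <- block_average(raster_band(outn, b), 4) - raster_band(scn$ms, b)
    rng <- diff(range(raster_band(scn$ms, b)))
    expect_lt(sqrt(mean(dif^2)), 0.01 * max(rng, 1e-12))
  }
})

test_that("PCA explained variance obeys the rank and trace identities", {
  # only one band varies -> rank-1 covariance, PC1 carries everything
  v <- array(0.2, c(5, 5, 8))
  v[, , 3] <- matrix(runif(25), 5, 5)
  p1 <- pca_reduce(ms_image(v), 1)
  expect_equal(p1$explained_variance[1], 1)

  sc <- small_scene(1)
  p <- pca_reduce(sc$ms, 3)
  expect_equal(sum(p$explained_variance), 1, tolerance = 1e-9)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
})

test_that("a collinear two-band toy projects onto the (1,1)/sqrt(2) axis", {
  v <- array(0, c(3, 1, 2))
  v[, 1, 1] <- c(0, 1, 2)
  v[, 1, 2] <- c(0, 1, 2)
  r <- ripaq_raster(v, 1)
  # pca_reduce accepts any band count; 8 bands only required upstream
  p <- pca_reduce(r, 1)
  expect_equal(abs(as.vector(p$rotation[, 1])), rep(1 / sqrt(2), 2))
  expect_equal(p$explained_variance[1], 1)
})

test_that("full-rank PCA reconstructs the centred data", {
  sc <- small_scene(1)
  d <- dim(sc$ms$values)
  m <- matrix(sc$ms$values, d[1] * d[2], 8)
  p <- pca_reduce(sc$ms, 8)
  scores <- sapply(p$components, function(cp) as.vector(raster_band(cp, 1)))
  rec <- scores %*% t(p$rotation) + matrix(p$center, nrow(m), 8, byrow = TRUE)
  expect_lt(max(abs(rec - m)) / max(abs(m)), 1e-6)
})

test_that("the composite stacks standardised PCs with the red-edge NDVI", {
  sc <- small_scene(1)
  nd <- re_ndvi(sc$ms)
  p <- pca_reduce(sc$ms, 3)
  comp <- build_composite(p, nd)
  expect_equal(dim(comp$values)[3], 4L)
  for (b in 1:4) {
    expect_lt(abs(mean(comp$values[, , b], na.rm = TRUE)), 1e-9)
  }
  # nodata propagates from any input band
  nd2 <- nd; nd2$values[3, 4, 1] <- NA
  comp2 <- build_composite(p, nd2)
  expect_true(all(is.na(comp2$values[3, 4, ])))
  # grid mismatch is an error
  ndsmall <- ripaq_raster(matrix(0, 4, 4), 2)
  expect_error(build_composite(p, ndsmall), "grid")
})

test_that("multi-date preprocessing averages the per-date composites", {
  sc1 <- cached("scene_md_11",
                generate_scene(scene_spec(width_px = 32, height_px = 32, seed = 11)))
  sc2 <- cached("scene_md_12",
                generate_scene(scene_spec(width_px = 32, height_px = 32, seed = 12)))
  both <- preprocess_scene(list(sc1$ms, sc2$ms), NULL)
  one <- preprocess_scene(sc1$ms, NULL)
  two <- preprocess_scene(sc2$ms, NULL)
  expect_equal(both$composite$values,
               (one$composite$values + two$composite$values) / 2)
})
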