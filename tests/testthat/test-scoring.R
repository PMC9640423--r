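# a straight east-west stream across a 40 x 100 px grid at 2 m
straight_grid <- function(H = 40, W = 100, res = 2, y = NULL) {
  grid <- ripaq_raster(matrix(0, H, W), res, origin = c(0, H * res))
  y0 <- if (is.null(y)) H * res / 2 + res / 2 else y  # on a row of centres
  line <- tibble::tibble(x = c(0, W * res), y = c(y0, y0))
  list(grid = grid, line = line, y0 = y0)
}

test_that("a straight stream buffer is a band split into upper and lower banks", {
  g <- straight_grid()
  buf <- buffer_stream(g$grid, width_m = 50, centerline = g$line)
  cc <- pixel_centers(g$grid)
  in_band <- abs(outer(cc$y, rep(1, 100)) - g$y0) <= 50
  expect_equal(buf$mask, in_band)
  # left bank (looking downstream, +x) is the northern half; a pixel exactly
  # on the line ties to the left bank
  expect_true(all(cc$y[which(buf$left[, 1])] >= g$y0))
  expect_true(all(cc$y[which(buf$right[, 1])] < g$y0))
  # width 0 keeps only pixel centres on the line
  buf0 <- buffer_stream(g$grid, width_m = 0, centerline = g$line)
  expect_equal(sum(buf0$mask), 100)
  expect_error(stream_field(tibble::tibble(x = c(1, 1), y = c(2, 2)), g$grid),
               "degenerate")
})

test_that("a meandering buffer area approaches the analytic band area", {
  sc <- small_scene(3)
  grid <- sc$truth$labels
  buf <- buffer_stream(grid, width_m = 30, centerline = sc$truth$centerline)
  # clip to the interior in x so the ends do not truncate the band
  cc <- pixel_centers(grid)
  interior <- cc$x > 30 & cc$x < max(cc$x) - 30
  got <- sum(buf$mask[, interior]) * grid$resolution^2
  len <- centerline_length(sc$truth$centerline[
    sc$truth$centerline$x > 30 & sc$truth$centerline$x < max(cc$x) - 30, ])
  expect_lt(abs(got - 2 * 30 * len) / (2 * 30 * len), 0.05)
})

test_that("stations come per bank, equally spaced, with disjoint footprints", {
  g <- straight_grid(H = 40, W = 900, res = 2)   # 1800 m reach
  st15 <- make_stations(g$line, 15)
  expect_equal(nrow(st15), 30L)
  expect_equal(unique(table(st15$bank)), 15L)
  expect_equal(diff(unique(st15$chainage_m)), rep(120, 14))

  st1 <- make_stations(g$line, 1)
  expect_equal(nrow(st1), 2L)
  expect_error(make_stations(g$line, 50), "too short")

  buf <- buffer_stream(g$grid, 50, centerline = g$line)
  cells <- lapply(seq_len(15), function(i) {
    station_cells(buf, "left", st15$chainage_from_m[2 * i - 1],
                  st15$chainage_to_m[2 * i - 1])
  })
  all_cells <- unlist(cells)
  expect_equal(length(all_cells), length(unique(all_cells)))
})

test_that("composition excludes water and renormalises to 100", {
  v <- matrix(c(rep(2, 60), rep(3, 40)), 10, 10)
  cr <- ripaq_raster(v + 0, 2, origin = c(0, 20))
  comp <- composition(cr, cells = 1:100)
  expect_equal(comp$pct[comp$class == "forest"], 60)
  expect_equal(comp$pct[comp$class == "crops"], 40)

  v2 <- matrix(c(rep(1, 50), rep(2, 30), rep(3, 20)), 10, 10)
  cr2 <- ripaq_raster(v2 + 0, 2, origin = c(0, 20))
  comp2 <- composition(cr2, cells = 1:100)
  expect_equal(sum(comp2$pct), 100)
  expect_equal(comp2$pct[comp2$class == "forest"], 60)
  expect_equal(comp2$pct[comp2$class == "crops"], 40)

  v3 <- matrix(1, 5, 5)
  expect_error(composition(ripaq_raster(v3 + 0, 2), cells = 1:25),
               "no scoreable pixels")
})

test_that("the RSQI evaluates the weighted land-use sum", {
  expect_equal(rsqi(c(forest = 100)), 100)
  expect_equal(rsqi(c(bare_soil = 100)), 17)
  expect_equal(rsqi(c(forest = 50, crops = 30, urban = 20)), 59.5)
  expect_error(rsqi(c(forest = 50)), "sum to 100")
  expect_error(rsqi(c(water = 100)), "no weight")
  expect_error(class_weights(forest = 1), "maximum")
  expect_error(class_weights(crops = -2), "weights")
})

test_that("the RSQI is monotone in the forest share and bounded in [17, 100]", {
  set.seed(4)
  for (i in 1:25) {
    p <- as.numeric(stats::rmultinom(1, 100, runif(4)))
    comp <- setNames(p, c("forest", "crops", "bare_soil", "urban"))
    s0 <- rsqi(comp)
    expect_gte(s0, 17); expect_lte(s0, 100)
    donor <- names(comp)[comp > 0 & names(comp) != "forest"][1]
    if (!is.na(donor)) {
      comp2 <- comp
      comp2["forest"] <- comp2["forest"] + 1
      comp2[donor] <- comp2[donor] - 1
      expect_gte(rsqi(comp2), s0)
    }
  }
})

test_that("RSQI categories follow the published bands", {
  expect_equal(rsqi_category(37), "very_low")
  expect_equal(rsqi_category(94), "high")
  expect_equal(rsqi_category(71.57), "moderate")
  expect_equal(rsqi_category(c(39.99, 40, 59.9, 60, 79.9, 80)),
               c("very_low", "low", "low", "moderate", "moderate", "high"))
})

test_that("QBR totals add the four blocks and reject invalid block scores", {
  expect_equal(qbr_total(c(25, 25, 25, 25)), 100L)
  expect_equal(qbr_total(c(0, 0, 0, 0)), 0L)
  expect_equal(qbr_total(c(15, 15, 15, 10)), 55L)
  expect_error(qbr_total(c(25, 25, 25)), "four")
  expect_error(qbr_total(c(25, 25, 25, 26)), "0, 5, 10")
  expect_error(qbr_total(c(25, 25, 25, 30)), "0, 5, 10")
})

test_that("QBR categories and restoration triage follow the published bands", {
  expect_equal(qbr_category(55), "moderate")
  expect_equal(qbr_category(100), "very_good")
  expect_equal(qbr_category(50), "poor")
  expect_equal(qbr_category(c(95, 90, 75, 70, 30, 25, 0)),
               c("very_good", "good", "good", "moderate", "poor", "bad", "bad"))
  expect_error(qbr_category(56), "multiples of 5")

  expect_equal(restoration_action(60), "recovery")
  expect_equal(restoration_action(40), "restoration")
  expect_equal(restoration_action(95), "conservation")
})

test_that("category functions are total and mutually exclusive on the domain", {
  qbr_domain <- seq(0, 100, by = 5)
  cats <- qbr_category(qbr_domain)
  acts <- restoration_action(qbr_domain)
  expect_false(any(is.na(cats)))
  expect_false(any(is.na(acts)))
  expect_equal(length(cats), length(qbr_domain))
  # each category occupies one contiguous, non-overlapping band
  expect_equal(rle(cats)$values, c("bad", "poor", "moderate", "good", "very_good"))
  expect_equal(rle(acts)$values, c("restoration", "recovery", "conservation"))
  rs <- seq(0, 100, by = 0.5)
  rcats <- rsqi_category(rs)
  expect_false(any(is.na(rcats)))
  expect_equal(rle(rcats)$values, c("very_low", "low", "moderate", "high"))
})

test_that("station scoring joins field QBR blocks into categories and triage", {
  g <- straight_grid(H = 40, W = 100, res = 2)
  v <- matrix(2, 40, 100)
  v[19:21, ] <- 1
  cr <- ripaq_raster(v + 0, 2, origin = c(0, 80))
  qbr <- tibble::tibble(station_id = c(1, 1), bank = c("left", "right"),
                        block1 = c(25, 10), block2 = c(25, 10),
                        block3 = c(25, 10), block4 = c(20, 10))
  sco <- score_stations(cr, g$line, n_stations = 1, qbr = qbr)
  expect_s3_class(sco, "ripaq_scores")
  expect_equal(nrow(sco), 2L)
  expect_equal(sco$rsqi, c(100, 100))
  expect_equal(sco$qbr_total, c(95L, 40L))
  expect_equal(sco$qbr_category, c("very_good", "poor"))
  expect_equal(sco$action, c("conservation", "restoration"))
})
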