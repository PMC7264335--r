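test_that("estimateBackground recovers a uniform background exactly", {
  p <- testParams(seed = 7L, readNoiseSd = 0, shotNoise = FALSE,
                  backgroundLevel = 120)
  f <- generateWellField(p)
  nuc <- channelData(f$stack, "nuclear")
  expect_equal(estimateBackground(nuc, f$labels, marginPx = 3L), 120)

  full <- LabelImage(matrix(1L, 8, 8), 8L)
  expect_error(estimateBackground(matrix(0, 8, 8), full),
               "degenerate-field")

  # halo-free objects: margin 0 and 3 see the same background pixels
  img <- matrix(50, 40, 40)
  lab <- matrix(0L, 40, 40); lab[10:14, 10:14] <- 1L
  img[10:14, 10:14] <- 900
  li <- LabelImage(lab, 8L)
  expect_equal(estimateBackground(img, li, 0L),
               estimateBackground(img, li, 3L))
})

test_that("measureCells computes floored background-corrected means", {
  img <- matrix(20, 30, 30)
  lab <- matrix(0L, 30, 30)
  lab[5:9, 5:9] <- 1L;  img[5:9, 5:9] <- 120    # corrected 100
  lab[20:24, 20:24] <- 2L; img[20:24, 20:24] <- 15  # raw below background
  cs <- ChannelStack(img, c(sensor = 1L), 16L)
  rec <- measureCells(cs, LabelImage(lab, 8L), marginPx = 0L)
  expect_equal(rec$raw_mean_sensor, c(120, 15))
  bg <- attr(rec, "background")[["sensor"]]
  expect_equal(rec$bg_mean_sensor, pmax(c(120, 15) - bg, 0))
  expect_equal(rec$bg_mean_sensor[2], 0)  # floored
  expect_equal(rec$area_px, c(25L, 25L))
  expect_equal(rec$centroid_row, c(7, 22))

  # empty label set is an empty table, not an error
  empty <- measureCells(cs, LabelImage(matrix(0L, 30, 30), 8L))
  expect_identical(nrow(empty), 0L)
})

test_that("measured sensor means match generator ground truth", {
  p <- testParams(seed = 29L, readNoiseSd = 0, shotNoise = FALSE,
                  pPositive = 0.5)
  f <- generateWellField(p)
  rec <- measureCells(f$stack, f$labels)
  bg <- attr(rec, "background")[["sensor"]]
  expect_equal(bg, p@backgroundLevel, tolerance = 1e-3)
  expect_true(all(abs(rec$bg_mean_sensor -
                      (f$truth$true_sensor - p@backgroundLevel)) < 1))
})

test_that("sensor/expression ratio is guarded and scale-invariant", {
  rec <- data.frame(bg_mean_sensor = c(100, 80, 10),
                    bg_mean_expression = c(50, 0, 40))
  out <- computeRatio(rec)
  expect_equal(out$ratio, c(2, NA, 0.25))

  set.seed(3)
  base <- data.frame(bg_mean_sensor = runif(50, 10, 500),
                     bg_mean_expression = runif(50, 10, 500))
  for (c0 in c(0.5, 2, 17)) {
    scaled <- base * c0
    expect_equal(computeRatio(scaled)$ratio, computeRatio(base)$ratio)
  }
})

test_that("control-null threshold follows mean + k * sample SD", {
  expect_equal(controlNullThreshold(c(10, 12, 14, 16, 18), 2),
               14 + 2 * sqrt(10))
  expect_equal(controlNullThreshold(rep(7, 5), 2), 7)
  expect_error(controlNullThreshold(5), "insufficient-control")
})

test_that("classification is strictly 'above' the threshold", {
  rec <- data.frame(bg_mean_sensor = c(399, 400, 401))
  out <- classifyCells(rec, classificationRule("fixed",
                                               fixedThreshold = 400))
  expect_identical(out$is_positive, c(FALSE, FALSE, TRUE))
  expect_error(classifyCells(rec, classificationRule("control_null")),
               "configuration error")
})

test_that("control-null rule on held-out null cells recovers the 2-SD tail", {
  set.seed(41)
  controls <- stats::rnorm(10000, 300, 40)
  heldOut <- data.frame(bg_mean_sensor = stats::rnorm(10000, 300, 40))
  out <- classifyCells(heldOut, classificationRule("control_null", kSd = 2),
                       controlValues = controls)
  expect_lt(abs(mean(out$is_positive) - (1 - stats::pnorm(2))), 0.005)
})

test_that("raising a fixed threshold never increases the positive count", {
  f <- generateWellField(testParams(seed = 37L, pPositive = 0.5))
  rec <- measureCells(f$stack, f$labels)
  nPos <- vapply(seq(0, 3000, by = 100), function(thr) {
    sum(classifyCells(rec, classificationRule("fixed",
                                              fixedThreshold = thr))$is_positive)
  }, numeric(1))
  expect_true(all(diff(nPos) <= 0))
})

test_that("well and sample summaries average the way replicates are pooled", {
  pm <- data.frame(well_id = c("W1", "W2", "W3", "W4"),
                   condition = "csf", replicate_index = c(1:3, 1),
                   sample_id = c("S1", "S1", "S1", "S2"))
  # three wells with per-well fractions 0.1, 0.2, 0.3 -> sample value 0.2
  cells <- rbind(
    data.frame(well_id = "W1", image_id = "a",
               is_positive = c(TRUE, rep(FALSE, 9))),
    data.frame(well_id = "W2", image_id = "a",
               is_positive = c(TRUE, TRUE, rep(FALSE, 8))),
    data.frame(well_id = "W3", image_id = "a",
               is_positive = c(TRUE, TRUE, TRUE, rep(FALSE, 7))))
  s <- summarizeWells(cells, pm)
  expect_equal(s$perWell$fraction_positive[1:3], c(0.1, 0.2, 0.3))
  expect_equal(s$perSample$fraction_positive[s$perSample$sample_id == "S1"],
               0.2)
  # W4 has zero cells: flagged, excluded from the sample mean
  expect_true(s$perWell$flagged[s$perWell$well_id == "W4"])
  expect_false("S2" %in% s$perSample$sample_id)
})

test_that("recovered per-well fractions track the generator's p_positive", {
  p <- synthParams(imageHeightPx = 448L, imageWidthPx = 448L, nCells = 500L,
                   pPositive = 0.30, seed = 43L)
  f <- generateWellField(p)
  seg <- segmentCells(f$stack, "expression", segmentationParams())
  rec <- classifyCells(computeRatio(measureCells(f$stack, seg)),
                       classificationRule("fixed"))
  expect_lt(abs(mean(rec$is_positive) - 0.30), 0.05)
})
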