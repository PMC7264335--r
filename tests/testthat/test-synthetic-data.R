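test_that("identical parameters give bit-identical fields and tables", {
  p <- testParams(seed = 11L, pPositive = 0.4)
  a <- generateWellField(p)
  b <- generateWellField(p)
  expect_identical(a$stack@pixels, b$stack@pixels)
  expect_identical(labelMatrix(a$labels), labelMatrix(b$labels))
  expect_identical(a$truth, b$truth)
})

test_that("positivity draws follow the documented Bernoulli sub-stream", {
  p <- synthParams(imageHeightPx = 384L, imageWidthPx = 384L,
                   nCells = 200L, pPositive = 0.5, seed = 21L)
  f <- generateWellField(p)
  s <- synthStreamSeeds(21L)
  set.seed(s[["positivity"]])
  replay <- stats::rbinom(200L, 1L, 0.5) == 1L
  expect_identical(f$truth$is_positive, replay)
  expect_identical(sum(f$truth$is_positive), sum(replay))
})

test_that("degenerate positive fractions are forced by construction", {
  f0 <- generateWellField(testParams(pPositive = 0, seed = 2L))
  expect_false(any(f0$truth$is_positive))
  f1 <- generateWellField(testParams(pPositive = 1, seed = 2L))
  expect_true(all(f1$truth$is_positive))
})

test_that("ground-truth table is dense, unique and mask-consistent", {
  f <- generateWellField(testParams(seed = 5L))
  expect_identical(f$truth$cell_id, seq_len(nrow(f$truth)))
  lab <- labelMatrix(f$labels)
  expect_identical(sort(unique(lab[lab > 0])), seq_len(nrow(f$truth)))
  expect_identical(as.integer(tabulate(lab[lab > 0])), f$truth$area_px)
})

test_that("noise-free in-mask sensor means match the recorded ground truth", {
  p <- testParams(seed = 9L, readNoiseSd = 0, shotNoise = FALSE,
                  backgroundLevel = 0, pPositive = 0.5)
  f <- generateWellField(p)
  sen <- channelData(f$stack, "sensor")
  lab <- labelMatrix(f$labels)
  for (i in f$truth$cell_id) {
    got <- mean(sen[lab == i])
    expect_lt(abs(got - f$truth$true_sensor[i]), 0.5)  # pixel quantization
  }
})

test_that("pPositive touches only the sensor channel", {
  a <- generateWellField(testParams(pPositive = 0.2, seed = 31L))
  b <- generateWellField(testParams(pPositive = 0.8, seed = 31L))
  expect_identical(channelData(a$stack, "nuclear"),
                   channelData(b$stack, "nuclear"))
  expect_identical(channelData(a$stack, "expression"),
                   channelData(b$stack, "expression"))
  expect_false(identical(channelData(a$stack, "sensor"),
                         channelData(b$stack, "sensor")))
  expect_identical(labelMatrix(a$labels), labelMatrix(b$labels))
})

test_that("invalid parameters and impossible densities error", {
  expect_error(synthParams(pPositive = 1.5), "pPositive")
  expect_error(synthParams(nucleusRadiusPx = c(-1, 2)), "nucleusRadiusPx")
  expect_error(
    generateWellField(synthParams(imageHeightPx = 40L, imageWidthPx = 40L,
                                  nCells = 100L, seed = 1L)),
    "density error")
})

test_that("pixel values are clipped to the declared bit depth", {
  p <- testParams(seed = 3L, bitDepth = 8L, nuclearMeanIntensity = 5000)
  f <- generateWellField(p)
  expect_lte(max(f$stack@pixels), 255)
  expect_gte(min(f$stack@pixels), 0)
})

test_that("in vivo blobs are co-localized and cancel under subtraction", {
  p <- testParams(seed = 13L, nCells = 12L, speckleDensity = 8L,
                  readNoiseSd = 0, shotNoise = FALSE)
  iv <- generateInvivoStack(p)
  g <- projectMax(iv$stack, "sensor")
  b <- projectMax(iv$stack, "auxiliary")
  d <- subtractChannel(g, b)
  expect_true(all(d[iv$blobMask > 0] == 0))
  # nuclei pixels are unchanged by the subtraction (blue holds background
  # only there)
  nucPix <- labelMatrix(iv$labels) > 0
  expect_equal(d[nucPix], g[nucPix] - p@backgroundLevel)
})

test_that("in vivo mode with no speckles leaves the blue channel flat", {
  p <- testParams(seed = 17L, nCells = 10L, speckleDensity = 0L,
                  readNoiseSd = 0, shotNoise = FALSE)
  iv <- generateInvivoStack(p)
  blue <- channelData(iv$stack, "auxiliary")
  expect_true(all(blue == p@backgroundLevel))
})

test_that("in vivo ground-truth nucleus areas lie in the 20-150 px band", {
  iv <- generateInvivoStack(testParams(seed = 19L, nCells = 30L,
                                       speckleDensity = 10L))
  expect_true(all(iv$truth$area_px >= 20L & iv$truth$area_px <= 150L))
})
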