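test_that("projectMax matches the per-pixel loop oracle", {
  px <- array(0, c(2, 2, 1, 2))
  px[, , 1, 1] <- matrix(c(0, 3, 5, 1), 2, 2)  # [[0,5],[3,1]]
  px[, , 1, 2] <- matrix(2, 2, 2)
  cs <- ChannelStack(px, c(sensor = 1L), 16L)
  expect_identical(projectMax(cs, "sensor"), matrix(c(2, 3, 5, 2), 2, 2))

  one <- ChannelStack(matrix(1:9, 3, 3), c(sensor = 1L), 16L)
  expect_identical(projectMax(one, "sensor"), matrix(as.numeric(1:9), 3, 3))

  set.seed(1)
  px <- array(sample(0:255, 8 * 8 * 3, TRUE), c(8, 8, 1, 3))
  cs <- ChannelStack(px, c(sensor = 1L), 16L)
  got <- projectMax(cs, "sensor")
  want <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) want[i, j] <- max(px[i, j, 1, ])
  expect_identical(got, want)
})

test_that("subtractChannel clips at zero and rejects shape mismatches", {
  a <- matrix(c(5, 200), 1, 2)
  b <- matrix(c(7, 50), 1, 2)
  expect_identical(subtractChannel(a, b), matrix(c(0, 150), 1, 2))
  expect_error(subtractChannel(a, matrix(0, 2, 2)), "shape mismatch")
})

test_that("liThreshold equals the exhaustive cross-entropy minimizer", {
  img <- matrix(c(rep(50, 60), rep(200, 40)), 10, 10)
  t0 <- liThreshold(img)
  expect_gte(t0, 50); expect_lt(t0, 200)
  expect_identical(unname(table(img > t0)), unname(table(c(rep(FALSE, 60),
                                                           rep(TRUE, 40)))))
  expect_identical(t0, oracleLiThreshold(img))

  expect_error(liThreshold(matrix(7, 4, 4)), "degenerate-input")

  for (s in 1:10) {
    set.seed(s)
    img <- matrix(sample(0:255, 48 * 48, TRUE), 48, 48)
    expect_identical(liThreshold(img), oracleLiThreshold(img))
  }
})

test_that("otsuThreshold maximizes between-class variance exactly", {
  oracleOtsu <- function(img) {
    v <- as.vector(img)
    cand <- min(v):(max(v) - 1L)
    bc <- vapply(cand, function(t) {
      n1 <- sum(v <= t); n2 <- sum(v > t)
      n1 * n2 * (mean(v[v <= t]) - mean(v[v > t]))^2
    }, numeric(1))
    cand[which.max(bc)]
  }
  for (s in 1:5) {
    set.seed(s)
    img <- matrix(c(stats::rpois(300, 30), stats::rpois(200, 180)), 25, 20)
    expect_identical(otsuThreshold(img), oracleOtsu(img))
  }
  expect_error(otsuThreshold(matrix(1, 3, 3)), "degenerate-input")
})

test_that("despeckle equals the naive sliding-window median oracle", {
  lone <- matrix(0, 9, 9); lone[5, 5] <- 1
  expect_true(all(despeckle(lone, 1) == 0))
  const <- matrix(3, 6, 6)
  expect_identical(despeckle(const, 5), const)
  set.seed(2)
  bin <- matrix(rbinom(32 * 32, 1, 0.4), 32, 32)
  expect_identical(despeckle(bin, 4), oracleDespeckle(bin, 4))
  gray <- matrix(sample(0:255, 32 * 32, TRUE), 32, 32)
  expect_identical(despeckle(gray, 4), oracleDespeckle(gray, 4))
  expect_identical(despeckle(gray, 0), gray)
  # a median never introduces new values
  expect_true(all(despeckle(gray, 2) %in% gray))
})

test_that("labelComponents matches a flood-fill oracle for 4 and 8 connectivity", {
  # touching diagonal blobs: one object under 8, two under 4
  m <- matrix(0, 6, 6)
  m[2:3, 2:3] <- 1; m[4:5, 4:5] <- 1
  l8 <- labelComponents(m > 0, 8L)
  l4 <- labelComponents(m > 0, 4L)
  expect_identical(nObjects(l8), 1L)
  expect_identical(nObjects(l4), 2L)
  expect_identical(labelMatrix(l8), oracleComponents(m > 0, 8L))
  expect_identical(labelMatrix(l4), oracleComponents(m > 0, 4L))

  for (s in 1:5) {
    set.seed(s)
    m <- matrix(rbinom(30 * 30, 1, 0.35), 30, 30) > 0
    for (conn in c(4L, 8L))
      expect_identical(labelMatrix(labelComponents(m, conn)),
                       oracleComponents(m, conn))
  }
})

test_that("labels are assigned in raster order of each object's first pixel", {
  m <- matrix(0, 5, 7)
  m[4, 1] <- 1          # first in column-major order...
  m[1, 5] <- 1          # ...but second object starts earlier in raster order
  lab <- labelMatrix(labelComponents(m > 0, 8L))
  expect_identical(lab[1, 5], 1L)
  expect_identical(lab[4, 1], 2L)
})

test_that("sizeFilter keeps the closed interval [20, 150]", {
  # four horizontal bars with areas 19, 20, 150, 151 on separate rows
  m <- matrix(0, 9, 160)
  m[1, 1:19] <- 1
  m[3, 1:20] <- 1
  m[5, 1:150] <- 1
  m[7, 1:151] <- 1
  lab <- labelComponents(m > 0, 8L)
  expect_identical(nObjects(lab), 4L)
  kept <- sizeFilter(lab, 20L, 150L)
  expect_identical(nObjects(kept), 2L)
  areas <- tabulate(labelMatrix(kept)[labelMatrix(kept) > 0])
  expect_identical(sort(areas), c(20L, 150L))

  empty <- LabelImage(matrix(0L, 4, 4), 8L)
  expect_identical(nObjects(sizeFilter(empty, 20L, 150L)), 0L)
  # all inside bounds: unchanged up to (raster-stable) relabeling
  expect_identical(labelMatrix(sizeFilter(lab, 1L, 200L)),
                   labelMatrix(lab))
  expect_error(sizeFilter(lab, 100L, 50L), "parameter error")
})

test_that("segmentCells recovers noise-free synthetic fields exactly", {
  p <- testParams(seed = 23L, nCells = 30L, readNoiseSd = 0,
                  shotNoise = FALSE)
  f <- generateWellField(p)
  seg <- segmentCells(f$stack, "nuclear", segmentationParams())
  expect_identical(nObjects(seg), nrow(f$truth))
  rec <- labelCentroids(labelMatrix(seg))
  matched <- greedyCentroidMatch(cbind(f$truth$row, f$truth$col), rec,
                                 maxDist = 2)
  expect_identical(matched, nrow(f$truth))
})

test_that("segmentCells honors size bounds, connectivity and border policy", {
  # one 10 px and one 60 px object with bounds [20, 150] -> one object
  img <- matrix(0, 64, 64)
  img[10:11, 10:14] <- 1000          # 10 px
  img[30:35, 30:39] <- 1000          # 60 px
  cs <- ChannelStack(img, c(nuclear = 1L), 16L)
  seg <- segmentCells(cs, "nuclear",
                      segmentationParams(thresholdMethod = "fixed",
                                         fixedThreshold = 500,
                                         despeckleRounds = 0L))
  expect_identical(nObjects(seg), 1L)

  # touching diagonal blobs: 8-connectivity merges, 4 keeps them apart
  img2 <- matrix(0, 32, 32)
  img2[5:10, 5:10] <- 1000; img2[11:16, 11:16] <- 1000
  cs2 <- ChannelStack(img2, c(nuclear = 1L), 16L)
  base <- segmentationParams(thresholdMethod = "fixed", fixedThreshold = 500,
                             despeckleRounds = 0L, minAreaPx = 1L,
                             maxAreaPx = 4096L)
  s8 <- segmentCells(cs2, "nuclear", base)
  base4 <- segmentationParams(thresholdMethod = "fixed",
                              fixedThreshold = 500, despeckleRounds = 0L,
                              minAreaPx = 1L, maxAreaPx = 4096L,
                              connectivity = 4L)
  s4 <- segmentCells(cs2, "nuclear", base4)
  expect_identical(nObjects(s8), max(oracleComponents(img2 > 500, 8L)))
  expect_identical(nObjects(s4), max(oracleComponents(img2 > 500, 4L)))

  # border policy: an object on the edge is dropped under "drop"
  img3 <- matrix(0, 32, 32)
  img3[1:5, 1:8] <- 1000; img3[15:19, 15:22] <- 1000
  cs3 <- ChannelStack(img3, c(nuclear = 1L), 16L)
  keep <- segmentCells(cs3, "nuclear",
                       segmentationParams(thresholdMethod = "fixed",
                                          fixedThreshold = 500,
                                          despeckleRounds = 0L))
  drop <- segmentCells(cs3, "nuclear",
                       segmentationParams(thresholdMethod = "fixed",
                                          fixedThreshold = 500,
                                          despeckleRounds = 0L,
                                          borderPolicy = "drop"))
  expect_identical(nObjects(keep), 2L)
  expect_identical(nObjects(drop), 1L)

  expect_error(segmentCells(ChannelStack(matrix(5, 8, 8),
                                         c(nuclear = 1L), 16L), "nuclear"),
               "degenerate-input")
})
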