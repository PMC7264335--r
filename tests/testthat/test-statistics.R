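test_that("sem follows the hand formula", {
  expect_equal(sem(c(2, 4, 6)), 2 / sqrt(3))
  expect_equal(sem(rep(5, 4)), 0)
  expect_error(sem(3), "n >= 2")
})

test_that("one-way ANOVA matches hand computation and the F tail", {
  r <- oneWayAnova(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(r@statistic, 13.5)
  expect_equal(unname(r@df), c(1, 4))
  expect_equal(r@pValue, 0.02131164, tolerance = 1e-6)
  # p equals numerical integration of the F density upper tail
  quad <- stats::integrate(function(x) stats::df(x, 1, 4), 13.5, Inf)$value
  expect_equal(r@pValue, quad, tolerance = 1e-6)

  same <- oneWayAnova(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))
  expect_equal(same@statistic, 0)
  expect_equal(same@pValue, 1)

  expect_error(oneWayAnova(list(a = c(2, 2), b = c(2, 2))), "undefined-F")
  expect_error(oneWayAnova(list(a = 1:3)), ">= 2 groups")
  expect_error(oneWayAnova(list(a = 1:3, b = 2)), "n >= 2")
})

test_that("F equals t squared for two groups", {
  for (s in 1:20) {
    set.seed(s)
    a <- stats::rnorm(sample(3:8, 1)); b <- stats::rnorm(sample(3:8, 1), 1)
    f <- oneWayAnova(list(a = a, b = b))@statistic
    t <- tTestUnpaired(a, b)@statistic
    expect_equal(f, t^2, tolerance = 1e-10)
  }
})

test_that("Tukey HSD reduces to the pooled t-test for two groups", {
  for (s in 1:10) {
    set.seed(s)
    a <- stats::rnorm(5); b <- stats::rnorm(4, 0.8)
    tk <- tukeyHsd(list(a = a, b = b))
    tt <- tTestUnpaired(a, b)
    expect_equal(tk@pairwise$adj_p, tt@pValue, tolerance = 1e-6)
  }
})

test_that("Tukey HSD handles identical groups and tabulated critical values", {
  tk <- tukeyHsd(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))
  expect_true(all(tk@pairwise$adj_p == 1))

  # k = 3 groups of n = 5 (df = 12) built so MS_within = 1 exactly and the
  # largest pair sits at the tabulated q_{0.05}(3, 12) = 3.773 critical value
  shape <- c(-2, -1, 0, 1, 2) / sqrt(2.5)
  d <- 3.773 * sqrt(1 / 5)
  tk2 <- tukeyHsd(list(a = shape, b = shape, c = shape + d))
  worst <- min(tk2@pairwise$adj_p)
  expect_equal(worst, 0.05, tolerance = 1e-3)
})

test_that("unpaired t-test matches hand computation and conventions", {
  r <- tTestUnpaired(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r@statistic, -3.674235, tolerance = 1e-6)
  expect_equal(unname(r@df), 4)
  expect_equal(r@pValue, 0.02131164, tolerance = 1e-6)

  same <- tTestUnpaired(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same@statistic, 0)
  expect_equal(same@pValue, 1)

  expect_error(tTestUnpaired(c(2, 2), c(2, 2)), "undefined")
  expect_warning(r0 <- tTestUnpaired(c(2, 2), c(5, 5)), "p -> 0")
  expect_equal(r0@pValue, 0)

  # strongly separated populations reach the p < 0.0001 regime
  set.seed(99)
  big <- tTestUnpaired(stats::rnorm(100, 2500, 300),
                       stats::rnorm(100, 600, 200))
  expect_lt(big@pValue, 1e-4)
})

test_that("p-values are symmetric under group relabeling and lie in [0, 1]", {
  for (s in 1:10) {
    set.seed(s)
    g <- list(a = stats::rnorm(4), b = stats::rnorm(5, 0.5),
              c = stats::rnorm(6, 1))
    r1 <- oneWayAnova(g)
    r2 <- oneWayAnova(rev(g))
    expect_equal(r1@pValue, r2@pValue, tolerance = 1e-12)
    expect_true(r1@pValue >= 0 && r1@pValue <= 1)
    tk1 <- sort(tukeyHsd(g)@pairwise$adj_p)
    tk2 <- sort(tukeyHsd(rev(g))@pairwise$adj_p)
    expect_equal(tk1, tk2, tolerance = 1e-10)
  }
})

test_that("Tukey familywise error under a four-group null stays near alpha", {
  set.seed(4242)
  nRuns <- 2000L
  anyRej <- logical(nRuns)
  for (i in seq_len(nRuns)) {
    g <- list(a = stats::rnorm(5), b = stats::rnorm(5),
              c = stats::rnorm(5), d = stats::rnorm(5))
    anyRej[i] <- any(tukeyHsd(g)@pairwise$adj_p < 0.05)
  }
  expect_lte(mean(anyRej), 0.065)
})
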