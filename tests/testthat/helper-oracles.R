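# Independent brute-force oracles used to validate the package's vectorized
# implementations. These deliberately avoid the code paths they check.

# minimum cross-entropy criterion evaluated directly from its definition:
# eta(t) = sum_{g<=t} h(g) g log(g/mu_low) + sum_{g>t} h(g) g log(g/mu_high),
# with g = 0 contributing 0; exhaustive search over integer thresholds.
oracleLiThreshold <- function(image) {
  v <- round(as.vector(image))
  cand <- min(v):(max(v) - 1L)
  eta <- vapply(cand, function(t) {
    lowv <- v[v <= t]; highv <- v[v > t]
    muLow <- mean(lowv); muHigh <- mean(highv)
    term <- function(vals, mu) {
      nz <- vals[vals > 0]
      if (!length(nz) || mu <= 0) 0 else sum(nz * log(nz / mu))
    }
    term(lowv, muLow) + term(highv, muHigh)
  }, numeric(1))
  cand[which.min(eta)]
}

# naive sliding-window 3x3 median with edge replication
oracleMedian3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- pmin(pmax(i + (-1:1), 1L), nr)
    jj <- pmin(pmax(j + (-1:1), 1L), nc)
    out[i, j] <- stats::median(m[ii, jj])
  }
  out
}

oracleDespeckle <- function(m, rounds) {
  for (k in seq_len(rounds)) m <- oracleMedian3x3(m)
  m
}

# flood-fill connected components (explicit stack), raster-stable labels
oracleComponents <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  offs <- if (connectivity == 8L)
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
          c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  lab <- matrix(0L, nr, nc)
  nextLab <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {  # raster scan
    if (!mask[i, j] || lab[i, j] != 0L) next
    nextLab <- nextLab + 1L
    stack <- list(c(i, j)); lab[i, j] <- nextLab
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(offs))) {
        a <- p[1] + offs[k, 1]; b <- p[2] + offs[k, 2]
        if (a >= 1 && a <= nr && b >= 1 && b <= nc &&
            mask[a, b] && lab[a, b] == 0L) {
          lab[a, b] <- nextLab
          stack[[length(stack) + 1L]] <- c(a, b)
        }
      }
    }
  }
  lab
}

# greedy nearest-centroid matching; returns the number of truth centroids
# matched to a distinct recovered centroid within maxDist px
greedyCentroidMatch <- function(truthRC, recRC, maxDist = 2) {
  if (!nrow(truthRC) || !nrow(recRC)) return(0L)
  used <- rep(FALSE, nrow(recRC))
  matched <- 0L
  for (i in seq_len(nrow(truthRC))) {
    d <- sqrt((recRC[, 1] - truthRC[i, 1])^2 +
              (recRC[, 2] - truthRC[i, 2])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= maxDist) {
      used[j] <- TRUE
      matched <- matched + 1L
    }
  }
  matched
}

# centroids of a label matrix as a (row, col) matrix in label order
labelCentroids <- function(lab) {
  k <- max(lab)
  if (k == 0L) return(matrix(numeric(), 0, 2))
  idx <- which(lab > 0)
  nr <- nrow(lab)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  cbind(tapply(rows, lab[idx], mean), tapply(cols, lab[idx], mean))
}

# small default generator settings so unit tests stay fast
testParams <- function(...) {
  args <- utils::modifyList(
    list(imageHeightPx = 192L, imageWidthPx = 192L, nCells = 25L),
    list(...))
  do.call(synthParams, args)
}
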