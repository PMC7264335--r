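#' SegmentationParams: parameters of the nucleus/cell segmentation chain
#'
#' @slot thresholdMethod \code{"li"} (minimum cross-entropy, default),
#'   \code{"otsu"}, or \code{"fixed"}.
#' @slot fixedThreshold AU cutoff when \code{thresholdMethod = "fixed"}.
#' @slot despeckleRounds iterations of the 3x3 median despeckle (>= 0).
#' @slot despeckleStage \code{"post"} (on the binary mask, default) or
#'   \code{"pre"} (on the grayscale image before thresholding).
#' @slot minAreaPx,maxAreaPx inclusive object-area bounds in px.
#' @slot connectivity 4 or 8 (default 8) for connected components.
#' @slot borderPolicy \code{"keep"} (default) or \code{"drop"}
#'   border-touching objects.
#' @export
setClass("SegmentationParams",
  representation(
    thresholdMethod = "character", fixedThreshold = "numeric",
    despeckleRounds = "integer", despeckleStage = "character",
    minAreaPx = "integer", maxAreaPx = "integer",
    connectivity = "integer", borderPolicy = "character"
  )
)

setValidity("SegmentationParams", function(object) {
  msg <- character()
  if (!(object@thresholdMethod %in% c("li", "otsu", "fixed")))
    msg <- c(msg, "thresholdMethod must be 'li', 'otsu' or 'fixed'")
  if (object@despeckleRounds < 0)
    msg <- c(msg, "despeckleRounds must be >= 0")
  if (!(object@despeckleStage %in% c("post", "pre")))
    msg <- c(msg, "despeckleStage must be 'post' or 'pre'")
  if (object@minAreaPx > object@maxAreaPx)
    msg <- c(msg, "parameter error: minAreaPx must be <= maxAreaPx")
  if (!(object@connectivity %in% c(4L, 8L)))
    msg <- c(msg, "connectivity must be 4 or 8")
  if (!(object@borderPolicy %in% c("keep", "drop")))
    msg <- c(msg, "borderPolicy must be 'keep' or 'drop'")
  if (length(msg)) msg else TRUE
})

#' Construct segmentation parameters
#'
#' Defaults: Li thresholding, one despeckle round on the binary mask,
#' inclusive area bounds 20-150 px (the nucleus-size band), 8-connectivity,
#' border-touching objects kept. The in vivo workflow ([runInvivo()]) uses
#' four despeckle rounds, matching the published mask recipe.
#'
#' @param thresholdMethod "li", "otsu" or "fixed".
#' @param fixedThreshold AU cutoff for the fixed method.
#' @param despeckleRounds 3x3 median iterations (default 1).
#' @param despeckleStage "post" (binary mask) or "pre" (grayscale).
#' @param minAreaPx,maxAreaPx inclusive area bounds (px).
#' @param connectivity 4 or 8.
#' @param borderPolicy "keep" or "drop".
#' @return a validated [SegmentationParams-class].
#' @export
segmentationParams <- function(thresholdMethod = c("li", "otsu", "fixed"),
                               fixedThreshold = 0,
                               despeckleRounds = 1L,
                               despeckleStage = c("post", "pre"),
                               minAreaPx = 20L, maxAreaPx = 150L,
                               connectivity = 8L,
                               borderPolicy = c("keep", "drop")) {
  new("SegmentationParams",
      thresholdMethod = match.arg(thresholdMethod),
      fixedThreshold = as.numeric(fixedThreshold),
      despeckleRounds = as.integer(despeckleRounds),
      despeckleStage = match.arg(despeckleStage),
      minAreaPx = as.integer(minAreaPx), maxAreaPx = as.integer(maxAreaPx),
      connectivity = as.integer(connectivity),
      borderPolicy = match.arg(borderPolicy))
}

#' Maximum-intensity z-projection of one channel
#'
#' Per-pixel maximum across the z-planes of the requested channel. A
#' single-plane channel is returned unchanged.
#'
#' @param stack a [ChannelStack-class].
#' @param role channel role name.
#' @return numeric matrix (row, col).
#' @export
projectMax <- function(stack, role) {
  x <- channelData(stack, role)
  if (is.matrix(x)) return(x)
  out <- x[, , 1L]
  for (k in seq_len(dim(x)[3L])[-1L]) out <- pmax(out, x[, , k])
  out
}

#' Clipped channel subtraction
#'
#' Per-pixel difference \code{minuend - subtrahend}, clipped at 0 (no
#' wraparound). Used to cancel autofluorescence visible in a second channel.
#'
#' @param minuend,subtrahend numeric matrices of identical shape.
#' @return numeric matrix.
#' @export
subtractChannel <- function(minuend, subtrahend) {
  if (!identical(dim(minuend), dim(subtrahend)))
    stop("shape mismatch: images must have identical dimensions")
  pmax(minuend - subtrahend, 0)
}

#' Li minimum cross-entropy threshold
#'
#' Returns the integer gray level \code{t} minimizing the minimum
#' cross-entropy criterion
#' \deqn{\eta(t) = \sum_{g \le t} h(g)\, g \log\frac{g}{\mu_{low}(t)}
#'              + \sum_{g > t} h(g)\, g \log\frac{g}{\mu_{high}(t)}}
#' over all integer thresholds for which both classes are non-empty, where
#' \code{h} is the intensity histogram and \eqn{\mu_{low}}/\eqn{\mu_{high}}
#' are the class mean intensities. Zero-intensity bins contribute 0 (the
#' limit \eqn{g \log g \to 0}). The minimization is exhaustive over the
#' histogram (computed with cumulative sums), so the returned value is the
#' global argmin; ties resolve to the smallest \code{t}. Binarization
#' convention downstream is strict: pixel \code{> t} is foreground.
#'
#' @param image numeric matrix of non-negative integer-valued intensities
#'   (non-integer values are rounded).
#' @return the threshold gray level (numeric scalar).
#' @examples
#' img <- matrix(c(rep(50, 60), rep(200, 40)), 10, 10)
#' liThreshold(img)
#' @export
liThreshold <- function(image) {
  v <- round(as.vector(image))
  if (any(v < 0)) stop("image must be non-negative")
  lo <- min(v); hi <- max(v)
  if (lo == hi)
    stop("degenerate-input error: constant image has no threshold")
  counts <- tabulate(v + 1L, nbins = hi + 1L)
  g <- 0:hi
  w <- counts * g
  cumN <- cumsum(counts); cumW <- cumsum(w)
  totN <- cumN[hi + 1L]; totW <- cumW[hi + 1L]
  glg <- counts * g * ifelse(g > 0, log(g), 0)
  totGLG <- sum(glg)
  cand <- lo:(hi - 1L)
  nLow <- cumN[cand + 1L]; wLow <- cumW[cand + 1L]
  nHigh <- totN - nLow; wHigh <- totW - wLow
  termLow <- ifelse(wLow > 0, wLow * log(wLow / nLow), 0)
  termHigh <- ifelse(wHigh > 0, wHigh * log(wHigh / nHigh), 0)
  eta <- totGLG - termLow - termHigh
  cand[which.min(eta)]
}

#' Otsu threshold on the integer histogram
#'
#' Maximizes the between-class variance over all integer thresholds; same
#' candidate and binarization conventions as [liThreshold()].
#'
#' @param image numeric matrix of non-negative integer-valued intensities.
#' @return the threshold gray level.
#' @export
otsuThreshold <- function(image) {
  v <- round(as.vector(image))
  if (any(v < 0)) stop("image must be non-negative")
  lo <- min(v); hi <- max(v)
  if (lo == hi)
    stop("degenerate-input error: constant image has no threshold")
  counts <- tabulate(v + 1L, nbins = hi + 1L)
  g <- 0:hi
  w <- counts * g
  cumN <- cumsum(counts); cumW <- cumsum(w)
  totN <- cumN[hi + 1L]; totW <- cumW[hi + 1L]
  cand <- lo:(hi - 1L)
  nLow <- cumN[cand + 1L]; wLow <- cumW[cand + 1L]
  nHigh <- totN - nLow; wHigh <- totW - wLow
  between <- nLow * nHigh * (wLow / nLow - wHigh / nHigh)^2
  cand[which.max(between)]
}

## one pass of the 3x3 median with edge replication, via the 19-comparator
## median-of-9 selection network (pmin/pmax on pixel vectors)
.median3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- m[c(1L, seq_len(nr), nr), c(1L, seq_len(nc), nc)]
  p <- vector("list", 9L)
  k <- 0L
  for (dc in 0:2) for (dr in 0:2) {
    k <- k + 1L
    p[[k]] <- pad[dr + seq_len(nr), dc + seq_len(nc)]
  }
  s <- function(a, b) {
    lo <- pmin(p[[a]], p[[b]]); p[[b]] <<- pmax(p[[a]], p[[b]]); p[[a]] <<- lo
  }
  s(2, 3); s(5, 6); s(8, 9)
  s(1, 2); s(4, 5); s(7, 8)
  s(2, 3); s(5, 6); s(8, 9)
  s(1, 4); s(6, 9); s(5, 8)
  s(4, 7); s(2, 5); s(3, 6)
  s(5, 8); s(5, 3); s(7, 5)
  s(5, 3)
  p[[5]]
}

#' Iterated 3x3 median despeckling
#'
#' Applies a 3x3 median filter \code{rounds} times with edge-replicated
#' borders. \code{rounds = 0} returns the input unchanged. The output value
#' range is a subset of the input range (a median never invents values).
#' Works on grayscale images and on binary masks alike.
#'
#' @param image numeric matrix.
#' @param rounds non-negative integer.
#' @return numeric matrix of the same shape.
#' @export
despeckle <- function(image, rounds) {
  rounds <- as.integer(rounds)
  if (rounds < 0) stop("rounds must be >= 0")
  for (i in seq_len(rounds)) image <- .median3x3(image)
  image
}

## row-major ("raster") key of a column-major linear index
.rasterKey <- function(idx, nr, nc) {
  r <- (idx - 1L) %% nr
  cl <- (idx - 1L) %/% nr
  as.numeric(r) * nc + cl
}

#' Label connected components of a binary mask
#'
#' Finds connected foreground components under 4- or 8-connectivity via a
#' pixel-adjacency graph (igraph) and assigns dense labels \code{1..K} in
#' raster-scan (row-major) order of each object's first pixel, so labeling
#' is order-stable and independent of discovery order.
#'
#' @param mask logical or 0/1 matrix; TRUE/non-zero = foreground.
#' @param connectivity 4 or 8.
#' @return a [LabelImage-class].
#' @export
labelComponents <- function(mask, connectivity = 8L) {
  connectivity <- as.integer(connectivity)
  if (!(connectivity %in% c(4L, 8L))) stop("connectivity must be 4 or 8")
  fg <- mask > 0
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  fgIdx <- which(fg)
  if (!length(fgIdx)) return(LabelImage(lab, connectivity))
  rank <- integer(nr * nc)
  rank[fgIdx] <- seq_along(fgIdx)
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  r0 <- (fgIdx - 1L) %% nr + 1L
  c0 <- (fgIdx - 1L) %/% nr + 1L
  edges <- integer()
  for (o in offs) {
    ok <- r0 + o[1] >= 1L & r0 + o[1] <= nr & c0 + o[2] <= nc
    j <- fgIdx[ok] + o[1] + o[2] * nr
    keep <- fg[j]
    a <- rank[fgIdx[ok][keep]]; b <- rank[j[keep]]
    if (length(a)) edges <- c(edges, rbind(a, b))
  }
  g <- igraph::make_empty_graph(n = length(fgIdx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  memb <- igraph::components(g)$membership
  ## order-stable relabel: component rank of its minimum raster key
  firstKey <- tapply(.rasterKey(fgIdx, nr, nc), memb, min)
  newLab <- integer(length(firstKey))
  newLab[order(firstKey)] <- seq_along(firstKey)
  lab[fgIdx] <- newLab[memb]
  LabelImage(lab, connectivity)
}

## dense raster-stable relabeling of an arbitrary label matrix
.relabelRaster <- function(lab) {
  idx <- which(lab > 0)
  if (!length(idx)) return(lab * 0L)
  nr <- nrow(lab); nc <- ncol(lab)
  key <- tapply(.rasterKey(idx, nr, nc), lab[idx], min)
  oldIds <- as.integer(names(key))
  newIds <- integer(max(oldIds))
  newIds[oldIds[order(key)]] <- seq_along(oldIds)
  out <- lab
  out[idx] <- newIds[lab[idx]]
  out
}

#' Filter labeled objects by area
#'
#' Removes objects whose pixel area lies outside the inclusive interval
#' \code{[minAreaPx, maxAreaPx]} ("between 20 and 150 px" is read as a
#' closed interval) and relabels survivors densely in raster order.
#'
#' @param labels a [LabelImage-class].
#' @param minAreaPx,maxAreaPx inclusive bounds in px.
#' @return a [LabelImage-class].
#' @export
sizeFilter <- function(labels, minAreaPx = 20L, maxAreaPx = 150L) {
  if (minAreaPx > maxAreaPx)
    stop("parameter error: minAreaPx must be <= maxAreaPx")
  lab <- labelMatrix(labels)
  k <- max(lab)
  if (k == 0L) return(labels)
  areas <- tabulate(lab[lab > 0L], nbins = k)
  drop <- which(areas < minAreaPx | areas > maxAreaPx)
  if (length(drop)) lab[lab %in% drop] <- 0L
  LabelImage(.relabelRaster(lab), connectivity(labels))
}

## drop objects touching the image border, relabel densely
.dropBorderObjects <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  touching <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
  touching <- touching[touching > 0L]
  if (length(touching)) lab[lab %in% touching] <- 0L
  .relabelRaster(lab)
}

#' Segment cells/nuclei from one channel
#'
#' The full mask chain: maximum z-projection of the named channel, optional
#' grayscale despeckle, global threshold (Li by default), binarization with
#' strict \code{> t}, optional mask despeckle, connected components under
#' the declared connectivity, inclusive size filter and dense raster-stable
#' relabeling. Deterministic for fixed input and parameters.
#'
#' @param stack a [ChannelStack-class].
#' @param role channel to segment on (\code{"nuclear"} for stain-based
#'   identification, \code{"expression"} for mCherry-based identification).
#' @param params a [SegmentationParams-class].
#' @return a [LabelImage-class].
#' @examples
#' f <- generateWellField(synthParams(nCells = 40, seed = 5))
#' seg <- segmentCells(f$stack, "nuclear", segmentationParams())
#' nObjects(seg)
#' @export
segmentCells <- function(stack, role = "nuclear",
                         params = segmentationParams()) {
  validObject(params)
  img <- projectMax(stack, role)
  if (min(img) == max(img))
    stop("degenerate-input error: constant channel cannot be segmented")
  if (params@despeckleStage == "pre" && params@despeckleRounds > 0)
    img <- despeckle(img, params@despeckleRounds)
  thr <- switch(params@thresholdMethod,
                li = liThreshold(img),
                otsu = otsuThreshold(img),
                fixed = params@fixedThreshold)
  mask <- (img > thr) * 1L
  if (params@despeckleStage == "post" && params@despeckleRounds > 0)
    mask <- despeckle(mask, params@despeckleRounds)
  li <- labelComponents(mask > 0, params@connectivity)
  lab <- labelMatrix(li)
  if (params@borderPolicy == "drop") lab <- .dropBorderObjects(lab)
  sizeFilter(LabelImage(lab, params@connectivity),
             params@minAreaPx, params@maxAreaPx)
}
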