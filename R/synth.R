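#' SynthParams: parameters of the synthetic microscopy generator
#'
#' Describes one synthetic field of view emulating a nuclear
#' fluorescent-reporter assay: disk-shaped nuclei in a nuclear-stain channel,
#' per-cell lognormal expression-reporter (mCherry) intensity, and a bimodal
#' sensor (EGFP) channel in which negative cells sit at a low baseline and
#' positive cells accumulate signal proportional to their expression level.
#' A uniform additive background, optional Poisson shot noise and Gaussian
#' read noise complete the image model. In the in vivo mode the generator
#' instead emits a two-channel z-stack in which bright autofluorescent blobs
#' are present, co-localized and intensity-matched, in both channels, while
#' nuclei appear only in the sensor (green) channel.
#'
#' All intensities are in AU on the raw camera-count scale; the rendered
#' image is clipped to \code{[0, 2^bitDepth - 1]} after noise.
#'
#' @slot imageHeightPx,imageWidthPx field size in pixels.
#' @slot nCells number of nuclei to place.
#' @slot nucleusRadiusPx length-2 numeric, min and max nucleus radius (px).
#' @slot pPositive fraction of reporter-positive cells in [0, 1].
#' @slot nuclearMeanIntensity peak nuclear-stain intensity (AU).
#' @slot mcherryLogMean,mcherryLogSd lognormal parameters of per-cell
#'   expression intensity (AU).
#' @slot sensorBaselineMean sensor intensity of negative cells (AU).
#' @slot sensorPositiveGain dimensionless gain: a positive cell's sensor
#'   intensity is \code{baseline + gain * mCherry}.
#' @slot backgroundLevel uniform additive background (AU).
#' @slot readNoiseSd Gaussian read-noise SD (AU); 0 disables.
#' @slot shotNoise logical; apply Poisson shot noise to the noise-free
#'   signal before read noise.
#' @slot speckleDensity number of autofluorescent blobs per field (in vivo
#'   mode); exact count, not a rate.
#' @slot blobRadiusPx length-2 numeric, blob radius range (px).
#' @slot blobMeanIntensity blob intensity (AU), identical in both channels.
#' @slot zPlanesN number of z-planes (in vivo mode).
#' @slot bitDepth 8 or 16.
#' @slot seed master seed; four documented sub-streams (placement,
#'   expression, positivity, noise) are derived from it, see
#'   [synthStreamSeeds()].
#' @export
setClass("SynthParams",
  representation(
    imageHeightPx = "integer", imageWidthPx = "integer", nCells = "integer",
    nucleusRadiusPx = "numeric", pPositive = "numeric",
    nuclearMeanIntensity = "numeric",
    mcherryLogMean = "numeric", mcherryLogSd = "numeric",
    sensorBaselineMean = "numeric", sensorPositiveGain = "numeric",
    backgroundLevel = "numeric", readNoiseSd = "numeric",
    shotNoise = "logical", speckleDensity = "integer",
    blobRadiusPx = "numeric", blobMeanIntensity = "numeric",
    zPlanesN = "integer", bitDepth = "integer", seed = "integer"
  )
)

setValidity("SynthParams", function(object) {
  msg <- character()
  if (object@pPositive < 0 || object@pPositive > 1)
    msg <- c(msg, "parameter error: pPositive must lie in [0, 1]")
  if (any(object@nucleusRadiusPx <= 0) ||
      length(object@nucleusRadiusPx) != 2L ||
      diff(object@nucleusRadiusPx) < 0)
    msg <- c(msg, "nucleusRadiusPx must be positive (min, max)")
  ints <- c(object@nuclearMeanIntensity, object@mcherryLogSd,
            object@sensorBaselineMean, object@sensorPositiveGain,
            object@backgroundLevel, object@readNoiseSd,
            object@blobMeanIntensity)
  if (any(ints < 0))
    msg <- c(msg, "intensity and noise parameters must be >= 0")
  if (object@nCells < 0) msg <- c(msg, "nCells must be >= 0")
  if (object@speckleDensity < 0) msg <- c(msg, "speckleDensity must be >= 0")
  if (object@zPlanesN < 1) msg <- c(msg, "zPlanesN must be >= 1")
  if (!(object@bitDepth %in% c(8L, 16L)))
    msg <- c(msg, "bitDepth must be 8 or 16")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SynthParams", function(object) {
  cat(sprintf(
    "SynthParams: %dx%d px, %d cells, p_positive = %g, seed = %d\n",
    object@imageHeightPx, object@imageWidthPx, object@nCells,
    object@pPositive, object@seed))
})

#' Construct generator parameters
#'
#' Defaults emulate a 16-bit wide-field acquisition of reporter cells:
#' nuclei of radius 3-5 px (areas of roughly 28-78 px, inside the 20-150 px
#' nucleus-size band used by the size filter), lognormal mCherry expression
#' around 2000 AU, sensor baseline 100 AU with unit gain for positives,
#' 100 AU background and 20 AU read noise. These values are synthetic
#' choices for comfortable class separability, not measurements.
#'
#' @param imageHeightPx,imageWidthPx field size (px).
#' @param nCells nuclei per field.
#' @param nucleusRadiusPx length-2 numeric (min, max) radius in px.
#' @param pPositive fraction of positive cells in [0, 1].
#' @param nuclearMeanIntensity nuclear-stain intensity (AU).
#' @param mcherryLogMean,mcherryLogSd lognormal expression parameters.
#' @param sensorBaselineMean negative-cell sensor intensity (AU).
#' @param sensorPositiveGain sensor gain on mCherry for positive cells.
#' @param backgroundLevel additive background (AU).
#' @param readNoiseSd Gaussian read noise SD (AU).
#' @param shotNoise logical, Poisson shot noise.
#' @param speckleDensity autofluorescent blobs per in vivo field.
#' @param blobRadiusPx length-2 blob radius range (px).
#' @param blobMeanIntensity blob intensity (AU).
#' @param zPlanesN z-planes for the in vivo stack.
#' @param bitDepth 8 or 16.
#' @param seed integer master seed.
#' @return a validated [SynthParams-class].
#' @examples
#' p <- synthParams(nCells = 50, pPositive = 0.5, seed = 1)
#' field <- generateWellField(p)
#' nObjects(field$labels)
#' @export
synthParams <- function(imageHeightPx = 512L, imageWidthPx = 512L,
                        nCells = 200L, nucleusRadiusPx = c(3, 5),
                        pPositive = 0.3, nuclearMeanIntensity = 3000,
                        mcherryLogMean = log(2000), mcherryLogSd = 0.4,
                        sensorBaselineMean = 100, sensorPositiveGain = 1,
                        backgroundLevel = 100, readNoiseSd = 20,
                        shotNoise = FALSE, speckleDensity = 30L,
                        blobRadiusPx = c(2, 5), blobMeanIntensity = 6000,
                        zPlanesN = 5L, bitDepth = 16L, seed = 1L) {
  new("SynthParams",
      imageHeightPx = as.integer(imageHeightPx),
      imageWidthPx = as.integer(imageWidthPx),
      nCells = as.integer(nCells),
      nucleusRadiusPx = as.numeric(nucleusRadiusPx),
      pPositive = as.numeric(pPositive),
      nuclearMeanIntensity = as.numeric(nuclearMeanIntensity),
      mcherryLogMean = as.numeric(mcherryLogMean),
      mcherryLogSd = as.numeric(mcherryLogSd),
      sensorBaselineMean = as.numeric(sensorBaselineMean),
      sensorPositiveGain = as.numeric(sensorPositiveGain),
      backgroundLevel = as.numeric(backgroundLevel),
      readNoiseSd = as.numeric(readNoiseSd),
      shotNoise = isTRUE(shotNoise),
      speckleDensity = as.integer(speckleDensity),
      blobRadiusPx = as.numeric(blobRadiusPx),
      blobMeanIntensity = as.numeric(blobMeanIntensity),
      zPlanesN = as.integer(zPlanesN),
      bitDepth = as.integer(bitDepth),
      seed = as.integer(seed))
}

#' Derive the generator's RNG sub-stream seeds
#'
#' The generator draws from four independent, documented sub-streams so that
#' any one stream can be replayed in isolation (e.g. to verify the positivity
#' draws without re-rendering pixels). Sub-seeds are obtained by seeding R's
#' default RNG with the master seed and drawing four integers.
#'
#' Stream contracts (given \code{s <- synthStreamSeeds(seed)}):
#' \describe{
#'   \item{placement}{nucleus radii, positions (rejection sampling) and, in
#'     vivo, z-plane assignments and blob geometry.}
#'   \item{expression}{\code{rlnorm(nCells, mcherryLogMean, mcherryLogSd)}.}
#'   \item{positivity}{\code{rbinom(nCells, 1, pPositive)}, in cell-id
#'     order.}
#'   \item{noise}{per-channel noise in fixed channel order (nuclear,
#'     expression, sensor; or green, blue): Poisson shot noise first if
#'     enabled, then Gaussian read noise.}
#' }
#'
#' @param seed integer master seed.
#' @return named integer vector with elements \code{placement},
#'   \code{expression}, \code{positivity}, \code{noise}.
#' @examples
#' s <- synthStreamSeeds(7)
#' set.seed(s[["positivity"]])
#' rbinom(5, 1, 0.5)  # replays the generator's positivity draws
#' @export
synthStreamSeeds <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  s <- sample.int(2147483646L, 4L)
  names(s) <- c("placement", "expression", "positivity", "noise")
  s
}

## Anti-aliased disk rendering: per-pixel coverage approximated as
## clamp(radius + 0.5 - distance_to_center, 0, 1). The mask counts pixels
## with coverage >= 0.5, i.e. pixels whose center lies within the radius.
.renderDisk <- function(h, w, row0, col0, radius) {
  r1 <- max(1L, floor(row0 - radius - 1)); r2 <- min(h, ceiling(row0 + radius + 1))
  c1 <- max(1L, floor(col0 - radius - 1)); c2 <- min(w, ceiling(col0 + radius + 1))
  rr <- r1:r2; cc <- c1:c2
  d <- sqrt(outer((rr - row0)^2, (cc - col0)^2, "+"))
  cov <- pmin(pmax(radius + 0.5 - d, 0), 1)
  dim(cov) <- dim(d)
  list(rows = rr, cols = cc, cov = cov)
}

## Sequential non-overlap placement: centers at least (r_i + r_j + 2) px
## apart (cells stay resolvable: anti-aliased rims never touch), and at
## least (radius + 1) px from every border. Errors after maxAttempts
## rejections (density error).
.placeDisks <- function(h, w, radii, existing = NULL,
                        maxAttemptsPerDisk = 500L) {
  n <- length(radii)
  rows <- numeric(n); cols <- numeric(n)
  exR <- if (is.null(existing)) numeric() else existing$row
  exC <- if (is.null(existing)) numeric() else existing$col
  exRad <- if (is.null(existing)) numeric() else existing$radius
  attempts <- 0L
  maxAttempts <- maxAttemptsPerDisk * max(1L, n)
  i <- 1L
  while (i <= n) {
    attempts <- attempts + 1L
    if (attempts > maxAttempts)
      stop("density error: could not place ", n,
           " non-overlapping nuclei in ", h, "x", w,
           " px after ", maxAttempts, " attempts")
    m <- radii[i] + 1
    row0 <- stats::runif(1, 1 + m, h - m)
    col0 <- stats::runif(1, 1 + m, w - m)
    allR <- c(exR, rows[seq_len(i - 1L)])
    allC <- c(exC, cols[seq_len(i - 1L)])
    allRad <- c(exRad, radii[seq_len(i - 1L)])
    if (length(allR)) {
      d2 <- (allR - row0)^2 + (allC - col0)^2
      if (any(d2 < (allRad + radii[i] + 2)^2)) next
    }
    rows[i] <- row0; cols[i] <- col0
    i <- i + 1L
  }
  data.frame(row = rows, col = cols, radius = radii)
}

## Shot noise (Poisson on the noise-free signal) then Gaussian read noise;
## fixed channel order is the caller's responsibility (stream discipline).
.addNoise <- function(img, shotNoise, readNoiseSd) {
  if (shotNoise) {
    v <- stats::rpois(length(img), lambda = as.vector(img))
    img <- array(v, dim = dim(img))
  }
  if (readNoiseSd > 0)
    img <- img + stats::rnorm(length(img), 0, readNoiseSd)
  img
}

.quantize <- function(img, bitDepth) {
  pmin(pmax(round(img), 0), 2^bitDepth - 1)
}

#' Generate a synthetic well-plate field of view with ground truth
#'
#' Renders one 3-channel field (nuclear stain, mCherry expression reporter,
#' EGFP sensor). Nuclei are anti-aliased disks placed without overlap
#' (center distance at least the sum of radii plus 1 px). Each cell draws a
#' lognormal mCherry intensity; cells drawn positive (Bernoulli with
#' \code{pPositive}) carry sensor intensity
#' \code{sensorBaselineMean + sensorPositiveGain * mCherry}, negatives only
#' the baseline. A uniform background, optional Poisson shot noise and
#' Gaussian read noise are added, then values are rounded and clipped to the
#' bit depth. The returned label image is the exact ground-truth mask
#' (pixels whose center falls inside a nucleus).
#'
#' The ground-truth intensities \code{true_mcherry} and \code{true_sensor}
#' are the mean noise-free rendered values (background included) over each
#' cell's mask pixels, so partially covered rim pixels are accounted for
#' exactly.
#'
#' @param params a [SynthParams-class].
#' @return list with elements \code{stack} ([ChannelStack-class], roles
#'   nuclear/expression/sensor), \code{labels} ([LabelImage-class]) and
#'   \code{truth} (data.frame: \code{cell_id, row, col, area_px,
#'   is_positive, true_mcherry, true_sensor}).
#' @examples
#' f <- generateWellField(synthParams(nCells = 30, seed = 42))
#' head(f$truth)
#' @export
generateWellField <- function(params) {
  validObject(params)
  h <- params@imageHeightPx; w <- params@imageWidthPx
  n <- params@nCells
  seeds <- synthStreamSeeds(params@seed)

  set.seed(seeds[["placement"]])
  radii <- stats::runif(n, params@nucleusRadiusPx[1], params@nucleusRadiusPx[2])
  pos <- .placeDisks(h, w, radii)

  set.seed(seeds[["expression"]])
  mch <- stats::rlnorm(n, params@mcherryLogMean, params@mcherryLogSd)

  set.seed(seeds[["positivity"]])
  isPos <- stats::rbinom(n, 1L, params@pPositive) == 1L

  sens <- ifelse(isPos,
                 params@sensorBaselineMean + params@sensorPositiveGain * mch,
                 params@sensorBaselineMean)

  bg <- params@backgroundLevel
  nuc <- matrix(bg, h, w); mchImg <- matrix(bg, h, w)
  senImg <- matrix(bg, h, w)
  lab <- matrix(0L, h, w)
  truth <- data.frame(cell_id = integer(n), row = numeric(n),
                      col = numeric(n), area_px = integer(n),
                      is_positive = logical(n), true_mcherry = numeric(n),
                      true_sensor = numeric(n))
  for (i in seq_len(n)) {
    dk <- .renderDisk(h, w, pos$row[i], pos$col[i], pos$radius[i])
    nuc[dk$rows, dk$cols] <- nuc[dk$rows, dk$cols] +
      params@nuclearMeanIntensity * dk$cov
    mchImg[dk$rows, dk$cols] <- mchImg[dk$rows, dk$cols] + mch[i] * dk$cov
    senImg[dk$rows, dk$cols] <- senImg[dk$rows, dk$cols] + sens[i] * dk$cov
    m <- dk$cov >= 0.5
    sub <- lab[dk$rows, dk$cols]; sub[m] <- i
    lab[dk$rows, dk$cols] <- sub
    ij <- which(m, arr.ind = TRUE)
    truth$cell_id[i] <- i
    truth$row[i] <- mean(dk$rows[ij[, 1]])
    truth$col[i] <- mean(dk$cols[ij[, 2]])
    truth$area_px[i] <- sum(m)
    truth$is_positive[i] <- isPos[i]
    truth$true_mcherry[i] <- mean(mchImg[dk$rows, dk$cols][m])
    truth$true_sensor[i] <- mean(senImg[dk$rows, dk$cols][m])
  }

  set.seed(seeds[["noise"]])
  nuc <- .addNoise(nuc, params@shotNoise, params@readNoiseSd)
  mchImg <- .addNoise(mchImg, params@shotNoise, params@readNoiseSd)
  senImg <- .addNoise(senImg, params@shotNoise, params@readNoiseSd)

  px <- array(0, c(h, w, 3L, 1L))
  px[, , 1L, 1L] <- .quantize(nuc, params@bitDepth)
  px[, , 2L, 1L] <- .quantize(mchImg, params@bitDepth)
  px[, , 3L, 1L] <- .quantize(senImg, params@bitDepth)
  stack <- ChannelStack(px, c(nuclear = 1L, expression = 2L, sensor = 3L),
                        bitDepth = params@bitDepth)
  list(stack = stack, labels = LabelImage(lab, 8L), truth = truth)
}

#' Generate a synthetic two-channel in vivo z-stack with ground truth
#'
#' Emulates a two-photon acquisition in which reporter-positive nuclei are
#' visible in the green (sensor) channel while bright autofluorescent blobs
#' appear, co-localized and intensity-matched, in both the green and the
#' blue (auxiliary) channel. Subtracting the blue maximum-intensity
#' projection from the green one therefore cancels the blobs and retains the
#' nuclei. Each nucleus and blob occupies one z-plane; planes are otherwise
#' independent. Nucleus radii are constrained so the rendered mask area lies
#' in 20-150 px (the nucleus-size band the downstream size filter uses);
#' out-of-band renders are redrawn.
#'
#' @param params a [SynthParams-class]; \code{speckleDensity} blobs and
#'   \code{zPlanesN} planes are used.
#' @return list with \code{stack} ([ChannelStack-class], roles sensor =
#'   green channel 1, auxiliary = blue channel 2), \code{truth} (nuclei
#'   only: \code{cell_id, row, col, area_px, z, true_sensor}),
#'   \code{labels} (projected 2-d ground-truth nucleus mask,
#'   [LabelImage-class]) and \code{blobMask} (integer matrix of projected
#'   blob footprints).
#' @examples
#' iv <- generateInvivoStack(synthParams(nCells = 20, speckleDensity = 10,
#'                                       seed = 3))
#' zPlanes(iv$stack)
#' @export
generateInvivoStack <- function(params) {
  validObject(params)
  h <- params@imageHeightPx; w <- params@imageWidthPx
  n <- params@nCells; nb <- params@speckleDensity
  nz <- params@zPlanesN
  seeds <- synthStreamSeeds(params@seed)

  set.seed(seeds[["placement"]])
  ## radius range intersected with what can render a 20-150 px mask
  rmin <- max(params@nucleusRadiusPx[1], 2.8)
  rmax <- min(max(params@nucleusRadiusPx[2], rmin), 6.4)
  radii <- stats::runif(n, rmin, rmax)
  blobRadii <- if (nb > 0)
    stats::runif(nb, params@blobRadiusPx[1], params@blobRadiusPx[2])
  else numeric()
  pos <- .placeDisks(h, w, c(radii, blobRadii))
  nucPos <- pos[seq_len(n), , drop = FALSE]
  blobPos <- pos[n + seq_len(nb), , drop = FALSE]
  zNuc <- sample.int(nz, n, replace = TRUE)
  zBlob <- if (nb > 0) sample.int(nz, nb, replace = TRUE) else integer()

  bg <- params@backgroundLevel
  green <- array(bg, c(h, w, nz)); blue <- array(bg, c(h, w, nz))
  lab <- matrix(0L, h, w); blobMask <- matrix(0L, h, w)
  truth <- data.frame(cell_id = integer(n), row = numeric(n),
                      col = numeric(n), area_px = integer(n),
                      z = integer(n), true_sensor = numeric(n))
  for (i in seq_len(n)) {
    repeat {
      dk <- .renderDisk(h, w, nucPos$row[i], nucPos$col[i], nucPos$radius[i])
      m <- dk$cov >= 0.5
      if (sum(m) >= 20L && sum(m) <= 150L) break
      nucPos$radius[i] <- stats::runif(1, rmin, rmax)
    }
    pl <- green[, , zNuc[i]]
    pl[dk$rows, dk$cols] <- pl[dk$rows, dk$cols] +
      params@nuclearMeanIntensity * dk$cov
    green[, , zNuc[i]] <- pl
    sub <- lab[dk$rows, dk$cols]; sub[m] <- i
    lab[dk$rows, dk$cols] <- sub
    ij <- which(m, arr.ind = TRUE)
    truth$cell_id[i] <- i
    truth$row[i] <- mean(dk$rows[ij[, 1]])
    truth$col[i] <- mean(dk$cols[ij[, 2]])
    truth$area_px[i] <- sum(m)
    truth$z[i] <- zNuc[i]
    truth$true_sensor[i] <- mean(pl[dk$rows, dk$cols][m])
  }
  for (j in seq_len(nb)) {
    dk <- .renderDisk(h, w, blobPos$row[j], blobPos$col[j], blobPos$radius[j])
    add <- params@blobMeanIntensity * dk$cov
    green[dk$rows, dk$cols, zBlob[j]] <-
      green[dk$rows, dk$cols, zBlob[j]] + add
    blue[dk$rows, dk$cols, zBlob[j]] <-
      blue[dk$rows, dk$cols, zBlob[j]] + add
    m <- dk$cov >= 0.5
    sub <- blobMask[dk$rows, dk$cols]; sub[m] <- j
    blobMask[dk$rows, dk$cols] <- sub
  }

  set.seed(seeds[["noise"]])
  green <- .addNoise(green, params@shotNoise, params@readNoiseSd)
  blue <- .addNoise(blue, params@shotNoise, params@readNoiseSd)

  px <- array(0, c(h, w, 2L, nz))
  px[, , 1L, ] <- .quantize(green, params@bitDepth)
  px[, , 2L, ] <- .quantize(blue, params@bitDepth)
  stack <- ChannelStack(px, c(sensor = 1L, auxiliary = 2L),
                        bitDepth = params@bitDepth)
  list(stack = stack, truth = truth, labels = LabelImage(lab, 8L),
       blobMask = blobMask)
}

#' Simulate a multi-condition well plate to disk
#'
#' Writes, for each condition and well, \code{fieldsPerWell} synthetic
#' 3-channel fields as multi-page TIFFs plus a plate-map CSV and per-field
#' ground-truth CSVs. Wells of the same condition are technical replicates;
#' consecutive triplets of wells share a sample id, mirroring a
#' patient-in-triplicate plate layout. Per-field seeds are derived from the
#' master seed, so the plate is fully reproducible.
#'
#' @param outDir output directory (created if needed).
#' @param conditions data.frame with columns \code{condition} (label),
#'   \code{p_positive} and \code{n_wells}.
#' @param fieldsPerWell fields imaged per well.
#' @param params template [SynthParams-class]; \code{pPositive} and
#'   \code{seed} are overridden per condition/field.
#' @param seed master seed for the plate.
#' @param wellsPerSample wells pooled into one sample id (default 3,
#'   technical triplicates).
#' @return invisibly, the plate map data.frame (columns \code{well_id,
#'   condition, replicate_index, sample_id}).
#' @export
simulatePlate <- function(outDir, conditions, fieldsPerWell = 3L,
                          params = synthParams(), seed = 1L,
                          wellsPerSample = 3L) {
  stopifnot(all(c("condition", "p_positive", "n_wells") %in%
                names(conditions)))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outDir, "truth"), showWarnings = FALSE)
  nWellsTotal <- sum(conditions$n_wells)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  fieldSeeds <- matrix(sample.int(2147483646L, nWellsTotal * fieldsPerWell),
                       nrow = nWellsTotal)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())

  rows <- list(); wellIdx <- 0L
  for (ci in seq_len(nrow(conditions))) {
    cond <- conditions$condition[ci]
    for (wi in seq_len(conditions$n_wells[ci])) {
      wellIdx <- wellIdx + 1L
      wellId <- sprintf("W%03d", wellIdx)
      sampleId <- sprintf("%s_S%02d", cond, (wi - 1L) %/% wellsPerSample + 1L)
      rows[[wellIdx]] <- data.frame(
        well_id = wellId, condition = cond,
        replicate_index = (wi - 1L) %% wellsPerSample + 1L,
        sample_id = sampleId)
      for (fi in seq_len(fieldsPerWell)) {
        p <- params
        p@pPositive <- as.numeric(conditions$p_positive[ci])
        p@seed <- fieldSeeds[wellIdx, fi]
        fld <- generateWellField(p)
        base <- sprintf("%s_f%02d", wellId, fi)
        writeStack(fld$stack, file.path(outDir, paste0(base, ".tif")))
        utils::write.csv(fld$truth,
                         file.path(outDir, "truth", paste0(base, ".csv")),
                         row.names = FALSE)
      }
    }
  }
  plateMap <- do.call(rbind, rows)
  utils::write.csv(plateMap, file.path(outDir, "plate_map.csv"),
                   row.names = FALSE)
  invisible(plateMap)
}

#' Simulate an in vivo imaging cohort to disk
#'
#' Writes paired two-channel z-stacks for \code{nAnimals} animals: one
#' "treated" stack per animal in which nuclei are bright (sensor stabilized)
#' and one "control" stack in which nuclei sit near the baseline, both with
#' autofluorescent blobs in the two channels. Emits a cohort CSV
#' (\code{animal, condition, path}).
#'
#' @param outDir output directory.
#' @param nAnimals animals (stack pairs).
#' @param params template [SynthParams-class].
#' @param controlIntensity nuclear sensor intensity for the control side
#'   (AU); default 800: dim but resolvable above the noise floor, far below
#'   the treated side, so both masks capture real nuclei.
#' @param seed master seed.
#' @return invisibly, the cohort data.frame.
#' @export
simulateInvivoCohort <- function(outDir, nAnimals = 9L,
                                 params = synthParams(nCells = 40L),
                                 controlIntensity = 800, seed = 1L) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  seeds <- matrix(sample.int(2147483646L, nAnimals * 2L), ncol = 2L)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  rows <- list()
  for (a in seq_len(nAnimals)) {
    for (side in 1:2) {
      p <- params
      p@seed <- seeds[a, side]
      if (side == 2L) p@nuclearMeanIntensity <- as.numeric(controlIntensity)
      iv <- generateInvivoStack(p)
      fn <- sprintf("animal%02d_%s.tif", a,
                    if (side == 1L) "treated" else "control")
      writeStack(iv$stack, file.path(outDir, fn))
      rows[[length(rows) + 1L]] <- data.frame(
        animal = sprintf("A%02d", a),
        condition = if (side == 1L) "treated" else "control",
        path = fn)
    }
  }
  cohort <- do.call(rbind, rows)
  utils::write.csv(cohort, file.path(outDir, "cohort.csv"),
                   row.names = FALSE)
  invisible(cohort)
}
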