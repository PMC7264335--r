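## iterated 3x3 box max filter = binary dilation with Chebyshev radius
## `rounds`; used to grow the cell footprint before background estimation
.dilateMask <- function(mask, rounds) {
  m <- mask > 0
  nr <- nrow(m); nc <- ncol(m)
  for (i in seq_len(rounds)) {
    pad <- m[c(1L, seq_len(nr), nr), c(1L, seq_len(nc), nc)]
    out <- m
    for (dc in 0:2) for (dr in 0:2)
      out <- out | pad[dr + seq_len(nr), dc + seq_len(nc)]
    m <- out
  }
  m
}

#' Estimate the per-image background intensity
#'
#' The background region of interest is the complement of the union of all
#' segmented objects dilated by \code{marginPx} (Chebyshev radius), i.e. all
#' non-cell pixels at least \code{marginPx} away from any object. Returns
#' the mean intensity over that region.
#'
#' @param image numeric matrix, one channel.
#' @param labels a [LabelImage-class] aligned to \code{image}.
#' @param marginPx dilation margin in px (default 3).
#' @return background estimate in AU (scalar).
#' @export
estimateBackground <- function(image, labels, marginPx = 3L) {
  lab <- labelMatrix(labels)
  if (!identical(dim(image), dim(lab)))
    stop("labels are not aligned to the image")
  bgMask <- !.dilateMask(lab > 0L, as.integer(marginPx))
  if (!any(bgMask))
    stop("degenerate-field error: no background pixels outside dilated objects")
  mean(image[bgMask])
}

#' Measure per-cell intensities in every channel
#'
#' For each labeled object and each channel role: the raw mean is the
#' arithmetic mean of in-mask pixel values (of the maximum z-projection for
#' stacks), and the background-corrected mean is the raw mean minus that
#' channel's per-image background estimate ([estimateBackground()]), floored
#' at 0. Centroids are 1-based (row, col) pixel-coordinate means.
#'
#' @param stack a [ChannelStack-class].
#' @param labels a [LabelImage-class] aligned to the stack.
#' @param marginPx background-ROI dilation margin (px).
#' @return data.frame with one row per cell: \code{cell_id, area_px,
#'   centroid_row, centroid_col}, then \code{raw_mean_<role>} and
#'   \code{bg_mean_<role>} per declared role. The per-channel background
#'   estimates are attached as attribute \code{"background"}. An empty label
#'   set yields an empty data.frame (not an error).
#' @export
measureCells <- function(stack, labels, marginPx = 3L) {
  lab <- labelMatrix(labels)
  roles <- names(channelRoles(stack))
  k <- max(lab)
  fg <- lab > 0L
  ids <- seq_len(k)
  if (k == 0L) {
    out <- data.frame(cell_id = integer(), area_px = integer(),
                      centroid_row = numeric(), centroid_col = numeric())
    for (role in roles) {
      out[[paste0("raw_mean_", role)]] <- numeric()
      out[[paste0("bg_mean_", role)]] <- numeric()
    }
    attr(out, "background") <- stats::setNames(rep(NA_real_, length(roles)),
                                               roles)
    return(out)
  }
  areas <- tabulate(lab[fg], nbins = k)
  idx <- which(fg)
  nr <- nrow(lab)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  labv <- lab[fg]
  out <- data.frame(
    cell_id = ids,
    area_px = areas,
    centroid_row = as.vector(rowsum(as.numeric(rows), labv)) / areas,
    centroid_col = as.vector(rowsum(as.numeric(cols), labv)) / areas)
  bgs <- numeric(length(roles)); names(bgs) <- roles
  for (role in roles) {
    img <- projectMax(stack, role)
    bgs[role] <- estimateBackground(img, labels, marginPx)
    rawMean <- as.vector(rowsum(img[fg], labv)) / areas
    out[[paste0("raw_mean_", role)]] <- rawMean
    out[[paste0("bg_mean_", role)]] <- pmax(rawMean - bgs[role], 0)
  }
  attr(out, "background") <- bgs
  out
}

#' Sensor-to-expression ratio per cell
#'
#' Adds a \code{ratio} column: background-corrected sensor mean divided by
#' background-corrected expression mean, normalizing the sensor signal to
#' the induction level. The ratio is undefined (NA) when the expression mean
#' does not exceed \code{epsilon}; such cells are excluded from ratio
#' summaries but keep their positivity call.
#'
#' @param records data.frame from [measureCells()] with
#'   \code{bg_mean_sensor} and \code{bg_mean_expression}.
#' @param epsilon positivity floor for the denominator (AU).
#' @return \code{records} with a \code{ratio} column.
#' @export
computeRatio <- function(records, epsilon = 1e-6) {
  need <- c("bg_mean_sensor", "bg_mean_expression")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records lack background-corrected means: ",
         paste(miss, collapse = ", "))
  records$ratio <- ifelse(records$bg_mean_expression > epsilon,
                          records$bg_mean_sensor /
                            records$bg_mean_expression,
                          NA_real_)
  records
}

#' Positivity threshold from a negative-control population
#'
#' \code{mean(control) + kSd * SD(control)} with the sample SD (n - 1
#' denominator). At least two control values are required.
#'
#' @param controlValues numeric vector of background-corrected control-cell
#'   intensities (AU).
#' @param kSd SD multiplier (default 2).
#' @return threshold in AU.
#' @examples
#' controlNullThreshold(c(10, 12, 14, 16, 18), kSd = 2)  # 14 + 2*sqrt(10)
#' @export
controlNullThreshold <- function(controlValues, kSd = 2) {
  if (length(controlValues) < 2L)
    stop("insufficient-control error: need >= 2 control values")
  mean(controlValues) + kSd * stats::sd(controlValues)
}

#' Classify cells as reporter-positive
#'
#' Sets \code{is_positive} by comparing the background-corrected mean of the
#' rule's channel against the rule's threshold with a strict \code{>}
#' ("above"): a value exactly at the threshold is negative. For the
#' \code{control_null} rule the threshold is
#' [controlNullThreshold()]\code{(controlValues, kSd)}; for the \code{fixed}
#' rule it is \code{fixedThreshold} (default 400 AU).
#'
#' @param records data.frame from [measureCells()].
#' @param rule a [ClassificationRule-class].
#' @param controlValues numeric vector of control-cell values (required for
#'   \code{control_null}).
#' @return \code{records} with an \code{is_positive} logical column; the
#'   threshold used is attached as attribute \code{"threshold"}.
#' @export
classifyCells <- function(records, rule = classificationRule("fixed"),
                          controlValues = NULL) {
  validObject(rule)
  col <- paste0("bg_mean_", rule@channelRole)
  if (!col %in% names(records))
    stop("records lack column ", col)
  thr <- if (rule@kind == "control_null") {
    if (is.null(controlValues))
      stop("configuration error: control_null rule requires controlValues")
    controlNullThreshold(controlValues, rule@kSd)
  } else rule@fixedThreshold
  v <- records[[col]]
  records$is_positive <- if (rule@strict) v > thr else v >= thr
  attr(records, "threshold") <- thr
  records
}

#' Aggregate cell calls to image, well and sample level
#'
#' Computes the fraction of positive cells per image, per well (cells pooled
#' across that well's images) and per sample (unweighted mean of the
#' sample's replicate-well fractions, mirroring per-patient averaging over
#' technical triplicates). Wells with zero cells are flagged and excluded
#' from the sample mean. Mean ratios are computed over cells with a defined
#' ratio.
#'
#' @param cellTable data.frame of classified cells with columns
#'   \code{well_id}, \code{image_id}, \code{is_positive} and optionally
#'   \code{ratio}.
#' @param plateMap data.frame from [readPlateMap()].
#' @return list with data.frames \code{perImage}, \code{perWell} (including
#'   a \code{flagged} column for zero-cell wells) and \code{perSample}
#'   (columns \code{sample_id, condition, n_wells, fraction_positive,
#'   mean_ratio}).
#' @export
summarizeWells <- function(cellTable, plateMap) {
  if (!nrow(plateMap)) stop("configuration error: empty plate map")
  for (col in c("well_id", "image_id", "is_positive"))
    if (!col %in% names(cellTable)) stop("cellTable lacks column ", col)
  if (!"ratio" %in% names(cellTable)) cellTable$ratio <- NA_real_

  agg <- function(df, keys) {
    sp <- split(df, df[keys], drop = FALSE, sep = "\r")
    res <- lapply(sp, function(d) {
      data.frame(n_cells = nrow(d),
                 n_positive = sum(d$is_positive),
                 fraction_positive = if (nrow(d)) mean(d$is_positive)
                                     else NA_real_,
                 mean_ratio = if (any(is.finite(d$ratio)))
                   mean(d$ratio[is.finite(d$ratio)]) else NA_real_)
    })
    keydf <- do.call(rbind, strsplit(names(sp), "\r", fixed = TRUE))
    out <- cbind(stats::setNames(as.data.frame(keydf,
                                               stringsAsFactors = FALSE),
                                 keys),
                 do.call(rbind, res))
    rownames(out) <- NULL
    out[order(out[[keys[1]]]), , drop = FALSE]
  }

  perImage <- if (nrow(cellTable))
    agg(cellTable, c("well_id", "image_id"))
  else data.frame(well_id = character(), image_id = character(),
                  n_cells = integer(), n_positive = integer(),
                  fraction_positive = numeric(), mean_ratio = numeric())

  ## per well: pool cells across the well's images; wells without cells are
  ## kept, flagged, and excluded from the sample mean
  perWell <- merge(plateMap,
                   if (nrow(cellTable)) agg(cellTable, "well_id")
                   else data.frame(well_id = character(),
                                   n_cells = integer(),
                                   n_positive = integer(),
                                   fraction_positive = numeric(),
                                   mean_ratio = numeric()),
                   by = "well_id", all.x = TRUE)
  perWell$n_cells[is.na(perWell$n_cells)] <- 0L
  perWell$n_positive[is.na(perWell$n_positive)] <- 0L
  perWell$flagged <- perWell$n_cells == 0L
  perWell <- perWell[order(perWell$well_id), , drop = FALSE]
  rownames(perWell) <- NULL

  ok <- perWell[!perWell$flagged, , drop = FALSE]
  sp <- split(ok, ok$sample_id)
  perSample <- do.call(rbind, lapply(sp, function(d) data.frame(
    sample_id = d$sample_id[1L],
    condition = d$condition[1L],
    n_wells = nrow(d),
    fraction_positive = mean(d$fraction_positive),
    mean_ratio = if (any(is.finite(d$mean_ratio)))
      mean(d$mean_ratio[is.finite(d$mean_ratio)]) else NA_real_)))
  if (is.null(perSample))
    perSample <- data.frame(sample_id = character(), condition = character(),
                            n_wells = integer(),
                            fraction_positive = numeric(),
                            mean_ratio = numeric())
  perSample <- perSample[order(perSample$sample_id), , drop = FALSE]
  rownames(perSample) <- NULL
  list(perImage = perImage, perWell = perWell, perSample = perSample)
}
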