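VALID_ROLES <- c("nuclear", "expression", "sensor", "auxiliary")

#' ChannelStack: a multi-channel (optionally z-stacked) fluorescence image
#'
#' Container for one field of view. Pixels are stored as a 4-dimensional
#' integer-valued array laid out \code{(row, col, channel, z)}; single-plane
#' images have \code{z = 1}. Each biological channel role (\code{"nuclear"},
#' \code{"expression"}, \code{"sensor"}, \code{"auxiliary"}) maps to exactly
#' one channel index. Pixel values are raw camera counts (AU) on a
#' \code{2^bitDepth - 1} scale; no rescaling is performed on construction or
#' load. Coordinates are 1-based \code{(row, col)} with the origin at the
#' top-left, matching R matrix indexing.
#'
#' @slot pixels numeric 4-d array \code{(row, col, channel, z)} of
#'   non-negative integer-valued counts.
#' @slot channelRoles named integer vector mapping role name to channel
#'   index, e.g. \code{c(nuclear = 1, expression = 2, sensor = 3)}.
#' @slot bitDepth integer, 8 or 16; pixel values must not exceed
#'   \code{2^bitDepth - 1}.
#'
#' @seealso [channelData()], [readStack()], [writeStack()]
#' @export
setClass("ChannelStack",
  representation(
    pixels = "array",
    channelRoles = "integer",
    bitDepth = "integer"
  )
)

setValidity("ChannelStack", function(object) {
  msg <- character()
  d <- dim(object@pixels)
  if (length(d) != 4L)
    msg <- c(msg, "pixels must be a 4-d array (row, col, channel, z)")
  if (!(object@bitDepth %in% c(8L, 16L)))
    msg <- c(msg, "bitDepth must be 8 or 16")
  roles <- object@channelRoles
  if (is.null(names(roles)) || any(!nzchar(names(roles))))
    msg <- c(msg, "channelRoles must be a named integer vector")
  else {
    if (!all(names(roles) %in% VALID_ROLES))
      msg <- c(msg, sprintf("channel roles must be among: %s",
                            paste(VALID_ROLES, collapse = ", ")))
    if (anyDuplicated(names(roles)))
      msg <- c(msg, "each role must map to exactly one channel")
    if (length(d) == 4L && length(roles) &&
        (any(roles < 1L) || any(roles > d[3L])))
      msg <- c(msg, "channelRoles indices out of range")
  }
  if (length(d) == 4L) {
    if (min(object@pixels) < 0)
      msg <- c(msg, "pixel values must be non-negative")
    if (max(object@pixels) > 2^object@bitDepth - 1)
      msg <- c(msg, "pixel values exceed 2^bitDepth - 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ChannelStack
#'
#' @param pixels a matrix (one channel, one plane), a 3-d array
#'   \code{(row, col, channel)} or a 4-d array \code{(row, col, channel, z)}.
#' @param channelRoles named integer vector mapping role names to channel
#'   indices (roles: \code{"nuclear"}, \code{"expression"}, \code{"sensor"},
#'   \code{"auxiliary"}).
#' @param bitDepth 8 or 16.
#' @return a validated [ChannelStack-class] object.
#' @examples
#' px <- array(0, c(16, 16, 2))
#' px[5:8, 5:8, 1] <- 900
#' cs <- ChannelStack(px, c(nuclear = 1, sensor = 2), bitDepth = 16)
#' nChannels(cs)
#' @export
ChannelStack <- function(pixels, channelRoles, bitDepth = 16L) {
  if (is.matrix(pixels)) dim(pixels) <- c(dim(pixels), 1L, 1L)
  if (length(dim(pixels)) == 3L) dim(pixels) <- c(dim(pixels), 1L)
  storage.mode(pixels) <- "double"
  roles <- channelRoles
  storage.mode(roles) <- "integer"
  new("ChannelStack", pixels = pixels, channelRoles = roles,
      bitDepth = as.integer(bitDepth))
}

#' LabelImage: an integer-labeled segmentation mask
#'
#' One field of view segmented into objects. Background pixels are 0 and
#' objects carry dense labels \code{1..K}, each a single connected component
#' under the declared connectivity (4 or 8). Labels are assigned in
#' raster-scan (row-major) order of each object's first pixel, so relabeling
#' is order-stable.
#'
#' @slot labels integer matrix \code{(row, col)}; 0 = background.
#' @slot connectivity integer, 4 or 8.
#' @seealso [labelComponents()], [sizeFilter()], [segmentCells()]
#' @export
setClass("LabelImage",
  representation(labels = "matrix", connectivity = "integer")
)

setValidity("LabelImage", function(object) {
  msg <- character()
  if (!(object@connectivity %in% c(4L, 8L)))
    msg <- c(msg, "connectivity must be 4 or 8")
  lab <- object@labels
  if (!is.numeric(lab))
    msg <- c(msg, "labels must be a numeric/integer matrix")
  else {
    u <- sort(unique(as.vector(lab)))
    u <- u[u != 0]
    if (length(u) && !identical(as.integer(u), seq_len(length(u))))
      msg <- c(msg, "object labels must be dense 1..K")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a LabelImage
#'
#' @param labels integer matrix, 0 = background, objects labeled 1..K
#'   densely.
#' @param connectivity 4 or 8 (the convention under which each object is one
#'   connected component).
#' @return a validated [LabelImage-class].
#' @export
LabelImage <- function(labels, connectivity = 8L) {
  storage.mode(labels) <- "integer"
  new("LabelImage", labels = labels, connectivity = as.integer(connectivity))
}

#' ClassificationRule: how a cell is called reporter-positive
#'
#' Two rules are supported, mirroring the two used in reporter-cell assays:
#' \describe{
#'   \item{\code{control_null}}{positive if the background-corrected mean of
#'     \code{channelRole} exceeds \code{mean + kSd * SD} of the same quantity
#'     measured in negative-control cells (sample SD, n-1 denominator).}
#'   \item{\code{fixed}}{positive if the background-corrected mean exceeds a
#'     fixed intensity threshold in AU (default 400).}
#' }
#' Both rules use a strict \code{>} comparison ("above"): a value exactly at
#' the threshold is negative.
#'
#' @slot kind \code{"control_null"} or \code{"fixed"}.
#' @slot kSd multiplier on the control SD (default 2).
#' @slot fixedThreshold fixed cutoff in AU (default 400).
#' @slot channelRole channel whose background-corrected mean is compared
#'   (\code{"sensor"} or \code{"expression"}).
#' @slot strict logical; strict inequality (always TRUE for the published
#'   rules, kept as a slot for transparency).
#' @export
setClass("ClassificationRule",
  representation(
    kind = "character",
    kSd = "numeric",
    fixedThreshold = "numeric",
    channelRole = "character",
    strict = "logical"
  )
)

setValidity("ClassificationRule", function(object) {
  msg <- character()
  if (!(object@kind %in% c("control_null", "fixed")))
    msg <- c(msg, "kind must be 'control_null' or 'fixed'")
  if (object@kind == "control_null" && object@kSd <= 0)
    msg <- c(msg, "kSd must be > 0 for the control_null rule")
  if (object@kind == "fixed" && object@fixedThreshold < 0)
    msg <- c(msg, "fixedThreshold must be >= 0")
  if (!(object@channelRole %in% c("sensor", "expression")))
    msg <- c(msg, "channelRole must be 'sensor' or 'expression'")
  if (length(msg)) msg else TRUE
})

#' Construct a ClassificationRule
#'
#' @param kind \code{"control_null"} (mean + kSd * SD of control cells) or
#'   \code{"fixed"} (fixed AU cutoff).
#' @param kSd SD multiplier for the control-null rule; default 2.
#' @param fixedThreshold AU cutoff for the fixed rule; default 400.
#' @param channelRole which background-corrected channel mean is compared;
#'   \code{"sensor"} (default) or \code{"expression"}.
#' @param strict logical; strict \code{>} comparison (default TRUE).
#' @return a validated [ClassificationRule-class].
#' @examples
#' classificationRule("fixed", fixedThreshold = 400)
#' classificationRule("control_null", kSd = 2)
#' @export
classificationRule <- function(kind = c("control_null", "fixed"), kSd = 2,
                               fixedThreshold = 400,
                               channelRole = "sensor", strict = TRUE) {
  kind <- match.arg(kind)
  new("ClassificationRule", kind = kind, kSd = as.numeric(kSd),
      fixedThreshold = as.numeric(fixedThreshold),
      channelRole = channelRole, strict = isTRUE(strict))
}

#' StatsResult: outcome of a group-comparison test
#'
#' @slot testName e.g. \code{"one_way_anova"}, \code{"tukey_hsd"},
#'   \code{"t_test_unpaired"}.
#' @slot statistic the F or t statistic.
#' @slot df numeric vector of degrees of freedom (between/within for F,
#'   pooled df for t).
#' @slot pValue the test p-value in [0, 1].
#' @slot pairwise data.frame of pairwise comparisons
#'   (\code{pair, mean_diff, adj_p}); empty for tests without a post hoc.
#' @export
setClass("StatsResult",
  representation(
    testName = "character",
    statistic = "numeric",
    df = "numeric",
    pValue = "numeric",
    pairwise = "data.frame"
  )
)

setValidity("StatsResult", function(object) {
  msg <- character()
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    msg <- c(msg, "pValue must lie in [0, 1]")
  if (nrow(object@pairwise) &&
      !all(c("pair", "mean_diff", "adj_p") %in% names(object@pairwise)))
    msg <- c(msg, "pairwise must have columns pair, mean_diff, adj_p")
  if (length(msg)) msg else TRUE
})

StatsResult <- function(testName, statistic, df, pValue,
                        pairwise = data.frame()) {
  new("StatsResult", testName = testName, statistic = as.numeric(statistic),
      df = as.numeric(df), pValue = as.numeric(pValue), pairwise = pairwise)
}
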