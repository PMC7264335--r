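#' Accessors for ChannelStack and LabelImage
#'
#' @param x a [ChannelStack-class] or [LabelImage-class].
#' @param role channel role name (\code{"nuclear"}, \code{"expression"},
#'   \code{"sensor"}, \code{"auxiliary"}).
#' @param z z-plane index, or \code{NULL} for all planes.
#' @name accessors
NULL

#' @rdname accessors
#' @return \code{channelData} returns a matrix (one z-plane) or a 3-d array
#'   \code{(row, col, z)} of the requested channel.
#' @export
setGeneric("channelData", function(x, role, z = NULL)
  standardGeneric("channelData"))

#' @rdname accessors
#' @export
setGeneric("channelRoles", function(x) standardGeneric("channelRoles"))

#' @rdname accessors
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))

#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("zPlanes", function(x) standardGeneric("zPlanes"))

#' @rdname accessors
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @rdname accessors
#' @export
setGeneric("connectivity", function(x) standardGeneric("connectivity"))

#' @rdname accessors
#' @export
setGeneric("nObjects", function(x) standardGeneric("nObjects"))

#' @rdname accessors
setMethod("channelData", "ChannelStack", function(x, role, z = NULL) {
  idx <- x@channelRoles[role]
  if (is.na(idx))
    stop("configuration error: no channel with role '", role, "'")
  if (is.null(z)) {
    out <- x@pixels[, , idx, , drop = FALSE]
    dim(out) <- dim(x@pixels)[c(1L, 2L, 4L)]
    if (dim(out)[3L] == 1L) dim(out) <- dim(out)[1:2]
    return(out)
  }
  x@pixels[, , idx, z]
})

#' @rdname accessors
setMethod("channelRoles", "ChannelStack", function(x) x@channelRoles)

#' @rdname accessors
setMethod("bitDepth", "ChannelStack", function(x) x@bitDepth)

#' @rdname accessors
setMethod("nChannels", "ChannelStack", function(x) dim(x@pixels)[3L])

#' @rdname accessors
setMethod("zPlanes", "ChannelStack", function(x) dim(x@pixels)[4L])

#' @rdname accessors
setMethod("dim", "ChannelStack", function(x) dim(x@pixels))

#' @rdname accessors
setMethod("labelMatrix", "LabelImage", function(x) x@labels)

#' @rdname accessors
setMethod("connectivity", "LabelImage", function(x) x@connectivity)

#' @rdname accessors
setMethod("nObjects", "LabelImage", function(x) max(0L, max(x@labels)))

#' @rdname accessors
setMethod("dim", "LabelImage", function(x) dim(x@labels))

setMethod("show", "ChannelStack", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ChannelStack: %d x %d px, %d channel(s), %d z-plane(s), %d-bit\n",
              d[1], d[2], d[3], d[4], object@bitDepth))
  cat("  roles:",
      paste(sprintf("%s=%d", names(object@channelRoles),
                    object@channelRoles), collapse = ", "), "\n")
})

setMethod("show", "LabelImage", function(object) {
  cat(sprintf("LabelImage: %d x %d px, %d object(s), %d-connectivity\n",
              nrow(object@labels), ncol(object@labels),
              nObjects(object), object@connectivity))
})

setMethod("show", "ClassificationRule", function(object) {
  if (object@kind == "control_null")
    cat(sprintf("ClassificationRule: control_null (mean + %g SD of control %s)\n",
                object@kSd, object@channelRole))
  else
    cat(sprintf("ClassificationRule: fixed (> %g AU on %s)\n",
                object@fixedThreshold, object@channelRole))
})

setMethod("show", "StatsResult", function(object) {
  cat(sprintf("StatsResult: %s\n", object@testName))
  cat(sprintf("  statistic = %.6g, df = (%s), p = %.4g\n",
              object@statistic, paste(object@df, collapse = ", "),
              object@pValue))
  if (nrow(object@pairwise)) {
    cat("  pairwise:\n")
    print(object@pairwise, row.names = FALSE)
  }
})
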