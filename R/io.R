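#' Read a multi-page TIFF into a ChannelStack
#'
#' Pages are interpreted channel-fastest: with \code{C} declared channels a
#' file of \code{P} pages yields \code{z = P / C} planes, pages ordered
#' \code{(c1 z1, c2 z1, ..., c1 z2, ...)}. Pixel values are read as raw
#' integer counts (no rescaling); bit depth is taken from the file.
#'
#' @param path TIFF file (8- or 16-bit, single- or multi-page).
#' @param roleMap named integer vector mapping role names to channel
#'   indices, e.g. \code{c(nuclear = 1, expression = 2, sensor = 3)}.
#' @param requiredRoles roles that must be present in \code{roleMap};
#'   default \code{"sensor"} (every workflow here measures the sensor
#'   channel). Missing roles raise a configuration error.
#' @return a [ChannelStack-class].
#' @seealso [writeStack()]
#' @export
readStack <- function(path, roleMap, requiredRoles = "sensor") {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  miss <- setdiff(requiredRoles, names(roleMap))
  if (length(miss))
    stop("configuration error: role_map is missing required role(s): ",
         paste(miss, collapse = ", "))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop("format error: not a readable TIFF: ", path,
                           " (", conditionMessage(e), ")"))
  nC <- max(as.integer(roleMap))
  nP <- length(pages)
  if (nP %% nC != 0L)
    stop("format error: ", nP, " page(s) not divisible by ", nC,
         " channel(s)")
  nZ <- nP %/% nC
  bd <- attr(tiff::readTIFF(path, info = TRUE, as.is = TRUE),
             "bits.per.sample")
  bd <- if (is.null(bd)) 16L else as.integer(bd)
  h <- nrow(pages[[1L]]); w <- ncol(pages[[1L]])
  px <- array(0, c(h, w, nC, nZ))
  k <- 0L
  for (z in seq_len(nZ)) for (ch in seq_len(nC)) {
    k <- k + 1L
    px[, , ch, z] <- pages[[k]]
  }
  ChannelStack(px, roleMap, bitDepth = bd)
}

#' Write a ChannelStack as a multi-page TIFF
#'
#' Pages are written channel-fastest (see [readStack()]); the round-trip
#' \code{readStack(writeStack(x))} is bit-identical. Channel roles are not
#' stored in the file; keep them in the run configuration.
#'
#' @param stack a [ChannelStack-class].
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeStack <- function(stack, path) {
  d <- dim(stack)
  scale <- 2^bitDepth(stack) - 1
  pages <- vector("list", d[3L] * d[4L])
  k <- 0L
  for (z in seq_len(d[4L])) for (ch in seq_len(d[3L])) {
    k <- k + 1L
    pages[[k]] <- stack@pixels[, , ch, z] / scale
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bitDepth(stack),
                  compression = "none")
  invisible(path)
}

#' Read/write a label mask as a 16-bit single-channel TIFF
#'
#' @param labels a [LabelImage-class].
#' @param path file path.
#' @param connectivity connectivity convention to attach on read.
#' @return \code{writeLabelImage}: invisibly, the path;
#'   \code{readLabelImage}: a [LabelImage-class].
#' @export
writeLabelImage <- function(labels, path) {
  lab <- labelMatrix(labels)
  if (max(lab) > 65535L) stop("more than 65535 objects cannot be stored")
  tiff::writeTIFF(lab / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname writeLabelImage
#' @export
readLabelImage <- function(path, connectivity = 8L) {
  lab <- tiff::readTIFF(path, as.is = TRUE)
  LabelImage(lab, connectivity)
}

#' Read and validate a plate map
#'
#' Delimited text with required columns \code{well_id} and \code{condition};
#' optional \code{replicate_index} and \code{sample_id}. Well ids must be
#' unique. When \code{sample_id} is absent or empty, each well becomes its
#' own sample (wells treated as independent replicates of their condition).
#'
#' @param path CSV file.
#' @return data.frame with columns \code{well_id, condition,
#'   replicate_index, sample_id}.
#' @export
readPlateMap <- function(path) {
  pm <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("well_id", "condition")
  miss <- setdiff(req, names(pm))
  if (length(miss))
    stop("validation error: plate map lacks column(s): ",
         paste(miss, collapse = ", "))
  if (!nrow(pm)) stop("configuration error: plate map is empty")
  if (anyDuplicated(pm$well_id))
    stop("validation error: duplicated well_id in plate map: ",
         paste(unique(pm$well_id[duplicated(pm$well_id)]), collapse = ", "))
  if (is.null(pm$replicate_index)) pm$replicate_index <- 1L
  if (is.null(pm$sample_id) || all(is.na(pm$sample_id)) ||
      all(!nzchar(as.character(pm$sample_id))))
    pm$sample_id <- pm$well_id
  pm[c("well_id", "condition", "replicate_index", "sample_id")]
}

.defaultConfig <- function(mode = "plate") {
  cfg <- list(
    mode = mode,
    paths = list(images_dir = ".", plate_map = "plate_map.csv",
                 cohort = "cohort.csv"),
    channels = list(nuclear = 1L, expression = 2L, sensor = 3L),
    segmentation = list(threshold_method = "li", fixed_threshold = 0,
                        despeckle_rounds = 1L, despeckle_stage = "post",
                        min_area_px = 20L, max_area_px = 150L,
                        connectivity = 8L, border_policy = "keep",
                        seed_channel = "expression"),
    classification = list(kind = "fixed", k_sd = 2, fixed_threshold = 400,
                          channel_role = "sensor",
                          control_condition = NULL),
    stats = list(alpha = 0.05),
    seed = 1L,
    output_dir = "fluorquant_out"
  )
  if (identical(mode, "invivo")) {
    ## published in vivo mask recipe: Li threshold, four despeckle rounds,
    ## 20-150 px nuclei, mask built on the blue-subtracted green projection
    cfg$channels <- list(sensor = 1L, auxiliary = 2L)
    cfg$segmentation$despeckle_rounds <- 4L
    cfg$segmentation$seed_channel <- "sensor"
  }
  cfg
}

#' Build, read and write a run configuration
#'
#' One YAML document drives both workflows. Sections: \code{mode}
#' ("plate" or "invivo"), \code{paths} (\code{images_dir},
#' \code{plate_map} or \code{cohort}), \code{channels} (role to TIFF page
#' index), \code{segmentation}, \code{classification}, \code{stats},
#' \code{seed} and \code{output_dir}. Omitted keys take the documented
#' defaults; key order in the file is irrelevant. The in vivo mode uses
#' four despeckle rounds unless the file overrides them.
#'
#' @param ... named overrides of the default configuration (nested lists
#'   are merged key-wise).
#' @param path YAML file.
#' @param config a configuration list.
#' @return a configuration list.
#' @examples
#' cfg <- runConfig(mode = "plate",
#'                  classification = list(kind = "control_null",
#'                                        control_condition = "control"))
#' cfg$classification$kind
#' @export
runConfig <- function(...) {
  ov <- list(...)
  mode <- if (is.null(ov$mode)) "plate" else ov$mode
  .mergeConfig(.defaultConfig(mode), ov)
}

.mergeConfig <- function(base, override) {
  for (k in names(override)) {
    if (is.list(override[[k]]) && is.list(base[[k]]))
      base[[k]] <- .mergeConfig(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path))
    stop("configuration error: config file not found: ", path)
  raw <- yaml::read_yaml(path)
  mode <- if (is.null(raw$mode)) "plate" else raw$mode
  if (!(mode %in% c("plate", "invivo")))
    stop("configuration error: mode must be 'plate' or 'invivo'")
  .mergeConfig(.defaultConfig(mode), raw)
}

#' @rdname runConfig
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.segParamsFromConfig <- function(cfg) {
  s <- cfg$segmentation
  segmentationParams(thresholdMethod = s$threshold_method,
                     fixedThreshold = s$fixed_threshold,
                     despeckleRounds = s$despeckle_rounds,
                     despeckleStage = s$despeckle_stage,
                     minAreaPx = s$min_area_px, maxAreaPx = s$max_area_px,
                     connectivity = s$connectivity,
                     borderPolicy = s$border_policy)
}

.ruleFromConfig <- function(cfg) {
  cl <- cfg$classification
  classificationRule(kind = cl$kind, kSd = cl$k_sd,
                     fixedThreshold = cl$fixed_threshold,
                     channelRole = cl$channel_role)
}
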