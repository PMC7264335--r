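.resolvePath <- function(path, baseDir) {
  if (file.exists(path)) path else file.path(baseDir, path)
}

.writeStatsCsv <- function(path, anova, tukey) {
  rows <- list()
  if (!is.null(anova))
    rows[[1L]] <- data.frame(test = anova@testName,
                             statistic = anova@statistic,
                             df1 = anova@df[1L], df2 = anova@df[2L],
                             p = anova@pValue, pair = NA_character_,
                             mean_diff = NA_real_, adj_p = NA_real_)
  if (!is.null(tukey) && nrow(tukey@pairwise))
    rows[[length(rows) + 1L]] <- data.frame(
      test = tukey@testName, statistic = tukey@statistic,
      df1 = tukey@df[1L], df2 = tukey@df[2L], p = tukey@pValue,
      pair = tukey@pairwise$pair, mean_diff = tukey@pairwise$mean_diff,
      adj_p = tukey@pairwise$adj_p)
  tab <- if (length(rows)) do.call(rbind, rows)
         else data.frame(test = character(), statistic = numeric(),
                         df1 = numeric(), df2 = numeric(), p = numeric(),
                         pair = character(), mean_diff = numeric(),
                         adj_p = numeric())
  utils::write.csv(tab, path, row.names = FALSE)
}

#' Run the well-plate analysis end to end
#'
#' For every well in the plate map, every field image
#' (\code{<well_id>_*.tif} under \code{paths$images_dir}) is read, cells are
#' segmented on the configured seed channel (mCherry expression by default,
#' so untransduced cells never enter the denominator), per-cell
#' background-corrected intensities and sensor/expression ratios are
#' measured, cells are classified positive under the configured rule
#' (control-null thresholds are estimated from all cells of the
#' \code{control_condition} wells, pooled across the experiment), and
#' fractions are aggregated per image, per well (pooled cells) and per
#' sample (mean over replicate wells). Group statistics (one-way ANOVA and
#' Tukey HSD on per-sample fractions by condition) complete the run.
#'
#' Per-field errors are logged and quarantine the field; the run aborts only
#' if more than half of all fields fail. The analysis itself is
#' deterministic: identical configuration and inputs give byte-identical
#' output CSVs (\code{cells.csv}, \code{per_image.csv}, \code{per_well.csv},
#' \code{per_sample.csv}, \code{stats.csv}), plus a \code{config.yaml} copy
#' and \code{log.txt} in \code{output_dir}.
#'
#' @param config a configuration list from [runConfig()] or a path to a
#'   YAML file ([readRunConfig()]).
#' @return invisibly, a list: \code{cells}, \code{summaries}
#'   (per image/well/sample), \code{anova}, \code{tukey}, \code{log},
#'   \code{outputDir}.
#' @export
runPlate <- function(config) {
  cfg <- if (is.character(config)) readRunConfig(config)
         else .mergeConfig(.defaultConfig(if (is.null(config$mode)) "plate"
                                          else config$mode), config)
  outDir <- cfg$output_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logLines <- character()
  note <- function(...) logLines <<- c(logLines, paste0(...))

  imagesDir <- cfg$paths$images_dir
  pm <- readPlateMap(.resolvePath(cfg$paths$plate_map, imagesDir))
  roleMap <- unlist(cfg$channels)
  segPar <- .segParamsFromConfig(cfg)
  rule <- .ruleFromConfig(cfg)
  seedChannel <- cfg$segmentation$seed_channel

  cellList <- list()
  nFields <- 0L; nFailed <- 0L
  for (wi in seq_len(nrow(pm))) {
    wellId <- pm$well_id[wi]
    files <- sort(list.files(imagesDir,
                             pattern = paste0("^", wellId, "_.*\\.tif$"),
                             full.names = TRUE))
    if (!length(files)) {
      note("well ", wellId, ": no images found")
      next
    }
    for (f in files) {
      nFields <- nFields + 1L
      res <- tryCatch({
        stack <- readStack(f, roleMap,
                           requiredRoles = c(seedChannel,
                                             rule@channelRole))
        labels <- segmentCells(stack, seedChannel, segPar)
        rec <- measureCells(stack, labels)
        rec <- computeRatio(rec)
        if (nrow(rec)) {
          rec$well_id <- wellId
          rec$image_id <- basename(f)
          rec$condition <- pm$condition[wi]
        }
        rec
      }, error = function(e) e)
      if (inherits(res, "error")) {
        nFailed <- nFailed + 1L
        note("field error [well ", wellId, ", file ", basename(f), "]: ",
             conditionMessage(res))
      } else if (nrow(res)) {
        cellList[[length(cellList) + 1L]] <- res
      }
    }
  }
  if (nFields == 0L) stop("configuration error: no field images found")
  if (nFailed > nFields / 2)
    stop("run failed: ", nFailed, " of ", nFields, " fields errored")

  cells <- do.call(rbind, cellList)
  if (is.null(cells)) stop("no cells segmented in any field")

  controlValues <- NULL
  if (rule@kind == "control_null") {
    cc <- cfg$classification$control_condition
    if (is.null(cc))
      stop("configuration error: control_null rule needs ",
           "classification$control_condition")
    controlValues <- cells[[paste0("bg_mean_", rule@channelRole)]][
      cells$condition == cc]
    if (length(controlValues) < 2L)
      stop("insufficient-control error: < 2 cells in condition '", cc, "'")
  }
  cells <- classifyCells(cells, rule, controlValues)
  note(sprintf("classified %d cells from %d fields (threshold %.4f AU)",
               nrow(cells), nFields - nFailed, attr(cells, "threshold")))

  summaries <- summarizeWells(cells, pm)
  flagged <- summaries$perWell$well_id[summaries$perWell$flagged]
  if (length(flagged))
    note("zero-cell wells excluded from sample means: ",
         paste(flagged, collapse = ", "))

  groups <- split(summaries$perSample$fraction_positive,
                  summaries$perSample$condition)
  groups <- groups[vapply(groups, length, 1L) >= 2L]
  anova <- NULL; tukey <- NULL
  if (length(groups) >= 2L) {
    anova <- oneWayAnova(groups)
    tukey <- tukeyHsd(groups, alpha = cfg$stats$alpha)
  } else {
    note("group statistics skipped: need >= 2 conditions with >= 2 samples")
  }

  utils::write.csv(cells, file.path(outDir, "cells.csv"), row.names = FALSE)
  utils::write.csv(summaries$perImage, file.path(outDir, "per_image.csv"),
                   row.names = FALSE)
  utils::write.csv(summaries$perWell, file.path(outDir, "per_well.csv"),
                   row.names = FALSE)
  utils::write.csv(summaries$perSample, file.path(outDir, "per_sample.csv"),
                   row.names = FALSE)
  .writeStatsCsv(file.path(outDir, "stats.csv"), anova, tukey)
  writeRunConfig(cfg, file.path(outDir, "config.yaml"))
  writeLines(logLines, file.path(outDir, "log.txt"))

  invisible(list(cells = cells, summaries = summaries, anova = anova,
                 tukey = tukey, log = logLines, outputDir = outDir))
}

#' Run the in vivo nuclei-mask workflow end to end
#'
#' For each stack listed in the cohort table (\code{animal, condition,
#' path}; paths relative to \code{paths$images_dir}): maximum z-projections
#' of the green (sensor) and blue (auxiliary) channels are formed, the blue
#' projection (autofluorescence only) is subtracted from the green one
#' (clipped at zero), the subtracted image is binarized with Li's minimum
#' cross-entropy threshold, the mask is despeckled (four 3x3 median rounds
#' by default), connected components are filtered to areas of 20-150 px
#' (nucleus size range), and each surviving nucleus contributes its mean
#' intensity of the subtracted image. Intensities are pooled per condition
#' across animals and compared with an unpaired two-tailed Student's t-test.
#'
#' Stacks that cannot be read or that retain no nuclei are skipped with a
#' logged warning. Outputs \code{nuclei.csv}, \code{stats.csv},
#' \code{config.yaml} and \code{log.txt} in \code{output_dir}.
#'
#' @param config configuration list (\code{mode = "invivo"}) or YAML path.
#' @return invisibly, a list: \code{nuclei} (per-nucleus table),
#'   \code{ttest} ([StatsResult-class] or NULL), \code{log},
#'   \code{outputDir}.
#' @export
runInvivo <- function(config) {
  cfg <- if (is.character(config)) readRunConfig(config)
         else .mergeConfig(.defaultConfig("invivo"), config)
  outDir <- cfg$output_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logLines <- character()
  note <- function(...) logLines <<- c(logLines, paste0(...))

  imagesDir <- cfg$paths$images_dir
  cohort <- utils::read.csv(.resolvePath(cfg$paths$cohort, imagesDir),
                            stringsAsFactors = FALSE)
  req <- c("animal", "condition", "path")
  if (!all(req %in% names(cohort)))
    stop("configuration error: cohort table needs columns ",
         paste(req, collapse = ", "))
  roleMap <- unlist(cfg$channels)
  segPar <- .segParamsFromConfig(cfg)

  nucList <- list()
  for (i in seq_len(nrow(cohort))) {
    res <- tryCatch({
      stack <- readStack(.resolvePath(cohort$path[i], imagesDir), roleMap,
                         requiredRoles = c("sensor", "auxiliary"))
      green <- projectMax(stack, "sensor")
      blue <- projectMax(stack, "auxiliary")
      sub <- subtractChannel(green, blue)
      thr <- liThreshold(sub)
      mask <- (sub > thr) * 1L
      if (segPar@despeckleRounds > 0)
        mask <- despeckle(mask, segPar@despeckleRounds)
      labels <- labelComponents(mask > 0, segPar@connectivity)
      labels <- sizeFilter(labels, segPar@minAreaPx, segPar@maxAreaPx)
      lab <- labelMatrix(labels)
      k <- max(lab)
      if (k == 0L) stop("no nuclei survive the size filter")
      fg <- lab > 0L
      areas <- tabulate(lab[fg], nbins = k)
      data.frame(animal = cohort$animal[i],
                 condition = cohort$condition[i],
                 nucleus_id = seq_len(k),
                 area_px = areas,
                 mean_intensity = as.vector(rowsum(sub[fg], lab[fg])) / areas)
    }, error = function(e) e)
    if (inherits(res, "error"))
      note("stack skipped [", cohort$animal[i], ", ",
           cohort$condition[i], "]: ", conditionMessage(res))
    else nucList[[length(nucList) + 1L]] <- res
  }
  nuclei <- do.call(rbind, nucList)
  if (is.null(nuclei)) stop("no usable stacks in cohort")

  conds <- unique(cohort$condition)
  ttest <- NULL
  if (length(conds) == 2L) {
    a <- nuclei$mean_intensity[nuclei$condition == conds[1L]]
    b <- nuclei$mean_intensity[nuclei$condition == conds[2L]]
    if (length(a) >= 2L && length(b) >= 2L) {
      ttest <- tTestUnpaired(a, b, twoTailed = TRUE)
      note(sprintf(
        "pooled comparison %s (n=%d nuclei) vs %s (n=%d): t = %.4g, p = %.4g",
        conds[1L], length(a), conds[2L], length(b),
        ttest@statistic, ttest@pValue))
    } else note("t-test skipped: a condition has < 2 nuclei")
  } else note("t-test skipped: expected exactly 2 conditions, got ",
              length(conds))

  utils::write.csv(nuclei, file.path(outDir, "nuclei.csv"),
                   row.names = FALSE)
  .writeStatsCsv(file.path(outDir, "stats.csv"), NULL, NULL)
  if (!is.null(ttest)) {
    tab <- data.frame(test = ttest@testName, statistic = ttest@statistic,
                      df1 = ttest@df[1L], df2 = NA_real_, p = ttest@pValue,
                      pair = paste(conds, collapse = "-"),
                      mean_diff = mean(nuclei$mean_intensity[
                        nuclei$condition == conds[1L]]) -
                        mean(nuclei$mean_intensity[
                          nuclei$condition == conds[2L]]),
                      adj_p = NA_real_)
    utils::write.csv(tab, file.path(outDir, "stats.csv"),
                     row.names = FALSE)
  }
  writeRunConfig(cfg, file.path(outDir, "config.yaml"))
  writeLines(logLines, file.path(outDir, "log.txt"))
  invisible(list(nuclei = nuclei, ttest = ttest, log = logLines,
                 outputDir = outDir))
}
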