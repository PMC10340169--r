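# Stage orchestration: simulate / analyze / apical / model, driven by one
# configuration list (YAML-serializable) with a single master seed.

#' Default run configuration
#'
#' The resolved configuration consumed by the pipeline stages. Defaults
#' reproduce the study constants: QC window 7854-31,415 um^2 with a
#' single-lumen requirement, 6 radial rings, ~30 central apical cells,
#' 500-tree forests with 5-fold cross-validation, and the
#' [simulationConfig()] defaults for synthetic plates. Pixel pitches
#' default to 1.30 um/px (10x fields) and 0.11 um/px (100x mosaics) and are
#' explicit configuration, not constants.
#'
#' @param ... named overrides merged recursively into the defaults.
#' @return nested list of class `runConfig`.
#' @export
defaultRunConfig <- function(...) {
  cfg <- list(
    schema_version = 1L,
    seed = 1L,
    paths = list(images = "fields", plateMap = "plate_map.csv",
                 output = "results"),
    channels = list(roles = c("counterstain", "lumen_marker")),
    pixelSizeUm = 1.30,
    apicalPixelSizeUm = 0.11,
    segmentation = list(sigmaPx = 2, threshold = "otsu", minAreaUm2 = 1000,
                        lumenSigmaPx = 1, closeRadiusPx = 3,
                        minLumenAreaUm2 = 50),
    qc = list(minAreaUm2 = 7854, maxAreaUm2 = 31415,
              requireSingleLumen = TRUE, excludeBorder = TRUE),
    radial = list(nRings = 6L),
    apical = list(k = 30L),
    modeling = list(nTrees = 500L, nFolds = 5L,
                    target = "concentration_um"),
    simulation = unclass(simulationConfig())
  )
  dots <- list(...)
  for (nm in names(dots)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(dots[[nm]]))
      modifyList(cfg[[nm]], dots[[nm]]) else dots[[nm]]
  }
  class(cfg) <- "runConfig"
  cfg
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @param config a `runConfig` list.
#' @return `readRunConfig` returns the merged `runConfig`;
#'   `writeRunConfig` returns `path` invisibly.
#' @export
readRunConfig <- function(path) {
  stopIfNot(file.exists(path), "config file not found: ", path)
  do.call(defaultRunConfig, yaml::read_yaml(path))
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @noRd
resolveOutDir <- function(config, outDir) {
  if (is.null(outDir)) outDir <- config$paths$output
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  outDir
}

#' Simulate a plate to disk
#'
#' Renders the design's fields, writing one multi-page TIFF per field, the
#' plate map, the ground-truth table and the resolved configuration.
#'
#' @param config a `runConfig` (or path to a YAML file).
#' @param design named list of [wellCondition()]s (default: the 8-dose
#'   series of [doseDesign()]).
#' @param outDir output directory (defaults to `config$paths$output`).
#' @param seed master seed (defaults to `config$seed`).
#' @return invisible list with the plate objects and written paths.
#' @export
runSimulate <- function(config = defaultRunConfig(), design = doseDesign(),
                        outDir = NULL, seed = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  if (is.null(seed)) seed <- config$seed
  outDir <- resolveOutDir(config, outDir)
  simCfg <- do.call(simulationConfig, config$simulation)
  plate <- simulatePlate(simCfg, design, seed = seed)
  imgDir <- file.path(outDir, "fields")
  dir.create(imgDir, showWarnings = FALSE)
  paths <- character(0)
  for (i in seq_along(plate$fields)) {
    f <- plate$fields[[i]]
    p <- file.path(imgDir, sprintf("field_%s_%02d.tif", plateWell(f),
                                   f@fieldIndex))
    writeField(f, p)
    paths <- c(paths, p)
  }
  write.csv(plate$plateMap, file.path(outDir, "plate_map.csv"),
            row.names = FALSE)
  write.csv(truthOrganoids(plate$truth),
            file.path(outDir, "ground_truth.csv"), row.names = FALSE)
  config$seed <- seed
  writeRunConfig(config, file.path(outDir, "resolved_config.yaml"))
  if (!length(plate$fields)) msg("empty design: no fields written")
  invisible(list(plate = plate, fieldPaths = paths, outDir = outDir))
}

#' Analyze fields into a QC-filtered feature table
#'
#' Runs the measurement pipeline over a list of fields (or a directory of
#' TIFFs): maximum projection, organoid segmentation, lumen segmentation
#' and assignment, feature assembly, metadata join and QC filtering.
#' Per-stage row counts are logged to stderr.
#'
#' @param fields list of [FieldImage-class] objects, or a directory of
#'   multi-page TIFF files written by [runSimulate()].
#' @param plateMap plate-map data.frame or CSV path.
#' @param config a `runConfig`.
#' @param outDir optional output directory; when given, `features.csv`,
#'   `qc_report.csv` and the resolved config are written there.
#' @param families feature families passed to [assembleRecords()].
#' @return list with `records` (all measured), `retained`, `qc` (report
#'   data.frame).
#' @export
runAnalyze <- function(fields, plateMap, config = defaultRunConfig(),
                       outDir = NULL,
                       families = c("shape", "intensity", "radial",
                                    "zernike", "texture", "engineered")) {
  if (is.character(config)) config <- readRunConfig(config)
  if (is.character(plateMap)) plateMap <- readPlateMap(plateMap)
  if (is.character(fields)) {
    tifs <- sort(list.files(fields, pattern = "\\.tif{1,2}$",
                            full.names = TRUE))
    fields <- lapply(tifs, function(p) {
      well <- sub("^field_([^_]+)_.*$", "\\1", basename(p))
      idx <- suppressWarnings(as.integer(
        sub("^field_[^_]+_(\\d+)\\.tiff?$", "\\1", basename(p))))
      readField(p, config$channels$roles, config$pixelSizeUm,
                plateWell = well,
                fieldIndex = if (is.na(idx)) 1L else idx)
    })
  }
  sg <- config$segmentation
  recs <- list()
  for (i in seq_along(fields)) {
    fld <- maxProject(fields[[i]])
    org <- segmentOrganoids(getChannel(fld, "counterstain"),
                            pixelSizeUm = pixelSize(fld),
                            sigmaPx = sg$sigmaPx, threshold = sg$threshold,
                            minAreaUm2 = sg$minAreaUm2)
    lum <- segmentLumens(getChannel(fld, "lumen_marker"), org,
                         sigmaPx = sg$lumenSigmaPx,
                         closeRadiusPx = sg$closeRadiusPx,
                         minLumenAreaUm2 = sg$minLumenAreaUm2)
    if (nObjects(org) == 0L) next
    recs[[length(recs) + 1L]] <-
      assembleRecords(fld, org, lum, families = families)
  }
  records <- if (length(recs)) do.call(rbind, recs) else data.frame()
  msg(sprintf("measured %d organoid(s) across %d field(s)",
              nrow(records), length(fields)))
  if (nrow(records)) records <- joinMetadata(records, plateMap)
  qc <- qcFilter(records, minAreaUm2 = config$qc$minAreaUm2,
                 maxAreaUm2 = config$qc$maxAreaUm2,
                 requireSingleLumen = config$qc$requireSingleLumen,
                 excludeBorder = config$qc$excludeBorder)
  msg(sprintf("QC retained %d / %d record(s)", nrow(qc$retained),
              nrow(records)))
  if (!is.null(outDir)) {
    outDir <- resolveOutDir(config, outDir)
    writeFeatureTable(qc$retained, file.path(outDir, "features.csv"))
    write.csv(qc$report, file.path(outDir, "qc_report.csv"),
              row.names = FALSE)
    writeRunConfig(config, file.path(outDir, "resolved_config.yaml"))
  }
  list(records = records, retained = qc$retained, qc = qc$report)
}

#' Model a feature table
#'
#' Scale/center, random-forest fit with cross-validation, importance
#' ranking and (for >= 2 groups) group comparisons on the engineered
#' area-ratio metric.
#'
#' @param features feature data.frame (QC-retained, metadata joined) or a
#'   CSV path.
#' @param config a `runConfig`; `config$modeling$target` names the target
#'   column.
#' @param outDir optional output directory for `model_report.json`,
#'   `importance.csv` and `group_stats.csv`.
#' @param seed seed for the forest (defaults to `config$seed`).
#' @return list with `report` ([ModelReport-class]), `importance` (ranked
#'   list) and `groupStats`.
#' @export
runModel <- function(features, config = defaultRunConfig(), outDir = NULL,
                     seed = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  if (is.character(features)) features <- readFeatureTable(features)
  if (is.null(seed)) seed <- config$seed
  target <- config$modeling$target
  fm <- buildFeatureMatrix(features, target)
  report <- fitRandomForest(fm, nFolds = config$modeling$nFolds,
                            nTrees = config$modeling$nTrees, seed = seed)
  imp <- rankImportance(report)
  groupStats <- NULL
  if ("area_ratio_sqrt" %in% names(features) &&
      length(unique(features[[target]])) >= 2L &&
      all(table(features[[target]]) >= 2L)) {
    groupStats <- groupCompare(features, "area_ratio_sqrt", target,
                               method = "anova_fdr")
  }
  if (!is.null(outDir)) {
    outDir <- resolveOutDir(config, outDir)
    jsonlite::write_json(
      list(mode = report@mode, score_train = report@scoreTrain,
           score_cv = report@scoreCV, n_trees = report@nTrees,
           n_folds = config$modeling$nFolds, seed = seed,
           target = target, n_rows = nrow(fm$x)),
      file.path(outDir, "model_report.json"), auto_unbox = TRUE, digits = NA)
    write.csv(imp$features, file.path(outDir, "importance.csv"),
              row.names = FALSE)
    if (!is.null(groupStats))
      write.csv(groupStats$pairs, file.path(outDir, "group_stats.csv"),
                row.names = FALSE)
    writeRunConfig(config, file.path(outDir, "resolved_config.yaml"))
  }
  list(report = report, importance = imp, groupStats = groupStats)
}

#' Measure apical mosaics from disk
#'
#' Runs [measureApicalMosaic()] over a directory of single-page
#' high-magnification TIFFs (or a list of matrices), writing one per-cell
#' CSV plus a combined summary table.
#'
#' @param images directory of TIFF files, a single path, or a named list
#'   of 2D matrices.
#' @param config a `runConfig`; `config$apicalPixelSizeUm` and
#'   `config$apical$k` apply.
#' @param outDir optional output directory for `apical_cells.csv` and
#'   `apical_summary.csv`.
#' @return list with `cells` (per-image data.frames, combined) and
#'   `summary` (one row per image).
#' @export
runApical <- function(images, config = defaultRunConfig(), outDir = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  if (is.character(images)) {
    paths <- if (length(images) == 1L && dir.exists(images))
      sort(list.files(images, pattern = "\\.tif{1,2}$", full.names = TRUE))
    else images
    images <- lapply(paths, function(p) {
      pg <- tiff::readTIFF(p, all = TRUE)
      if (is.list(pg)) pg[[1L]] else pg
    })
    names(images) <- basename(paths)
  }
  if (is.null(names(images)))
    names(images) <- sprintf("mosaic_%02d", seq_along(images))
  cells <- list(); summaries <- list()
  for (nm in names(images)) {
    m <- measureApicalMosaic(images[[nm]],
                             pixelSizeUm = config$apicalPixelSizeUm,
                             k = config$apical$k,
                             metadata = list(image = nm))
    cc <- m$cells; cc$image <- nm
    cells[[nm]] <- cc
    summaries[[nm]] <- m$summary
  }
  cells <- do.call(rbind, cells)
  summary <- do.call(rbind, summaries)
  if (!is.null(outDir)) {
    outDir <- resolveOutDir(config, outDir)
    write.csv(cells, file.path(outDir, "apical_cells.csv"), row.names = FALSE)
    write.csv(summary, file.path(outDir, "apical_summary.csv"),
              row.names = FALSE)
    writeRunConfig(config, file.path(outDir, "resolved_config.yaml"))
  }
  list(cells = cells, summary = summary)
}
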