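# End-to-end orchestration: simulate or load a cube, mask vegetation, run the
# two-stage green-level cascade, build VI tables per pretreatment and class,
# screen correlations, select sensitive indices, and fit LNC models. Every
# artifact is written as CSV/JSON under one run directory together with a
# manifest of file hashes, so a rerun with the same config is byte-identical.

#' Assemble a pipeline configuration
#'
#' @param sceneConfig a [sceneConfig()] for a simulated run, or \code{NULL}
#'   when reading from disk.
#' @param cubePath,samplePath ENVI header and sample-table CSV (used when
#'   \code{sceneConfig} is NULL).
#' @param pretreatments character vector of pretreatment methods (subset of
#'   OS/GF/SG/GFSG; at least one).
#' @param nLevels,mode classifier level count and construction mode.
#' @param stage1Keep stage-1 labels re-classified (default c(4, 5)).
#' @param stage2Keep stage-2 labels retained for analysis (default c(3, 4,
#'   5)).
#' @param alpha,minAbsR sensitive-index thresholds.
#' @param models model methods to fit (subset of MLR/PCR/PLSR/SVMR; at least
#'   one).
#' @param testFraction held-out fraction.
#' @param roiHeight,roiWidth sampling window (default 30 x 30).
#' @param seed mandatory integer master seed.
#' @param outDir output directory.
#' @return list of class "PipelineConfig".
#' @export
pipelineConfig <- function(sceneConfig = NULL, cubePath = NULL,
                           samplePath = NULL,
                           pretreatments = c("OS", "GFSG"),
                           nLevels = 10L, mode = "equal_width",
                           stage1Keep = c(4L, 5L), stage2Keep = c(3L, 4L, 5L),
                           alpha = 0.05, minAbsR = 0.2,
                           models = c("MLR", "SVMR"),
                           testFraction = 0.3,
                           roiHeight = 30L, roiWidth = 30L,
                           seed, outDir = tempfile("canopyLevels_run_")) {
  if (missing(seed)) stop("seed is mandatory")
  if (!length(pretreatments)) stop("need at least one pretreatment")
  if (!length(models)) stop("need at least one model method")
  pretreatments <- match.arg(toupper(pretreatments),
                             c("OS", "GF", "SG", "GFSG"), several.ok = TRUE)
  models <- match.arg(toupper(models), c("MLR", "PCR", "PLSR", "SVMR"),
                      several.ok = TRUE)
  if (is.null(sceneConfig) && (is.null(cubePath) || is.null(samplePath)))
    stop("provide either sceneConfig or cubePath + samplePath")
  structure(list(sceneConfig = sceneConfig, cubePath = cubePath,
                 samplePath = samplePath, pretreatments = pretreatments,
                 nLevels = as.integer(nLevels), mode = mode,
                 stage1Keep = as.integer(stage1Keep),
                 stage2Keep = as.integer(stage2Keep),
                 alpha = alpha, minAbsR = minAbsR, models = models,
                 testFraction = testFraction,
                 roiHeight = as.integer(roiHeight),
                 roiWidth = as.integer(roiWidth),
                 seed = as.integer(seed), outDir = outDir),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipelineConfig()]; a \code{scene:}
#' block (keys of [sceneConfig()]) requests a simulated run.
#'
#' @param path YAML file.
#' @return A "PipelineConfig".
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  sc <- NULL
  if (!is.null(y$scene)) {
    scArgs <- y$scene
    if (is.null(scArgs$seed)) scArgs$seed <- y$seed
    sc <- do.call(sceneConfig, scArgs)
  }
  args <- y[setdiff(names(y), "scene")]
  args$sceneConfig <- sc
  do.call(pipelineConfig, args)
}

.writeCsv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

.stageLog <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full de-interference pipeline
#'
#' Stage order: input (simulate or load) -> vegetation mask -> two-stage
#' green-level cascade -> per-pretreatment VI tables for the retained
#' stage-2 classes and for all vegetation pixels -> correlation report ->
#' sensitive-index selection -> feature combination -> model fits. All
#' randomness is routed through the single config seed, so outputs are a
#' pure function of (inputs, config).
#'
#' @param config a [pipelineConfig()].
#' @return Invisibly, a manifest list: output paths, md5 hashes, seed, plus
#'   the in-memory results (mask, maps, tables, report, sensitive sets,
#'   models).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  .stageLog("input", "loading scene")
  if (!is.null(config$sceneConfig)) {
    scene <- generateScene(config$sceneConfig)
    cube <- scene$cube
    samples <- scene$truth$samples
  } else {
    cube <- readEnviCube(config$cubePath)
    samples <- readSampleTable(config$samplePath)
    scene <- NULL
  }
  files <- c(files, .writeCsv(samples, file.path(config$outDir, "samples.csv")))

  .stageLog("mask", "unsupervised vegetation mask")
  mask <- tryCatch(vegetationMask(cube, seed = config$seed),
                   error = function(e) stop("stage mask: ", conditionMessage(e)))
  files <- c(files, .writeCsv(classPixelStats(mask),
                              file.path(config$outDir, "mask_stats.csv")))

  .stageLog("classify", "two-stage green-level cascade")
  maps <- tryCatch(
    cascadeClassify(cube, mask, stage1Keep = config$stage1Keep,
                    nLevels = config$nLevels, mode = config$mode),
    error = function(e) stop("stage classify: ", conditionMessage(e)))
  files <- c(files,
    .writeCsv(classPixelStats(maps$stage1),
              file.path(config$outDir, "stage1_stats.csv")),
    .writeCsv(classPixelStats(maps$stage2),
              file.path(config$outDir, "stage2_stats.csv")))

  .stageLog("indices", "VI tables per class and pretreatment")
  viTables <- list()
  for (m in config$pretreatments) {
    spec <- preprocessSpec(m)
    for (lab in config$stage2Keep) {
      tab <- buildViTable(cube, maps$stage2, samples, labels = lab,
                          pretreat = spec, roiHeight = config$roiHeight,
                          roiWidth = config$roiWidth)
      attr(tab, "classLabel") <- paste0("2-", lab)
      key <- sprintf("vi_2-%d_%s", lab, m)
      viTables[[key]] <- tab
      files <- c(files, .writeCsv(tab, file.path(config$outDir,
                                                 paste0(key, ".csv"))))
    }
    allTab <- buildViTable(cube, mask, samples, pretreat = spec,
                           roiHeight = config$roiHeight,
                           roiWidth = config$roiWidth)
    attr(allTab, "classLabel") <- "all-veg"
    key <- sprintf("vi_all_%s", m)
    viTables[[key]] <- allTab
    files <- c(files, .writeCsv(allTab, file.path(config$outDir,
                                                  paste0(key, ".csv"))))
  }

  .stageLog("correlate", "Pearson screening against LNC")
  report <- correlateViLnc(viTables)
  files <- c(files, .writeCsv(report,
                              file.path(config$outDir, "correlations.csv")))

  .stageLog("select", "sensitive indices")
  lastM <- config$pretreatments[length(config$pretreatments)]
  classReport <- report[report$method == lastM &
                          report$class != "all-veg", , drop = FALSE]
  sens <- selectSensitive(classReport, alpha = config$alpha,
                          minAbsR = config$minAbsR)
  sensDf <- data.frame(
    class = rep(names(sens), lengths(sens)),
    index = unlist(sens, use.names = FALSE), stringsAsFactors = FALSE)
  files <- c(files, .writeCsv(sensDf,
                              file.path(config$outDir, "sensitive.csv")))

  .stageLog("model", paste(config$models, collapse = ", "))
  classTabs <- viTables[sprintf("vi_2-%d_%s", config$stage2Keep, lastM)]
  names(classTabs) <- paste0("2-", config$stage2Keep)
  models <- list()
  if (nrow(sensDf)) {
    feats <- combineFeatures(classTabs, sens, seed = config$seed)
    split <- splitSamples(nrow(feats$x), config$testFraction, config$seed)
    for (m in config$models) {
      rep_m <- tryCatch(
        fitPredict(feats, m, seed = config$seed,
                   testFraction = config$testFraction, split = split),
        error = function(e) {
          .stageLog("model", m, " skipped: ", conditionMessage(e)); NULL
        })
      if (!is.null(rep_m)) {
        models[[m]] <- rep_m
        files <- c(files, .writeCsv(
          rep_m$predictions,
          file.path(config$outDir, sprintf("pred_%s.csv", m))))
      }
    }
  } else .stageLog("model", "no sensitive indices; models skipped")
  modelSummary <- if (length(models)) data.frame(
    method = names(models),
    r2 = vapply(models, `[[`, numeric(1), "r2"),
    rmse = vapply(models, `[[`, numeric(1), "rmse"),
    mae = vapply(models, `[[`, numeric(1), "mae"),
    stringsAsFactors = FALSE) else
    data.frame(method = character(0), r2 = numeric(0), rmse = numeric(0),
               mae = numeric(0))
  files <- c(files, .writeCsv(modelSummary,
                              file.path(config$outDir, "models.csv")))

  manifestPath <- file.path(config$outDir, "manifest.json")
  manifest <- list(
    seed = config$seed,
    version = as.character(utils::packageVersion("canopyLevels")),
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(manifest = manifest, manifestPath = manifestPath,
                 outDir = config$outDir, mask = mask, maps = maps,
                 viTables = viTables, report = report, sensitive = sens,
                 models = models,
                 samples = samples, scene = scene))
}
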