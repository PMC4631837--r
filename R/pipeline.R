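#' Pipeline configuration
#'
#' One document holding every tunable of the pipeline, each defaulting to
#' the study value where one is stated and to the package's documented
#' default otherwise. Unknown keys are rejected, so config files cannot
#' silently misspell a parameter.
#'
#' @param ... overrides of the default keys (see Details).
#' @details Keys: \code{featureConfig} (list, see [featureConfig()]);
#'   \code{scaleLo}, \code{scaleHi} (feature scaling interval, default
#'   \eqn{[-1, 1]}); \code{lsK}, \code{lsT} (affinity graph), \code{nSelect}
#'   (retained features, default 10); \code{fit} (list, see [fitConfig()]);
#'   \code{testFraction} (held-out fraction, default 0.1); \code{seed};
#'   and the synthetic-benchmark keys \code{nTextures}, \code{imageSize},
#'   \code{nRaters}, \code{nReps}, \code{noiseSd}, \code{raterBiasSd}.
#' @return named list of configuration values.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    featureConfig = featureConfig(),
    scaleLo = -1, scaleHi = 1,
    lsK = 5L, lsT = NULL, nSelect = 10L,
    fit = fitConfig(),
    testFraction = 0.1,
    seed = 1L,
    nTextures = 30L, imageSize = 128L,
    nRaters = 20L, nReps = 5L, noiseSd = 5, raterBiasSd = 2)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(dots)] <- dots
  cfg
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file whose keys are a subset of [pipelineConfig()]'s.
#' @return named list of configuration values.
#' @export
readPipelineConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipelineConfig, raw)
}

#' Seeded train/test split
#'
#' Uniform split without replacement; the test set has
#' \code{round(fraction * n)} members.
#'
#' @param ids character or integer identifiers (length >= 2).
#' @param fraction test fraction in (0, 1) (default 0.1).
#' @param seed integer seed.
#' @return list with elements \code{train} and \code{test}.
#' @examples
#' lengths(splitDataset(paste0("t", 1:151), fraction = 0.1, seed = 7))
#' @export
splitDataset <- function(ids, fraction = 0.1, seed = 1L) {
  n <- length(ids)
  if (n < 2L) stop("need at least 2 ids to split", call. = FALSE)
  if (fraction <= 0 || fraction >= 1)
    stop("'fraction' must lie in (0, 1)", call. = FALSE)
  nTest <- round(fraction * n)
  nTest <- max(1L, min(n - 1L, nTest))
  testIdx <- withSeed(seed, sort(sample.int(n, nTest)))
  list(train = ids[-testIdx], test = ids[testIdx])
}

#' Run the full pipeline and write its artifacts
#'
#' Executes extract, scale, select, split, fit and evaluate, writing to
#' \code{outputDir}: \code{features.csv}, \code{selection.csv} and
#' \code{selection.json}, \code{model.json}, \code{evaluation_train.csv} and
#' \code{evaluation_test.csv}, and \code{run_log.txt} capturing every
#' resolved parameter and seed. Inputs are either a directory of images plus
#' a ratings CSV (first column texture id, columns G1..G3, T1..T4, Q) or —
#' with \code{synthetic = TRUE} — a simulated benchmark whose planted
#' hierarchy stands in for human raters.
#'
#' @param config list from [pipelineConfig()].
#' @param imageDir directory of PNG/TIFF/JPEG textures (ignored when
#'   \code{synthetic}).
#' @param ratingsCsv CSV of averaged ratings (ignored when
#'   \code{synthetic}).
#' @param outputDir where artifacts are written (created if needed).
#' @param synthetic generate the inputs with [makeBenchmarkDataset()].
#' @return invisibly, a list with the fitted hierarchy and both evaluation
#'   tables.
#' @export
runPipeline <- function(config = pipelineConfig(), imageDir = NULL,
                        ratingsCsv = NULL, outputDir = "texaes_run",
                        synthetic = FALSE) {
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outputDir, "run_log.txt")
  logLines <- c(sprintf("run started %s", format(Sys.time())),
                sprintf("seed: %d", config$seed),
                utils::capture.output(utils::str(config)))

  if (synthetic) {
    bench <- makeBenchmarkDataset(
      nTextures = config$nTextures, seed = config$seed,
      size = config$imageSize, nSelect = config$nSelect,
      noiseSd = config$noiseSd, raterBiasSd = config$raterBiasSd,
      nRaters = config$nRaters, nReps = config$nReps, k = config$lsK)
    X <- bench$features; Xs <- bench$scaled
    sel <- bench$selection; selX <- bench$selected
    ratings <- bench$ratings
  } else {
    if (is.null(imageDir) || !dir.exists(imageDir))
      stop("image directory not found: ",
           if (is.null(imageDir)) "(none given)" else imageDir,
           call. = FALSE)
    if (is.null(ratingsCsv) || !file.exists(ratingsCsv))
      stop("ratings CSV not found: ",
           if (is.null(ratingsCsv)) "(none given)" else ratingsCsv,
           call. = FALSE)
    X <- extractFeatureMatrix(imageDir, config$featureConfig)
    Xs <- scaleFeatures(X, config$scaleLo, config$scaleHi)
    g <- buildAffinityGraph(Xs, k = config$lsK, t = config$lsT)
    sel <- selectFeatures(laplacianScores(Xs, g), mode = "top_k",
                          value = config$nSelect)
    selX <- Xs[, selectedFeatures(sel), drop = FALSE]
    colnames(selX) <- paste0("f", seq_len(ncol(selX)))
    rdf <- utils::read.csv(ratingsCsv, check.names = FALSE)
    ratings <- as.matrix(rdf[, -1L, drop = FALSE])
    rownames(ratings) <- rdf[[1L]]
    common <- intersect(rownames(X), rownames(ratings))
    if (!length(common))
      stop("features and ratings share no texture identifiers",
           call. = FALSE)
    selX <- selX[common, , drop = FALSE]
    ratings <- ratings[common, , drop = FALSE]
  }

  writeFeatureCSV(X, file.path(outputDir, "features.csv"))
  writeSelectionCSV(sel, file.path(outputDir, "selection.csv"))
  writeSelectionJSON(sel, file.path(outputDir, "selection.json"))

  ids <- rownames(selX)
  split <- splitDataset(ids, fraction = config$testFraction,
                        seed = config$seed)
  scaling <- attr(Xs, "scaling")
  h <- fitHierarchy(selX[split$train, , drop = FALSE],
                    ratings[split$train, , drop = FALSE],
                    cfg = config$fit, scaling = scaling)
  writeHierarchyJSON(h, file.path(outputDir, "model.json"))

  evTrain <- evaluateHierarchy(h, selX[split$train, , drop = FALSE],
                               ratings[split$train, , drop = FALSE])
  evTest <- evaluateHierarchy(h, selX[split$test, , drop = FALSE],
                              ratings[split$test, , drop = FALSE])
  utils::write.csv(evTrain, file.path(outputDir, "evaluation_train.csv"),
                   row.names = FALSE)
  utils::write.csv(evTest, file.path(outputDir, "evaluation_test.csv"),
                   row.names = FALSE)

  logLines <- c(logLines,
                sprintf("textures: %d (train %d / test %d)", length(ids),
                        length(split$train), length(split$test)),
                sprintf("selected features: %s",
                        paste(selectedFeatures(sel), collapse = ", ")),
                sprintf("run finished %s", format(Sys.time())))
  writeLines(logLines, logPath)
  invisible(list(hierarchy = h, evaluationTrain = evTrain,
                 evaluationTest = evTest, split = split,
                 selection = sel))
}
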