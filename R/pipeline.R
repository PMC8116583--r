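## End-to-end orchestration: synthesize (or load) cases, extract the
## feature pool, split, select, fit and evaluate, writing a
## self-describing run directory.

#' Pipeline configuration
#'
#' Validated configuration for [runFullPipeline()]. Either `inputDir`
#' (a dataset written by [generateDataset()]) or `params` (synthesis on
#' the fly) must be given.
#'
#' @param outDir run output directory.
#' @param params a [cohortParams()] object for on-the-fly synthesis.
#' @param inputDir directory with a generated dataset (manifest.json).
#' @param seed pipeline seed (split and any synthesis).
#' @param trainFraction training fraction in (0, 1).
#' @param binWidth texture discretisation bin width.
#' @param imageSizePx rendered image side length for synthesis.
#' @param cameraConstant Littmann camera constant; default matches
#'   [defaultCameraConstant()] for `imageSizePx`.
#' @param kMax maximum number of path features considered.
#' @param target `"mChT"`, `"pChT"` or `"both"`.
#' @return Validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(outDir, params = NULL, inputDir = NULL,
                           seed = 1, trainFraction = 0.7, binWidth = 25,
                           imageSizePx = 192,
                           cameraConstant = defaultCameraConstant(imageSizePx),
                           kMax = 25, target = "both") {
  if (is.null(params) && is.null(inputDir))
    stop("either params or inputDir must be supplied")
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie strictly between 0 and 1")
  if (binWidth <= 0) stop("binWidth must be positive")
  if (!(target %in% c("mChT", "pChT", "both")))
    stop("target must be 'mChT', 'pChT' or 'both'")
  cfg <- list(outDir = outDir, params = params, inputDir = inputDir,
              seed = as.integer(seed), trainFraction = trainFraction,
              binWidth = binWidth, imageSizePx = as.integer(imageSizePx),
              cameraConstant = cameraConstant, kMax = as.integer(kMax),
              target = target)
  class(cfg) <- "PipelineConfig"
  cfg
}

.logLine <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), "  ", ...)
  writeLines(msg, con)
}

#' Run the full analysis pipeline
#'
#' Stages: synthesise (or load) cases; build ROI masks and extract the
#' feature pool per case; write the feature table; split into training
#' and test sets; order features by LASSO entry, choose the feature count
#' by the held-out adjusted-R-squared rule, fit the indicator model(s);
#' evaluate on the test set. Every artifact lands in the run directory:
#' `features.csv`, `model_<target>.json`, `selection_<target>.csv`,
#' `adjr2_<target>.png`, `evaluation_<target>.csv`, `config.json` and
#' `run.log`. Per-case failures are recorded and summarised, never
#' silently dropped; identical config and seed give identical CSV/JSON
#' outputs.
#'
#' @param config a [pipelineConfig()] object.
#' @return Invisible list with the feature table, models, selection paths
#'   and evaluation tables.
#' @export
runFullPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(config$outDir, "run.log")
  con <- file(logPath, open = "wt")
  on.exit(close(con), add = TRUE)
  t0 <- Sys.time()
  .logLine(con, "pipeline start, seed ", config$seed)

  ## stage 1: cases
  if (!is.null(config$inputDir)) {
    manifest <- jsonlite::read_json(file.path(config$inputDir, "manifest.json"),
                                    simplifyVector = TRUE)
    subjects <- readFeatureTable(file.path(config$inputDir, "subjects.csv"))
    truth <- readFeatureTable(file.path(config$inputDir, "truth.csv"))
    getCase <- function(i) {
      lc <- loadCase(file.path(config$inputDir, paste0(subjects$id[i], ".png")),
                     file.path(config$inputDir, paste0(subjects$id[i], ".json")))
      lc$mag <- littmannScale(subjects$al[i], manifest$cameraConstant)
      lc
    }
    .logLine(con, "loaded dataset from ", config$inputDir,
             " (", nrow(subjects), " cases)")
  } else {
    prm <- config$params
    prm$seed <- config$seed
    coh <- sampleSubjects(prm)
    subjects <- coh$subjects
    truth <- coh$truth
    getCase <- function(i)
      renderFundusCase(subjects[i, ], truth[i, ], config$imageSizePx,
                       config$cameraConstant,
                       seed = (config$seed * 10007L + i) %% 2147483647L)
    .logLine(con, "synthesised cohort of ", nrow(subjects), " subjects")
  }

  ## stage 2: feature extraction
  n <- nrow(subjects)
  rows <- vector("list", n)
  failures <- character()
  for (i in seq_len(n)) {
    rows[[i]] <- tryCatch({
      cs <- getCase(i)
      masks <- buildRoiMasks(cs$annotation, cs$mag)
      fv <- extractPool(cs$image, cs$annotation, masks, cs$mag,
                        config$binWidth)
      if (isTRUE(attr(fv, "flagged"))) {
        failures <- c(failures, paste0(subjects$id[i], ": ",
                                       attr(fv, "flagReason")))
        NULL
      } else fv
    }, error = function(e) {
      failures <<- c(failures, paste0(subjects$id[i], ": ",
                                      conditionMessage(e)))
      NULL
    })
  }
  ok <- !vapply(rows, is.null, TRUE)
  if (length(failures))
    .logLine(con, "flagged/failed cases (excluded): ",
             paste(failures, collapse = "; "))
  if (!any(ok)) stop("no case survived feature extraction")
  feat <- as.data.frame(do.call(rbind, rows[ok]))
  feat <- cbind(data.frame(id = subjects$id[ok], stringsAsFactors = FALSE),
                feat,
                mChT = subjects$mcht[ok], pChT = subjects$pcht[ok],
                al = subjects$al[ok])
  writeFeatureTable(feat, file.path(config$outDir, "features.csv"))
  .logLine(con, "extracted ", sum(ok), " feature vectors of length ",
           ncol(feat) - 4)

  ## stage 3: split
  sp <- splitCohort(feat, config$trainFraction, config$seed)
  .logLine(con, "split: ", nrow(sp$train), " train / ", nrow(sp$test), " test")

  featureCols <- setdiff(names(feat), c("id", "mChT", "pChT", "al"))
  targets <- if (config$target == "both") c("mChT", "pChT") else config$target
  models <- list(); paths <- list(); evals <- list()
  for (tg in targets) {
    pathT <- suppressWarnings(
      lassoOrder(sp$train[, featureCols], sp$train[[tg]], config$kMax))
    sel <- selectFeatureCount(pathT, sp$train, sp$test, tg)
    model <- fitIod(sp$train, sel$features, tg)
    models[[tg]] <- model; paths[[tg]] <- sel$path
    saveModel(model, file.path(config$outDir, paste0("model_", tg, ".json")))
    selDf <- data.frame(k = seq_along(sel$path@featureOrder),
                        feature = sel$path@featureOrder,
                        adjR2Train = sel$path@adjR2Train,
                        adjR2Test = sel$path@adjR2Test,
                        selected = seq_along(sel$path@featureOrder) <= sel$k)
    .writeCsv(selDf, file.path(config$outDir, paste0("selection_", tg, ".csv")))
    grDevices::png(file.path(config$outDir, paste0("adjr2_", tg, ".png")),
                   width = 720, height = 480)
    ylim <- range(c(selDf$adjR2Train, selDf$adjR2Test), finite = TRUE)
    graphics::plot(selDf$k, selDf$adjR2Train, type = "b", pch = 16,
                   col = "steelblue", ylim = ylim,
                   xlab = "number of selected features",
                   ylab = "adjusted R-squared",
                   main = paste0("Feature-count selection (", tg, ")"))
    graphics::lines(selDf$k, selDf$adjR2Test, type = "b", pch = 17,
                    col = "firebrick")
    graphics::abline(v = sel$k, lty = 2)
    graphics::legend("bottomright", c("training", "test"), pch = c(16, 17),
                     col = c("steelblue", "firebrick"), bty = "n")
    grDevices::dev.off()
    ev <- evaluateIod(model, sp$test)
    evals[[tg]] <- ev
    .writeCsv(ev$table, file.path(config$outDir,
                                  paste0("evaluation_", tg, ".csv")))
    .logLine(con, tg, ": k* = ", sel$k, ", test adjR2 = ",
             signif(sel$path@adjR2Test[sel$k], 4), ", r(IOD, ", tg, ") = ",
             signif(ev$table$r[ev$table$variable == tg], 4))
  }

  cfgOut <- config
  cfgOut$params <- if (!is.null(config$params)) unclass(config$params)
  jsonlite::write_json(
    c(list(package = "fundusIOD",
           version = as.character(utils::packageVersion("fundusIOD")),
           nCasesUsed = sum(ok), nCasesFlagged = length(failures)),
      unclass(cfgOut)),
    file.path(config$outDir, "config.json"), auto_unbox = TRUE, digits = NA,
    null = "null", pretty = TRUE)
  .logLine(con, "done in ", round(as.numeric(difftime(Sys.time(), t0,
                                                      units = "secs")), 1), " s")
  invisible(list(features = feat, split = sp, models = models,
                 paths = paths, evaluations = evals,
                 flagged = failures))
}
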