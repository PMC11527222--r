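## End-to-end pipeline: generate -> (extract) -> train -> predict -> evaluate,
## plus the alpha sensitivity sweep. The command-line script shipped under
## inst/scripts/clockscore is a thin wrapper over these functions.

#' Default pipeline configuration
#'
#' @param seed global seed.
#' @param outDir artifact directory.
#' @param nPerClass synthetic images per score class.
#' @param side image side in pixels.
#' @param head model head.
#' @param testFraction stratified hold-out fraction.
#' @param train named list overriding \code{\link{trainConfig}} fields.
#' @param writeImages logical; write the generated PNGs (slower).
#' @return nested named list with a stable content hash (see
#'   \code{\link{configHash}}).
#' @export
runConfig <- function(seed = 1L, outDir = tempfile("clockscore_run"),
                      nPerClass = 100L, side = 48L, head = "ordinal6",
                      testFraction = 0.1, train = list(),
                      writeImages = FALSE) {
  tc <- utils::modifyList(trainConfig(), train)
  list(seed = as.integer(seed), outDir = outDir,
       nPerClass = as.integer(nPerClass), side = as.integer(side),
       head = head, testFraction = testFraction, train = tc,
       writeImages = writeImages)
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror \code{\link{runConfig}}.
#' @param overrides named list of values taking precedence over the file.
#' @return configuration list.
#' @export
readRunConfig <- function(path, overrides = list()) {
  y <- yaml::read_yaml(path)
  bad <- setdiff(names(y), names(formals(runConfig)))
  if (length(bad))
    csError("InvalidConfig", paste("unknown config keys:", paste(bad, collapse = ", ")))
  cfg <- do.call(runConfig, utils::modifyList(y, overrides))
  cfg
}

.logLine <- function(logPath, stage, seed, hash, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage = stage, seed = seed, configHash = hash), list(...))
  cat(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)),
      "\n", sep = "", file = logPath, append = TRUE)
}

#' Run the full synthetic pipeline
#'
#' Generates a class-balanced synthetic clock dataset, makes a stratified
#' train/test split, trains the configured model with the two-phase
#' schedule, predicts on the hold-out and writes all artifacts (manifest,
#' checkpoint, predictions CSV, metrics JSON, JSON-lines log) to the output
#' directory.
#'
#' @param config list from \code{\link{runConfig}}.
#' @return list with \code{model}, \code{history}, \code{report}
#'   (\linkS4class{MetricsReport}), \code{split} and \code{outDir}.
#' @export
runPipeline <- function(config = runConfig()) {
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  hash <- configHash(config)
  logPath <- file.path(config$outDir, "run.jsonl")
  jsonlite::write_json(config, file.path(config$outDir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      .logLine(logPath, name, config$seed, hash, status = "error",
               message = conditionMessage(e))
      csError("StageError", sprintf("stage '%s' failed: %s", name,
                                    conditionMessage(e)))
    })
    .logLine(logPath, name, config$seed, hash, status = "ok")
    res
  }
  ds <- stage("generate", generateClockDataset(
    config$nPerClass, seed = config$seed, side = config$side,
    dir = if (config$writeImages) file.path(config$outDir, "images") else NULL))
  utils::write.csv(ds$manifest, file.path(config$outDir, "manifest.csv"),
                   row.names = FALSE)
  split <- stage("split", stratifiedSplit(ds$manifest$score,
                                          config$testFraction, config$seed))
  fit <- stage("train", {
    model <- buildClockModel(head = config$head, inputSide = config$side,
                             seed = config$seed)
    trainTwoPhase(model,
                  ds$images[, , split$train, drop = FALSE],
                  ds$manifest$score[split$train],
                  ds$images[, , split$test, drop = FALSE],
                  ds$manifest$score[split$test],
                  config$train)
  })
  saveClockModel(fit$model, file.path(config$outDir, "checkpoint.rds"),
                 config = config)
  utils::write.csv(fit$history, file.path(config$outDir, "history.csv"),
                   row.names = FALSE)
  res <- stage("predict", {
    probs <- predictProbs(fit$model, ds$images[, , split$test, drop = FALSE])
    writePredictions(probs, ds$manifest$id[split$test],
                     file.path(config$outDir, "predictions.csv"),
                     truth = ds$manifest$score[split$test])
  })
  report <- stage("evaluate", {
    pred <- if (config$head == "binary") NULL
            else metricsReport(res$decoded_score, ds$manifest$score[split$test])
    pred
  })
  if (!is.null(report))
    reportAsList(report, file.path(config$outDir, "metrics.json"))
  list(model = fit$model, history = fit$history, report = report,
       split = split, outDir = config$outDir)
}

#' Alpha sensitivity sweep
#'
#' Trains one ordinal model per alpha value under otherwise identical,
#' seeded conditions and tabulates hold-out accuracy, RMSE, overestimation
#' rate and the off-by-one accuracies — the shape of a sensitivity analysis
#' on the loss asymmetry.
#'
#' @param alphas alpha values to sweep.
#' @param config base configuration (head is forced to "ordinal6").
#' @param csvPath optional output CSV.
#' @return data.frame: alpha, accuracy, rmse, overestimationRate,
#'   accRPlus1, accRPm1, gamma.
#' @export
sweepAlpha <- function(alphas = c(0.5, 0.55, 0.6, 0.65, 0.7, 0.75),
                       config = runConfig(), csvPath = NULL) {
  config$head <- "ordinal6"
  ds <- generateClockDataset(config$nPerClass, seed = config$seed,
                             side = config$side)
  split <- stratifiedSplit(ds$manifest$score, config$testFraction, config$seed)
  rows <- lapply(alphas, function(a) {
    cfg <- config$train; cfg$alpha <- a
    model <- buildClockModel(head = "ordinal6", inputSide = config$side,
                             seed = config$seed)
    fit <- trainTwoPhase(model,
                         ds$images[, , split$train, drop = FALSE],
                         ds$manifest$score[split$train], config = cfg)
    pred <- predictScores(fit$model, ds$images[, , split$test, drop = FALSE])
    truth <- ds$manifest$score[split$test]
    acc <- accuracySuite(pred, truth)
    data.frame(alpha = a, accuracy = acc[["accuracy"]],
               rmse = rmseScore(pred, truth),
               overestimationRate = overestimationRate(pred, truth),
               accRPlus1 = acc[["accRPlus1"]], accRPm1 = acc[["accRPm1"]],
               gamma = tryCatch(gammaStat(pred, truth),
                                clockscoreError = function(e) NA_real_))
  })
  out <- do.call(rbind, rows)
  if (!is.null(csvPath)) utils::write.csv(out, csvPath, row.names = FALSE)
  out
}
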