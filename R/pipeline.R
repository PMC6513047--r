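#' Full-run configuration
#'
#' Nested configuration for the end-to-end demo pipeline.  Every key has a
#' default, so \code{runConfig()} is complete without any external file;
#' unknown keys in any section are rejected.  Sections mirror the stage
#' configurations: \code{cohort} (nVolumes, fracNormal, pArtifact,
#' maxLesions), \code{phantom} ([phantomConfig()] arguments),
#' \code{preprocess} ([preprocessConfig()]), \code{network}
#' ([networkConfig()] minus input shape), \code{train} ([trainConfig()]),
#' \code{summary} ([summaryConfig()]).
#'
#' @param seed global seed; stage seeds are derived from it.
#' @param outDir output directory.
#' @param cohort,phantom,preprocess,network,train,summary named lists of
#'   overrides for the corresponding section.
#' @return a validated nested list of class \code{runConfig}.
#' @export
runConfig <- function(seed = 1L, outDir = tempfile("octsum_run_"),
                      cohort = list(), phantom = list(), preprocess = list(),
                      network = list(), train = list(), summary = list()) {
  checkKeys <- function(given, allowed, section) {
    bad <- setdiff(names(given), allowed)
    if (length(bad))
      stop(sprintf("unknown key(s) in section '%s': %s", section,
                   paste(bad, collapse = ", ")))
    given
  }
  cohortDefaults <- list(nVolumes = 6L, fracNormal = 0.3, pArtifact = 0.5,
                         maxLesions = 3L)
  cohort <- utils::modifyList(
    cohortDefaults, checkKeys(cohort, names(cohortDefaults), "cohort"))
  phantom <- checkKeys(phantom, names(formals(phantomConfig)), "phantom")
  preprocess <- checkKeys(preprocess, names(formals(preprocessConfig)),
                          "preprocess")
  network <- checkKeys(network, setdiff(names(formals(networkConfig)),
                                        "inputShape"), "network")
  train <- checkKeys(train, names(formals(trainConfig)), "train")
  summary <- checkKeys(summary, names(formals(summaryConfig)), "summary")
  structure(list(seed = as.integer(seed), outDir = outDir, cohort = cohort,
                 phantom = phantom, preprocess = preprocess,
                 network = network, train = train, summary = summary),
            class = "runConfig")
}

#' Load a run configuration from YAML
#'
#' The file may define any subset of the [runConfig()] sections; unknown
#' sections or keys are rejected.
#'
#' @param path YAML file.
#' @param ... overrides applied after the file (e.g. \code{seed}).
#' @return a \code{runConfig}.
#' @export
readRunConfig <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(runConfig))
  bad <- setdiff(names(raw), allowed)
  if (length(bad))
    stop("unknown section(s) in ", path, ": ", paste(bad, collapse = ", "))
  do.call(runConfig, utils::modifyList(raw, list(...)))
}

pipelineStage <- function(name, verbose, expr) {
  if (verbose) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), name))
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the end-to-end demo pipeline
#'
#' Executes generate, preprocess, split, train, predict, summarise,
#' evaluate and render at the configured (desk) scale, writing every
#' artifact under \code{config$outDir} and returning a manifest with
#' content hashes.  Stages derive their seeds from the global seed, so a
#' rerun with the same configuration reproduces the deterministic artifacts
#' hash-for-hash.
#'
#' @param config a [runConfig()].
#' @param verbose print stage progress.
#' @return manifest list: \code{files} (data.frame path/md5), \code{metrics}
#'   (test-set evaluation), \code{summaries} (per test volume), \code{outDir}.
#' @export
runPipeline <- function(config = runConfig(), verbose = FALSE) {
  stopifnot(inherits(config, "runConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  outfile <- function(...) file.path(config$outDir, ...)

  phantomCfg <- do.call(deskPhantomConfig, config$phantom)
  preCfg <- do.call(preprocessConfig, config$preprocess)
  netCfg <- do.call(networkConfig, config$network)
  trainCfg <- do.call(trainConfig, config$train)
  sumCfg <- do.call(summaryConfig, config$summary)

  volumes <- pipelineStage("generate", verbose, {
    vols <- generateCohort(config$cohort$nVolumes, phantomCfg,
                           seed = deriveSeed(config$seed, 1),
                           fracNormal = config$cohort$fracNormal,
                           pArtifact = config$cohort$pArtifact,
                           maxLesions = config$cohort$maxLesions)
    writeVolume(vols[[1]], outfile("volume_example.tiff"))
    vols
  })
  ids <- vapply(volumes, volumeId, "")

  split <- pipelineStage("split", verbose,
    splitVolumes(ids, trainCfg$fractions, deriveSeed(config$seed, 2)))

  sets <- pipelineStage("preprocess", verbose, {
    sets <- lapply(split, function(s) collectSlices(volumes, s, preCfg))
    pre1 <- preprocessVolume(volumes[[1]], preCfg, "denovo")
    writeVolume(pre1, outfile("preprocessed_example.tiff"))
    sets
  })

  fit <- pipelineStage("train", verbose, {
    net <- buildDenovoNet(netCfg, seed = deriveSeed(config$seed, 3))
    fit <- trainClassifier(net, sets$train$x, sets$train$y,
                           sets$val$x, sets$val$y, trainCfg, preCfg,
                           verbose = verbose)
    utils::write.csv(fit$history, outfile("history.csv"), row.names = FALSE)
    saveNet(fit$net, outfile("checkpoint.json"))
    fit
  })

  preds <- pipelineStage("predict", verbose, {
    preds <- predictSlices(fit$net, sets$test$x)
    preds$volume <- sets$test$volume
    jsonlite::write_json(preds, outfile("flags.json"), digits = NA)
    preds
  })

  summaries <- pipelineStage("summarise", verbose, {
    testVols <- volumes[ids %in% split$test]
    summaries <- lapply(testVols, function(v) {
      pv <- preds[preds$volume == volumeId(v), ]
      usable <- which(sliceLabels(v) != "poor_quality")
      summarizeVolume(sort(usable[pv$flag]), nSlices(v), sumCfg, volumeId(v))
    })
    jsonlite::write_json(lapply(summaries, summaryToList),
                         outfile("summary.json"), auto_unbox = TRUE)
    renderSummary(testVols[[1]], summaries[[1]],
                  outfile("enface.png"), outfile("montage.png"))
    summaries
  })

  metrics <- pipelineStage("evaluate", verbose, {
    m <- confusionMetrics(sets$test$y, as.integer(preds$flag))
    m$auc <- if (length(unique(sets$test$y)) == 2)
      rocAuc(sets$test$y, preds$probability) else NA_real_
    utils::write.csv(m, outfile("metrics.csv"), row.names = FALSE)
    m
  })

  resolved <- config
  resolved$outDir <- NULL
  yaml::write_yaml(unclass(resolved), outfile("config_resolved.yaml"))
  paths <- list.files(config$outDir, full.names = TRUE)
  manifest <- data.frame(path = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         row.names = NULL)
  list(files = manifest, metrics = metrics, summaries = summaries,
       outDir = config$outDir)
}

summaryToList <- function(s) {
  list(volume_id = s@volumeId, T = s@gapT, fallback = s@fallback,
       regions = lapply(s@regions, function(r)
         list(first = r$first, median = r$median, last = r$last,
              flagged = r$flagged)),
       keyframes = s@keyframes)
}

#' Save / load network weights
#'
#' Checkpoints are plain JSON holding the [networkConfig()] and all weights
#' at full precision.
#'
#' @param net a \linkS4class{DenovoNet}.
#' @param path checkpoint path.
#' @return \code{loadNet}: the restored \linkS4class{DenovoNet}.
#' @export
saveNet <- function(net, path) {
  obj <- list(config = unclass(net@config),
              convW = lapply(net@convW, as.vector),
              convB = net@convB,
              convDims = lapply(net@convW, dim),
              fcW = as.vector(net@fcW), fcDim = dim(net@fcW), fcB = net@fcB)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveNet
#' @export
loadNet <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(networkConfig, obj$config[c("filterWidths", "inputShape",
                                             "nClasses", "poolingMode")])
  dims <- obj$convDims
  if (is.matrix(dims)) dims <- split(dims, row(dims))  # simplified by jsonlite
  convW <- lapply(seq_len(7), function(i)
    matrix(obj$convW[[i]], dims[[i]][1], dims[[i]][2]))
  new("DenovoNet", config = cfg, convW = convW,
      convB = lapply(obj$convB, as.numeric),
      fcW = matrix(obj$fcW, obj$fcDim[1], obj$fcDim[2]),
      fcB = as.numeric(obj$fcB))
}
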