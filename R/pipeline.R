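#' Default pipeline configuration
#'
#' A complete configuration list for [runPipeline()], desk-scaled by default
#' (64x64 lattice, 60 cells, short save window, few epochs) so that the full
#' simulate / build-dataset / train / evaluate chain runs in minutes on one
#' CPU.  The full-scale published protocol corresponds to
#' `latticeSize = 256`, `nCells = 1000`, `mcsEnd = 20000`, `saveEvery = 1`,
#' `epochs = 100`, `nTrainSims = 20`.
#'
#' @param ... named overrides of any configuration entry.
#' @return a named list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    latticeSize = 64L, nCells = 60L,
    mcsStartSave = 200, mcsEnd = 700, saveEvery = 10,
    nTrainSims = 2L, nEvalSims = 1L,
    horizon = 100, splitFraction = 0.8,
    depth = 2L, baseChannels = 8L, epochs = 5L,
    lr = 1e-3, batchSize = 8L,
    evalT0 = 400, evalIterations = 3L,
    params = list())
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

.configParams <- function(cfg) {
  do.call(cpmParams, c(list(latticeSize = cfg$latticeSize,
                            nCellsInitial = cfg$nCells), cfg$params))
}

.configHash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(cfg[order(names(cfg))], tf)
  unname(tools::md5sum(tf))
}

#' Run the full surrogate-modeling pipeline
#'
#' Simulate training and evaluation runs, build the paired dataset, train
#' the surrogate, and evaluate the rollout against ground truth and the
#' frozen-reference baseline - all from one seeded configuration.  Each
#' stage writes its artifact into `outDir` stamped with the configuration
#' hash; a completed stage (artifact present with a matching hash) is
#' skipped on re-run.
#'
#' @param config a [pipelineConfig()] list (or path to a YAML file with the
#'   same fields).
#' @param outDir artifact directory (created if missing).
#' @param dryRun list the stages and planned artifacts without executing.
#' @param verbose print stage progress.
#' @return invisibly, a list with the artifact paths, the metrics report of
#'   the evaluation stage, and the configuration hash.  In dry-run mode, the
#'   stage plan.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempfile("cpmunet_"),
                        dryRun = FALSE, verbose = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config must carry an explicit seed")
  hash <- .configHash(config)
  stages <- c("simulate", "dataset", "train", "evaluate")
  paths <- file.path(outDir, c(
    simulate = sprintf("runs_%s.rds", hash),
    dataset = sprintf("dataset_%s.rds", hash),
    train = sprintf("model_%s.rds", hash),
    evaluate = sprintf("metrics_%s.rds", hash)))
  names(paths) <- stages
  if (dryRun) {
    plan <- data.frame(stage = stages, artifact = unname(paths),
                       done = file.exists(paths))
    if (verbose) print(plan)
    return(invisible(plan))
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  p <- .configParams(config)

  if (!file.exists(paths[["simulate"]])) {
    say("[simulate] %d train + %d eval runs on %dx%d",
        config$nTrainSims, config$nEvalSims, config$latticeSize, config$latticeSize)
    trainRuns <- lapply(seq_len(config$nTrainSims), function(i)
      simulateVasculogenesis(p, seed = config$seed + i - 1L,
                             mcsStartSave = config$mcsStartSave,
                             mcsEnd = config$mcsEnd,
                             saveEvery = config$saveEvery))
    evalRuns <- lapply(seq_len(config$nEvalSims), function(i)
      simulateVasculogenesis(p, seed = config$seed + 1000L + i - 1L,
                             mcsStartSave = config$mcsStartSave,
                             mcsEnd = config$mcsEnd,
                             saveEvery = config$saveEvery))
    saveRDS(list(train = trainRuns, eval = evalRuns), paths[["simulate"]])
  } else say("[simulate] artifact present, skipping")
  runs <- readRDS(paths[["simulate"]])

  if (!file.exists(paths[["dataset"]])) {
    say("[dataset] horizon %g, split %.2f", config$horizon, config$splitFraction)
    ds <- makeDataset(runs$train, horizon = config$horizon,
                      splitFraction = config$splitFraction, seed = config$seed)
    writeDataset(ds, paths[["dataset"]])
  } else say("[dataset] artifact present, skipping")
  ds <- readDataset(paths[["dataset"]])

  if (!file.exists(paths[["train"]])) {
    say("[train] depth %d, base %d, %d epochs over %d pairs",
        config$depth, config$baseChannels, config$epochs, length(ds@trainIdx))
    net <- buildSurrogate(depth = config$depth, baseChannels = config$baseChannels,
                          horizon = config$horizon, lr = config$lr,
                          batchSize = config$batchSize, seed = config$seed)
    net <- trainSurrogate(net, ds, epochs = config$epochs, seed = config$seed,
                          verbose = verbose)
    saveSurrogate(net, paths[["train"]])
  } else say("[train] artifact present, skipping")
  net <- loadSurrogate(paths[["train"]])

  if (!file.exists(paths[["evaluate"]])) {
    say("[evaluate] rollout from MCS %g for %d iterations over %d runs",
        config$evalT0, config$evalIterations, length(runs$eval))
    report <- evaluateRollout(net, runs$eval, t0Mcs = config$evalT0,
                              nIterations = config$evalIterations,
                              horizon = config$horizon)
    saveRDS(report, paths[["evaluate"]])
    utils::write.csv(report$perStep,
                     sub("\\.rds$", ".csv", paths[["evaluate"]]),
                     row.names = FALSE)
    jsonlite::write_json(report$summary,
                         sub("\\.rds$", ".json", paths[["evaluate"]]),
                         dataframe = "rows", digits = NA)
  } else say("[evaluate] artifact present, skipping")
  report <- readRDS(paths[["evaluate"]])

  invisible(list(paths = paths, report = report, hash = hash, model = net))
}

#' Wall-clock comparison of surrogate and mechanistic advancement
#'
#' Times, on identical starting configurations, (i) advancing the
#' mechanistic simulation by one horizon (100 MCS) and (ii) one surrogate
#' evaluation.  Results are hardware- and BLAS-dependent by nature and are
#' reported for orientation, never as a correctness gate.
#'
#' @param model a trained [UNetSurrogate-class].
#' @param states list of [LatticeState-class] starting configurations.
#' @param params the [CPMParams-class] for mechanistic advancement.
#' @param horizon MCS advanced per replicate.
#' @param normalization field normalization for the surrogate input frames.
#' @return list with `records` (method, replicate, seconds) and `summary`
#'   (per-method median and s.d. of the wall time, n).
#' @export
benchmarkSurrogate <- function(model, states, params, horizon = 100,
                               normalization = NULL) {
  stopifnot(length(states) >= 1)
  if (is.null(normalization))
    normalization <- if (params@decayRate > 0 && params@secretionRate > 0)
      params@secretionRate / params@decayRate else 1
  rec <- list()
  for (i in seq_along(states)) {
    t0 <- proc.time()[["elapsed"]]
    invisible(runMCS(states[[i]], params, horizon))
    rec[[length(rec) + 1L]] <- data.frame(
      method = "mechanistic", replicate = i,
      seconds = proc.time()[["elapsed"]] - t0)
    fr <- renderFrame(states[[i]], normalization)
    t0 <- proc.time()[["elapsed"]]
    invisible(predictFrame(model, fr))
    rec[[length(rec) + 1L]] <- data.frame(
      method = "surrogate", replicate = i,
      seconds = proc.time()[["elapsed"]] - t0)
  }
  records <- do.call(rbind, rec)
  summary <- do.call(rbind, lapply(split(records, records$method), function(d)
    data.frame(method = d$method[1], n = nrow(d),
               medianSeconds = median(d$seconds), sdSeconds = sd(d$seconds))))
  rownames(summary) <- NULL
  list(records = records, summary = summary)
}
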