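#' Subset a tensor to a task context
#'
#' @param x a [SpikeCountTensor-class].
#' @param person,bodyPart,touchType optional level(s) to keep.
#' @return A [SpikeCountTensor-class] with matching trials.
#' @export
subsetContext <- function(x, person = NULL, bodyPart = NULL, touchType = NULL) {
  td <- as.data.frame(trialData(x))
  keep <- rep(TRUE, nrow(td))
  if (!is.null(person)) keep <- keep & td$person %in% person
  if (!is.null(bodyPart)) keep <- keep & td$bodyPart %in% bodyPart
  if (!is.null(touchType)) keep <- keep & td$touchType %in% touchType
  if (!any(keep)) stop("no trials match the requested context", call. = FALSE)
  x[, which(keep)]
}

#' Demixed-subspace generalization across a held-out dimension
#'
#' For each session, trials at one level of the held-out dimension form the
#' training context; demixed axes for the other two factors are fit there
#' ([fitDemixedAxes()]) and the other level's trials are projected
#' ([projectHeldout()]). Reported per session and marginalization: the
#' separation ratio (test-level separation / training separation) and the
#' train-test latent pattern correlation.
#'
#' @param sessions list of [SpikeCountTensor-class] (multidimensional task).
#' @param heldout `"person"`, `"bodyPart"` or `"touchType"`. For
#'   `"touchType"` the train/test levels are the first two touch types
#'   unless given.
#' @param trainLevel,testLevel levels of the held-out dimension.
#' @return Long `data.frame`: `session`, `marginalization`,
#'   `separationRatio`, `patternCorrelation`.
#' @export
subspaceGeneralization <- function(sessions,
                                   heldout = c("person", "bodyPart",
                                               "touchType"),
                                   trainLevel = NULL, testLevel = NULL) {
  heldout <- match.arg(heldout)
  levs <- switch(heldout, person = PERSONS, bodyPart = BODY_PARTS,
                 touchType = TOUCH_TYPES)
  if (is.null(trainLevel)) trainLevel <- levs[1L]
  if (is.null(testLevel)) testLevel <- levs[2L]
  factors <- setdiff(c("person", "bodyPart", "touchType"), heldout)
  out <- lapply(sessions, function(x) {
    args <- setNames(list(trainLevel), heldout)
    train <- do.call(subsetContext, c(list(x), args))
    args[[heldout]] <- testLevel
    test <- do.call(subsetContext, c(list(x), args))
    fit <- fitDemixedAxes(train, factors = factors)
    proj <- projectHeldout(fit, test)
    trSep <- trainSeparation(fit)
    margs <- rownames(trSep)
    data.frame(session = sessionId(x), marginalization = margs,
               separationRatio = vapply(margs, function(m)
                 proj$separation[[m]][1L] / trSep[m, 1L], 1),
               patternCorrelation = proj$patternCorrelation[margs])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Discrimination-axis transfer across all task dimensions
#'
#' Runs the normalized-generalization analysis for a canonical battery of
#' train/test pairs: touch-type information tested across person and body
#' part, body-part information across person and touch type, and person
#' information across body part and touch type.
#'
#' @param sessions list of [SpikeCountTensor-class] (multidimensional task).
#' @param nResamples,seed see [normalizedGeneralization()].
#' @return Long `data.frame`: `information`, `across`, `session`, `value`.
#' @export
axisTransferSummary <- function(sessions, nResamples = 25L, seed = 1L) {
  lab <- function(p, b, tt) conditionLabel(p, b, tt)
  battery <- list(
    list(info = "touchType", across = "person",
         train = c(lab("actual", "cheek", "pinch"), lab("actual", "cheek", "press")),
         test = c(lab("observed", "cheek", "pinch"), lab("observed", "cheek", "press"))),
    list(info = "touchType", across = "bodyPart",
         train = c(lab("actual", "cheek", "pinch"), lab("actual", "cheek", "press")),
         test = c(lab("actual", "shoulder", "pinch"), lab("actual", "shoulder", "press"))),
    list(info = "bodyPart", across = "person",
         train = c(lab("actual", "cheek", "pinch"), lab("actual", "shoulder", "pinch")),
         test = c(lab("observed", "cheek", "pinch"), lab("observed", "shoulder", "pinch"))),
    list(info = "bodyPart", across = "touchType",
         train = c(lab("actual", "cheek", "pinch"), lab("actual", "shoulder", "pinch")),
         test = c(lab("actual", "cheek", "press"), lab("actual", "shoulder", "press"))),
    list(info = "person", across = "bodyPart",
         train = c(lab("actual", "cheek", "pinch"), lab("observed", "cheek", "pinch")),
         test = c(lab("actual", "shoulder", "pinch"), lab("observed", "shoulder", "pinch"))),
    list(info = "person", across = "touchType",
         train = c(lab("actual", "cheek", "pinch"), lab("observed", "cheek", "pinch")),
         test = c(lab("actual", "cheek", "press"), lab("observed", "cheek", "press"))))
  out <- list()
  for (b in battery) {
    for (x in sessions) {
      g <- normalizedGeneralization(x, b$train, x, b$test,
                                    nResamples = nResamples, seed = seed)
      out[[length(out) + 1L]] <- data.frame(information = b$info,
                                            across = b$across,
                                            session = sessionId(x),
                                            value = g$value)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Derive a per-stage child seed from a global seed
#'
#' Deterministic fan-out so stages can be rerun in isolation: a polynomial
#' hash of the stage name is folded into the global seed modulo 2^31 - 1.
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @return Integer seed.
#' @export
deriveSeed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 99991
  as.integer((as.numeric(seed) * 100003 + h) %% (2^31 - 1))
}

#' Default pipeline configuration
#'
#' Sizes default to the recorded task scale (119 units and 8 sessions for
#' the multidimensional task; 126 and 6 for the basic task) but can be
#' reduced for quick runs.
#'
#' @param task `"BSMT"` or `"MSMT"`.
#' @param seed global seed.
#' @param nUnits,nSessions,trialsPerCondition generator sizes.
#' @param decodeStep decoding window step in seconds (coarsen to speed up).
#' @param nResamples split-half correlation resamples.
#' @return Named list understood by [runAll()].
#' @export
defaultConfig <- function(task = c("MSMT", "BSMT"), seed = 1L,
                          nUnits = if (task == "BSMT") 126L else 119L,
                          nSessions = if (task == "BSMT") 6L else 8L,
                          trialsPerCondition = 10L, decodeStep = 0.1,
                          nResamples = 250L) {
  task <- match.arg(task)
  list(task = task, seed = seed, nUnits = nUnits, nSessions = nSessions,
       trialsPerCondition = trialsPerCondition, decodeStep = decodeStep,
       nResamples = nResamples, q = 0.05, nFolds = 10L,
       timeline = defaultTimeline())
}

#' Run the full analysis pipeline on a simulated dataset
#'
#' Simulates a population, applies unit selection, and runs every stage
#' (tuning, discriminability, split-half correlation, touch-type decoding
#' for the multidimensional task, congruency-model selection, and — for the
#' multidimensional task — subspace and axis-transfer generalization),
#' writing per-stage CSV/JSON outputs and a manifest with content hashes.
#' A fixed config + seed reproduces every output bit-exactly.
#'
#' @param config list from [defaultConfig()].
#' @param outDir output directory (created if needed).
#' @param stages character vector of stages to run (default all).
#' @return Invisibly, the manifest list.
#' @export
runAll <- function(config = defaultConfig(), outDir = "popcongruence-run",
                   stages = c("tuning", "di", "corr", "decode", "models",
                              "subspace", "axis-transfer")) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  msg <- function(...) message(sprintf("[%s] %s",
                                       format(Sys.time(), "%H:%M:%S"),
                                       sprintf(...)))
  task <- config$task
  msg("simulate: task=%s units=%d sessions=%d", task, config$nUnits,
      config$nSessions)
  pop <- generatePopulation(task, nUnits = config$nUnits,
                            nSessions = config$nSessions,
                            trialsPerCondition = config$trialsPerCondition,
                            timeline = config$timeline,
                            seed = deriveSeed(config$seed, "simulate"))
  sessions <- lapply(pop$sessions, function(x) x[selectUnits(x), ])
  saveTruth(pop$truth, file.path(outDir, "truth.csv"))
  mode <- if (task == "BSMT") "binary" else "sp_sharing"
  summaryJson <- list(task = task, seed = config$seed,
                      nUnitsSelected = vapply(sessions, nUnits, 1L))

  if ("tuning" %in% stages) {
    msg("stage tuning")
    tun <- do.call(rbind, lapply(sessions, tuningAnalysis, q = config$q))
    write.csv(tun, file.path(outDir, "tuning.csv"), row.names = FALSE)
    fr <- fractionResponsive(tun, seed = deriveSeed(config$seed, "tuning"))
    write.csv(fr, file.path(outDir, "fraction_responsive.csv"),
              row.names = FALSE)
    summaryJson$fractionResponsive <- setNames(fr$fraction, fr$condition)
  }
  if ("di" %in% stages) {
    msg("stage di")
    di <- do.call(rbind, lapply(sessions, function(x) {
      v <- discriminabilityIndex(x)
      data.frame(session = sessionId(x), condition = names(v),
                 di = as.numeric(v))
    }))
    write.csv(di, file.path(outDir, "discriminability.csv"), row.names = FALSE)
    summaryJson$diMean <- mean(di$di)
  }
  if ("corr" %in% stages) {
    msg("stage corr")
    cms <- lapply(sessions, splithalfCorrelation,
                  nResamples = config$nResamples,
                  seed = deriveSeed(config$seed, "corr"))
    cmAvg <- Reduce(`+`, cms) / length(cms)
    write.csv(cmAvg, file.path(outDir, "correlation_matrix.csv"))
    summaryJson$withinConditionCorr <- mean(diag(cmAvg))
  }
  if ("decode" %in% stages && task == "MSMT") {
    msg("stage decode (field Ac)")
    curves <- lapply(sessions, timeResolvedAccuracy, field = "Ac",
                     step = config$decodeStep)
    dec <- decodingAcrossSessions(curves)
    write.csv(dec, file.path(outDir, "decoding_Ac.csv"), row.names = FALSE)
    summaryJson$peakDecodingAccuracy <- max(dec$mean)
  }
  if ("models" %in% stages) {
    msg("stage models")
    fits <- lapply(sessions, function(x) {
      tl <- timeline(x)
      y <- t(windowRate(x, tl$analysis) - windowRate(x, tl$baseline))
      fitAndSelect(y, as.data.frame(trialData(x)), mode = mode,
                   nFolds = config$nFolds,
                   seed = deriveSeed(config$seed, "models"))
    })
    best <- unlist(lapply(fits, `[[`, "bestByBic"))
    hist <- populationModelHistogram(best, models = fits[[1L]]$models,
                                     mode = mode)
    write.csv(hist, file.path(outDir, "model_histogram.csv"),
              row.names = FALSE)
    catHist <- categoryHistogram(hist)
    write.csv(catHist, file.path(outDir, "category_histogram.csv"),
              row.names = FALSE)
    jsonlite::write_json(lapply(fits[[1L]]$models, as.integer),
                         file.path(outDir, "model_catalog.json"))
    summaryJson$categoryPercent <- setNames(catHist$percent, catHist$category)
  }
  if ("subspace" %in% stages && task == "MSMT") {
    msg("stage subspace")
    sub <- subspaceGeneralization(sessions, heldout = "person")
    write.csv(sub, file.path(outDir, "subspace_generalization.csv"),
              row.names = FALSE)
    summaryJson$subspacePatternCorrelation <-
      vapply(split(sub$patternCorrelation, sub$marginalization), mean, 1)
  }
  if ("axis-transfer" %in% stages && task == "MSMT") {
    msg("stage axis-transfer")
    at <- axisTransferSummary(sessions,
                              seed = deriveSeed(config$seed, "axis-transfer"))
    write.csv(at, file.path(outDir, "axis_transfer.csv"), row.names = FALSE)
    summaryJson$axisTransfer <-
      vapply(split(at$value, paste(at$information, at$across, sep = "/")),
             mean, 1)
  }
  jsonlite::write_json(summaryJson, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- setdiff(list.files(outDir, full.names = TRUE),
                   file.path(outDir, "manifest.json"))
  manifest <- list(config = config[setdiff(names(config), "timeline")],
                   stages = stages,
                   elapsedSec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
                   files = lapply(files, function(f)
                     list(name = basename(f),
                          md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
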