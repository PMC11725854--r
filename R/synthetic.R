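#' Simulate one neuron's spike counts
#'
#' The neuron fires at `baseline` Hz everywhere except during the response
#' window, where conditions whose sensory field belongs to a responsive class
#' add that class's selectivity-pattern increment for the trial's touch type.
#' The response window defaults to the analysis window of the timeline (the
#' 0.5 s offset of that window absorbs stimulus-delivery delay and neural
#' latency), so the expected analysis-window rate is exactly
#' `baseline + SP[touchType]` for responsive fields and `baseline` otherwise.
#'
#' @param baseline baseline rate in Hz (>= 0).
#' @param model canonical congruency assignment (see [enumerateModels()]).
#' @param spPerClass list (length `max(model)`) of selectivity patterns, each
#'   a named numeric vector of Hz increments over `pinch, press, rub, tap`
#'   (a scalar is recycled across touch types).
#' @param trialData data.frame of trial labels (`person`, `bodyPart`,
#'   `touchType`).
#' @param timeline see [defaultTimeline()].
#' @param binWidth bin width in seconds (default 0.01).
#' @param noise `"poisson"` (independent Poisson counts per bin) or
#'   `"gaussian"` (per-trial Gaussian rate jitter with SD `sigmaHz`, spikes
#'   spread multinomially over bins — for closed-form checks on rates).
#' @param sigmaHz Gaussian rate SD in Hz.
#' @param responseWindow seconds pair; default `timeline$analysis`.
#' @return Integer matrix `trials x bins` of spike counts.
#' @export
generateNeuron <- function(baseline, model, spPerClass, trialData,
                           timeline = defaultTimeline(), binWidth = 0.01,
                           noise = c("poisson", "gaussian"), sigmaHz = 1,
                           responseWindow = NULL) {
  noise <- match.arg(noise)
  td <- as.data.frame(trialData)
  if (is.null(responseWindow)) responseWindow <- timeline$analysis
  edges <- seq(timeline$coverage[1L], timeline$coverage[2L], by = binWidth)
  nb <- length(edges) - 1L
  mids <- edges[-length(edges)] + binWidth / 2
  inResp <- mids > responseWindow[1L] & mids < responseWindow[2L]

  spPerClass <- lapply(spPerClass, function(sp) {
    if (length(sp) == 1L) sp <- rep(sp, 4L)
    stopifnot(length(sp) == 4L, all(is.finite(sp)))
    setNames(as.numeric(sp), TOUCH_TYPES)
  })
  inc <- trialIncrements(model, spPerClass, td)
  if (any(baseline + inc < 0))
    stop("negative expected rate: baseline + SP increment must be >= 0",
         call. = FALSE)
  nt <- nrow(td)
  out <- matrix(0L, nt, nb)
  for (i in seq_len(nt)) {
    lam <- rep(baseline, nb)
    lam[inResp] <- baseline + inc[i]
    if (noise == "poisson") {
      out[i, ] <- rpois(nb, lam * binWidth)
    } else {
      # one rate draw per trial for each of the two rate regimes, spikes
      # spread uniformly over the regime's bins
      for (seg in list(which(inResp), which(!inResp))) {
        if (length(seg) == 0L) next
        r <- max(0, lam[seg[1L]] + rnorm(1L, 0, sigmaHz))
        nSpk <- round(r * length(seg) * binWidth)
        if (nSpk > 0)
          out[i, seg] <- out[i, seg] +
            as.integer(rmultinom(1L, nSpk, rep(1, length(seg))))
      }
    }
  }
  out
}

# Hz increment of each trial given a model and its class SPs.
trialIncrements <- function(model, spPerClass, td) {
  field <- sensoryField(td$person, td$bodyPart)
  cls <- model[match(field, names(model))]
  vapply(seq_len(nrow(td)), function(i) {
    if (cls[i] == 0L) return(0)
    sp <- spPerClass[[cls[i]]]
    if (length(sp) == 1L) return(unname(sp))
    unname(sp[td$touchType[i]])
  }, 1)
}

# Canonical trial table for one session of a task.
sessionTrialTable <- function(task, trialsPerCondition, session = 1L) {
  ct <- conditionTable(task)
  td <- ct[rep(seq_len(nrow(ct)), each = trialsPerCondition),
           c("person", "bodyPart", "touchType")]
  td$session <- session
  td$trial <- seq_len(nrow(td))
  rownames(td) <- NULL
  td[, c("session", "trial", "person", "bodyPart", "touchType")]
}

#' Default congruency-model mixture for the generator
#'
#' Majority mass on idiosyncratic/complex assignments with a minority of
#' body-part-specific (mirror-like) congruent models, qualitatively echoing
#' the heterogeneity of recorded populations: 12% body-part specific, 10%
#' invariant, 8% person specific and 10% unresponsive in the basic task
#' (binary); 5% body-part specific in the multidimensional task with the
#' rest spread over the other models.
#'
#' @param task `"BSMT"` or `"MSMT"`.
#' @return Named probability vector over model ids.
#' @export
defaultModelMixture <- function(task = c("MSMT", "BSMT")) {
  task <- match.arg(task)
  mode <- if (task == "BSMT") "binary" else "sp_sharing"
  models <- enumerateModels(4L, mode)
  cats <- vapply(models, categorizeModel, "", mode = mode)
  p <- setNames(numeric(length(models)), names(models))
  if (task == "BSMT") {
    p[cats == "body_part_specific"] <- 0.12 / sum(cats == "body_part_specific")
    p[cats == "invariant"] <- 0.10
    p[cats == "person_specific"] <- 0.08 / sum(cats == "person_specific")
    p[cats == "unresponsive"] <- 0.10
    rest <- cats == "idiosyncratic"
  } else {
    p[cats == "body_part_specific"] <- 0.05 / sum(cats == "body_part_specific")
    p[cats == "invariant"] <- 0.05
    rest <- !(cats %in% c("body_part_specific", "invariant"))
  }
  p[rest] <- (1 - sum(p)) / sum(rest)
  p
}

#' Generate a multi-session population with known congruency models
#'
#' Each session draws a fresh set of units (populations are re-recorded
#' daily). Per unit: a congruency model from `modelMixture`, a baseline rate
#' uniform on `baselineRange`, and an independent selectivity pattern per
#' class with touch-type increments uniform on `spRange`; SNR metadata is
#' drawn from a gamma distribution (shape 4, scale 0.5).
#'
#' @param task `"BSMT"` or `"MSMT"`.
#' @param nUnits units per session (default 119, the multidimensional-task
#'   scale; use 126 for the basic task).
#' @param nSessions number of sessions (default 8; 6 for the basic task).
#' @param trialsPerCondition trials per condition per session (default 10).
#' @param modelMixture named probability vector over model ids; default
#'   [defaultModelMixture()].
#' @param baselineRange Hz range for baselines.
#' @param spRange Hz range for selectivity-pattern increments.
#' @param noise,sigmaHz see [generateNeuron()].
#' @param timeline,binWidth see [generateNeuron()].
#' @param seed integer seed; fixing it fixes the dataset bit-for-bit.
#' @return List with `sessions` (list of [SpikeCountTensor-class]) and
#'   `truth` (data.frame: `session`, `unit`, `model_id`, `baseline_hz`,
#'   `sp_class`, `sp_pinch`, `sp_press`, `sp_rub`, `sp_tap`; one row per
#'   unit and class, `sp_class = 0` for unresponsive units).
#' @export
generatePopulation <- function(task = c("MSMT", "BSMT"), nUnits = 119L,
                               nSessions = 8L, trialsPerCondition = 10L,
                               modelMixture = defaultModelMixture(task),
                               baselineRange = c(1, 10), spRange = c(2, 15),
                               noise = "poisson", sigmaHz = 1,
                               timeline = defaultTimeline(), binWidth = 0.01,
                               seed = 1L) {
  task <- match.arg(task)
  stopifnot(trialsPerCondition >= 2L)
  mode <- if (task == "BSMT") "binary" else "sp_sharing"
  models <- enumerateModels(4L, mode)
  if (!all(names(modelMixture) %in% names(models)))
    stop("modelMixture references unknown model id(s): ",
         paste(setdiff(names(modelMixture), names(models)), collapse = ", "),
         call. = FALSE)
  stopifnot(abs(sum(modelMixture) - 1) < 1e-8)
  set.seed(seed)
  sessions <- vector("list", nSessions)
  truth <- list()
  for (s in seq_len(nSessions)) {
    td <- sessionTrialTable(task, trialsPerCondition, session = s)
    edges <- seq(timeline$coverage[1L], timeline$coverage[2L], by = binWidth)
    cts <- array(0L, dim = c(nUnits, nrow(td), length(edges) - 1L))
    modelIds <- sample(names(modelMixture), nUnits, replace = TRUE,
                       prob = modelMixture)
    snr <- rgamma(nUnits, shape = 4, scale = 0.5)
    for (u in seq_len(nUnits)) {
      m <- models[[modelIds[u]]]
      k <- max(m)
      base <- runif(1L, baselineRange[1L], baselineRange[2L])
      sps <- lapply(seq_len(max(k, 0L)), function(cl)
        setNames(runif(4L, spRange[1L], spRange[2L]), TOUCH_TYPES))
      cts[u, , ] <- generateNeuron(base, m, sps, td, timeline, binWidth,
                                   noise = noise, sigmaHz = sigmaHz)
      rows <- if (k == 0L)
        data.frame(session = s, unit = u, model_id = modelIds[u],
                   baseline_hz = base, sp_class = 0L, sp_pinch = NA_real_,
                   sp_press = NA_real_, sp_rub = NA_real_, sp_tap = NA_real_)
      else do.call(rbind, lapply(seq_len(k), function(cl)
        data.frame(session = s, unit = u, model_id = modelIds[u],
                   baseline_hz = base, sp_class = cl,
                   sp_pinch = sps[[cl]]["pinch"], sp_press = sps[[cl]]["press"],
                   sp_rub = sps[[cl]]["rub"], sp_tap = sps[[cl]]["tap"])))
      truth[[length(truth) + 1L]] <- rows
    }
    sessions[[s]] <- SpikeCountTensor(cts, edges, td,
                                      unitData = data.frame(meanRate = NA_real_,
                                                            snr = snr),
                                      sessionId = s, timeline = timeline)
    # recompute measured mean rate (constructor computed from NA -> redo)
    ud <- as.data.frame(unitData(sessions[[s]]))
    totalDur <- nrow(td) * (max(edges) - min(edges))
    ud$meanRate <- apply(cts, 1L, sum) / totalDur
    sessions[[s]]@unitData <- S4Vectors::DataFrame(ud)
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(sessions = sessions, truth = truth)
}

#' Generate a compositional population
#'
#' Population condition means follow an additive latent structure:
#' `r(c) = baseline + W_body b(c) + W_touch t(c) + kappa W_int i(c) +
#' personGain W_person p(c)` with one-hot level codes and row-centered
#' loading matrices (so each term is a pure effect). The body-by-touch
#' interaction loadings are drawn independently for each person context, so
#' a nonzero `kappa` produces an interaction that does not transfer across
#' actual/observed. With `personSpecific = TRUE` the touch and body loadings
#' themselves are redrawn per person (no shared basic-level code).
#'
#' @param nUnits,nSessions,trialsPerCondition,timeline,binWidth,noise,sigmaHz
#'   as in [generatePopulation()].
#' @param baseline mean baseline rate in Hz.
#' @param loadingSd SD of loading entries in Hz.
#' @param kappa interaction strength multiplier (0 = purely additive).
#' @param personGain strength of the additive person term.
#' @param personSpecific draw separate touch/body loadings per person.
#' @param seed integer seed.
#' @return List with `sessions` (list of [SpikeCountTensor-class]) and
#'   `truth` (per-session list of the loading matrices and the
#'   `units x conditions` expected-rate matrix).
#' @export
generateCompositionalPopulation <- function(nUnits = 119L, nSessions = 8L,
                                            trialsPerCondition = 10L,
                                            baseline = 10, loadingSd = 2,
                                            kappa = 0, personGain = 0,
                                            personSpecific = FALSE,
                                            noise = "poisson", sigmaHz = 1,
                                            timeline = defaultTimeline(),
                                            binWidth = 0.01, seed = 1L) {
  set.seed(seed)
  ct <- conditionTable("MSMT")
  nC <- nrow(ct)
  rowCenter <- function(W) W - rowMeans(W)
  sessions <- vector("list", nSessions)
  truthList <- vector("list", nSessions)
  for (s in seq_len(nSessions)) {
    Wb <- rowCenter(matrix(rnorm(nUnits * 2L, 0, loadingSd), nUnits))
    Wt <- rowCenter(matrix(rnorm(nUnits * 4L, 0, loadingSd), nUnits))
    Wp <- rowCenter(matrix(rnorm(nUnits * 2L, 0, loadingSd), nUnits))
    WbP <- list(actual = Wb, observed = if (personSpecific)
      rowCenter(matrix(rnorm(nUnits * 2L, 0, loadingSd), nUnits)) else Wb)
    WtP <- list(actual = Wt, observed = if (personSpecific)
      rowCenter(matrix(rnorm(nUnits * 4L, 0, loadingSd), nUnits)) else Wt)
    # interaction loadings per person context (8 body x touch combos each),
    # double-centered so they carry no main effects
    mkWi <- function() {
      Wi <- matrix(rnorm(nUnits * 8L, 0, loadingSd), nUnits)
      combo <- expand.grid(touch = TOUCH_TYPES, body = BODY_PARTS)
      for (u in seq_len(nUnits)) {
        m <- matrix(Wi[u, ], nrow = 4L)   # touch x body
        m <- m - rowMeans(m)
        m <- sweep(m, 2L, colMeans(m))
        Wi[u, ] <- as.numeric(m)
      }
      list(W = Wi, combo = combo)
    }
    WiP <- list(actual = mkWi(), observed = mkWi())
    R <- matrix(baseline, nUnits, nC)
    for (ci in seq_len(nC)) {
      p <- ct$person[ci]; b <- ct$bodyPart[ci]; tt <- ct$touchType[ci]
      comboIdx <- which(WiP[[p]]$combo$touch == tt & WiP[[p]]$combo$body == b)
      R[, ci] <- R[, ci] +
        WbP[[p]][, match(b, BODY_PARTS)] +
        WtP[[p]][, match(tt, TOUCH_TYPES)] +
        kappa * WiP[[p]]$W[, comboIdx] +
        personGain * Wp[, match(p, PERSONS)]
    }
    R <- pmax(R, 0.1)
    td <- sessionTrialTable("MSMT", trialsPerCondition, session = s)
    condIdx <- match(conditionLabel(td$person, td$bodyPart, td$touchType),
                     ct$condition)
    edges <- seq(timeline$coverage[1L], timeline$coverage[2L], by = binWidth)
    nb <- length(edges) - 1L
    mids <- edges[-length(edges)] + binWidth / 2
    inResp <- mids > timeline$analysis[1L] & mids < timeline$analysis[2L]
    cts <- array(0L, dim = c(nUnits, nrow(td), nb))
    for (i in seq_len(nrow(td))) {
      lam <- matrix(baseline, nUnits, nb)
      lam[, inResp] <- R[, condIdx[i]]
      if (noise == "poisson") {
        cts[, i, ] <- rpois(length(lam), lam * binWidth)
      } else {
        r <- pmax(0, R[, condIdx[i]] + rnorm(nUnits, 0, sigmaHz))
        nResp <- sum(inResp)
        for (u in seq_len(nUnits)) {
          nSpk <- round(r[u] * nResp * binWidth)
          if (nSpk > 0)
            cts[u, i, inResp] <- as.integer(rmultinom(1L, nSpk, rep(1, nResp)))
          nBase <- round(baseline * (nb - nResp) * binWidth)
          if (nBase > 0)
            cts[u, i, !inResp] <- as.integer(rmultinom(1L, nBase,
                                                       rep(1, nb - nResp)))
        }
      }
    }
    snr <- rgamma(nUnits, shape = 4, scale = 0.5)
    sessions[[s]] <- SpikeCountTensor(cts, edges, td,
                                      unitData = data.frame(
                                        meanRate = apply(cts, 1L, sum) /
                                          (nrow(td) * (max(edges) - min(edges))),
                                        snr = snr),
                                      sessionId = s, timeline = timeline)
    truthList[[s]] <- list(conditionMeans = R, Wb = WbP, Wt = WtP, Wp = Wp,
                           Wi = WiP, kappa = kappa, personGain = personGain)
  }
  list(sessions = sessions, truth = truthList)
}

#' Save a generated population's ground truth
#'
#' @param truth the `truth` data.frame from [generatePopulation()].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
saveTruth <- function(truth, path) {
  write.csv(truth, path, row.names = FALSE)
  invisible(path)
}
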