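#' SpikeCountTensor: trial-aligned binned spike counts
#'
#' Container for one recording session: a `units x trials x bins` array of
#' spike counts in uniform 10 ms bins aligned to stimulus onset, per-trial
#' condition labels, and per-unit metadata (mean firing rate and a
#' signal-to-noise ratio carried as supplied metadata).
#'
#' @slot counts integer array, `units x trials x bins`, nonnegative.
#' @slot binEdges numeric vector of length `bins + 1`, seconds relative to
#'   stimulus onset; uniform, contiguous, half-open bins `[left, right)`.
#' @slot trialData [S4Vectors::DataFrame] with columns `session`, `trial`,
#'   `person`, `bodyPart`, `touchType`.
#' @slot unitData [S4Vectors::DataFrame] with columns `meanRate` (Hz) and
#'   `snr` (dimensionless; may be `NA` if unavailable).
#' @slot sessionId integer scalar.
#' @slot timeline list as returned by [defaultTimeline()].
#'
#' @importClassesFrom S4Vectors DataFrame
#' @exportClass SpikeCountTensor
setClass("SpikeCountTensor",
  slots = c(counts = "array", binEdges = "numeric", trialData = "DataFrame",
            unitData = "DataFrame", sessionId = "integer", timeline = "list"))

setValidity("SpikeCountTensor", function(object) {
  d <- dim(object@counts)
  if (length(d) != 3L) return("counts must be a 3-d array (units x trials x bins)")
  if (any(object@counts < 0)) return("counts must be nonnegative")
  if (any(object@counts != round(object@counts))) return("counts must be integers")
  if (length(object@binEdges) != d[3L] + 1L)
    return("binEdges must have length nBins + 1")
  w <- diff(object@binEdges)
  if (any(w <= 0)) return("binEdges must be strictly increasing")
  if (max(abs(w - w[1L])) > 1e-9) return("bins must be uniform")
  if (nrow(object@trialData) != d[2L])
    return(sprintf("trialData has %d rows but counts has %d trials",
                   nrow(object@trialData), d[2L]))
  if (nrow(object@unitData) != d[1L])
    return(sprintf("unitData has %d rows but counts has %d units",
                   nrow(object@unitData), d[1L]))
  td <- as.data.frame(object@trialData)
  ok <- tryCatch({ validateTrialLabels(td, "trialData"); TRUE },
                 error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) return(ok)
  tab <- table(conditionLabel(td$person, td$bodyPart, td$touchType))
  if (length(unique(as.integer(tab))) > 1L) {
    bad <- names(tab)[which.min(tab)]
    return(sprintf("unbalanced design: condition '%s' has %d trials, others up to %d",
                   bad, min(tab), max(tab)))
  }
  TRUE
})

#' Construct a SpikeCountTensor
#'
#' @param counts `units x trials x bins` array of nonnegative integers.
#' @param binEdges bin edges in seconds relative to stimulus onset.
#' @param trialData data.frame with `session`, `trial`, `person`, `bodyPart`,
#'   `touchType` columns.
#' @param unitData optional data.frame with `meanRate` and `snr`; `meanRate`
#'   is computed from the counts when absent, `snr` defaults to `NA`.
#' @param sessionId session identifier.
#' @param timeline trial timeline, see [defaultTimeline()].
#' @return A validated [SpikeCountTensor-class] object.
#' @export
SpikeCountTensor <- function(counts, binEdges, trialData, unitData = NULL,
                             sessionId = 1L, timeline = defaultTimeline()) {
  storage.mode(counts) <- "integer"
  nu <- dim(counts)[1L]
  if (is.null(unitData)) unitData <- data.frame(row.names = seq_len(nu))
  unitData <- as.data.frame(unitData)
  if (is.null(unitData$meanRate)) {
    totalDur <- dim(counts)[2L] * (max(binEdges) - min(binEdges))
    unitData$meanRate <- apply(counts, 1L, sum) / totalDur
  }
  if (is.null(unitData$snr)) unitData$snr <- NA_real_
  new("SpikeCountTensor", counts = counts, binEdges = as.numeric(binEdges),
      trialData = S4Vectors::DataFrame(as.data.frame(trialData)),
      unitData = S4Vectors::DataFrame(unitData),
      sessionId = as.integer(sessionId), timeline = timeline)
}

#' @describeIn SpikeCountTensor-class number of units
#' @param x,object a `SpikeCountTensor`.
#' @export
nUnits <- function(x) dim(x@counts)[1L]

#' @describeIn SpikeCountTensor-class number of trials
#' @export
nTrials <- function(x) dim(x@counts)[2L]

#' @describeIn SpikeCountTensor-class number of time bins
#' @export
nBins <- function(x) dim(x@counts)[3L]

#' @describeIn SpikeCountTensor-class the count array
#' @importFrom BiocGenerics counts
#' @exportMethod counts
setMethod("counts", "SpikeCountTensor", function(object) object@counts)

#' Accessors for SpikeCountTensor metadata
#'
#' @param x a [SpikeCountTensor-class].
#' @return `trialData()`/`unitData()` return a `DataFrame`; `binEdges()` and
#'   `timeline()` their respective slots; `sessionId()` an integer.
#' @name tensor-accessors
NULL

#' @rdname tensor-accessors
#' @export
trialData <- function(x) x@trialData

#' @rdname tensor-accessors
#' @export
unitData <- function(x) x@unitData

#' @rdname tensor-accessors
#' @export
binEdges <- function(x) x@binEdges

#' @rdname tensor-accessors
#' @export
timeline <- function(x) x@timeline

#' @rdname tensor-accessors
#' @export
sessionId <- function(x) x@sessionId

#' @describeIn SpikeCountTensor-class subset units (i) and/or trials (j)
#' @param i,j unit and trial indices.
#' @param ...,drop ignored (present for generic compatibility).
#' @export
setMethod("[", "SpikeCountTensor",
  function(x, i, j, ..., drop = FALSE) {
    if (missing(i)) i <- seq_len(nUnits(x))
    if (missing(j)) j <- seq_len(nTrials(x))
    initialize(x, counts = x@counts[i, j, , drop = FALSE],
               trialData = x@trialData[j, , drop = FALSE],
               unitData = x@unitData[i, , drop = FALSE])
  })

setMethod("show", "SpikeCountTensor", function(object) {
  d <- dim(object@counts)
  td <- as.data.frame(object@trialData)
  nCond <- length(unique(conditionLabel(td$person, td$bodyPart, td$touchType)))
  cat(sprintf("SpikeCountTensor: %d units x %d trials x %d bins (%.0f ms)\n",
              d[1L], d[2L], d[3L], 1000 * diff(object@binEdges[1:2])))
  cat(sprintf("  session %d, %d conditions, time %.2f..%.2f s\n",
              object@sessionId, nCond, min(object@binEdges), max(object@binEdges)))
})

#' Mean firing rate per unit and trial within a time window
#'
#' The window is snapped outward to the enclosing bin edges (deterministic),
#' and the rate is total spike count in the snapped window divided by its
#' duration.
#'
#' @param x a [SpikeCountTensor-class].
#' @param window numeric length-2, seconds relative to stimulus onset.
#' @return `units x trials` matrix of rates in Hz.
#' @export
windowRate <- function(x, window) {
  stopifnot(length(window) == 2L, window[2L] > window[1L])
  e <- binEdges(x)
  tol <- 1e-9
  if (window[1L] < e[1L] - tol || window[2L] > e[length(e)] + tol)
    stop(sprintf("window [%g, %g] outside tensor coverage [%g, %g]",
                 window[1L], window[2L], e[1L], e[length(e)]), call. = FALSE)
  i1 <- max(which(e <= window[1L] + tol))           # snap left edge outward
  i2 <- min(which(e >= window[2L] - tol))           # snap right edge outward
  bins <- seq.int(i1, i2 - 1L)
  dur <- e[i2] - e[i1]
  apply(counts(x)[, , bins, drop = FALSE], c(1L, 2L), sum) / dur
}

#' Unit-selection mask
#'
#' Units are retained when their mean firing rate exceeds `minRate` and their
#' signal-to-noise ratio exceeds `minSnr` (both strict inequalities).
#'
#' @param x a [SpikeCountTensor-class].
#' @param minRate Hz threshold (default 0.5).
#' @param minSnr SNR threshold (default 0.5); set to `NULL` to disable the
#'   SNR criterion.
#' @return Logical vector of length `nUnits(x)`.
#' @export
selectUnits <- function(x, minRate = 0.5, minSnr = 0.5) {
  ud <- as.data.frame(unitData(x))
  mask <- ud$meanRate > minRate
  if (!is.null(minSnr)) {
    if (anyNA(ud$snr))
      stop("unit SNR metadata is missing; supply unitData$snr or call with minSnr = NULL",
           call. = FALSE)
    mask <- mask & ud$snr > minSnr
  }
  mask
}
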