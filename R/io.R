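#' Save a dataset to HDF5 + CSV (+ optional JSON timeline)
#'
#' Layout: `/counts` (units x trials x bins integer array), `/bin_edges`
#' (float64 seconds), `/unit_meta/mean_rate`, `/unit_meta/snr`,
#' `/session_id`; the trial table is a CSV with header
#' `session,trial,person,body_part,touch_type`.
#'
#' @param x a [SpikeCountTensor-class].
#' @param h5Path output HDF5 file (overwritten).
#' @param trialCsv output CSV path for the trial table.
#' @param configJson optional path for a JSON dump of the timeline.
#' @return Invisibly, `h5Path`.
#' @seealso [loadDataset()]
#' @export
saveDataset <- function(x, h5Path, trialCsv, configJson = NULL) {
  if (file.exists(h5Path)) unlink(h5Path)
  rhdf5::h5createFile(h5Path)
  rhdf5::h5write(counts(x), h5Path, "counts")
  rhdf5::h5write(binEdges(x), h5Path, "bin_edges")
  rhdf5::h5createGroup(h5Path, "unit_meta")
  ud <- as.data.frame(unitData(x))
  rhdf5::h5write(as.numeric(ud$meanRate), h5Path, "unit_meta/mean_rate")
  rhdf5::h5write(as.numeric(ud$snr), h5Path, "unit_meta/snr")
  rhdf5::h5write(sessionId(x), h5Path, "session_id")
  rhdf5::h5closeAll()
  td <- as.data.frame(trialData(x))
  out <- data.frame(session = td$session, trial = td$trial, person = td$person,
                    body_part = td$bodyPart, touch_type = td$touchType)
  write.csv(out, trialCsv, row.names = FALSE, quote = FALSE)
  if (!is.null(configJson))
    jsonlite::write_json(timeline(x), configJson, auto_unbox = TRUE, digits = NA)
  invisible(h5Path)
}

#' Load a dataset from HDF5 + CSV
#'
#' Validates the trial table (required columns, enum membership, balanced
#' trial counts per condition) with errors that name the offending row or
#' condition, and round-trips [saveDataset()] output bit-exactly.
#'
#' @param h5Path HDF5 file written by [saveDataset()] (or following its layout).
#' @param trialCsv CSV trial table with header
#'   `session,trial,person,body_part,touch_type`.
#' @param configJson optional JSON timeline; [defaultTimeline()] when `NULL`.
#' @return A validated [SpikeCountTensor-class].
#' @export
loadDataset <- function(h5Path, trialCsv, configJson = NULL) {
  if (!file.exists(h5Path)) stop("no such file: ", h5Path, call. = FALSE)
  cts <- rhdf5::h5read(h5Path, "counts")
  be <- as.numeric(rhdf5::h5read(h5Path, "bin_edges"))
  meanRate <- as.numeric(rhdf5::h5read(h5Path, "unit_meta/mean_rate"))
  snr <- as.numeric(rhdf5::h5read(h5Path, "unit_meta/snr"))
  sid <- as.integer(rhdf5::h5read(h5Path, "session_id"))
  rhdf5::h5closeAll()
  raw <- read.csv(trialCsv, stringsAsFactors = FALSE)
  required <- c("session", "trial", "person", "body_part", "touch_type")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L)
    stop(sprintf("%s is missing required column(s): %s", trialCsv,
                 paste(missing, collapse = ", ")), call. = FALSE)
  td <- data.frame(session = raw$session, trial = raw$trial,
                   person = raw$person, bodyPart = raw$body_part,
                   touchType = raw$touch_type)
  validateTrialLabels(td, basename(trialCsv))
  if (nrow(td) != dim(cts)[2L])
    stop(sprintf("trial table has %d rows but counts array has %d trials",
                 nrow(td), dim(cts)[2L]), call. = FALSE)
  timeline <- if (is.null(configJson)) defaultTimeline()
              else jsonlite::read_json(configJson, simplifyVector = TRUE)
  SpikeCountTensor(cts, be, td,
                   unitData = data.frame(meanRate = meanRate, snr = snr),
                   sessionId = sid, timeline = timeline)
}

#' Validate a dataset on disk
#'
#' Thin wrapper around [loadDataset()] that reports success or the first
#' validation failure, for command-line use.
#'
#' @inheritParams loadDataset
#' @return `TRUE` invisibly on success (errors otherwise).
#' @export
validateDataset <- function(h5Path, trialCsv, configJson = NULL) {
  x <- loadDataset(h5Path, trialCsv, configJson)
  message(sprintf("OK: %d units, %d trials, %d bins", nUnits(x), nTrials(x),
                  nBins(x)))
  invisible(TRUE)
}
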