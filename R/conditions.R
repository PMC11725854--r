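#' @import methods
#' @importFrom stats aggregate coef cor dist lm median p.adjust pnorm pt qt
#'   quantile rbinom rgamma rmultinom rnorm rpois runif sd setNames t.test var
#' @importFrom utils read.csv write.csv
NULL

# Canonical vocabularies of the factorial touch design. Order is load-bearing:
# it fixes every matrix layout in the package (person-major, then body part,
# then touch type alphabetical).
PERSONS     <- c("actual", "observed")
BODY_PARTS  <- c("cheek", "shoulder")
TOUCH_TYPES <- c("pinch", "press", "rub", "tap")
FIELDS      <- c("Ac", "As", "Oc", "Os")
TASKS       <- c("BSMT", "MSMT")

#' Sensory field (format) of a person/body-part combination
#'
#' The four sensory fields are actual cheek (Ac), actual shoulder (As),
#' observed cheek (Oc) and observed shoulder (Os).
#'
#' @param person character vector, `"actual"` or `"observed"`.
#' @param bodyPart character vector, `"cheek"` or `"shoulder"`.
#' @return Character vector of field codes in `c("Ac","As","Oc","Os")`.
#' @examples
#' sensoryField("actual", "cheek")
#' @export
sensoryField <- function(person, bodyPart) {
  stopifnot(all(person %in% PERSONS), all(bodyPart %in% BODY_PARTS))
  paste0(ifelse(person == "actual", "A", "O"),
         ifelse(bodyPart == "cheek", "c", "s"))
}

#' Canonical condition table for a task
#'
#' Enumerates the cells of the factorial design in canonical order: actual
#' before observed, cheek before shoulder, touch types alphabetical. The
#' basic task (BSMT) crosses person and body part with touch type fixed to
#' rub (4 conditions); the multidimensional task (MSMT) is the full
#' 2 x 2 x 4 factorial (16 conditions).
#'
#' @param task `"BSMT"` or `"MSMT"`.
#' @return A `data.frame` with columns `person`, `bodyPart`, `touchType`,
#'   `field` and `condition` (the canonical label string), one row per cell.
#' @examples
#' nrow(conditionTable("MSMT"))  # 16
#' @export
conditionTable <- function(task = c("MSMT", "BSMT")) {
  task <- match.arg(task)
  tt <- if (task == "BSMT") "rub" else TOUCH_TYPES
  grid <- expand.grid(touchType = tt, bodyPart = BODY_PARTS, person = PERSONS,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("person", "bodyPart", "touchType")]
  grid$field <- sensoryField(grid$person, grid$bodyPart)
  grid$condition <- conditionLabel(grid$person, grid$bodyPart, grid$touchType)
  grid
}

#' @rdname conditionTable
#' @param bodyPart,touchType label components (recycled).
#' @export
conditionLabel <- function(person, bodyPart, touchType) {
  paste(person, bodyPart, touchType, sep = ".")
}

# Validate trial metadata columns against the enums; `where` names the
# offending source (file, argument) in error messages.
validateTrialLabels <- function(df, where = "trial table") {
  required <- c("session", "trial", "person", "bodyPart", "touchType")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop(sprintf("%s is missing required column(s): %s", where,
                 paste(missing, collapse = ", ")), call. = FALSE)
  checkEnum <- function(col, allowed) {
    bad <- which(!(df[[col]] %in% allowed))
    if (length(bad) > 0L)
      stop(sprintf("%s row %d: invalid %s '%s' (allowed: %s)", where, bad[1L],
                   col, df[[col]][bad[1L]], paste(allowed, collapse = ", ")),
           call. = FALSE)
  }
  checkEnum("person", PERSONS)
  checkEnum("bodyPart", BODY_PARTS)
  checkEnum("touchType", TOUCH_TYPES)
  invisible(df)
}

#' Condition factor for trial metadata
#'
#' Maps per-trial labels to a factor whose levels are the canonical condition
#' order of the task (all levels retained even if absent).
#'
#' @param trialData a data.frame-like object with `person`, `bodyPart`,
#'   `touchType` columns.
#' @param task `"BSMT"` or `"MSMT"`; default inferred from the touch types
#'   present (only rub implies BSMT).
#' @return Factor of length `nrow(trialData)`.
#' @export
conditionFactor <- function(trialData, task = NULL) {
  td <- as.data.frame(trialData)
  if (is.null(task))
    task <- if (all(td$touchType == "rub")) "BSMT" else "MSMT"
  levs <- conditionTable(task)$condition
  factor(conditionLabel(td$person, td$bodyPart, td$touchType), levels = levs)
}

#' Default trial timeline
#'
#' Times are seconds relative to stimulus onset. The baseline window is the
#' 1 s preceding onset; the analysis window starts 0.5 s after onset (to
#' absorb delays in delivering the stimulus) and ends 0.5 s after the end of
#' the 3 s stimulation phase.
#'
#' @param stimDuration stimulation duration in seconds.
#' @return List with `baseline`, `stimDuration`, `analysis` and `coverage`
#'   (the minimal time span a tensor must cover).
#' @export
defaultTimeline <- function(stimDuration = 3) {
  list(baseline = c(-1, 0),
       stimDuration = stimDuration,
       analysis = c(0.5, stimDuration + 0.5),
       coverage = c(-1.5, stimDuration + 1))
}
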