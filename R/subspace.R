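#' Condition-mean rates in sliding windows
#'
#' @param x a [SpikeCountTensor-class].
#' @param windows `data.frame` with `start` and `end` columns (seconds), or
#'   `NULL` for the single analysis window.
#' @return `units x conditions x windows` array (conditions in canonical
#'   order among those present).
#' @export
conditionMeanArray <- function(x, windows = NULL) {
  if (is.null(windows)) {
    a <- timeline(x)$analysis
    windows <- data.frame(start = a[1L], end = a[2L])
  }
  condF <- droplevels(conditionFactor(trialData(x)))
  levs <- levels(condF)
  out <- array(0, dim = c(nUnits(x), length(levs), nrow(windows)),
               dimnames = list(NULL, levs, NULL))
  for (w in seq_len(nrow(windows))) {
    r <- windowRate(x, c(windows$start[w], windows$end[w]))
    out[, , w] <- t(rowsum(t(r), condF) / as.numeric(table(condF)))
  }
  out
}

#' Sliding windows for subspace trajectories
#'
#' @param width,step,span window width, step, and first/last start (s).
#' @return `data.frame` with `start` and `end` columns.
#' @export
slidingWindows <- function(width = 0.75, step = 0.1, span = c(-0.5, 2.5)) {
  starts <- seq(span[1L], span[2L], by = step)
  data.frame(start = starts, end = starts + width)
}

#' Marginalize condition means over task factors
#'
#' Decomposes a `units x conditions` matrix of condition means within one
#' training context (e.g. the 2 body parts x 4 touch types of a single
#' person) into the grand mean, the additive marginal effect of each factor,
#' and their interaction. The decomposition is the exact balanced-design
#' ANOVA identity: the parts sum back to the condition means.
#'
#' @param M `units x conditions` matrix.
#' @param condInfo `data.frame` with one column per factor for each column
#'   of `M`.
#' @param factors character length-2 naming the columns of `condInfo` to
#'   marginalize over (default body part and touch type); each needs >= 2
#'   levels present.
#' @return List of `units x conditions` matrices `grand`, one per factor,
#'   and `interaction`, plus `effects` with the per-level effect matrices.
#' @export
marginalizedMeans <- function(M, condInfo,
                              factors = c("bodyPart", "touchType")) {
  M <- as.matrix(M)
  stopifnot(length(factors) == 2L, all(factors %in% names(condInfo)))
  fs <- lapply(factors, function(fc) droplevels(factor(condInfo[[fc]])))
  names(fs) <- factors
  if (any(vapply(fs, nlevels, 1L) < 2L))
    stop("each marginalized factor needs >= 2 levels present", call. = FALSE)
  grand <- rowMeans(M)
  Gm <- matrix(grand, nrow(M), ncol(M))
  effects <- list(); parts <- list()
  for (fc in factors) {
    eff <- t(rowsum(t(M), fs[[fc]]) / as.numeric(table(fs[[fc]]))) - grand
    effects[[fc]] <- eff
    parts[[fc]] <- eff[, as.integer(fs[[fc]]), drop = FALSE]
  }
  Gi <- M - Gm - parts[[1L]] - parts[[2L]]
  c(list(grand = Gm), parts, list(interaction = Gi, effects = effects))
}

#' Fit demixed factor axes on a training context
#'
#' Learns, for each marginalization (body part, touch type, interaction), a
#' small set of unit-space axes capturing that factor's variance in the
#' training context: the condition means per time window are marginalized
#' (see [marginalizedMeans()]) and each marginalization's
#' `units x (conditions * windows)` matrix is reduced by SVD (a
#' demixed-PCA-style objective; decoder = encoder = leading singular
#' vectors). Training latents are the marginalized components projected
#' onto their own axes, so each latent isolates its factor. Because the
#' balanced-design marginalizations are orthogonal, the
#' per-marginalization variance fractions sum to 1.
#'
#' @param x a [SpikeCountTensor-class]; use a single level of the held-out
#'   dimension (e.g. actual-touch trials) as the training context.
#' @param factors character length-2 naming the trial factors to demix
#'   (default body part and touch type; any two of `person`, `bodyPart`,
#'   `touchType`).
#' @param nComp named integer vector of components per marginalization
#'   (default: factor levels - 1, and 3 for the interaction).
#' @param windows see [conditionMeanArray()]; default the analysis window.
#' @return Object of class `demixedAxes`: per-marginalization `axes`
#'   (`units x components`, unit-norm columns), `varianceExplained`, the
#'   training `latents` (`components x conditions x windows`), `condInfo`,
#'   and `windows`.
#' @export
fitDemixedAxes <- function(x, factors = c("bodyPart", "touchType"),
                           nComp = NULL, windows = NULL) {
  A <- conditionMeanArray(x, windows)
  condInfo <- condInfoFromLabels(colnames(A))
  nW <- dim(A)[3L]
  if (is.null(nComp)) {
    nComp <- vapply(factors, function(fc)
      max(1L, length(unique(condInfo[[fc]])) - 1L), 1L)
    nComp <- c(nComp, interaction = 3L)
  }
  if (any(nComp > nUnits(x)))
    stop("more components requested than units available", call. = FALSE)
  margs <- c(factors, "interaction")
  flat <- setNames(vector("list", 3L), margs)
  decs <- vector("list", nW)
  for (w in seq_len(nW)) {
    decs[[w]] <- marginalizedMeans(A[, , w], condInfo, factors)
    for (m in margs)
      flat[[m]] <- cbind(flat[[m]], decs[[w]][[m]])
  }
  totalVar <- sum(vapply(flat, function(M) sum(M^2), 1))
  out <- list(axes = list(), varianceExplained = numeric(0),
              latents = list(), condInfo = condInfo, windows = windows,
              nComp = nComp, factors = factors)
  for (m in margs) {
    k <- min(nComp[[m]], nUnits(x))
    sv <- svd(flat[[m]], nu = k, nv = 0L)
    out$axes[[m]] <- sv$u
    out$varianceExplained[[m]] <- sum(flat[[m]]^2) / totalVar
    lat <- array(0, dim = c(k, ncol(A), nW),
                 dimnames = list(NULL, colnames(A), NULL))
    for (w in seq_len(nW))
      lat[, , w] <- t(sv$u) %*% decs[[w]][[m]]
    out$latents[[m]] <- lat
  }
  names(out$varianceExplained) <- margs
  class(out) <- "demixedAxes"
  out
}

#' Project a held-out context onto learned axes
#'
#' The test-context condition means are marginalized with the training
#' factors (so a uniform context gain does not masquerade as factor
#' structure) and each marginalized component is projected onto the
#' corresponding training axes. For each marginalization the function
#' also reports the level separation (mean distance between factor-level
#' centroids in latent space) per window and, against the training latents,
#' the pattern correlation (Pearson correlation between training and test
#' latent condition patterns, matched on the shared factors).
#'
#' @param fit a `demixedAxes` object.
#' @param x test-context [SpikeCountTensor-class] with the same units.
#' @return List with `latents`, `separation` (per marginalization x window)
#'   and `patternCorrelation` (per marginalization).
#' @export
projectHeldout <- function(fit, x) {
  A <- conditionMeanArray(x, fit$windows)
  if (dim(A)[1L] != nrow(fit$axes[[1L]]))
    stop("unit count mismatch between training axes and test tensor",
         call. = FALSE)
  condInfo <- condInfoFromLabels(colnames(A))
  nW <- dim(A)[3L]
  margs <- names(fit$axes)
  latents <- list(); separation <- list(); pcor <- numeric(0)
  # match train/test conditions on the demixed factors
  key <- do.call(paste, condInfo[fit$factors])
  trainKey <- do.call(paste, fit$condInfo[fit$factors])
  idx <- match(key, trainKey)
  decs <- lapply(seq_len(nW), function(w)
    marginalizedMeans(A[, , w], condInfo, fit$factors))
  for (m in margs) {
    U <- fit$axes[[m]]
    lat <- array(0, dim = c(ncol(U), ncol(A), nW),
                 dimnames = list(NULL, colnames(A), NULL))
    for (w in seq_len(nW))
      lat[, , w] <- t(U) %*% decs[[w]][[m]]
    latents[[m]] <- lat
    separation[[m]] <- vapply(seq_len(nW), function(w)
      levelSeparation(lat[, , w, drop = FALSE], condInfo, m, fit$factors), 1)
    tr <- as.numeric(fit$latents[[m]][, idx, , drop = FALSE])
    te <- as.numeric(lat)
    pcor[[m]] <- if (sd(tr) == 0 || sd(te) == 0) 0 else cor(tr, te)
  }
  names(pcor) <- margs
  list(latents = latents, separation = separation,
       patternCorrelation = pcor)
}

# Factor columns from canonical condition label strings.
condInfoFromLabels <- function(labels) {
  parts <- do.call(rbind, strsplit(labels, ".", fixed = TRUE))
  data.frame(person = parts[, 1L], bodyPart = parts[, 2L],
             touchType = parts[, 3L])
}

# Mean pairwise distance between factor-level centroids in latent space.
levelSeparation <- function(lat, condInfo, marg, factors) {
  lat <- lat[, , 1L, drop = TRUE]
  if (is.null(dim(lat))) lat <- matrix(lat, nrow = 1L)
  groups <- if (marg == "interaction")
    do.call(paste, condInfo[factors]) else condInfo[[marg]]
  cent <- rowsum(t(lat), groups) / as.numeric(table(groups))
  d <- as.matrix(dist(cent))
  mean(d[upper.tri(d)])
}

#' Training-context level separation per marginalization
#'
#' @param fit a `demixedAxes` object.
#' @return Matrix `marginalizations x windows` of separations on the
#'   training latents.
#' @export
trainSeparation <- function(fit) {
  margs <- names(fit$axes)
  nW <- dim(fit$latents[[1L]])[3L]
  out <- matrix(0, length(margs), nW, dimnames = list(margs, NULL))
  for (m in margs)
    for (w in seq_len(nW))
      out[m, w] <- levelSeparation(fit$latents[[m]][, , w, drop = FALSE],
                                   fit$condInfo, m, fit$factors)
  out
}

#' Learn a discrimination axis between two conditions
#'
#' Unit-norm direction in unit space separating a condition pair: the
#' difference of condition means whitened by the pooled per-unit variance
#' (equivalent to LDA with diagonal covariance).
#'
#' @param Xa,Xb `trials x units` rate matrices for the two conditions
#'   (>= 2 trials each).
#' @param varFloor variance floor.
#' @return Unit-norm numeric vector (length = units).
#' @export
learnDiscriminationAxis <- function(Xa, Xb, varFloor = 1e-6) {
  Xa <- as.matrix(Xa); Xb <- as.matrix(Xb)
  stopifnot(nrow(Xa) >= 2L, nrow(Xb) >= 2L)
  d <- colMeans(Xa) - colMeans(Xb)
  v <- (apply(Xa, 2L, var) * (nrow(Xa) - 1L) +
        apply(Xb, 2L, var) * (nrow(Xb) - 1L)) / (nrow(Xa) + nrow(Xb) - 2L)
  w <- d / pmax(v, varFloor)
  nrm <- sqrt(sum(w^2))
  if (nrm == 0)
    stop("cannot learn axis: identical condition means and zero variance",
         call. = FALSE)
  w / nrm
}

#' Normalized generalization of a discrimination axis
#'
#' Cross-validated transfer index: per resample, the training pair's trials
#' are split in half; the axis is learned on one half, the training
#' separation is the (signed) difference of mean projections on the held-out
#' half, and the test separation is the same difference for the test pair's
#' trials. The index is the mean ratio test/train: 1 means the test context
#' separates as well as training data the axis never saw, 0 means no
#' transfer.
#'
#' @param train a [SpikeCountTensor-class] providing the training context.
#' @param trainPair character length-2 of condition labels in `train`.
#' @param test a [SpikeCountTensor-class] for the test context (same units).
#' @param testPair character length-2 of condition labels in `test`.
#' @param nResamples number of half-splits (default 25).
#' @param seed integer seed.
#' @param window rate window; default the analysis window.
#' @return List with `value` (mean index) and `values` (per resample).
#' @export
normalizedGeneralization <- function(train, trainPair, test, testPair,
                                     nResamples = 25L, seed = 1L,
                                     window = NULL) {
  if (nUnits(train) != nUnits(test))
    stop("unit count mismatch between train and test tensors", call. = FALSE)
  if (is.null(window)) window <- timeline(train)$analysis
  ratesTr <- windowRate(train, window)
  ratesTe <- windowRate(test, window)
  cTr <- conditionFactor(trialData(train))
  cTe <- conditionFactor(trialData(test))
  getTrials <- function(rates, condF, cond) {
    idx <- which(condF == cond)
    if (length(idx) < 2L)
      stop("condition '", cond, "' has fewer than 2 trials", call. = FALSE)
    t(rates[, idx, drop = FALSE])
  }
  Xa <- getTrials(ratesTr, cTr, trainPair[1L])
  Xb <- getTrials(ratesTr, cTr, trainPair[2L])
  Ya <- getTrials(ratesTe, cTe, testPair[1L])
  Yb <- getTrials(ratesTe, cTe, testPair[2L])
  set.seed(seed)
  vals <- vapply(seq_len(nResamples), function(i) {
    ha <- sample(nrow(Xa)) <= nrow(Xa) / 2
    hb <- sample(nrow(Xb)) <= nrow(Xb) / 2
    w <- learnDiscriminationAxis(Xa[ha, , drop = FALSE],
                                 Xb[hb, , drop = FALSE])
    dTrain <- mean(Xa[!ha, , drop = FALSE] %*% w) -
      mean(Xb[!hb, , drop = FALSE] %*% w)
    dTest <- mean(Ya %*% w) - mean(Yb %*% w)
    if (abs(dTrain) < 1e-12) return(NA_real_)
    dTest / dTrain
  }, 1)
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L)
    stop("train-pair separation is degenerate in every resample", call. = FALSE)
  list(value = mean(vals), values = vals)
}
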