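#' Train a diagonal-covariance linear discriminant classifier
#'
#' Gaussian classifier in which only the class means differ (shared
#' covariance) and the covariance is diagonal: per-class feature means plus
#' one pooled within-class variance per feature, floored at `varFloor` for
#' features that are silent in a window. Priors are equal (the design is
#' balanced). Ties in the decision rule break toward the earlier class in
#' canonical (factor level) order.
#'
#' @param X `trials x features` matrix of firing rates.
#' @param y class labels (factor or coercible); >= 2 classes, each with
#'   >= 1 trial.
#' @param varFloor variance floor in Hz^2 (default `1e-6`).
#' @return Object of class `diagLda` with `means`, `vars`, `classes`.
#' @export
trainDiagLda <- function(X, y, varFloor = 1e-6) {
  X <- as.matrix(X)
  f <- droplevels(as.factor(y))
  stopifnot(nlevels(f) >= 2L, nrow(X) == length(f))
  nC <- table(f)
  mu <- rowsum(X, f) / as.numeric(nC)
  centered <- X - mu[as.integer(f), , drop = FALSE]
  dfree <- nrow(X) - nlevels(f)
  v <- if (dfree > 0L) colSums(centered^2) / dfree else rep(0, ncol(X))
  v <- pmax(v, varFloor)
  structure(list(means = mu, vars = v, classes = levels(f)),
            class = "diagLda")
}

#' Decision scores and predictions of a diagonal LDA classifier
#'
#' The score of class `c` for a point `x` is the shared-variance Gaussian
#' log-likelihood up to a class-independent constant:
#' `score_c(x) = -0.5 * sum_j (x_j - mu_cj)^2 / v_j`.
#'
#' @param object a `diagLda` fit.
#' @param newX `trials x features` matrix.
#' @param type `"class"` for labels, `"score"` for the score matrix.
#' @param ... unused.
#' @return Character vector of predicted classes, or a `trials x classes`
#'   score matrix.
#' @export
predict.diagLda <- function(object, newX, type = c("class", "score"), ...) {
  type <- match.arg(type)
  newX <- as.matrix(newX)
  K <- nrow(object$means)
  scores <- vapply(seq_len(K), function(k) {
    d <- newX - matrix(object$means[k, ], nrow(newX), ncol(newX), byrow = TRUE)
    -0.5 * as.numeric(d^2 %*% (1 / object$vars))
  }, numeric(nrow(newX)))
  scores <- matrix(scores, nrow = nrow(newX),
                   dimnames = list(NULL, object$classes))
  if (type == "score") return(scores)
  object$classes[apply(scores, 1L, which.max)]   # which.max: first = canonical
}

#' Stratified leave-one-out cross-validated accuracy
#'
#' Every trial is held out once, the classifier is refit on the remainder,
#' and the proportion of correct held-out predictions is returned.
#'
#' @param X `trials x features` matrix.
#' @param y class labels; every class needs >= 2 trials.
#' @param varFloor see [trainDiagLda()].
#' @return Proportion correct in `[0, 1]`.
#' @export
loocvAccuracy <- function(X, y, varFloor = 1e-6) {
  X <- as.matrix(X)
  f <- droplevels(as.factor(y))
  stopifnot(all(table(f) >= 2L))
  n <- nrow(X)
  correct <- logical(n)
  for (i in seq_len(n)) {
    fit <- trainDiagLda(X[-i, , drop = FALSE], f[-i], varFloor)
    correct[i] <- predict(fit, X[i, , drop = FALSE]) == as.character(f[i])
  }
  mean(correct)
}

#' Time-resolved touch-type decoding
#'
#' Sliding-window classification (default 300 ms windows stepped at 10 ms,
#' starting 0.5 s before stimulation onset) of the four touch types within
#' one sensory field, using all units (no selection on significance) and
#' stratified leave-one-out cross-validation.
#'
#' @param x a [SpikeCountTensor-class] of the multidimensional task.
#' @param field sensory field to decode within (`"Ac"`, `"As"`, `"Oc"`,
#'   `"Os"`).
#' @param classVar trial column holding the decoded classes (default
#'   `"touchType"`).
#' @param width window width in seconds.
#' @param step step between window starts in seconds.
#' @param start first window start in seconds.
#' @param stop last window start in seconds (default runs the window end
#'   through stimulation offset + 0.5 s); starts beyond coverage are
#'   truncated with a warning.
#' @param varFloor see [trainDiagLda()].
#' @return `data.frame` with `windowStart` and `accuracy`; attribute
#'   `chance` gives 1/number of classes.
#' @export
timeResolvedAccuracy <- function(x, field = "Ac", classVar = "touchType",
                                 width = 0.3, step = 0.01, start = -0.5,
                                 stop = NULL, varFloor = 1e-6) {
  td <- as.data.frame(trialData(x))
  keep <- sensoryField(td$person, td$bodyPart) == field
  stopifnot(any(keep))
  y <- factor(td[[classVar]][keep])
  e <- binEdges(x)
  if (is.null(stop)) stop <- timeline(x)$stimDuration + 0.5 - width
  maxStart <- e[length(e)] - width
  if (stop > maxStart + 1e-9) {
    warning("window extends beyond tensor coverage; curve truncated")
    stop <- maxStart
  }
  starts <- seq(start, stop + 1e-9, by = step)
  # cumulative counts over bins for O(1) window sums
  cum <- aperm(apply(counts(x)[, keep, , drop = FALSE], c(1L, 2L), cumsum),
               c(2L, 3L, 1L))                       # units x trials x bins
  binW <- diff(e[1:2])
  acc <- vapply(starts, function(s0) {
    i1 <- max(which(e <= s0 + 1e-9))
    i2 <- min(which(e >= s0 + width - 1e-9))
    w <- cum[, , i2 - 1L] - (if (i1 > 1L) cum[, , i1 - 1L] else 0)
    X <- t(w) / (e[i2] - e[i1])
    loocvAccuracy(X, y, varFloor)
  }, 1)
  out <- data.frame(windowStart = starts, accuracy = acc)
  attr(out, "chance") <- 1 / nlevels(y)
  out
}

#' Average decoding curves across sessions
#'
#' @param curves list of [timeResolvedAccuracy()] outputs (one per session).
#' @return `data.frame` with `windowStart`, `mean`, `lo`, `hi` (95% CI
#'   across sessions).
#' @export
decodingAcrossSessions <- function(curves) {
  starts <- curves[[1L]]$windowStart
  accMat <- vapply(curves, function(d) d$accuracy, numeric(length(starts)))
  ci <- t(apply(as.matrix(accMat), 1L, sessionCI))
  data.frame(windowStart = starts, mean = ci[, "mean"], lo = ci[, "lo"],
             hi = ci[, "hi"])
}
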