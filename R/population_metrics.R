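#' Discriminability index against baseline
#'
#' For each condition, the per-unit mean firing rates in the analysis window
#' are concatenated into a vector `A` and the per-unit baseline-window rates
#' into `B`; the index is the standardized difference
#' `DI = (mean(A) - mean(B)) / sqrt((var(A) + var(B)) / 2)`.
#' When both vectors are constant and equal the index is 0; constant unequal
#' vectors are an error (undefined). A cross-validated Mahalanobis variant
#' (split-half mean differences whitened by the pooled diagonal covariance)
#' is available with `method = "mahalanobis"`.
#'
#' @param x a [SpikeCountTensor-class] with >= 2 units.
#' @param conditions condition labels to evaluate (default: all present).
#' @param method `"formula"` (the standardized difference above) or
#'   `"mahalanobis"`.
#' @param nResamples split-half resamples for the Mahalanobis variant.
#' @param seed seed for the Mahalanobis variant.
#' @return Named numeric vector of indices, one per condition.
#' @export
discriminabilityIndex <- function(x, conditions = NULL,
                                  method = c("formula", "mahalanobis"),
                                  nResamples = 50L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(nUnits(x) >= 2L)
  tl <- timeline(x)
  stim <- windowRate(x, tl$analysis)
  base <- windowRate(x, tl$baseline)
  condF <- conditionFactor(trialData(x))
  if (is.null(conditions)) conditions <- levels(droplevels(condF))
  vapply(conditions, function(cc) {
    idx <- which(condF == cc)
    if (length(idx) == 0L) return(NA_real_)
    if (method == "formula") {
      A <- rowMeans(stim[, idx, drop = FALSE])
      B <- rowMeans(base[, idx, drop = FALSE])
      diStandardized(A, B)
    } else {
      cvMahalanobisDI(t(stim[, idx, drop = FALSE]),
                      t(base[, idx, drop = FALSE]), nResamples, seed)
    }
  }, 1)
}

# The printed standardized-difference formula; kept separate so it can be
# applied to arbitrary vectors.
diStandardized <- function(A, B) {
  sA2 <- var(A); sB2 <- var(B)
  num <- mean(A) - mean(B)
  if (sA2 == 0 && sB2 == 0) {
    if (num == 0) return(0)
    stop("discriminability index undefined: zero variance with unequal means",
         call. = FALSE)
  }
  num / sqrt((sA2 + sB2) / 2)
}

# Cross-validated Mahalanobis distance between two trial sets (trials x
# units): mean differences from independent half-splits, whitened by the
# pooled diagonal variance, averaged over resamples. Signed square root.
cvMahalanobisDI <- function(Xa, Xb, nResamples = 50L, seed = 1L) {
  set.seed(seed)
  nA <- nrow(Xa); nB <- nrow(Xb); p <- ncol(Xa)
  v <- (apply(Xa, 2L, var) * (nA - 1L) + apply(Xb, 2L, var) * (nB - 1L)) /
    (nA + nB - 2L)
  v <- pmax(v, 1e-6)
  d2 <- vapply(seq_len(nResamples), function(i) {
    ha <- sample(nA) <= nA / 2
    hb <- sample(nB) <= nB / 2
    d1 <- colMeans(Xa[ha, , drop = FALSE]) - colMeans(Xb[hb, , drop = FALSE])
    d2 <- colMeans(Xa[!ha, , drop = FALSE]) - colMeans(Xb[!hb, , drop = FALSE])
    sum(d1 * d2 / v) / p
  }, 1)
  m <- mean(d2)
  sign(m) * sqrt(abs(m))
}

#' Summarize a per-session statistic with mean and 95% CI
#'
#' @param values numeric vector, one value per session.
#' @return Named vector `mean`, `lo`, `hi` (t-interval; degenerate at the
#'   mean for a single session).
#' @export
sessionCI <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  m <- mean(values)
  if (n < 2L) return(c(mean = m, lo = m, hi = m))
  half <- stats::qt(0.975, n - 1L) * sd(values) / sqrt(n)
  c(mean = m, lo = m - half, hi = m + half)
}

#' Split-half cross-validated population-vector correlation
#'
#' For each resample, the trials of every condition are split in half
#' (ceil/floor for odd counts, the larger half alternating across
#' resamples); each half yields one mean population-rate vector per
#' condition, and entry `(i, j)` is the Pearson correlation between half-1
#' of condition `i` and half-2 of condition `j`, symmetrized and averaged
#' over resamples. The diagonal is the within-condition (noise-ceiling)
#' correlation.
#'
#' @param x a [SpikeCountTensor-class]; every condition needs >= 2 trials.
#' @param nResamples number of random splits (default 250).
#' @param seed integer seed.
#' @return Symmetric correlation matrix with condition dimnames and
#'   attribute `nResamples`.
#' @export
splithalfCorrelation <- function(x, nResamples = 250L, seed = 1L) {
  rates <- windowRate(x, timeline(x)$analysis)   # units x trials
  condF <- droplevels(conditionFactor(trialData(x)))
  levs <- levels(condF)
  idxByCond <- split(seq_along(condF), condF)
  nPer <- lengths(idxByCond)
  if (any(nPer < 2L))
    stop("split-half correlation needs >= 2 trials per condition; offending: ",
         paste(names(nPer)[nPer < 2L], collapse = ", "), call. = FALSE)
  set.seed(seed)
  K <- length(levs)
  acc <- matrix(0, K, K, dimnames = list(levs, levs))
  for (r in seq_len(nResamples)) {
    M1 <- matrix(0, nUnits(x), K)
    M2 <- matrix(0, nUnits(x), K)
    for (ci in seq_len(K)) {
      idx <- sample(idxByCond[[ci]])
      nHalf <- if (r %% 2L == 0L) ceiling(length(idx) / 2) else floor(length(idx) / 2)
      h1 <- idx[seq_len(nHalf)]
      h2 <- idx[-seq_len(nHalf)]
      M1[, ci] <- rowMeans(rates[, h1, drop = FALSE])
      M2[, ci] <- rowMeans(rates[, h2, drop = FALSE])
    }
    R <- suppressWarnings(cor(M1, M2))
    R[is.na(R)] <- 0
    acc <- acc + (R + t(R)) / 2
  }
  out <- acc / nResamples
  attr(out, "nResamples") <- nResamples
  out
}

#' Two-sample test of matched vs mismatched correlations
#'
#' Welch two-sample t-test of session-level correlation values for matched
#' condition pairs against mismatched pairs.
#'
#' @param matched,mismatched numeric vectors of correlation values.
#' @return `htest` object from [stats::t.test].
#' @export
withinBetweenTest <- function(matched, mismatched) {
  stopifnot(length(matched) > 1L, length(mismatched) > 1L)
  if (sd(matched) == 0 && sd(mismatched) == 0)
    stop("degenerate variance: all correlation values identical", call. = FALSE)
  t.test(matched, mismatched)
}

#' Matched / mismatched body-part pair values from a correlation matrix
#'
#' Matched pairs are cross-person pairs with the same body part (the
#' mirror comparison, e.g. actual cheek vs observed cheek); mismatched
#' pairs cross both person and body part.
#'
#' @param cm correlation matrix from [splithalfCorrelation()] on a
#'   basic-task (4-condition) dataset.
#' @return List with `matched` and `mismatched` numeric vectors.
#' @export
bodyPartPairValues <- function(cm) {
  ct <- conditionTable("BSMT")
  stopifnot(all(ct$condition %in% rownames(cm)))
  g <- function(a, b) cm[ct$condition[a], ct$condition[b]]
  # canonical order: actual.cheek, actual.shoulder, observed.cheek, observed.shoulder
  list(matched = c(g(1L, 3L), g(2L, 4L)),
       mismatched = c(g(1L, 4L), g(2L, 3L)))
}
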