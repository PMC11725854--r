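#' Benjamini-Hochberg FDR mask
#'
#' Step-up procedure at level `q`: reject the hypotheses with the `k`
#' smallest p-values where `k` is the largest index with
#' `p_(k) <= k q / m`.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return Logical rejection mask (empty for empty input).
#' @export
fdrCorrect <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0L) return(logical(0))
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  p.adjust(pvalues, method = "BH") <= q
}

#' Per-neuron condition tuning model
#'
#' Ordinary least squares of baseline-subtracted firing rate on condition
#' indicators with no intercept (the zero reference is the pre-stimulus
#' baseline): `FR - baseline = sum_c beta_c X_c`. Coefficients therefore
#' equal per-condition mean modulation; two-sided t-statistics and p-values
#' are reported per condition, with significance from the
#' Benjamini-Hochberg correction across the conditions of the unit.
#'
#' @param stimRates Hz vector, one analysis-window rate per trial.
#' @param baselineRates Hz vector, one baseline-window rate per trial.
#' @param conditions factor (or coercible) of per-trial condition labels;
#'   every level present must have at least 2 trials.
#' @param q FDR level.
#' @return `data.frame` with `condition`, `beta`, `t`, `p`, `significant`.
#' @export
fitConditionModel <- function(stimRates, baselineRates, conditions, q = 0.05) {
  y <- stimRates - baselineRates
  f <- droplevels(as.factor(conditions))
  tab <- table(f)
  if (any(tab < 2L))
    stop("each condition needs >= 2 trials; offending: ",
         paste(names(tab)[tab < 2L], collapse = ", "), call. = FALSE)
  n <- length(y)
  K <- nlevels(f)
  beta <- tapply(y, f, mean)
  dfree <- n - K
  s2 <- sum((y - beta[f])^2) / dfree
  se <- sqrt(s2 / tab)
  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), dfree)
  if (s2 == 0) { tstat[beta != 0] <- Inf * sign(beta[beta != 0]); p[beta != 0] <- 0
                 tstat[beta == 0] <- 0; p[beta == 0] <- 1 }
  data.frame(condition = levels(f), beta = as.numeric(beta),
             t = as.numeric(tstat), p = as.numeric(p),
             significant = fdrCorrect(as.numeric(p), q))
}

#' Tuning analysis for every unit of a session
#'
#' @param x a [SpikeCountTensor-class].
#' @param q FDR level (applied within each unit's set of conditions).
#' @return Long `data.frame`: `session`, `unit`, `condition`, `beta`, `t`,
#'   `p`, `significant`.
#' @export
tuningAnalysis <- function(x, q = 0.05) {
  tl <- timeline(x)
  stim <- windowRate(x, tl$analysis)
  base <- windowRate(x, tl$baseline)
  conds <- conditionFactor(trialData(x))
  out <- lapply(seq_len(nUnits(x)), function(u) {
    fit <- fitConditionModel(stim[u, ], base[u, ], conds, q = q)
    cbind(session = sessionId(x), unit = u, fit)
  })
  do.call(rbind, out)
}

#' Fraction of responsive units per condition, with bootstrap CI
#'
#' Proportions are computed per session and summarized across sessions by
#' their mean and a seeded percentile bootstrap 95% CI (1,000 resamples).
#'
#' @param tuning rbind-ed output of [tuningAnalysis()] over sessions.
#' @param nBoot bootstrap resamples.
#' @param seed bootstrap seed.
#' @return `data.frame`: `condition`, `fraction`, `lo`, `hi`, `nSessions`,
#'   plus attribute `"perSession"` with the session-level proportions.
#' @export
fractionResponsive <- function(tuning, nBoot = 1000L, seed = 1L) {
  stopifnot(nrow(tuning) > 0L)
  per <- aggregate(significant ~ condition + session, data = tuning, FUN = mean)
  set.seed(seed)
  out <- lapply(split(per, per$condition), function(d) {
    v <- d$significant
    bm <- vapply(seq_len(nBoot), function(i) mean(sample(v, replace = TRUE)), 1)
    data.frame(condition = d$condition[1L], fraction = mean(v),
               lo = quantile(bm, 0.025, names = FALSE),
               hi = quantile(bm, 0.975, names = FALSE), nSessions = length(v))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "perSession") <- per
  res
}

#' Event-related averages
#'
#' Mean firing rate in sliding windows (default 750 ms width, 100 ms step,
#' window starts from -0.5 to +2.5 s), per unit and condition, with SEM
#' across trials.
#'
#' @param x a [SpikeCountTensor-class].
#' @param width window width in seconds.
#' @param step step between window starts in seconds.
#' @param span first and last window start in seconds.
#' @return Long `data.frame`: `unit`, `condition`, `windowStart`, `meanHz`,
#'   `semHz`.
#' @export
eventRelatedAverage <- function(x, width = 0.75, step = 0.1,
                                span = c(-0.5, 2.5)) {
  e <- binEdges(x)
  starts <- seq(span[1L], span[2L], by = step)
  if (starts[1L] < e[1L] - 1e-9 || starts[length(starts)] + width > e[length(e)] + 1e-9)
    stop("event-related-average span outside tensor coverage", call. = FALSE)
  conds <- conditionFactor(trialData(x))
  out <- vector("list", length(starts))
  for (w in seq_along(starts)) {
    r <- windowRate(x, c(starts[w], starts[w] + width))   # units x trials
    mu <- t(apply(r, 1L, tapply, conds, mean))
    sem <- t(apply(r, 1L, tapply, conds, function(v) sd(v) / sqrt(length(v))))
    out[[w]] <- data.frame(unit = rep(seq_len(nUnits(x)), ncol(mu)),
                           condition = rep(colnames(mu), each = nrow(mu)),
                           windowStart = starts[w], meanHz = as.numeric(mu),
                           semHz = as.numeric(sem))
  }
  res <- do.call(rbind, out)
  res[!is.na(res$meanHz), ]
}
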