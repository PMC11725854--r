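#' Congruency models across sensory fields
#'
#' A congruency model assigns each sensory field (Ac, As, Oc, Os) either to
#' "unresponsive" (class 0) or to a shared selectivity-pattern class. Two
#' assignments describe the same model iff they induce the same partition of
#' the responsive fields, so models are kept in canonical form: class ids are
#' numbered by first appearance in field order.
#'
#' In `binary` mode every responsive field shares a single class (the 0/1
#' weighting-coefficient scheme of the basic task): with 4 fields there are
#' 2^4 = 16 models including the all-unresponsive one. In `sp_sharing` mode
#' responsive fields are partitioned into classes with distinct selectivity
#' patterns; with 4 fields there are 51 models (the all-unresponsive
#' assignment is excluded).
#'
#' @name congruency-models
NULL

# Canonicalize: renumber nonzero classes by order of first appearance.
canonicalizeAssignment <- function(a) {
  a <- as.integer(a)
  out <- integer(length(a))
  seen <- integer(0)
  for (i in seq_along(a)) {
    if (a[i] == 0L) next
    k <- match(a[i], seen)
    if (is.na(k)) { seen <- c(seen, a[i]); k <- length(seen) }
    out[i] <- k
  }
  out
}

modelId <- function(a) paste(a, collapse = "")

#' Enumerate all congruency models
#'
#' Generates every assignment of fields to `{unresponsive, class 1..n}`,
#' canonicalizes, and removes duplicates.
#'
#' @param nFields number of sensory fields (4 for this task).
#' @param mode `"binary"` (shared 0/1 coefficient; includes the
#'   all-unresponsive model) or `"sp_sharing"` (partition into
#'   selectivity-pattern classes; excludes it).
#' @return Named list of canonical integer assignment vectors (0 =
#'   unresponsive); names are the model ids (digits concatenated in field
#'   order).
#' @examples
#' length(enumerateModels(4, "binary"))      # 16
#' length(enumerateModels(4, "sp_sharing"))  # 51
#' @export
enumerateModels <- function(nFields = 4L, mode = c("sp_sharing", "binary")) {
  mode <- match.arg(mode)
  stopifnot(nFields >= 1L)
  maxClass <- if (mode == "binary") 1L else nFields
  grid <- do.call(expand.grid, rep(list(0:maxClass), nFields))
  canon <- apply(as.matrix(grid), 1L, canonicalizeAssignment)
  canon <- if (is.matrix(canon)) t(canon) else matrix(canon, ncol = 1L)
  ids <- apply(canon, 1L, modelId)
  keep <- !duplicated(ids)
  models <- lapply(which(keep), function(i) {
    a <- canon[i, ]
    if (nFields == 4L) names(a) <- FIELDS
    a
  })
  names(models) <- ids[keep]
  if (mode == "sp_sharing")
    models <- models[names(models) != strrep("0", nFields)]
  # deterministic order: by number of responsive fields, then id
  ord <- order(vapply(models, function(a) sum(a > 0L), 1L), names(models))
  models[ord]
}

#' Design matrix for a congruency model
#'
#' Models are fit on baseline-subtracted firing rates with no intercept, so
#' that all models (including the fully responsive ones) are mutually
#' distinct and full rank. In `binary` mode there is one shared-amplitude
#' column per class (indicator that the trial's field belongs to the class);
#' in `sp_sharing` mode one column per class x touch type. Trials in
#' unresponsive fields load on no column (predicted response 0).
#'
#' @param model canonical assignment vector (see [enumerateModels()]).
#' @param trialData data.frame with `person`, `bodyPart`, `touchType`.
#' @param mode `"binary"` or `"sp_sharing"`.
#' @return Numeric matrix `trials x parameters` (possibly 0 columns for the
#'   all-unresponsive model).
#' @export
designMatrix <- function(model, trialData, mode = c("sp_sharing", "binary")) {
  mode <- match.arg(mode)
  td <- as.data.frame(trialData)
  field <- sensoryField(td$person, td$bodyPart)
  fieldClass <- model[match(field, names(model))]
  k <- max(model)
  if (k == 0L)
    return(matrix(0, nrow = nrow(td), ncol = 0L))
  cols <- list()
  for (cl in seq_len(k)) {
    inClass <- as.numeric(fieldClass == cl)
    if (mode == "binary") {
      cols[[sprintf("class%d", cl)]] <- inClass
    } else {
      for (tt in TOUCH_TYPES) {
        nm <- sprintf("class%d.%s", cl, tt)
        cols[[nm]] <- inClass * as.numeric(td$touchType == tt)
      }
    }
  }
  X <- do.call(cbind, cols)
  # BSMT designs only contain rub trials: drop touch-type columns that are
  # structurally empty (all-zero on every trial of the design).
  X[, colSums(X != 0) > 0L | rep(mode == "binary", ncol(X)), drop = FALSE]
}

#' Fit all candidate congruency models and select the best
#'
#' Each model is fit by ordinary least squares to baseline-subtracted
#' analysis-window rates. Selection uses the Bayesian information criterion,
#' `BIC = n log(RSS/n) + k log(n)` with `k` the number of regression
#' coefficients, and the cross-validated coefficient of determination from
#' condition-stratified K-fold cross-validation,
#' `cvR2 = 1 - sum((y - yhat_heldout)^2) / sum((y - mean(y))^2)`.
#' Ties (within `1e-8`) break toward fewer parameters, then canonical order.
#'
#' @param rates `trials x units` matrix (or vector for one unit) of
#'   baseline-subtracted rates in Hz.
#' @param trialData data.frame with `person`, `bodyPart`, `touchType`.
#' @param mode `"binary"` or `"sp_sharing"`.
#' @param models candidate list from [enumerateModels()].
#' @param nFolds folds for cvR2 (default 10).
#' @param seed seed for the fold assignment.
#' @return List with `bic` and `cvr2` (`models x units` matrices),
#'   `bestByBic`, `bestByCvr2` (model-id character vectors, `NA` for
#'   zero-variance units), `zeroVariance` (logical), `coefficients` (list of
#'   per-model coefficient matrices) and `models`.
#' @export
fitAndSelect <- function(rates, trialData, mode = c("sp_sharing", "binary"),
                         models = enumerateModels(4L, mode), nFolds = 10L,
                         seed = 1L) {
  mode <- match.arg(mode)
  Y <- as.matrix(rates)
  td <- as.data.frame(trialData)
  n <- nrow(Y)
  stopifnot(nrow(td) == n)
  cond <- conditionFactor(td)
  nPar <- vapply(models, function(m) ncol(designMatrix(m, td, mode)), 1L)

  # stratified folds: within each condition, trials are dealt round-robin
  # over folds in a seeded random order
  set.seed(seed)
  fold <- integer(n)
  for (cc in levels(droplevels(cond))) {
    idx <- sample(which(cond == cc))
    fold[idx] <- rep_len(seq_len(nFolds), length(idx))
  }

  rssFit <- function(X, Ytr, Yte = NULL, Xte = NULL) {
    if (ncol(X) == 0L) {
      pred <- matrix(0, nrow = if (is.null(Yte)) nrow(Ytr) else nrow(Yte),
                     ncol = ncol(Ytr))
      resid <- (if (is.null(Yte)) Ytr else Yte) - pred
      return(list(coef = matrix(0, 0L, ncol(Ytr)), resid = resid))
    }
    qrX <- qr(X)
    B <- qr.coef(qrX, Ytr)
    B[is.na(B)] <- 0
    pred <- (if (is.null(Xte)) X else Xte) %*% B
    list(coef = B, resid = (if (is.null(Yte)) Ytr else Yte) - pred)
  }

  nm <- length(models)
  nuU <- ncol(Y)
  bic <- matrix(NA_real_, nm, nuU, dimnames = list(names(models), colnames(Y)))
  cvr2 <- bic
  coefs <- vector("list", nm); names(coefs) <- names(models)
  sstot <- colSums(sweep(Y, 2L, colMeans(Y))^2)
  for (mi in seq_len(nm)) {
    X <- designMatrix(models[[mi]], td, mode)
    full <- rssFit(X, Y)
    rss <- colSums(full$resid^2)
    # floor numerically-zero residuals so exact fits tie (and the tie breaks
    # toward fewer parameters) instead of ranking on rounding dust
    rss <- pmax(rss, sstot * 1e-12, 1e-300)
    bic[mi, ] <- n * log(rss / n) + nPar[mi] * log(n)
    coefs[[mi]] <- full$coef
    ssres <- numeric(nuU)
    for (f in seq_len(nFolds)) {
      te <- fold == f
      if (!any(te)) next
      cvfit <- rssFit(X[!te, , drop = FALSE], Y[!te, , drop = FALSE],
                      Y[te, , drop = FALSE], X[te, , drop = FALSE])
      ssres <- ssres + colSums(cvfit$resid^2)
    }
    cvr2[mi, ] <- 1 - ssres / sstot
  }

  zeroVar <- sstot <= 1e-12
  pickBest <- function(score, decreasing) {
    apply(score, 2L, function(s) {
      best <- if (decreasing) max(s) else min(s)
      cand <- which(abs(s - best) <= 1e-8)
      cand <- cand[order(nPar[cand], cand)]          # fewest parameters wins
      names(models)[cand[1L]]
    })
  }
  bestByBic <- pickBest(bic, decreasing = FALSE)
  bestByCvr2 <- pickBest(cvr2, decreasing = TRUE)
  bestByBic[zeroVar] <- NA_character_
  bestByCvr2[zeroVar] <- NA_character_
  list(bic = bic, cvr2 = cvr2, bestByBic = bestByBic, bestByCvr2 = bestByCvr2,
       zeroVariance = zeroVar, coefficients = coefs, models = models)
}

#' Categorize a congruency model
#'
#' Basic-task (binary) categories follow the four-way scheme: `invariant`
#' (all fields responsive with one shared coefficient), `body_part_specific`
#' (responsive to one body part in both persons — the mirror-like pattern),
#' `person_specific` (responsive to both body parts of one person),
#' `idiosyncratic` (all other responsive patterns), plus `unresponsive` for
#' the all-zero model.
#'
#' The multidimensional-task (sp_sharing) mapping uses eight structural
#' categories (the package's own taxonomy): `invariant` (all four fields,
#' one class), `body_part_specific` (classes are cross-person body-part
#' pairs), `person_specific` (classes are within-person pairs),
#' `single_field` (one responsive field), `three_field_one_class`,
#' `two_class_other`, `idiosyncratic` (everything else), `unresponsive`.
#'
#' @param model canonical assignment vector.
#' @param mode `"binary"` or `"sp_sharing"`.
#' @return Category string.
#' @export
categorizeModel <- function(model, mode = c("sp_sharing", "binary")) {
  mode <- match.arg(mode)
  a <- as.integer(model)
  stopifnot(length(a) == 4L)           # field order Ac, As, Oc, Os
  resp <- which(a > 0L)
  k <- max(a)
  if (length(resp) == 0L) return("unresponsive")
  classes <- lapply(seq_len(k), function(cl) which(a == cl))
  bodyPairs <- list(c(1L, 3L), c(2L, 4L))   # {Ac,Oc}, {As,Os}
  personPairs <- list(c(1L, 2L), c(3L, 4L)) # {Ac,As}, {Oc,Os}
  isPairSet <- function(pairs)
    all(vapply(classes, function(cl)
      any(vapply(pairs, function(p) identical(sort(cl), p), TRUE)), TRUE))
  if (mode == "binary") {
    if (length(resp) == 4L) return("invariant")
    if (isPairSet(bodyPairs)) return("body_part_specific")
    if (isPairSet(personPairs)) return("person_specific")
    return("idiosyncratic")
  }
  if (length(resp) == 4L && k == 1L) return("invariant")
  if (isPairSet(bodyPairs)) return("body_part_specific")
  if (isPairSet(personPairs)) return("person_specific")
  if (length(resp) == 1L) return("single_field")
  if (length(resp) == 3L && k == 1L) return("three_field_one_class")
  if (k == 2L) return("two_class_other")
  "idiosyncratic"
}

#' Population histogram of best models and categories
#'
#' @param fit result of [fitAndSelect()], or a character vector of best model
#'   ids.
#' @param models candidate list (required when `fit` is a character vector).
#' @param mode `"binary"` or `"sp_sharing"`.
#' @param criterion `"bic"` or `"cvr2"` (ignored for character input).
#' @return `data.frame` with `model`, `category`, `count`, `percent`, one row
#'   per model with nonzero count plus one `NA`-model row for zero-variance
#'   units if any.
#' @export
populationModelHistogram <- function(fit, models = NULL,
                                     mode = c("sp_sharing", "binary"),
                                     criterion = c("bic", "cvr2")) {
  mode <- match.arg(mode)
  criterion <- match.arg(criterion)
  if (is.list(fit) && !is.null(fit$models)) {
    models <- fit$models
    best <- if (criterion == "bic") fit$bestByBic else fit$bestByCvr2
  } else best <- as.character(fit)
  stopifnot(!is.null(models))
  tab <- table(factor(best, levels = names(models)), useNA = "ifany")
  cats <- vapply(models, categorizeModel, "", mode = mode)
  out <- data.frame(model = names(tab),
                    category = c(cats, if (anyNA(names(tab))) "unresponsive")[
                      seq_along(tab)],
                    count = as.integer(tab))
  out$category[is.na(out$model)] <- "unresponsive"
  out$percent <- 100 * out$count / sum(out$count)
  out[out$count > 0L | !is.na(out$model), ]
}

#' Category percentages from a model histogram
#'
#' @param hist output of [populationModelHistogram()].
#' @return `data.frame` with `category`, `count`, `percent`.
#' @export
categoryHistogram <- function(hist) {
  agg <- aggregate(count ~ category, data = hist, FUN = sum)
  agg$percent <- 100 * agg$count / sum(agg$count)
  agg
}
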