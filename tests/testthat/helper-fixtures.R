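# Fixtures are built in code. Noiseless tensors use 0.5 s bins so that
# constant rates map to integer per-bin counts (rate * 0.5 must be integer).

noiselessTensor <- function(condRates, trialsPerCondition = 2L,
                            task = "MSMT", baselineRates = 0,
                            timeline = defaultTimeline()) {
  ct <- conditionTable(task)
  stopifnot(ncol(condRates) == nrow(ct))
  nu <- nrow(condRates)
  baselineRates <- rep(baselineRates, length.out = nu)
  td <- data.frame(
    session = 1L, trial = seq_len(nrow(ct) * trialsPerCondition),
    person = rep(ct$person, each = trialsPerCondition),
    bodyPart = rep(ct$bodyPart, each = trialsPerCondition),
    touchType = rep(ct$touchType, each = trialsPerCondition))
  edges <- seq(timeline$coverage[1L], timeline$coverage[2L], by = 0.5)
  nb <- length(edges) - 1L
  mids <- edges[-length(edges)] + 0.25
  inResp <- mids > timeline$analysis[1L] & mids < timeline$analysis[2L]
  condIdx <- rep(seq_len(nrow(ct)), each = trialsPerCondition)
  cts <- array(0L, dim = c(nu, nrow(td), nb))
  for (i in seq_len(nrow(td))) {
    lam <- matrix(rep(baselineRates, nb), nu, nb)
    lam[, inResp] <- condRates[, condIdx[i]]
    stopifnot(all(lam * 0.5 == round(lam * 0.5)))
    cts[, i, ] <- as.integer(lam * 0.5)
  }
  SpikeCountTensor(cts, edges, td,
                   unitData = data.frame(meanRate = rowMeans(condRates) + 1,
                                         snr = 1),
                   sessionId = 1L, timeline = timeline)
}

# Independent brute-force count of SP-sharing models: enumerate all
# labelings field -> {0, 1..n}, reduce each to (responsive set, partition)
# via sorted class blocks, count distinct.
bruteForceModelCount <- function(n) {
  grid <- do.call(expand.grid, rep(list(0:n), n))
  key <- apply(as.matrix(grid), 1L, function(a) {
    blocks <- split(which(a > 0), a[a > 0])
    blocks <- blocks[order(vapply(blocks, min, 1L))]
    paste(vapply(blocks, paste, "", collapse = ","), collapse = "|")
  })
  length(unique(key[key != ""]))
}

# Independent oracle: naive Bayes with shared per-feature variance, written
# with explicit loops.
naiveBayesSharedVarScores <- function(train, yTrain, test, varFloor = 1e-6) {
  classes <- levels(droplevels(as.factor(yTrain)))
  mu <- sapply(classes, function(cl)
    colMeans(train[yTrain == cl, , drop = FALSE]))
  ss <- 0; n <- 0
  for (cl in classes) {
    Xc <- train[yTrain == cl, , drop = FALSE]
    for (i in seq_len(nrow(Xc))) ss <- ss + (Xc[i, ] - mu[, cl])^2
    n <- n + nrow(Xc)
  }
  v <- pmax(ss / (n - length(classes)), varFloor)
  out <- matrix(0, nrow(test), length(classes),
                dimnames = list(NULL, classes))
  for (i in seq_len(nrow(test)))
    for (k in seq_along(classes))
      out[i, k] <- -0.5 * sum((test[i, ] - mu[, k])^2 / v)
  out
}

# Bell numbers via the Bell triangle (independent of the enumeration code).
bellNumbers <- function(maxN) {
  b <- numeric(maxN + 1L); b[1L] <- 1
  row <- 1
  for (n in seq_len(maxN)) {
    newRow <- numeric(n + 1L)
    newRow[1L] <- row[length(row)]
    for (k in seq_len(n)) newRow[k + 1L] <- newRow[k] + row[k]
    b[n + 1L] <- newRow[1L]
    row <- newRow
  }
  b   # b[k+1] = Bell(k)
}
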