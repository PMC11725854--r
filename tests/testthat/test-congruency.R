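test_that("model enumeration matches brute force and the subset-Bell formula", {
  expect_length(enumerateModels(4L, "binary"), 16L)
  expect_length(enumerateModels(4L, "sp_sharing"), 51L)
  expect_length(enumerateModels(2L, "sp_sharing"), 4L)
  expect_length(enumerateModels(3L, "sp_sharing"), 14L)
  bell <- bellNumbers(5L)
  for (n in 1:5) {
    formulaCount <- sum(vapply(1:n, function(k) choose(n, k) * bell[k + 1L], 1))
    expect_length(enumerateModels(n, "sp_sharing"), formulaCount)
    expect_equal(length(enumerateModels(n, "sp_sharing")),
                 bruteForceModelCount(n))
    expect_length(enumerateModels(n, "binary"), 2^n)
  }
  # canonical form and uniqueness
  ids <- names(enumerateModels(4L, "sp_sharing"))
  expect_false(any(duplicated(ids)))
  expect_equal(popcongruence:::canonicalizeAssignment(c(2L, 2L, 0L, 1L)),
               c(1L, 1L, 0L, 2L))
})

test_that("design matrices have the documented shapes and full rank", {
  td <- conditionTable("MSMT")
  td <- data.frame(person = rep(td$person, each = 2L),
                   bodyPart = rep(td$bodyPart, each = 2L),
                   touchType = rep(td$touchType, each = 2L))
  allOne <- setNames(c(1L, 1L, 1L, 1L), c("Ac", "As", "Oc", "Os"))
  X <- designMatrix(allOne, td, "sp_sharing")
  expect_equal(ncol(X), 4L)   # one column per touch type, single class
  acOnly <- setNames(c(1L, 0L, 0L, 0L), names(allOne))
  X2 <- designMatrix(acOnly, td, "sp_sharing")
  expect_equal(ncol(X2), 4L)
  isAc <- td$person == "actual" & td$bodyPart == "cheek"
  expect_true(all(rowSums(X2[!isAc, , drop = FALSE]) == 0))
  expect_true(all(rowSums(X2[isAc, , drop = FALSE]) == 1))
  # exhaustive rank audit on the balanced design
  for (m in enumerateModels(4L, "sp_sharing")) {
    Xm <- designMatrix(m, td, "sp_sharing")
    expect_equal(qr(Xm)$rank, ncol(Xm))
  }
  for (m in enumerateModels(4L, "binary")) {
    Xm <- designMatrix(m, td, "binary")
    expect_equal(qr(Xm)$rank, ncol(Xm))
  }
})

test_that("noiseless neurons are recovered exactly with cvR2 = 1", {
  td <- popcongruence:::sessionTrialTable("MSMT", 2L)
  models <- enumerateModels(4L, "sp_sharing")
  for (mid in c("1111", "1122", "1000", "1234")) {
    m <- models[[mid]]
    sps <- lapply(seq_len(max(m)), function(cl)
      setNames(c(2, 6, 10, 14) + 3 * cl, c("pinch", "press", "rub", "tap")))
    y <- popcongruence:::trialIncrements(m, sps, td)
    fit <- fitAndSelect(y, td, mode = "sp_sharing")
    expect_equal(unname(fit$bestByBic), mid)
    expect_equal(unname(fit$cvr2[mid, 1L]), 1, tolerance = 1e-10)
  }
})

test_that("pure-noise neurons select parsimonious models with cvR2 at or below zero", {
  td <- popcongruence:::sessionTrialTable("MSMT", 10L)
  set.seed(23L)
  Y <- matrix(rnorm(160L * 200L), 160L)
  fit <- fitAndSelect(Y, td, mode = "sp_sharing", seed = 2L)
  nPar <- vapply(fit$models, function(m)
    ncol(designMatrix(m, td, "sp_sharing")), 1L)
  chosen <- nPar[fit$bestByBic]
  expect_gt(mean(chosen == min(nPar)), 0.6)  # mostly the 4-parameter models
  expect_lte(median(chosen), min(nPar))
  cvBest <- vapply(seq_len(ncol(Y)), function(u)
    fit$cvr2[fit$bestByCvr2[u], u], 1)
  expect_lte(median(cvBest), 0.02)
})

test_that("model selection is invariant to trial order and unit relabeling", {
  set.seed(24L)
  td <- popcongruence:::sessionTrialTable("MSMT", 5L)
  models <- enumerateModels(4L, "sp_sharing")
  m <- models[["1122"]]
  sps <- list(setNames(c(10, 2, 2, 2), c("pinch", "press", "rub", "tap")),
              setNames(c(2, 2, 10, 6), c("pinch", "press", "rub", "tap")))
  y <- popcongruence:::trialIncrements(m, sps, td) + rnorm(nrow(td), 0, 0.5)
  fit1 <- fitAndSelect(y, td, mode = "sp_sharing", seed = 5L)
  perm <- sample(nrow(td))
  fit2 <- fitAndSelect(y[perm], td[perm, ], mode = "sp_sharing", seed = 5L)
  expect_identical(unname(fit1$bestByBic), unname(fit2$bestByBic))
  Y <- cbind(a = y, b = y + rnorm(length(y), 0, 0.1))
  fit3 <- fitAndSelect(Y, td, mode = "sp_sharing", seed = 5L)
  fit4 <- fitAndSelect(Y[, 2:1], td, mode = "sp_sharing", seed = 5L)
  expect_identical(unname(fit3$bestByBic), unname(rev(fit4$bestByBic)))
})

test_that("BIC prefers the generative model over supersets at task size", {
  set.seed(25L)
  td <- popcongruence:::sessionTrialTable("MSMT", 10L)
  m <- enumerateModels(4L, "sp_sharing")[["1100"]]  # nested in e.g. 1122, 1111
  sps <- list(setNames(c(8, 2, 12, 4), c("pinch", "press", "rub", "tap")))
  mu <- popcongruence:::trialIncrements(m, sps, td)
  Y <- matrix(rnorm(160L * 100L, mu, 2), 160L)
  fit <- fitAndSelect(Y, td, mode = "sp_sharing", seed = 6L)
  expect_gt(mean(fit$bestByBic == "1100"), 0.9)
})

test_that("categorization follows the structural rules", {
  f <- c("Ac", "As", "Oc", "Os")
  expect_equal(categorizeModel(setNames(c(1L, 2L, 1L, 2L), f)), "body_part_specific")
  expect_equal(categorizeModel(setNames(c(1L, 1L, 1L, 1L), f)), "invariant")
  expect_equal(categorizeModel(setNames(c(1L, 1L, 2L, 2L), f)), "person_specific")
  expect_equal(categorizeModel(setNames(c(1L, 0L, 1L, 0L), f)), "body_part_specific")
  expect_equal(categorizeModel(setNames(c(0L, 1L, 0L, 1L), f)), "body_part_specific")
  expect_equal(categorizeModel(setNames(c(1L, 0L, 0L, 0L), f)), "single_field")
  expect_equal(categorizeModel(setNames(c(1L, 1L, 1L, 0L), f)), "three_field_one_class")
  expect_equal(categorizeModel(setNames(c(1L, 1L, 1L, 2L), f)), "two_class_other")
  expect_equal(categorizeModel(setNames(c(1L, 2L, 3L, 4L), f)), "idiosyncratic")
  expect_equal(categorizeModel(setNames(c(0L, 0L, 0L, 0L), f), "binary"), "unresponsive")
  # binary scheme
  expect_equal(categorizeModel(setNames(c(1L, 1L, 1L, 1L), f), "binary"), "invariant")
  expect_equal(categorizeModel(setNames(c(1L, 0L, 1L, 0L), f), "binary"), "body_part_specific")
  expect_equal(categorizeModel(setNames(c(1L, 1L, 0L, 0L), f), "binary"), "person_specific")
  expect_equal(categorizeModel(setNames(c(1L, 0L, 0L, 1L), f), "binary"), "idiosyncratic")
  # every enumerated model maps to exactly one category
  for (mode in c("binary", "sp_sharing")) {
    cats <- vapply(enumerateModels(4L, mode), categorizeModel, "", mode = mode)
    expect_true(all(nzchar(cats)))
  }
})

test_that("histograms concentrate on generative categories for a mirror-rich population", {
  set.seed(26L)
  models <- enumerateModels(4L, "binary")
  mix <- setNames(rep(0, 16L), names(models))
  cats <- vapply(models, categorizeModel, "", mode = "binary")
  mix[cats == "body_part_specific"] <- 0.12 / 2
  mix[cats == "invariant"] <- 0.30
  mix["1000"] <- 0.38; mix["0010"] <- 0.20
  pop <- generatePopulation("BSMT", nUnits = 200L, nSessions = 1L,
                            modelMixture = mix, baselineRange = c(3, 3),
                            spRange = c(8, 14), seed = 27L)
  x <- pop$sessions[[1L]]
  tl <- timeline(x)
  y <- t(windowRate(x, tl$analysis) - windowRate(x, tl$baseline))
  fit <- fitAndSelect(y, as.data.frame(trialData(x)), mode = "binary",
                      seed = 7L)
  hist <- populationModelHistogram(fit, mode = "binary")
  catHist <- categoryHistogram(hist)
  bps <- catHist$percent[catHist$category == "body_part_specific"] / 100
  # generator truth: 12% mirror-like, binomial 3-sigma band at n = 200
  expect_lt(abs(bps - 0.12), 3 * sqrt(0.12 * 0.88 / 200) + 0.02)
})
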