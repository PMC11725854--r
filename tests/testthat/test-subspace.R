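test_that("marginalization is an exact linear decomposition", {
  set.seed(41L)
  ct <- conditionTable("MSMT")
  act <- ct$person == "actual"
  for (rep in 1:10) {
    M <- matrix(rnorm(30L * 8L, 5, 3), 30L)
    dec <- marginalizedMeans(M, ct[act, ])
    recon <- dec$grand + dec$bodyPart + dec$touchType + dec$interaction
    expect_equal(recon, M, tolerance = 1e-10, ignore_attr = TRUE)
    # balanced-design orthogonality: component energies sum to total
    tot <- sum((M - dec$grand)^2)
    parts <- sum(dec$bodyPart^2) + sum(dec$touchType^2) + sum(dec$interaction^2)
    expect_equal(parts, tot, tolerance = 1e-8)
  }
  expect_error(marginalizedMeans(matrix(1, 2, 4), ct[1:4, ]), ">= 2 levels")
})

test_that("pure-factor populations put their variance in the right marginal", {
  ct <- conditionTable("MSMT")
  act <- which(ct$person == "actual")
  nu <- 30L
  set.seed(42L)
  # touch-type-only coding: condition means depend only on touch type
  Wt <- matrix(rnorm(nu * 4L), nu)
  M <- Wt[, match(ct$touchType[act], c("pinch", "press", "rub", "tap"))]
  dec <- marginalizedMeans(M, ct[act, ])
  expect_lt(sum(dec$bodyPart^2), 1e-20)
  expect_lt(sum(dec$interaction^2), 1e-20)
  expect_gt(sum(dec$touchType^2), 1)
})

test_that("demixed axes recover a rank-1 factor signal", {
  ct <- conditionTable("MSMT")
  act <- which(ct$person == "actual")
  nu <- 40L
  set.seed(43L)
  w <- sample(c(-4, -2, 2, 4), nu, replace = TRUE)  # even Hz loadings
  bodySign <- ifelse(ct$bodyPart[act] == "cheek", 1, -1)
  condRates <- 10 + outer(w, bodySign)              # exact rank-1 body signal
  full <- matrix(10, nu, 16L)
  full[, act] <- condRates
  full[, -act] <- condRates
  x <- noiselessTensor(full, trialsPerCondition = 2L)
  w <- w / sqrt(sum(w^2))
  fit <- fitDemixedAxes(subsetContext(x, person = "actual"))
  expect_gt(abs(sum(fit$axes$bodyPart[, 1L] * w)), 0.95)
  expect_gt(fit$varianceExplained[["bodyPart"]], 0.8)
  # variance fractions sum to 1 over the three marginalizations
  expect_equal(sum(fit$varianceExplained), 1, tolerance = 1e-10)
})

test_that("projection of the training context reproduces training latents", {
  set.seed(44L)
  pop <- generateCompositionalPopulation(nUnits = 30L, nSessions = 1L,
                                         personGain = 0, seed = 45L)
  x <- pop$sessions[[1L]]
  train <- subsetContext(x, person = "actual")
  fit <- fitDemixedAxes(train)
  proj <- projectHeldout(fit, train)
  for (m in names(fit$latents))
    expect_equal(proj$latents[[m]], fit$latents[[m]], tolerance = 1e-10)
  expect_equal(unname(proj$patternCorrelation[c("bodyPart", "touchType")]),
               c(1, 1), tolerance = 1e-10)
})

test_that("discrimination axes point at the separating coordinate and are scale-stable", {
  set.seed(46L)
  Xa <- cbind(rnorm(20L, 10), matrix(rnorm(20L * 4L), 20L))
  Xb <- cbind(rnorm(20L, 0), matrix(rnorm(20L * 4L), 20L))
  w <- learnDiscriminationAxis(Xa, Xb)
  expect_gt(abs(w[1L]), 0.95)
  w2 <- learnDiscriminationAxis(2 * Xa, 2 * Xb)
  expect_gt(sum(w * w2), 0.99)   # same direction after scaling all rates
  expect_error(learnDiscriminationAxis(matrix(1, 3, 2), matrix(1, 3, 2)),
               "identical condition means")
  # same-distribution pair: axis direction unstable across draws
  cosines <- vapply(1:40, function(i) {
    A <- matrix(rnorm(20L * 5L), 20L); B <- matrix(rnorm(20L * 5L), 20L)
    C <- matrix(rnorm(20L * 5L), 20L); D <- matrix(rnorm(20L * 5L), 20L)
    sum(learnDiscriminationAxis(A, B) * learnDiscriminationAxis(C, D))
  }, 1)
  expect_lt(abs(mean(cosines)), 0.15)
})

test_that("normalized generalization is 1 for identical contexts and 0 for null pairs", {
  pop <- generateCompositionalPopulation(nUnits = 50L, nSessions = 1L,
                                         personGain = 0, seed = 47L)
  x <- pop$sessions[[1L]]
  pair <- c("actual.cheek.pinch", "actual.cheek.press")
  g <- normalizedGeneralization(x, pair, x, pair, nResamples = 20L, seed = 3L)
  expect_lt(abs(g$value - 1), 0.15)
  # test pair drawn from one distribution: no separation to transfer
  gNull <- normalizedGeneralization(
    x, pair, x, c("actual.shoulder.rub", "actual.shoulder.rub"),
    nResamples = 20L, seed = 3L)
  expect_lt(abs(gNull$value), 0.2)
  # swapping train and test roles gives a compatible index for exchangeable data
  testPair <- c("observed.cheek.pinch", "observed.cheek.press")
  g12 <- normalizedGeneralization(x, pair, x, testPair, 25L, seed = 4L)
  g21 <- normalizedGeneralization(x, testPair, x, pair, 25L, seed = 4L)
  expect_lt(abs(g12$value - g21$value), 0.35)
})
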