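test_that("noiseless tuning recovers exact condition betas", {
  # unit 1: 10 Hz in condition 1, baseline 2 Hz elsewhere; unit 2 flat
  condRates <- rbind(c(10, rep(2, 15)), rep(4, 16))
  x <- noiselessTensor(condRates, trialsPerCondition = 2L,
                       baselineRates = c(2, 4))
  fits <- tuningAnalysis(x)
  u1 <- fits[fits$unit == 1L, ]
  expect_equal(u1$beta[u1$condition == "actual.cheek.pinch"], 8)
  expect_true(u1$significant[u1$condition == "actual.cheek.pinch"])
  expect_equal(sum(u1$significant), 1L)
  u2 <- fits[fits$unit == 2L, ]
  expect_equal(u2$beta, rep(0, 16))
  expect_false(any(u2$significant))
})

test_that("the indicator-design OLS matches the lm oracle", {
  set.seed(31L)
  for (rep in 1:5) {
    n <- 48L
    cond <- factor(rep(letters[1:4], each = 12L))
    stim <- rnorm(n, mean = as.integer(cond)); base <- rnorm(n, 1)
    fit <- fitConditionModel(stim, base, cond)
    ref <- summary(lm(I(stim - base) ~ 0 + cond))$coefficients
    expect_equal(fit$beta, unname(ref[, 1L]), tolerance = 1e-10)
    expect_equal(fit$t, unname(ref[, 3L]), tolerance = 1e-10)
    expect_equal(fit$p, unname(ref[, 4L]), tolerance = 1e-10)
  }
})

test_that("BH mask equals the exhaustive step-up oracle", {
  bhOracle <- function(p, q) {
    m <- length(p)
    ord <- order(p)
    k <- which(p[ord] <= seq_len(m) * q / m)
    out <- rep(FALSE, m)
    if (length(k) > 0L) out[ord[seq_len(max(k))]] <- TRUE
    out
  }
  expect_identical(fdrCorrect(c(0.01, 0.02, 0.03, 0.5), 0.05),
                   c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(fdrCorrect(rep(1, 6)), rep(FALSE, 6))
  expect_identical(fdrCorrect(0.04, 0.05), TRUE)
  expect_identical(fdrCorrect(numeric(0)), logical(0))
  set.seed(11L)
  for (rep in 1:200) {
    m <- sample(1:12, 1L)
    p <- round(runif(m)^sample(1:3, 1L), 3)
    q <- sample(c(0.01, 0.05, 0.1, 0.25), 1L)
    expect_identical(fdrCorrect(p, q), bhOracle(p, q))
  }
})

test_that("tuning has high power at strong effects and controls FDR under the null", {
  set.seed(21L)
  # power: 5 Hz effect in one of 4 conditions, sigma 1 Hz, 10 trials each
  hits <- vapply(1:200, function(i) {
    cond <- factor(rep(1:4, each = 10L))
    stim <- rnorm(40L, ifelse(cond == 1L, 5, 0), 1)
    fit <- fitConditionModel(stim, rep(0, 40L), cond)
    fit$significant[1L]
  }, TRUE)
  expect_gt(mean(hits), 0.9)

  # realized FDR under a global null stays at or below q
  falseRej <- vapply(1:500, function(i) {
    cond <- factor(rep(1:4, each = 10L))
    fit <- fitConditionModel(rnorm(40L), rnorm(40L), cond)
    any(fit$significant)
  }, TRUE)
  # per-unit family: P(any false rejection) <= q; allow 3 sigma MC slack
  expect_lt(mean(falseRej), 0.05 + 3 * sqrt(0.05 * 0.95 / 500))
})

test_that("responsive fractions track generator truth and the null rate", {
  set.seed(5L)
  # 50% of units respond strongly to every condition
  nu <- 40L
  condRates <- rbind(matrix(20, nu / 2, 16L), matrix(2, nu / 2, 16L))
  sessions <- lapply(1:3, function(s) {
    pop <- generatePopulation("MSMT", nUnits = 1L, nSessions = 1L, seed = s)
    x <- pop$sessions[[1L]]
    td <- as.data.frame(trialData(x))
    cts <- array(0L, dim = c(nu, nTrials(x), nBins(x)))
    m <- setNames(c(1L, 1L, 1L, 1L), c("Ac", "As", "Oc", "Os"))
    for (u in seq_len(nu)) {
      sp <- if (u <= nu / 2) rep(18, 4) else rep(0, 4)
      cts[u, , ] <- generateNeuron(2, m, list(sp), td)
    }
    y <- SpikeCountTensor(cts, binEdges(x), td, sessionId = s)
    tuningAnalysis(y)
  })
  fr <- fractionResponsive(do.call(rbind, sessions))
  expect_true(all(abs(fr$fraction - 0.5) < 0.1))
})

test_that("event-related averages have the published window grid", {
  condRates <- matrix(4, 1, 16L)
  x <- noiselessTensor(condRates, trialsPerCondition = 2L, baselineRates = 4)
  era <- eventRelatedAverage(x)
  expect_equal(length(unique(era$windowStart)), 31L)  # -0.5 .. 2.5 by 0.1
  expect_equal(range(era$windowStart), c(-0.5, 2.5))
  # constant-rate unit: perfectly flat trace with zero SEM
  expect_equal(unique(era$meanHz), 4)
  expect_equal(unique(era$semHz), 0)

  # zero-spike unit: all-zero trace
  x0 <- noiselessTensor(matrix(0, 1, 16L), trialsPerCondition = 2L)
  era0 <- eventRelatedAverage(x0)
  expect_true(all(era0$meanHz == 0) && all(era0$semHz == 0))
  expect_error(eventRelatedAverage(x, span = c(-2, 2.5)), "coverage")
})
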