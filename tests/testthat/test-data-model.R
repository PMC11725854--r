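test_that("save/load round-trips a generated dataset bit-exactly", {
  pop <- generatePopulation("MSMT", nUnits = 4L, nSessions = 1L, seed = 7L)
  x <- pop$sessions[[1L]]
  h5 <- tempfile(fileext = ".h5"); csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  saveDataset(x, h5, csv, js)
  y <- loadDataset(h5, csv, js)
  expect_identical(counts(y), counts(x))
  expect_equal(binEdges(y), binEdges(x))
  expect_equal(as.data.frame(trialData(y)), as.data.frame(trialData(x)))
  expect_equal(as.data.frame(unitData(y)), as.data.frame(unitData(x)))
  expect_identical(sessionId(y), sessionId(x))
})

test_that("invalid trial tables are rejected with informative errors", {
  pop <- generatePopulation("MSMT", nUnits = 2L, nSessions = 1L, seed = 7L)
  x <- pop$sessions[[1L]]
  h5 <- tempfile(fileext = ".h5"); csv <- tempfile(fileext = ".csv")
  saveDataset(x, h5, csv)

  bad <- read.csv(csv)
  bad$touch_type[5L] <- "poke"
  csv2 <- tempfile(fileext = ".csv")
  write.csv(bad, csv2, row.names = FALSE)
  expect_error(loadDataset(h5, csv2), "row 5.*poke")

  noCol <- read.csv(csv); noCol$person <- NULL
  csv3 <- tempfile(fileext = ".csv")
  write.csv(noCol, csv3, row.names = FALSE)
  expect_error(loadDataset(h5, csv3), "missing required column.*person")
})

test_that("a condition missing one trial triggers a balance error naming it", {
  pop <- generatePopulation("MSMT", nUnits = 2L, nSessions = 1L, seed = 3L)
  x <- pop$sessions[[1L]]
  drop <- which(conditionFactor(trialData(x)) == "actual.cheek.pinch")[1L]
  keep <- setdiff(seq_len(nTrials(x)), drop)
  expect_error(
    SpikeCountTensor(counts(x)[, keep, , drop = FALSE], binEdges(x),
                     as.data.frame(trialData(x))[keep, ],
                     as.data.frame(unitData(x))),
    "unbalanced.*actual.cheek.pinch")
})

test_that("windowRate is count over duration, snaps outward, and is additive", {
  # one unit, 9 spikes spread over the 3 s analysis window
  pop <- generatePopulation("MSMT", nUnits = 1L, nSessions = 1L, seed = 1L)
  x <- pop$sessions[[1L]]
  cts <- counts(x); cts[] <- 0L
  mids <- binEdges(x)[-1L] - 0.005
  inWin <- which(mids > 0.5 & mids < 3.5)
  cts[1L, 1L, inWin[seq(1L, length(inWin), length.out = 9L)]] <- 1L
  y <- SpikeCountTensor(cts, binEdges(x), as.data.frame(trialData(x)),
                        as.data.frame(unitData(x)))
  expect_equal(windowRate(y, c(0.5, 3.5))[1L, 1L], 3.0)
  expect_equal(windowRate(y, c(-1, 0))[1L, 1L], 0)
  expect_error(windowRate(y, c(3, 6)), "outside tensor coverage")
  # snapped outward: [0.501, 3.499] covers the same bins as [0.5, 3.5]
  expect_equal(windowRate(y, c(0.501, 3.499)), windowRate(y, c(0.5, 3.5)))

  # additivity: rate over [a,c] equals duration-weighted mean over [a,b],[b,c]
  r <- windowRate(x, c(0.5, 3.5))
  r1 <- windowRate(x, c(0.5, 2.0))
  r2 <- windowRate(x, c(2.0, 3.5))
  expect_equal(r, (1.5 * r1 + 1.5 * r2) / 3, tolerance = 1e-12)
})

test_that("window rates recover a known Poisson rate", {
  td <- data.frame(session = 1L, trial = 1:10, person = "actual",
                   bodyPart = "cheek", touchType = "rub")
  m <- setNames(c(1L, 1L, 1L, 1L), c("Ac", "As", "Oc", "Os"))
  set.seed(42L)
  cts <- generateNeuron(0, m, list(rep(5, 4)), td)  # 5 Hz in analysis window
  analysisBins <- 201:500                           # [0.5, 3.5] s at 10 ms
  rates <- rowSums(cts[, analysisBins]) / 3
  se <- sqrt(5 / 3) / sqrt(10)                      # Poisson SE of a 3 s rate
  expect_lt(abs(mean(rates) - 5), 3 * se)
})

test_that("unit selection applies strict thresholds and is monotone", {
  pop <- generatePopulation("MSMT", nUnits = 3L, nSessions = 1L, seed = 2L)
  x <- pop$sessions[[1L]]
  ud <- data.frame(meanRate = c(0.4, 10, 2), snr = c(5, 0.6, 0.5))
  x@unitData <- S4Vectors::DataFrame(ud)
  mask <- selectUnits(x)
  expect_identical(mask, c(FALSE, TRUE, FALSE))  # 0.4 Hz out; snr 0.5 not > 0.5
  # monotone: raising either threshold never adds units
  for (mr in c(0.1, 1, 5)) for (ms in c(0.1, 0.55, 2)) {
    m1 <- selectUnits(x, mr, ms)
    expect_true(all(selectUnits(x, mr + 1, ms) <= m1))
    expect_true(all(selectUnits(x, mr, ms + 1) <= m1))
  }
  x@unitData$snr <- NA_real_
  expect_error(selectUnits(x), "SNR metadata")
  expect_identical(selectUnits(x, minSnr = NULL), c(FALSE, TRUE, TRUE))
})

test_that("the recorded-census fixture passes 756 of 805 units", {
  pop <- generatePopulation("BSMT", nUnits = 2L, nSessions = 1L, seed = 2L)
  x <- pop$sessions[[1L]]
  # synthetic metadata fixture shaped like the basic-task census
  cts <- counts(x)[rep(1L, 805L), , , drop = FALSE]
  ud <- data.frame(meanRate = c(rep(2, 740), rep(0.2, 30), rep(3, 35)),
                   snr = c(rep(1.2, 740), rep(1.0, 30), c(rep(0.3, 19), rep(2, 16))))
  y <- SpikeCountTensor(cts, binEdges(x), as.data.frame(trialData(x)), ud)
  expect_equal(sum(selectUnits(y)), 756L)
})
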