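test_that("subtracting a stack from itself leaves only the restored baseline", {
  g <- smallGeometry()
  p <- SimParams(g, list(smallFocus()), baselineF0 = 800, bleachTau = 6,
                 noiseSd = 0, nTrials = 1L, seed = 1L)
  ts <- simulateTrialSet(p)
  stim <- ts$stim[[1]]
  sameAsBlank <- TrialStack(frames(stim), g, "blank", landmarks(stim))
  res <- subtractBlank(stim, sameAsBlank)
  # difference is zero, so every frame equals the per-pixel pre-stimulus mean
  win <- 1:(g@stimOnsetFrame - 1)
  base <- colMeans(frames(stim)[win, , ])
  for (f in c(1L, 30L, 60L)) {
    expect_equal(frames(res)[f, , ], base, tolerance = 1e-12)
  }
  expect_true(res@bleachCorrected)
})

test_that("blank subtraction recovers the ground-truth evoked field", {
  g <- smallGeometry()
  ts <- simulateTrialSet(noiselessParams(g))
  corrected <- subtractBlank(ts$stim[[1]], ts$blank[[1]])
  dff <- computeDff(corrected)
  expect_equal(frames(dff), ts$truth$evoked, tolerance = 1e-6)
})

test_that("subtraction and averaging enforce their contracts", {
  g <- smallGeometry()
  ts <- simulateTrialSet(noiselessParams(g, nTrials = 2L))
  g2 <- smallGeometry(nFrames = 59L)
  short <- TrialStack(frames(ts$blank[[1]])[1:59, , ], g2, "blank")
  expect_error(subtractBlank(ts$stim[[1]], short), "mismatch")
  expect_error(subtractBlank(ts$blank[[1]], ts$blank[[2]]), "blank")
  expect_error(averageTrials(list()), "at least one")
  expect_error(averageTrials(list(ts$stim[[1]], ts$blank[[1]])), "mixed kind")
})

test_that("averaging is idempotent on identical trials and shrinks white noise by 1/sqrt(n)", {
  g <- smallGeometry(nFrames = 30L, height = 20L, width = 20L, stimOnsetFrame = 10L)
  ts <- simulateTrialSet(noiselessParams(g))
  avg <- averageTrials(list(ts$stim[[1]], ts$stim[[1]], ts$stim[[1]]))
  expect_equal(frames(avg), frames(ts$stim[[1]]), tolerance = 1e-12)

  sigma <- 3
  p <- SimParams(g, list(), baselineF0 = 1000, bleachTau = Inf, noiseSd = sigma,
                 nTrials = 40L, seed = 9L)
  blanks <- simulateTrialSet(p)$blank
  resid <- frames(averageTrials(blanks)) - 1000
  expect_equal(sd(resid), sigma / sqrt(40), tolerance = 0.1)
})

test_that("dF/F follows its definition and rejects non-positive baselines", {
  g <- smallGeometry()
  const <- TrialStack(array(250, c(g@nFrames, g@height, g@width)), g, "stimulated")
  expect_true(all(frames(computeDff(const)) == 0))

  arr <- array(100, c(g@nFrames, g@height, g@width))
  arr[30, 10, 10] <- 101
  expect_equal(frames(computeDff(TrialStack(arr, g, "stimulated")))[30, 10, 10],
               0.01, tolerance = 1e-12)

  bad <- array(100, c(g@nFrames, g@height, g@width))
  bad[, 7, 9] <- 0
  expect_error(computeDff(TrialStack(bad, g, "stimulated")), "row 7, col 9")
  expect_error(computeDff(const, baselineWindow = 18:25), "precede")
})

test_that("full noiseless pipeline recovers the configured amplitude to 1e-6", {
  g <- smallGeometry()
  ts <- simulateTrialSet(noiselessParams(g, nTrials = 2L))
  dff <- preprocessTrials(ts$stim, ts$blank, kernelSize = 1L)
  expect_equal(max(frames(dff)[, 20, 28]), 0.0089, tolerance = 1e-6)
  expect_identical(provenance(dff), c("subtract", "average", "dff", "filter"))
})

test_that("the spatial filter is an exact box mean with a constant-preserving border", {
  g <- smallGeometry()
  expect_error(spatialFilter(constantDff(0, g), kernelSize = 8L), "odd")

  const <- constantDff(0.005, g)
  expect_equal(frames(spatialFilter(const, 9L)), frames(const), tolerance = 1e-15)
  expect_identical(frames(spatialFilter(const, 1L)), frames(const))

  imp <- constantDff(0, g)
  imp@frames[10, 20, 28] <- 81e-4
  sm <- frames(spatialFilter(imp, 9L))[10, , ]
  expect_equal(sm[16:24, 24:32], matrix(1e-4, 9, 9), tolerance = 1e-15)
  expect_true(all(sm[1:10, ] == 0))
})

test_that("the filter matches direct convolution on random frames", {
  set.seed(7)
  for (k in c(3L, 9L)) {
    m <- matrix(rnorm(18 * 25), 18, 25)
    g <- AcquisitionGeometry(nFrames = 2L, height = 18L, width = 25L,
                             stimOnsetFrame = 2L)
    mv <- new("DffMovie", frames = array(rep(m, each = 2), c(2, 18, 25)),
              geometry = g, provenance = "dff")
    expect_equal(frames(spatialFilter(mv, k))[1, , ], oracleBoxFilter(m, k),
                 tolerance = 1e-12)
  }
})

test_that("subtract-then-average equals average-then-subtract", {
  g <- smallGeometry(nFrames = 30L, height = 16L, width = 16L, stimOnsetFrame = 10L)
  p <- SimParams(g, list(smallFocus(centerRow = 8, centerCol = 8, sigma = 3)),
                 baselineF0 = 900, bleachTau = 5, noiseSd = 2,
                 trialJitterCv = 0.05, nTrials = 6L, seed = 21L)
  ts <- simulateTrialSet(p)
  a <- averageTrials(mapply(subtractBlank, ts$stim, ts$blank, SIMPLIFY = FALSE))
  b <- subtractBlank(averageTrials(ts$stim), averageTrials(ts$blank))
  expect_equal(frames(a), frames(b), tolerance = 1e-10)
})

test_that("40-trial averaging recovers amplitudes within 10% at unit single-trial SNR", {
  g <- studyGeometry()
  errs <- vapply(1:20, function(s) {
    amp <- 0.006
    # single-trial dF/F noise approximately equal to the peak amplitude
    noiseSd <- amp * 1000 / sqrt(2)
    p <- SimParams(g, list(smallFocus(amplitude = amp, centerRow = 24,
                                      centerCol = 32, sigma = 12)),
                   baselineF0 = 1000, bleachTau = 10, noiseSd = noiseSd,
                   nTrials = 40L, seed = 100L + s)
    ts <- simulateTrialSet(p)
    dff <- preprocessTrials(ts$stim, ts$blank)
    m <- detectResponse(dff)
    if (!m@detected) return(1)
    abs(peakAmplitude(m) - amp) / amp
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})
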