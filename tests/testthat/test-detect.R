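test_that("noise estimation follows sampling theory and its contracts", {
  g <- smallGeometry()
  zero <- constantDff(0, g)
  est <- estimateNoise(zero)
  expect_true(all(est@perPixelSd == 0))
  expect_error(estimateNoise(zero, window = 5L), "at least 2")
  expect_error(estimateNoise(zero, window = 10:25), "precede")

  set.seed(11)
  noisy <- zero
  noisy@frames[] <- rnorm(length(noisy@frames), 0, 1e-3)
  est2 <- estimateNoise(noisy, window = 1:19)
  expect_equal(mean(est2@perPixelSd), 1e-3, tolerance = 0.05)
  pooled <- estimateNoise(noisy, window = 1:19, pooled = TRUE)
  expect_equal(max(pooled@perPixelSd), min(pooled@perPixelSd))
})

test_that("the 7xSD rule is one-sided and exact at its threshold", {
  g <- smallGeometry(nFrames = 10L, height = 8L, width = 8L, stimOnsetFrame = 8L)
  mv <- constantDff(0, g)
  mv@frames[9, 4, 4] <- 0.0080
  mv@frames[9, 5, 5] <- 0.0069
  mv@frames[10, 6, 6] <- -0.010
  noise <- new("NoiseEstimate", perPixelSd = matrix(0.001, 8, 8), window = 1:7)
  masks <- significanceMask(mv, noise, k = 7)
  expect_true(masks[9, 4, 4])
  expect_false(masks[9, 5, 5])
  expect_false(masks[10, 6, 6])

  zeroNoise <- new("NoiseEstimate", perPixelSd = matrix(0, 8, 8), window = 1:7)
  expect_error(significanceMask(mv, zeroNoise), "floor")
  expect_true(significanceMask(mv, zeroNoise, floor = 1e-4)[9, 4, 4])
})

test_that("raising k never enlarges masks; lowering mMin never delays the initial frame", {
  g <- smallGeometry()
  ts <- simulateTrialSet(noiselessParams(g))
  dff <- preprocessTrials(ts$stim, ts$blank)
  noise <- estimateNoise(dff)
  m7 <- significanceMask(dff, noise, k = 7, floor = 1e-4)
  m9 <- significanceMask(dff, noise, k = 9, floor = 1e-4)
  expect_true(all(m7 | !m9))

  f5 <- extractInitialResponse(m7, dff, mMin = 5L)$initialFrame
  f1 <- extractInitialResponse(m7, dff, mMin = 1L)$initialFrame
  expect_lte(f1, f5)
})

test_that("empty masks yield detected = FALSE, not an error", {
  g <- smallGeometry()
  m <- detectResponse(constantDff(1e-6, g), floor = 1e-4)
  expect_false(m@detected)
  expect_true(is.na(m@peakAmplitude))
})

test_that("noiseless detection matches closed-form kinetics at the focus", {
  g <- smallGeometry()
  amp <- 0.006
  ts <- simulateTrialSet(noiselessParams(g, list(smallFocus(amplitude = amp))))
  dff <- preprocessTrials(ts$stim, ts$blank, kernelSize = 1L)
  m <- detectResponse(dff, floor = 1e-4)
  expect_true(m@detected)
  expect_identical(m@initialCenter, c(20L, 28L))
  expect_equal(peakAmplitude(m), amp, tolerance = 1e-9)

  # expected peak frame from an independent evaluation of the kernel
  tms <- (seq_len(g@nFrames) - 1) * g@frameInterval
  kernel <- responseKernel(tms - (g@stimOnsetFrame - 1) * g@frameInterval - 30)
  expect_identical(m@peakFrame, which.max(kernel))
  expect_false(is.na(m@decay9010))
})

test_that("a monotone rising trace has an undefined decay time", {
  g <- smallGeometry()
  mv <- constantDff(0, g)
  ramp <- seq(0, 0.01, length.out = g@nFrames)
  for (f in seq_len(g@nFrames)) mv@frames[f, 18:22, 26:30] <- ramp[f]
  m <- detectResponse(mv, floor = 1e-4)
  expect_true(m@detected)
  expect_true(is.na(m@decay9010))
})

test_that("with two foci the earlier-onset focus defines the initial response", {
  g <- AcquisitionGeometry(nFrames = 80L, height = 60L, width = 80L,
                           stimOnsetFrame = 26L)
  f1 <- smallFocus(amplitude = 0.005, centerRow = 20, centerCol = 24,
                   sigma = 5, onsetDelay = 30, label = "S1")
  f2 <- smallFocus(amplitude = 0.006, centerRow = 42, centerCol = 60,
                   sigma = 5, onsetDelay = 42, label = "S2_IOR")
  ts <- simulateTrialSet(noiselessParams(g, list(f1, f2)))
  dff <- preprocessTrials(ts$stim, ts$blank)
  m <- detectResponse(dff, floor = 1e-4)
  expect_true(any(m@initialRegion[, 1] == 20 & m@initialRegion[, 2] == 24))
  expect_false(any(m@initialRegion[, 1] == 42 & m@initialRegion[, 2] == 60))

  # site-restricted detection isolates the later focus
  m2 <- detectResponse(dff, floor = 1e-4,
                       within = list(center = c(42, 60), radius = 15),
                       site = "S2_IOR")
  expect_identical(m2@initialCenter, c(42L, 60L))
  expect_gt(m2@initialFrame, m@initialFrame)
})

test_that("detection agrees exactly with the brute-force reference on small movies", {
  for (s in 1:5) {
    set.seed(s)
    g <- AcquisitionGeometry(nFrames = 40L, height = 20L, width = 20L,
                             stimOnsetFrame = 12L)
    f <- smallFocus(amplitude = runif(1, 0.004, 0.01),
                    centerRow = sample(6:14, 1), centerCol = sample(6:14, 1),
                    sigma = runif(1, 2, 4), onsetDelay = runif(1, 10, 60))
    p <- SimParams(g, list(f), baselineF0 = 1000, bleachTau = 10,
                   noiseSd = 1.0, nTrials = 10L, seed = 50L + s)
    ts <- simulateTrialSet(p)
    dff <- preprocessTrials(ts$stim, ts$blank, kernelSize = 3L)
    noise <- estimateNoise(dff)
    floorAbs <- 1e-4
    m <- detectResponse(dff, floor = floorAbs)
    thrMap <- pmax(7 * noise@perPixelSd, floorAbs)
    o <- oracleDetect(frames(dff), thrMap, mMin = 5L)
    expect_identical(m@detected, o$detected)
    if (o$detected) {
      expect_identical(m@initialFrame, o$initialFrame)
      expect_identical(m@initialCenter, o$center)
      expect_identical(m@peakFrame, o$peakFrame)
      expect_equal(peakAmplitude(m), o$peakAmplitude, tolerance = 1e-15)
      expect_identical(pixKey(m@initialRegion), pixKey(o$region))
    }
  }
})

test_that("identical movies give identical metrics", {
  g <- smallGeometry()
  ts <- simulateTrialSet(noiselessParams(g))
  dff <- preprocessTrials(ts$stim, ts$blank)
  a <- detectResponse(dff, floor = 1e-4)
  b <- detectResponse(dff, floor = 1e-4)
  expect_identical(a@initialRegion, b@initialRegion)
  expect_identical(peakAmplitude(a), peakAmplitude(b))
})

test_that("ROI time courses are exact for degenerate and synthetic inputs", {
  g <- smallGeometry()
  const <- constantDff(0.003, g)
  tc <- roiTimecourse(const, c(20, 28), 4)
  expect_true(all(tc$dff == 0.003))
  expect_equal(tc$time_ms, (seq_len(g@nFrames) - 1) * 4)
  expect_error(roiTimecourse(const, c(2, 2), 5), "outside")

  ts <- simulateTrialSet(noiselessParams(g))
  dff <- preprocessTrials(ts$stim, ts$blank, kernelSize = 1L)
  single <- roiTimecourse(dff, c(20, 28), 0)
  expect_equal(single$dff, ts$truth$evoked[, 20, 28], tolerance = 1e-6)

  # disc average equals the direct evaluation of the generative field
  disc <- roiTimecourse(dff, c(20, 28), 3)
  inDisc <- which(vsdmap:::discMask(g@height, g@width, c(20, 28), 3))
  flatTruth <- matrix(ts$truth$evoked, nrow = g@nFrames)
  expect_equal(disc$dff, rowMeans(flatTruth[, inDisc]), tolerance = 1e-6)
})
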