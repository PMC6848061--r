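#' Reduced acquisition geometry for stochastic validation studies
#'
#' A cropped field (64 x 48 px at the full pixel pitch, 75 frames of
#' 4 ms, stimulus at frame 26) used by the Monte-Carlo studies so that
#' many 40-trial acquisitions stay cheap; all timing and noise
#' parameters are those of the full acquisition.
#'
#' @return an \code{AcquisitionGeometry}
#' @export
studyGeometry <- function() {
  AcquisitionGeometry(nFrames = 75L, height = 48L, width = 64L,
                      stimOnsetFrame = 26L)
}

# Raw-fluorescence noise SD that yields a given dF/F noise SD after
# blank subtraction (variance doubles), n-trial averaging (1/n) and
# division by the baseline F0.
.rawNoiseFor <- function(targetDffSd, baselineF0, nTrials) {
  targetDffSd * baselineF0 * sqrt(nTrials / 2)
}

#' Monte-Carlo amplitude-recovery study
#'
#' For each seed, draws a true peak amplitude uniformly on
#' \code{ampRange}, simulates a 40-trial stimulated/blank acquisition at
#' realistic noise (dF/F baseline SD \code{targetDffSd} after
#' subtraction and averaging, before spatial smoothing), runs the full
#' preprocessing and 7xSD detection chain, and compares the recovered
#' peak amplitude with the truth.
#'
#' @param nSeeds number of Monte-Carlo repetitions
#' @param seed master seed
#' @param ampRange true-amplitude range, dF/F fraction
#' @param targetDffSd post-averaging baseline dF/F noise SD
#' @param nTrials trials per acquisition
#' @param jitterCv trial-to-trial amplitude jitter CV
#' @param geometry field geometry (default \code{\link{studyGeometry}})
#' @return data.frame(seed, true_amplitude, recovered, detected,
#'   rel_error)
#' @export
amplitudeRecoveryStudy <- function(nSeeds = 50L, seed = 1L,
                                   ampRange = c(0.002, 0.009),
                                   targetDffSd = 3e-4, nTrials = 40L,
                                   jitterCv = 0.1,
                                   geometry = studyGeometry()) {
  f0 <- 1000
  noiseSd <- .rawNoiseFor(targetDffSd, f0, nTrials)
  out <- lapply(seq_len(nSeeds), function(i) {
    set.seed(subSeed(seed, 300L + i))
    amp <- runif(1, ampRange[1L], ampRange[2L])
    focus <- ResponseFocus("S1", centerRow = 24, centerCol = 32, sigma = 12,
                           amplitude = amp, onsetDelay = 30)
    params <- SimParams(geometry, list(focus), baselineF0 = f0,
                        bleachTau = 10, noiseSd = noiseSd,
                        trialJitterCv = jitterCv, nTrials = nTrials,
                        seed = subSeed(seed, 600L + i))
    ts <- simulateTrialSet(params)
    dff <- preprocessTrials(ts$stim, ts$blank)
    m <- detectResponse(dff)
    rec <- if (m@detected) m@peakAmplitude else NA_real_
    data.frame(seed = i, true_amplitude = amp, recovered = rec,
               detected = m@detected,
               rel_error = if (m@detected) abs(rec - amp) / amp else 1)
  })
  do.call(rbind, out)
}

#' Monte-Carlo false-detection study on noise-only cohorts
#'
#' Same acquisition and noise conditions as
#' \code{\link{amplitudeRecoveryStudy}} but with no evoked focus; counts
#' how often the 7xSD rule (with the default speckle guard) declares a
#' detected response where none exists.
#'
#' @inheritParams amplitudeRecoveryStudy
#' @return logical vector, one detection flag per seed
#' @export
falseDetectionStudy <- function(nSeeds = 100L, seed = 1L,
                                targetDffSd = 3e-4, nTrials = 40L,
                                geometry = studyGeometry()) {
  f0 <- 1000
  noiseSd <- .rawNoiseFor(targetDffSd, f0, nTrials)
  vapply(seq_len(nSeeds), function(i) {
    params <- SimParams(geometry, list(), baselineF0 = f0, bleachTau = 10,
                        noiseSd = noiseSd, nTrials = nTrials,
                        seed = subSeed(seed, 900L + i))
    ts <- simulateTrialSet(params)
    dff <- preprocessTrials(ts$stim, ts$blank)
    detectResponse(dff)@detected
  }, logical(1))
}
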