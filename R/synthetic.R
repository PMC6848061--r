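#' Alpha-like temporal response kernel
#'
#' Temporal shape of an evoked VSD transient: an alpha-function rise
#' \code{(t/tauRise) * exp(1 - t/tauRise)} multiplied by an exponential
#' decay \code{exp(-t/tauDecay)}, zero for t < 0.  The generator
#' normalizes the kernel to peak 1 over the sampled frame grid, so a
#' focus's configured amplitude is exactly the peak dF/F it produces.
#'
#' @param t time since response onset, ms (vector)
#' @param tauRise,tauDecay rise and decay constants, ms (tauRise < tauDecay)
#' @return kernel values, same length as \code{t}
#' @export
responseKernel <- function(t, tauRise = 10, tauDecay = 80) {
  stopifnot(tauRise > 0, tauRise < tauDecay)
  out <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  out[pos] <- (tp / tauRise) * exp(1 - tp / tauRise) * exp(-tp / tauDecay)
  out
}

#' Canonical landmark placement for a field geometry
#'
#' A reference \code{\link{LandmarkFrame}}: the MCA runs roughly
#' vertically through the caudal part of the field and the rhinal fissure
#' roughly horizontally through its ventral part, crossing near the
#' ventro-caudal corner as on the real cortical surface.
#'
#' @param geometry an \code{AcquisitionGeometry}
#' @return a \code{LandmarkFrame}
#' @export
referenceLandmarks <- function(geometry = AcquisitionGeometry()) {
  h <- geometry@height
  w <- geometry@width
  LandmarkFrame(
    mcaPoints = rbind(c(0.15 * h, 0.72 * w), c(0.85 * h, 0.66 * w)),
    rfPoints = rbind(c(0.80 * h, 0.10 * w), c(0.86 * h, 0.95 * w))
  )
}

# Noiseless evoked dF/F movie (nominal amplitudes): sum over foci of
# amplitude * Gaussian(space) * kernel(time), kernel normalized to peak 1
# on the sampled frame grid.
.evokedMovie <- function(geometry, foci) {
  nF <- geometry@nFrames
  h <- geometry@height
  w <- geometry@width
  times <- frameTimes(geometry)
  stimTime <- (geometry@stimOnsetFrame - 1L) * geometry@frameInterval
  evoked <- array(0, dim = c(nF, h, w))
  for (f in foci) {
    tc <- responseKernel(times - stimTime - f@onsetDelay, f@tauRise, f@tauDecay)
    if (max(tc) > 0) tc <- tc / max(tc)
    rr <- matrix(seq_len(h), h, w)
    cc <- matrix(seq_len(w), h, w, byrow = TRUE)
    spatial <- exp(-((rr - f@centerRow)^2 + (cc - f@centerCol)^2) / (2 * f@sigma^2))
    evoked <- evoked + f@amplitude * outer(tc, spatial)
  }
  evoked
}

#' Generate one synthetic trial set (stimulated + blank stacks)
#'
#' Produces \code{nTrials} stimulated and \code{nTrials} blank raw
#' fluorescence stacks under the generative model
#' \deqn{stim = F_0 \cdot bleach(t) \cdot (1 + s_i \sum_j resp_j(x,y,t)) + noise,}
#' \deqn{blank = F_0 \cdot bleach(t) + noise,}
#' with \code{bleach(t) = exp(-t / bleachTau)} shared between the
#' stimulated and blank members of a pair, per-trial amplitude scale
#' \code{s_i} drawn with CV \code{trialJitterCv}, and iid Gaussian sensor
#' noise.  Identical \code{SimParams} (including seed) give identical
#' output.
#'
#' @param params a \code{\link{SimParams}} object
#' @return a list with elements \code{stim} and \code{blank} (lists of
#'   \code{TrialStack}) and \code{truth}, the ground-truth record
#'   (per-trial amplitude scales and per-focus amplitudes, the bleach
#'   curve, the nominal evoked dF/F movie, foci and landmarks)
#' @export
simulateTrialSet <- function(params) {
  validObject(params)
  g <- params@geometry
  set.seed(params@seed)
  times <- frameTimes(g)
  bleach <- if (is.finite(params@bleachTau)) {
    exp(-(times / 1000) / params@bleachTau)
  } else {
    rep(1, g@nFrames)
  }
  evoked <- .evokedMovie(g, params@foci)
  baseArr <- params@baselineF0 * array(bleach, dim = dim(evoked))
  trialScale <- if (params@trialJitterCv > 0) {
    pmax(rnorm(params@nTrials, 1, params@trialJitterCv), 0)
  } else {
    rep(1, params@nTrials)
  }
  stim <- vector("list", params@nTrials)
  blank <- vector("list", params@nTrials)
  for (i in seq_len(params@nTrials)) {
    s <- baseArr * (1 + trialScale[i] * evoked)
    b <- baseArr
    if (params@noiseSd > 0) {
      s <- s + array(rnorm(length(s), 0, params@noiseSd), dim = dim(s))
      b <- b + array(rnorm(length(b), 0, params@noiseSd), dim = dim(b))
    }
    stim[[i]] <- TrialStack(s, g, "stimulated", params@landmarks)
    blank[[i]] <- TrialStack(b, g, "blank", params@landmarks)
  }
  amps <- vapply(params@foci, function(f) f@amplitude, numeric(1))
  truth <- list(
    trialScale = trialScale,
    trialAmplitudes = outer(trialScale, amps),
    bleach = bleach,
    evoked = evoked,
    foci = params@foci,
    landmarks = params@landmarks
  )
  list(stim = stim, blank = blank, truth = truth)
}

# Rigidly displace a LandmarkFrame (used to emulate cross-animal
# anatomical variability).
.displaceLandmarks <- function(ref, translation, rotationDeg, resolvable = TRUE) {
  tr <- RigidTransform(rotationDeg, translation,
                       pivot = lineIntersection(ref@mcaPoints, ref@rfPoints))
  LandmarkFrame(
    mcaPoints = applyTransform(tr, ref@mcaPoints),
    rfPoints = applyTransform(tr, ref@rfPoints),
    resolvable = resolvable
  )
}

#' Generate a multi-animal cohort of calibrated response amplitudes
#'
#' Draws per-animal true peak amplitudes for each group x site target and
#' per-animal landmark placements displaced from a reference.  In
#' \code{calibrate = "exact"} mode the draws of each group x site cell are
#' rescaled so that their realized mean and SEM equal the targets to
#' numerical precision (requires n >= 2); in \code{"stochastic"} mode they
#' are plain Gaussian draws with the target mean and SD = SEM * sqrt(n).
#' Draws are seeded per site, so groups with identical targets and n
#' receive identical draws.
#'
#' @param groups data.frame with columns \code{group}, \code{site},
#'   \code{mean_pct}, \code{sem_pct}, \code{n} (amplitudes in percent)
#' @param seed integer RNG seed
#' @param calibrate "exact" or "stochastic"
#' @param geometry field geometry for landmark placement
#' @param landmarkSdPx,landmarkSdDeg SDs of the per-animal landmark
#'   translation (px) and rotation (degrees)
#' @param unresolvableFraction expected fraction of animals whose
#'   landmarks are flagged unresolvable (excluded from overlap maps)
#' @param minAmplitude smallest admissible true amplitude (fraction);
#'   draw sets whose calibrated minimum falls below it are redrawn
#'   deterministically, since a peak dF/F is physically non-negative and
#'   must stay detectable
#' @return a list: \code{amplitudes} (data.frame animal_id, group, site,
#'   amplitude as a fraction), \code{landmarks} (named list of
#'   \code{LandmarkFrame} per animal), \code{reference} landmark frame
#' @export
simulateCohort <- function(groups, seed = 1L,
                           calibrate = c("stochastic", "exact"),
                           geometry = AcquisitionGeometry(),
                           landmarkSdPx = 3, landmarkSdDeg = 2,
                           unresolvableFraction = 0, minAmplitude = 1e-4) {
  calibrate <- match.arg(calibrate)
  stopifnot(all(c("group", "site", "mean_pct", "sem_pct", "n") %in% names(groups)))
  if (any(groups$sem_pct <= 0)) stop("target SEM must be > 0")
  if (any(groups$n < 2)) stop("cohort groups need n >= 2")
  sites <- unique(groups$site)
  grpNames <- unique(groups$group)
  nPer <- vapply(grpNames, function(gl) {
    nn <- unique(groups$n[groups$group == gl])
    if (length(nn) != 1L) stop("inconsistent n across sites within group ", gl)
    as.integer(nn)
  }, integer(1))
  amp <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    row <- groups[i, ]
    siteIdx <- match(row$site, sites)
    m <- row$mean_pct / 100
    sdTarget <- row$sem_pct / 100 * sqrt(row$n)
    if (calibrate == "exact" && row$n < 2L)
      stop("exact calibration requires n >= 2 (SEM undefined)")
    # Amplitudes are physically non-negative and right-skewed when the
    # group SD is comparable to its mean, so the base draws come from a
    # gamma matched to the target mean/SD, standardized; draw sets whose
    # calibrated minimum would be unphysically small are redrawn
    # deterministically (attempt index folded into the seed).
    shape <- max((m / sdTarget)^2, 0.25)
    for (attempt in 0:99) {
      set.seed(subSeed(seed, siteIdx + 7919L * attempt))
      z <- (rgamma(row$n, shape = shape, rate = 1) - shape) / sqrt(shape)
      x <- if (calibrate == "exact") {
        m + (z - mean(z)) / sd(z) * sdTarget
      } else {
        m + z * sdTarget
      }
      if (min(x) >= minAmplitude) break
    }
    if (min(x) < minAmplitude)
      stop(sprintf(
        "could not draw admissible amplitudes for group %s at site %s (targets %.3g +/- %.3g)",
        row$group, row$site, m, sdTarget))
    data.frame(
      animal_id = sprintf("%s_%02d", row$group, seq_len(row$n)),
      group = row$group, site = row$site, amplitude = x,
      stringsAsFactors = FALSE
    )
  }))
  ref <- referenceLandmarks(geometry)
  animals <- unique(amp$animal_id)
  lm <- vector("list", length(animals))
  names(lm) <- animals
  for (j in seq_along(animals)) {
    set.seed(subSeed(seed, 1000L + j))
    lm[[j]] <- .displaceLandmarks(
      ref,
      translation = rnorm(2, 0, landmarkSdPx),
      rotationDeg = rnorm(1, 0, landmarkSdDeg),
      resolvable = runif(1) >= unresolvableFraction
    )
  }
  list(amplitudes = amp, landmarks = lm, reference = ref, seed = seed,
       calibrate = calibrate)
}

#' Generate synthetic von Frey behavioral sessions
#'
#' For each animal, day and filament force, draws the number of
#' head-withdrawals out of \code{nStimuli} binomially, with withdrawal
#' probability given by a logistic psychometric function of force centred
#' at the animal's true threshold.  With \code{slope = Inf} the function
#' degenerates to a step: no withdrawals below threshold, all withdrawals
#' at and above it.
#'
#' @param forces filament forces in grams, strictly increasing
#' @param trueThreshold true threshold in grams; scalar or one value per day
#' @param slope psychometric slope (1/g); \code{Inf} for deterministic
#' @param nStimuli stimuli per force (default 5)
#' @param days character vector of day labels
#' @param animalIds character vector of animal ids
#' @param seed integer RNG seed
#' @return data.frame with columns \code{animal_id}, \code{day},
#'   \code{force_g}, \code{n_stimuli}, \code{n_withdrawals}
#' @export
simulateVonFreySessions <- function(forces = c(4, 8, 15, 26, 30, 40, 50, 60, 100),
                                    trueThreshold, slope = Inf, nStimuli = 5L,
                                    days = "pre", animalIds = "a01", seed = 1L) {
  if (length(forces) == 0L) stop("empty filament force set")
  if (any(diff(forces) <= 0)) stop("forces must be strictly increasing")
  thr <- rep_len(trueThreshold, length(days))
  set.seed(as.integer(seed))
  out <- list()
  for (a in animalIds) {
    for (d in seq_along(days)) {
      p <- if (is.infinite(slope)) {
        as.numeric(forces >= thr[d])
      } else {
        plogis(slope * (forces - thr[d]))
      }
      nw <- rbinom(length(forces), nStimuli, p)
      out[[length(out) + 1L]] <- data.frame(
        animal_id = a, day = days[d], force_g = forces,
        n_stimuli = as.integer(nStimuli), n_withdrawals = nw,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
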