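#' @import methods
NULL

#' Acquisition geometry of a VSD movie
#'
#' Describes one stimulus-locked acquisition: frame timing, field size in
#' pixels, pixel pitch in mm, and the (1-based) frame at which the stimulus
#' is delivered.  Defaults reproduce a 6.4 x 4.8 mm field imaged at
#' 184 x 124 px, 4 ms/frame (250 Hz), 125 frames (500 ms), stimulus at
#' frame 26 (100 ms into the sweep).
#'
#' @slot frameInterval sampling interval, ms
#' @slot nFrames number of frames per acquisition
#' @slot height,width field size, pixels
#' @slot mmPerPixelX,mmPerPixelY pixel pitch, mm/pixel
#' @slot stimOnsetFrame 1-based index of the first stimulated frame
#' @export
setClass("AcquisitionGeometry",
  representation(
    frameInterval = "numeric", nFrames = "integer",
    height = "integer", width = "integer",
    mmPerPixelX = "numeric", mmPerPixelY = "numeric",
    stimOnsetFrame = "integer"
  )
)

setValidity("AcquisitionGeometry", function(object) {
  msg <- character()
  if (!isTRUE(object@frameInterval > 0)) msg <- c(msg, "frameInterval must be > 0")
  if (!isTRUE(object@nFrames >= 2L)) msg <- c(msg, "nFrames must be >= 2")
  if (!isTRUE(object@height >= 1L) || !isTRUE(object@width >= 1L))
    msg <- c(msg, "height and width must be >= 1")
  if (!isTRUE(object@stimOnsetFrame >= 1L) ||
      !isTRUE(object@stimOnsetFrame <= object@nFrames))
    msg <- c(msg, "stimOnsetFrame must lie within 1..nFrames")
  if (length(msg)) msg else TRUE
})

#' @param frameInterval,nFrames,height,width,mmPerPixelX,mmPerPixelY,stimOnsetFrame
#'   see slots
#' @return an \code{AcquisitionGeometry} object
#' @rdname AcquisitionGeometry-class
#' @export
AcquisitionGeometry <- function(frameInterval = 4, nFrames = 125L,
                                height = 124L, width = 184L,
                                mmPerPixelX = 6.4 / 184, mmPerPixelY = 4.8 / 124,
                                stimOnsetFrame = 26L) {
  new("AcquisitionGeometry",
    frameInterval = as.numeric(frameInterval), nFrames = as.integer(nFrames),
    height = as.integer(height), width = as.integer(width),
    mmPerPixelX = mmPerPixelX, mmPerPixelY = mmPerPixelY,
    stimOnsetFrame = as.integer(stimOnsetFrame)
  )
}

setMethod("show", "AcquisitionGeometry", function(object) {
  cat(sprintf(
    "AcquisitionGeometry: %d x %d px, %d frames @ %g ms, stim at frame %d (%g ms)\n",
    object@height, object@width, object@nFrames, object@frameInterval,
    object@stimOnsetFrame, (object@stimOnsetFrame - 1) * object@frameInterval
  ))
})

#' Anatomical landmark lines for cross-animal alignment
#'
#' Two lines on the cortical surface image — the middle cerebral artery
#' (MCA) and the rhinal fissure — each given by two (row, col) points.
#' When \code{resolvable} the two lines intersect in exactly one point,
#' which anchors the rigid alignment; animals whose landmarks cannot be
#' resolved are excluded from overlap maps rather than aligned.
#'
#' @slot mcaPoints,rfPoints 2 x 2 numeric matrices, one (row, col) point per row
#' @slot resolvable logical flag
#' @export
setClass("LandmarkFrame",
  representation(mcaPoints = "matrix", rfPoints = "matrix", resolvable = "logical")
)

setValidity("LandmarkFrame", function(object) {
  msg <- character()
  for (nm in c("mcaPoints", "rfPoints")) {
    m <- slot(object, nm)
    if (!is.numeric(m) || !all(dim(m) == c(2L, 2L)) || !all(is.finite(m)))
      msg <- c(msg, sprintf("%s must be a finite 2x2 numeric matrix", nm))
  }
  if (length(msg) == 0 && isTRUE(object@resolvable)) {
    d1 <- object@mcaPoints[2L, ] - object@mcaPoints[1L, ]
    d2 <- object@rfPoints[2L, ] - object@rfPoints[1L, ]
    if (abs(d1[1L] * d2[2L] - d1[2L] * d2[1L]) < 1e-12)
      msg <- c(msg, "resolvable landmarks require non-parallel MCA and rhinal-fissure lines")
  }
  if (length(msg)) msg else TRUE
})

#' @param mcaPoints,rfPoints,resolvable see slots
#' @rdname LandmarkFrame-class
#' @export
LandmarkFrame <- function(mcaPoints, rfPoints, resolvable = TRUE) {
  new("LandmarkFrame",
    mcaPoints = rbind(mcaPoints[1L, ], mcaPoints[2L, ]),
    rfPoints = rbind(rfPoints[1L, ], rfPoints[2L, ]),
    resolvable = isTRUE(resolvable)
  )
}

setMethod("show", "LandmarkFrame", function(object) {
  cat(sprintf(
    "LandmarkFrame (%s): MCA (%.1f,%.1f)-(%.1f,%.1f), RF (%.1f,%.1f)-(%.1f,%.1f)\n",
    if (object@resolvable) "resolvable" else "unresolvable",
    object@mcaPoints[1, 1], object@mcaPoints[1, 2],
    object@mcaPoints[2, 1], object@mcaPoints[2, 2],
    object@rfPoints[1, 1], object@rfPoints[1, 2],
    object@rfPoints[2, 1], object@rfPoints[2, 2]
  ))
})

#' One cortical response focus for the synthetic generator
#'
#' Parameterizes an evoked depolarization focus: a Gaussian spatial profile
#' centred at (\code{centerRow}, \code{centerCol}) with spread \code{sigma},
#' and an alpha-like temporal kernel delayed by \code{onsetDelay} after the
#' stimulus with rise/decay constants \code{tauRise} < \code{tauDecay}.
#' \code{amplitude} is the peak fractional dF/F (dimensionless: 0.0089 is a
#' 0.89\% response).
#'
#' @slot label site name, e.g. "S1" or "S2/IOR"
#' @slot centerRow,centerCol focus centre, pixels
#' @slot sigma spatial spread, pixels
#' @slot amplitude peak fractional dF/F
#' @slot onsetDelay delay after the stimulus, ms
#' @slot tauRise,tauDecay kinetic time constants, ms
#' @export
setClass("ResponseFocus",
  representation(
    label = "character", centerRow = "numeric", centerCol = "numeric",
    sigma = "numeric", amplitude = "numeric", onsetDelay = "numeric",
    tauRise = "numeric", tauDecay = "numeric"
  )
)

setValidity("ResponseFocus", function(object) {
  msg <- character()
  num <- c(object@centerRow, object@centerCol, object@sigma, object@amplitude,
           object@onsetDelay, object@tauRise, object@tauDecay)
  if (!all(is.finite(num))) msg <- c(msg, "all focus parameters must be finite")
  else {
    if (object@amplitude < 0) msg <- c(msg, "amplitude must be >= 0")
    if (object@sigma <= 0) msg <- c(msg, "sigma must be > 0")
    if (object@onsetDelay < 0) msg <- c(msg, "onsetDelay must be >= 0")
    if (!(object@tauRise < object@tauDecay))
      msg <- c(msg, "tauRise must be < tauDecay")
    if (object@tauRise <= 0) msg <- c(msg, "tauRise must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' @param label,centerRow,centerCol,sigma,amplitude,onsetDelay,tauRise,tauDecay
#'   see slots
#' @rdname ResponseFocus-class
#' @export
ResponseFocus <- function(label, centerRow, centerCol, sigma = 8,
                          amplitude = 0.0089, onsetDelay = 30,
                          tauRise = 10, tauDecay = 80) {
  new("ResponseFocus",
    label = as.character(label), centerRow = as.numeric(centerRow),
    centerCol = as.numeric(centerCol), sigma = as.numeric(sigma),
    amplitude = as.numeric(amplitude), onsetDelay = as.numeric(onsetDelay),
    tauRise = as.numeric(tauRise), tauDecay = as.numeric(tauDecay)
  )
}

#' Parameters of one synthetic trial set
#'
#' Bundles everything needed to generate one animal's stimulus-locked
#' acquisition: the geometry, the response foci, the raw-fluorescence
#' baseline and its bleaching time constant, the sensor noise SD, the
#' trial-to-trial amplitude jitter (coefficient of variation), the number
#' of stimulated/blank trial pairs, landmarks and the RNG seed.
#'
#' @slot geometry an \code{AcquisitionGeometry}
#' @slot foci list of \code{ResponseFocus}
#' @slot baselineF0 mean raw fluorescence, a.u.
#' @slot bleachTau bleaching time constant, s (\code{Inf} disables bleaching)
#' @slot noiseSd raw-fluorescence Gaussian noise SD, a.u.
#' @slot trialJitterCv per-trial amplitude jitter CV
#' @slot nTrials number of stimulated (and blank) trials
#' @slot landmarks a \code{LandmarkFrame}
#' @slot seed RNG seed
#' @export
setClass("SimParams",
  representation(
    geometry = "AcquisitionGeometry", foci = "list", baselineF0 = "numeric",
    bleachTau = "numeric", noiseSd = "numeric", trialJitterCv = "numeric",
    nTrials = "integer", landmarks = "LandmarkFrame", seed = "integer"
  )
)

setValidity("SimParams", function(object) {
  msg <- character()
  if (!isTRUE(object@baselineF0 > 0)) msg <- c(msg, "baselineF0 must be > 0")
  if (!isTRUE(object@noiseSd >= 0)) msg <- c(msg, "noiseSd must be >= 0")
  if (!isTRUE(object@bleachTau > 0)) msg <- c(msg, "bleachTau must be > 0")
  if (!isTRUE(object@nTrials >= 1L)) msg <- c(msg, "nTrials must be >= 1")
  if (!isTRUE(object@trialJitterCv >= 0)) msg <- c(msg, "trialJitterCv must be >= 0")
  ok <- vapply(object@foci, function(f) is(f, "ResponseFocus"), logical(1))
  if (length(ok) && !all(ok)) msg <- c(msg, "foci must be ResponseFocus objects")
  if (length(msg)) msg else TRUE
})

#' @param geometry,foci,baselineF0,bleachTau,noiseSd,trialJitterCv,nTrials,landmarks,seed
#'   see slots
#' @rdname SimParams-class
#' @export
SimParams <- function(geometry = AcquisitionGeometry(), foci = list(),
                      baselineF0 = 1000, bleachTau = 10, noiseSd = 0,
                      trialJitterCv = 0, nTrials = 40L,
                      landmarks = referenceLandmarks(geometry), seed = 1L) {
  new("SimParams",
    geometry = geometry, foci = foci, baselineF0 = as.numeric(baselineF0),
    bleachTau = as.numeric(bleachTau), noiseSd = as.numeric(noiseSd),
    trialJitterCv = as.numeric(trialJitterCv), nTrials = as.integer(nTrials),
    landmarks = landmarks, seed = as.integer(seed)
  )
}

#' A stimulus-locked (or blank) fluorescence movie
#'
#' Raw fluorescence frames plus acquisition metadata.  \code{frames} is a
#' 3-D array indexed \code{[frame, row, col]}.  \code{kind} distinguishes
#' stimulated acquisitions from no-stimulation (blank) ones used for
#' bleaching removal.  \code{bleachCorrected} is set by blank subtraction;
#' \code{provenance} records the preprocessing steps applied so far.
#'
#' @slot frames numeric array, frame x row x col
#' @slot geometry an \code{AcquisitionGeometry}
#' @slot kind "stimulated" or "blank"
#' @slot landmarks a \code{LandmarkFrame}
#' @slot bleachCorrected logical
#' @slot provenance character vector of applied steps
#' @export
setClass("TrialStack",
  representation(
    frames = "array", geometry = "AcquisitionGeometry", kind = "character",
    landmarks = "LandmarkFrame", bleachCorrected = "logical",
    provenance = "character"
  )
)

setValidity("TrialStack", function(object) {
  msg <- character()
  d <- dim(object@frames)
  g <- object@geometry
  if (length(d) != 3L) msg <- c(msg, "frames must be a 3-D array")
  else if (!all(d == c(g@nFrames, g@height, g@width)))
    msg <- c(msg, sprintf(
      "frames dim (%s) does not match geometry (%d, %d, %d)",
      paste(d, collapse = ", "), g@nFrames, g@height, g@width
    ))
  if (!object@kind %in% c("stimulated", "blank"))
    msg <- c(msg, "kind must be 'stimulated' or 'blank'")
  if (!all(is.finite(object@frames))) msg <- c(msg, "frames must be finite")
  if (length(msg)) msg else TRUE
})

#' @param frames,geometry,kind,landmarks,bleachCorrected,provenance see slots
#' @rdname TrialStack-class
#' @export
TrialStack <- function(frames, geometry, kind = c("stimulated", "blank"),
                       landmarks = referenceLandmarks(geometry),
                       bleachCorrected = FALSE, provenance = character()) {
  new("TrialStack",
    frames = frames, geometry = geometry, kind = match.arg(kind),
    landmarks = landmarks, bleachCorrected = bleachCorrected,
    provenance = provenance
  )
}

setMethod("show", "TrialStack", function(object) {
  g <- object@geometry
  cat(sprintf(
    "TrialStack (%s%s): %d frames of %d x %d px, range [%.4g, %.4g]\n",
    object@kind, if (object@bleachCorrected) ", bleach-corrected" else "",
    g@nFrames, g@height, g@width, min(object@frames), max(object@frames)
  ))
})

#' A dF/F movie
#'
#' Per-pixel fractional fluorescence change over frames, produced by
#' \code{\link{computeDff}} and optionally smoothed by
#' \code{\link{spatialFilter}}.  Values are dimensionless fractions
#' (0.0089 = 0.89\%).
#'
#' @slot frames numeric array, frame x row x col
#' @slot geometry an \code{AcquisitionGeometry}
#' @slot provenance character vector of applied steps (append-only)
#' @export
setClass("DffMovie",
  representation(frames = "array", geometry = "AcquisitionGeometry",
                 provenance = "character")
)

setValidity("DffMovie", function(object) {
  d <- dim(object@frames)
  g <- object@geometry
  if (length(d) != 3L || !all(d == c(g@nFrames, g@height, g@width)))
    return("frames dim does not match geometry")
  TRUE
})

setMethod("show", "DffMovie", function(object) {
  g <- object@geometry
  cat(sprintf(
    "DffMovie: %d frames of %d x %d px, peak %.4g (%.3g%%)\n  provenance: %s\n",
    g@nFrames, g@height, g@width, max(object@frames), 100 * max(object@frames),
    paste(object@provenance, collapse = " -> ")
  ))
})

#' Baseline-noise estimate
#'
#' Per-pixel sample SD of the dF/F signal over a pre-stimulus frame
#' window; the detection rule thresholds at a multiple (default 7) of it.
#'
#' @slot perPixelSd numeric matrix, row x col
#' @slot window integer vector of (pre-stimulus) frame indices used
#' @export
setClass("NoiseEstimate",
  representation(perPixelSd = "matrix", window = "integer")
)

setValidity("NoiseEstimate", function(object) {
  if (any(object@perPixelSd < 0)) return("SDs must be >= 0")
  TRUE
})

#' Descriptors of one detected evoked response
#'
#' The initial response is the connected significant region in the first
#' frame with a significant signal increase; its intensity-weighted
#' centroid is the anchor at which the peak amplitude and peak frame are
#' measured.  The maximum response is the significant region containing
#' that centre in the peak frame.  \code{decay9010} is the 90--10\% decay
#' time at the centre (ms), \code{NA} if the trace does not fall below
#' 10\% of peak within the sweep.
#'
#' @slot detected logical
#' @slot site configured site label ("" if none)
#' @slot initialFrame,peakFrame 1-based frame indices (NA if undetected)
#' @slot initialRegion,maxResponseOutline n x 2 integer matrices of (row, col)
#' @slot initialCenter length-2 integer (row, col)
#' @slot peakAmplitude fractional dF/F
#' @slot decay9010 ms, or NA
#' @export
setClass("ResponseMetrics",
  representation(
    detected = "logical", site = "character",
    initialFrame = "integer", initialRegion = "matrix",
    initialCenter = "integer", peakFrame = "integer",
    peakAmplitude = "numeric", maxResponseOutline = "matrix",
    decay9010 = "numeric"
  )
)

setMethod("show", "ResponseMetrics", function(object) {
  if (!object@detected) {
    cat("ResponseMetrics: no significant response detected\n")
    return(invisible(NULL))
  }
  cat(sprintf(
    paste0(
      "ResponseMetrics%s: initial frame %d (%d px region, centre %d,%d); ",
      "peak %.4g%% at frame %d; max outline %d px; 90-10%% decay %s\n"
    ),
    if (nzchar(object@site)) sprintf(" [%s]", object@site) else "",
    object@initialFrame, nrow(object@initialRegion),
    object@initialCenter[1L], object@initialCenter[2L],
    100 * object@peakAmplitude, object@peakFrame,
    nrow(object@maxResponseOutline),
    if (is.na(object@decay9010)) "undefined" else sprintf("%.1f ms", object@decay9010)
  ))
})

#' Rigid (rotation + translation) image transform
#'
#' Maps a point p to R(p - pivot) + pivot + translation, with R the
#' rotation by \code{rotation} degrees in (row, col) coordinates.
#'
#' @slot rotation degrees
#' @slot translation length-2 numeric (row, col) offset
#' @slot pivot length-2 numeric (row, col) rotation centre
#' @export
setClass("RigidTransform",
  representation(rotation = "numeric", translation = "numeric", pivot = "numeric")
)

setValidity("RigidTransform", function(object) {
  if (!all(is.finite(c(object@rotation, object@translation, object@pivot))) ||
      length(object@translation) != 2L || length(object@pivot) != 2L)
    return("rotation, translation (2) and pivot (2) must be finite")
  TRUE
})

#' @param rotation,translation,pivot see slots
#' @rdname RigidTransform-class
#' @export
RigidTransform <- function(rotation = 0, translation = c(0, 0), pivot = c(0, 0)) {
  new("RigidTransform",
    rotation = as.numeric(rotation),
    translation = as.numeric(translation), pivot = as.numeric(pivot)
  )
}

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf(
    "RigidTransform: %.3f deg about (%.2f, %.2f), translation (%.2f, %.2f)\n",
    object@rotation, object@pivot[1L], object@pivot[2L],
    object@translation[1L], object@translation[2L]
  ))
})

#' Cross-animal overlap (incidence) map
#'
#' Per-pixel count of animals whose aligned maximum-response outline
#' covers the pixel, and the mask of pixels covered in at least
#' \code{fraction} of animals (count >= ceiling(fraction * nAnimals)).
#'
#' @slot counts integer matrix, row x col
#' @slot nAnimals number of non-excluded animals
#' @slot contourMask logical matrix of the majority region
#' @slot fraction threshold fraction (default 0.5)
#' @slot excludedAnimals labels of animals excluded (unresolvable landmarks)
#' @export
setClass("OverlapMap",
  representation(
    counts = "matrix", nAnimals = "integer", contourMask = "matrix",
    fraction = "numeric", excludedAnimals = "character"
  )
)

setValidity("OverlapMap", function(object) {
  msg <- character()
  if (any(object@counts < 0L) || any(object@counts > object@nAnimals))
    msg <- c(msg, "counts must lie in 0..nAnimals")
  if (any(object@contourMask & object@counts < 1L))
    msg <- c(msg, "contourMask must be within covered pixels")
  if (length(msg)) msg else TRUE
})

setMethod("show", "OverlapMap", function(object) {
  cat(sprintf(
    "OverlapMap: %d animals (%d excluded), max count %d, >=%d%% contour %d px\n",
    object@nAnimals, length(object@excludedAnimals), max(object@counts),
    round(100 * object@fraction), sum(object@contourMask)
  ))
})

#' Pooled two-sample Student's t-test result
#'
#' @slot t statistic
#' @slot df degrees of freedom (n1 + n2 - 2)
#' @slot p two-sided probability
#' @slot alphaCorrected Bonferroni-family threshold used for the label
#' @slot significant logical
#' @slot degenerate TRUE when both groups had zero variance with unequal
#'   means (t infinite, p reported as 0)
#' @export
setClass("TTestResult",
  representation(
    t = "numeric", df = "numeric", p = "numeric",
    alphaCorrected = "numeric", significant = "logical", degenerate = "logical"
  )
)

setMethod("show", "TTestResult", function(object) {
  cat(sprintf(
    "TTestResult: t = %.4g, df = %g, p = %.4g (%ssignificant at %.4g)%s\n",
    object@t, object@df, object@p,
    if (object@significant) "" else "not ", object@alphaCorrected,
    if (object@degenerate) " [degenerate]" else ""
  ))
})
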