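#' Estimate baseline noise
#'
#' Per-pixel sample SD of the dF/F signal over a pre-stimulus frame
#' window.  The detection rule declares a response significant where the
#' signal exceeds a multiple (default 7) of this SD.
#'
#' @param movie a \code{\link{DffMovie}}
#' @param window integer frame indices (1-based), all pre-stimulus,
#'   length >= 2; default all pre-stimulus frames
#' @param pooled if TRUE, replace the per-pixel map by its global pooled
#'   (root-mean-square) value at every pixel
#' @return a \code{\link{NoiseEstimate}}
#' @export
estimateNoise <- function(movie, window = NULL, pooled = FALSE) {
  g <- movie@geometry
  if (is.null(window)) window <- defaultBaselineWindow(g)
  window <- as.integer(window)
  if (length(window) < 2L) stop("noise window needs at least 2 frames (SD undefined)")
  if (max(window) >= g@stimOnsetFrame || min(window) < 1L)
    stop("noise window must precede the stimulus onset frame")
  x <- movie@frames[window, , , drop = FALSE]
  nw <- length(window)
  m <- colMeans(x)
  ss <- colSums(sweep(x, c(2L, 3L), m, "-")^2)
  sdMap <- sqrt(ss / (nw - 1L))
  if (pooled) sdMap[] <- sqrt(mean(sdMap^2))
  new("NoiseEstimate", perPixelSd = sdMap, window = window)
}

#' Per-frame significance masks
#'
#' A pixel is significant in a frame iff its (positive-going) dF/F value
#' exceeds \code{k} times the baseline-noise SD at that pixel; negative
#' deflections are never significant.  With noiseless synthetic input the
#' SD map is zero everywhere, so an absolute threshold \code{floor}
#' (dF/F units) must be supplied; the effective threshold is
#' \code{max(k * SD, floor)} per pixel.
#'
#' @param movie a \code{\link{DffMovie}}
#' @param noise a \code{\link{NoiseEstimate}}
#' @param k SD multiplier (default 7)
#' @param floor absolute dF/F threshold floor (default 0 = none)
#' @return logical array of the same dimensions as the movie
#' @export
significanceMask <- function(movie, noise, k = 7, floor = 0) {
  stopifnot(k > 0)
  if (!identical(dim(noise@perPixelSd), dim(movie@frames)[2:3]))
    stop("noise map shape does not match the movie")
  if (all(noise@perPixelSd == 0) && floor <= 0)
    stop("all-zero noise SD map: supply an absolute threshold floor")
  thr <- pmax(k * noise@perPixelSd, floor)
  sweep(movie@frames, c(2L, 3L), thr, ">")
}

#' Extract the initial response
#'
#' The initial frame is the earliest frame containing at least
#' \code{mMin} significant pixels (a speckle guard); the initial region
#' is the largest 8-connected significant component in that frame, and
#' the initial centre is its intensity-weighted centroid rounded to the
#' nearest pixel.
#'
#' @param masks logical array from \code{\link{significanceMask}}
#' @param movie the \code{\link{DffMovie}} the masks were computed from
#' @param mMin minimum significant pixels to declare the initial frame
#' @return list(detected, initialFrame, initialRegion, initialCenter);
#'   \code{detected = FALSE} (not an error) when no frame qualifies
#' @export
extractInitialResponse <- function(masks, movie, mMin = 5L) {
  counts <- apply(masks, 1L, sum)
  qual <- which(counts >= mMin)
  if (length(qual) == 0L) {
    return(list(detected = FALSE, initialFrame = NA_integer_,
                initialRegion = matrix(integer(), 0L, 2L),
                initialCenter = c(NA_integer_, NA_integer_)))
  }
  f0 <- qual[1L]
  comps <- connectedComponents(masks[f0, , ])
  region <- comps[[1L]]
  wts <- movie@frames[cbind(f0, region[, 1L], region[, 2L])]
  center <- round(c(
    sum(region[, 1L] * wts) / sum(wts),
    sum(region[, 2L] * wts) / sum(wts)
  ))
  list(detected = TRUE, initialFrame = as.integer(f0),
       initialRegion = region, initialCenter = as.integer(center))
}

#' Extract the peak descriptors
#'
#' The peak frame is the earliest argmax over frames >= initialFrame of
#' the signal at the initial-response centre; the peak amplitude is that
#' maximum.  The maximum-response outline is the 8-connected significant
#' component containing the centre in the peak frame.  The 90--10\% decay
#' time is measured on the falling phase of the centre trace with linear
#' interpolation between frames; it is \code{NA} when the trace does not
#' fall below 10\% of peak within the sweep.
#'
#' @param movie a \code{\link{DffMovie}}
#' @param masks logical array from \code{\link{significanceMask}}
#' @param initialCenter integer (row, col)
#' @param initialFrame integer frame index
#' @return list(peakFrame, peakAmplitude, maxResponseOutline, decay9010)
#' @export
extractPeak <- function(movie, masks, initialCenter, initialFrame) {
  g <- movie@geometry
  trace <- movie@frames[, initialCenter[1L], initialCenter[2L]]
  cand <- initialFrame:g@nFrames
  peakFrame <- cand[which.max(trace[cand])]
  peakAmplitude <- trace[peakFrame]
  comps <- connectedComponents(masks[peakFrame, , ])
  outline <- matrix(integer(), 0L, 2L)
  for (comp in comps) {
    if (any(comp[, 1L] == initialCenter[1L] & comp[, 2L] == initialCenter[2L])) {
      outline <- comp
      break
    }
  }
  decay <- .decayTime(trace, peakFrame, g@frameInterval)
  list(peakFrame = as.integer(peakFrame), peakAmplitude = peakAmplitude,
       maxResponseOutline = outline, decay9010 = decay)
}

# 90-10% decay time (ms) on the falling phase of a trace, linear
# interpolation between frames; NA when 10% is never reached.
.decayTime <- function(trace, peakFrame, frameInterval) {
  peak <- trace[peakFrame]
  if (peak <= 0) return(NA_real_)
  post <- trace[peakFrame:length(trace)]
  crossDown <- function(level) {
    below <- which(post < level)
    if (length(below) == 0L) return(NA_real_)
    i <- below[1L]
    if (i == 1L) return(0)
    frac <- (post[i - 1L] - level) / (post[i - 1L] - post[i])
    (i - 2L + frac) * frameInterval
  }
  t90 <- crossDown(0.9 * peak)
  t10 <- crossDown(0.1 * peak)
  if (is.na(t10) || is.na(t90)) return(NA_real_)
  t10 - t90
}

#' Detect an evoked response and assemble its descriptors
#'
#' Runs noise estimation, 7xSD thresholding, initial-response and peak
#' extraction on a (smoothed) dF/F movie and returns a
#' \code{\link{ResponseMetrics}} object.  \code{within} optionally
#' restricts detection to a disc around a configured site centre, so the
#' responses of two cortical sites (e.g. S1 and S2/IOR) in the same movie
#' can be measured separately; the site label comes from configuration,
#' never from anatomy inference.
#'
#' @param movie a \code{\link{DffMovie}}
#' @param k SD multiplier (default 7)
#' @param mMin speckle guard, minimum pixels in the initial frame
#' @param baselineWindow noise window (default all pre-stimulus frames)
#' @param floor absolute threshold floor, dF/F units
#' @param within optional list(center = c(row, col), radius = px)
#' @param site optional site label carried into the result
#' @param pooledNoise use the globally pooled SD instead of per-pixel
#' @return a \code{\link{ResponseMetrics}}
#' @export
detectResponse <- function(movie, k = 7, mMin = 5L, baselineWindow = NULL,
                           floor = 0, within = NULL, site = "",
                           pooledNoise = FALSE) {
  noise <- estimateNoise(movie, baselineWindow, pooled = pooledNoise)
  masks <- significanceMask(movie, noise, k = k, floor = floor)
  if (!is.null(within)) {
    g <- movie@geometry
    disc <- discMask(g@height, g@width, within$center, within$radius)
    masks <- sweep(masks, c(2L, 3L), disc, "&")
  }
  init <- extractInitialResponse(masks, movie, mMin = mMin)
  if (!init$detected) {
    return(new("ResponseMetrics",
      detected = FALSE, site = site, initialFrame = NA_integer_,
      initialRegion = matrix(integer(), 0L, 2L),
      initialCenter = c(NA_integer_, NA_integer_), peakFrame = NA_integer_,
      peakAmplitude = NA_real_, maxResponseOutline = matrix(integer(), 0L, 2L),
      decay9010 = NA_real_
    ))
  }
  pk <- extractPeak(movie, masks, init$initialCenter, init$initialFrame)
  new("ResponseMetrics",
    detected = TRUE, site = site, initialFrame = init$initialFrame,
    initialRegion = init$initialRegion, initialCenter = init$initialCenter,
    peakFrame = pk$peakFrame, peakAmplitude = pk$peakAmplitude,
    maxResponseOutline = pk$maxResponseOutline, decay9010 = pk$decay9010
  )
}

#' ROI time course
#'
#' Mean dF/F per frame over a disc of the given radius (0 = the single
#' centre pixel), exported as a table with explicit time in ms.
#'
#' @param movie a \code{\link{DffMovie}}
#' @param center integer (row, col)
#' @param radius disc radius, pixels
#' @return data.frame(frame, time_ms, dff)
#' @export
roiTimecourse <- function(movie, center, radius = 0) {
  g <- movie@geometry
  if (center[1L] - radius < 1 || center[1L] + radius > g@height ||
      center[2L] - radius < 1 || center[2L] + radius > g@width)
    stop("ROI extends outside the field of view")
  disc <- discMask(g@height, g@width, center, radius)
  idx <- which(disc)
  flat <- matrix(movie@frames, nrow = g@nFrames)
  vals <- flat[, idx, drop = FALSE]
  data.frame(
    frame = seq_len(g@nFrames),
    time_ms = frameTimes(g),
    dff = rowMeans(vals)
  )
}
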