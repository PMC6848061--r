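#' Remove dye bleaching by blank subtraction
#'
#' Subtracts a no-stimulation (blank) acquisition framewise from a
#' stimulated one, removing the shared bleaching drift, then re-references
#' the difference by adding back the blank's per-pixel pre-stimulus mean
#' so the subsequent dF/F denominator stays a physical fluorescence level.
#'
#' @param stim stimulated \code{\link{TrialStack}}
#' @param blank blank \code{\link{TrialStack}} with identical geometry
#' @return a bleach-corrected stimulated \code{TrialStack}
#' @export
subtractBlank <- function(stim, blank) {
  if (stim@kind != "stimulated" || blank@kind != "blank")
    stop("subtractBlank() needs one stimulated and one blank stack, got ",
         stim@kind, " and ", blank@kind)
  if (!identical(dim(stim@frames), dim(blank@frames)))
    stop(sprintf(
      "geometry mismatch: stimulated is (%s), blank is (%s)",
      paste(dim(stim@frames), collapse = "x"),
      paste(dim(blank@frames), collapse = "x")
    ))
  win <- defaultBaselineWindow(stim@geometry)
  blankBase <- colMeans(blank@frames[win, , , drop = FALSE])
  diff <- stim@frames - blank@frames
  diff <- sweep(diff, c(2L, 3L), blankBase, "+")
  TrialStack(diff, stim@geometry, "stimulated", stim@landmarks,
             bleachCorrected = TRUE,
             provenance = c(stim@provenance, "subtract"))
}

#' Average a sequence of trials
#'
#' Pixelwise arithmetic mean of stacks of identical geometry and kind;
#' white sensor noise is reduced by 1/sqrt(n).
#'
#' @param trials list of \code{\link{TrialStack}} objects
#' @return the mean \code{TrialStack}
#' @export
averageTrials <- function(trials) {
  if (length(trials) == 0L) stop("averageTrials() needs at least one trial")
  kinds <- vapply(trials, function(s) s@kind, character(1))
  if (length(unique(kinds)) != 1L)
    stop("trials of mixed kind cannot be averaged: ",
         paste(unique(kinds), collapse = ", "))
  dims <- vapply(trials, function(s) paste(dim(s@frames), collapse = "x"), character(1))
  if (length(unique(dims)) != 1L) stop("trials differ in geometry")
  mean_ <- Reduce(`+`, lapply(trials, function(s) s@frames)) / length(trials)
  first <- trials[[1L]]
  TrialStack(mean_, first@geometry, first@kind, first@landmarks,
             bleachCorrected = first@bleachCorrected,
             provenance = c(first@provenance, "average"))
}

#' Compute the dF/F movie
#'
#' Per pixel, F is the mean raw fluorescence over the pre-stimulus
#' baseline window and every frame becomes (value - F) / F.  Baseline
#' frames therefore average to zero at every pixel.
#'
#' @param stack a \code{\link{TrialStack}}
#' @param baselineWindow integer frame indices (1-based) preceding the
#'   stimulus; default all pre-stimulus frames
#' @return a \code{\link{DffMovie}}
#' @export
computeDff <- function(stack, baselineWindow = NULL) {
  g <- stack@geometry
  if (is.null(baselineWindow)) baselineWindow <- defaultBaselineWindow(g)
  baselineWindow <- as.integer(baselineWindow)
  if (length(baselineWindow) == 0L) stop("baseline window is empty")
  if (max(baselineWindow) >= g@stimOnsetFrame || min(baselineWindow) < 1L)
    stop("baseline window must precede the stimulus onset frame")
  f0 <- colMeans(stack@frames[baselineWindow, , , drop = FALSE])
  if (any(f0 <= 0)) {
    bad <- which(f0 <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-positive baseline fluorescence at pixel (row %d, col %d)",
                 bad[1L], bad[2L]))
  }
  dff <- sweep(sweep(stack@frames, c(2L, 3L), f0, "-"), c(2L, 3L), f0, "/")
  new("DffMovie", frames = dff, geometry = g,
      provenance = c(stack@provenance, "dff"))
}

#' Spatial smoothing of a dF/F movie
#'
#' Applies a per-frame 2-D mean (box) filter of odd size \code{kernelSize}
#' (default 9 x 9), or a Gaussian of the same footprint, with symmetric
#' border padding so spatially constant frames are unchanged.
#'
#' @param movie a \code{\link{DffMovie}}
#' @param kernelSize odd kernel width in pixels
#' @param type "box" (default) or "gaussian"
#' @return the smoothed \code{DffMovie}
#' @export
spatialFilter <- function(movie, kernelSize = 9L, type = c("box", "gaussian")) {
  type <- match.arg(type)
  kernelSize <- as.integer(kernelSize)
  if (kernelSize < 1L || kernelSize %% 2L == 0L)
    stop("kernelSize must be an odd positive integer")
  out <- movie@frames
  if (kernelSize > 1L) {
    fun <- if (type == "box") boxFilter2D else gaussFilter2D
    for (f in seq_len(dim(out)[1L])) out[f, , ] <- fun(out[f, , ], kernelSize)
  }
  new("DffMovie", frames = out, geometry = movie@geometry,
      provenance = c(movie@provenance, "filter"))
}

#' Full preprocessing driver
#'
#' Enforces the canonical order subtract -> average -> dF/F -> filter on a
#' set of stimulated/blank trial pairs and records it in the provenance.
#'
#' @param stim,blank lists of stimulated and blank \code{TrialStack}s,
#'   paired by position
#' @param baselineWindow see \code{\link{computeDff}}
#' @param kernelSize see \code{\link{spatialFilter}}; 1 disables smoothing
#' @param filterType "box" or "gaussian"
#' @return a smoothed \code{\link{DffMovie}}
#' @export
preprocessTrials <- function(stim, blank, baselineWindow = NULL,
                             kernelSize = 9L, filterType = "box") {
  if (length(stim) != length(blank))
    stop("stim and blank trial lists differ in length")
  corrected <- mapply(subtractBlank, stim, blank, SIMPLIFY = FALSE)
  avg <- averageTrials(corrected)
  dff <- computeDff(avg, baselineWindow)
  spatialFilter(dff, kernelSize, filterType)
}
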