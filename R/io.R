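# TIFF + JSON-sidecar stack I/O and CSV table I/O.

.sidecarPath <- function(path) paste0(path, ".json")

.landmarksToList <- function(lm) {
  list(
    mca_points = unname(apply(lm@mcaPoints, 1L, as.numeric, simplify = FALSE)),
    rf_points = unname(apply(lm@rfPoints, 1L, as.numeric, simplify = FALSE)),
    resolvable = lm@resolvable
  )
}

.landmarksFromList <- function(x) {
  asMat <- function(v) if (is.matrix(v)) v else do.call(rbind, v)
  LandmarkFrame(
    mcaPoints = asMat(x$mca_points),
    rfPoints = asMat(x$rf_points),
    resolvable = isTRUE(x$resolvable)
  )
}

#' Write a trial stack as multi-page TIFF with a JSON sidecar
#'
#' Frames are stored as 16-bit unsigned integers with a floating-point
#' scale factor recorded in the sidecar (raw fluorescence is in arbitrary
#' units, so exactness is preserved by the scale).  The sidecar carries
#' the geometry, the stack kind, the landmarks and the provenance.
#'
#' @param stack a \code{\link{TrialStack}}
#' @param path output TIFF path; the sidecar is written to
#'   \code{paste0(path, ".json")}
#' @return \code{path}, invisibly
#' @export
writeStack <- function(stack, path) {
  g <- stack@geometry
  mx <- max(stack@frames)
  # integer payloads within 16-bit range are stored losslessly at scale 1
  scale <- if (mx <= 65535 && min(stack@frames) >= 0 &&
               all(stack@frames == round(stack@frames))) {
    1
  } else if (mx > 0) {
    mx / 65535
  } else {
    1
  }
  pages <- lapply(seq_len(g@nFrames), function(f) {
    round(stack@frames[f, , ] / scale) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  sidecar <- list(
    geometry = list(
      frame_interval_ms = g@frameInterval, n_frames = g@nFrames,
      height = g@height, width = g@width,
      mm_per_pixel_x = g@mmPerPixelX, mm_per_pixel_y = g@mmPerPixelY,
      stim_onset_frame = g@stimOnsetFrame,
      duration_ms = g@nFrames * g@frameInterval
    ),
    kind = stack@kind,
    scale = scale,
    bleach_corrected = stack@bleachCorrected,
    provenance = as.list(stack@provenance),
    landmarks = .landmarksToList(stack@landmarks)
  )
  jsonlite::write_json(sidecar, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a trial stack written by \code{\link{writeStack}}
#'
#' Validates the TIFF payload against the sidecar: a missing sidecar and
#' any mismatch between the recorded geometry and the actual page count
#' or page size are errors.  For 16-bit payloads write-then-read is
#' bit-exact.
#'
#' @param path TIFF path
#' @return a \code{\link{TrialStack}}
#' @export
readStack <- function(path) {
  sc <- .sidecarPath(path)
  if (!file.exists(sc))
    stop("missing sidecar: expected ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  gm <- meta$geometry
  g <- AcquisitionGeometry(
    frameInterval = gm$frame_interval_ms, nFrames = gm$n_frames,
    height = gm$height, width = gm$width,
    mmPerPixelX = gm$mm_per_pixel_x, mmPerPixelY = gm$mm_per_pixel_y,
    stimOnsetFrame = gm$stim_onset_frame
  )
  if (length(pages) != g@nFrames)
    stop(sprintf("sidecar records %d frames but TIFF has %d pages",
                 g@nFrames, length(pages)))
  if (!all(dim(pages[[1L]]) == c(g@height, g@width)))
    stop(sprintf("sidecar geometry %dx%d does not match TIFF pages %s",
                 g@height, g@width, paste(dim(pages[[1L]]), collapse = "x")))
  arr <- array(0, dim = c(g@nFrames, g@height, g@width))
  for (f in seq_along(pages)) arr[f, , ] <- round(pages[[f]] * 65535) * meta$scale
  lmk <- .landmarksFromList(meta$landmarks)
  TrialStack(arr, g, meta$kind, lmk,
             bleachCorrected = isTRUE(meta$bleach_corrected),
             provenance = unlist(meta$provenance) %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export response metrics as JSON
#'
#' Writes every \code{\link{ResponseMetrics}} field (frames, pixel sets,
#' amplitudes, decay) plus an optional provenance record.
#'
#' @param metrics a \code{\link{ResponseMetrics}}
#' @param path output JSON path
#' @param provenance optional character vector recorded alongside
#' @return \code{path}, invisibly
#' @export
writeMetricsJson <- function(metrics, path, provenance = character()) {
  x <- list(
    detected = metrics@detected,
    site = metrics@site,
    initial_frame = metrics@initialFrame,
    initial_region = if (nrow(metrics@initialRegion)) {
      unname(apply(metrics@initialRegion, 1L, as.integer, simplify = FALSE))
    } else list(),
    initial_center = as.integer(metrics@initialCenter),
    peak_frame = metrics@peakFrame,
    peak_amplitude = metrics@peakAmplitude,
    peak_amplitude_pct = 100 * metrics@peakAmplitude,
    max_response_outline = if (nrow(metrics@maxResponseOutline)) {
      unname(apply(metrics@maxResponseOutline, 1L, as.integer, simplify = FALSE))
    } else list(),
    decay_90_10_ms = metrics@decay9010,
    provenance = as.list(provenance)
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read / write von Frey session tables
#'
#' Plain CSV with columns \code{animal_id}, \code{day}, \code{force_g},
#' \code{n_stimuli}, \code{n_withdrawals} (units in the headers).
#' Reading validates the schema and the count invariant
#' 0 <= n_withdrawals <= n_stimuli.
#'
#' @param table data.frame in the schema above
#' @param path CSV path
#' @return \code{readVonFreyCsv}: the validated data.frame
#' @export
writeVonFreyCsv <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeVonFreyCsv
#' @export
readVonFreyCsv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "day", "force_g", "n_stimuli", "n_withdrawals")
  if (!all(need %in% names(x)))
    stop("von Frey CSV must have columns: ", paste(need, collapse = ", "))
  if (any(x$n_withdrawals < 0 | x$n_withdrawals > x$n_stimuli))
    stop("withdrawal counts outside 0..n_stimuli")
  x
}
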