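# Intersection of two lines, each given by a 2x2 matrix of (row, col)
# points.  Errors if the lines are parallel.
lineIntersection <- function(a, b) {
  d1 <- a[2L, ] - a[1L, ]
  d2 <- b[2L, ] - b[1L, ]
  det <- d1[1L] * (-d2[2L]) - (-d2[1L]) * d1[2L]
  if (abs(det) < 1e-12) stop("landmark lines are parallel")
  rhs <- b[1L, ] - a[1L, ]
  t <- (rhs[1L] * (-d2[2L]) - (-d2[1L]) * rhs[2L]) / det
  a[1L, ] + t * d1
}

# Direction angle (degrees, in (-90, 90]) of the line through a 2x2
# point matrix, modulo 180 so the point order is irrelevant.
.lineAngle <- function(p) {
  d <- p[2L, ] - p[1L, ]
  ang <- atan2(d[1L], d[2L]) * 180 / pi
  ang <- ang %% 180
  if (ang > 90) ang <- ang - 180
  ang
}

#' Apply a rigid transform to points
#'
#' @param transform a \code{\link{RigidTransform}}
#' @param points n x 2 matrix (or length-2 vector) of (row, col) points
#' @return transformed points, same shape
#' @export
applyTransform <- function(transform, points) {
  vec <- is.null(dim(points))
  p <- if (vec) matrix(points, 1L, 2L) else points
  th <- transform@rotation * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  centered <- sweep(p, 2L, transform@pivot)
  out <- centered %*% R
  out <- sweep(out, 2L, transform@pivot + transform@translation, "+")
  if (vec) out[1L, ] else out
}

#' Invert a rigid transform
#'
#' \code{applyTransform(invertTransform(t), applyTransform(t, p))}
#' recovers \code{p} to numerical precision.
#'
#' @param transform a \code{\link{RigidTransform}}
#' @return the inverse \code{RigidTransform}
#' @export
invertTransform <- function(transform) {
  RigidTransform(
    rotation = -transform@rotation,
    translation = -transform@translation,
    pivot = transform@pivot + transform@translation
  )
}

#' Fit the landmark alignment transform
#'
#' Maps a moving animal's MCA / rhinal-fissure frame onto a reference
#' frame: the rotation (about the moving frame's line intersection)
#' aligns the rhinal-fissure directions, and the translation maps the
#' moving intersection onto the reference intersection.  Animals whose
#' landmarks are flagged unresolvable cannot be aligned; for them the
#' function returns \code{NULL} (the caller excludes the animal, it is
#' not an error).
#'
#' @param moving,reference \code{\link{LandmarkFrame}} objects
#' @return a \code{\link{RigidTransform}}, or \code{NULL} if either
#'   frame is unresolvable
#' @export
fitLandmarkTransform <- function(moving, reference) {
  if (!moving@resolvable || !reference@resolvable) return(NULL)
  pivotM <- lineIntersection(moving@mcaPoints, moving@rfPoints)
  pivotR <- lineIntersection(reference@mcaPoints, reference@rfPoints)
  dAng <- .lineAngle(reference@rfPoints) - .lineAngle(moving@rfPoints)
  if (dAng > 90) dAng <- dAng - 180
  if (dAng <= -90) dAng <- dAng + 180
  RigidTransform(rotation = dAng, translation = pivotR - pivotM, pivot = pivotM)
}

#' Warp a binary outline
#'
#' Nearest-neighbour mapping of a pixel set under a rigid transform;
#' pixels mapped outside the field are dropped and their count recorded
#' in the \code{"dropped"} attribute.
#'
#' @param outline n x 2 integer matrix of (row, col) pixels
#' @param transform a \code{\link{RigidTransform}}
#' @param geometry the target \code{AcquisitionGeometry}
#' @return m x 2 integer matrix of warped pixels (deduplicated)
#' @export
warpOutline <- function(outline, transform, geometry) {
  if (nrow(outline) == 0L) {
    out <- matrix(integer(), 0L, 2L)
    attr(out, "dropped") <- 0L
    return(out)
  }
  mapped <- round(applyTransform(transform, outline))
  inside <- mapped[, 1L] >= 1 & mapped[, 1L] <= geometry@height &
    mapped[, 2L] >= 1 & mapped[, 2L] <= geometry@width
  kept <- unique(mapped[inside, , drop = FALSE])
  storage.mode(kept) <- "integer"
  colnames(kept) <- c("row", "col")
  attr(kept, "dropped") <- sum(!inside)
  kept
}

#' Build the cross-animal overlap map
#'
#' Counts, per pixel, how many animals' aligned maximum-response outlines
#' cover it, and thresholds the counts at
#' \code{ceiling(fraction * nAnimals)} to obtain the majority contour
#' (the region responding in at least that fraction of animals; with the
#' default 0.5 and odd n this is the strict majority).
#'
#' @param outlines list of aligned n x 2 pixel matrices, one per
#'   non-excluded animal
#' @param geometry the common \code{AcquisitionGeometry}
#' @param fraction threshold fraction of animals (default 0.5)
#' @param excluded labels of excluded animals, recorded in the result
#' @return an \code{\link{OverlapMap}}
#' @export
buildOverlap <- function(outlines, geometry, fraction = 0.5,
                         excluded = character()) {
  if (length(outlines) == 0L)
    stop("no non-excluded animals to overlap")
  counts <- matrix(0L, geometry@height, geometry@width)
  for (o in outlines) {
    if (nrow(o) > 0L) counts[o] <- counts[o] + 1L
  }
  n <- length(outlines)
  thr <- ceiling(fraction * n)
  new("OverlapMap",
    counts = counts, nAnimals = as.integer(n),
    contourMask = counts >= thr, fraction = fraction,
    excludedAnimals = excluded
  )
}

#' Boundary pixels of a mask
#'
#' The pixels of a logical mask having at least one 8-neighbour (or
#' field border) outside the mask; exported as the contour polyline of an
#' overlap map.
#'
#' @param mask logical matrix
#' @return n x 2 integer matrix of boundary (row, col) pixels
#' @export
maskBoundary <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  padded <- matrix(FALSE, h + 2L, w + 2L)
  padded[2:(h + 1L), 2:(w + 1L)] <- mask
  interior <- matrix(TRUE, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    interior <- interior & padded[(2:(h + 1L)) + dr, (2:(w + 1L)) + dc]
  }
  bd <- which(mask & !interior, arr.ind = TRUE)
  colnames(bd) <- c("row", "col")
  bd
}
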