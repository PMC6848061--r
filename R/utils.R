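# Internal numerics shared across modules.

# Frame times in ms for a geometry (frame i covers [(i-1)*dt, i*dt)).
frameTimes <- function(geometry) {
  (seq_len(geometry@nFrames) - 1) * geometry@frameInterval
}

# Default pre-stimulus baseline window: all frames before the stimulus.
defaultBaselineWindow <- function(geometry) {
  if (geometry@stimOnsetFrame < 2L)
    stop("geometry has no pre-stimulus frames for a baseline window")
  seq_len(geometry@stimOnsetFrame - 1L)
}

# 1-D running mean of the columns of a matrix with symmetric (mirrored,
# edge included) border padding.  k must be odd.
.boxCols <- function(m, k) {
  n <- nrow(m)
  h <- (k - 1L) %/% 2L
  idx <- c(pmin(h:1, n), seq_len(n), pmax(n - seq_len(h) + 1L, 1L))
  padded <- m[idx, , drop = FALSE]
  cs <- apply(padded, 2L, cumsum)
  cs <- rbind(0, cs)
  (cs[(k + 1L):(k + n), , drop = FALSE] - cs[seq_len(n), , drop = FALSE]) / k
}

# Separable 2-D uniform (box) mean filter with symmetric border padding.
boxFilter2D <- function(m, k) {
  t(.boxCols(t(.boxCols(m, k)), k))
}

# 2-D Gaussian smoothing via a truncated, normalized separable kernel of
# width k (sigma = k/4), same border rule as the box filter.
gaussFilter2D <- function(m, k) {
  h <- (k - 1L) %/% 2L
  w <- exp(-((-h):h)^2 / (2 * (k / 4)^2))
  w <- w / sum(w)
  conv <- function(x) {
    n <- nrow(x)
    idx <- c(pmin(h:1, n), seq_len(n), pmax(n - seq_len(h) + 1L, 1L))
    padded <- x[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(x))
    for (j in seq_len(k)) out <- out + w[j] * padded[(j - 1L) + seq_len(n), , drop = FALSE]
    out
  }
  t(conv(t(conv(m))))
}

# 8-connected components of a logical matrix.  Returns a list of n x 2
# integer matrices of (row, col) pixel coordinates, largest first.
connectedComponents <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  on <- which(mask)
  if (length(on) == 0L) return(list())
  remaining <- rep(TRUE, h * w)
  remaining[-on] <- FALSE
  offsets <- c(-1L, 1L, -h, h, -h - 1L, -h + 1L, h - 1L, h + 1L)
  comps <- list()
  for (seed in on) {
    if (!remaining[seed]) next
    comp <- integer(0)
    frontier <- seed
    remaining[seed] <- FALSE
    while (length(frontier)) {
      comp <- c(comp, frontier)
      rows <- ((frontier - 1L) %% h) + 1L
      nbr <- rep(frontier, each = 8L) + offsets
      rowsRep <- rep(rows, each = 8L)
      nbrRows <- ((nbr - 1L) %% h) + 1L
      ok <- nbr >= 1L & nbr <= h * w & abs(nbrRows - rowsRep) <= 1L
      nbr <- unique(nbr[ok])
      frontier <- nbr[remaining[nbr]]
      remaining[frontier] <- FALSE
    }
    comps[[length(comps) + 1L]] <- comp
  }
  comps <- comps[order(vapply(comps, length, integer(1)), decreasing = TRUE)]
  lapply(comps, function(ix) {
    cbind(row = ((ix - 1L) %% h) + 1L, col = ((ix - 1L) %/% h) + 1L)
  })
}

# Logical disc mask of a given radius (pixels) around an integer centre.
discMask <- function(h, w, center, radius) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rr - center[1L])^2 + (cc - center[2L])^2 <= radius^2
}

# Derive a reproducible 32-bit sub-seed from a base seed and a stream id.
subSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(stream) * 12289) %% 2147483647)
}
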