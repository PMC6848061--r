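# Independent brute-force references, written with plain loops and kept
# deliberately separate from the package's code paths.

# Direct O(n^2 k^2) box convolution with symmetric (edge-included)
# mirror padding.
oracleBoxFilter <- function(m, k) {
  h <- nrow(m); w <- ncol(m); half <- (k - 1) / 2
  reflect <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- matrix(0, h, w)
  for (r in 1:h) for (c in 1:w) {
    acc <- 0
    for (dr in -half:half) for (dc in -half:half) {
      acc <- acc + m[reflect(r + dr, h), reflect(c + dc, w)]
    }
    out[r, c] <- acc / k^2
  }
  out
}

# Recursive-free flood fill, 8-connectivity, over a logical matrix.
oracleComponents <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nextLab <- 0L
  for (r0 in 1:h) for (c0 in 1:w) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    nextLab <- nextLab + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- nextLab
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1L] + dr; c <- p[2L] + dc
        if (r >= 1 && r <= h && c >= 1 && c <= w &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nextLab
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lapply(seq_len(nextLab), function(l) which(lab == l, arr.ind = TRUE))
}

# Exhaustive reference for initial-response / peak extraction.  thrMap
# is the per-pixel absolute threshold; returns the same descriptors as
# the package path.
oracleDetect <- function(arr, thrMap, mMin = 5L) {
  nF <- dim(arr)[1L]
  initFrame <- NA_integer_
  for (f in 1:nF) {
    sig <- matrix(FALSE, dim(arr)[2L], dim(arr)[3L])
    for (r in seq_len(dim(arr)[2L])) for (c in seq_len(dim(arr)[3L])) {
      sig[r, c] <- arr[f, r, c] > thrMap[r, c]
    }
    if (sum(sig) >= mMin) { initFrame <- f; initMask <- sig; break }
  }
  if (is.na(initFrame)) return(list(detected = FALSE))
  comps <- oracleComponents(initMask)
  sizes <- vapply(comps, nrow, integer(1))
  region <- comps[[which.max(sizes)]]
  wts <- numeric(nrow(region))
  for (i in seq_len(nrow(region))) wts[i] <- arr[initFrame, region[i, 1L], region[i, 2L]]
  center <- round(c(sum(region[, 1L] * wts), sum(region[, 2L] * wts)) / sum(wts))
  best <- initFrame
  for (f in initFrame:nF) {
    if (arr[f, center[1L], center[2L]] > arr[best, center[1L], center[2L]]) best <- f
  }
  list(detected = TRUE, initialFrame = initFrame, region = region,
       center = as.integer(center), peakFrame = best,
       peakAmplitude = arr[best, center[1L], center[2L]])
}

# Canonical pixel-set representation for set comparisons.
pixKey <- function(m) sort(paste(m[, 1L], m[, 2L]))
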