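#' Group summary (mean, SEM, n)
#'
#' @param values numeric vector of per-animal measurements
#' @param label group label
#' @return data.frame(label, mean, sem, n); \code{sem} is the sample SD
#'   (n - 1 denominator) over sqrt(n), \code{NA} when n = 1
#' @export
summarizeGroup <- function(values, label = "") {
  n <- length(values)
  if (n == 0L) stop("cannot summarize an empty group")
  data.frame(
    label = label,
    mean = mean(values),
    sem = if (n >= 2L) sd(values) / sqrt(n) else NA_real_,
    n = n,
    stringsAsFactors = FALSE
  )
}

#' Pooled two-sample Student's t-test from summary statistics
#'
#' Reconstructs each group SD as SEM * sqrt(n), pools the variances with
#' n1 + n2 - 2 degrees of freedom, and evaluates the classic (equal
#' variance) Student's t with a two-sided p.  Works directly from
#' printed (mean, SEM, N) triplets, which raw-data routines cannot.
#' When both SDs are zero: equal means give t = 0, p = 1; unequal means
#' are the degenerate infinite-t case, reported as p = 0 with
#' \code{degenerate = TRUE}.  A Welch variant (unpooled variances,
#' Welch-Satterthwaite df) is available behind \code{welch = TRUE}.
#'
#' @param meanA,semA,nA,meanB,semB,nB group summaries
#' @param familySize,alpha Bonferroni-family labelling, see
#'   \code{\link{bonferroniLabel}}
#' @param welch use the Welch (unpooled) variant
#' @param strictPrinted see \code{\link{bonferroniLabel}}
#' @return a \code{\link{TTestResult}}
#' @export
tTestFromSummary <- function(meanA, semA, nA, meanB, semB, nB,
                             familySize = 3L, alpha = 0.05,
                             welch = FALSE, strictPrinted = FALSE) {
  stopifnot(nA >= 2L, nB >= 2L)
  sdA <- semA * sqrt(nA)
  sdB <- semB * sqrt(nB)
  degenerate <- FALSE
  if (welch) {
    seSq <- sdA^2 / nA + sdB^2 / nB
    if (seSq == 0) {
      if (meanA == meanB) {
        t <- 0; df <- nA + nB - 2; p <- 1
      } else {
        t <- sign(meanA - meanB) * Inf; df <- nA + nB - 2; p <- 0
        degenerate <- TRUE
      }
    } else {
      t <- (meanA - meanB) / sqrt(seSq)
      df <- seSq^2 / ((sdA^2 / nA)^2 / (nA - 1) + (sdB^2 / nB)^2 / (nB - 1))
      p <- 2 * pt(-abs(t), df)
    }
  } else {
    df <- nA + nB - 2
    spSq <- ((nA - 1) * sdA^2 + (nB - 1) * sdB^2) / df
    if (spSq == 0) {
      if (meanA == meanB) {
        t <- 0; p <- 1
      } else {
        t <- sign(meanA - meanB) * Inf; p <- 0
        degenerate <- TRUE
      }
    } else {
      t <- (meanA - meanB) / (sqrt(spSq) * sqrt(1 / nA + 1 / nB))
      p <- 2 * pt(-abs(t), df)
    }
  }
  lab <- bonferroniLabel(p, familySize, alpha, strictPrinted)
  new("TTestResult",
    t = t, df = df, p = p, alphaCorrected = lab$alphaCorrected,
    significant = lab$significant, degenerate = degenerate
  )
}

#' Pooled two-sample Student's t-test from raw values
#'
#' Summarizes each group and delegates to
#' \code{\link{tTestFromSummary}}; by construction the two routes agree
#' to numerical precision.
#'
#' @param a,b numeric vectors (each n >= 2)
#' @inheritParams tTestFromSummary
#' @return a \code{\link{TTestResult}}
#' @export
tTestFromRaw <- function(a, b, familySize = 3L, alpha = 0.05,
                         welch = FALSE, strictPrinted = FALSE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  sa <- summarizeGroup(a)
  sb <- summarizeGroup(b)
  tTestFromSummary(sa$mean, sa$sem, sa$n, sb$mean, sb$sem, sb$n,
                   familySize = familySize, alpha = alpha, welch = welch,
                   strictPrinted = strictPrinted)
}

#' Bonferroni-family significance labelling
#'
#' The per-comparison threshold is alpha / familySize.  Its presentation
#' follows the round-down convention that prints 0.05 / 3 as 0.016, but
#' by default significance is decided against the exact quotient
#' (0.01666...); \code{strictPrinted = TRUE} decides against the printed
#' 3-decimal value instead.
#'
#' @param p two-sided probability
#' @param familySize number of comparisons in the family (default 3)
#' @param alpha family-wise level (default 0.05)
#' @param strictPrinted decide against the printed threshold
#' @return list(alphaCorrected = printed threshold, alphaExact,
#'   significant)
#' @export
bonferroniLabel <- function(p, familySize = 3L, alpha = 0.05,
                            strictPrinted = FALSE) {
  stopifnot(familySize >= 1L)
  exact <- alpha / familySize
  printed <- floor(exact * 1000) / 1000
  list(
    alphaCorrected = printed,
    alphaExact = exact,
    significant = p < (if (strictPrinted) printed else exact)
  )
}

#' All pairwise group comparisons of a summary table
#'
#' For every stimulation-site / cortical-region cell of a group-summary
#' table, runs the pooled t-test on each pair of groups and labels it
#' against the Bonferroni-corrected threshold (family = number of
#' pairwise comparisons per cell, default 3).
#'
#' @param tbl data.frame with columns \code{stimulation}, \code{region},
#'   \code{group}, \code{mean_pct}, \code{sem_pct}, \code{n}
#' @param familySize,alpha,strictPrinted see \code{\link{bonferroniLabel}}
#' @return data.frame with one row per comparison: stimulation, region,
#'   group_a, group_b, t, df, p, alpha_corrected, significant
#' @export
compareGroupTable <- function(tbl, familySize = 3L, alpha = 0.05,
                              strictPrinted = FALSE) {
  need <- c("stimulation", "region", "group", "mean_pct", "sem_pct", "n")
  stopifnot(all(need %in% names(tbl)))
  cells <- unique(tbl[, c("stimulation", "region")])
  out <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- tbl[tbl$stimulation == cells$stimulation[i] &
                  tbl$region == cells$region[i], ]
    grps <- unique(cell$group)
    for (a in seq_along(grps)) {
      for (b in seq_along(grps)) {
        if (b <= a) next
        ga <- cell[cell$group == grps[a], ][1L, ]
        gb <- cell[cell$group == grps[b], ][1L, ]
        res <- tTestFromSummary(ga$mean_pct, ga$sem_pct, ga$n,
                                gb$mean_pct, gb$sem_pct, gb$n,
                                familySize = familySize, alpha = alpha,
                                strictPrinted = strictPrinted)
        out[[length(out) + 1L]] <- data.frame(
          stimulation = cells$stimulation[i], region = cells$region[i],
          group_a = grps[a], group_b = grps[b],
          t = res@t, df = res@df, p = res@p,
          alpha_corrected = res@alphaCorrected,
          significant = res@significant,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, out)
}

#' Printed group summaries of the pl-ION imaging study
#'
#' Loads the table of published per-group peak-amplitude summaries
#' (mean % dF/F, SEM, N) for each stimulation site and cortical region:
#' whisker pad (S1/S2 jointly), mandibular molar pulp and mentum skin
#' (S1 and S2/IOR separately), for the sham, pl-ION and
#' pl-ION + minocycline groups 3 days after surgery.  Shipped as plain
#' CSV under \code{inst/extdata}; used to reconstruct the study's group
#' statistics and to calibrate synthetic cohorts.
#'
#' @return data.frame(stimulation, region, group, mean_pct, sem_pct, n)
#' @export
groupSummaryTable <- function() {
  path <- system.file("extdata", "group_summaries.csv", package = "vsdmap",
                      mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
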