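#' Head-withdrawal threshold for one animal-day session
#'
#' The HWT is the minimum tested filament force whose withdrawal count
#' reaches the criterion (default 3 of 5).  When no force qualifies the
#' threshold is censored above the strongest filament and reported as
#' \code{Inf} with \code{censored = TRUE}; censored values are never
#' averaged into group summaries.
#'
#' @param forces tested forces, grams
#' @param withdrawals withdrawal counts, same length
#' @param nStimuli stimuli applied per force (default 5)
#' @param criterion withdrawals required (default 3, i.e. >= 3 of 5; the
#'   stricter > 3 variant is \code{criterion = 4})
#' @return list(hwt_g, censored)
#' @export
computeHwt <- function(forces, withdrawals, nStimuli = 5L, criterion = 3L) {
  if (length(forces) != length(withdrawals))
    stop("forces and withdrawals differ in length")
  if (anyDuplicated(forces))
    stop("duplicate force rows within a session")
  if (any(withdrawals < 0 | withdrawals > nStimuli))
    stop("withdrawal counts must lie in 0..nStimuli")
  ord <- order(forces)
  qual <- withdrawals[ord] >= criterion
  if (!any(qual)) return(list(hwt_g = Inf, censored = TRUE))
  list(hwt_g = forces[ord][which(qual)[1L]], censored = FALSE)
}

#' Longitudinal HWT profiles and per-day group summaries
#'
#' Applies the HWT rule to every (animal, day) session of a von Frey
#' trial table and summarizes each day across animals.  Group means and
#' SEMs are computed on uncensored thresholds only; censored counts are
#' reported separately.
#'
#' @param table data.frame with columns \code{animal_id}, \code{day},
#'   \code{force_g}, \code{n_stimuli}, \code{n_withdrawals}
#' @param criterion see \code{\link{computeHwt}}
#' @return list(profile = per-animal-day data.frame(animal_id, day,
#'   hwt_g, censored), summary = per-day data.frame(day, mean_g, sem_g,
#'   n, n_censored))
#' @export
buildHwtProfiles <- function(table, criterion = 3L) {
  need <- c("animal_id", "day", "force_g", "n_stimuli", "n_withdrawals")
  stopifnot(all(need %in% names(table)))
  dayLevels <- unique(table$day)
  keys <- unique(table[, c("animal_id", "day")])
  prof <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sel <- table$animal_id == keys$animal_id[i] & table$day == keys$day[i]
    res <- computeHwt(table$force_g[sel], table$n_withdrawals[sel],
                      nStimuli = table$n_stimuli[sel][1L],
                      criterion = criterion)
    data.frame(animal_id = keys$animal_id[i], day = keys$day[i],
               hwt_g = res$hwt_g, censored = res$censored,
               stringsAsFactors = FALSE)
  }))
  summ <- do.call(rbind, lapply(dayLevels, function(d) {
    x <- prof[prof$day == d, ]
    ok <- x$hwt_g[!x$censored]
    data.frame(
      day = d,
      mean_g = if (length(ok)) mean(ok) else NA_real_,
      sem_g = if (length(ok) >= 2L) sd(ok) / sqrt(length(ok)) else NA_real_,
      n = length(ok),
      n_censored = sum(x$censored),
      stringsAsFactors = FALSE
    )
  }))
  list(profile = prof, summary = summ)
}
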