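#' Default cortical-site configuration for synthetic cohorts
#'
#' Placement and kinetics of the evoked foci emulated for each
#' stimulation site on the 184 x 124 px field: whisker-pad stimulation
#' evokes one barrel-field focus (S1/S2, not discriminated); molar-pulp
#' and mentum-skin stimulation evoke an S1 focus and a later S2/IOR
#' focus near the MCA / rhinal-fissure crossing.  Onset delays (30 ms
#' S1, 42 ms S2/IOR) make the S1 focus the initial response.
#'
#' @return named list: per stimulation label, a list of focus templates
#'   (region, centerRow, centerCol, sigma, onsetDelay, tauRise, tauDecay)
#' @export
defaultSiteConfig <- function() {
  list(
    whisker_pad = list(
      list(region = "S1_S2", centerRow = 62, centerCol = 92, sigma = 8,
           onsetDelay = 30, tauRise = 10, tauDecay = 80)
    ),
    molar_pulp = list(
      list(region = "S1", centerRow = 40, centerCol = 60, sigma = 8,
           onsetDelay = 30, tauRise = 10, tauDecay = 80),
      list(region = "S2_IOR", centerRow = 90, centerCol = 130, sigma = 8,
           onsetDelay = 42, tauRise = 10, tauDecay = 80)
    ),
    mentum_skin = list(
      list(region = "S1", centerRow = 45, centerCol = 70, sigma = 8,
           onsetDelay = 30, tauRise = 10, tauDecay = 80),
      list(region = "S2_IOR", centerRow = 92, centerCol = 135, sigma = 8,
           onsetDelay = 42, tauRise = 10, tauDecay = 80)
    )
  )
}

#' Assemble a full pipeline run configuration
#'
#' Collects every stage's parameters into one serializable list whose
#' hash is embedded in all outputs.  \code{groups} follows the
#' \code{\link{groupSummaryTable}} schema (stimulation, region, group,
#' mean_pct, sem_pct, n); animals are simulated per stimulation site.
#'
#' @param groups group-target data.frame
#' @param geometry an \code{AcquisitionGeometry}
#' @param siteConfig see \code{\link{defaultSiteConfig}}
#' @param baselineF0,bleachTau,noiseSd,trialJitterCv,nTrials generator
#'   settings (see \code{\link{SimParams}}); in \code{calibrate = "exact"}
#'   mode the deterministic settings \code{noiseSd = 0},
#'   \code{bleachTau = Inf}, \code{trialJitterCv = 0}, \code{nTrials = 1}
#'   are forced
#' @param baselineWindow,kernelSize,filterType preprocessing settings
#' @param k,mMin,floor,siteRadius detection settings (\code{siteRadius}
#'   is the per-site restriction disc, px)
#' @param fraction overlap threshold fraction
#' @param familySize,alpha statistics settings
#' @param calibrate "exact" or "stochastic" cohort calibration
#' @param compensateGain divide generator amplitudes by the measured
#'   gain of the measurement chain so recovered peaks sit on the target
#'   scale (exact mode)
#' @param unresolvableFraction fraction of animals with unresolvable
#'   landmarks
#' @param seed master RNG seed
#' @return a config list with class \code{"vsdmapConfig"}
#' @export
runConfig <- function(groups, geometry = AcquisitionGeometry(),
                      siteConfig = defaultSiteConfig(),
                      baselineF0 = 1000, bleachTau = Inf, noiseSd = 0,
                      trialJitterCv = 0, nTrials = 1L,
                      baselineWindow = NULL, kernelSize = 9L,
                      filterType = "box",
                      k = 7, mMin = 5L, floor = 5e-5, siteRadius = 30,
                      fraction = 0.5, familySize = 3L, alpha = 0.05,
                      calibrate = "exact", compensateGain = TRUE,
                      unresolvableFraction = 0, seed = 1L) {
  if (identical(calibrate, "exact")) {
    noiseSd <- 0; bleachTau <- Inf; trialJitterCv <- 0; nTrials <- 1L
  }
  cfg <- list(
    groups = groups, geometry = geometry, siteConfig = siteConfig,
    sim = list(baselineF0 = baselineF0, bleachTau = bleachTau,
               noiseSd = noiseSd, trialJitterCv = trialJitterCv,
               nTrials = as.integer(nTrials)),
    preprocess = list(baselineWindow = baselineWindow,
                      kernelSize = as.integer(kernelSize),
                      filterType = filterType),
    detect = list(k = k, mMin = as.integer(mMin), floor = floor,
                  siteRadius = siteRadius),
    overlap = list(fraction = fraction),
    stats = list(familySize = as.integer(familySize), alpha = alpha),
    calibrate = calibrate, compensateGain = isTRUE(compensateGain),
    unresolvableFraction = unresolvableFraction,
    seed = as.integer(seed)
  )
  class(cfg) <- "vsdmapConfig"
  cfg
}

# Build the ResponseFocus list of one animal's acquisition for a
# stimulation site, with per-region amplitudes.
.fociFor <- function(templates, amplitudes) {
  lapply(templates, function(tp) {
    ResponseFocus(
      label = tp$region, centerRow = tp$centerRow, centerCol = tp$centerCol,
      sigma = tp$sigma, amplitude = amplitudes[[tp$region]],
      onsetDelay = tp$onsetDelay, tauRise = tp$tauRise, tauDecay = tp$tauDecay
    )
  })
}

# Simulate, preprocess and detect one animal's acquisition for one
# stimulation site; returns one ResponseMetrics per region.
.measureAnimal <- function(cfg, templates, amplitudes, landmarksFrame, seed) {
  params <- SimParams(
    geometry = cfg$geometry, foci = .fociFor(templates, amplitudes),
    baselineF0 = cfg$sim$baselineF0, bleachTau = cfg$sim$bleachTau,
    noiseSd = cfg$sim$noiseSd, trialJitterCv = cfg$sim$trialJitterCv,
    nTrials = cfg$sim$nTrials, landmarks = landmarksFrame, seed = seed
  )
  ts <- simulateTrialSet(params)
  dff <- preprocessTrials(ts$stim, ts$blank,
                          baselineWindow = cfg$preprocess$baselineWindow,
                          kernelSize = cfg$preprocess$kernelSize,
                          filterType = cfg$preprocess$filterType)
  res <- lapply(templates, function(tp) {
    detectResponse(dff,
      k = cfg$detect$k, mMin = cfg$detect$mMin, floor = cfg$detect$floor,
      within = list(center = c(tp$centerRow, tp$centerCol),
                    radius = cfg$detect$siteRadius),
      site = tp$region
    )
  })
  names(res) <- vapply(templates, function(tp) tp$region, character(1))
  res
}

# Measure the gain of the full measurement chain (generation through
# detection) for one focus template by probing with a known noiseless
# amplitude; the chain is linear in amplitude, so one probe suffices.
.measureGain <- function(cfg, tp) {
  probeAmp <- 0.01
  probeCfg <- cfg
  probeCfg$sim$noiseSd <- 0
  probeCfg$sim$bleachTau <- Inf
  probeCfg$sim$trialJitterCv <- 0
  probeCfg$sim$nTrials <- 1L
  amps <- list(probeAmp)
  names(amps) <- tp$region
  res <- .measureAnimal(probeCfg, list(tp), amps,
                        referenceLandmarks(cfg$geometry), seed = 1L)
  if (!res[[1L]]@detected)
    stop("gain probe produced no detectable response for region ", tp$region)
  res[[1L]]@peakAmplitude / probeAmp
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Generates a cohort per stimulation site from the group targets,
#' pushes every animal's acquisition through blank subtraction, trial
#' averaging, dF/F, spatial smoothing and 7xSD response detection,
#' aligns maximum-response outlines by the MCA / rhinal-fissure
#' landmarks into per-group overlap maps (excluding unresolvable
#' animals), and computes pooled t statistics with Bonferroni labels on
#' the recovered peak amplitudes.  Deterministic given the config,
#' whose hash is embedded in every output.
#'
#' @param cfg a config from \code{\link{runConfig}}
#' @param outDir optional directory: writes \code{metrics.csv} and
#'   \code{stats.csv} (units in headers, config hash in a column)
#' @return list: \code{metrics} (per animal x region recovered peaks),
#'   \code{stats} (pairwise comparisons), \code{summaries} (per-cell
#'   mean/SEM/n of recovered peaks, in %), \code{overlaps} (nested list
#'   of \code{OverlapMap} per stimulation/group/region),
#'   \code{excluded}, \code{configHash}, \code{config}
#' @export
runPipeline <- function(cfg, outDir = NULL) {
  stopifnot(inherits(cfg, "vsdmapConfig"))
  hash <- rlang::hash(unclass(cfg))
  gains <- list()
  metrics <- list()
  outlines <- list()
  excluded <- character()
  stims <- unique(cfg$groups$stimulation)
  animalCounter <- 0L
  for (st in stims) {
    templates <- cfg$siteConfig[[st]]
    if (is.null(templates)) stop("no site configuration for stimulation ", st)
    gTargets <- cfg$groups[cfg$groups$stimulation == st, ]
    cohortGroups <- data.frame(
      group = gTargets$group, site = gTargets$region,
      mean_pct = gTargets$mean_pct, sem_pct = gTargets$sem_pct,
      n = gTargets$n, stringsAsFactors = FALSE
    )
    cohort <- simulateCohort(
      cohortGroups, seed = subSeed(cfg$seed, match(st, stims)),
      calibrate = cfg$calibrate, geometry = cfg$geometry,
      unresolvableFraction = cfg$unresolvableFraction
    )
    regions <- vapply(templates, function(tp) tp$region, character(1))
    for (tp in templates) {
      key <- paste(st, tp$region, sep = "/")
      gains[[key]] <- if (cfg$compensateGain) .measureGain(cfg, tp) else 1
    }
    animals <- unique(cohort$amplitudes$animal_id)
    for (aid in animals) {
      animalCounter <- animalCounter + 1L
      rows <- cohort$amplitudes[cohort$amplitudes$animal_id == aid, ]
      amps <- as.list(rows$amplitude[match(regions, rows$site)] /
                        unlist(gains[paste(st, regions, sep = "/")]))
      names(amps) <- regions
      lmk <- cohort$landmarks[[aid]]
      res <- .measureAnimal(cfg, templates, amps, lmk,
                            seed = subSeed(cfg$seed, 5000L + animalCounter))
      tr <- fitLandmarkTransform(lmk, cohort$reference)
      if (is.null(tr)) excluded <- c(excluded, paste(st, aid, sep = "/"))
      for (rg in regions) {
        m <- res[[rg]]
        metrics[[length(metrics) + 1L]] <- data.frame(
          stimulation = st, group = rows$group[1L], animal_id = aid,
          region = rg, detected = m@detected,
          true_amplitude_pct = 100 * rows$amplitude[match(rg, rows$site)],
          peak_pct = 100 * m@peakAmplitude,
          initial_frame = m@initialFrame, peak_frame = m@peakFrame,
          decay_90_10_ms = m@decay9010,
          landmarks_resolvable = lmk@resolvable,
          stringsAsFactors = FALSE
        )
        if (!is.null(tr) && m@detected) {
          okey <- paste(st, rows$group[1L], rg, sep = "/")
          warped <- warpOutline(m@maxResponseOutline, tr, cfg$geometry)
          outlines[[okey]] <- c(outlines[[okey]], list(warped))
        }
      }
    }
  }
  metrics <- do.call(rbind, metrics)
  overlaps <- lapply(names(outlines), function(key) {
    st <- strsplit(key, "/", fixed = TRUE)[[1L]][1L]
    buildOverlap(outlines[[key]], cfg$geometry,
                 fraction = cfg$overlap$fraction,
                 excluded = grep(paste0("^", st, "/"), excluded, value = TRUE))
  })
  names(overlaps) <- names(outlines)
  summaries <- do.call(rbind, lapply(
    split(metrics, list(metrics$stimulation, metrics$region, metrics$group),
          drop = TRUE),
    function(x) {
      s <- summarizeGroup(x$peak_pct[x$detected])
      data.frame(stimulation = x$stimulation[1L], region = x$region[1L],
                 group = x$group[1L], mean_pct = s$mean, sem_pct = s$sem,
                 n = s$n, stringsAsFactors = FALSE)
    }
  ))
  rownames(summaries) <- NULL
  stats <- .pairwiseStats(metrics, cfg$stats$familySize, cfg$stats$alpha)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    metrics$config_hash <- hash
    stats$config_hash <- hash
    write.csv(metrics, file.path(outDir, "metrics.csv"), row.names = FALSE)
    write.csv(stats, file.path(outDir, "stats.csv"), row.names = FALSE)
    metrics$config_hash <- NULL
    stats$config_hash <- NULL
  }
  list(metrics = metrics, stats = stats, summaries = summaries,
       overlaps = overlaps, excluded = excluded, configHash = hash,
       config = cfg)
}

# Pairwise pooled t-tests on recovered peak amplitudes.
.pairwiseStats <- function(metrics, familySize, alpha) {
  cells <- unique(metrics[, c("stimulation", "region")])
  out <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- metrics[metrics$stimulation == cells$stimulation[i] &
                      metrics$region == cells$region[i] & metrics$detected, ]
    grps <- unique(cell$group)
    for (a in seq_along(grps)) for (b in seq_along(grps)) {
      if (b <= a) next
      va <- cell$peak_pct[cell$group == grps[a]]
      vb <- cell$peak_pct[cell$group == grps[b]]
      res <- tTestFromRaw(va, vb, familySize = familySize, alpha = alpha)
      out[[length(out) + 1L]] <- data.frame(
        stimulation = cells$stimulation[i], region = cells$region[i],
        group_a = grps[a], group_b = grps[b], t = res@t, df = res@df,
        p = res@p, alpha_corrected = res@alphaCorrected,
        significant = res@significant, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
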