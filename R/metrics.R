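# Assay performance metrics: points per peak, measurement windows,
# retention-time stability over run sequences, dynamic range, and the
# triggered-vs-scheduled mode comparison.

#' Points per peak and measurement windows for one run
#'
#' For each light target: the number of quantitative scans falling
#' inside its integration boundaries (points per peak), the measurement
#' window (time between the first and last quantitative scan for the
#' target), and the apex retention time. Undetected targets are
#' excluded from the mean and tallied separately.
#'
#' @param run A [RunRecord-class].
#' @param quantRecords Output of [quantifyRun()] for the same run.
#' @return list: `perPeptide` (data.frame targetId, points, window,
#'   apexRt, detected), `meanPoints`, `meanWindow`, `maxWindow`,
#'   `nMissing`.
#' @export
pointsPerPeak <- function(run, quantRecords) {
  sc <- run@scans
  q <- sc[sc$kind == "QUANT_MS2", ]
  lightTarget <- sub("/light$", "", q$targetId)
  per <- lapply(seq_len(nrow(quantRecords)), function(i) {
    r <- quantRecords[i, ]
    tms <- q$time[lightTarget == r$targetId]
    if (!r$detected || !length(tms))
      return(data.frame(targetId = r$targetId, points = 0L, window = 0,
                        apexRt = NA_real_, detected = FALSE))
    data.frame(targetId = r$targetId,
               points = sum(tms >= r$start & tms <= r$end),
               window = if (length(tms) > 1) max(tms) - min(tms) else 0,
               apexRt = r$apexTime, detected = TRUE)
  })
  per <- do.call(rbind, c(per, list(make.row.names = FALSE)))
  det <- per[per$detected, ]
  list(perPeptide = per,
       meanPoints = if (nrow(det)) mean(det$points) else NA_real_,
       meanWindow = if (nrow(det)) mean(det$window) else NA_real_,
       maxWindow = if (nrow(det)) max(det$window) else NA_real_,
       nMissing = sum(!per$detected))
}

#' Retention-time stability over a run sequence
#'
#' Per run and target, the apex retention time is estimated as the time
#' of the maximum of the summed heavy (internal-standard) trace, with
#' no sub-scan interpolation; the per-target sample SD over runs is
#' reported with its mean and maximum across targets. Targets missing
#' in more than half the runs are excluded with a warning.
#'
#' @param runs List of [RunRecord-class] (>= 2).
#' @param panel The [TransitionPanel-class].
#' @param tolPpm Trace-extraction tolerance (ppm).
#' @return list: `apexMatrix` (targets x runs), `sd` (per target),
#'   `meanSd`, `maxSd`, `nRuns`.
#' @export
rtStability <- function(runs, panel, tolPpm = 20) {
  if (length(runs) < 2) stop("need at least 2 runs")
  targets <- unique(panel@peptides$targetId)
  apex <- matrix(NA_real_, length(targets), length(runs),
                 dimnames = list(targets, NULL))
  for (r in seq_along(runs)) {
    traces <- extractTraces(runs[[r]], panel, tolPpm)
    hv <- traces[traces$isHeavy, ]
    for (tid in unique(hv$targetId)) {
      d <- hv[hv$targetId == tid, ]
      s <- vapply(split(d$intensity, d$time), sum, numeric(1))
      if (length(s) && max(s) > 0)
        apex[tid, r] <- as.numeric(names(s))[which.max(s)]
    }
  }
  present <- rowMeans(!is.na(apex))
  if (any(present <= 0.5)) {
    warning("target(s) missing in more than half the runs excluded: ",
            paste(rownames(apex)[present <= 0.5], collapse = ", "))
    apex <- apex[present > 0.5, , drop = FALSE]
  }
  sds <- apply(apex, 1, sd, na.rm = TRUE)
  list(apexMatrix = apex, sd = sds, meanSd = mean(sds), maxSd = max(sds),
       nRuns = length(runs))
}

#' Dynamic range of the detected protein set
#'
#' A protein counts as detected in a sample when at least one of its
#' peptides is quantified from >= 3 nonzero transitions; proteins
#' detected in at least `minFraction` of samples enter the span. The
#' span is log10(max/min) of the ground-truth protein medians of that
#' set.
#'
#' @param study Result of [quantifyStudy()].
#' @param truth The [GroundTruth-class] the study was simulated from.
#' @param minFraction Required detection rate across samples (default
#'   0.9).
#' @return list: `span` (orders of magnitude), `detected` (protein ids),
#'   `detectionRate` (per protein).
#' @export
dynamicRange <- function(study, truth, minFraction = 0.9) {
  pep <- study$peptides
  bySample <- tapply(pep$reliable, list(pep$proteinId, pep$sample), any)
  rate <- rowMeans(bySample)
  detected <- names(rate)[rate >= minFraction]
  if (length(detected) < 2)
    stop("fewer than 2 proteins detected; dynamic range undefined")
  med <- truth@proteins$median[match(detected, truth@proteins$proteinId)]
  list(span = log10(max(med) / min(med)), detected = detected,
       detectionRate = rate)
}

#' Compare triggered and scheduled acquisition under drift
#'
#' Simulates, at each drift jitter magnitude and from identical seeds,
#' one triggered run and one scheduled run (windows: undrifted apex
#' +/- `windowHalfWidth`), and reports per-mode completeness (percent
#' of light targets quantified from at least three nonzero transitions,
#' the detection rule used throughout) and mean points per peak.
#' Scheduled runs carry no internal-standard watch scans, so their
#' integration boundaries are taken from the light traces.
#'
#' @param panel A [TransitionPanel-class].
#' @param driftSds Numeric vector of per-run jitter SDs (s) to test.
#' @param windowHalfWidth Scheduling half-window (s, default 15).
#' @param gradient,params As elsewhere.
#' @param seed Master seed (same for both modes at each magnitude).
#' @param log10Span,isAmplitude Ground-truth settings.
#' @return data.frame: `driftSd`, `mode`, `completeness` (percent),
#'   `meanPointsPerPeak`.
#' @export
compareModes <- function(panel, driftSds = c(0, 60), windowHalfWidth = 15,
                         gradient = gradient100SPD(),
                         params = acquisitionParams(), seed = 1L,
                         log10Span = 3, isAmplitude = 1e4) {
  # mid-abundance band: the comparison probes scheduling robustness, not
  # the sensitivity floor
  truth <- generateGroundTruth(panel, log10Span, 1L, seed,
                               isAmplitude = isAmplitude, log10Min = 1)
  profiles <- elutionProfiles(panel, gradient)
  windows <- data.frame(targetId = profiles$targetId,
                        start = profiles$apexRt - windowHalfWidth,
                        end = profiles$apexRt + windowHalfWidth)
  rows <- list()
  for (ds in driftSds) {
    dm <- driftModel(jitterSd = ds, seed = seed)
    for (mode in c("surequant", "prm")) {
      run <- simulateRun(panel, truth, 1L, gradient, params, dm,
                         runIndex = 1L, seed = seed, mode = mode,
                         rtWindows = windows)
      q <- quantifyRun(run, panel,
                       boundarySource = if (mode == "prm") "light" else "heavy")
      ppp <- pointsPerPeak(run, q)
      # quantified = the detection rule used throughout: at least three
      # transitions with nonzero integrated area
      ok <- q$reliable
      rows[[length(rows) + 1L]] <- data.frame(
        driftSd = ds, mode = mode,
        completeness = 100 * mean(ok),
        meanPointsPerPeak = ppp$meanPoints)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
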