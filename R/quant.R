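# Skyline-equivalent quantification chain: transition trace extraction,
# internal-standard-anchored integration boundaries, trapezoidal
# integration, TIC normalization, protein rollup and 0-100 rescaling.

#' Extract transition traces from a run record
#'
#' For each targeted scan, the summed intensity of centroids within the
#' ppm tolerance of each expected transition m/z (the centroided DIA
#' filtering step). Quantitative scans feed the light traces; watch
#' scans feed the heavy (internal-standard) traces. A transition with no
#' centroid in tolerance contributes a 0 point at that scan time, so
#' interferents inside the tolerance are added to the trace by design.
#'
#' @param run A [RunRecord-class].
#' @param panel The [TransitionPanel-class].
#' @param tolPpm Fragment match tolerance (default 20 ppm).
#' @return data.frame: `peptideId`, `targetId`, `isHeavy`,
#'   `transitionId`, `time`, `intensity`, ordered by time within
#'   transition.
#' @export
extractTraces <- function(run, panel, tolPpm = 20) {
  sc <- run@scans
  ce <- run@centroids
  targeted <- which(sc$kind %in% c("WATCH_MS2", "QUANT_MS2"))
  if (!length(targeted))
    return(data.frame(peptideId = character(), targetId = character(),
                      isHeavy = logical(), transitionId = character(),
                      time = numeric(), intensity = numeric()))
  tr <- panel@transitions
  pep <- panel@peptides
  ceSplit <- split(seq_len(nrow(ce)), ce$scanId)
  out <- vector("list", length(targeted))
  for (i in seq_along(targeted)) {
    s <- targeted[i]
    pid <- sc$targetId[s]
    ti <- tr[tr$peptideId == pid, ]
    rows <- ceSplit[[as.character(sc$scanId[s])]]
    mz <- ce$mz[rows]; int <- ce$intensity[rows]
    vals <- vapply(ti$mz, function(em)
      sum(int[abs(mz - em) <= em * tolPpm * 1e-6]), numeric(1))
    out[[i]] <- list(pid = pid, time = sc$time[s],
                     tid = paste0(ti$ionType, ti$fragmentIndex), vals = vals)
  }
  n <- vapply(out, function(x) length(x$vals), integer(1))
  pid <- rep.int(vapply(out, `[[`, character(1), "pid"), n)
  m <- match(pid, pep$peptideId)
  df <- data.frame(
    peptideId = pid, targetId = pep$targetId[m], isHeavy = pep$isHeavy[m],
    transitionId = unlist(lapply(out, `[[`, "tid"), use.names = FALSE),
    time = rep.int(vapply(out, `[[`, numeric(1), "time"), n),
    intensity = unlist(lapply(out, `[[`, "vals"), use.names = FALSE))
  df[order(df$peptideId, df$transitionId, df$time), ]
}

#' Detect integration boundaries from a heavy-peptide trace
#'
#' Automates the manual boundary revision step: the per-time summed
#' heavy trace is scanned for the contiguous region around its apex
#' where intensity is at least `threshold` (default 5 %) of the apex
#' value. The same boundaries are then applied to the light partner
#' (internal-standard-anchored integration). An all-zero or empty heavy
#' trace flags the peptide as not detected. The apex is picked with
#' neighbour support (see the source comment), so an isolated
#' interferent spike does not displace the peak.
#'
#' @param heavyTrace data.frame with `time` and `intensity` (multiple
#'   transitions allowed; they are summed per time point).
#' @param threshold Fraction of the apex defining the boundary.
#' @return list: `detected`, `start`, `end`, `apexTime` (NA when not
#'   detected). The region always contains the apex time.
#' @export
detectBoundaries <- function(heavyTrace, threshold = 0.05) {
  if (nrow(heavyTrace) == 0)
    return(list(detected = FALSE, start = NA_real_, end = NA_real_,
                apexTime = NA_real_))
  s <- vapply(split(heavyTrace$intensity, heavyTrace$time), sum, numeric(1))
  tm <- as.numeric(names(s))
  o <- order(tm)
  tm <- tm[o]; s <- s[o]
  if (all(s <= 0))
    return(list(detected = FALSE, start = NA_real_, end = NA_real_,
                apexTime = NA_real_))
  # neighbour-supported apex: a candidate apex must be backed by at least
  # one adjacent elevated point, so a lone interferent spike cannot hijack
  # the peak (real peaks at the duty-cycle sampling always span several
  # points)
  if (length(s) >= 3) {
    nb <- pmax(c(-Inf, s[-length(s)]), c(s[-1], -Inf))
    sup <- pmin(s, nb)
    cand <- which(sup == max(sup))
    apex <- cand[which.max(s[cand])]   # tie on support: highest raw point
    if (s[apex] <= 0) apex <- which.max(s)
  } else {
    apex <- which.max(s)
  }
  ok <- s >= threshold * s[apex]
  lo <- apex
  while (lo > 1 && ok[lo - 1]) lo <- lo - 1
  hi <- apex
  while (hi < length(s) && ok[hi + 1]) hi <- hi + 1
  list(detected = TRUE, start = tm[lo], end = tm[hi], apexTime = tm[apex])
}

#' Trapezoidal integration of a trace between boundaries
#'
#' @param time,intensity Trace points (need not be pre-sorted).
#' @param start,end Integration boundaries (s).
#' @return Trapezoidal area of the points with `start <= time <= end`;
#'   0 if fewer than two points fall inside.
#' @export
integrateTrace <- function(time, intensity, start, end) {
  keep <- time >= start & time <= end
  t <- time[keep]; y <- intensity[keep]
  if (length(t) < 2) return(0)
  o <- order(t)
  t <- t[o]; y <- y[o]
  sum(diff(t) * (head(y, -1) + y[-1]) / 2)
}

#' Total-ion-current chromatogram area of a run
#'
#' TIC is computed from MS1 scans only (per-scan summed centroid
#' intensity), integrated by the trapezoid rule over the run.
#'
#' @param run A [RunRecord-class].
#' @return TIC chromatogram area.
#' @export
ticArea <- function(run) {
  ms1 <- run@scans[run@scans$kind == "MS1", ]
  integrateTrace(ms1$time, ms1$tic, -Inf, Inf)
}

#' TIC-normalize peak areas across runs
#'
#' Scale-preserving ratio normalization: each run's areas are divided by
#' its TIC chromatogram area and multiplied by the median TIC area
#' across runs, so a uniform intensity scaling of one run leaves its
#' normalized areas unchanged while values stay on the raw scale.
#'
#' @param areas Numeric matrix (targets x runs) or vector (one value per
#'   run) of total fragment areas.
#' @param ticAreas Numeric vector of per-run TIC areas (same run order).
#' @return Normalized areas with the shape of `areas`.
#' @export
ticNormalize <- function(areas, ticAreas) {
  if (any(!is.finite(ticAreas)) || any(ticAreas <= 0)) {
    bad <- which(!is.finite(ticAreas) | ticAreas <= 0)
    stop("non-positive TIC area for run(s): ", paste(bad, collapse = ", "))
  }
  f <- median(ticAreas) / ticAreas
  if (is.matrix(areas)) sweep(areas, 2, f, `*`) else areas * f
}

#' Roll peptide values up to a protein value
#'
#' Arithmetic mean of the available (non-missing) peptide values;
#' missing (NA), never zero, when no peptide was quantified.
#'
#' @param peptideValues Numeric vector (NAs allowed).
#' @return Protein value, or NA when all inputs are missing.
#' @export
proteinRollup <- function(peptideValues) {
  v <- peptideValues[!is.na(peptideValues)]
  if (!length(v)) return(NA_real_)
  mean(v)
}

#' Rescale protein values to 0-100 per protein
#'
#' Min-max rescaling across samples, separately per protein (matrix
#' row): (v - min) / (max - min) * 100. Missing entries stay missing; a
#' row with fewer than 2 non-missing values passes through as missing;
#' a constant row becomes all 0 with a warning.
#'
#' @param proteinValues Numeric matrix, proteins x samples.
#' @return Matrix of the same shape with values in [0, 100] (or NA).
#' @export
rescale0to100 <- function(proteinValues) {
  out <- proteinValues
  for (i in seq_len(nrow(proteinValues))) {
    v <- proteinValues[i, ]
    ok <- !is.na(v)
    if (sum(ok) < 2) { out[i, ok] <- NA_real_; next }
    rng <- range(v[ok])
    if (rng[1] == rng[2]) {
      warning("constant values for protein '", rownames(proteinValues)[i],
              "'; rescaled to 0")
      out[i, ok] <- 0
    } else {
      out[i, ok] <- (v[ok] - rng[1]) / (rng[2] - rng[1]) * 100
    }
  }
  out
}

#' Quantify one run
#'
#' The per-run half of the quantification chain: extract traces, derive
#' integration boundaries from each target's heavy trace, integrate the
#' light transitions inside those boundaries, and sum to the total
#' fragment area. Records with fewer than 3 nonzero transitions inside
#' the boundaries are flagged as unreliable (`reliable = FALSE`).
#'
#' @param run A [RunRecord-class].
#' @param panel The [TransitionPanel-class].
#' @param tolPpm Fragment tolerance for trace extraction (ppm).
#' @param boundaryThreshold Boundary threshold fraction (default 0.05).
#' @param boundarySource "heavy" (default; internal-standard-anchored)
#'   or "light" (for acquisition modes without watch scans, e.g. the
#'   scheduled-PRM comparator).
#' @return data.frame, one row per light target: `targetId`,
#'   `proteinId`, `detected`, `start`, `end`, `apexTime`, `totalArea`,
#'   `nNonzeroTransitions`, `reliable`. Undetected targets carry NA
#'   areas (missing, not zero).
#' @export
quantifyRun <- function(run, panel, tolPpm = 20, boundaryThreshold = 0.05,
                        boundarySource = c("heavy", "light")) {
  boundarySource <- match.arg(boundarySource)
  traces <- extractTraces(run, panel, tolPpm)
  p <- panel@peptides[!panel@peptides$isHeavy, ]
  res <- lapply(seq_len(nrow(p)), function(i) {
    tid <- p$targetId[i]
    hv <- traces[traces$targetId == tid & traces$isHeavy, ]
    lt <- traces[traces$targetId == tid & !traces$isHeavy, ]
    b <- detectBoundaries(if (boundarySource == "heavy") hv else lt,
                          boundaryThreshold)
    if (!b$detected)
      return(data.frame(targetId = tid, proteinId = p$proteinId[i],
                        detected = FALSE, start = NA_real_, end = NA_real_,
                        apexTime = NA_real_, totalArea = NA_real_,
                        nNonzeroTransitions = 0L, reliable = FALSE))
    areas <- vapply(split(lt, lt$transitionId), function(d)
      integrateTrace(d$time, d$intensity, b$start, b$end), numeric(1))
    data.frame(targetId = tid, proteinId = p$proteinId[i], detected = TRUE,
               start = b$start, end = b$end, apexTime = b$apexTime,
               totalArea = sum(areas),
               nNonzeroTransitions = sum(areas > 0),
               reliable = sum(areas > 0) >= 3L)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Quantify a multi-sample study
#'
#' Applies [quantifyRun()] to each run, TIC-normalizes total fragment
#' areas across runs, averages peptide values into protein values, and
#' rescales each protein to 0-100 across samples.
#'
#' @param runs List of [RunRecord-class], one per sample (sample order =
#'   list order).
#' @param panel The [TransitionPanel-class].
#' @param tolPpm,boundaryThreshold Passed to [quantifyRun()].
#' @return list with `peptides` (long data.frame: sample, targetId,
#'   proteinId, detected, totalArea, normArea, reliable), `peptideMatrix`
#'   (normalized areas, targets x samples), `proteinMatrix` (rolled-up,
#'   proteins x samples), `rescaled` (0-100 per protein), `ticAreas`.
#' @export
quantifyStudy <- function(runs, panel, tolPpm = 20, boundaryThreshold = 0.05) {
  per <- lapply(seq_along(runs), function(s) {
    q <- quantifyRun(runs[[s]], panel, tolPpm, boundaryThreshold)
    q$sample <- s
    q
  })
  long <- do.call(rbind, c(per, list(make.row.names = FALSE)))
  tics <- vapply(runs, ticArea, numeric(1))
  targets <- unique(long$targetId)
  amat <- matrix(NA_real_, length(targets), length(runs),
                 dimnames = list(targets, seq_along(runs)))
  for (s in seq_along(runs)) {
    q <- per[[s]]
    amat[q$targetId, s] <- q$totalArea
  }
  nmat <- ticNormalize(amat, tics)
  long$normArea <- nmat[cbind(match(long$targetId, targets), long$sample)]
  protOf <- long$proteinId[match(targets, long$targetId)]
  prots <- sort(unique(protOf))
  pmat <- matrix(NA_real_, length(prots), length(runs),
                 dimnames = list(prots, seq_along(runs)))
  for (pr in prots) for (s in seq_along(runs))
    pmat[pr, s] <- proteinRollup(nmat[protOf == pr, s])
  list(peptides = long, peptideMatrix = nmat, proteinMatrix = pmat,
       rescaled = rescale0to100(pmat), ticAreas = tics)
}

#' Log2 completeness matrices
#'
#' Peptide-by-sample and protein-by-sample log2 matrices of normalized
#' areas, with missing values encoded as NA (never -Inf). Optionally
#' written as CSV.
#'
#' @param study Result of [quantifyStudy()].
#' @param prefix Optional path prefix; writes `<prefix>_peptides.csv`
#'   and `<prefix>_proteins.csv`.
#' @return list: `peptideLog2`, `proteinLog2`.
#' @export
completenessMatrix <- function(study, prefix = NULL) {
  lg <- function(m) {
    out <- log2(m)
    out[!is.finite(out)] <- NA_real_
    out
  }
  res <- list(peptideLog2 = lg(study$peptideMatrix),
              proteinLog2 = lg(study$proteinMatrix))
  if (!is.null(prefix)) {
    write.csv(res$peptideLog2, paste0(prefix, "_peptides.csv"))
    write.csv(res$proteinLog2, paste0(prefix, "_proteins.csv"))
  }
  res
}
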