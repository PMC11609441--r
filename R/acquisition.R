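# Discrete-event model of the internal-standard-triggered acquisition
# duty cycle, plus the scheduled-PRM comparator.
#
# Each duty cycle: one MS1 survey scan; every heavy (internal-standard)
# precursor observed in the MS1 centroids above its intensity threshold
# gets a fast low-resolution watch MS2; if at least `triggerMinIons` of
# its expected product ions match within the fragment tolerance, a
# high-resolution quantitative MS2 is placed at the offset (light)
# precursor m/z in the same cycle. Watch+quant units that would overflow
# the cycle budget are deferred, never dropped.

#' AcquisitionParams class
#'
#' Instrument and trigger settings for the simulated orbitrap method.
#' Defaults follow the published method: MS1 at resolution 120000 with
#' 50 ms injection time and a 2 s cycle; watch scans at 7500 / 10 ms;
#' quantitative scans at 60000 / 250 ms; 10 ppm precursor and 20 ppm
#' fragment tolerances; at least three product ions to trigger. AGC
#' targets are carried as metadata only; injection times are treated as
#' fixed.
#'
#' @slot ms1Resolution,ms1InjectionTime MS1 resolution and injection time (s).
#' @slot cyclePeriod Duty-cycle period (s).
#' @slot watchResolution,watchInjectionTime Watch-scan settings.
#' @slot quantResolution,quantInjectionTime Quantitative-scan settings.
#' @slot precursorTolPpm,fragmentTolPpm Match tolerances (ppm).
#' @slot triggerMinIons Product ions required to trigger an offset scan.
#' @slot isIntensityFraction IS detection threshold as a fraction of the
#'   IS apex amplitude.
#' @slot isolationWidth Isolation window width (Th).
#' @slot scanOverhead Fixed per-scan overhead (s).
#' @slot agcTargets Named metadata, not simulated.
#' @export
setClass("AcquisitionParams",
         representation(ms1Resolution = "numeric", ms1InjectionTime = "numeric",
                        cyclePeriod = "numeric",
                        watchResolution = "numeric",
                        watchInjectionTime = "numeric",
                        quantResolution = "numeric",
                        quantInjectionTime = "numeric",
                        precursorTolPpm = "numeric", fragmentTolPpm = "numeric",
                        triggerMinIons = "integer",
                        isIntensityFraction = "numeric",
                        isolationWidth = "numeric", scanOverhead = "numeric",
                        agcTargets = "character"))

setValidity("AcquisitionParams", function(object) {
  if (object@ms1InjectionTime <= 0 || object@watchInjectionTime <= 0 ||
      object@quantInjectionTime <= 0 || object@cyclePeriod <= 0)
    return("all times must be positive")
  if (object@triggerMinIons < 1L) return("triggerMinIons must be >= 1")
  if (object@precursorTolPpm <= 0 || object@fragmentTolPpm <= 0)
    return("tolerances must be positive")
  TRUE
})

#' @describeIn AcquisitionParams constructor with published defaults
#' @param ... Slot overrides, e.g. `cyclePeriod = 3`.
#' @export
acquisitionParams <- function(...) {
  defaults <- list(
    ms1Resolution = 120000, ms1InjectionTime = 0.050, cyclePeriod = 2,
    watchResolution = 7500, watchInjectionTime = 0.010,
    quantResolution = 60000, quantInjectionTime = 0.250,
    precursorTolPpm = 10, fragmentTolPpm = 20, triggerMinIons = 3L,
    isIntensityFraction = 0.01, isolationWidth = 1.0, scanOverhead = 0.005,
    agcTargets = c(ms1 = "300%", watch = "1000%", quant = "1000%"))
  args <- list(...)
  if ("triggerMinIons" %in% names(args))
    args$triggerMinIons <- as.integer(args$triggerMinIons)
  do.call(new, c(list("AcquisitionParams"), utils::modifyList(defaults, args)))
}

setMethod("show", "AcquisitionParams", function(object) {
  cat(sprintf(
    paste0("AcquisitionParams: MS1 %g/%.0f ms, watch %g/%.0f ms, quant ",
           "%g/%.0f ms, cycle %.1f s, trigger >= %d ions, tol %g/%g ppm\n"),
    object@ms1Resolution, 1000 * object@ms1InjectionTime,
    object@watchResolution, 1000 * object@watchInjectionTime,
    object@quantResolution, 1000 * object@quantInjectionTime,
    object@cyclePeriod, object@triggerMinIons, object@precursorTolPpm,
    object@fragmentTolPpm))
})

.TRANSIENTS <- c(`7500` = 0.016, `15000` = 0.032, `30000` = 0.064,
                 `60000` = 0.128, `120000` = 0.256)

#' Duration of one orbitrap scan
#'
#' max(injection time, orbitrap transient for the resolution) plus a
#' fixed overhead. The transient table covers resolutions 7500, 15000,
#' 30000, 60000 and 120000; other values fall back to the nearest
#' documented resolution with a warning.
#'
#' @param resolution Orbitrap resolution setting.
#' @param injectionTime Maximum injection time (s).
#' @param overhead Fixed per-scan overhead (s, default 5 ms).
#' @return Scan duration in seconds.
#' @examples
#' scanDuration(60000, 0.250)  # 0.255
#' scanDuration(7500, 0.010)   # 0.021
#' @export
scanDuration <- function(resolution, injectionTime, overhead = 0.005) {
  known <- as.numeric(names(.TRANSIENTS))
  if (!resolution %in% known) {
    nearest <- known[which.min(abs(known - resolution))]
    warning("resolution ", resolution, " not in transient table; using ",
            nearest)
    resolution <- nearest
  }
  max(injectionTime, .TRANSIENTS[[as.character(resolution)]]) + overhead
}

#' Count expected transitions matched by observed centroids
#'
#' Each centroid is assigned to its nearest expected transition within
#' the ppm tolerance (ties broken toward the lower expectation index);
#' a centroid consumes at most one expectation, and an expectation
#' matched by one or more centroids counts once.
#'
#' @param centroidMz Observed centroid m/z values.
#' @param expectedMz Expected transition m/z values.
#' @param tolPpm Match tolerance (ppm of the expected m/z).
#' @return Integer count of matched expectations.
#' @export
matchFragments <- function(centroidMz, expectedMz, tolPpm) {
  if (tolPpm <= 0) stop("tolPpm must be positive")
  if (!length(centroidMz) || !length(expectedMz)) return(0L)
  hit <- logical(length(expectedMz))
  for (mz in centroidMz) {
    d <- abs(mz - expectedMz)
    ok <- d <= expectedMz * tolPpm * 1e-6
    if (any(ok)) {
      j <- which(ok)[which.min(d[ok])]  # which.min takes the first = lowest index
      hit[j] <- TRUE
    }
  }
  sum(hit)
}

#' RunRecord class
#'
#' One simulated instrument run: the ordered scan table, the centroid
#' peaks of every scan in long format, and the resolved parameters.
#'
#' `@scans` columns: `scanId`, `time` (s), `kind` (MS1 / WATCH_MS2 /
#' QUANT_MS2), `targetId` (peptideId of the scanned precursor, NA for
#' MS1), `isolationMz`, `resolution`, `injectionTime`,
#' `matchedFragments` (watch scans only), `tic` (summed centroid
#' intensity).
#'
#' @slot runIndex Zero-based run index.
#' @slot gradientName LC method name.
#' @slot scans Scan-event table, strictly ordered in time.
#' @slot centroids data.frame `scanId`, `mz`, `intensity`.
#' @slot params Resolved acquisition parameters (list form).
#' @slot seed Seed the run was simulated with.
#' @export
setClass("RunRecord",
         representation(runIndex = "integer", gradientName = "character",
                        scans = "data.frame", centroids = "data.frame",
                        params = "list", seed = "integer"))

setValidity("RunRecord", function(object) {
  tm <- object@scans$time
  if (length(tm) > 1 && any(diff(tm) <= 0))
    return("scan events must be strictly ordered in time")
  TRUE
})

setMethod("show", "RunRecord", function(object) {
  k <- table(object@scans$kind)
  cat(sprintf("RunRecord %d (%s): %d scans (%s), %d centroids\n",
              object@runIndex, object@gradientName, nrow(object@scans),
              paste(names(k), as.integer(k), sep = "=", collapse = ", "),
              nrow(object@centroids)))
})

#' @describeIn RunRecord scan-table accessor
#' @param run A `RunRecord`.
#' @export
runScans <- function(run) run@scans

#' @describeIn RunRecord centroid-table accessor
#' @export
runCentroids <- function(run) run@centroids

.noiseSdlog <- function(cv) sqrt(log(1 + cv^2))

# per-run lookup tables so the per-scan path is pure vector arithmetic
.signalCache <- function(signals) {
  pr <- signals@precursors
  tr <- signals@transitions
  trPrec <- match(tr$peptideId, pr$peptideId)
  list(precMz = pr$precursorMz, apex = pr$apexRt, sigma = pr$sigma,
       tail = pr$tailFactor, precAmp = pr$amplitude,
       trMz = tr$mz, trAmp = tr$amplitude, trPrec = trPrec,
       trRowsByPrec = split(seq_len(nrow(tr)), trPrec))
}

.peakValue <- function(apex, sigma, tail, amp, t) {
  s <- sigma * (1 + (tail - 1) * (t >= apex))
  z <- (t - apex) / s
  v <- amp * exp(-0.5 * z * z)
  v[abs(z) > 5] <- 0
  v
}

# true + noise + background + floor for one MS2 scan; returns list(mz, int)
.acquireSpectrum <- function(signals, center, t, params, streams,
                             cache = NULL) {
  if (is.null(cache)) cache <- .signalCache(signals)
  visible <- which(abs(cache$precMz - center) <= params@isolationWidth / 2)
  rows <- unlist(cache$trRowsByPrec[as.character(visible)], use.names = FALSE)
  pi <- cache$trPrec[rows]
  int <- .peakValue(cache$apex[pi], cache$sigma[pi], cache$tail[pi],
                    cache$trAmp[rows], t)
  mz <- cache$trMz[rows]
  keep <- int > 0
  mz <- mz[keep]; int <- int[keep]
  if (signals@noiseCv > 0 && length(int)) {
    s <- .noiseSdlog(signals@noiseCv)
    int <- int * .withStream(streams, "noise",
                             rlnorm(length(int), -s^2 / 2, s))
  }
  bg <- signals@background
  if (bg@ionsPerScan > 0) {
    b <- .withStream(streams, "background",
                     .sampleBackgroundVec(bg, bg@mzRange, mz,
                                          params@fragmentTolPpm))
    mz <- c(mz, b$mz); int <- c(int, b$intensity)
  }
  keep <- int >= signals@floor
  list(mz = mz[keep], intensity = int[keep])
}

#' Acquire one simulated MS2 spectrum
#'
#' The centroid list a single MS2 scan would observe: true transition
#' intensities at the scan time for every precursor inside the isolation
#' window, multiplied by lognormal shot noise, merged with background
#' ions, and cut at the detection floor.
#'
#' @param signals A [SignalSet-class].
#' @param isolationMz Isolation window center (Th).
#' @param t Scan time (s).
#' @param params An [AcquisitionParams-class].
#' @param seed Seed for the noise/background draws of this one scan.
#' @return data.frame: `mz`, `intensity`.
#' @export
acquireQuantSpectrum <- function(signals, isolationMz, t,
                                 params = acquisitionParams(), seed = 1L) {
  streams <- .makeStreams(c(noise = .subSeed(seed, "noise"),
                            background = .subSeed(seed, "background")))
  as.data.frame(.acquireSpectrum(signals, isolationMz, t, params, streams))
}

# scan accumulator ---------------------------------------------------------

.newAcc <- function() {
  env <- new.env(parent = emptyenv())
  env$scans <- vector("list", 2048); env$cent <- vector("list", 2048)
  env$n <- 0L
  env
}

.addScan <- function(acc, time, kind, targetId, isolationMz, resolution,
                     injectionTime, matched, mz, int) {
  n <- acc$n + 1L
  if (n > length(acc$scans)) {
    length(acc$scans) <- 2L * length(acc$scans)
    length(acc$cent) <- 2L * length(acc$cent)
  }
  acc$scans[[n]] <- list(time = time, kind = kind, targetId = targetId,
                         isolationMz = isolationMz, resolution = resolution,
                         injectionTime = injectionTime, matched = matched,
                         tic = sum(int))
  acc$cent[[n]] <- list(mz = mz, int = int)
  acc$n <- n
}

.accToRecord <- function(acc, runIndex, gradientName, params, seed) {
  s <- acc$scans[seq_len(acc$n)]
  ce <- acc$cent[seq_len(acc$n)]
  nc <- vapply(ce, function(x) length(x$mz), integer(1))
  scans <- data.frame(
    scanId = seq_len(acc$n),
    time = vapply(s, `[[`, numeric(1), "time"),
    kind = vapply(s, `[[`, character(1), "kind"),
    targetId = vapply(s, `[[`, character(1), "targetId"),
    isolationMz = vapply(s, `[[`, numeric(1), "isolationMz"),
    resolution = vapply(s, `[[`, numeric(1), "resolution"),
    injectionTime = vapply(s, `[[`, numeric(1), "injectionTime"),
    matchedFragments = vapply(s, `[[`, integer(1), "matched"),
    tic = vapply(s, `[[`, numeric(1), "tic"))
  centroids <- data.frame(
    scanId = rep.int(seq_len(acc$n), nc),
    mz = unlist(lapply(ce, `[[`, "mz"), use.names = FALSE),
    intensity = unlist(lapply(ce, `[[`, "int"), use.names = FALSE))
  new("RunRecord", runIndex = as.integer(runIndex),
      gradientName = gradientName, scans = scans, centroids = centroids,
      params = .paramsAsList(params), seed = as.integer(seed))
}

.paramsAsList <- function(p) {
  nm <- slotNames(p)
  setNames(lapply(nm, function(x) slot(p, x)), nm)
}

.ms1Scan <- function(signals, t, params, streams, acc, cache = NULL) {
  if (is.null(cache)) cache <- .signalCache(signals)
  int <- .peakValue(cache$apex, cache$sigma, cache$tail, cache$precAmp, t)
  mz <- cache$precMz
  keep <- int > 0
  mz <- mz[keep]; int <- int[keep]
  if (signals@noiseCv > 0 && length(int)) {
    s <- .noiseSdlog(signals@noiseCv)
    int <- int * .withStream(streams, "noise",
                             rlnorm(length(int), -s^2 / 2, s))
  }
  fl <- int >= signals@floor
  mz <- mz[fl]; int <- int[fl]
  .addScan(acc, t, "MS1", NA_character_, NA_real_, params@ms1Resolution,
           params@ms1InjectionTime, NA_integer_, mz, int)
  list(mz = mz, intensity = int)
}

#' Simulate one internal-standard-triggered (SureQuant-style) run
#'
#' Runs the full duty-cycle event loop over the active gradient. At each
#' cycle one MS1 scan is taken; every heavy precursor whose MS1 centroid
#' (within the precursor ppm tolerance) is at or above its detection
#' threshold (`isIntensityFraction` x IS apex amplitude) receives a
#' watch MS2 on the heavy m/z, and if at least `triggerMinIons` of its
#' expected transitions match within the fragment tolerance, one
#' quantitative MS2 at the offset (light) m/z follows in the same cycle.
#' Watch+quant units that would exceed the cycle budget are deferred to
#' the head of the next cycle.
#'
#' @param signals A [SignalSet-class] for the run.
#' @param panel The [TransitionPanel-class] the signals were rendered
#'   from.
#' @param params An [AcquisitionParams-class].
#' @param gradient A [GradientMethod-class].
#' @param runIndex Zero-based run index (metadata).
#' @param seed Seed for the run's noise and background streams.
#' @return A [RunRecord-class].
#' @export
runSureQuant <- function(signals, panel, params = acquisitionParams(),
                         gradient = gradient100SPD(), runIndex = 0L,
                         seed = 1L) {
  streams <- .makeStreams(c(
    noise = .subSeed(seed, "noise", runIndex),
    background = .subSeed(seed, "background", runIndex)))
  pr <- signals@precursors
  heavyRows <- which(pr$isHeavy)
  heavyIds <- pr$peptideId[heavyRows]
  thresholds <- params@isIntensityFraction * pr$amplitude[heavyRows]
  expMz <- lapply(heavyIds, function(id)
    signals@transitions$mz[signals@transitions$peptideId == id])
  lightId <- sub("/heavy$", "/light", heavyIds)
  lightMz <- pr$precursorMz[match(lightId, pr$peptideId)]
  dMS1 <- scanDuration(params@ms1Resolution, params@ms1InjectionTime,
                       params@scanOverhead)
  dW <- scanDuration(params@watchResolution, params@watchInjectionTime,
                     params@scanOverhead)
  dQ <- scanDuration(params@quantResolution, params@quantInjectionTime,
                     params@scanOverhead)
  L <- gradient@activeLength
  acc <- .newAcc()
  cache <- .signalCache(signals)
  cycleStart <- 0
  pending <- integer()
  while (cycleStart < L) {
    t <- cycleStart
    ms1 <- .ms1Scan(signals, t, params, streams, acc, cache)
    t <- t + dMS1
    budgetEnd <- cycleStart + params@cyclePeriod
    # heavy precursors seen in this MS1 within the precursor tolerance
    seen <- vapply(seq_along(heavyRows), function(k) {
      mzH <- pr$precursorMz[heavyRows[k]]
      near <- abs(ms1$mz - mzH) <= mzH * params@precursorTolPpm * 1e-6
      any(near) && max(ms1$intensity[near]) >= thresholds[k]
    }, logical(1))
    todo <- unique(c(pending, which(seen)))
    pending <- integer()
    for (k in todo) {
      if (t + dW + dQ > budgetEnd) { pending <- c(pending, k); next }
      hRow <- heavyRows[k]
      wc <- .acquireSpectrum(signals, pr$precursorMz[hRow], t, params,
                             streams, cache)
      matched <- matchFragments(wc$mz, expMz[[k]], params@fragmentTolPpm)
      .addScan(acc, t, "WATCH_MS2", heavyIds[k], pr$precursorMz[hRow],
               params@watchResolution, params@watchInjectionTime,
               as.integer(matched), wc$mz, wc$intensity)
      t <- t + dW
      if (matched >= params@triggerMinIons) {
        offMz <- offsetMz(pr$precursorMz[hRow], pr$labelDelta[hRow],
                          pr$charge[hRow])
        qc <- .acquireSpectrum(signals, offMz, t, params, streams, cache)
        .addScan(acc, t, "QUANT_MS2", lightId[k], offMz,
                 params@quantResolution, params@quantInjectionTime,
                 NA_integer_, qc$mz, qc$intensity)
        t <- t + dQ
      }
    }
    cycleStart <- max(cycleStart + params@cyclePeriod, t)
  }
  .accToRecord(acc, runIndex, gradient@name, params, seed)
}

#' Simulate one scheduled-PRM comparator run
#'
#' Every light precursor whose scheduling window contains the cycle
#' start time receives a quantitative MS2 every cycle, regardless of
#' signal, under the same scan-time budget (overflowing scans are
#' deferred to the next cycle). Overlapping windows are allowed.
#'
#' @param signals A [SignalSet-class].
#' @param panel The panel.
#' @param rtWindows data.frame: `targetId`, `start`, `end` (s), one row
#'   per light target.
#' @param params An [AcquisitionParams-class].
#' @param gradient A [GradientMethod-class].
#' @param runIndex Zero-based run index.
#' @param seed Seed for noise/background streams.
#' @return A [RunRecord-class].
#' @export
runScheduledPRM <- function(signals, panel, rtWindows,
                            params = acquisitionParams(),
                            gradient = gradient100SPD(), runIndex = 0L,
                            seed = 1L) {
  streams <- .makeStreams(c(
    noise = .subSeed(seed, "noise", runIndex),
    background = .subSeed(seed, "background", runIndex)))
  pr <- signals@precursors
  lightRows <- which(!pr$isHeavy)
  lightIds <- pr$peptideId[lightRows]
  w <- rtWindows[match(pr$targetId[lightRows], rtWindows$targetId), ]
  if (any(is.na(w$start)))
    stop("rtWindows missing for: ",
         paste(pr$targetId[lightRows][is.na(w$start)], collapse = ", "))
  dMS1 <- scanDuration(params@ms1Resolution, params@ms1InjectionTime,
                       params@scanOverhead)
  dQ <- scanDuration(params@quantResolution, params@quantInjectionTime,
                     params@scanOverhead)
  L <- gradient@activeLength
  acc <- .newAcc()
  cache <- .signalCache(signals)
  cycleStart <- 0
  pending <- integer()
  while (cycleStart < L) {
    t <- cycleStart
    .ms1Scan(signals, t, params, streams, acc, cache)
    t <- t + dMS1
    budgetEnd <- cycleStart + params@cyclePeriod
    due <- which(w$start <= cycleStart & cycleStart <= w$end)
    todo <- unique(c(pending, due))
    pending <- integer()
    for (k in todo) {
      if (t + dQ > budgetEnd) { pending <- c(pending, k); next }
      row <- lightRows[k]
      qc <- .acquireSpectrum(signals, pr$precursorMz[row], t, params,
                             streams, cache)
      .addScan(acc, t, "QUANT_MS2", lightIds[k], pr$precursorMz[row],
               params@quantResolution, params@quantInjectionTime,
               NA_integer_, qc$mz, qc$intensity)
      t <- t + dQ
    }
    cycleStart <- max(cycleStart + params@cyclePeriod, t)
  }
  .accToRecord(acc, runIndex, gradient@name, params, seed)
}

#' Write a run's scan table and centroids to CSV
#'
#' Writes `<prefix>_scans.csv` (one row per scan event),
#' `<prefix>_centroids.csv` (long format: scanId, mz, intensity) and a
#' `<prefix>_meta.csv` sidecar (run index, gradient, seed).
#'
#' @param run A [RunRecord-class].
#' @param prefix Output path prefix.
#' @return Character vector of the three paths, invisibly.
#' @export
writeRunCsv <- function(run, prefix) {
  ps <- paste0(prefix, "_scans.csv")
  pc <- paste0(prefix, "_centroids.csv")
  pm <- paste0(prefix, "_meta.csv")
  write.csv(run@scans, ps, row.names = FALSE)
  write.csv(run@centroids, pc, row.names = FALSE)
  write.csv(data.frame(runIndex = run@runIndex,
                       gradientName = run@gradientName, seed = run@seed),
            pm, row.names = FALSE)
  invisible(c(ps, pc, pm))
}

#' Read a run back from its CSV tables
#'
#' Inverse of [writeRunCsv()]. Acquisition parameters are not
#' round-tripped; the quantification chain does not need them.
#'
#' @param prefix Path prefix used when writing.
#' @return A [RunRecord-class].
#' @export
readRunCsv <- function(prefix) {
  scans <- read.csv(paste0(prefix, "_scans.csv"), stringsAsFactors = FALSE)
  centroids <- read.csv(paste0(prefix, "_centroids.csv"))
  meta <- read.csv(paste0(prefix, "_meta.csv"), stringsAsFactors = FALSE)
  scans$targetId <- as.character(scans$targetId)
  new("RunRecord", runIndex = as.integer(meta$runIndex[1]),
      gradientName = meta$gradientName[1], scans = scans,
      centroids = centroids, params = list(),
      seed = as.integer(meta$seed[1]))
}
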