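# Synthetic-sample ground truth and signal rendering: protein
# concentrations over the assay dynamic range, peptide response factors,
# the constant internal-standard spike, matrix background ions, and the
# per-concern RNG streams.

#' GroundTruth class
#'
#' The simulated "sample" truth: per-protein median concentrations laid
#' out log-uniformly over the requested span, per-sample lognormal
#' biological variation, a fixed lognormal response factor per peptide
#' (how efficiently a peptide reports its protein), and the constant
#' internal-standard amplitude shared by every heavy peptide in every
#' run (the fixed spike per injection).
#'
#' @slot proteins data.frame: `proteinId`, `median` (relative units).
#' @slot concentrations data.frame: `sample`, `proteinId`,
#'   `concentration`.
#' @slot responses data.frame: `targetId`, `proteinId`,
#'   `responseFactor`.
#' @slot isAmplitude Internal-standard apex amplitude (constant).
#' @slot log10Span Requested span in orders of magnitude.
#' @slot seed Integer seed used for the truth stream.
#' @export
setClass("GroundTruth",
         representation(proteins = "data.frame", concentrations = "data.frame",
                        responses = "data.frame", isAmplitude = "numeric",
                        log10Span = "numeric", seed = "integer"))

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d proteins over %.1f orders, %d sample(s), IS amplitude %g\n",
    nrow(object@proteins), object@log10Span,
    length(unique(object@concentrations$sample)), object@isAmplitude))
})

#' Generate ground-truth protein concentrations for a study
#'
#' Protein medians are placed log-uniformly (deterministic, evenly
#' spaced in log10 over protein names sorted alphabetically) across
#' `log10Span` orders of magnitude; each sample draws a lognormal
#' biological deviation around its protein median. Peptide response
#' factors are lognormal and fixed across samples. All draws come from
#' a dedicated "truth" RNG stream derived from `seed`.
#'
#' @param panel A [TransitionPanel-class].
#' @param log10Span Orders of magnitude between the highest and lowest
#'   protein median (default 6, the assay's demonstrated range).
#' @param nSamples Number of samples.
#' @param seed Integer seed.
#' @param bioSdlog Lognormal sdlog of per-sample biological variation
#'   (default 0.25).
#' @param responseSdlog Lognormal sdlog of per-peptide response factors
#'   (default 0.25).
#' @param isAmplitude Internal-standard apex amplitude, identical for
#'   every heavy peptide and run (default 1e4).
#' @param log10Min log10 of the lowest protein median (default 0, i.e.
#'   the ladder starts at 1 relative unit).
#' @return A [GroundTruth-class].
#' @export
generateGroundTruth <- function(panel, log10Span = 6, nSamples = 1L,
                                seed = 1L, bioSdlog = 0.25,
                                responseSdlog = 0.25, isAmplitude = 1e4,
                                log10Min = 0) {
  if (log10Span < 0) stop("log10Span must be >= 0")
  p <- panel@peptides[!panel@peptides$isHeavy, ]
  if (nrow(p) == 0L) stop("empty panel")
  prot <- sort(unique(p$proteinId))
  med <- if (length(prot) == 1L) 10^(log10Min + log10Span / 2) else
    10^seq(log10Min, log10Min + log10Span, length.out = length(prot))
  proteins <- data.frame(proteinId = prot, median = med)
  draws <- .withSeed(.subSeed(seed, "truth"), list(
    bio = rlnorm(nSamples * length(prot), -bioSdlog^2 / 2, bioSdlog),
    resp = rlnorm(nrow(p), -responseSdlog^2 / 2, responseSdlog)))
  conc <- data.frame(
    sample = rep(seq_len(nSamples), each = length(prot)),
    proteinId = rep(prot, nSamples),
    concentration = rep(med, nSamples) * draws$bio)
  responses <- data.frame(targetId = p$targetId, proteinId = p$proteinId,
                          responseFactor = draws$resp)
  new("GroundTruth", proteins = proteins, concentrations = conc,
      responses = responses, isAmplitude = isAmplitude,
      log10Span = log10Span, seed = as.integer(seed))
}

#' BackgroundModel class
#'
#' Matrix background ions in MS2 scans: a Poisson number of centroids
#' per scan with lognormal intensities; a configurable fraction are
#' "interferents" placed within the fragment match tolerance of randomly
#' chosen true transitions, the rest uniform over the observed m/z
#' range.
#'
#' @slot ionsPerScan Poisson mean count per MS2 scan.
#' @slot mzRange Observed fragment m/z range, c(lo, hi).
#' @slot intensityMeanlog,intensitySdlog Lognormal intensity parameters.
#' @slot interferentFraction Fraction placed near true transitions.
#' @export
setClass("BackgroundModel",
         representation(ionsPerScan = "numeric", mzRange = "numeric",
                        intensityMeanlog = "numeric",
                        intensitySdlog = "numeric",
                        interferentFraction = "numeric"))

setValidity("BackgroundModel", function(object) {
  if (object@ionsPerScan < 0) return("ionsPerScan must be >= 0")
  if (object@interferentFraction < 0 || object@interferentFraction > 1)
    return("interferentFraction must be in [0,1]")
  TRUE
})

#' @describeIn BackgroundModel constructor
#' @param ionsPerScan Poisson mean ion count per MS2 scan.
#' @param mzRange Fragment m/z range.
#' @param intensityMeanlog,intensitySdlog Lognormal intensity parameters.
#' @param interferentFraction Fraction of ions placed within tolerance
#'   of true transitions.
#' @export
backgroundModel <- function(ionsPerScan = 20, mzRange = c(100, 1500),
                            intensityMeanlog = log(2), intensitySdlog = 1,
                            interferentFraction = 0.05) {
  new("BackgroundModel", ionsPerScan = ionsPerScan, mzRange = mzRange,
      intensityMeanlog = intensityMeanlog, intensitySdlog = intensitySdlog,
      interferentFraction = interferentFraction)
}

#' Draw background centroids for one MS2 scan
#'
#' Draws from the current RNG state (the acquisition engine calls this
#' inside its dedicated background stream).
#'
#' @param model A [BackgroundModel-class].
#' @param mzWindow Observable m/z window, c(lo, hi).
#' @param trueMz True transition m/z values interferents may shadow.
#' @param tolPpm Placement tolerance for interferents (ppm).
#' @return data.frame: `mz`, `intensity` (possibly zero rows).
#' @export
sampleBackground <- function(model, mzWindow = model@mzRange,
                             trueMz = numeric(), tolPpm = 10) {
  as.data.frame(.sampleBackgroundVec(model, mzWindow, trueMz, tolPpm))
}

.sampleBackgroundVec <- function(model, mzWindow, trueMz, tolPpm) {
  n <- rpois(1, model@ionsPerScan)
  if (n == 0L) return(list(mz = numeric(), intensity = numeric()))
  isInt <- runif(n) < model@interferentFraction & length(trueMz) > 0
  mz <- runif(n, mzWindow[1], mzWindow[2])
  if (any(isInt)) {
    anchor <- trueMz[sample.int(length(trueMz), sum(isInt), replace = TRUE)]
    mz[isInt] <- anchor * (1 + runif(sum(isInt), -tolPpm, tolPpm) * 1e-6)
  }
  keep <- mz >= mzWindow[1] & mz <= mzWindow[2]
  list(mz = mz[keep],
       intensity = rlnorm(sum(keep), model@intensityMeanlog,
                          model@intensitySdlog))
}

#' SignalSet class
#'
#' Fully rendered per-run signal functions for one sample: per-precursor
#' amplitudes and elution parameters plus per-transition amplitudes
#' (precursor amplitude times a fixed fragment weight vector summing
#' to 1). Light amplitudes are concentration x response factor; heavy
#' amplitudes are the constant internal-standard amplitude.
#'
#' @slot precursors data.frame: `peptideId`, `targetId`, `proteinId`,
#'   `isHeavy`, `precursorMz`, `charge`, `labelDelta`, `amplitude`,
#'   `apexRt`, `sigma`, `tailFactor`.
#' @slot transitions data.frame: `peptideId`, `transitionId`, `mz`,
#'   `weight`, `amplitude`.
#' @slot noiseCv Multiplicative lognormal shot-noise CV on centroids.
#' @slot floor Detection floor: centroids below this intensity are
#'   dropped (the sensitivity limit of the simulated instrument).
#' @slot background A [BackgroundModel-class] or NULL-like empty model.
#' @slot sample Sample index this set was rendered for.
#' @export
setClass("SignalSet",
         representation(precursors = "data.frame", transitions = "data.frame",
                        noiseCv = "numeric", floor = "numeric",
                        background = "BackgroundModel", sample = "integer"))

setMethod("show", "SignalSet", function(object) {
  cat(sprintf(
    "SignalSet: sample %d, %d precursors, %d transitions, noise CV %.1f%%, floor %g\n",
    object@sample, nrow(object@precursors), nrow(object@transitions),
    100 * object@noiseCv, object@floor))
})

#' Fixed fragment weight vector
#'
#' Deterministic per-peptide split of precursor signal across its
#' transitions: proportional to (k, k-1, ..., 1), normalized to sum
#' to 1.
#'
#' @param k Number of transitions.
#' @return Numeric vector of length `k` summing to 1.
#' @export
fragmentWeights <- function(k) {
  w <- rev(seq_len(k))
  w / sum(w)
}

#' Render per-run signal functions for one sample
#'
#' Combines ground truth, panel and (possibly drifted) elution profiles
#' into a [SignalSet-class]: each transition's intensity at time t is
#' precursor amplitude x fragment weight x peak shape. A protein at
#' zero concentration yields identically zero light transitions while
#' its heavy transitions are unaffected.
#'
#' @param truth A [GroundTruth-class].
#' @param panel A [TransitionPanel-class].
#' @param profiles Profile table from [elutionProfiles()] (after any
#'   [applyDrift()]).
#' @param sample Sample index into the ground truth.
#' @param noiseCv Centroid shot-noise CV (default 0.05).
#' @param floor Detection floor intensity (default 0.05).
#' @param background A [BackgroundModel-class]; use
#'   `backgroundModel(ionsPerScan = 0)` to disable.
#' @return A [SignalSet-class].
#' @export
renderSignals <- function(truth, panel, profiles, sample = 1L,
                          noiseCv = 0.05, floor = 0.05,
                          background = backgroundModel()) {
  p <- panel@peptides
  if (!all(p$targetId %in% profiles$targetId))
    stop("profiles missing for: ",
         paste(setdiff(p$targetId, profiles$targetId), collapse = ", "))
  conc <- truth@concentrations[truth@concentrations$sample == sample, ]
  if (nrow(conc) == 0L) stop("no such sample in ground truth: ", sample)
  concOf <- setNames(conc$concentration, conc$proteinId)
  respOf <- setNames(truth@responses$responseFactor, truth@responses$targetId)
  prof <- profiles[match(p$targetId, profiles$targetId), ]
  amp <- ifelse(p$isHeavy, truth@isAmplitude,
                concOf[p$proteinId] * respOf[p$targetId])
  prec <- data.frame(
    peptideId = p$peptideId, targetId = p$targetId, proteinId = p$proteinId,
    isHeavy = p$isHeavy, precursorMz = p$precursorMz, charge = p$charge,
    labelDelta = p$labelDelta, amplitude = unname(amp),
    apexRt = prof$apexRt, sigma = prof$sigma, tailFactor = prof$tailFactor)
  tr <- panel@transitions
  trs <- do.call(rbind, c(lapply(seq_len(nrow(prec)), function(i) {
    ti <- tr[tr$peptideId == prec$peptideId[i], ]
    w <- fragmentWeights(nrow(ti))
    data.frame(peptideId = ti$peptideId,
               transitionId = paste0(ti$ionType, ti$fragmentIndex),
               mz = ti$mz, weight = w, amplitude = prec$amplitude[i] * w)
  }), list(make.row.names = FALSE)))
  new("SignalSet", precursors = prec, transitions = trs, noiseCv = noiseCv,
      floor = floor, background = background, sample = as.integer(sample))
}

#' Noiseless transition intensity at a time point
#'
#' The rendered (ground-truth) intensity of each row of
#' `signals@transitions[rows, ]` at time `t`, before noise, background
#' and the detection floor.
#'
#' @param signals A [SignalSet-class].
#' @param rows Row indices into `signals@transitions`.
#' @param t Time (s, scalar).
#' @return Numeric vector of intensities.
#' @export
transitionIntensity <- function(signals, rows, t) {
  tr <- signals@transitions[rows, , drop = FALSE]
  i <- match(tr$peptideId, signals@precursors$peptideId)
  pr <- signals@precursors[i, , drop = FALSE]
  peakIntensity(pr$apexRt, pr$sigma, tr$amplitude, t, pr$tailFactor)
}

#' Noiseless precursor intensity at a time point
#'
#' @param signals A [SignalSet-class].
#' @param t Time (s, scalar).
#' @return Numeric vector, one entry per row of `signals@precursors`.
#' @export
precursorIntensity <- function(signals, t) {
  pr <- signals@precursors
  peakIntensity(pr$apexRt, pr$sigma, pr$amplitude, t, pr$tailFactor)
}

# --- RNG streams ---------------------------------------------------------
# Named independent streams: each concern owns a saved .Random.seed state;
# drawing from one stream leaves the others untouched, so e.g. disabling
# background leaves the noise draws bit-identical.

.makeStreams <- function(seeds) {
  env <- new.env(parent = emptyenv())
  for (nm in names(seeds)) {
    env[[nm]] <- .withSeed(seeds[[nm]], get(".Random.seed", globalenv()))
  }
  env
}

.withStream <- function(streams, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  assign(".Random.seed", streams[[name]], globalenv())
  res <- expr
  streams[[name]] <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  res
}
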