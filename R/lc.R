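# Chromatography model: gradient methods, retention-time prediction,
# Gaussian elution peaks, run-to-run drift.

#' GradientMethod class
#'
#' A standardized LC method. The two shipped presets mirror the
#' samples-per-day methods: 100SPD (active gradient 690 s = 11.5 min,
#' cycle 864 s = 14.4 min, 1.5 ul/min) and 60SPD (active gradient
#' 1320 s = 22 min).
#'
#' @slot name Method name.
#' @slot activeLength Active gradient length (s).
#' @slot cycleTime Full LC cycle time (s); must be >= activeLength.
#' @slot flowRate Flow rate (ul/min), informational.
#' @export
setClass("GradientMethod",
         representation(name = "character", activeLength = "numeric",
                        cycleTime = "numeric", flowRate = "numeric"))

setValidity("GradientMethod", function(object) {
  if (object@activeLength <= 0) return("activeLength must be positive")
  if (object@cycleTime < object@activeLength)
    return("cycleTime must be >= activeLength")
  TRUE
})

setMethod("show", "GradientMethod", function(object) {
  cat(sprintf("GradientMethod '%s': active %.0f s, cycle %.0f s, %.1f ul/min\n",
              object@name, object@activeLength, object@cycleTime,
              object@flowRate))
})

#' Construct an LC gradient method
#'
#' @param name Method label.
#' @param activeLength Active gradient length (s).
#' @param cycleTime LC cycle time (s), default = activeLength.
#' @param flowRate Flow rate (ul/min), informational.
#' @return A [GradientMethod-class].
#' @export
gradientMethod <- function(name, activeLength, cycleTime = activeLength,
                           flowRate = 1.5) {
  new("GradientMethod", name = name, activeLength = activeLength,
      cycleTime = cycleTime, flowRate = flowRate)
}

#' @rdname gradientMethod
#' @export
gradient100SPD <- function() gradientMethod("100SPD", 690, 864, 1.5)

#' @rdname gradientMethod
#' @export
gradient60SPD <- function() gradientMethod("60SPD", 1320, 1584, 1.5)

#' @describeIn gradientMethod active gradient length accessor (s)
#' @param gradient A `GradientMethod`.
#' @export
activeLength <- function(gradient) gradient@activeLength

#' Predict a peptide's apex retention time on a gradient
#'
#' A deterministic, documented stand-in for observed elution (not a
#' physical model): the mean Kyte-Doolittle hydropathy is mapped
#' affinely onto the central [0.1, 0.9] fraction of the active gradient,
#' with a small dispersion term derived from the fractional part of the
#' unmodified peptide mass so that co-ranking peptides still separate.
#' Depends only on the bare sequence, so heavy and light partners elute
#' identically, and predictions on two gradients differ exactly by the
#' ratio of active lengths.
#'
#' @param sequence Peptide sequence.
#' @param gradient A [GradientMethod-class].
#' @return Apex retention time in seconds.
#' @export
predictRt <- function(sequence, gradient) {
  aa <- .checkResidues(sequence)
  h <- mean(.KYTE_DOOLITTLE[aa])
  base <- min(1, max(0, (h + 4.5) / 9))
  disp <- peptideMass(sequence) %% 1
  u <- 0.85 * base + 0.15 * disp
  (0.1 + 0.8 * u) * gradient@activeLength
}

#' Elution profile table for a panel
#'
#' One row per heavy/light target pair: apex RT from [predictRt()], a
#' common peak width, and tail factor. Heavy and light partners share
#' the profile exactly (the internal standard co-elutes with the
#' endogenous peptide by construction).
#'
#' Default width sigma = 3 s on the 100SPD gradient, scaled by the
#' active-length ratio for other gradients (about a 14 s base width at
#' 5 % height, consistent with sub-30 s measurement windows).
#'
#' @param panel A [TransitionPanel-class].
#' @param gradient A [GradientMethod-class].
#' @param sigma Peak width SD (s); default scales with gradient length.
#' @param tailFactor Right/left width ratio (1 = symmetric Gaussian).
#' @return data.frame: `targetId`, `sequence`, `apexRt`, `sigma`,
#'   `tailFactor`.
#' @export
elutionProfiles <- function(panel, gradient,
                            sigma = 3 * gradient@activeLength / 690,
                            tailFactor = 1) {
  p <- panel@peptides[!panel@peptides$isHeavy, ]
  data.frame(
    targetId = p$targetId, sequence = p$sequence,
    apexRt = vapply(p$sequence, predictRt, numeric(1), gradient = gradient,
                    USE.NAMES = FALSE),
    sigma = sigma, tailFactor = tailFactor)
}

#' Peak intensity at a time point
#'
#' Bi-Gaussian peak value: amplitude at the apex, width `sigma` on the
#' left and `sigma * tailFactor` on the right, truncated to zero beyond
#' +/- 5 sigma of the respective side (documented truncation; the
#' omitted area is below 1e-5 of the total).
#'
#' @param apexRt Apex retention time (s).
#' @param sigma Peak SD (s).
#' @param amplitude Apex intensity.
#' @param t Time (s); vectorised.
#' @param tailFactor Right-side width multiplier (default 1, symmetric).
#' @return Intensity at `t`.
#' @export
peakIntensity <- function(apexRt, sigma, amplitude, t, tailFactor = 1) {
  s <- ifelse(t >= apexRt, sigma * tailFactor, sigma)
  z <- (t - apexRt) / s
  ifelse(abs(z) > 5, 0, amplitude * exp(-0.5 * z^2))
}

#' DriftModel class
#'
#' Run-to-run retention-time instability: a slow linear drift per run
#' plus Gaussian per-run apex jitter, as seen over long continuous
#' injection sequences. Shifts are drawn per target pair, so heavy and
#' light partners always move together.
#'
#' @slot jitterSd Per-run apex jitter SD (s), >= 0.
#' @slot linearDrift Systematic drift per run (s/run).
#' @slot seed Base RNG seed; run `i` uses a sub-seed derived from
#'   (seed, i), so any run's shifts are reproducible in isolation.
#' @export
setClass("DriftModel",
         representation(jitterSd = "numeric", linearDrift = "numeric",
                        seed = "integer"))

setValidity("DriftModel", function(object) {
  if (object@jitterSd < 0) return("jitterSd must be >= 0")
  TRUE
})

#' @describeIn DriftModel constructor
#' @param jitterSd Per-run jitter SD (s).
#' @param linearDrift Linear drift (s/run).
#' @param seed Integer seed.
#' @export
driftModel <- function(jitterSd = 0, linearDrift = 0, seed = 1L) {
  new("DriftModel", jitterSd = jitterSd, linearDrift = linearDrift,
      seed = as.integer(seed))
}

setMethod("show", "DriftModel", function(object) {
  cat(sprintf("DriftModel: jitter SD %.2f s, linear %.3f s/run, seed %d\n",
              object@jitterSd, object@linearDrift, object@seed))
})

#' Apply retention-time drift to elution profiles for one run
#'
#' apex' = apex + linearDrift * runIndex + N(0, jitterSd), one draw per
#' target pair, clipped to the active gradient. Deterministic per
#' (model seed, runIndex).
#'
#' @param profiles Profile table from [elutionProfiles()].
#' @param runIndex Zero-based run index in the sequence.
#' @param model A [DriftModel-class].
#' @param gradient A [GradientMethod-class] (for clipping).
#' @return The profile table with shifted `apexRt`.
#' @export
applyDrift <- function(profiles, runIndex, model, gradient) {
  shift <- model@linearDrift * runIndex
  if (model@jitterSd > 0) {
    shift <- shift + .withSeed(
      .subSeed(model@seed, "drift", runIndex),
      rnorm(nrow(profiles), 0, model@jitterSd))
  }
  profiles$apexRt <- pmin(gradient@activeLength,
                          pmax(0, profiles$apexRt + shift))
  profiles
}

# --- seed plumbing -------------------------------------------------------
# Each stochastic concern (truth, drift, noise, background) draws from its
# own derived sub-seed so toggling one concern leaves the others
# bit-identical. Sub-seeds stay below 2^31 - 1.

.subSeed <- function(seed, tag, index = 0L) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 7919 + as.numeric(index) * 104729)
             %% 2147483629)
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  expr
}
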