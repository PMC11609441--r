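# Orchestration: wiring panel, ground truth, LC, drift and acquisition
# into single runs and multi-sample studies.

#' Simulate one complete run
#'
#' Convenience wrapper: predicts elution profiles on the gradient,
#' applies run-indexed drift, renders the signal set for one sample of
#' the ground truth, and executes the acquisition engine in either
#' triggered ("surequant") or scheduled ("prm") mode.
#'
#' @param panel A [TransitionPanel-class].
#' @param truth A [GroundTruth-class].
#' @param sample Sample index into the truth.
#' @param gradient A [GradientMethod-class].
#' @param params An [AcquisitionParams-class].
#' @param drift A [DriftModel-class].
#' @param runIndex Zero-based run index (drives linear drift and the
#'   per-run jitter sub-seed).
#' @param seed Seed for the run's noise/background streams.
#' @param noiseCv,floor,background Passed to [renderSignals()].
#' @param mode "surequant" (triggered) or "prm" (scheduled).
#' @param rtWindows For mode "prm": data.frame `targetId`, `start`,
#'   `end`; defaults to undrifted apex +/- 15 s.
#' @return A [RunRecord-class].
#' @export
simulateRun <- function(panel, truth, sample = 1L,
                        gradient = gradient100SPD(),
                        params = acquisitionParams(),
                        drift = driftModel(), runIndex = 0L, seed = 1L,
                        noiseCv = 0.05, floor = 0.05,
                        background = backgroundModel(),
                        mode = c("surequant", "prm"), rtWindows = NULL) {
  mode <- match.arg(mode)
  profiles <- elutionProfiles(panel, gradient)
  drifted <- applyDrift(profiles, runIndex, drift, gradient)
  signals <- renderSignals(truth, panel, drifted, sample, noiseCv, floor,
                           background)
  if (mode == "surequant") {
    runSureQuant(signals, panel, params, gradient, runIndex, seed)
  } else {
    if (is.null(rtWindows))
      rtWindows <- data.frame(targetId = profiles$targetId,
                              start = profiles$apexRt - 15,
                              end = profiles$apexRt + 15)
    runScheduledPRM(signals, panel, rtWindows, params, gradient, runIndex,
                    seed)
  }
}

#' Simulate a multi-sample study
#'
#' Generates ground truth for `nSamples` samples and simulates one
#' triggered run per sample (run index = sample index - 1).
#'
#' @param panel A [TransitionPanel-class] (default: the shipped
#'   nine-protein panel).
#' @param nSamples Number of samples/runs (default 42).
#' @param log10Span Dynamic-range span of the protein medians.
#' @param seed Master seed; per-concern sub-seeds are derived from it.
#' @param gradient,params,drift,noiseCv,floor,background As in
#'   [simulateRun()].
#' @param isAmplitude,bioSdlog,responseSdlog Passed to
#'   [generateGroundTruth()].
#' @return list: `truth`, `runs` (list of [RunRecord-class]), `panel`,
#'   `gradient`, `params`.
#' @export
simulateStudy <- function(panel = defaultPanel(), nSamples = 42L,
                          log10Span = 6, seed = 1L,
                          gradient = gradient100SPD(),
                          params = acquisitionParams(),
                          drift = driftModel(seed = seed),
                          noiseCv = 0.05, floor = 0.05,
                          background = backgroundModel(),
                          isAmplitude = 1e4, bioSdlog = 0.25,
                          responseSdlog = 0.25) {
  truth <- generateGroundTruth(panel, log10Span, nSamples, seed,
                               bioSdlog, responseSdlog, isAmplitude)
  runs <- lapply(seq_len(nSamples), function(s)
    simulateRun(panel, truth, s, gradient, params, drift,
                runIndex = s - 1L, seed = seed, noiseCv = noiseCv,
                floor = floor, background = background))
  list(truth = truth, runs = runs, panel = panel, gradient = gradient,
       params = params)
}
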