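# Shared fixtures, all built in code at test time.

# two-protein mini panel: fast to simulate, still exercises pairing
tinyProteins <- function() {
  c(TNFA = "VNLLSAIKELTEAGQLFSSDR",
    MMP2 = "AFQVWSDVTPLRTGDLFTAVSELGHK")
}

tinyPanel <- function() buildPanel(tinyProteins())

# noiseless, background-free settings for exact checks
cleanRun <- function(panel, truth, sample = 1L, seed = 1L, runIndex = 0L,
                     drift = driftModel(), mode = "surequant",
                     rtWindows = NULL, params = acquisitionParams(),
                     gradient = gradient100SPD()) {
  simulateRun(panel, truth, sample, gradient, params, drift, runIndex, seed,
              noiseCv = 0, floor = 0, background = backgroundModel(0),
              mode = mode, rtWindows = rtWindows)
}

# a SignalSet where only the first k transitions of each heavy peptide
# carry signal (used to probe the trigger threshold)
kIonSignals <- function(panel, k, seed = 1L) {
  truth <- generateGroundTruth(panel, 0, 1L, seed)
  profiles <- elutionProfiles(panel, gradient100SPD())
  sig <- renderSignals(truth, panel, profiles, 1L, noiseCv = 0, floor = 0,
                       background = backgroundModel(0))
  tr <- sig@transitions
  heavyIds <- sig@precursors$peptideId[sig@precursors$isHeavy]
  for (id in heavyIds) {
    rows <- which(tr$peptideId == id)
    if (length(rows) > k) tr$amplitude[rows[-seq_len(k)]] <- 0
  }
  sig@transitions <- tr
  sig
}

# exact 5PL used as immunoassay ground truth in several tests
toyCurve <- function() fivePL(a = 50, b = 1.2, c = 500, d = 30000, g = 0.8)
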