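---
title: "Simulating internal-standard-triggered PRM: models and design choices"
author: "isoPRM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating internal-standard-triggered PRM: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoPRM)
```

## The method being modelled

Internal-standard-triggered parallel reaction monitoring (IS-PRM, marketed
as SureQuant) spikes a fixed amount of stable-isotope-labelled synthetic
peptides — chemically identical to the endogenous targets but heavier by
+8.014 Da (labelled lysine) or +10.008 Da (labelled arginine) — into every
sample. The spiked peptides are abundant and always present, so the
instrument can *watch* for them cheaply: each duty cycle starts with an MS1
survey scan, and whenever a heavy precursor is seen above an intensity
threshold, a fast low-resolution MS2 ("watch" scan) checks its fragments.
Only when at least three expected product ions match does the instrument
spend a slow, sensitive, high-resolution MS2 on the endogenous peptide, at
the *offset* precursor m/z (heavy m/z minus label delta over charge).
Because the trigger follows the internal standard in real time, the method
needs no retention-time scheduling and is robust to drift — the property
this package exists to demonstrate quantitatively.

isoPRM implements the whole workflow at desk scale: panel design from
protein sequences, synthetic LC-MS signals with known ground truth, the
triggered acquisition loop (and a scheduled-PRM comparator), the
Skyline-equivalent quantification chain, performance metrics, and the
five-parameter-logistic immunoassay math used for orthogonal validation.

## Panel design

Proteins are digested in silico (cleavage after K/R; by default not before
proline) and candidates are kept only if they are 8–21 residues long,
methionine-free, end in K or R, and carry no missed cleavage — the
published quantotypic-peptide rules. The original assay then ranked
candidates by observed DDA intensity and database evidence; a desk-scale
package cannot reproduce that, so ranking uses a deterministic surrogate
(closeness of length to 12 residues plus closeness of mean Kyte–Doolittle
hydropathy to zero, ties broken lexicographically). The surrogate is *not*
a detectability predictor; it exists to make panel construction
reproducible.

Each selected peptide becomes a light/heavy precursor pair (charge 2 by
default) with five singly charged y-ion transitions, y3 upward — low
fragment indices are skipped to stay clear of the immonium-ion mass
region. The shipped nine-protein FASTA is **synthetic**: only three of the
assay's published peptide sequences are public (VNLLSAIK, IPVALGLK,
AFQVWSDVTPLR), so the stand-in proteins are concatenations of designed
tryptic peptides that carry those three plus invented companions.

## Chromatography and drift

Two gradient presets mirror the standardized LC methods: 100SPD (active
gradient 690 s, cycle 864 s, 1.5 µl/min) and 60SPD (1320 s). Retention
prediction is a documented *non-physical stand-in*: mean Kyte–Doolittle
hydropathy mapped affinely onto the central 80 % of the gradient, plus a
small deterministic dispersion term taken from the fractional part of the
peptide mass so that similar peptides still separate. It depends only on
the bare sequence, so heavy/light partners co-elute exactly, and
predictions scale exactly with gradient length.

Peaks are (bi-)Gaussian with σ = 3 s on 100SPD (≈14 s base width at 5 %
height), scaled by gradient-length ratio otherwise, truncated at ±5σ
(omitted area < 1e-5). Run-to-run instability is a linear drift per run
plus Gaussian per-run apex jitter drawn once per peptide pair, so partners
always move together; each run's jitter comes from a sub-seed of the drift
model's seed and is reproducible in isolation.

## Ground truth and signal rendering

Protein medians are placed log-uniformly (deterministically, evenly spaced
in log10) across a configurable span — 6 orders of magnitude by default,
matching the assay's demonstrated range; per-sample biological variation
is lognormal (sdlog 0.25). Each peptide carries a fixed lognormal response
factor (sdlog 0.25) standing in for ionization efficiency, so light
amplitude = concentration × response. Heavy amplitude is one constant for
every peptide and run, modelling the fixed 0.8 pmol spike; the default
(1e4 relative units) sits mid-range of the concentration ladder.

Precursor signal is split over transitions by a fixed weight vector
proportional to (5,4,3,2,1)/15. Centroids receive multiplicative lognormal
shot noise (CV 5 % by default) and scans receive Poisson background ions
(20 per MS2 scan, lognormal intensities, 5 % of them "interferents"
placed within the fragment tolerance of true transitions). Centroids below
a detection floor (0.05 relative units) are dropped — without a floor the
dynamic-range claim would be a tautology. Each stochastic concern (truth,
drift, noise, background) draws from its own derived RNG stream, so
disabling one leaves the others bit-identical.

What the generator does *not* emulate: real peptide ionization and
fragmentation physics, AGC dynamics (targets are metadata; injection times
are fixed maxima), FAIMS, chimeric precursor interference in MS1, detector
saturation, and retention prediction grounded in chemistry. Passing tests
therefore demonstrate the *logic* of triggered acquisition and
quantification, not instrument fidelity.

## The acquisition engine

Scan duration = max(injection time, orbitrap transient) + 5 ms overhead,
with the transient table {7500→16, 15000→32, 30000→64, 60000→128,
120000→256 ms}. Defaults follow the published method: MS1 at 120000 / 50
ms on a 2 s cycle; watch scans 7500 / 10 ms; quantitative scans 60000 /
250 ms; 10 ppm precursor and 20 ppm fragment tolerances; trigger at ≥3
matched product ions.

Design choices where the description leaves freedom:

* **IS detection** reads the heavy precursor straight from the MS1
  centroids (threshold: 1 % of the IS apex amplitude) rather than via a
  separate pseudo-trigger scan — the simplest faithful reading.
* **Budget policy**: a watch+quant unit is started only if it fits in the
  remaining cycle; otherwise it is deferred to the head of the next cycle,
  never dropped. MS1 is always scheduled first. This is deterministic and
  auditable; real firmware differs in unpublished ways.
* **Isolation width** defaults to 1.0 Th (the published value covers DDA
  only), enough to exclude the heavy partner at +4 Th (charge 2).
* At most one quantitative scan per peptide per cycle.
* Fragment matching is greedy-nearest: each centroid consumes at most one
  expected transition, ties to the lower index.

The scheduled-PRM comparator quantifies every light precursor whose fixed
retention-time window contains the cycle start, every cycle, signal or
not, under the same budget rules.

## Quantification chain

Traces are extracted per targeted scan by summing centroids within ±20 ppm
of each expected transition (watch scans feed heavy traces, quantitative
scans light traces). Integration boundaries automate the manual
revise-against-the-heavy-peptide step: the contiguous region of the summed
heavy trace at ≥5 % of its apex, applied unchanged to the light partner.
The apex must be supported by an adjacent elevated point so that a lone
interferent spike cannot displace it (peaks sampled on a 2 s duty cycle
always span several points); on a sampled trace the 5 % width
underestimates the continuous-time value by up to one scan spacing per
side. Areas are trapezoidal; fewer than two points integrate to zero;
undetected peptides propagate as missing, never zero.

Normalization divides each run's total fragment areas by its TIC
chromatogram area — computed from MS1 scans only, one documented reading
of "total ion current chromatogram area" — and multiplies by the median
TIC across runs, keeping values on the raw scale (a pure ratio would also
satisfy the description; the median anchor was chosen for
interpretability). Peptides are averaged into protein values; each protein
is then min-max rescaled to 0–100 across samples. A record is flagged
unreliable when fewer than three transitions integrate nonzero, echoing
the at-least-three-transitions rule; the same rule defines "detected" in
the dynamic-range metric (in ≥90 % of samples).

## Immunoassay module

The five-parameter logistic y = d + (a−d)/(1+(x/c)^b)^g is fitted by
Levenberg–Marquardt with 1/y² weighting (the standard for immunoassay
calibration; unweighted fits let the upper plateau dominate), with c on
the log axis for conditioning and a deterministic initializer. The three
published exclusion rules are applied in a fixed, documented order —
replicate CV > 10 %, then end-standard flattening (<10 % from the
neighbour, repeated until stable), then fit / recovery outside 80–120 % /
refit until stable — because the source does not state an order; at least
five standards must survive. The sample-censoring bound ("above or below
the standard curve average net MFI") is ambiguous; it is implemented as
the net-MFI range of the surviving standards, and flagged as such.
Back-calculation is the analytic 5PL inverse times the dilution factor;
out-of-range wells are censored with a side indicator, and a duplicate
whose partner is censored is kept as a flagged singleton. The plate
simulator renders 7-point 1:4 triplicate standards and duplicate samples
at 1:50 / 1:500 / 1:10000, and can mark an analyte curve-less to mirror an
analyte shipped without a reference standard. Note that with only seven
points and five parameters a lone distorted standard is often absorbed by
the refit; the recovery rule becomes discriminating on denser series.

## Numerical conventions and problem sizes

Mass constants are stored to five decimals and compared at three (the
printed precision); the heavy-label deltas are *derived* from the 13C/15N
isotope masses rather than stored. Apex retention times are argmax of the
sampled heavy trace with no sub-scan interpolation, so reported RT SDs
include a quantization component of about cycle/√12 ≈ 0.6 s. The package's
own validation uses one 365-run stress sequence with 5 s jitter for RT
stability, single runs for points-per-peak and window checks, and
42-sample studies for recovery and dynamic-range properties — sizes chosen
to match the figures being reproduced while remaining desk-scale.

## Known limitations

The simulator shares no calibration with any real instrument: absolute
concentrations (e.g. wound-exudate µg/ml values), FAIMS behaviour and
patient biology are out of reach by design, and the retention model is
ordinal rather than physical. Conclusions supported here are comparative
and structural: trigger logic, scheduling robustness under drift, the
arithmetic of the quantification chain, and the calibration rules.

```{r quick-demo, eval = FALSE}
panel <- defaultPanel()
truth <- generateGroundTruth(panel, log10Span = 6, nSamples = 1, seed = 1)
run <- simulateRun(panel, truth, 1, seed = 1)
quant <- quantifyRun(run, panel)
pointsPerPeak(run, quant)[c("meanPoints", "maxWindow")]
```
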