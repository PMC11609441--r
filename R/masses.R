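# Monoisotopic mass arithmetic for peptides, fragments and isotope labels.
# Constants are stored to 5 decimals; printed-precision comparisons are
# made at 3 decimals.

.MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931
)

.WATER  <- 18.01056
.PROTON <- 1.00728

# isotope masses used to derive the heavy-label deltas
.C12 <- 12.00000
.C13 <- 13.00335
.N14 <- 14.00307
.N15 <- 15.00011

#' Monoisotopic residue masses
#'
#' Standard monoisotopic masses (Da) of the 20 amino-acid residues.
#'
#' @return Named numeric vector, one entry per one-letter residue code.
#' @export
residueMasses <- function() .MONO

#' Mass constants and modification deltas
#'
#' Water and proton masses plus the fixed-modification deltas used
#' throughout: carbamidomethyl-Cys (+57.021 Da, from elemental C2H3NO),
#' oxidation (+15.995 Da), and the heavy labels. The heavy-Lys and
#' heavy-Arg deltas are derived from the isotope substitutions
#' (6 x 13C + 2 x 15N for Lys, +8.014 Da; 6 x 13C + 4 x 15N for Arg,
#' +10.008 Da) rather than stored literally.
#'
#' @return Named list with elements `water`, `proton`, `carbamidomethyl`,
#'   `oxidation`, `heavyK`, `heavyR`.
#' @examples
#' massConstants()$heavyK  # 8.014 to printed precision
#' @export
massConstants <- function() {
  dC <- .C13 - .C12
  dN <- .N15 - .N14
  list(
    water  = .WATER,
    proton = .PROTON,
    # C2H3NO on cysteine; hydrogen 1.00783, nitrogen 14.00307, oxygen 15.99491
    carbamidomethyl = 2 * .C12 + 3 * 1.00783 + .N14 + 15.99491,
    oxidation = 15.99491,
    heavyK = 6 * dC + 2 * dN,
    heavyR = 6 * dC + 4 * dN
  )
}

#' Heavy-label mass delta for a peptide
#'
#' The stable-isotope label delta carried by the C-terminal residue of a
#' tryptic peptide: +8.014 Da for lysine, +10.008 Da for arginine.
#'
#' @param sequence Peptide sequence ending in K or R.
#' @return Label delta in Da.
#' @export
labelDelta <- function(sequence) {
  cterm <- substring(sequence, nchar(sequence), nchar(sequence))
  k <- massConstants()
  if (cterm == "K") return(k$heavyK)
  if (cterm == "R") return(k$heavyR)
  stop("peptide '", sequence, "' does not end in K or R; no heavy label defined")
}

.checkResidues <- function(sequence) {
  aa <- strsplit(sequence, "")[[1]]
  bad <- which(!aa %in% names(.MONO))
  if (length(bad))
    stop("non-standard residue '", aa[bad[1]], "' at position ", bad[1],
         " in '", sequence, "'")
  aa
}

#' Per-residue fixed-modification deltas
#'
#' Builds the per-residue delta vector for a peptide: carbamidomethyl on
#' every cysteine (fixed, on by default as in standard alkylation
#' workflows) and, for heavy internal standards, the isotope label on the
#' C-terminal K/R.
#'
#' @param sequence Peptide sequence.
#' @param heavy Apply the C-terminal heavy label?
#' @param carbamidomethyl Apply +57.021 to every C?
#' @return Numeric vector of deltas, one per residue (0 where unmodified).
#' @export
peptideMods <- function(sequence, heavy = FALSE, carbamidomethyl = TRUE) {
  aa <- .checkResidues(sequence)
  k <- massConstants()
  mods <- numeric(length(aa))
  if (carbamidomethyl) mods[aa == "C"] <- k$carbamidomethyl
  if (heavy) mods[length(aa)] <- mods[length(aa)] + labelDelta(sequence)
  mods
}

#' Monoisotopic peptide mass
#'
#' Sum of residue masses, per-residue modification deltas, and one water.
#'
#' @param sequence Peptide sequence (20 standard one-letter codes).
#' @param mods Optional numeric vector of per-residue modification deltas;
#'   either length 0 (none) or one entry per residue.
#' @return Monoisotopic mass in Da.
#' @export
peptideMass <- function(sequence, mods = numeric()) {
  aa <- .checkResidues(sequence)
  if (length(mods) && length(mods) != length(aa))
    stop("mods must be empty or one delta per residue")
  sum(.MONO[aa]) + sum(mods) + .WATER
}

#' Precursor m/z from neutral mass and charge
#'
#' @param mass Neutral monoisotopic mass (Da).
#' @param charge Positive integer charge.
#' @return m/z in Th: (mass + charge * proton) / charge.
#' @export
precursorMz <- function(mass, charge) {
  if (any(charge < 1)) stop("charge must be >= 1")
  (mass + charge * .PROTON) / charge
}

#' Fragment ion m/z (b/y series)
#'
#' Monoisotopic m/z of a b- or y-series fragment, including any
#' per-residue modifications on the covered residues. b ions cover the
#' N-terminal `index` residues (mass = sum residues + charge protons);
#' y ions cover the C-terminal `index` residues (mass = sum residues +
#' water + charge protons).
#'
#' @param sequence Peptide sequence.
#' @param ionType "b" or "y".
#' @param index Fragment ordinal, 1 <= index <= nchar(sequence) - 1.
#' @param charge Fragment charge (default 1).
#' @param mods Per-residue modification deltas (see [peptideMods()]).
#' @return m/z in Th.
#' @export
fragmentMz <- function(sequence, ionType, index, charge = 1, mods = numeric()) {
  aa <- .checkResidues(sequence)
  n <- length(aa)
  if (length(mods) == 0) mods <- numeric(n)
  if (length(mods) != n) stop("mods must be empty or one delta per residue")
  if (index < 1 || index > n - 1)
    stop("fragment index ", index, " out of range for length-", n, " peptide")
  if (!ionType %in% c("b", "y")) stop("ionType must be 'b' or 'y'")
  idx <- if (ionType == "b") seq_len(index) else seq.int(n - index + 1, n)
  frag <- sum(.MONO[aa[idx]]) + sum(mods[idx])
  if (ionType == "y") frag <- frag + .WATER
  (frag + charge * .PROTON) / charge
}

#' Offset (endogenous) precursor m/z from a heavy precursor
#'
#' The quantitative scan of the triggered acquisition is placed at the
#' heavy precursor m/z minus the label delta divided by the charge.
#'
#' @param heavyMz Heavy precursor m/z (Th).
#' @param delta Label mass delta (Da), e.g. `massConstants()$heavyK`.
#' @param charge Precursor charge.
#' @return Light-precursor m/z in Th.
#' @export
offsetMz <- function(heavyMz, delta, charge) {
  if (any(charge < 1)) stop("charge must be >= 1")
  heavyMz - delta / charge
}
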