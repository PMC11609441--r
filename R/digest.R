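# In-silico tryptic digestion and panel candidate filtering.

#' Tryptic digestion of a protein sequence
#'
#' Cleaves after every K or R. With `prolineRule = TRUE` (default,
#' matching common trypsin practice) a K/R immediately followed by
#' proline is not cleaved. The products partition the input in order.
#'
#' @param sequence Protein sequence over the 20 standard residue letters.
#' @param prolineRule Suppress cleavage before proline?
#' @return Character vector of peptide sequences whose concatenation
#'   equals the input.
#' @examples
#' digestSequence("AKRG", prolineRule = FALSE)  # "AK" "R" "G"
#' digestSequence("AKPR")                        # "AKPR"
#' @export
digestSequence <- function(sequence, prolineRule = TRUE) {
  aa <- .checkResidues(sequence)
  n <- length(aa)
  if (n == 0L) return(character())
  cut <- which(aa %in% c("K", "R"))
  cut <- cut[cut < n]
  if (prolineRule && length(cut)) cut <- cut[aa[cut + 1L] != "P"]
  starts <- c(1L, cut + 1L)
  ends <- c(cut, n)
  vapply(seq_along(starts),
         function(i) paste(aa[starts[i]:ends[i]], collapse = ""),
         character(1))
}

#' Filter digestion products against the panel-design rules
#'
#' A candidate is accepted iff it is 8-21 residues long, contains no
#' methionine, ends in K or R, and carries zero missed cleavages (no
#' internal K/R except immediately before a proline). Every failed rule
#' is reported per peptide.
#'
#' @param peptides Character vector of peptide sequences (typically
#'   digestion products).
#' @return data.frame with columns `peptide`, `accepted` (logical) and
#'   `reasons` (semicolon-joined failure descriptions, "" if accepted),
#'   in input order. The function is idempotent on its accepted subset.
#' @export
filterCandidates <- function(peptides) {
  res <- lapply(peptides, function(p) {
    aa <- .checkResidues(p)
    n <- length(aa)
    reasons <- character()
    if (n < 8 || n > 21)
      reasons <- c(reasons, sprintf("length %d outside [8,21]", n))
    if ("M" %in% aa)
      reasons <- c(reasons, "contains methionine")
    if (!aa[n] %in% c("K", "R"))
      reasons <- c(reasons, "C-terminal residue not K/R")
    internal <- which(aa[-n] %in% c("K", "R"))
    missed <- internal[aa[internal + 1L] != "P"]
    if (length(missed))
      reasons <- c(reasons, sprintf("%d missed cleavage(s)", length(missed)))
    data.frame(peptide = p, accepted = length(reasons) == 0L,
               reasons = paste(reasons, collapse = "; "))
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Deterministic surrogate score for peptide candidate ranking
#'
#' The original assay ranked candidates by observed DDA intensity and
#' database evidence; this package replaces that with a reproducible
#' surrogate: closeness of length to 12 residues plus closeness of the
#' mean Kyte-Doolittle hydropathy to mid-range. Higher is better; ties
#' are broken lexicographically by the caller.
#'
#' @param sequence Peptide sequence.
#' @return Numeric score (higher = preferred).
#' @export
candidateScore <- function(sequence) {
  aa <- .checkResidues(sequence)
  -abs(length(aa) - 12) - abs(mean(.KYTE_DOOLITTLE[aa]))
}

.KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)
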