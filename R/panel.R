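# TransitionPanel: the targeted assay definition (heavy/light precursor
# pairs with their transition lists), plus construction from protein
# sequences and Skyline-flavoured CSV I/O.

#' TransitionPanel class
#'
#' Holds a targeted assay panel: one row per precursor (heavy/light pair
#' members are separate precursors sharing a `targetId`) in `@peptides`,
#' and one row per transition in `@transitions`.
#'
#' `@peptides` columns: `peptideId` (unique, `<sequence>/<charge>/<label>`),
#' `targetId` (`<sequence>/<charge>`, shared by a heavy/light pair),
#' `proteinId`, `sequence`, `charge`, `isHeavy`, `precursorMz`,
#' `labelDelta`.
#'
#' `@transitions` columns: `peptideId`, `ionType` ("b"/"y"),
#' `fragmentIndex`, `fragmentCharge`, `mz`.
#'
#' Validity requires every light precursor to have exactly one heavy
#' partner with identical sequence and charge, and every precursor to
#' carry at least three transitions.
#'
#' @slot peptides data.frame of precursors.
#' @slot transitions data.frame of transitions.
#' @export
setClass("TransitionPanel",
         representation(peptides = "data.frame", transitions = "data.frame"))

setValidity("TransitionPanel", function(object) {
  p <- object@peptides
  tr <- object@transitions
  need <- c("peptideId", "targetId", "proteinId", "sequence", "charge",
            "isHeavy", "precursorMz", "labelDelta")
  if (!all(need %in% names(p)))
    return(paste("missing peptide columns:",
                 paste(setdiff(need, names(p)), collapse = ", ")))
  if (anyDuplicated(p$peptideId)) return("duplicate peptideId")
  light <- p[!p$isHeavy, ]
  heavy <- p[p$isHeavy, ]
  if (!setequal(light$targetId, heavy$targetId) ||
      nrow(light) != nrow(heavy))
    return("every light precursor needs exactly one heavy partner")
  cnt <- table(factor(tr$peptideId, levels = p$peptideId))
  if (any(cnt < 3))
    return(paste("precursor(s) with fewer than 3 transitions:",
                 paste(names(cnt)[cnt < 3], collapse = ", ")))
  if (any(tr$mz <= 0) || any(p$precursorMz <= 0)) return("non-positive m/z")
  TRUE
})

#' @describeIn TransitionPanel precursor table accessor
#' @param panel A `TransitionPanel`.
#' @export
panelPeptides <- function(panel) panel@peptides

#' @describeIn TransitionPanel transition table accessor
#' @export
panelTransitions <- function(panel) panel@transitions

#' @describeIn TransitionPanel proteins represented in the panel
#' @export
panelProteins <- function(panel) sort(unique(panel@peptides$proteinId))

setMethod("show", "TransitionPanel", function(object) {
  p <- object@peptides
  cat("TransitionPanel:", length(unique(p$proteinId)), "proteins,",
      sum(!p$isHeavy), "light +", sum(p$isHeavy), "heavy precursors,",
      nrow(object@transitions), "transitions\n")
  cat("  peptides:", paste(head(unique(p$sequence), 6), collapse = ", "),
      if (length(unique(p$sequence)) > 6) "..." else "", "\n")
})

.peptideId <- function(sequence, charge, heavy)
  sprintf("%s/%d/%s", sequence, charge, ifelse(heavy, "heavy", "light"))

.makePrecursor <- function(sequence, charge, heavy, proteinId,
                           nTransitions = 5L) {
  mods <- peptideMods(sequence, heavy = heavy)
  mz <- precursorMz(peptideMass(sequence, mods), charge)
  idx <- seq.int(3L, 3L + nTransitions - 1L)
  pep <- data.frame(
    peptideId = .peptideId(sequence, charge, heavy),
    targetId = sprintf("%s/%d", sequence, charge),
    proteinId = proteinId, sequence = sequence, charge = charge,
    isHeavy = heavy, precursorMz = mz, labelDelta = labelDelta(sequence))
  tr <- data.frame(
    peptideId = pep$peptideId, ionType = "y", fragmentIndex = idx,
    fragmentCharge = 1L,
    mz = vapply(idx, function(i) fragmentMz(sequence, "y", i, 1L, mods),
                numeric(1)))
  list(peptide = pep, transitions = tr)
}

#' Build a targeted panel from protein sequences
#'
#' Digests each protein in silico, filters candidates by the panel-design
#' rules (see [filterCandidates()]), ranks survivors by the deterministic
#' surrogate score (ties broken lexicographically), keeps the top
#' `peptidesPerProtein`, and emits a heavy/light precursor pair per
#' peptide with `transitionsPerPeptide` singly charged y-ion transitions
#' starting at y3 (low fragment indices are skipped to avoid the
#' immonium-mass region).
#'
#' @param proteins Named character vector of protein sequences, or an
#'   `AAStringSet`.
#' @param peptidesPerProtein Peptides selected per protein (default 2).
#' @param transitionsPerPeptide Transitions per precursor (default 5).
#' @param charge Precursor charge state (default 2).
#' @param prolineRule Passed to [digestSequence()].
#' @return A [TransitionPanel-class].
#' @export
buildPanel <- function(proteins, peptidesPerProtein = 2L,
                       transitionsPerPeptide = 5L, charge = 2L,
                       prolineRule = TRUE) {
  if (is(proteins, "AAStringSet"))
    proteins <- setNames(as.character(proteins), names(proteins))
  if (is.null(names(proteins)) || any(names(proteins) == ""))
    stop("protein sequences must be named")
  sel <- lapply(names(proteins), function(id) {
    cand <- filterCandidates(digestSequence(proteins[[id]], prolineRule))
    acc <- cand$peptide[cand$accepted]
    acc <- unique(acc)
    if (length(acc) < peptidesPerProtein)
      stop("protein '", id, "' yields only ", length(acc),
           " accepted candidate(s); need ", peptidesPerProtein)
    sc <- vapply(acc, candidateScore, numeric(1))
    acc[order(-sc, acc)][seq_len(peptidesPerProtein)]
  })
  names(sel) <- names(proteins)
  flat <- unlist(sel, use.names = FALSE)
  dup <- unique(flat[duplicated(flat)])
  if (length(dup)) {
    warning("peptide(s) shared by multiple proteins excluded: ",
            paste(dup, collapse = ", "))
    sel <- lapply(sel, setdiff, y = dup)
  }
  parts <- list()
  for (id in names(sel)) {
    for (pep in sel[[id]]) {
      for (hv in c(FALSE, TRUE)) {
        parts[[length(parts) + 1L]] <-
          .makePrecursor(pep, charge, hv, id, transitionsPerPeptide)
      }
    }
  }
  new("TransitionPanel",
      peptides = do.call(rbind, c(lapply(parts, `[[`, "peptide"),
                                  list(make.row.names = FALSE))),
      transitions = do.call(rbind, c(lapply(parts, `[[`, "transitions"),
                                     list(make.row.names = FALSE))))
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file (multi-record, wrapped lines supported).
#' @return Named character vector of sequences.
#' @export
readProteinFasta <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  setNames(as.character(aas), sub("\\s.*$", "", names(aas)))
}

#' The default nine-protein synthetic demonstration panel
#'
#' Builds the shipped panel: nine wound-biomarker proteins (MMP2, MMP9,
#' neutrophil elastase, IL1B, TNFA, S100A8, S100A9, COL1A1, FN1)
#' represented by synthetic stand-in sequences that carry the three
#' published quantotypic peptides (VNLLSAIK, IPVALGLK, AFQVWSDVTPLR)
#' plus designed tryptic stand-ins; 2 peptides per protein, heavy+light,
#' 5 transitions each.
#'
#' @return A [TransitionPanel-class] with 18 light + 18 heavy precursors.
#' @export
defaultPanel <- function() {
  fa <- system.file("extdata", "synthetic_panel_proteins.fasta",
                    package = "isoPRM", mustWork = TRUE)
  buildPanel(readProteinFasta(fa))
}

.PANEL_COLS <- c("ProteinName", "PeptideSequence", "PrecursorCharge",
                 "IsotopeLabelType", "PrecursorMz", "FragmentIon",
                 "FragmentCharge", "ProductMz")

#' Write a panel to a Skyline-flavoured transition-list CSV
#'
#' One row per transition with columns ProteinName, PeptideSequence,
#' PrecursorCharge, IsotopeLabelType (light/heavy), PrecursorMz,
#' FragmentIon (e.g. "y5"), FragmentCharge, ProductMz. UTF-8, header
#' mandatory; m/z written at 6 decimals. Deterministic: identical panels
#' produce byte-identical files.
#'
#' @param panel A `TransitionPanel`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writePanelCsv <- function(panel, path) {
  p <- panel@peptides
  tr <- panel@transitions
  m <- match(tr$peptideId, p$peptideId)
  out <- data.frame(
    ProteinName = p$proteinId[m],
    PeptideSequence = p$sequence[m],
    PrecursorCharge = p$charge[m],
    IsotopeLabelType = ifelse(p$isHeavy[m], "heavy", "light"),
    PrecursorMz = sprintf("%.6f", p$precursorMz[m]),
    FragmentIon = paste0(tr$ionType, tr$fragmentIndex),
    FragmentCharge = tr$fragmentCharge,
    ProductMz = sprintf("%.6f", tr$mz))
  out <- out[order(out$ProteinName, out$PeptideSequence, out$IsotopeLabelType,
                   out$FragmentIon), ]
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a transition-list CSV back into a TransitionPanel
#'
#' Inverse of [writePanelCsv()]. Malformed rows are reported with their
#' line number; a header-only or empty file is a "no targets" error; the
#' at-least-three-transitions rule is enforced by class validity.
#'
#' @param path CSV path.
#' @return A [TransitionPanel-class].
#' @export
readPanelCsv <- function(path) {
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse '", path, "': ",
                                          conditionMessage(e)))
  miss <- setdiff(.PANEL_COLS, names(df))
  if (length(miss))
    stop("missing column(s) in '", path, "': ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("no targets: '", path, "' contains no rows")
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    ok <- nzchar(r$PeptideSequence) && !is.na(r$PrecursorCharge) &&
      r$IsotopeLabelType %in% c("light", "heavy") &&
      grepl("^[by][0-9]+$", r$FragmentIon) && !is.na(r$ProductMz) &&
      !is.na(r$PrecursorMz)
    if (!ok) stop("malformed row at line ", i + 1L, " of '", path, "'")
  }
  key <- .peptideId(df$PeptideSequence, df$PrecursorCharge,
                    df$IsotopeLabelType == "heavy")
  first <- !duplicated(key)
  peps <- data.frame(
    peptideId = key[first],
    targetId = sprintf("%s/%d", df$PeptideSequence[first],
                       df$PrecursorCharge[first]),
    proteinId = df$ProteinName[first],
    sequence = df$PeptideSequence[first],
    charge = as.integer(df$PrecursorCharge[first]),
    isHeavy = df$IsotopeLabelType[first] == "heavy",
    precursorMz = as.numeric(df$PrecursorMz[first]),
    labelDelta = vapply(df$PeptideSequence[first], labelDelta, numeric(1),
                        USE.NAMES = FALSE))
  trs <- data.frame(
    peptideId = key,
    ionType = substring(df$FragmentIon, 1, 1),
    fragmentIndex = as.integer(substring(df$FragmentIon, 2)),
    fragmentCharge = as.integer(df$FragmentCharge),
    mz = as.numeric(df$ProductMz))
  new("TransitionPanel", peptides = peps, transitions = trs)
}
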