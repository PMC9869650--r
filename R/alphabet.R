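#' The canonical 20-letter amino-acid alphabet
#'
#' All prediction matrices, confusion matrices and per-class metric tables in
#' this package are ordered by this fixed alphabet.
#'
#' @return Character vector of the 20 one-letter amino-acid codes in the
#'   canonical order \code{ACDEFGHIKLMNPQRSTVWY}.
#' @examples
#' aminoAcids()
#' @export
aminoAcids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Marker used for residues whose identity could not be canonicalized
#' @return The single character \code{"X"}.
#' @export
unknownResidue <- function() "X"

# standard 20 three-letter codes
.aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

# common non-canonical residues mapped to a canonical parent. Covers the
# modified residues routinely seen in crystal structures (selenomethionine,
# phospho/methyl variants, alternate histidine protonation names).
.aaSubstitutions <- c(
  MSE = "M",  # selenomethionine
  SEC = "C",  # selenocysteine (U)
  PYL = "K",  # pyrrolysine (O)
  HSD = "H", HSE = "H", HSP = "H", HIE = "H", HID = "H", HIP = "H",
  CSO = "C", CSD = "C", CME = "C", OCS = "C", CSS = "C",
  SEP = "S", TPO = "T", PTR = "Y",  # phosphoserine/-threonine/-tyrosine
  MLY = "K", M3L = "K", KCX = "K", LLP = "K",
  HYP = "P",  # hydroxyproline
  FME = "M",  # N-formylmethionine
  PCA = "E",  # pyroglutamate
  SAR = "G", AIB = "A", ABA = "A",
  MLE = "L", NLE = "L", MVA = "V", IIL = "I"
)

#' Canonicalize a three-letter residue code
#'
#' Maps the standard 20 three-letter codes to their one-letter symbol and a
#' shipped table of common non-canonical residues to their canonical parent
#' (e.g. \code{MSE} to \code{M}, \code{SEC} to \code{C}, \code{PYL} to
#' \code{K}). Codes absent from both tables return the unknown marker.
#' Total function: never errors. One-letter codes already in the alphabet
#' (or the unknown marker) pass through unchanged, so the function is
#' idempotent over its own output.
#'
#' @param aa3 Character vector of uppercase residue codes.
#' @return Character vector of one-letter codes, \code{unknownResidue()} where
#'   no mapping exists.
#' @examples
#' canonicalizeResidue(c("ALA", "MSE", "XYZ"))
#' @export
canonicalizeResidue <- function(aa3) {
  aa3 <- toupper(as.character(aa3))
  out <- .aa3to1[aa3]
  sub <- is.na(out)
  out[sub] <- .aaSubstitutions[aa3[sub]]
  # idempotence: accept already-canonical one-letter input
  passthrough <- is.na(out) & aa3 %in% c(aminoAcids(), unknownResidue())
  out[passthrough] <- aa3[passthrough]
  out[is.na(out)] <- unknownResidue()
  unname(out)
}

# BLOSUM62 restricted to the canonical alphabet, loaded once from Biostrings.
.blosumEnv <- new.env(parent = emptyenv())

#' Substitution-similarity matrix used by the similarity metric
#'
#' BLOSUM62 log-odds scores restricted to the canonical 20-letter alphabet.
#' Two residues are counted as "similar" when their score is strictly
#' positive, i.e. the substitution occurs more often in nature than expected
#' by chance; identity is always similar.
#'
#' @return A 20 x 20 integer matrix with \code{aminoAcids()} dimnames.
#' @export
similarityMatrix <- function() {
  if (is.null(.blosumEnv$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    aa <- aminoAcids()
    .blosumEnv$m <- e$BLOSUM62[aa, aa]
  }
  .blosumEnv$m
}
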