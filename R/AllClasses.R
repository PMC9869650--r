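#' @import methods
NULL

#' BackboneStructure: one protein chain's backbone
#'
#' Ordered residues of a single chain with backbone heavy-atom coordinates
#' (N, CA, C, O), the native amino acid of each position, and the crystal
#' resolution when the header carried one. Coordinates are in Angstrom and
#' residue numbering is author numbering (insertion codes appended).
#'
#' @slot chainKey Identifier of the form \code{"PDBID_CHAIN"}.
#' @slot seqIds Author residue numbers (with insertion code) as character.
#' @slot aaTrue One-letter native amino acid per residue; \code{"X"} when
#'   canonicalization failed.
#' @slot coords Numeric array \code{n x 4 x 3}; second dimension named
#'   \code{N, CA, C, O}; \code{NA} for missing atoms.
#' @slot complete Logical per residue: all four backbone atoms present.
#' @slot resolution Resolution in Angstrom, or \code{numeric(0)} when absent.
#' @exportClass BackboneStructure
setClass("BackboneStructure",
  representation(
    chainKey = "character",
    seqIds = "character",
    aaTrue = "character",
    coords = "array",
    complete = "logical",
    resolution = "numeric"
  )
)

setValidity("BackboneStructure", function(object) {
  n <- length(object@seqIds)
  msgs <- character(0)
  if (length(object@chainKey) != 1L || !nzchar(object@chainKey))
    msgs <- c(msgs, "chainKey must be a single non-empty string")
  if (length(object@aaTrue) != n || length(object@complete) != n)
    msgs <- c(msgs, "aaTrue/complete lengths must match seqIds")
  d <- dim(object@coords)
  if (length(d) != 3L || d[1] != n || d[2] != 4L || d[3] != 3L)
    msgs <- c(msgs, "coords must be an n x 4 x 3 array")
  else if (!identical(dimnames(object@coords)[[2]], c("N", "CA", "C", "O")))
    msgs <- c(msgs, "coords atom dimension must be named N, CA, C, O")
  else if (n > 0 && any(object@complete &
                        apply(object@coords, 1L, function(m) any(!is.finite(m)))))
    msgs <- c(msgs, "residues flagged complete must have finite coordinates")
  if (length(object@resolution) > 1L ||
      (length(object@resolution) == 1L &&
       (!is.finite(object@resolution) || object@resolution <= 0)))
    msgs <- c(msgs, "resolution must be absent (numeric(0)) or a single value > 0")
  if (!all(object@aaTrue %in% c(aminoAcids(), unknownResidue())))
    msgs <- c(msgs, "aaTrue entries must be canonical letters or the unknown marker")
  if (length(msgs)) msgs else TRUE
})

#' PredictionSet: one model's per-residue probability rows
#'
#' Row i is the predicted probability distribution over the 20-letter
#' alphabet for the i-th scored residue of its chain; rows belonging to one
#' chain are contiguous and in structure order.
#'
#' @slot modelName Name of the design method that produced the rows.
#' @slot probs Numeric matrix \code{n x 20}, columns in alphabet order; every
#'   row non-negative and summing to 1 within 1e-6.
#' @slot chainKeys Character vector of length n: the chain of each row.
#' @slot positions Integer bookkeeping positions from the input file.
#' @exportClass PredictionSet
setClass("PredictionSet",
  representation(
    modelName = "character",
    probs = "matrix",
    chainKeys = "character",
    positions = "integer"
  )
)

setValidity("PredictionSet", function(object) {
  msgs <- character(0)
  p <- object@probs
  n <- nrow(p)
  if (length(object@modelName) != 1L || !nzchar(object@modelName))
    msgs <- c(msgs, "modelName must be a single non-empty string")
  if (ncol(p) != 20L || !identical(colnames(p), aminoAcids()))
    msgs <- c(msgs, "probs must have 20 columns named by the canonical alphabet")
  if (length(object@chainKeys) != n || length(object@positions) != n)
    msgs <- c(msgs, "chainKeys/positions must have one entry per probability row")
  if (n > 0) {
    if (any(p < 0)) msgs <- c(msgs, "probabilities must be non-negative")
    if (any(abs(rowSums(p) - 1) > 1e-6))
      msgs <- c(msgs, "every probability row must sum to 1 within 1e-6")
    r <- rle(object@chainKeys)
    if (anyDuplicated(r$values))
      msgs <- c(msgs, "rows of one chain must be contiguous")
  }
  if (length(msgs)) msgs else TRUE
})

#' DatasetMap: manifest of chains, CATH architectures and structure files
#'
#' @slot entries \code{data.frame} with columns \code{chainKey},
#'   \code{architecture} (CATH C.A code), \code{foldClass} (one of
#'   mainly-alpha, mainly-beta, alpha-beta, special) and
#'   \code{structurePath}.
#' @exportClass DatasetMap
setClass("DatasetMap", representation(entries = "data.frame"))

.foldClasses <- c("mainly-alpha", "mainly-beta", "alpha-beta", "special")

setValidity("DatasetMap", function(object) {
  e <- object@entries
  msgs <- character(0)
  need <- c("chainKey", "architecture", "foldClass", "structurePath")
  if (!all(need %in% names(e)))
    msgs <- c(msgs, paste("entries must have columns:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(e$chainKey)) msgs <- c(msgs, "chainKey entries must be unique")
    if (!all(e$foldClass %in% .foldClasses))
      msgs <- c(msgs, "foldClass must be mainly-alpha/mainly-beta/alpha-beta/special")
    if (!all(grepl("^[0-9]\\.[0-9]+$", e$architecture)))
      msgs <- c(msgs, "architecture codes must match digit.digits (CATH C.A)")
  }
  if (length(msgs)) msgs else TRUE
})

#' ModelReport: the full stratified metric report for one model
#'
#' @slot modelName Model identifier.
#' @slot perClass Per-amino-acid metric table (recall, precision, f1, auc,
#'   entropy_bits, bias, n_true, n_pred).
#' @slot global One-row \code{data.frame} of group metrics over all scored
#'   residues.
#' @slot byChain,bySS,byFoldClass,byArchitecture Stratified group-metric
#'   tables (one row per stratum).
#' @slot confusion 20 x 20 true-by-predicted count matrix.
#' @slot resolutionR Pearson correlation of per-chain accuracy with
#'   resolution, or \code{numeric(0)} when undefined.
#' @slot exclusions Per-chain counts of residues excluded from scoring.
#' @slot scoredKeys \code{"chainKey:seqId"} identifiers of the scored
#'   residues, used to enforce identical evaluation sets across models.
#' @exportClass ModelReport
setClass("ModelReport",
  representation(
    modelName = "character",
    perClass = "data.frame",
    global = "data.frame",
    byChain = "data.frame",
    bySS = "data.frame",
    byFoldClass = "data.frame",
    byArchitecture = "data.frame",
    confusion = "matrix",
    resolutionR = "numeric",
    exclusions = "data.frame",
    scoredKeys = "character"
  )
)

setValidity("ModelReport", function(object) {
  msgs <- character(0)
  cm <- object@confusion
  if (!identical(dim(cm), c(20L, 20L)))
    msgs <- c(msgs, "confusion must be 20 x 20")
  if (sum(cm) != length(object@scoredKeys))
    msgs <- c(msgs, "confusion total must equal the number of scored residues")
  nGlobal <- object@global$n_residues
  for (nm in c("byChain", "bySS", "byFoldClass", "byArchitecture")) {
    tab <- slot(object, nm)
    if (nrow(tab) && sum(tab$n_residues) != nGlobal)
      msgs <- c(msgs, sprintf("%s residue counts must sum to the global count", nm))
  }
  if (length(msgs)) msgs else TRUE
})
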