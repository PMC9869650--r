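#' Assemble the scored-residue table
#'
#' Joins a chain's canonicalized residues with a model's probability rows and
#' the stratification labels into the flat table every metric operates on.
#' Rarely called directly; \code{\link{buildModelReport}} drives it. Rows are
#' one scored residue each; \code{probs} is a 20-column matrix column.
#'
#' @param aaTrue True one-letter codes.
#' @param probs \code{n x 20} probability matrix, alphabet-ordered columns.
#' @param chainKey,ss,foldClass,architecture,resolution Per-residue labels
#'   (recycled if length 1); \code{resolution} may be \code{NA}.
#' @param seqId Per-residue identifiers (default running index).
#' @return \code{data.frame} with columns \code{chainKey}, \code{seqId},
#'   \code{aaTrue}, \code{pred} (argmax letter, alphabet-order ties),
#'   \code{ss}, \code{foldClass}, \code{architecture}, \code{resolution} and
#'   the matrix column \code{probs}.
#' @export
scoredResidues <- function(aaTrue, probs, chainKey = "chain", ss = "C",
                           foldClass = "special", architecture = "6.10",
                           resolution = NA_real_, seqId = NULL) {
  n <- length(aaTrue)
  stopifnot(nrow(probs) == n, ncol(probs) == 20L)
  if (!all(aaTrue %in% aminoAcids()))
    stop("aaTrue must contain only canonical letters")
  if (is.null(colnames(probs))) colnames(probs) <- aminoAcids()
  if (is.null(seqId)) seqId <- as.character(seq_len(n))
  df <- data.frame(chainKey = rep_len(chainKey, n),
                   seqId = as.character(seqId),
                   aaTrue = aaTrue,
                   pred = predictedLetters(probs),
                   ss = rep_len(ss, n),
                   foldClass = rep_len(foldClass, n),
                   architecture = rep_len(architecture, n),
                   resolution = rep_len(resolution, n),
                   stringsAsFactors = FALSE)
  df$probs <- probs
  df
}

#' Argmax letter of each probability row (ties broken by alphabet order)
#' @param probs \code{n x 20} matrix with alphabet-ordered columns.
#' @return Character vector of predicted one-letter codes.
#' @export
predictedLetters <- function(probs) {
  aminoAcids()[max.col(probs, ties.method = "first")]
}

#' Build the 20 x 20 confusion matrix
#'
#' Entry (a, b) counts scored residues whose true amino acid is a and whose
#' argmax prediction is b; rows are truth, columns prediction, both in
#' canonical alphabet order. The total equals the number of scored residues.
#'
#' @param scored Table from \code{\link{scoredResidues}}.
#' @return Integer matrix with \code{aminoAcids()} dimnames.
#' @export
buildConfusion <- function(scored) {
  if (!nrow(scored)) stop("cannot build a confusion matrix from zero residues")
  aa <- aminoAcids()
  m <- table(factor(scored$aaTrue, levels = aa),
             factor(scored$pred, levels = aa))
  m <- unclass(m)
  dimnames(m) <- list(aa, aa)
  storage.mode(m) <- "integer"
  m
}

#' Per-amino-acid metrics
#'
#' For each of the 20 classes: recall, precision and F1 from the confusion
#' matrix; one-vs-rest ROC AUC using the class's predicted probability as
#' score (Mann-Whitney midrank form, so probability ties contribute 1/2);
#' Shannon entropy (bits) of the row-normalized confusion distribution of the
#' class; and prediction bias
#' \code{(n_predicted - n_true) / n_true} (0 calibrated, -1 never predicted).
#' Metrics with a zero denominator (class absent from truth or never
#' predicted, or AUC with no positives/negatives) are \code{NA}.
#'
#' @param scored Table from \code{\link{scoredResidues}}.
#' @param cm Optional confusion matrix built from the same rows.
#' @return \code{data.frame}, one row per letter: \code{aa}, \code{n_true},
#'   \code{n_pred}, \code{recall}, \code{precision}, \code{f1}, \code{auc},
#'   \code{entropy_bits}, \code{bias}.
#' @export
perClassMetrics <- function(scored, cm = NULL) {
  if (is.null(cm)) cm <- buildConfusion(scored)
  aa <- aminoAcids()
  nTrue <- rowSums(cm); nPred <- colSums(cm)
  recall <- ifelse(nTrue > 0, diag(cm) / nTrue, NA_real_)
  precision <- ifelse(nPred > 0, diag(cm) / nPred, NA_real_)
  f1 <- ifelse(!is.na(recall) & !is.na(precision) & (recall + precision) > 0,
               2 * recall * precision / (recall + precision), NA_real_)
  entropy <- vapply(seq_along(aa), function(i) {
    if (nTrue[i] == 0) return(NA_real_)
    q <- cm[i, ] / nTrue[i]
    q <- q[q > 0]
    -sum(q * log2(q))
  }, 0)
  bias <- ifelse(nTrue > 0, (nPred - nTrue) / nTrue, NA_real_)
  auc <- vapply(aa, function(a) {
    pos <- scored$aaTrue == a
    nP <- sum(pos); nN <- sum(!pos)
    if (nP == 0 || nN == 0) return(NA_real_)
    r <- rank(scored$probs[, a])  # midranks handle ties
    (sum(r[pos]) - nP * (nP + 1) / 2) / (nP * nN)
  }, 0)
  data.frame(aa = aa, n_true = as.integer(nTrue), n_pred = as.integer(nPred),
             recall = unname(recall), precision = unname(precision),
             f1 = unname(f1), auc = unname(auc),
             entropy_bits = unname(entropy), bias = unname(bias),
             stringsAsFactors = FALSE)
}

#' Group metrics over a set of scored residues
#'
#' Accuracy (sequence recovery), macro-precision and macro-recall
#' (unweighted means over the classes for which they are defined, so that
#' chain composition does not masquerade as prediction quality), BLOSUM62
#' similarity (argmax counts as correct when its substitution score against
#' the truth is positive; identity always counts) and top-3 accuracy (true
#' residue among the three highest-probability letters, ties broken by
#' alphabet order).
#'
#' @param scored Table from \code{\link{scoredResidues}}.
#' @return One-row \code{data.frame}: \code{accuracy},
#'   \code{macro_precision}, \code{macro_recall}, \code{similarity},
#'   \code{top3}, \code{n_residues}.
#' @export
groupMetrics <- function(scored) {
  if (!nrow(scored)) stop("cannot compute group metrics on zero residues")
  cm <- buildConfusion(scored)
  pc <- perClassMetrics(scored, cm)
  accuracy <- mean(scored$aaTrue == scored$pred)
  macroRecall <- mean(pc$recall[!is.na(pc$recall)])
  # macro-precision averages only classes present in the truth AND predicted
  # at least once; classes failing either are skipped, not imputed 0
  precOK <- !is.na(pc$precision) & pc$n_true > 0
  macroPrecision <- if (any(precOK)) mean(pc$precision[precOK]) else NA_real_
  sim <- similarityMatrix()
  similarity <- mean(sim[cbind(scored$aaTrue, scored$pred)] > 0 |
                     scored$aaTrue == scored$pred)
  p <- scored$probs
  trueIdx <- match(scored$aaTrue, aminoAcids())
  top3 <- mean(vapply(seq_len(nrow(p)), function(i) {
    trueIdx[i] %in% order(-p[i, ])[1:3]  # stable order = alphabet ties
  }, TRUE))
  data.frame(accuracy = accuracy, macro_precision = macroPrecision,
             macro_recall = macroRecall, similarity = similarity,
             top3 = top3, n_residues = nrow(scored))
}

#' Group metrics per stratum
#'
#' Splits the scored residues by a stratum label (secondary-structure state,
#' fold class, architecture, chain, ...) and computes
#' \code{\link{groupMetrics}} independently within each; empty strata are
#' omitted. Because every residue lands in exactly one stratum, the
#' residue-weighted mean of per-stratum accuracies reconstructs the global
#' accuracy exactly.
#'
#' @param scored Table from \code{\link{scoredResidues}}.
#' @param strata Character vector: the stratum of each residue, or the name
#'   of a column of \code{scored}.
#' @return \code{data.frame}: \code{stratum} plus the group-metric columns,
#'   one row per non-empty stratum, in order of first appearance.
#' @export
stratifiedMetrics <- function(scored, strata) {
  if (length(strata) == 1L && strata %in% names(scored))
    strata <- scored[[strata]]
  if (length(strata) != nrow(scored))
    stop("every residue must receive a stratum label")
  levs <- unique(strata)
  out <- lapply(levs, function(s) {
    g <- groupMetrics(scored[strata == s, , drop = FALSE])
    cbind(data.frame(stratum = s, stringsAsFactors = FALSE), g)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Correlation between per-chain accuracy and crystal resolution
#'
#' Pearson correlation of chain-level sequence recovery against structure
#' resolution; chains without a resolution are excluded. Undefined (returned
#' as \code{NA} with a warning) when fewer than 3 usable chains remain or
#' either variable has zero variance.
#'
#' @param perChain \code{data.frame} with columns \code{accuracy} and
#'   \code{resolution}.
#' @return Single numeric Pearson r, or \code{NA}.
#' @export
resolutionCorrelation <- function(perChain) {
  ok <- is.finite(perChain$accuracy) & is.finite(perChain$resolution)
  x <- perChain$accuracy[ok]; y <- perChain$resolution[ok]
  if (length(x) < 3L) {
    warning("resolution correlation undefined: fewer than 3 chains with resolution")
    return(NA_real_)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("resolution correlation undefined: zero variance")
    return(NA_real_)
  }
  stats::cor(x, y)
}
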