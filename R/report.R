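#' Build the full stratified metric report for one model
#'
#' Drives the whole pipeline for one prediction set: loads each chain's
#' backbone from the dataset map, canonicalizes residues (positions whose
#' identity cannot be canonicalized are excluded from scoring and counted),
#' aligns the model's probability rows to the remaining residues by order
#' (hard error on a count mismatch), assigns secondary structure with the
#' built-in assigner or from a directory of DSSP files, and computes every
#' metric group: per amino acid, global, per chain, per secondary-structure
#' state, per fold class, per architecture, plus the accuracy-versus-
#' resolution correlation.
#'
#' @param preds A \linkS4class{PredictionSet}.
#' @param dmap A \linkS4class{DatasetMap}; every chain in \code{preds} must
#'   appear in it.
#' @param baseDir Directory that the map's structure paths are relative to
#'   (default the map's own values as given).
#' @param ssSource \code{"builtin"} for the package's Kabsch-Sander assigner
#'   or \code{"dssp-dir"} to import per-structure DSSP files.
#' @param dsspDir Directory of \code{<pdbid>.dssp} files when
#'   \code{ssSource = "dssp-dir"}.
#' @param verbose Log per-chain progress (default FALSE).
#' @return A \linkS4class{ModelReport}.
#' @export
buildModelReport <- function(preds, dmap, baseDir = ".",
                             ssSource = c("builtin", "dssp-dir"),
                             dsspDir = NULL, verbose = FALSE) {
  stopifnot(is(preds, "PredictionSet"), is(dmap, "DatasetMap"))
  ssSource <- match.arg(ssSource)
  if (ssSource == "dssp-dir" && is.null(dsspDir))
    stop("ssSource = 'dssp-dir' requires dsspDir")
  entries <- dmap@entries
  chains <- unique(preds@chainKeys)
  missing <- setdiff(chains, entries$chainKey)
  if (length(missing))
    stop("chain(s) in predictions missing from dataset map: ",
         paste(missing, collapse = ", "))

  scoredList <- list(); exclList <- list()
  for (ck in chains) {
    ent <- entries[entries$chainKey == ck, ]
    path <- ent$structurePath
    if (!file.exists(path)) path <- file.path(baseDir, ent$structurePath)
    chain <- readPDBBackbone(path, sub(".*_", "", ck), verbose = verbose)
    known <- chain@aaTrue != unknownResidue()
    rows <- which(preds@chainKeys == ck)
    if (length(rows) != sum(known))
      stop(sprintf(
        "chain %s: %d prediction rows but %d canonicalized residues",
        ck, length(rows), sum(known)))
    ssAll <- .chainSecondaryStructure(chain, ssSource, dsspDir, path)
    res <- if (length(chain@resolution)) chain@resolution else NA_real_
    scoredList[[ck]] <- scoredResidues(
      aaTrue = chain@aaTrue[known],
      probs = preds@probs[rows, , drop = FALSE],
      chainKey = ck, ss = ssAll[known],
      foldClass = ent$foldClass, architecture = ent$architecture,
      resolution = res, seqId = chain@seqIds[known])
    exclList[[ck]] <- data.frame(chainKey = ck,
                                 fold_class = ent$foldClass,
                                 n_residues = nResidues(chain),
                                 n_scored = sum(known),
                                 n_excluded_unknown = sum(!known),
                                 n_incomplete = sum(!chain@complete),
                                 stringsAsFactors = FALSE)
  }
  scored <- do.call(rbind, c(scoredList, make.row.names = FALSE))
  cm <- buildConfusion(scored)
  byChain <- stratifiedMetrics(scored, "chainKey")
  chainRes <- vapply(byChain$stratum, function(ck)
    scored$resolution[scored$chainKey == ck][1], 0)
  rr <- withCallingHandlers(
    resolutionCorrelation(data.frame(accuracy = byChain$accuracy,
                                     resolution = chainRes)),
    warning = function(w) invokeRestart("muffleWarning"))
  new("ModelReport",
      modelName = preds@modelName,
      perClass = perClassMetrics(scored, cm),
      global = groupMetrics(scored),
      byChain = byChain,
      bySS = stratifiedMetrics(scored, "ss"),
      byFoldClass = stratifiedMetrics(scored, "foldClass"),
      byArchitecture = stratifiedMetrics(scored, "architecture"),
      confusion = cm,
      resolutionR = if (is.na(rr)) numeric(0) else rr,
      exclusions = do.call(rbind, c(exclList, make.row.names = FALSE)),
      scoredKeys = paste(scored$chainKey, scored$seqId, sep = ":"))
}

.chainSecondaryStructure <- function(chain, ssSource, dsspDir, pdbPath) {
  if (ssSource == "builtin")
    return(assignSecondaryStructure(chain)$state3)
  base <- tolower(sub("\\.pdb$", "", basename(pdbPath), ignore.case = TRUE))
  cand <- file.path(dsspDir, paste0(base, c(".dssp", ".DSSP")))
  f <- cand[file.exists(cand)][1]
  if (is.na(f))
    stop("no DSSP file for structure ", basename(pdbPath), " in ", dsspDir)
  lab <- readDSSPFile(f)
  lab <- lab[lab$chain == sub(".*_", "", chain@chainKey), , drop = FALSE]
  ss <- rep("C", nResidues(chain))
  hit <- match(chain@seqIds, lab$resno)
  ss[!is.na(hit)] <- reduce8to3(lab$ss8[hit[!is.na(hit)]])
  ss
}

#' Compare models over fold classes
#'
#' Tabulates one metric (default accuracy) per model, globally and per CATH
#' fold class. All reports must cover the identical scored residue set; a
#' mismatch is an error rather than a silent intersection, so bars are never
#' computed on different benchmarks.
#'
#' @param reports List of \linkS4class{ModelReport} (at least 2).
#' @param metric One of \code{"accuracy"}, \code{"macro_recall"},
#'   \code{"macro_precision"}, \code{"similarity"}, \code{"top3"}.
#' @return Wide \code{data.frame}: one row per model (input order), columns
#'   \code{model}, \code{global}, then one per fold class present.
#' @export
compareModels <- function(reports, metric = "accuracy") {
  if (length(reports) < 2L) stop("need at least 2 reports to compare")
  stopifnot(all(vapply(reports, is, TRUE, "ModelReport")))
  metric <- match.arg(metric, c("accuracy", "macro_recall",
                                "macro_precision", "similarity", "top3"))
  keys <- lapply(reports, function(r) sort(r@scoredKeys))
  for (i in seq_along(reports)[-1])
    if (!identical(keys[[1]], keys[[i]]))
      stop("models evaluated on different residue sets: ",
           reports[[1]]@modelName, " vs ", reports[[i]]@modelName)
  classes <- .foldClasses[.foldClasses %in% reports[[1]]@byFoldClass$stratum]
  rows <- lapply(reports, function(r) {
    fc <- r@byFoldClass
    vals <- vapply(classes, function(cl) fc[[metric]][fc$stratum == cl], 0)
    out <- data.frame(model = r@modelName, global = r@global[[metric]],
                      stringsAsFactors = FALSE)
    for (cl in classes) out[[cl]] <- vals[[cl]]
    out
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Write a report's metric tables as tidy CSVs
#'
#' Emits \code{per_class.csv}, \code{per_chain.csv}, \code{per_ss.csv},
#' \code{per_fold_class.csv}, \code{per_architecture.csv},
#' \code{confusion.csv} (long: true, predicted, count),
#' \code{composition.csv} (chains and residues per fold class) and
#' \code{exclusions.csv}. Output is deterministic: identical inputs give
#' byte-identical files.
#'
#' @param report A \linkS4class{ModelReport}.
#' @param outDir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
writeReport <- function(report, outDir) {
  stopifnot(is(report, "ModelReport"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    p <- file.path(outDir, name)
    utils::write.csv(.roundForOutput(df), p, row.names = FALSE, quote = FALSE)
    p
  }
  paths <- c(
    w(report@perClass, "per_class.csv"),
    w(report@byChain, "per_chain.csv"),
    w(report@bySS, "per_ss.csv"),
    w(report@byFoldClass, "per_fold_class.csv"),
    w(report@byArchitecture, "per_architecture.csv"),
    w(.confusionLong(report@confusion), "confusion.csv"),
    w(.composition(report), "composition.csv"),
    w(report@exclusions, "exclusions.csv"))
  g <- cbind(data.frame(model = report@modelName), report@global,
             resolution_r = if (length(report@resolutionR))
               report@resolutionR else NA_real_)
  paths <- c(paths, w(g, "summary.csv"))
  invisible(paths)
}

.roundForOutput <- function(df) {
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(x) round(x, 10))
  df
}

.confusionLong <- function(cm) {
  df <- expand.grid(true = rownames(cm), predicted = colnames(cm),
                    stringsAsFactors = FALSE)
  df$count <- as.integer(cm[cbind(df$true, df$predicted)])
  df[order(df$true, df$predicted), ]
}

.composition <- function(report) {
  fc <- report@byFoldClass
  ex <- report@exclusions
  chains <- vapply(fc$stratum, function(cl)
    sum(ex$fold_class == cl), 0L)
  data.frame(fold_class = fc$stratum, n_chains = as.integer(chains),
             n_residues = fc$n_residues, stringsAsFactors = FALSE)
}

#' Render the standard benchmark plots with CSV twins
#'
#' Produces the four standard panels: (A) per-amino-acid prediction bias
#' versus abundance, (B) per-chain accuracy versus resolution with the
#' Pearson r, (C) the confusion heat map and, when a comparison table is
#' supplied, (D) grouped per-fold-class bars. Every panel writes its
#' underlying numbers as a CSV twin first; plotting is a thin layer on top
#' and tests assert only on the CSVs. Panel B is skipped with a notice when
#' the resolution correlation is undefined.
#'
#' @param report A \linkS4class{ModelReport}.
#' @param outDir Output directory.
#' @param comparison Optional table from \code{\link{compareModels}}.
#' @param width,height Device size in inches.
#' @return Invisibly, the paths written.
#' @export
renderPlots <- function(report, outDir, comparison = NULL,
                        width = 7, height = 5) {
  stopifnot(is(report, "ModelReport"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wcsv <- function(df, name) {
    p <- file.path(outDir, name)
    utils::write.csv(.roundForOutput(df), p, row.names = FALSE, quote = FALSE)
    p
  }
  save <- function(plot, name) {
    p <- file.path(outDir, name)
    tryCatch({
      grDevices::pdf(p, width = width, height = height)
      print(plot)
      grDevices::dev.off()
      p
    }, error = function(e) {
      message("plot device unavailable, CSV twin written: ",
              conditionMessage(e))
      character(0)
    })
  }

  pc <- report@perClass
  biasTab <- data.frame(aa = pc$aa, n_true = pc$n_true, n_pred = pc$n_pred,
                        bias = pc$bias)
  paths <- c(paths, wcsv(biasTab, "bias_abundance.csv"))
  pA <- ggplot2::ggplot(biasTab,
          ggplot2::aes(x = factor(aa, aminoAcids()), y = bias)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "amino acid", y = "prediction bias",
                  title = paste0(report@modelName, ": prediction bias")) +
    ggplot2::theme_minimal()
  paths <- c(paths, save(pA, "bias_abundance.pdf"))

  if (length(report@resolutionR)) {
    bc <- report@byChain
    resTab <- data.frame(chain = bc$stratum, accuracy = bc$accuracy)
    paths <- c(paths, wcsv(cbind(resTab, r = report@resolutionR),
                           "accuracy_resolution.csv"))
  } else {
    message("resolution correlation undefined; accuracy-resolution panel skipped")
  }

  cl <- .confusionLong(report@confusion)
  paths <- c(paths, wcsv(cl, "confusion.csv"))
  pC <- ggplot2::ggplot(cl, ggplot2::aes(
          x = factor(predicted, aminoAcids()),
          y = factor(true, rev(aminoAcids())),
          fill = count)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "predicted", y = "true",
                  title = paste0(report@modelName, ": confusion")) +
    ggplot2::theme_minimal()
  paths <- c(paths, save(pC, "confusion.pdf"))

  if (!is.null(comparison)) {
    long <- do.call(rbind, lapply(seq_len(nrow(comparison)), function(i) {
      strata <- setdiff(names(comparison), "model")
      data.frame(model = comparison$model[i], stratum = strata,
                 value = as.numeric(comparison[i, strata]),
                 stringsAsFactors = FALSE)
    }))
    paths <- c(paths, wcsv(long, "comparison.csv"))
    pD <- ggplot2::ggplot(long, ggplot2::aes(
            x = stratum, y = value, fill = model)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = "fold class", y = "metric") +
      ggplot2::theme_minimal()
    paths <- c(paths, save(pD, "comparison.pdf"))
  }
  invisible(paths)
}
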