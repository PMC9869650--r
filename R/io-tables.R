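#' Read a prediction matrix CSV into a PredictionSet
#'
#' Expected dialect: header \code{chain_key,position,A,C,...,Y} with the 20
#' probability columns in canonical alphabet order (any column order is
#' accepted; they are reindexed). Rows of one chain must be contiguous and in
#' structure order; \code{position} is bookkeeping only. Each row is
#' validated: negative entries are an error; a row sum within
#' \code{[0.99, 1.01]} is renormalized to 1 preserving proportions; a sum
#' outside that band is a validation error naming the row.
#'
#' @param path CSV file path.
#' @param modelName Model label; default the file name without extension.
#' @param verbose Log the number of rows read (default TRUE).
#' @return A \linkS4class{PredictionSet}.
#' @export
readPredictionCSV <- function(path, modelName = NULL, verbose = TRUE) {
  if (!file.exists(path)) stop("prediction CSV not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  aa <- aminoAcids()
  need <- c("chain_key", "position", aa)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("prediction CSV is missing column(s): ", paste(missing, collapse = ", "))
  p <- as.matrix(df[, aa])
  storage.mode(p) <- "double"
  if (anyNA(p)) stop("prediction CSV contains non-numeric probabilities")
  neg <- which(apply(p < 0, 1L, any))
  if (length(neg))
    stop("negative probability in row ", neg[1], " of ", path)
  s <- rowSums(p)
  bad <- which(s < 0.99 | s > 1.01)
  if (length(bad))
    stop(sprintf("probability row %d of %s sums to %.4f (outside [0.99, 1.01])",
                 bad[1], path, s[bad[1]]))
  p <- p / s
  if (is.null(modelName))
    modelName <- sub("\\.[^.]*$", "", basename(path))
  if (verbose)
    message(sprintf("readPredictionCSV: %s: %d rows, %d chain(s)",
                    basename(path), nrow(p), length(unique(df$chain_key))))
  new("PredictionSet", modelName = modelName, probs = p,
      chainKeys = as.character(df$chain_key),
      positions = as.integer(df$position))
}

#' Write a PredictionSet in the prediction-CSV dialect
#' @param x A \linkS4class{PredictionSet}.
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
writePredictionCSV <- function(x, path) {
  stopifnot(is(x, "PredictionSet"))
  df <- data.frame(chain_key = x@chainKeys, position = x@positions,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(x@probs, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dataset map manifest
#'
#' Dialect: whitespace-separated \code{chain_key architecture_code
#' structure_path}, one entry per line; \code{#} comments and blank lines
#' ignored. The fold class is derived from the leading CATH class digit of
#' the architecture code: 1 mainly-alpha, 2 mainly-beta, 3 alpha-beta,
#' anything else special.
#'
#' @param path Manifest file path.
#' @param verbose Log the number of entries (default TRUE).
#' @return A \linkS4class{DatasetMap}.
#' @export
readDatasetMap <- function(path, verbose = TRUE) {
  if (!file.exists(path)) stop("dataset map not found: ", path)
  raw <- readLines(path, warn = FALSE)
  stripped <- sub("#.*$", "", raw)
  idx <- which(nzchar(trimws(stripped)))
  entries <- lapply(idx, function(i) {
    f <- strsplit(trimws(stripped[i]), "[[:space:]]+")[[1]]
    if (length(f) != 3L)
      stop("dataset map line ", i, ": expected 3 fields, got ", length(f))
    if (!grepl("^[0-9]\\.[0-9]+$", f[2]))
      stop("dataset map line ", i, ": malformed architecture code '", f[2], "'")
    f
  })
  chainKey <- vapply(entries, `[`, "", 1L)
  if (anyDuplicated(chainKey))
    stop("duplicate chain_key in dataset map: ",
         chainKey[duplicated(chainKey)][1])
  architecture <- vapply(entries, `[`, "", 2L)
  classDigit <- substr(architecture, 1, 1)
  foldClass <- ifelse(classDigit == "1", "mainly-alpha",
               ifelse(classDigit == "2", "mainly-beta",
               ifelse(classDigit == "3", "alpha-beta", "special")))
  if (verbose)
    message(sprintf("readDatasetMap: %s: %d entries", basename(path), length(idx)))
  new("DatasetMap", entries = data.frame(
    chainKey = chainKey, architecture = architecture,
    foldClass = foldClass,
    structurePath = vapply(entries, `[`, "", 3L),
    stringsAsFactors = FALSE))
}

#' Write a DatasetMap manifest
#' @param x A \linkS4class{DatasetMap}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeDatasetMap <- function(x, path) {
  stopifnot(is(x, "DatasetMap"))
  e <- x@entries
  writeLines(c("# chain_key architecture_code structure_path",
               sprintf("%s %s %s", e$chainKey, e$architecture, e$structurePath)),
             path)
  invisible(path)
}

#' Read per-residue secondary structure from a classic DSSP output file
#'
#' Parses the data section that follows the \code{"  #  RESIDUE"} header of
#' DSSP's classic text format: one residue per line with chain id, author
#' residue number and the 8-state code in its fixed column. Chain-break
#' (\code{!}) lines are skipped; a blank structure code is coil.
#'
#' @param path DSSP output file.
#' @return \code{data.frame} with columns \code{chain}, \code{resno}
#'   (character, insertion code appended) and \code{ss8}.
#' @export
readDSSPFile <- function(path) {
  if (!file.exists(path)) stop("DSSP file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (!length(hdr))
    stop("not a classic DSSP file (no '  #  RESIDUE' header): ", path)
  body <- lines[seq.int(hdr[1] + 1L, length.out = max(0L, length(lines) - hdr[1]))]
  body <- body[nzchar(trimws(body))]
  out <- list()
  for (ln in body) {
    aa <- substr(ln, 14, 14)
    if (aa == "!") next  # chain break
    resno <- trimws(substr(ln, 6, 11))  # author number + insertion code
    chain <- substr(ln, 12, 12)
    ss <- substr(ln, 17, 17)
    if (ss %in% c(" ", "")) ss <- "C"  # blank code (possibly trimmed) is coil
    out[[length(out) + 1L]] <- c(chain, resno, ss)
  }
  if (!length(out))
    return(data.frame(chain = character(0), resno = character(0),
                      ss8 = character(0), stringsAsFactors = FALSE))
  m <- do.call(rbind, out)
  data.frame(chain = m[, 1], resno = m[, 2], ss8 = m[, 3],
             stringsAsFactors = FALSE)
}
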