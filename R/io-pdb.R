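#' Read one chain's backbone from a PDB file
#'
#' Parses the named chain into a \linkS4class{BackboneStructure}: backbone
#' heavy atoms (N, CA, C, O) per residue, native amino acid canonicalized via
#' \code{\link{canonicalizeResidue}}, and the resolution from the
#' \code{REMARK 2} header when present. Only the first model of multi-model
#' files is used. Alternate locations are resolved to the highest-occupancy
#' record (ties: first encountered). Water and HETATM records that do not
#' canonicalize to a standard amino acid (ligands, ions) are excluded;
#' HETATM amino-acid variants such as MSE are retained. Residues missing some
#' backbone atoms are retained with \code{isComplete()} FALSE.
#'
#' @param path Path to a PDB-format text file.
#' @param chainId Single chain identifier present in the file.
#' @param verbose Log parsed/excluded record counts (default TRUE).
#' @return A \linkS4class{BackboneStructure}.
#' @export
readPDBBackbone <- function(path, chainId, verbose = TRUE) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e))
  )
  atoms <- pdb$atom
  if (!chainId %in% atoms$chain)
    stop("chain '", chainId, "' not found in ", path)
  atoms <- atoms[atoms$chain == chainId &
                 atoms$elety %in% c("N", "CA", "C", "O"), , drop = FALSE]
  nRaw <- nrow(atoms)
  atoms <- atoms[atoms$resid != "HOH", , drop = FALSE]

  ins <- ifelse(is.na(atoms$insert) | atoms$insert == "", "", atoms$insert)
  resKey <- paste0(atoms$resno, ins)
  # residues in file order
  keys <- unique(resKey)
  aa1 <- character(0); seqIds <- character(0)
  coords <- array(NA_real_, c(0, 4, 3))
  keepRows <- list()
  excluded <- 0L
  for (k in keys) {
    rows <- atoms[resKey == k, , drop = FALSE]
    # ligand/water policy: retain if any ATOM record, or a HETATM residue
    # whose name canonicalizes to a standard amino acid
    aa <- canonicalizeResidue(rows$resid[1])
    if (!any(rows$type == "ATOM") && aa == unknownResidue()) {
      excluded <- excluded + 1L
      next
    }
    keepRows[[k]] <- rows
  }

  n <- length(keepRows)
  coords <- array(NA_real_, c(n, 4, 3),
                  dimnames = list(NULL, c("N", "CA", "C", "O"),
                                  c("x", "y", "z")))
  aa1 <- character(n); seqIds <- names(keepRows)
  for (i in seq_len(n)) {
    rows <- keepRows[[i]]
    aa1[i] <- canonicalizeResidue(rows$resid[1])
    for (atom in c("N", "CA", "C", "O")) {
      cand <- rows[rows$elety == atom, , drop = FALSE]
      if (!nrow(cand)) next
      occ <- ifelse(is.na(cand$o), 1, cand$o)
      best <- which(occ == max(occ))[1]  # ties: first encountered
      xyz <- as.numeric(cand[best, c("x", "y", "z")])
      if (any(!is.finite(xyz)))
        stop("unparseable coordinates for residue ", seqIds[i],
             " atom ", atom, " in ", path)
      coords[i, atom, ] <- xyz
    }
  }
  complete <- apply(coords, 1L, function(m) all(is.finite(m)))

  resolution <- .parseResolution(path)
  pdbId <- toupper(sub("\\.pdb$", "", basename(path), ignore.case = TRUE))
  if (verbose)
    message(sprintf("readPDBBackbone: %s chain %s: %d residues (%d complete), %d hetero record(s) excluded",
                    basename(path), chainId, n, sum(complete), excluded))
  new("BackboneStructure",
      chainKey = paste0(pdbId, "_", chainId),
      seqIds = seqIds, aaTrue = aa1, coords = coords,
      complete = unname(complete), resolution = resolution)
}

.parseResolution <- function(path) {
  head <- readLines(path, n = 500L, warn = FALSE)
  rem <- grep("^REMARK   2 RESOLUTION\\.", head, value = TRUE)
  if (!length(rem)) return(numeric(0))
  rest <- sub("^REMARK   2 RESOLUTION\\.", "", rem[1])
  m <- regmatches(rest, regexpr("[0-9]+\\.?[0-9]*", rest))
  if (!length(m)) return(numeric(0))
  as.numeric(m)
}

#' Write a backbone chain as minimal PDB text
#'
#' Fixed-width writer used for fixtures and round-trip checks: emits a
#' \code{REMARK 2} resolution header (when the structure has one) followed by
#' one ATOM record per present backbone atom, coordinates at the PDB's three
#' decimal places.
#'
#' @param x A \linkS4class{BackboneStructure}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
writeBackbonePDB <- function(x, path) {
  stopifnot(is(x, "BackboneStructure"))
  lines <- c(sprintf("HEADER    SYNTHETIC BACKBONE                      01-JAN-26   %s",
                     substr(sub("_.*", "", x@chainKey), 1, 4)))
  if (length(x@resolution))
    lines <- c(lines, sprintf("REMARK   2 RESOLUTION. %4.2f ANGSTROMS.", x@resolution))
  chain <- sub(".*_", "", x@chainKey)
  aa3 <- names(.aa3to1)[match(x@aaTrue, .aa3to1)]
  aa3[is.na(aa3)] <- "UNK"
  serial <- 0L
  for (i in seq_len(nResidues(x))) {
    resno <- as.integer(sub("[A-Za-z]$", "", x@seqIds[i]))
    icode <- sub("^[-0-9]+", "", x@seqIds[i])
    if (!nzchar(icode)) icode <- " "
    for (atom in c("N", "CA", "C", "O")) {
      xyz <- x@coords[i, atom, ]
      if (any(!is.finite(xyz))) next
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, paste0(" ", atom), aa3[i], chain, resno, icode,
        xyz[1], xyz[2], xyz[3], 1.00, 0.00, substr(atom, 1, 1)))
    }
  }
  lines <- c(lines, "TER", "END")
  writeLines(lines, path)
  invisible(path)
}
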