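# Kabsch-Sander electrostatic hydrogen-bond model constants
.ksCoupling <- 0.084 * 332     # partial charges times dielectric factor
.ksEnergyCutoff <- -0.5        # kcal/mol; bonds below this are stored
.ksMinSeparation <- 2L         # minimum |donor - acceptor| sequence distance
.ksClashDistance <- 0.5        # Angstrom; shorter distances are a clash

#' Place backbone amide hydrogens
#'
#' PDB backbones lack hydrogens, so the donor H of each amide is
#' reconstructed geometrically: 1.01 Angstrom from N along the normalized sum
#' of the unit vectors (N - C_prev) and (N - CA), an approximation of the
#' convention used by hydrogen-bond based secondary-structure assigners. The
#' first residue, prolines (no amide H) and residues with missing atoms or a
#' broken preceding peptide bond get no hydrogen.
#'
#' @param chain A \linkS4class{BackboneStructure}.
#' @return Numeric \code{n x 3} matrix of H coordinates, \code{NA} rows where
#'   no hydrogen is placed.
#' @export
placeAmideHydrogens <- function(chain) {
  stopifnot(is(chain, "BackboneStructure"))
  co <- chain@coords
  n <- nResidues(chain)
  H <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  for (i in seq_len(n)) {
    if (i == 1L || chain@aaTrue[i] == "P") next
    if (!chain@complete[i] || !chain@complete[i - 1]) next
    if (!.hasPeptideBond(co, i)) next
    N <- co[i, "N", ]; CA <- co[i, "CA", ]; Cp <- co[i - 1, "C", ]
    u1 <- N - Cp; u1 <- u1 / sqrt(sum(u1^2))
    u2 <- N - CA; u2 <- u2 / sqrt(sum(u2^2))
    u <- u1 + u2
    nu <- sqrt(sum(u^2))
    if (nu < 1e-9) next
    H[i, ] <- N + 1.01 * u / nu
  }
  H
}

#' Kabsch-Sander hydrogen-bond energy
#'
#' Electrostatic energy of an N-H...O=C interaction:
#' \code{E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN)} kcal/mol, where
#' the distances pair the acceptor's O and C with the donor's N and H. A bond
#' is considered formed when \code{E < -0.5} kcal/mol.
#'
#' @param acceptorC,acceptorO Acceptor residue's carbonyl C and O (3-vectors,
#'   Angstrom).
#' @param donorN,donorH Donor residue's amide N and H.
#' @return Energy in kcal/mol.
#' @export
kabschSanderEnergy <- function(acceptorC, acceptorO, donorN, donorH) {
  d <- function(a, b) sqrt(sum((a - b)^2))
  rON <- d(acceptorO, donorN); rCH <- d(acceptorC, donorH)
  rOH <- d(acceptorO, donorH); rCN <- d(acceptorC, donorN)
  if (min(rON, rCH, rOH, rCN) <= .ksClashDistance)
    stop(sprintf("atom clash between donor and acceptor (min distance %.2f A)",
                 min(rON, rCH, rOH, rCN)))
  .ksCoupling * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
}

#' Backbone hydrogen bonds of a chain
#'
#' Evaluates the Kabsch-Sander energy for every acceptor/donor residue pair
#' at sequence separation of at least 2 and returns the pairs whose energy is
#' below the -0.5 kcal/mol threshold.
#'
#' @param chain A \linkS4class{BackboneStructure}.
#' @param hydrogens Optional precomputed matrix from
#'   \code{\link{placeAmideHydrogens}}.
#' @return \code{data.frame} with columns \code{acceptor} (residue index
#'   donating the C=O), \code{donor} (residue index donating the N-H) and
#'   \code{energy} (kcal/mol).
#' @export
hydrogenBonds <- function(chain, hydrogens = NULL) {
  stopifnot(is(chain, "BackboneStructure"))
  if (is.null(hydrogens)) hydrogens <- placeAmideHydrogens(chain)
  co <- chain@coords
  n <- nResidues(chain)
  accOK <- chain@complete
  donOK <- is.finite(hydrogens[, 1])
  out <- list()
  for (i in which(accOK)) {
    for (j in which(donOK)) {
      if (abs(i - j) < .ksMinSeparation) next
      # cheap distance prefilter: O-N beyond 5.2 A cannot reach -0.5 kcal/mol
      if (sqrt(sum((co[i, "O", ] - co[j, "N", ])^2)) > 5.2) next
      e <- kabschSanderEnergy(co[i, "C", ], co[i, "O", ],
                              co[j, "N", ], hydrogens[j, ])
      if (e < .ksEnergyCutoff)
        out[[length(out) + 1L]] <- c(i, j, e)
    }
  }
  if (!length(out))
    return(data.frame(acceptor = integer(0), donor = integer(0),
                      energy = numeric(0)))
  m <- do.call(rbind, out)
  data.frame(acceptor = as.integer(m[, 1]), donor = as.integer(m[, 2]),
             energy = m[, 3])
}

#' Assign secondary structure from backbone hydrogen bonds
#'
#' Simplified Kabsch-Sander assignment: an alpha-helix turn exists at i when
#' the carbonyl of residue i bonds the amide of residue i+4; residues
#' i..i+3 are helical when turns exist at both i-1 and i. Strand residues
#' are those participating in a parallel or antiparallel bridge (the two
#' standard bond patterns), at sequence separation of at least 3. Helix takes
#' precedence over strand; everything else, including incomplete residues, is
#' coil. The built-in assigner emits only H/E/C in its 8-state column;
#' 3-10/pi helices and finer states appear only via DSSP import.
#'
#' @param chain A \linkS4class{BackboneStructure}.
#' @return \code{data.frame} with columns \code{state3} (H/E/C),
#'   \code{state8} and \code{excluded} (TRUE for residues that could not be
#'   assessed because atoms were missing).
#' @export
assignSecondaryStructure <- function(chain) {
  stopifnot(is(chain, "BackboneStructure"))
  n <- nResidues(chain)
  hb <- hydrogenBonds(chain)
  bond <- matrix(FALSE, n, n)  # bond[i, j]: CO(i) accepts from NH(j)
  if (nrow(hb)) bond[cbind(hb$acceptor, hb$donor)] <- TRUE
  turn4 <- function(i) i >= 1 && i + 4 <= n && bond[i, i + 4]
  isH <- rep(FALSE, n); isE <- rep(FALSE, n)
  for (i in 2:max(2, n)) {
    if (i + 3 > n) break
    if (turn4(i - 1) && turn4(i)) isH[i:(i + 3)] <- TRUE
  }
  if (n >= 4) {
    b <- function(i, j) i >= 1 && j >= 1 && i <= n && j <= n && bond[i, j]
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (j - i < 3) next
        para <- (b(i - 1, j) && b(j, i + 1)) || (b(j - 1, i) && b(i, j + 1))
        anti <- (b(i, j) && b(j, i)) || (b(i - 1, j + 1) && b(j - 1, i + 1))
        if (para || anti) { isE[i] <- TRUE; isE[j] <- TRUE }
      }
    }
  }
  state3 <- ifelse(isH, "H", ifelse(isE, "E", "C"))  # helix precedence
  excluded <- !chain@complete
  state3[excluded] <- "C"
  data.frame(state3 = state3, state8 = state3, excluded = excluded,
             stringsAsFactors = FALSE)
}

#' Reduce 8-state secondary structure to 3 states
#'
#' Standard mapping: H, G, I (helices) to H; E, B (strand/bridge) to E;
#' T, S, C (turn, bend, coil) to C.
#'
#' @param state8 Character vector of 8-state codes.
#' @return Character vector of H/E/C.
#' @export
reduce8to3 <- function(state8) {
  map <- c(H = "H", G = "H", I = "H", E = "E", B = "E",
           T = "C", S = "C", C = "C")
  out <- map[state8]
  if (anyNA(out))
    stop("unknown 8-state code: ", state8[is.na(out)][1])
  unname(out)
}
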