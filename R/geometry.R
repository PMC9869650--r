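#' Signed dihedral angle of four points
#'
#' Standard IUPAC torsion: looking down the p2-p3 axis, the angle from the
#' p1-p2 bond to the p3-p4 bond, positive clockwise, reported in degrees in
#' (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstrom).
#' @return Angle in degrees.
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9)
    stop("undefined torsion: colinear points")
  b2u <- b2 / sqrt(sum(b2^2))
  ang <- atan2(sum(.cross3(n1, n2) * b2u), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# peptide bond C(i-1)-N(i) must be a real bond; larger gaps are chain breaks
.peptideBondMax <- 2.5

.hasPeptideBond <- function(coords, i) {
  if (i < 2) return(FALSE)
  cPrev <- coords[i - 1, "C", ]; n <- coords[i, "N", ]
  all(is.finite(cPrev)) && all(is.finite(n)) &&
    sqrt(sum((n - cPrev)^2)) <= .peptideBondMax
}

#' Backbone phi/psi torsions of a chain
#'
#' phi(i) from C(i-1), N(i), CA(i), C(i); psi(i) from N(i), CA(i), C(i),
#' N(i+1). The first residue has no phi and the last no psi; positions whose
#' required neighbour atoms are missing, or that sit across a chain break
#' (peptide C-N distance above 2.5 Angstrom), get \code{NA}.
#'
#' @param chain A \linkS4class{BackboneStructure}.
#' @return \code{data.frame} with numeric columns \code{phi}, \code{psi}
#'   (degrees, \code{NA} when absent), one row per residue.
#' @export
phiPsi <- function(chain) {
  stopifnot(is(chain, "BackboneStructure"))
  co <- chain@coords
  n <- nResidues(chain)
  phi <- rep(NA_real_, n); psi <- rep(NA_real_, n)
  fin <- function(...) all(vapply(list(...), function(v) all(is.finite(v)), TRUE))
  for (i in seq_len(n)) {
    if (i > 1 && .hasPeptideBond(co, i)) {
      p <- list(co[i - 1, "C", ], co[i, "N", ], co[i, "CA", ], co[i, "C", ])
      if (fin(p[[1]], p[[2]], p[[3]], p[[4]]))
        phi[i] <- tryCatch(dihedralAngle(p[[1]], p[[2]], p[[3]], p[[4]]),
                           error = function(e) NA_real_)
    }
    if (i < n && .hasPeptideBond(co, i + 1)) {
      p <- list(co[i, "N", ], co[i, "CA", ], co[i, "C", ], co[i + 1, "N", ])
      if (fin(p[[1]], p[[2]], p[[3]], p[[4]]))
        psi[i] <- tryCatch(dihedralAngle(p[[1]], p[[2]], p[[3]], p[[4]]),
                           error = function(e) NA_real_)
    }
  }
  data.frame(phi = phi, psi = psi)
}

#' True-versus-predicted Ramachandran comparison table
#'
#' For each amino-acid letter, bins the (phi, psi) pairs of the positions
#' where that letter is the true residue and, separately, where it is the
#' predicted residue, on a fixed 10-degree grid over (-180, 180]. Contrasting
#' the two histograms shows in which backbone conformations a method
#' overpredicts a residue type. Positions with an undefined phi or psi are
#' excluded from both modes.
#'
#' @param torsions \code{data.frame} from \code{\link{phiPsi}}.
#' @param trueSeq,predictedSeq Character vectors of one-letter codes, same
#'   length as \code{torsions}.
#' @param binWidth Bin width in degrees (default 10).
#' @return Long \code{data.frame} with columns \code{aa}, \code{mode}
#'   (\code{"true"}/\code{"predicted"}), \code{phi_bin}, \code{psi_bin}
#'   (left bin edges, degrees) and \code{count}; zero cells omitted.
#' @export
ramachandranComparison <- function(torsions, trueSeq, predictedSeq,
                                   binWidth = 10) {
  n <- nrow(torsions)
  if (length(trueSeq) != n || length(predictedSeq) != n)
    stop("trueSeq/predictedSeq length must match the torsion table")
  ok <- is.finite(torsions$phi) & is.finite(torsions$psi)
  edge <- function(a) {
    # (-180, 180]: angle on a left-open grid; exact multiples belong to the
    # bin whose right edge they are
    b <- ceiling(a / binWidth) * binWidth - binWidth
    pmax(pmin(b, 180 - binWidth), -180)
  }
  rows <- list()
  for (mode in c("true", "predicted")) {
    lab <- if (mode == "true") trueSeq else predictedSeq
    for (a in aminoAcids()) {
      sel <- ok & lab == a
      if (!any(sel)) next
      tab <- table(phi = edge(torsions$phi[sel]), psi = edge(torsions$psi[sel]))
      df <- as.data.frame(tab, stringsAsFactors = FALSE)
      df <- df[df$Freq > 0, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        aa = a, mode = mode,
        phi_bin = as.numeric(df$phi), psi_bin = as.numeric(df$psi),
        count = as.integer(df$Freq), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(aa = character(0), mode = character(0),
                      phi_bin = numeric(0), psi_bin = numeric(0),
                      count = integer(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
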