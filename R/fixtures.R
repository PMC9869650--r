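# Ideal peptide geometry used by all fixture builders (standard values).
.idealGeom <- list(
  b_NCA = 1.458, b_CAC = 1.525, b_CN = 1.329, b_CO = 1.231,
  ang_NCAC = 111.2, ang_CACN = 116.2, ang_CNCA = 121.7, ang_CACO = 120.8,
  omega = 180
)

# Natural-extension reference frame: place a new atom at the given bond
# length/angle/torsion from atoms a-b-c.
.placeAtom <- function(a, b, c, bond, angleDeg, torsionDeg) {
  th <- angleDeg * pi / 180; ph <- torsionDeg * pi / 180
  bc <- c - b; bcu <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- .cross3(ab, bcu); n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bcu)
  d <- c(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  c + d[1] * bcu + d[2] * m + d[3] * n
}

#' Build an ideal-geometry backbone from phi/psi torsions
#'
#' Grows a poly-peptide backbone by natural extension using fixed ideal bond
#' lengths (N-CA 1.458, CA-C 1.525, C-N 1.329 Angstrom) and angles, with the
#' peptide omega torsion fixed trans (180 degrees). The i-th input pair sets
#' phi(i) and psi(i); phi(1) is undefined by construction and psi(n) is used
#' only to orient the final carbonyl oxygen. Recomputing \code{\link{phiPsi}}
#' on the result returns the inputs to numerical precision, which is the
#' round-trip property the geometry tests rely on.
#'
#' @param phiPsiList Two-column matrix or data.frame of (phi, psi) in
#'   degrees, one row per residue.
#' @param sequence Optional character vector of one-letter codes (default
#'   all alanine).
#' @param chainKey Chain identifier (default \code{"FIXT_A"}).
#' @param resolution Optional resolution annotation in Angstrom.
#' @return A \linkS4class{BackboneStructure}.
#' @export
buildChainFromTorsions <- function(phiPsiList, sequence = NULL,
                                   chainKey = "FIXT_A",
                                   resolution = numeric(0)) {
  tor <- as.matrix(phiPsiList)
  if (!nrow(tor)) stop("empty torsion list")
  if (ncol(tor) != 2L) stop("phiPsiList must have two columns (phi, psi)")
  n <- nrow(tor)
  if (is.null(sequence)) sequence <- rep("A", n)
  if (length(sequence) != n) stop("sequence length must match torsion rows")
  if (!all(sequence %in% aminoAcids())) stop("invalid letter in sequence")
  g <- .idealGeom
  co <- array(NA_real_, c(n, 4, 3),
              dimnames = list(NULL, c("N", "CA", "C", "O"), c("x", "y", "z")))
  co[1, "N", ] <- c(0, 0, 0)
  co[1, "CA", ] <- c(g$b_NCA, 0, 0)
  # first C: correct N-CA-C angle, placed in the xy-plane
  co[1, "C", ] <- .placeAtom(c(0, -1, 0), co[1, "N", ], co[1, "CA", ],
                             g$b_CAC, g$ang_NCAC, 0)
  for (i in seq_len(n)[-1]) {
    co[i, "N", ] <- .placeAtom(co[i - 1, "N", ], co[i - 1, "CA", ],
                               co[i - 1, "C", ], g$b_CN, g$ang_CACN,
                               tor[i - 1, 2])
    co[i, "CA", ] <- .placeAtom(co[i - 1, "CA", ], co[i - 1, "C", ],
                                co[i, "N", ], g$b_NCA, g$ang_CNCA, g$omega)
    co[i, "C", ] <- .placeAtom(co[i - 1, "C", ], co[i, "N", ],
                               co[i, "CA", ], g$b_CAC, g$ang_NCAC,
                               tor[i, 1])
  }
  # carbonyl O in the peptide plane, anti to the next N (psi + 180)
  for (i in seq_len(n))
    co[i, "O", ] <- .placeAtom(co[i, "N", ], co[i, "CA", ], co[i, "C", ],
                               g$b_CO, g$ang_CACO, tor[i, 2] + 180)
  new("BackboneStructure", chainKey = chainKey,
      seqIds = as.character(seq_len(n)), aaTrue = sequence,
      coords = co, complete = rep(TRUE, n), resolution = resolution)
}

#' Ideal alpha-helix fixture
#'
#' An n-residue backbone built from uniform helical torsions
#' (phi, psi) = (-57, -47) degrees; the built-in assigner labels its interior
#' residues H.
#'
#' @param n Number of residues, at least 6.
#' @param sequence Optional sequence (default all alanine).
#' @param chainKey Chain identifier.
#' @param resolution Optional resolution annotation.
#' @return A \linkS4class{BackboneStructure}.
#' @export
makeIdealHelix <- function(n, sequence = NULL, chainKey = "HELX_A",
                           resolution = numeric(0)) {
  if (n < 6) stop("an ideal helix fixture needs at least 6 residues")
  buildChainFromTorsions(cbind(rep(-57, n), rep(-47, n)),
                         sequence = sequence, chainKey = chainKey,
                         resolution = resolution)
}

#' Two-stranded antiparallel beta-sheet fixture
#'
#' Two flat, fully extended strands laid antiparallel in a common plane at
#' the given inter-strand spacing, with carbonyls registered so that the
#' cross-strand N-H...O=C hydrogen bonds of an antiparallel ladder form.
#' Returned as a single \linkS4class{BackboneStructure} whose two segments
#' are separated by a chain break (no peptide bond across the gap).
#'
#' @param strandLen Residues per strand, at least 4.
#' @param separation Inter-strand spacing in Angstrom (default 4.8).
#' @param sequence Optional sequence of length \code{2 * strandLen}.
#' @param chainKey Chain identifier.
#' @param resolution Optional resolution annotation.
#' @return A \linkS4class{BackboneStructure} of \code{2 * strandLen} residues.
#' @export
makeAntiparallelSheet <- function(strandLen, separation = 4.8,
                                  sequence = NULL, chainKey = "SHET_A",
                                  resolution = numeric(0)) {
  if (strandLen < 4) stop("a sheet fixture needs at least 4 residues per strand")
  n <- strandLen
  s1 <- buildChainFromTorsions(cbind(rep(-180, n), rep(180, n)))
  co1 <- s1@coords
  # strand axis and sheet plane from the first strand's CA trace
  axis <- co1[n, "CA", ] - co1[1, "CA", ]
  axis <- axis / sqrt(sum(axis^2))
  # in-plane normal: component of the C=O direction perpendicular to the axis
  od <- co1[1, "O", ] - co1[1, "C", ]
  perp <- od - sum(od * axis) * axis
  perp <- perp / sqrt(sum(perp^2))
  # strand 2: rotate 180 degrees about perp (runs antiparallel, stays in
  # plane), then shift across the sheet and slide along the axis to register
  # the carbonyls (registry derived in the methods vignette)
  R <- 2 * outer(perp, perp) - diag(3)
  co2 <- co1
  for (i in seq_len(n)) for (atom in c("N", "CA", "C", "O"))
    co2[i, atom, ] <- as.numeric(R %*% co1[i, atom, ])
  # align: place strand 2 so residue k pairs with residue n+1-k
  shift <- co1[n, "CA", ] + separation * perp - co2[1, "CA", ]
  for (i in seq_len(n)) for (atom in c("N", "CA", "C", "O"))
    co2[i, atom, ] <- co2[i, atom, ] + shift
  co <- array(NA_real_, c(2 * n, 4, 3),
              dimnames = list(NULL, c("N", "CA", "C", "O"), c("x", "y", "z")))
  co[seq_len(n), , ] <- co1
  co[n + seq_len(n), , ] <- co2
  if (is.null(sequence)) sequence <- rep("A", 2 * n)
  if (length(sequence) != 2 * n) stop("sequence length must be 2 * strandLen")
  new("BackboneStructure", chainKey = chainKey,
      seqIds = as.character(c(seq_len(n), 100 + seq_len(n))),
      aaTrue = sequence, coords = co, complete = rep(TRUE, 2 * n),
      resolution = resolution)
}

#' Synthetic predictors with planted, analytically known behaviour
#'
#' Emits one probability row per truth residue according to \code{kind}:
#' \describe{
#'   \item{perfect}{one-hot at the true residue.}
#'   \item{uniform}{all entries 0.05.}
#'   \item{constant}{one-hot at \code{letter} everywhere.}
#'   \item{biased}{with probability \code{strength} a one-hot at
#'     \code{letter}, otherwise a one-hot at the truth; expected accuracy is
#'     \code{(1 - strength) + strength * f_letter} where \code{f_letter} is
#'     the frequency of \code{letter} in the truth.}
#'   \item{softmax_noise}{softmax of Gaussian logits (sd 1) with a +2 shift
#'     on the true class, divided by \code{temperature}.}
#' }
#' All stochastic kinds are deterministic given \code{seed}.
#'
#' @param truth Character vector of true one-letter codes.
#' @param kind One of \code{"perfect"}, \code{"uniform"}, \code{"constant"},
#'   \code{"biased"}, \code{"softmax_noise"}.
#' @param letter Target letter for \code{constant}/\code{biased}.
#' @param strength Bias strength in [0, 1] for \code{biased}.
#' @param temperature Positive temperature for \code{softmax_noise}.
#' @param seed Integer seed for the stochastic kinds.
#' @param chainKeys Chain key per residue (default one chain
#'   \code{"FIXT_A"}).
#' @param modelName Model label (default derived from \code{kind}).
#' @return A \linkS4class{PredictionSet}.
#' @export
makePredictions <- function(truth,
                            kind = c("perfect", "uniform", "constant",
                                     "biased", "softmax_noise"),
                            letter = "A", strength = 0.5, temperature = 1,
                            seed = 1L, chainKeys = NULL, modelName = NULL) {
  kind <- match.arg(kind)
  if (!all(truth %in% aminoAcids())) stop("invalid letter in truth sequence")
  aa <- aminoAcids()
  n <- length(truth)
  if (is.null(chainKeys)) chainKeys <- rep("FIXT_A", n)
  if (is.null(modelName)) modelName <- kind
  oneHot <- function(letters) {
    m <- matrix(0, length(letters), 20, dimnames = list(NULL, aa))
    m[cbind(seq_along(letters), match(letters, aa))] <- 1
    m
  }
  p <- switch(kind,
    perfect = oneHot(truth),
    uniform = matrix(0.05, n, 20, dimnames = list(NULL, aa)),
    constant = {
      stopifnot(letter %in% aa)
      oneHot(rep(letter, n))
    },
    biased = {
      stopifnot(letter %in% aa, strength >= 0, strength <= 1)
      old <- .seedScope(seed)
      on.exit(.restoreSeed(old), add = TRUE)
      flip <- stats::runif(n) < strength
      oneHot(ifelse(flip, letter, truth))
    },
    softmax_noise = {
      stopifnot(temperature > 0)
      old <- .seedScope(seed)
      on.exit(.restoreSeed(old), add = TRUE)
      logits <- matrix(stats::rnorm(n * 20), n, 20)
      logits[cbind(seq_len(n), match(truth, aa))] <-
        logits[cbind(seq_len(n), match(truth, aa))] + 2
      z <- exp(logits / temperature)
      m <- z / rowSums(z)
      dimnames(m) <- list(NULL, aa)
      m
    })
  new("PredictionSet", modelName = modelName, probs = p,
      chainKeys = chainKeys, positions = seq_len(n))
}

# run code under a given RNG seed without disturbing the caller's RNG state
.seedScope <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}
.restoreSeed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Fold-class composition of the full published benchmark
#'
#' Loads the packaged static composition table of the curated 595-structure
#' benchmark: number of chains per CATH fold class (mainly-alpha 70,
#' mainly-beta 282, alpha-beta 196, special 47). Shipped for composition
#' bookkeeping; the structures themselves are not bundled.
#'
#' @return \code{data.frame} with columns \code{fold_class}, \code{chains}.
#' @export
publishedComposition <- function() {
  path <- system.file("extdata", "benchmark_composition.csv",
                      package = "designbench", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a miniature synthetic benchmark to disk
#'
#' Generates a deterministic toy benchmark spanning all four CATH fold
#' classes: ideal-geometry structures (helical chains for mainly-alpha,
#' sheets for mainly-beta, mixed helix+strand for alpha-beta, irregular coil
#' for special) with seeded sequences and resolutions, a dataset map,
#' synthetic DSSP-style label files, and sidecar bookkeeping
#' (\code{planted_composition.csv} with the planted per-class chain counts
#' and a copy of the published benchmark composition table). Every file
#' passes the package's own readers; two runs with the same seed are
#' byte-identical.
#'
#' @param outDir Output directory (created if needed).
#' @param seed Integer seed.
#' @param chainsPerClass Chains per fold class (default 2, i.e. 8 chains).
#' @return Invisibly, a list with the dataset-map path, the truth sequences
#'   and the planted composition table.
#' @export
makeToyBenchmark <- function(outDir, seed = 7L, chainsPerClass = 2L) {
  ok <- dir.exists(outDir) || dir.create(outDir, recursive = TRUE,
                                         showWarnings = FALSE)
  if (!ok || file.access(outDir, 2L) != 0L)
    stop("cannot write to directory: ", outDir)
  dir.create(file.path(outDir, "structs"), showWarnings = FALSE)
  dir.create(file.path(outDir, "dssp"), showWarnings = FALSE)
  old <- .seedScope(seed)
  on.exit(.restoreSeed(old), add = TRUE)
  aa <- aminoAcids()

  classes <- data.frame(
    foldClass = .foldClasses,
    architecture = c("1.10", "2.40", "3.40", "6.10"),
    stringsAsFactors = FALSE)
  entries <- list(); truths <- list()
  for (ci in seq_len(nrow(classes))) {
    for (k in seq_len(chainsPerClass)) {
      pdbId <- sprintf("T%d%02d", ci, k)
      key <- paste0(pdbId, "_A")
      resol <- round(stats::runif(1, 1.2, 2.9), 2)
      n <- 18L + 2L * (k - 1L)
      seqs <- sample(aa, if (classes$foldClass[ci] == "mainly-beta") 16L else n,
                     replace = TRUE)
      chain <- switch(classes$foldClass[ci],
        "mainly-alpha" = makeIdealHelix(n, sequence = seqs, chainKey = key,
                                        resolution = resol),
        "mainly-beta" = makeAntiparallelSheet(8L, sequence = seqs,
                                              chainKey = key,
                                              resolution = resol),
        "alpha-beta" = {
          tor <- rbind(cbind(rep(-57, 10), rep(-47, 10)),
                       cbind(rep(-120, n - 10), rep(120, n - 10)))
          buildChainFromTorsions(tor, sequence = seqs, chainKey = key,
                                 resolution = resol)
        },
        "special" = {
          tor <- cbind(stats::runif(n, -150, -60), stats::runif(n, 60, 170))
          buildChainFromTorsions(tor, sequence = seqs, chainKey = key,
                                 resolution = resol)
        })
      pdbPath <- file.path("structs", paste0(tolower(pdbId), ".pdb"))
      writeBackbonePDB(chain, file.path(outDir, pdbPath))
      ss <- assignSecondaryStructure(chain)
      writeSyntheticDSSP(chain, ss$state8,
                         file.path(outDir, "dssp", paste0(tolower(pdbId), ".dssp")))
      entries[[key]] <- data.frame(chainKey = key,
                                   architecture = classes$architecture[ci],
                                   foldClass = classes$foldClass[ci],
                                   structurePath = pdbPath,
                                   stringsAsFactors = FALSE)
      truths[[key]] <- residueSequence(chain)
    }
  }
  dmap <- new("DatasetMap", entries = do.call(rbind, c(entries,
                                                       make.row.names = FALSE)))
  writeDatasetMap(dmap, file.path(outDir, "dataset_map.txt"))
  planted <- data.frame(fold_class = .foldClasses,
                        chains = rep(chainsPerClass, 4L))
  utils::write.csv(planted, file.path(outDir, "planted_composition.csv"),
                   row.names = FALSE, quote = FALSE)
  file.copy(system.file("extdata", "benchmark_composition.csv",
                        package = "designbench", mustWork = TRUE),
            file.path(outDir, "benchmark_composition.csv"), overwrite = TRUE)
  writeLines(unlist(lapply(names(truths), function(k)
    paste0(k, " ", paste(truths[[k]], collapse = "")))),
    file.path(outDir, "truth_sequences.txt"))
  invisible(list(datasetMap = file.path(outDir, "dataset_map.txt"),
                 truth = truths, planted = planted))
}

#' Write a synthetic DSSP-style file for a chain
#'
#' Emits the classic DSSP column layout (header line then one fixed-width
#' data line per residue) carrying the given 8-state labels. Synthetic:
#' the labels come from the caller, not from the DSSP program.
#'
#' @param chain A \linkS4class{BackboneStructure}.
#' @param ss8 Character vector of 8-state codes, one per residue.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeSyntheticDSSP <- function(chain, ss8, path) {
  stopifnot(nResidues(chain) == length(ss8))
  chainId <- sub(".*_", "", chain@chainKey)
  hdr <- c("==== Secondary Structure Definition, synthetic fixture ====",
           "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N    N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI    X-CA   Y-CA   Z-CA")
  lines <- vapply(seq_len(nResidues(chain)), function(i) {
    ss <- ifelse(ss8[i] == "C", " ", ss8[i])
    sprintf("%5d%5s %s %s  %s", i, chain@seqIds[i], chainId,
            chain@aaTrue[i], ss)
  }, "")
  writeLines(c(hdr, lines), path)
  invisible(path)
}
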