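test_that("dihedral convention: planar cis is 0, trans is 180, colinear errors", {
  expect_equal(dihedralAngle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 0)
  expect_equal(dihedralAngle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)), 180)
  expect_error(dihedralAngle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "colinear")
})

test_that("torsion round-trip through the chain builder is exact to 1e-6 degrees", {
  set.seed(21)
  for (k in 1:5) {
    n <- sample(4:25, 1)
    tor <- cbind(runif(n, -179, 179), runif(n, -179, 179))
    pp <- phiPsi(buildChainFromTorsions(tor))
    expect_lt(max(abs(pp$phi[-1] - tor[-1, 1])), 1e-6)
    expect_lt(max(abs(pp$psi[-n] - tor[-n, 2])), 1e-6)
    expect_true(is.na(pp$phi[1]) && is.na(pp$psi[n]))
  }
  # helix fixture: all interior pairs at the construction torsions
  pph <- phiPsi(makeIdealHelix(18))
  expect_lt(max(abs(pph$phi[-1] - (-57))), 1e-6)
  expect_lt(max(abs(pph$psi[-18] - (-47))), 1e-6)
})

test_that("absent torsions: single residues and missing neighbour atoms", {
  single <- buildChainFromTorsions(cbind(-57, -47))
  pp <- phiPsi(single)
  expect_true(is.na(pp$phi) && is.na(pp$psi))

  ch <- makeIdealHelix(8)
  co <- backboneCoords(ch)
  co[4, "C", ] <- NA_real_
  broken <- new("BackboneStructure", chainKey = chainKey(ch),
                seqIds = seqIds(ch), aaTrue = residueSequence(ch),
                coords = co, complete = replace(isComplete(ch), 4, FALSE),
                resolution = numeric(0))
  pp2 <- phiPsi(broken)
  expect_true(is.na(pp2$phi[5]))  # phi(i+1) needs C(i)
  expect_true(is.na(pp2$phi[4]) && is.na(pp2$psi[4]))
  expect_false(is.na(pp2$phi[3]))
})

test_that("dihedral is invariant under rigid motion and flips sign under mirror reflection", {
  set.seed(33)
  for (k in 1:10) {
    pts <- lapply(1:4, function(i) rnorm(3) * 3)
    ref <- tryCatch(do.call(dihedralAngle, pts), error = function(e) NULL)
    if (is.null(ref)) next
    R <- randomRotation(); t <- rnorm(3) * 10
    moved <- lapply(pts, function(p) as.numeric(R %*% p) + t)
    expect_equal(do.call(dihedralAngle, moved), ref, tolerance = 1e-9)
    mirrored <- lapply(pts, function(p) p * c(1, 1, -1))
    m <- do.call(dihedralAngle, mirrored)
    if (abs(abs(ref) - 180) > 1e-9)  # +/-180 are the same torsion
      expect_equal(m, -ref, tolerance = 1e-9)
  }
})

test_that("Ramachandran comparison: histogram totals, perfect and constant predictors, degenerate input", {
  set.seed(44)
  n <- 60
  tor <- cbind(runif(n, -179, 179), runif(n, -179, 179))
  ch <- buildChainFromTorsions(tor)
  pp <- phiPsi(ch)
  truth <- sample(aminoAcids(), n, replace = TRUE)

  tab <- ramachandranComparison(pp, truth, truth)
  # identical labelings: identical histograms per amino acid
  tt <- tab[tab$mode == "true", c("aa", "phi_bin", "psi_bin", "count")]
  pt <- tab[tab$mode == "predicted", c("aa", "phi_bin", "psi_bin", "count")]
  rownames(tt) <- rownames(pt) <- NULL
  expect_identical(tt, pt)
  # each histogram's counts sum to its contributing residues
  defined <- is.finite(pp$phi) & is.finite(pp$psi)
  for (a in unique(truth)) {
    expect_equal(sum(tab$count[tab$aa == a & tab$mode == "true"]),
                 sum(defined & truth == a))
  }
  # all bin edges on the 10-degree grid within (-180, 180]
  expect_true(all(tab$phi_bin %% 10 == 0 & tab$phi_bin >= -180 &
                  tab$phi_bin <= 170))

  # constant-G predictor: all predicted mass in G, none elsewhere
  tabG <- ramachandranComparison(pp, truth, rep("G", n))
  predRows <- tabG[tabG$mode == "predicted", ]
  expect_true(all(predRows$aa == "G"))
  expect_equal(sum(predRows$count), sum(defined))

  empty <- ramachandranComparison(data.frame(phi = numeric(0),
                                             psi = numeric(0)),
                                  character(0), character(0))
  expect_equal(nrow(empty), 0L)
  expect_error(ramachandranComparison(pp, truth, truth[-1]), "length")
})
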