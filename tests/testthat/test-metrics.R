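aa <- aminoAcids()

oneHotMatrix <- function(letters) {
  m <- matrix(0, length(letters), 20, dimnames = list(NULL, aa))
  m[cbind(seq_along(letters), match(letters, aa))] <- 1
  m
}

test_that("confusion matrix: identity, constant predictor, brute-force agreement", {
  set.seed(7)
  truth <- sample(aa, 50, replace = TRUE)
  sc <- scoredResidues(truth, oneHotMatrix(truth))
  cm <- buildConfusion(sc)
  expect_equal(sum(diag(cm)), 50L)
  expect_equal(sum(cm), 50L)

  scA <- scoredResidues(truth, oneHotMatrix(rep("A", 50)))
  cmA <- buildConfusion(scA)
  expect_true(all(cmA[, setdiff(aa, "A")] == 0))
  expect_equal(sum(cmA[, "A"]), 50L)

  sc2 <- randomScored(200, seed = 101)
  expect_identical(buildConfusion(sc2), bruteConfusion(sc2$aaTrue, sc2$pred))

  expect_error(buildConfusion(sc2[0, ]), "zero residues")
})

test_that("per-class metrics on a perfect predictor are the identity values", {
  set.seed(8)
  truth <- sample(aa, 120, replace = TRUE)
  pc <- perClassMetrics(scoredResidues(truth, oneHotMatrix(truth)))
  present <- pc$n_true > 0
  expect_true(all(pc$recall[present] == 1))
  expect_true(all(pc$precision[present] == 1))
  expect_true(all(pc$f1[present] == 1))
  expect_true(all(pc$auc[present] == 1))
  expect_true(all(pc$entropy_bits[present] == 0))
  expect_true(all(pc$bias[present] == 0))
  expect_true(all(is.na(pc$recall[!present])))
})

test_that("prediction bias is (n_pred - n_true) / n_true with -1 for never-predicted", {
  # 10 true D of which 5 predicted D, plus 10 predicted D from true E;
  # class Y: 10 true, never predicted
  truth <- c(rep("D", 10), rep("E", 10), rep("Y", 10))
  pred <- c(rep("D", 5), rep("A", 5), rep("D", 10), rep("A", 10))
  pc <- perClassMetrics(scoredResidues(truth, oneHotMatrix(pred)))
  expect_equal(pc$bias[pc$aa == "D"], (15 - 10) / 10)   # +0.5
  expect_equal(pc$bias[pc$aa == "Y"], -1)
  expect_true(is.na(pc$bias[pc$aa == "W"]))             # no truth occurrences
})

test_that("per-class AUC equals the brute-force pairwise oracle within 1e-9", {
  for (seed in c(301, 302, 303)) {
    sc <- randomScored(300, seed = seed)
    pc <- perClassMetrics(sc)
    for (a in aa) {
      oracle <- bruteAUC(sc$probs[, a], sc$aaTrue == a)
      if (is.na(oracle)) expect_true(is.na(pc$auc[pc$aa == a]))
      else expect_equal(pc$auc[pc$aa == a], oracle, tolerance = 1e-9)
    }
  }
})

test_that("confusion-row entropy: zero when pure, log2(20) when uniform", {
  # class A predicted uniformly across all 20 letters, 5 times each
  truth <- rep("A", 100)
  pred <- rep(aa, each = 5)
  pc <- perClassMetrics(scoredResidues(truth, oneHotMatrix(pred)))
  expect_equal(pc$entropy_bits[pc$aa == "A"], log2(20), tolerance = 1e-12)
})

test_that("group metrics: identity case, macro-recall arithmetic, similarity vs accuracy", {
  set.seed(9)
  truth <- sample(aa, 80, replace = TRUE)
  g <- groupMetrics(scoredResidues(truth, oneHotMatrix(truth)))
  expect_equal(g$accuracy, 1); expect_equal(g$macro_recall, 1)
  expect_equal(g$similarity, 1); expect_equal(g$top3, 1)

  # two classes with recalls 1.0 and 0.5 average to 0.75
  truth2 <- c(rep("A", 10), rep("C", 10))
  pred2 <- c(rep("A", 10), rep("C", 5), rep("A", 5))
  g2 <- groupMetrics(scoredResidues(truth2, oneHotMatrix(pred2)))
  expect_equal(g2$macro_recall, 0.75)

  # L predicted as I: a positive BLOSUM62 substitution, so similar but wrong
  expect_gt(similarityMatrix()["L", "I"], 0)
  g3 <- groupMetrics(scoredResidues(rep("L", 10), oneHotMatrix(rep("I", 10))))
  expect_equal(g3$accuracy, 0)
  expect_equal(g3$similarity, 1)
})

test_that("constant majority predictor on a 90/10 set: accuracy 0.9 but macro-recall 0.5", {
  truth <- c(rep("L", 90), rep("W", 10))
  g <- groupMetrics(scoredResidues(truth, oneHotMatrix(rep("L", 100))))
  expect_equal(g$accuracy, 0.9)
  expect_equal(g$macro_recall, 0.5)
})

test_that("bounds and ordering invariants hold on random instances", {
  for (seed in c(601, 602)) {
    sc <- randomScored(250, seed = seed, concentration = 2)
    g <- groupMetrics(sc)
    expect_gte(g$top3, g$accuracy)
    expect_true(all(unlist(g[c("accuracy", "macro_precision", "macro_recall",
                               "similarity", "top3")]) >= 0))
    expect_true(all(unlist(g[c("accuracy", "macro_precision", "macro_recall",
                               "similarity", "top3")]) <= 1))
    pc <- perClassMetrics(sc)
    ok <- !is.na(pc$entropy_bits)
    expect_true(all(pc$entropy_bits[ok] >= 0 & pc$entropy_bits[ok] <= log2(20)))
    expect_true(all(pc$bias[!is.na(pc$bias)] >= -1))
    # permutation invariance
    perm <- sample(nrow(sc))
    expect_equal(groupMetrics(sc[perm, ]), g)
  }
})

test_that("stratified metrics: partition identity and exact accuracy conservation", {
  sc <- randomScored(300, seed = 71)
  one <- stratifiedMetrics(sc, rep("all", nrow(sc)))
  expect_equal(one[, -1], groupMetrics(sc))

  for (seed in 1:10) {
    set.seed(seed)
    strata <- sample(letters[1:sample(2:6, 1)], nrow(sc), replace = TRUE)
    st <- stratifiedMetrics(sc, strata)
    weighted <- sum(st$accuracy * st$n_residues) / sum(st$n_residues)
    expect_equal(weighted, groupMetrics(sc)$accuracy, tolerance = 1e-12)
    expect_equal(sum(st$n_residues), nrow(sc))
  }
})

test_that("resolution correlation: exact cases and direct-formula oracle", {
  res <- c(1, 1.5, 2, 2.5, 3)
  acc <- 1 - 0.2 * res  # exactly linear, negative slope
  expect_equal(resolutionCorrelation(data.frame(accuracy = acc,
                                                resolution = res)), -1)
  expect_warning(
    r0 <- resolutionCorrelation(data.frame(accuracy = rep(0.5, 5),
                                           resolution = res)),
    "zero variance")
  expect_true(is.na(r0))
  expect_warning(
    r1 <- resolutionCorrelation(data.frame(accuracy = c(0.2, 0.4),
                                           resolution = c(1, 2))),
    "fewer than 3")
  expect_true(is.na(r1))

  set.seed(55)
  df <- data.frame(accuracy = runif(50), resolution = runif(50, 1, 3))
  df$resolution[c(3, 9)] <- NA  # chains without resolution are excluded
  keep <- is.finite(df$resolution)
  expect_equal(resolutionCorrelation(df),
               brutePearson(df$accuracy[keep], df$resolution[keep]),
               tolerance = 1e-12)
})
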