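# shared end-to-end scaffold: one toy benchmark per test file run
localBenchmark <- function(env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  info <- makeToyBenchmark(dir, seed = 7)
  truth <- unlist(info$truth, use.names = FALSE)
  keys <- rep(names(info$truth), lengths(info$truth))
  list(dir = dir, info = info, truth = truth, keys = keys,
       dmap = readDatasetMap(file.path(dir, "dataset_map.txt"),
                             verbose = FALSE))
}

test_that("perfect predictor end-to-end: every metric is the identity value in every stratum", {
  bm <- localBenchmark()
  preds <- makePredictions(bm$truth, "perfect", chainKeys = bm$keys,
                           modelName = "perfect")
  rep1 <- buildModelReport(preds, bm$dmap, baseDir = bm$dir)
  g <- globalMetrics(rep1)
  expect_equal(g$accuracy, 1); expect_equal(g$macro_recall, 1)
  expect_equal(g$similarity, 1); expect_equal(g$top3, 1)
  for (which in c("chain", "ss", "fold_class", "architecture")) {
    st <- strataMetrics(rep1, which)
    expect_true(all(st$accuracy == 1), label = which)
  }
  pc <- perClass(rep1)
  present <- pc$n_true > 0
  expect_true(all(pc$bias[present] == 0))
  expect_true(all(pc$entropy_bits[present] == 0))
  cm <- confusionMatrix(rep1)
  expect_equal(sum(diag(cm)), sum(cm))
  # all four stratifications partition the same scored set
  expect_equal(sum(strataMetrics(rep1, "ss")$n_residues), g$n_residues)
  expect_equal(sum(strataMetrics(rep1, "fold_class")$n_residues), g$n_residues)
})

test_that("constant-argmax predictor end-to-end accuracy equals the alanine fraction", {
  bm <- localBenchmark()
  preds <- makePredictions(bm$truth, "constant", letter = "A",
                           chainKeys = bm$keys, modelName = "constA")
  rep1 <- buildModelReport(preds, bm$dmap, baseDir = bm$dir)
  expect_equal(globalMetrics(rep1)$accuracy, mean(bm$truth == "A"))
})

test_that("builtin and DSSP-import secondary-structure routes agree on the toy benchmark", {
  bm <- localBenchmark()
  preds <- makePredictions(bm$truth, "perfect", chainKeys = bm$keys)
  r1 <- buildModelReport(preds, bm$dmap, baseDir = bm$dir)
  r2 <- buildModelReport(preds, bm$dmap, baseDir = bm$dir,
                         ssSource = "dssp-dir",
                         dsspDir = file.path(bm$dir, "dssp"))
  expect_equal(strataMetrics(r1, "ss"), strataMetrics(r2, "ss"))
})

test_that("validation errors: unknown chains and row-count mismatches are loud", {
  bm <- localBenchmark()
  ghost <- makePredictions(c("A", "C"), "perfect",
                           chainKeys = rep("ZZZZ_A", 2))
  expect_error(buildModelReport(ghost, bm$dmap, baseDir = bm$dir),
               "missing from dataset map.*ZZZZ_A")
  short <- makePredictions(bm$truth[-1], "perfect",
                           chainKeys = bm$keys[-1], modelName = "short")
  expect_error(buildModelReport(short, bm$dmap, baseDir = bm$dir),
               "prediction rows but")
})

test_that("unknown residues are excluded from scoring and counted per chain", {
  dir <- withr::local_tempdir()
  ch <- makeIdealHelix(8, chainKey = "UNK1_A", resolution = 2.0)
  pdb <- file.path(dir, "unk1.pdb")
  writeBackbonePDB(ch, pdb)
  # swap residue 3's name for an unmappable code
  lines <- readLines(pdb)
  lines <- gsub("ALA A   3", "XXX A   3", lines)
  writeLines(lines, pdb)
  dmap <- new("DatasetMap", entries = data.frame(
    chainKey = "UNK1_A", architecture = "1.10",
    foldClass = "mainly-alpha", structurePath = pdb))
  preds <- makePredictions(residueSequence(ch)[-3], "perfect",
                           chainKeys = rep("UNK1_A", 7))
  rep1 <- buildModelReport(preds, dmap)
  expect_equal(globalMetrics(rep1)$n_residues, 7L)
  ex <- exclusions(rep1)
  expect_equal(ex$n_excluded_unknown, 1L)
  expect_equal(ex$n_scored, 7L)
})

test_that("model comparison: identical sets required, dominance, deterministic ordering", {
  bm <- localBenchmark()
  mk <- function(kind, name, ...) {
    ps <- makePredictions(bm$truth, kind, chainKeys = bm$keys,
                          modelName = name, ...)
    buildModelReport(ps, bm$dmap, baseDir = bm$dir)
  }
  perfect <- mk("perfect", "perfect")
  constA <- mk("constant", "constA", letter = "A")
  tab <- compareModels(list(perfect, constA))
  expect_equal(tab$model, c("perfect", "constA"))  # input order kept
  strata <- setdiff(names(tab), "model")
  expect_true(all(tab[1, strata] >= tab[2, strata]))

  tab2 <- compareModels(list(perfect, perfect))
  expect_equal(unlist(tab2[1, -1]), unlist(tab2[2, -1]))

  # planted noise ordering: stronger bias away from truth -> lower accuracy
  b25 <- mk("biased", "b25", letter = "G", strength = 0.25, seed = 5)
  b75 <- mk("biased", "b75", letter = "G", strength = 0.75, seed = 5)
  tab3 <- compareModels(list(perfect, b25, b75))
  expect_true(all(diff(rev(tab3$global)) > 0))

  # a report over a different residue set is refused
  sub <- bm$truth[bm$keys != bm$keys[1]]
  subKeys <- bm$keys[bm$keys != bm$keys[1]]
  other <- buildModelReport(
    makePredictions(sub, "perfect", chainKeys = subKeys, modelName = "sub"),
    bm$dmap, baseDir = bm$dir)
  expect_error(compareModels(list(perfect, other)), "different residue sets")
})

test_that("report CSVs: structural row counts, composition bookkeeping, byte determinism", {
  bm <- localBenchmark()
  preds <- makePredictions(bm$truth, "softmax_noise", chainKeys = bm$keys,
                           modelName = "noisy", seed = 3)
  rep1 <- buildModelReport(preds, bm$dmap, baseDir = bm$dir)
  constG <- buildModelReport(
    makePredictions(bm$truth, "constant", letter = "G",
                    chainKeys = bm$keys, modelName = "constG"),
    bm$dmap, baseDir = bm$dir)
  comparison <- compareModels(list(rep1, constG))

  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  writeReport(rep1, out1); renderPlots(rep1, out1, comparison = comparison)
  writeReport(rep1, out2); renderPlots(rep1, out2, comparison = comparison)

  bias <- read.csv(file.path(out1, "bias_abundance.csv"))
  expect_equal(nrow(bias), 20L)
  confusion <- read.csv(file.path(out1, "confusion.csv"))
  expect_equal(nrow(confusion), 400L)
  comp <- read.csv(file.path(out1, "comparison.csv"))
  expect_equal(nrow(comp), 2L * 5L)  # 2 models x (global + 4 fold classes)

  # composition bookkeeping matches the planted per-class chain counts
  composition <- read.csv(file.path(out1, "composition.csv"))
  planted <- read.csv(file.path(bm$dir, "planted_composition.csv"))
  expect_equal(composition$n_chains[match(planted$fold_class,
                                          composition$fold_class)],
               planted$chains)

  # accuracy-resolution panel has the Pearson r when defined
  expect_true(file.exists(file.path(out1, "accuracy_resolution.csv")))

  for (f in list.files(out1, pattern = "\\.csv$")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }
})

test_that("the command-line interface runs end-to-end with exit codes 0 and 2", {
  cli <- system.file("cli", "designbench.R", package = "designbench")
  dir <- withr::local_tempdir()
  rscript <- file.path(R.home("bin"), "Rscript")
  s1 <- system2(rscript, c(cli, "fixtures", "--out", shQuote(dir),
                           "--seed", "7"), stdout = FALSE, stderr = FALSE)
  expect_equal(s1, 0L)
  truthLines <- strsplit(readLines(file.path(dir, "truth_sequences.txt")), " ")
  preds <- do.call(rbind, lapply(truthLines, function(tl) {
    truth <- strsplit(tl[2], "")[[1]]
    as.data.frame(predictionMatrix(makePredictions(truth, "perfect")),
                  check.names = FALSE) |>
      cbind(chain_key = tl[1], position = seq_along(truth)) |>
      (\(d) d[, c("chain_key", "position", aminoAcids())])()
  }))
  predCsv <- file.path(dir, "perfect.csv")
  write.csv(preds, predCsv, row.names = FALSE, quote = FALSE)
  out <- file.path(dir, "out")
  s2 <- system2(rscript, c(cli, "run", "--predictions", shQuote(predCsv),
                           "--dataset-map",
                           shQuote(file.path(dir, "dataset_map.txt")),
                           "--structures", shQuote(dir),
                           "--out", shQuote(out)),
                stdout = FALSE, stderr = FALSE)
  expect_equal(s2, 0L)
  summary <- read.csv(file.path(out, "summary.csv"))
  expect_equal(summary$accuracy, 1)
  s3 <- system2(rscript, c(cli, "run", "--predictions", "nope.csv",
                           "--dataset-map", "nope.txt", "--out",
                           shQuote(out)), stdout = FALSE, stderr = FALSE)
  expect_equal(s3, 2L)
})
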