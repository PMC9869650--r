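# Independent brute-force oracles the metric tests compare against.
# These deliberately share no code with the package implementations.

bruteConfusion <- function(aaTrue, pred) {
  aa <- aminoAcids()
  m <- matrix(0L, 20, 20, dimnames = list(aa, aa))
  for (i in seq_along(aaTrue))
    for (a in aa) for (b in aa)
      if (aaTrue[i] == a && pred[i] == b) m[a, b] <- m[a, b] + 1L
  m
}

# one-vs-rest AUC by explicit pairwise comparison: concordant pairs count 1,
# score ties count 1/2
bruteAUC <- function(scores, positive) {
  pos <- which(positive); neg <- which(!positive)
  if (!length(pos) || !length(neg)) return(NA_real_)
  total <- 0
  for (i in pos) for (j in neg) {
    if (scores[i] > scores[j]) total <- total + 1
    else if (scores[i] == scores[j]) total <- total + 0.5
  }
  total / (length(pos) * length(neg))
}

# textbook covariance-formula Pearson correlation
brutePearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sxy / (sqrt(sum((x - mean(x))^2) / (n - 1)) *
         sqrt(sum((y - mean(y))^2) / (n - 1)))
}

# random scored-residue tables with probabilistic predictions
randomScored <- function(n, seed, concentration = 1) {
  set.seed(seed)
  aa <- aminoAcids()
  truth <- sample(aa, n, replace = TRUE)
  p <- matrix(stats::rexp(n * 20), n, 20)
  p[cbind(seq_len(n), match(truth, aa))] <-
    p[cbind(seq_len(n), match(truth, aa))] + concentration
  p <- p / rowSums(p)
  colnames(p) <- aa
  scoredResidues(truth, p,
                 foldClass = sample(c("mainly-alpha", "mainly-beta",
                                      "alpha-beta", "special"),
                                    n, replace = TRUE))
}

randomRotation <- function() {
  # QR of a random Gaussian matrix, sign-fixed to a proper rotation
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
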