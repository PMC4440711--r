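# Shared fixtures built in code.

# A toy PWM with distinct, reproducible cell values.
toy_pwm <- function(seed = 11, offset = -5, threshold = 0.5) {
  set.seed(seed)
  M <- matrix(round(stats::runif(100, -3, 3), 3), 20, 5,
              dimnames = list(cleavescan:::AA_ALPHABET,
                              cleavescan:::SUBSITES))
  pwm(M, offset = offset, threshold = threshold, enzyme = "toy")
}

# A strictly positive frequency_matrix (no offset cells touched) on which
# 2^score equals the product of frequency ratios.
positive_freq <- function(seed = 5) {
  set.seed(seed)
  P <- matrix(stats::runif(100, 0.2, 1), 20, 5)
  P <- sweep(P, 2, colSums(P), "/")
  Pb <- matrix(stats::runif(100, 0.2, 1), 20, 5)
  Pb <- sweep(Pb, 2, colSums(Pb), "/")
  dimnames(P) <- dimnames(Pb) <- list(cleavescan:::AA_ALPHABET,
                                      cleavescan:::SUBSITES)
  fm <- list(P = P, Pbckgr = Pb, n_substrates = 50L, n_excluded = 0L)
  class(fm) <- "frequency_matrix"
  fm
}

random_window <- function(n = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(cleavescan:::AA_ALPHABET, 5, replace = TRUE), collapse = ""),
    character(1))
}

# Small substrate set written in dash notation for IO tests.
write_toy_substrates <- function(path, lines = c("ggsgPSA-LDAtasgaet",
                                                 "ggsgAAA-LVKtasgaet",
                                                 "ggsgKPL-GLWtasgaet")) {
  writeLines(c("# toy substrates", lines), path)
  path
}

# Brute-force AUC: pair counting with ties worth one half.
auc_bruteforce <- function(score, label) {
  pos <- score[label == 1]
  neg <- score[label == 0]
  pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(pairs)
}
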