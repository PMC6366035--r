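# Shared fixtures for the suite, built in code.

# Printed reporter-construct motif with full complementarity to the mature
# miR-21 target, and the mature miR-21 sequence.
MIR21_MATURE <- "UAGCUUAUCAGACUGAUGUUGA"
MIR21_TARGET_MOTIF <- "TCAACATCAGTCTGATAAGCTAAA"

# small deterministic mature miRNA set for scanner fixtures
fixture_matures <- function(n = 5L, len = 22L, seed = 101L) {
  set.seed(seed)
  out <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  }, character(1L))
  names(out) <- sprintf("mir_%02d", seq_len(n))
  out
}

# brute-force sliding-window oracle for non-overlapping pattern counting
oracle_scan <- function(utr, site) {
  n <- nchar(utr); k <- nchar(site)
  count <- 0L
  i <- 1L
  while (i + k - 1L <= n) {
    if (substr(utr, i, i + k - 1L) == site) {
      count <- count + 1L
      i <- i + k
    } else {
      i <- i + 1L
    }
  }
  count
}

# rank-then-Pearson Spearman oracle (average ranks for ties)
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# small synthetic model instance used across model tests
small_sim <- function(seed = 7L, noise_sd = 0, n_mrna = 200L, n_mirna = 12L,
                      n_active = n_mirna) {
  simulate_dataset(n_mrna = n_mrna, n_mirna = n_mirna, n_active = n_active,
                   noise_sd = noise_sd, seed = seed)
}
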