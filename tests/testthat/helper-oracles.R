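# Independent oracles used across test files.

# Brute-force triplet classifier: tests the four explicit pattern-consistent
# forms (4-r-3, 3-r-2, 2-r-1, 1-r-4) rather than the successor arithmetic.
brute_triplet <- function(p1, p2, p3) {
  if (p1 == p2 && p2 == p3) return("repetition")
  if (p1 == p3) return("span")
  forms <- list(c(4, 3), c(3, 2), c(2, 1), c(1, 4))
  for (f in forms) {
    if (p1 == f[1] && p3 == f[2]) return("pattern_consistent")
  }
  "inconsistent"
}

# Exhaustive-permutation directional p-value for the Welch statistic (the
# same studentized statistic is recomputed under every group relabelling;
# permuting the raw mean difference would be a different test when variances
# or sizes differ).
perm_welch_p <- function(on, off) {
  welch_t <- function(a, b) {
    (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
  }
  pooled <- c(on, off)
  n1 <- length(on)
  obs <- welch_t(on, off)
  picks <- utils::combn(length(pooled), n1)
  stats <- apply(picks, 2, function(i) welch_t(pooled[i], pooled[-i]))
  mean(stats >= obs - 1e-12)
}

# Small cohort simulated once per file when needed.
make_profiles <- function(n, condition = "single", ...) {
  lapply(seq_len(n), function(i) {
    agent_profile(sprintf("t_%03d", i), condition, ...)
  })
}
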