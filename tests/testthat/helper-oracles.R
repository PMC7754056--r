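# Independent brute-force oracles used to pin expected values. They share no
# code with the implementation paths they check.

# P(X >= k) for a hypergeometric draw, by enumerating every size-n subset of
# a population whose first K members are marked.
oracle_hyper_upper_tail <- function(N, K, n, k) {
  if (n == 0L) return(if (k <= 0L) 1 else 0)
  subsets <- utils::combn(N, n)
  overlaps <- colSums(subsets <= K)
  mean(overlaps >= k)
}

# One-sided rank-sum p-value by enumerating every assignment of the pooled
# values to the "high" group; the statistic is counted as Mann-Whitney pairs
# (strict wins + half-credit ties), a different route from rank sums. A large
# count of (high < low) pairs is evidence for "high stochastically smaller",
# so the p-value is the upper tail of U' = #{a < b} + 0.5 #{a == b}.
oracle_ranksum_less <- function(high, low) {
  pooled <- c(high, low)
  n <- length(pooled); n1 <- length(high)
  u_of <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sum(outer(a, b, `<`)) + 0.5 * sum(outer(a, b, `==`))
  }
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(n, n1)
  u_all <- apply(combos, 2L, u_of)
  mean(u_all >= u_obs - 1e-9)
}

# Exhaustive null pair-count distribution for a small two-stratum instance:
# all C(|low|, n_cases) x C(|high|, n_controls) splits.
oracle_null_pair_distribution <- function(v_low, v_high, n_cases, n_controls) {
  lows <- utils::combn(length(v_low), n_cases)
  highs <- utils::combn(length(v_high), n_controls)
  counts <- integer(0)
  for (i in seq_len(ncol(lows)))
    for (j in seq_len(ncol(highs)))
      counts <- c(counts, sum(outer(v_low[lows[, i]], v_high[highs[, j]], `<`)))
  counts
}

# A small healthy cohort with named dimensions, for plumbing tests.
toy_matrix <- function(n_genes = 20L, n_samples = 50L, seed = 1L) {
  set.seed(seed)
  m <- matrix(rlnorm(n_genes * n_samples, 2, 0.4), nrow = n_genes,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%03d", seq_len(n_samples))))
  m
}

write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
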