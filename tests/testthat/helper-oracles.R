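# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and, where possible, the same base R routine).

# upper-tail binomial probability by direct log-space summation
oracle_binom_tail <- function(k, n, p) {
  if (k <= 0) {
    return(1)
  }
  if (k > n) {
    return(0)
  }
  ks <- k:n
  sum(exp(lchoose(n, ks) + ks * log(p) + (n - ks) * log1p(-p)))
}

# BH step-up by hand: sort, p * m / rank, cumulative min from the top,
# unsort, cap at 1
oracle_bh <- function(p) {
  m <- length(p)
  if (m == 0) {
    return(numeric(0))
  }
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# hypergeometric upper tail P(X >= k) by exhaustive enumeration of all
# C(N, n) draws (N <= 12)
oracle_hyper_tail <- function(k, K, n, N) {
  stopifnot(N <= 12)
  members <- seq_len(N) <= K
  draws <- utils::combn(N, n)
  hits <- colSums(matrix(members[draws], nrow = n))
  mean(hits >= k)
}

# two-sided exact rank-sum p-value by enumeration of all group assignments,
# replicating the two-tail doubling rule of the exact Wilcoxon test
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  m <- length(a)
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  sets <- utils::combn(length(pooled), m)
  ws <- colSums(matrix(r[sets], nrow = m)) - m * (m + 1) / 2
  p_low <- mean(ws <= w_obs)
  p_high <- mean(ws >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

# Pearson chi-squared from first principles
oracle_chi2 <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# codon translation via seqinr (independent of Biostrings' GENETIC_CODE)
oracle_translate <- function(codon) {
  seqinr::translate(strsplit(tolower(codon), "")[[1]])
}

oracle_coding_effect <- function(codon, pos_in_codon, alt_base) {
  edited <- codon
  substr(edited, pos_in_codon, pos_in_codon) <- alt_base
  aa_ref <- oracle_translate(codon)
  aa_alt <- oracle_translate(edited)
  if (aa_ref == aa_alt) {
    "synonymous"
  } else if (aa_ref == "*") {
    "stop_loss"
  } else if (aa_alt == "*") {
    "stop_gain"
  } else {
    "nonsynonymous"
  }
}

# 99% binomial confidence interval (normal approximation) around p0
binom_ci99 <- function(p0, n) {
  hw <- 2.576 * sqrt(p0 * (1 - p0) / n)
  c(p0 - hw, p0 + hw)
}
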