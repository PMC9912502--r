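# Brute-force statistical oracles, independent of the implementation paths
# they check.

# KS D by double loop over the pooled support
brute_ks_D <- function(s1, s2) {
  xs <- sort(unique(c(s1, s2)))
  max(vapply(xs, function(x) abs(mean(s1 <= x) - mean(s2 <= x)), 0))
}

# Fisher two-sided p by summing hypergeometric point probabilities no
# larger than the observed table's, conditioning on both margins
brute_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  qs <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(qs, r1, r2, c1)
  pobs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# Exact two-sided rank-sum p by enumerating every assignment of ranks to
# group 1 (no ties assumed); doubles the smaller tail as wilcox.test does
brute_wilcox_p <- function(g1, g2) {
  n1 <- length(g1)
  pooled <- c(g1, g2)
  rks <- rank(pooled)
  W_obs <- sum(rks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  Ws <- apply(combs, 2, function(idx) sum(rks[idx]) - n1 * (n1 + 1) / 2)
  p <- if (W_obs > n1 * length(g2) / 2) mean(Ws >= W_obs) else
    mean(Ws <= W_obs)
  min(1, 2 * p)
}

# Hypergeometric over-representation p by enumerating every possible
# category draw of size n from a universe of size N with m annotated genes
brute_hyper_p <- function(q, m, N, n) {
  sets <- utils::combn(N, n)
  annotated <- seq_len(m)  # wlog the first m universe genes are annotated
  hits <- apply(sets, 2, function(s) sum(s %in% annotated))
  mean(hits >= q)
}

# Benjamini-Hochberg from the definition
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(adj, 1)[order(o)]
}

# small deterministic count fixture: 3 transcripts x 6 samples, one cross
toy_count_matrix <- function() {
  counts <- matrix(c(10L, 20L, 12L, 18L, 15L, 16L,
                     100L, 110L, 95L, 105L, 98L, 102L,
                     5L, 5L, 5L, 5L, 5L, 5L),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(paste0("t", 1:3),
                                   paste0("s", 1:6)))
  samples <- tibble::tibble(
    sample_id = paste0("s", 1:6), cross_id = "cr1",
    role = rep(c("parent1", "parent2", "F1"), each = 2),
    replicate = rep(1:2, 3))
  count_matrix(counts, samples)
}

# DE-like tibble straight from chosen role means (bypasses testing)
means_to_de <- function(X1, X2, F1, cross_id = "cr1",
                        ids = sprintf("g%04d", seq_along(X1))) {
  tibble::tibble(cross_id = cross_id, transcript_id = ids,
                 X1_bar = X1, X2_bar = X2, F1_bar = F1,
                 log2FC = log2(X1 / X2), pvalue = 0, padj = 0,
                 is_DE = TRUE)
}
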