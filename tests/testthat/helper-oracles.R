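# Independent brute-force oracles used to pin expected values.

# Exact hypergeometric upper tail by rational enumeration: for N <= 12 every
# binomial coefficient is a small exact integer, so the sum of fractions is
# exact to double rounding.
oracleHypergeomSF <- function(k, N, K, n) {
  if (k <= max(0, K + n - N)) return(1)
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Exact binomial-split two-sided p-value for equal group sizes: conditional
# probability of each split is C(t, y) / 2^t, an exact dyadic rational.
# Enumerates all splits and sums those no more probable than the observed.
oracleBinomSplitEqual <- function(y1, t) {
  num <- choose(t, 0:t)            # exact integers up to C(30,15)
  sum(num[num <= num[y1 + 1]]) / 2^t
}

# Brute-force binomial-split p-value for arbitrary group sizes, enumerated
# directly on the probability scale (independent of the log-space path).
oracleBinomSplitGeneral <- function(y1, t, n1, n2) {
  probs <- dbinom(0:t, t, n1 / (n1 + n2))
  sum(probs[probs <= probs[y1 + 1] * (1 + 1e-7)])
}

# Exhaustive Spearman null for n = 6 without ties: distribution of rho over
# all 720 rank permutations.
spearmanNull6 <- function() {
  perms <- function(v) {
    if (length(v) == 1) return(matrix(v, 1))
    out <- NULL
    for (i in seq_along(v))
      out <- rbind(out, cbind(v[i], perms(v[-i])))
    out
  }
  p <- perms(1:6)
  apply(p, 1, function(r) cor(r, 1:6, method = "spearman"))
}

# Small deterministic hand-built network: 2 triads sharing nothing.
toyNetwork <- function() {
  retained <- data.frame(
    id_a = c("mir1", "mir1", "mir2", "mir2"),
    id_b = c("circ1", "gene1", "circ2", "gene2"),
    pair_type = c("mirna_circ", "mirna_mrna", "mirna_circ", "mirna_mrna"),
    method = "spearman",
    coefficient = c(-0.9, -0.85, -0.95, -0.8),
    n_samples = 6L, stringsAsFactors = FALSE)
  sponge <- data.frame(
    circ_id = c("circ1", "circ2"), mrna_id = c("gene1", "gene2"),
    k = 1L, K = 1L, n = 1L, N = 50L,
    pvalue = c(0.02, 0.02), pcc = c(0.95, 0.97),
    shared_mirnas = c("mir1", "mir2"), stringsAsFactors = FALSE)
  buildNetwork(retained, sponge, tissue = "toy")
}
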