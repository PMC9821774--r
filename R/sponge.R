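#' Hypergeometric shared-sponge test over candidate circRNA-mRNA pairs
#'
#' Step three of the ceRNA construction. For each candidate pair, let `K` be
#' the number of miRNAs negatively paired with the circRNA, `n` the number
#' negatively paired with the mRNA (both among the retained negative pairs),
#' `k` their intersection, and `N` the miRNA universe size. The pair is
#' scored with the hypergeometric upper tail `P(X >= k)` and retained iff
#' `p < alpha` (strict; default 0.05). Optionally, BH adjustment can be
#' applied before gating (off by default; the adjusted column is then used
#' for the gate and flagged in the output).
#'
#' @param candidatePairs output of [filterCernaPairs()].
#' @param retainedPairs output of [filterMirnaTargetPairs()] (defines the
#'   per-transcript miRNA sets).
#' @param universeSize miRNA universe size `N` (positive integer).
#' @param alpha strict retention cutoff on the (possibly adjusted) p-value.
#' @param adjust apply BH across candidate pairs before gating.
#' @return data.frame of retained sponge edges: `circ_id`, `mrna_id`, `k`,
#'   `K`, `n`, `N`, `pvalue`, `pcc`, `shared_mirnas`; attribute `"tested"`
#'   holds the number of candidates scored and attribute `"adjusted"`
#'   whether BH was applied.
#' @export
spongeTest <- function(candidatePairs, retainedPairs, universeSize,
                       alpha = 0.05, adjust = FALSE) {
  if (length(universeSize) != 1 || is.na(universeSize) || universeSize < 1)
    stop("configuration error: empty miRNA universe")
  circSets <- split(retainedPairs$id_a[retainedPairs$pair_type == "mirna_circ"],
                    retainedPairs$id_b[retainedPairs$pair_type == "mirna_circ"])
  mrnaSets <- split(retainedPairs$id_a[retainedPairs$pair_type == "mirna_mrna"],
                    retainedPairs$id_b[retainedPairs$pair_type == "mirna_mrna"])
  m <- nrow(candidatePairs)
  out <- data.frame(circ_id = character(m), mrna_id = character(m),
                    k = integer(m), K = integer(m), n = integer(m),
                    N = integer(m), pvalue = numeric(m), pcc = numeric(m),
                    shared_mirnas = character(m), stringsAsFactors = FALSE)
  for (i in seq_len(m)) {
    ci <- candidatePairs$id_a[i]; mi <- candidatePairs$id_b[i]
    sc <- unique(circSets[[ci]]); sm <- unique(mrnaSets[[mi]])
    shared <- intersect(sc, sm)
    out$circ_id[i] <- ci; out$mrna_id[i] <- mi
    out$k[i] <- length(shared); out$K[i] <- length(sc)
    out$n[i] <- length(sm); out$N[i] <- universeSize
    out$pvalue[i] <- hypergeomSF(length(shared), universeSize,
                                 length(sc), length(sm))
    out$pcc[i] <- candidatePairs$coefficient[i]
    out$shared_mirnas[i] <- paste(sort(shared), collapse = ";")
  }
  gate <- if (adjust && m > 0) bhAdjust(out$pvalue) else out$pvalue
  kept <- out[gate < alpha, , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "tested") <- m
  attr(kept, "adjusted") <- isTRUE(adjust)
  kept
}
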