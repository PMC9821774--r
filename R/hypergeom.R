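#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` items from a
#' population of `N` that contains `K` successes. Used to score whether two
#' transcripts share at least the observed number of common miRNA
#' regulators given the sizes of their regulator sets within the miRNA
#' universe. Computed by summing log-binomial terms
#' `lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)` over
#' `j = k..min(K, n)` with log-sum-exp, so it is stable for large `N`.
#'
#' @param k observed overlap, `0 <= k <= min(K, n)`.
#' @param N population (universe) size.
#' @param K number of successes in the population.
#' @param n number of draws.
#' @return `P(X >= k)` in `[0, 1]`; exactly 1 for `k = 0`.
#' @examples
#' hypergeomSF(4, 20, 8, 6)
#' @export
hypergeomSF <- function(k, N, K, n) {
  stopifnot(length(k) == 1, length(N) == 1, length(K) == 1, length(n) == 1)
  if (K < 0 || n < 0 || N < 0 || K > N || n > N)
    stop("domain error: need 0 <= K, n <= N")
  if (k < 0 || k > min(K, n))
    stop("domain error: need 0 <= k <= min(K, n)")
  if (k <= max(0, K + n - N)) return(1)
  j <- k:min(K, n)
  lt <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
  min(1, exp(.logSumExp(lt)))
}
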