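#' Exact conditional negative-binomial test for a two-group split
#'
#' Conditions on the total pseudo-count of a feature across all samples and
#' asks whether the split of that total between the two condition groups is
#' surprising. With equalized library sizes the group sums are NB
#' distributed (`Y1 ~ NB(n1*mu, n1/phi)`, `Y2 ~ NB(n2*mu, n2/phi)` for
#' dispersion `phi`), and the conditional distribution of `Y1` given
#' `Y1 + Y2 = t` is evaluated over all splits `0..t`. The two-sided p-value
#' is the minimum-likelihood sum: the total conditional probability of all
#' splits whose probability does not exceed that of the observed split (a
#' relative tie tolerance of 1e-7 guards against floating-point ties, as in
#' conditional exact tests generally). At `phi = 0` the conditional law is
#' exactly Binomial(t, n1/(n1+n2)) and the test reduces to the exact
#' binomial-split test.
#'
#' @param x integer vector of per-sample pseudo-counts for one feature
#'   (library sizes already equalized, see [equalizeLibrarySizes()]).
#' @param condition factor/vector of two conditions over samples.
#' @param dispersion common NB dispersion, `>= 0`.
#' @return two-sided p-value in (0, 1].
#' @examples
#' nbExactTest(c(5L, 6L, 5L, 20L, 22L, 19L),
#'             rep(c("NHS", "HS"), each = 3), dispersion = 0.1)
#' @export
nbExactTest <- function(x, condition, dispersion) {
  if (dispersion < 0)
    stop("dispersion must be >= 0")
  condition <- as.factor(condition)
  if (nlevels(condition) != 2L)
    stop("invalid design: exactly two conditions required")
  g1 <- condition == levels(condition)[1]
  .exactSplitPval(sum(x[g1]), sum(x[!g1]), sum(g1), sum(!g1), dispersion)
}

# p-value for observed group sums (y1, y2) with group sizes (n1, n2)
.exactSplitPval <- function(y1, y2, n1, n2, phi) {
  t <- y1 + y2
  if (t == 0) return(1)
  y <- 0:t
  if (phi == 0) {
    logp <- stats::dbinom(y, t, n1 / (n1 + n2), log = TRUE)
  } else {
    mu <- t / (n1 + n2)
    logp <- stats::dnbinom(y, mu = n1 * mu, size = n1 / phi, log = TRUE) +
      stats::dnbinom(t - y, mu = n2 * mu, size = n2 / phi, log = TRUE)
    logp <- logp - .logSumExp(logp)
  }
  pobs <- logp[y1 + 1L]
  min(1, sum(exp(logp[logp <= pobs + log1p(1e-7)])))
}

.logSumExp <- function(lx) {
  m <- max(lx)
  m + log(sum(exp(lx - m)))
}

#' Per-feature exact-test p-values for a matrix
#'
#' Applies [nbExactTest()] row-wise after library-size equalization.
#'
#' @param x count matrix (features x samples).
#' @param condition factor/vector of two conditions over columns.
#' @param dispersion common NB dispersion; estimated with
#'   [estimateCommonDispersion()] when `NULL`.
#' @param equalize equalize library sizes first (default TRUE).
#' @return named numeric vector of p-values.
#' @export
nbExactTestMatrix <- function(x, condition, dispersion = NULL,
                              equalize = TRUE) {
  condition <- as.factor(condition)
  if (equalize) x <- equalizeLibrarySizes(x)
  if (is.null(dispersion))
    dispersion <- estimateCommonDispersion(x, condition, equalize = FALSE)
  g1 <- condition == levels(condition)[1]
  y1 <- rowSums(x[, g1, drop = FALSE])
  y2 <- rowSums(x[, !g1, drop = FALSE])
  n1 <- sum(g1); n2 <- sum(!g1)
  p <- vapply(seq_along(y1), function(i)
    .exactSplitPval(y1[i], y2[i], n1, n2, dispersion), numeric(1))
  names(p) <- rownames(x)
  p
}
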