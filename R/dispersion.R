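#' Common NB dispersion by conditional likelihood
#'
#' Estimates a single dispersion shared by all features, maximizing the
#' conditional likelihood of the within-group counts given each group's
#' total. With equal library sizes (see [equalizeLibrarySizes()]) the
#' counts of a group are i.i.d. NB with common size `r = 1/dispersion`, and
#' conditional on their sum the group follows a Dirichlet-multinomial whose
#' likelihood depends only on `r` — the group mean cancels, which is what
#' makes the per-feature terms poolable. The profile conditional
#' log-likelihood, summed over features and condition groups, is maximized
#' by golden-section search on the log-dispersion scale over
#' `[1e-4, 10]`. All-zero features are excluded.
#'
#' @param x count matrix (features x samples), pseudo-counts with equalized
#'   library sizes; a raw matrix is equalized internally.
#' @param condition factor/vector of two conditions over columns.
#' @param equalize equalize library sizes first (default TRUE).
#' @return the estimated dispersion (positive scalar).
#' @export
estimateCommonDispersion <- function(x, condition, equalize = TRUE) {
  condition <- as.factor(condition)
  if (nlevels(condition) != 2L)
    stop("invalid design: exactly two conditions required")
  if (any(table(condition) < 2L))
    stop("invalid design: each condition needs >= 2 replicates")
  if (equalize) x <- equalizeLibrarySizes(x)
  keep <- rowSums(x) > 0
  if (!any(keep))
    stop("estimation error: no feature with nonzero counts")
  x <- x[keep, , drop = FALSE]
  groups <- lapply(levels(condition), function(l)
    x[, condition == l, drop = FALSE])

  negll <- function(logphi) {
    r <- 1 / exp(logphi)
    ll <- 0
    for (g in groups) {
      n <- ncol(g)
      z <- rowSums(g)
      ll <- ll + sum(lgamma(g + r)) - length(g) * lgamma(r) -
        sum(lgamma(z + n * r)) + nrow(g) * lgamma(n * r)
    }
    -ll
  }
  opt <- stats::optimize(negll, interval = log(c(1e-4, 10)), tol = 1e-6)
  exp(opt$minimum)
}
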