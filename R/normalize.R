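#' Counts-per-million normalization
#'
#' Scales each sample (column) to a library size of one million:
#' `cpm = count / column_sum * 1e6`.
#'
#' @param x count matrix (features x samples) or [RNACountSet-class].
#' @return real-valued matrix of the same dimensions; every column sums to
#'   `1e6`.
#' @export
setGeneric("normalizeCPM", function(x) standardGeneric("normalizeCPM"))

#' @rdname normalizeCPM
#' @export
setMethod("normalizeCPM", "matrix", function(x) {
  ls <- colSums(x)
  zero <- ls == 0
  if (any(zero))
    stop("degenerate sample(s) with all-zero counts: ",
         paste(colnames(x)[zero], collapse = ", "))
  sweep(x, 2L, ls, "/") * 1e6
})

#' @rdname normalizeCPM
#' @export
setMethod("normalizeCPM", "RNACountSet", function(x)
  normalizeCPM(assay(x, "counts")))

#' Per-feature log2 fold change of mean CPM
#'
#' `log2((mean CPM treatment + pseudocount) / (mean CPM control +
#' pseudocount))`, i.e. HS over NHS in the default design. A fold change of
#' 2 corresponds to a value of 1.
#'
#' @param x count matrix (features x samples).
#' @param condition factor/vector over columns; its first level (or
#'   `control`) is the denominator condition.
#' @param pseudocount added to both group means; default 1.
#' @param control optional control label overriding the first factor level.
#' @return named numeric vector of log2 fold changes.
#' @export
log2FoldChange <- function(x, condition, pseudocount = 1, control = NULL) {
  condition <- as.factor(condition)
  if (!is.null(control)) condition <- stats::relevel(condition, control)
  lev <- levels(condition)
  if (length(lev) != 2L)
    stop("invalid design: exactly two conditions required, got ",
         length(lev))
  if (any(table(condition) < 2L))
    stop("invalid design: each condition needs >= 2 samples")
  cpm <- normalizeCPM(x)
  m0 <- rowMeans(cpm[, condition == lev[1], drop = FALSE])
  m1 <- rowMeans(cpm[, condition == lev[2], drop = FALSE])
  log2((m1 + pseudocount) / (m0 + pseudocount))
}

#' Equalize library sizes by pseudo-counts
#'
#' Scales each sample's counts to the geometric-mean library size and rounds
#' to integers, so that all samples share a common effective depth. The
#' exact conditional test assumes this equalized input.
#'
#' @param x count matrix.
#' @return integer matrix of pseudo-counts.
#' @export
equalizeLibrarySizes <- function(x) {
  ls <- colSums(x)
  zero <- ls == 0
  if (any(zero))
    stop("degenerate sample(s) with all-zero counts: ",
         paste(colnames(x)[zero], collapse = ", "))
  target <- exp(mean(log(ls)))
  y <- round(sweep(x, 2L, ls, "/") * target)
  storage.mode(y) <- "integer"
  y
}
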