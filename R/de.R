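#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment via [stats::p.adjust()] after domain validation.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted values in `[0, 1]`, order-preserving under the BH
#'   ranking.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differential expression for one RNA class
#'
#' Per-feature log2 fold change (mean CPM, pseudocount-stabilised), exact
#' conditional NB p-value at a common dispersion, and BH FDR. The
#' significance gate is class-specific: circRNAs and miRNAs need
#' `|log2FC| >= log2(fcThreshold)` and `p < deAlpha`; mRNAs need
#' `|log2FC| >= log2(fcThreshold)` and `FDR < mrnaFdr`. Direction is `up`
#' for `log2FC >= log2(fcThreshold)`, `down` for `<= -log2(fcThreshold)`,
#' else `none`.
#'
#' @param x count matrix (features x samples) or an [RNACountSet-class]
#'   (optionally restricted to one tissue via `tissue`).
#' @param condition factor/vector of two conditions over columns, control
#'   level first (ignored for `RNACountSet`, whose colData is used).
#' @param rnaClass one of `"circRNA"`, `"miRNA"`, `"mRNA"`.
#' @param dispersion common NB dispersion; estimated when `NULL`.
#' @param pseudocount pseudocount for the fold change (default 1).
#' @param fcThreshold fold-change gate (default 2).
#' @param deAlpha p-value gate for circRNA/miRNA (default 0.05).
#' @param mrnaFdr FDR gate for mRNA (default 0.05).
#' @param tissue for `RNACountSet` input: tissue to restrict to.
#' @param control control condition label (for matrix input with unordered
#'   condition levels).
#' @param ... passed between methods.
#' @return a DE table: data.frame with columns `feature_id`, `log2fc`,
#'   `pvalue`, `fdr`, `significant`, `direction`.
#' @export
setGeneric("callDE", function(x, ...) standardGeneric("callDE"))

#' @rdname callDE
#' @export
setMethod("callDE", "matrix", function(x, condition, rnaClass,
                                       dispersion = NULL, pseudocount = 1,
                                       fcThreshold = 2, deAlpha = 0.05,
                                       mrnaFdr = 0.05, control = NULL, ...) {
  if (!rnaClass %in% VALID_RNA_CLASSES)
    stop("unknown rnaClass: ", rnaClass)
  condition <- as.factor(condition)
  if (!is.null(control)) condition <- stats::relevel(condition, control)
  lfc <- log2FoldChange(x, condition, pseudocount = pseudocount)
  p <- nbExactTestMatrix(x, condition, dispersion = dispersion)
  fdr <- bhAdjust(p)
  lfcGate <- log2(fcThreshold)
  probGate <- if (rnaClass == "mRNA") fdr < mrnaFdr else p < deAlpha
  sig <- abs(lfc) >= lfcGate & probGate
  dir <- ifelse(lfc >= lfcGate, "up", ifelse(lfc <= -lfcGate, "down", "none"))
  data.frame(feature_id = rownames(x), log2fc = unname(lfc),
             pvalue = unname(p), fdr = unname(fdr),
             significant = unname(sig), direction = unname(dir),
             stringsAsFactors = FALSE, row.names = NULL)
})

#' @rdname callDE
#' @export
setMethod("callDE", "RNACountSet", function(x, tissue = NULL, ...) {
  if (!is.null(tissue)) x <- tissueSubset(x, tissue)
  cond <- colData(x)$condition
  lev <- S4Vectors::metadata(x)$conditionLevels
  ctrl <- if (!is.null(lev)) lev[1] else cond[1]
  callDE(assay(x, "counts"), condition = cond, rnaClass = rnaClass(x),
         control = ctrl, ...)
})

#' Write a DE table as TSV
#'
#' @param de DE table from [callDE()].
#' @param path output path.
#' @param rnaClass,tissue optional annotation columns.
#' @return `path`, invisibly.
#' @export
writeDETable <- function(de, path, rnaClass = NA, tissue = NA) {
  out <- cbind(feature_id = de$feature_id,
               rna_class = rnaClass, tissue = tissue,
               de[, c("log2fc", "pvalue", "fdr", "significant", "direction")])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
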