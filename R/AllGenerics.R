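#' RNA class of a count set
#'
#' @param x an [RNACountSet-class].
#' @return a length-1 character: `"circRNA"`, `"miRNA"` or `"mRNA"`.
#' @export
setGeneric("rnaClass", function(x) standardGeneric("rnaClass"))

#' Sample table of a study design
#'
#' @param x a [StudyDesign-class].
#' @param ... unused.
#' @return a data.frame with columns `sample_id`, `tissue`, `condition`,
#'   `replicate`, one row per sample.
#' @export
setGeneric("sampleInfo", function(x, ...) standardGeneric("sampleInfo"))

#' Subset an object to one tissue
#'
#' @param x an [RNACountSet-class].
#' @param tissue a tissue label present in the object.
#' @return an object of the same class restricted to the tissue's samples.
#' @export
setGeneric("tissueSubset", function(x, tissue) standardGeneric("tissueSubset"))

#' Summarise a ceRNA network
#'
#' @param x a [CeRNANetwork-class].
#' @return a list of node counts per RNA class, edge counts per edge type,
#'   the circRNA-mRNA pair count, and per-class degree distributions.
#' @export
setGeneric("networkSummary", function(x) standardGeneric("networkSummary"))

#' Accessors for network components
#'
#' @param x a [CeRNANetwork-class].
#' @return `networkNodes()`: the node data.frame; `networkEdges()`: the edge
#'   data.frame.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname networkNodes
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
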