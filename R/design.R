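#' Create a two-condition multi-tissue study design
#'
#' The default layout mirrors a hypothalamic-pituitary-mammary (HPM) axis
#' heat-stress study: three tissues, a non-heat-stress (NHS) control group
#' and a heat-stress (HS) group, three biological replicates each, i.e. 18
#' samples in total.
#'
#' @param tissues character vector of distinct tissue labels.
#' @param conditions exactly two distinct condition labels, control first.
#' @param replicates biological replicates per tissue x condition (>= 2).
#' @param seed integer seed recorded with the design.
#' @return a [StudyDesign-class].
#' @examples
#' d <- generateDesign()
#' nrow(sampleInfo(d))  # 18
#' @export
generateDesign <- function(tissues = c("hypothalamus", "pituitary",
                                       "mammary_gland"),
                           conditions = c("NHS", "HS"),
                           replicates = 3L,
                           seed = 1L) {
  new("StudyDesign",
      tissues = as.character(tissues),
      conditions = as.character(conditions),
      replicates = as.integer(replicates),
      seed = as.integer(seed))
}

.tissueInitials <- function(tissues) {
  ini <- toupper(substr(tissues, 1L, 1L))
  if (anyDuplicated(ini))
    ini <- toupper(substr(gsub("[^A-Za-z]", "", tissues), 1L, 3L))
  if (anyDuplicated(ini))
    ini <- make.unique(ini, sep = "")
  ini
}

#' @rdname sampleInfo
#' @export
setMethod("sampleInfo", "StudyDesign", function(x, ...) {
  ini <- .tissueInitials(x@tissues)
  grid <- expand.grid(replicate = seq_len(x@replicates),
                      condition = x@conditions,
                      tissue = x@tissues,
                      KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("tissue", "condition", "replicate")]
  grid$sample_id <- paste0(grid$condition, "_",
                           ini[match(grid$tissue, x@tissues)],
                           grid$replicate)
  rownames(grid) <- NULL
  grid[, c("sample_id", "tissue", "condition", "replicate")]
})

setMethod("show", "StudyDesign", function(object) {
  cat("StudyDesign:", length(object@tissues), "tissue(s) x 2 conditions x",
      object@replicates, "replicates =",
      length(object@tissues) * 2L * object@replicates, "samples\n")
  cat("  tissues:   ", paste(object@tissues, collapse = ", "), "\n")
  cat("  conditions:", paste(object@conditions, collapse = " vs "),
      "(control first)\n")
})

#' Condition factor for a set of samples
#'
#' @param design a [StudyDesign-class].
#' @param sample_ids sample identifiers from [sampleInfo()].
#' @return factor with the control condition as first level.
#' @keywords internal
designCondition <- function(design, sample_ids) {
  info <- sampleInfo(design)
  idx <- match(sample_ids, info$sample_id)
  if (anyNA(idx))
    stop("unknown sample IDs: ",
         paste(sample_ids[is.na(idx)], collapse = ", "))
  factor(info$condition[idx], levels = design@conditions)
}
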