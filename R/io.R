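#' Read a count matrix from TSV
#'
#' Expects a tab-delimited file whose header row holds sample IDs and whose
#' first column holds feature IDs; `#` lines are ignored. The matrix is
#' validated: unique IDs, numeric nonnegative integer counts. Malformed
#' cells are reported with their location.
#'
#' @param path TSV file path.
#' @param rnaClass optional RNA class; when given together with `metadata`
#'   an [RNACountSet-class] is returned instead of a bare matrix.
#' @param metadata optional sample-metadata data.frame (see
#'   [readSampleMetadata()]).
#' @return integer matrix (features x samples), or an [RNACountSet-class].
#' @export
readExpressionTSV <- function(path, rnaClass = NULL, metadata = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("parse error in ", path, ": need a feature-ID column plus samples")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("parse error in ", path, ": duplicated feature ID(s): ",
         paste(dup, collapse = ", "))
  }
  if (anyDuplicated(colnames(df)[-1]))
    stop("parse error in ", path, ": duplicated sample IDs")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(m), nrow(m)))) & !is.na(m), arr.ind = TRUE)
    loc <- if (nrow(bad)) sprintf(" (e.g. feature %s, sample %s)",
                                  ids[bad[1, 1]], colnames(m)[bad[1, 2]])
           else ""
    stop("parse error in ", path, ": non-numeric counts", loc)
  }
  bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stop("parse error in ", path,
         sprintf(": negative/non-integer count at feature %s, sample %s",
                 ids[bad[1, 1]], colnames(m)[bad[1, 2]]))
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  if (!is.null(rnaClass) && !is.null(metadata))
    RNACountSet(m, metadata, rnaClass)
  else m
}

#' Write a count matrix (or RNACountSet) as TSV
#'
#' @param x matrix or [RNACountSet-class].
#' @param path output path.
#' @param idColumn header of the feature-ID column.
#' @return `path`, invisibly.
#' @export
writeExpressionTSV <- function(x, path, idColumn = "feature_id") {
  m <- if (is(x, "RNACountSet")) assay(x, "counts") else x
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- idColumn
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample metadata
#'
#' The metadata TSV has columns `sample_id`, `tissue`, `condition`,
#' `replicate`.
#'
#' @param path TSV path.
#' @return data.frame of sample metadata.
#' @export
readSampleMetadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue", "condition", "replicate")
  if (!all(need %in% names(df)))
    stop("metadata must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in metadata")
  df
}

#' @rdname readSampleMetadata
#' @param x data.frame of sample metadata.
#' @export
writeSampleMetadata <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a miRNA-target interaction table
#'
#' Columns `mirna_id`, `target_id`, `target_type` with `target_type` in
#' {circRNA, mRNA}; rows must be unique.
#'
#' @param path TSV path.
#' @return data.frame of interactions.
#' @export
readInteractionsTSV <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("mirna_id", "target_id", "target_type")
  if (!all(need %in% names(df)))
    stop("interaction table must have columns ", paste(need, collapse = ", "))
  if (!all(df$target_type %in% VALID_TARGET_TYPES))
    stop("target_type must be one of ",
         paste(VALID_TARGET_TYPES, collapse = ", "))
  key <- paste(df$mirna_id, df$target_id, df$target_type)
  if (anyDuplicated(key))
    stop("duplicated interaction rows: ",
         paste(utils::head(unique(key[duplicated(key)]), 3), collapse = "; "))
  df[, need]
}

#' @rdname readInteractionsTSV
#' @param x data.frame of interactions.
#' @export
writeInteractionsTSV <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize / load ground truth as JSON
#'
#' @param truth a [GroundTruth-class].
#' @param path JSON path.
#' @return `readGroundTruthJSON()` returns a [GroundTruth-class].
#' @export
writeGroundTruthJSON <- function(truth, path) {
  jsonlite::write_json(list(planted_de = truth@plantedDE,
                            planted_triads = truth@plantedTriads,
                            planted_interactions = truth@plantedInteractions),
                       path, dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeGroundTruthJSON
#' @export
readGroundTruthJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  asdf <- function(d, cols) {
    if (is.null(d) || !length(d)) {
      out <- as.data.frame(setNames(rep(list(character()), length(cols)),
                                    cols), stringsAsFactors = FALSE)
      return(out)
    }
    as.data.frame(d, stringsAsFactors = FALSE)[, cols]
  }
  new("GroundTruth",
      plantedDE = asdf(x$planted_de, c("class", "feature_id", "direction")),
      plantedTriads = asdf(x$planted_triads,
                           c("circ_id", "mirna_id", "mrna_id")),
      plantedInteractions = asdf(x$planted_interactions,
                                 c("mirna_id", "target_id", "target_type")))
}
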