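.sigFeatures <- function(de) de$feature_id[de$significant]

#' Filter predicted miRNA-target pairs by negative Spearman correlation
#'
#' Step one of the ceRNA construction: among predicted miRNA-target
#' interactions whose miRNA and target are BOTH significantly
#' differentially expressed, keep exactly the pairs whose Spearman rank
#' correlation across the tissue's samples is strictly below
#' `sccThreshold` (default -0.7). Interactions referencing unknown features
#' are skipped with a warning; pairs with a constant expression vector are
#' excluded as undefined and counted.
#'
#' @param deTables named list of DE tables (`circRNA`, `miRNA`, `mRNA`) for
#'   one tissue, from [callDE()].
#' @param interactions interaction data.frame (`mirna_id`, `target_id`,
#'   `target_type`).
#' @param expr named list of expression matrices (CPM) per RNA class, same
#'   tissue, identical sample columns.
#' @param sccThreshold strict Spearman cutoff; keep if SCC < threshold.
#' @param conditionGroups optional list of column-index vectors (one per
#'   condition) for within-condition correlation; `NULL` pools all samples.
#' @return data.frame of retained pairs: `id_a` (miRNA), `id_b` (target),
#'   `pair_type` (`mirna_circ`/`mirna_mrna`), `method`, `coefficient`,
#'   `n_samples`; attribute `"skipped"` counts unknown-feature and
#'   constant-expression exclusions.
#' @export
filterMirnaTargetPairs <- function(deTables, interactions, expr,
                                   sccThreshold = -0.7,
                                   conditionGroups = NULL) {
  sigMir <- .sigFeatures(deTables$miRNA)
  sigTarget <- list(circRNA = .sigFeatures(deTables$circRNA),
                    mRNA = .sigFeatures(deTables$mRNA))
  n <- ncol(expr$miRNA)
  res <- vector("list", nrow(interactions))
  skippedUnknown <- 0L; skippedConstant <- 0L
  for (i in seq_len(nrow(interactions))) {
    mir <- interactions$mirna_id[i]
    tg <- interactions$target_id[i]
    tt <- interactions$target_type[i]
    if (!mir %in% rownames(expr$miRNA) || !tg %in% rownames(expr[[tt]])) {
      skippedUnknown <- skippedUnknown + 1L
      next
    }
    if (!(mir %in% sigMir) || !(tg %in% sigTarget[[tt]])) next
    rho <- .groupedCor(expr$miRNA[mir, ], expr[[tt]][tg, ], "spearman",
                       conditionGroups)
    if (is.na(rho)) {
      skippedConstant <- skippedConstant + 1L
      next
    }
    if (rho < sccThreshold)
      res[[i]] <- data.frame(
        id_a = mir, id_b = tg,
        pair_type = if (tt == "circRNA") "mirna_circ" else "mirna_mrna",
        method = "spearman", coefficient = rho, n_samples = n,
        stringsAsFactors = FALSE)
  }
  if (skippedUnknown > 0L)
    warning(skippedUnknown, " interaction(s) referenced unknown features",
            " and were skipped")
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(id_a = character(), id_b = character(),
                      pair_type = character(), method = character(),
                      coefficient = numeric(), n_samples = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- c(unknown = skippedUnknown,
                            constant = skippedConstant)
  out
}

#' Filter candidate circRNA-mRNA pairs by positive Pearson correlation
#'
#' Step two: candidate circRNA-mRNA pairs are those sharing at least one
#' common miRNA among the retained negative pairs; a candidate is kept iff
#' its Pearson correlation (computed on `log2(CPM + 1)`) is strictly above
#' `pccThreshold` (default 0.9). Each kept pair records its common-miRNA
#' set.
#'
#' @param deTables named list of DE tables for the tissue (members of
#'   retained pairs are DE by construction; kept for interface symmetry).
#' @param retainedPairs output of [filterMirnaTargetPairs()].
#' @param expr named list of CPM matrices per class (same samples).
#' @param pccThreshold strict Pearson cutoff; keep if PCC > threshold.
#' @param conditionGroups see [filterMirnaTargetPairs()].
#' @return data.frame of kept pairs: `id_a` (circRNA), `id_b` (mRNA),
#'   `pair_type = "circ_mrna"`, `method`, `coefficient`, `n_samples`,
#'   `common_mirnas` (semicolon-joined).
#' @export
filterCernaPairs <- function(deTables, retainedPairs, expr,
                             pccThreshold = 0.9, conditionGroups = NULL) {
  circOf <- retainedPairs[retainedPairs$pair_type == "mirna_circ", ]
  mrnaOf <- retainedPairs[retainedPairs$pair_type == "mirna_mrna", ]
  mirs <- intersect(unique(circOf$id_a), unique(mrnaOf$id_a))
  cand <- list()
  for (m in mirs) {
    cc <- circOf$id_b[circOf$id_a == m]
    mm <- mrnaOf$id_b[mrnaOf$id_a == m]
    for (ci in cc) for (mi in mm) {
      key <- paste(ci, mi, sep = "\r")
      cand[[key]] <- c(cand[[key]], m)
    }
  }
  if (!length(cand))
    return(data.frame(id_a = character(), id_b = character(),
                      pair_type = character(), method = character(),
                      coefficient = numeric(), n_samples = integer(),
                      common_mirnas = character(), stringsAsFactors = FALSE))
  n <- ncol(expr$circRNA)
  logCirc <- log2(expr$circRNA + 1)
  logMrna <- log2(expr$mRNA + 1)
  keys <- names(cand)
  res <- vector("list", length(keys))
  for (i in seq_along(keys)) {
    parts <- strsplit(keys[i], "\r", fixed = TRUE)[[1]]
    ci <- parts[1]; mi <- parts[2]
    r <- .groupedCor(logCirc[ci, ], logMrna[mi, ], "pearson",
                     conditionGroups)
    if (!is.na(r) && r > pccThreshold)
      res[[i]] <- data.frame(
        id_a = ci, id_b = mi, pair_type = "circ_mrna", method = "pearson",
        coefficient = r, n_samples = n,
        common_mirnas = paste(sort(unique(cand[[i]])), collapse = ";"),
        stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(id_a = character(), id_b = character(),
                      pair_type = character(), method = character(),
                      coefficient = numeric(), n_samples = integer(),
                      common_mirnas = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a correlation-pair table as TSV
#'
#' @param pairs data.frame from [filterMirnaTargetPairs()] or
#'   [filterCernaPairs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePairsTSV <- function(pairs, path) {
  if (is.null(pairs$common_mirnas)) pairs$common_mirnas <- ""
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
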