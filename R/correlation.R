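#' Spearman and Pearson correlation with degenerate-input handling
#'
#' Thin wrappers over [stats::cor()]. Spearman uses mid-ranks (average ranks
#' for ties), i.e. the Pearson correlation of ranks. A constant vector makes
#' the coefficient undefined: `NA_real_` is returned so that callers can
#' exclude (and count) the pair rather than silently treating it as zero.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation coefficient in `[-1, 1]`, or `NA_real_` if either
#'   vector is constant.
#' @examples
#' spearmanCor(1:4, c(1, 3, 2, 4))  # 0.8
#' pearsonCor(1:3, c(1, 2, 4))
#' @export
spearmanCor <- function(x, y) .corOrNA(x, y, "spearman")

#' @rdname spearmanCor
#' @export
pearsonCor <- function(x, y) .corOrNA(x, y, "pearson")

.corOrNA <- function(x, y, method) {
  if (length(x) != length(y))
    stop("x and y must have equal length")
  if (length(x) < 3L)
    stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(NA_real_)
  stats::cor(x, y, method = method)
}

# correlation across sample groups: pooled, or conservative within-condition
# combination (the coefficient closest to zero across conditions, so a pair
# passes only if it passes in every condition)
.groupedCor <- function(x, y, method, groups = NULL) {
  if (is.null(groups))
    return(.corOrNA(x, y, method))
  vals <- vapply(groups, function(idx) .corOrNA(x[idx], y[idx], method),
                 numeric(1))
  if (anyNA(vals)) return(NA_real_)
  vals[which.min(abs(vals))]
}
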