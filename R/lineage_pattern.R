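# Layer 2: the stage-specific sets are integrated into one lineage-specific
# pattern (the mean expression of each stage's own genes, evaluated at that
# stage), and the whole matrix is screened for genes whose profile follows
# that pattern by Spearman rank correlation.

#' Integrate stage-specific gene sets into a lineage pattern
#'
#' The representative value at stage `s` is the arithmetic mean, over the
#' stage-`s`-specific genes, of their expression at stage `s`. With
#' `full_profile = TRUE` the alternative aggregation is used instead: the
#' mean full profile of the union of all layer-1 genes.
#'
#' @param expr Numeric matrix (genes x stages).
#' @param layer1 A `stage_gene_sets` object or a named list mapping every
#'   stage (matrix column) to a non-empty character vector of gene symbols.
#' @param full_profile Use the union-mean-profile aggregation. Default off.
#' @return Named numeric vector (class `lineage_pattern`), one value per
#'   stage in column order.
#' @export
integrate_lineage_pattern <- function(expr, layer1, full_profile = FALSE) {
  validate_expression_matrix(expr)
  sets <- if (inherits(layer1, "stage_gene_sets")) layer1$sets else layer1
  stages <- colnames(expr)
  missing_stage <- setdiff(stages, names(sets))
  if (length(missing_stage))
    abort_validation("no layer-1 set for stage(s): ",
                     paste(missing_stage, collapse = ", "))
  empty <- stages[vapply(sets[stages], length, 0L) == 0L]
  if (length(empty))
    abort_validation("empty layer-1 set at stage(s): ",
                     paste(empty, collapse = ", "))
  unknown <- setdiff(unique(unlist(sets[stages])), rownames(expr))
  if (length(unknown))
    abort_validation("layer-1 gene(s) absent from the matrix: ",
                     paste(unknown, collapse = ", "))
  values <- if (full_profile) {
    colMeans(expr[unique(unlist(sets[stages])), , drop = FALSE])
  } else {
    vapply(stages, function(s) mean(expr[sets[[s]], s]), 0)
  }
  names(values) <- stages
  structure(values, class = c("lineage_pattern", "numeric"))
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, via [stats::cor()]. Both
#' vectors must have at least three values and must not be constant.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation value in `[-1, 1]`.
#' @export
#' @examples
#' spearman_rho(c(1, 2, 3), c(2, 4, 6))
spearman_rho <- function(x, y) {
  if (length(x) != length(y))
    abort_validation("vectors must have equal length")
  if (length(x) < 3L)
    abort_validation("need at least three paired values")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    abort_validation("non-finite values in input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    abort_validation("correlation undefined for a constant vector")
  stats::cor(x, y, method = "spearman")
}

#' Screen the matrix for genes following the lineage pattern
#'
#' Returns every non-constant gene whose Spearman correlation with the
#' pattern strictly exceeds `config$rho_min`, with the correlation recorded.
#' Constant (zero-variance) genes are excluded and tallied in the
#' `skipped_constant` attribute. Output order is deterministic: descending
#' rho, then symbol.
#'
#' @param expr Numeric matrix (genes x stages).
#' @param pattern A `lineage_pattern` (or named numeric vector aligned with
#'   the matrix columns).
#' @param config A [pipeline_config()].
#' @param tf_list Optional character vector of known TF symbols; adds an
#'   `is_tf` column.
#' @return A data.frame of class `correlated_gene_set` with columns `gene`,
#'   `rho` (and `is_tf` when `tf_list` is given); attribute
#'   `skipped_constant` counts excluded zero-variance genes.
#' @export
find_correlated_genes <- function(expr, pattern, config = pipeline_config(),
                                  tf_list = NULL) {
  validate_expression_matrix(expr)
  if (!is.null(names(pattern)) && !identical(names(pattern), colnames(expr)))
    abort_validation("pattern stages do not align with matrix columns")
  if (length(pattern) != ncol(expr))
    abort_validation("pattern length does not match the number of stages")
  keep <- apply(expr, 1L, stats::sd) > 0
  skipped <- sum(!keep)
  res <- if (any(keep)) {
    sub <- expr[keep, , drop = FALSE]
    rho <- suppressWarnings(
      stats::cor(t(sub), as.numeric(pattern), method = "spearman"))[, 1]
    sel <- !is.na(rho) & rho > config$rho_min
    data.frame(gene = rownames(sub)[sel], rho = unname(rho[sel]),
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene = character(0), rho = numeric(0), stringsAsFactors = FALSE)
  }
  res <- res[order(-res$rho, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  if (!is.null(tf_list))
    res$is_tf <- res$gene %in% canonical_symbol(tf_list)
  attr(res, "skipped_constant") <- skipped
  class(res) <- c("correlated_gene_set", "data.frame")
  res
}
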