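# Permutation significance of the correlated gene set: columns of the
# expression matrix are shuffled independently (destroying each gene's
# profile while conserving every stage's value distribution), the
# correlated-gene screen is re-run against the fixed lineage pattern, and
# the Jaccard overlap with the reference set is recorded per shuffle.

#' Shuffle an expression matrix column-wise
#'
#' Each column (stage) is permuted independently, so the multiset of values
#' per stage is conserved while gene profiles are destroyed. Gene and stage
#' labels are unchanged. Uses the current RNG stream; seed beforehand for
#' reproducibility.
#'
#' @param expr Numeric matrix (genes x stages).
#' @return Shuffled matrix with identical dimnames.
#' @export
shuffle_columns <- function(expr) {
  out <- expr
  n <- nrow(expr)
  for (j in seq_len(ncol(expr)))
    out[, j] <- expr[sample.int(n), j]
  out
}

#' Jaccard index of two gene sets
#'
#' `|a intersect b| / |a union b|`; defined as 0 when both sets are empty.
#'
#' @param a,b Character vectors (treated as sets).
#' @return Value in `[0, 1]`.
#' @export
#' @examples
#' jaccard_index(c("a", "b"), c("b", "c"))
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Column-permutation significance of the correlated gene set
#'
#' For each of `config$n_perm` shuffles (independent sub-streams derived from
#' the master seed), the matrix columns are permuted independently, the
#' correlated-gene screen is re-run against the fixed input pattern, and the
#' Jaccard overlap with the reference set is computed. The p-value is the
#' fraction of shuffles whose overlap strictly exceeds `config$tau` (or the
#' `(count + 1) / (n + 1)` variant when `config$adjusted_pvalue` is on).
#'
#' With `config$full_recompute = TRUE` (and `expr` rows covering the global
#' regulators) layer 1 and the pattern are re-derived on every shuffled
#' matrix instead; shuffles on which a stage signature or the pattern cannot
#' be built contribute an empty gene set.
#'
#' @param expr Numeric matrix (genes x stages).
#' @param pattern A `lineage_pattern` aligned with the matrix columns.
#' @param reference The observed correlated gene set (character vector or
#'   `correlated_gene_set`); must be non-empty.
#' @param config A [pipeline_config()]; uses `n_perm`, `tau`, `seed`,
#'   `rho_min`.
#' @return Object of class `permutation_result`: list with `n_perm`, `tau`,
#'   `jaccards` (one value per shuffle), `exceed_count`, `p_value`, `seed`.
#' @export
permutation_significance <- function(expr, pattern, reference,
                                     config = pipeline_config()) {
  validate_expression_matrix(expr)
  ref <- if (inherits(reference, "correlated_gene_set")) reference$gene
         else as.character(reference)
  ref <- unique(ref)
  if (!length(ref))
    abort_validation("reference gene set is empty; the test is undefined")

  seeds <- derive_seeds(config$seed, config$n_perm)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))

  shuffled_set <- function(shuf) {
    if (config$full_recompute) {
      tryCatch({
        l1 <- find_stage_gene_sets(shuf, config)
        pat <- integrate_lineage_pattern(shuf, l1,
                                         full_profile = config$pattern_full_profile)
        find_correlated_genes(shuf, pat, config)$gene
      }, pathdevfate_validation_error = function(e) character(0))
    } else {
      find_correlated_genes(shuf, pattern, config)$gene
    }
  }

  jaccards <- vapply(seq_len(config$n_perm), function(i) {
    set.seed(seeds[i])
    jaccard_index(ref, shuffled_set(shuffle_columns(expr)))
  }, 0)

  exceed <- sum(jaccards > config$tau)
  p <- if (config$adjusted_pvalue) (exceed + 1) / (config$n_perm + 1)
       else exceed / config$n_perm
  structure(list(n_perm = config$n_perm, tau = config$tau,
                 jaccards = jaccards, exceed_count = exceed,
                 p_value = p, seed = config$seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation_result: %d shuffle(s), %d with Jaccard > %g, p = %g\n",
    x$n_perm, x$exceed_count, x$tau, x$p_value))
  invisible(x)
}
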