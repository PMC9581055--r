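#' Pipeline configuration
#'
#' Bundles the tunable parameters of the lineage screening pipeline. Defaults
#' reproduce the published analysis conditions: a strict Spearman threshold of
#' 0.9 for both the stage-specific and the lineage-wide screens, a strict
#' (tie-free) peak requirement, an in-degree threshold of 5 for influencers
#' ("regulated by more than five TFs"), a Jaccard overlap threshold of 0.05
#' and 1000 column shuffles for the permutation test.
#'
#' @param rho_min Spearman rank-correlation threshold; genes must exceed it
#'   strictly (`rho > rho_min`) to be retained. In `[-1, 1]`.
#' @param strict_peak Logical; require a gene's own profile to peak strictly
#'   (no ties) at the signature's stage in the layer-1 screen.
#' @param l In-degree threshold for influencer nodes; a node qualifies when
#'   its in-degree is strictly greater than `l`. Non-negative.
#' @param tau Jaccard overlap threshold for the permutation test; shuffles
#'   with overlap strictly greater than `tau` count as exceedances.
#' @param n_perm Number of column shuffles for the permutation test (>= 1).
#' @param seed Master RNG seed; all randomized operations derive their streams
#'   from it.
#' @param global_regulators Character vector of curated global-regulator
#'   symbols used to seed the stage signatures (canonicalized on input).
#' @param log2_transform Logical; apply `log2(x + 1)` to expression values at
#'   load time before any correlation. Default off.
#' @param max_violations Loosened-criterion option for the monotone tree
#'   rules: number of strict inequalities a gene may violate and still pass.
#'   Default 0 (exact adherence).
#' @param pattern_full_profile Logical; if `TRUE`, the integrated lineage
#'   pattern is the mean full profile of the union of all layer-1 genes
#'   instead of the per-stage mean of each stage's own genes. Default off.
#' @param include_tf_tf Logical; if `TRUE`, the subnetwork also admits edges
#'   between two layer-3 TFs even when the regulated TF is not a layer-2
#'   member. Default off.
#' @param full_recompute Logical; if `TRUE`, the permutation test re-derives
#'   layer 1 and the lineage pattern on every shuffled matrix instead of
#'   holding the pattern fixed. Default off.
#' @param adjusted_pvalue Logical; if `TRUE`, report the permutation p-value
#'   as `(exceed + 1) / (n_perm + 1)` instead of the plain `exceed / n_perm`
#'   count convention. Default off.
#'
#' @return An object of class `pipeline_config` (a validated list).
#' @export
#' @examples
#' cfg <- pipeline_config(l = 5, n_perm = 200, seed = 42)
#' cfg$rho_min
pipeline_config <- function(rho_min = 0.9,
                            strict_peak = TRUE,
                            l = 5L,
                            tau = 0.05,
                            n_perm = 1000L,
                            seed = 1L,
                            global_regulators = character(),
                            log2_transform = FALSE,
                            max_violations = 0L,
                            pattern_full_profile = FALSE,
                            include_tf_tf = FALSE,
                            full_recompute = FALSE,
                            adjusted_pvalue = FALSE) {
  if (!is.numeric(rho_min) || length(rho_min) != 1L || is.na(rho_min) ||
      rho_min < -1 || rho_min > 1)
    abort_validation("rho_min must be a single value in [-1, 1]")
  if (!is.numeric(l) || length(l) != 1L || is.na(l) || l < 0)
    abort_validation("l (in-degree threshold) must be a single value >= 0")
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0 || tau > 1)
    abort_validation("tau must be a single value in [0, 1]")
  if (!is.numeric(n_perm) || length(n_perm) != 1L || is.na(n_perm) || n_perm < 1)
    abort_validation("n_perm must be >= 1")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    abort_validation("seed must be a single integer")
  if (!is.numeric(max_violations) || max_violations < 0)
    abort_validation("max_violations must be >= 0")

  structure(list(
    rho_min = as.numeric(rho_min),
    strict_peak = isTRUE(strict_peak),
    l = as.numeric(l),
    tau = as.numeric(tau),
    n_perm = as.integer(n_perm),
    seed = as.integer(seed),
    global_regulators = canonical_symbol(global_regulators),
    log2_transform = isTRUE(log2_transform),
    max_violations = as.integer(max_violations),
    pattern_full_profile = isTRUE(pattern_full_profile),
    include_tf_tf = isTRUE(include_tf_tf),
    full_recompute = isTRUE(full_recompute),
    adjusted_pvalue = isTRUE(adjusted_pvalue)
  ), class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pathdevfate pipeline configuration\n")
  cat(sprintf("  rho_min: %g   strict_peak: %s   l: %g   tau: %g\n",
              x$rho_min, x$strict_peak, x$l, x$tau))
  cat(sprintf("  n_perm: %d   seed: %d   global regulators: %d\n",
              x$n_perm, x$seed, length(x$global_regulators)))
  invisible(x)
}
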