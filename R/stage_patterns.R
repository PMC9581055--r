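# Layer 1: stage-specific gene detection. A small curated set of "global
# regulators" seeds one expression signature per stage (the mean profile of
# the regulators peaking there); the whole matrix is then screened for genes
# that follow that signature (Spearman rho above threshold) and, in strict
# mode, peak at the same stage. For branched lineages a monotone tree rule
# replaces the correlation screen.

#' Detect the peak stage of an expression profile
#'
#' @param profile Numeric vector of expression values across stages, named
#'   with stage labels (unnamed profiles are addressed by index).
#' @param strict If `TRUE` (default), the peak must strictly exceed every
#'   other value; a tied maximum (including a constant profile) yields `NA`.
#'   If `FALSE`, the first argmax in stage order is returned.
#' @return The peak stage label (or index as character when unnamed), or
#'   `NA_character_` when no strict peak exists.
#' @export
#' @examples
#' detect_peak_stage(c(ESC = 2, MES = 9, HB = 3, HE = 1, HP = 1, MAC = 1))
detect_peak_stage <- function(profile, strict = TRUE) {
  if (length(profile) < 2L)
    abort_validation("profile must have at least two stages")
  if (!all(is.finite(profile)))
    abort_validation("profile contains non-finite values")
  labels <- names(profile) %||% as.character(seq_along(profile))
  i <- which.max(profile)
  if (strict && sum(profile == profile[i]) > 1L)
    return(NA_character_)
  labels[i]
}

#' Build the expression signature of one stage
#'
#' Restricted to the global-regulator rows of the matrix, finds the
#' regulators whose profile peaks (strictly) at `stage` and averages their
#' profiles into the stage signature. At least one regulator must peak there.
#'
#' @param regulator_profiles Numeric matrix (regulators x stages).
#' @param stage Stage label (must be a column of the matrix).
#' @return A `stage_signature`: list with `stage`, `members` (the peaking
#'   regulators) and `profile` (their mean expression per stage).
#' @export
build_stage_signature <- function(regulator_profiles, stage) {
  if (!is.matrix(regulator_profiles) || is.null(colnames(regulator_profiles)))
    abort_validation("regulator_profiles must be a matrix with stage colnames")
  if (!stage %in% colnames(regulator_profiles))
    abort_validation("stage '", stage, "' is not a column of the matrix")
  peaks <- apply(regulator_profiles, 1L, detect_peak_stage, strict = TRUE)
  members <- rownames(regulator_profiles)[!is.na(peaks) & peaks == stage]
  if (!length(members))
    abort_validation("no global regulator peaks at stage '", stage,
                     "'; signature unavailable")
  profile <- colMeans(regulator_profiles[members, , drop = FALSE])
  # mean of strictly peaked profiles is itself strictly peaked; assert anyway
  stopifnot(identical(detect_peak_stage(profile, strict = TRUE), stage))
  structure(list(stage = stage, members = sort(members), profile = profile),
            class = "stage_signature")
}

#' @export
print.stage_signature <- function(x, ...) {
  cat(sprintf("stage_signature for %s: %d regulator(s) [%s]\n",
              x$stage, length(x$members), paste(x$members, collapse = ", ")))
  invisible(x)
}

#' Screen the matrix for genes following one stage signature
#'
#' A gene is stage-specific when its Spearman rank correlation with the
#' signature profile strictly exceeds `config$rho_min` and (when
#' `config$strict_peak` is on) its own profile peaks strictly at the
#' signature's stage. Zero-variance genes are excluded.
#'
#' @param expr Numeric matrix (genes x stages).
#' @param signature A `stage_signature`.
#' @param config A [pipeline_config()].
#' @return Sorted character vector of gene symbols.
#' @export
find_stage_specific_genes <- function(expr, signature, config = pipeline_config()) {
  validate_expression_matrix(expr)
  if (!identical(colnames(expr), names(signature$profile)))
    abort_validation("signature stages do not align with matrix columns")
  keep <- apply(expr, 1L, stats::sd) > 0
  if (!any(keep)) return(character(0))
  sub <- expr[keep, , drop = FALSE]
  rho <- suppressWarnings(
    stats::cor(t(sub), signature$profile, method = "spearman"))[, 1]
  sel <- !is.na(rho) & rho > config$rho_min
  if (config$strict_peak && any(sel)) {
    pk <- apply(sub[sel, , drop = FALSE], 1L, detect_peak_stage, strict = TRUE)
    sel[sel] <- !is.na(pk) & pk == signature$stage
  }
  sort(rownames(sub)[sel])
}

#' Layer-1 screen across all stages of a linear lineage
#'
#' Builds one signature per stage from the configured global regulators and
#' screens the matrix against each.
#'
#' @param expr Numeric matrix (genes x stages), columns in lineage order.
#' @param config A [pipeline_config()]; `global_regulators` must name at
#'   least one row of `expr`.
#' @return A `stage_gene_sets` object: list with `sets` (stage -> sorted gene
#'   symbols) and `signatures` (stage -> `stage_signature`).
#' @export
find_stage_gene_sets <- function(expr, config = pipeline_config()) {
  validate_expression_matrix(expr)
  regs <- intersect(config$global_regulators, rownames(expr))
  if (!length(regs))
    abort_validation("none of the global regulators are present in the matrix")
  reg_expr <- expr[regs, , drop = FALSE]
  stages <- colnames(expr)
  signatures <- lapply(stages, function(s) build_stage_signature(reg_expr, s))
  names(signatures) <- stages
  sets <- lapply(signatures, function(sg)
    find_stage_specific_genes(expr, sg, config))
  structure(list(sets = sets, signatures = signatures),
            class = "stage_gene_sets")
}

#' @export
print.stage_gene_sets <- function(x, ...) {
  sizes <- vapply(x$sets, length, 0L)
  cat("stage_gene_sets:\n")
  for (s in names(sizes)) cat(sprintf("  %s: %d gene(s)\n", s, sizes[s]))
  invisible(x)
}

#' Cell-specific genes under the monotone tree rules
#'
#' For a branched lineage, a gene is specific to `target_cell` when its
#' expression strictly increases along every edge of the root-to-target path
#' and strictly decreases along the target-to-leaf continuation(s). Cells off
#' that path are ignored. When the target is internal and several descendant
#' leaves exist, the decreasing run is required along every continuation
#' unless `leaf` names one. `max_violations` (default 0, i.e. exact
#' adherence) allows a loosened variant in which a gene may violate up to
#' that many of the strict inequalities.
#'
#' @param expr Numeric matrix (genes x stages); columns must cover every cell
#'   on the evaluated paths.
#' @param tree A `lineage_topology`.
#' @param target_cell The cell state whose specific genes are sought.
#' @param leaf Optional terminal cell naming a single continuation.
#' @param max_violations Number of strict inequalities a gene may violate.
#' @return Sorted character vector of gene symbols.
#' @export
find_cell_specific_genes_tree <- function(expr, tree, target_cell, leaf = NULL,
                                          max_violations = 0L) {
  validate_expression_matrix(expr)
  if (!target_cell %in% tree$nodes)
    abort_validation("target cell '", target_cell, "' is not in the lineage")
  up <- lineage_path_to(tree, target_cell)
  downs <- lineage_continuations(tree, target_cell, leaf = leaf)
  cells <- unique(c(up, unlist(downs)))
  missing <- setdiff(cells, colnames(expr))
  if (length(missing))
    abort_validation("lineage cell(s) absent from the matrix: ",
                     paste(missing, collapse = ", "))

  inc_pairs <- if (length(up) > 1L)
    cbind(up[-length(up)], up[-1]) else matrix(character(0), 0, 2)
  dec_pairs <- do.call(rbind, c(list(matrix(character(0), 0, 2)),
    lapply(downs, function(p) cbind(p[-length(p)], p[-1]))))

  viol <- rep(0L, nrow(expr))
  if (nrow(inc_pairs))
    for (i in seq_len(nrow(inc_pairs)))
      viol <- viol + as.integer(!(expr[, inc_pairs[i, 2]] > expr[, inc_pairs[i, 1]]))
  if (nrow(dec_pairs))
    for (i in seq_len(nrow(dec_pairs)))
      viol <- viol + as.integer(!(expr[, dec_pairs[i, 2]] < expr[, dec_pairs[i, 1]]))
  sort(rownames(expr)[viol <= max_violations])
}
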