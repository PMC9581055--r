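# End-to-end orchestration: layers 1-4, regulatory-path extraction and the
# optional permutation test, with all file outputs under one directory and a
# single self-contained JSON run report.

#' Run the full lineage screening pipeline
#'
#' Executes, in order: the layer-1 stage-specific screen (signature-based on
#' a linear lineage, monotone tree rules on a branched one), integration of
#' the lineage pattern, the layer-2 correlated-gene screen, the layer-3
#' regulator lookup, subnetwork assembly, regulatory-path extraction and
#' (optionally) the column-permutation significance test. Inputs may be
#' given as paths (loaded with the `iodata` readers) or as already-loaded
#' objects.
#'
#' When `out_dir` is given, writes per-stage gene lists
#' (`<stage>_layer1.txt`), `pattern.tsv`, `correlated_genes.tsv`,
#' `layer3_tfs.txt`, `network_edges.tsv`, `network.graphml`,
#' `regulatory_path.json`, `path.graphml`, `jaccards.txt` and `report.json`.
#' The report is self-contained and deterministic: re-running with the same
#' inputs and seed reproduces it byte-identically.
#'
#' @param expr Expression matrix or path to a TSV/CSV file.
#' @param interactions `interaction_table` or path to a 4-column TSV.
#' @param lineage `lineage_topology` or path to a YAML/JSON config.
#' @param regulators Optional global-regulator symbols (character vector or
#'   path to a one-symbol-per-line file); overrides
#'   `config$global_regulators`. Required for linear mode.
#' @param config A [pipeline_config()].
#' @param mode `"linear"` (signature screen) or `"tree"` (monotone rules).
#' @param target_cell Terminal cell of the analyzed lineage (tree mode).
#' @param tf_list Optional known-TF symbols (vector or path); defaults to
#'   the distinct regulators of the interaction table.
#' @param out_dir Optional output directory (created if needed).
#' @param run_permutation Run the permutation test (default `TRUE`).
#' @param dialect Expression file dialect when `expr` is a path.
#' @return Invisibly, a `pipeline_result`: list with `layer1`, `pattern`,
#'   `layer2`, `layer3`, `network`, `path`, `permutation` and the `report`
#'   list.
#' @export
run_pipeline <- function(expr, interactions, lineage, regulators = NULL,
                         config = pipeline_config(),
                         mode = c("linear", "tree"), target_cell = NULL,
                         tf_list = NULL, out_dir = NULL,
                         run_permutation = TRUE, dialect = "tsv") {
  mode <- match.arg(mode)
  warnings_log <- character(0)
  note <- function(...) warnings_log <<- c(warnings_log, paste0(...))

  if (is.character(expr) && length(expr) == 1L)
    expr <- read_expression(expr, dialect = dialect,
                            log2_transform = config$log2_transform)
  else if (config$log2_transform)
    expr <- log2(expr + 1)
  validate_expression_matrix(expr)
  if (is.character(interactions) && length(interactions) == 1L)
    interactions <- read_interactions(interactions)
  if (is.character(lineage) && length(lineage) == 1L &&
      file.exists(lineage))
    lineage <- read_lineage(lineage)
  if (!inherits(lineage, "lineage_topology"))
    abort_validation("lineage must be a lineage_topology or a config path")
  if (!is.null(regulators)) {
    if (length(regulators) == 1L && file.exists(regulators))
      regulators <- readLines(regulators)
    config$global_regulators <- canonical_symbol(regulators)
  }
  if (is.null(tf_list)) tf_list <- unique(interactions$regulator)
  else if (length(tf_list) == 1L && file.exists(tf_list))
    tf_list <- canonical_symbol(readLines(tf_list))

  # layer 1 + stage order
  if (mode == "linear") {
    if (lineage$kind != "linear")
      abort_validation("mode 'linear' requires a linear lineage topology")
    stages <- lineage$nodes
    missing <- setdiff(stages, colnames(expr))
    if (length(missing))
      abort_validation("lineage stage(s) absent from the matrix: ",
                       paste(missing, collapse = ", "))
    if (!all(colnames(expr) %in% stages))
      note("matrix column(s) not in the lineage were dropped: ",
           paste(setdiff(colnames(expr), stages), collapse = ", "))
    expr <- expr[, stages, drop = FALSE]
    if (!length(config$global_regulators))
      abort_validation("linear mode needs global regulators ",
                       "(config$global_regulators or the regulators argument)")
    layer1 <- find_stage_gene_sets(expr, config)
  } else {
    if (is.null(target_cell))
      abort_validation("tree mode requires target_cell")
    if (!target_cell %in% lineage$nodes)
      abort_validation("target cell '", target_cell,
                       "' is not in the lineage")
    leaves <- lineage_leaves(lineage)
    if (!target_cell %in% leaves)
      abort_validation("target cell '", target_cell,
                       "' must be a terminal cell of the lineage")
    stages <- lineage_path_to(lineage, target_cell)
    missing <- setdiff(stages, colnames(expr))
    if (length(missing))
      abort_validation("lineage cell(s) absent from the matrix: ",
                       paste(missing, collapse = ", "))
    sets <- lapply(stages, function(s)
      find_cell_specific_genes_tree(expr, lineage, s,
                                    leaf = if (s != target_cell) target_cell,
                                    max_violations = config$max_violations))
    names(sets) <- stages
    expr <- expr[, stages, drop = FALSE]
    layer1 <- structure(list(sets = sets, signatures = NULL),
                        class = "stage_gene_sets")
  }

  pattern <- integrate_lineage_pattern(expr, layer1,
                                       full_profile = config$pattern_full_profile)
  layer2 <- find_correlated_genes(expr, pattern, config, tf_list = tf_list)
  if (attr(layer2, "skipped_constant") > 0)
    note(attr(layer2, "skipped_constant"),
         " constant gene(s) skipped in the correlation screen")
  overlap12 <- length(intersect(layer2$gene, unique(unlist(layer1$sets))))

  layer3 <- find_regulators(layer2$gene, interactions)
  net <- build_subnetwork(layer2, interactions,
                          include_tf_tf = config$include_tf_tf)
  if (igraph::graph_attr(net, "dropped_self_loops") > 0)
    note(igraph::graph_attr(net, "dropped_self_loops"),
         " self-loop(s) dropped from the subnetwork")

  path <- if (igraph::vcount(net) == 0L) {
    note("regulatory network is empty; no pathway extracted")
    empty_regulatory_path(config$l)
  } else {
    withCallingHandlers(
      extract_regulatory_path(net, config),
      warning = function(w) {
        note(conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }
  if (length(path$unreachable))
    note("influencer(s) outside the selected component: ",
         paste(path$unreachable, collapse = ", "))

  permutation <- NULL
  if (run_permutation) {
    if (nrow(layer2) == 0L) {
      note("permutation test skipped: empty correlated gene set")
    } else {
      permutation <- permutation_significance(expr, pattern, layer2, config)
    }
  }

  report <- list(
    tool = "pathdevfate",
    version = as.character(utils::packageVersion("pathdevfate")),
    mode = mode,
    target_cell = target_cell,
    config = unclass(config),
    stages = stages,
    layer1 = list(per_stage = lapply(layer1$sets, length),
                  total_unique = length(unique(unlist(layer1$sets)))),
    pattern = as.list(unclass(pattern)),
    layer2 = list(n_genes = nrow(layer2),
                  n_tfs = sum(layer2$is_tf %||% FALSE),
                  overlap_with_layer1 = overlap12,
                  skipped_constant = attr(layer2, "skipped_constant")),
    layer3 = list(n_tfs = length(layer3)),
    network = list(n_nodes = igraph::vcount(net),
                   n_edges = igraph::ecount(net),
                   n_tfs = sum(igraph::V(net)$role %in% c("TF", "both")),
                   n_targets = sum(igraph::V(net)$role %in% c("target", "both")),
                   dropped_self_loops = igraph::graph_attr(net, "dropped_self_loops")),
    path = list(l = path$l,
                influencers = path$influencers,
                connectors = path$connectors,
                unreachable = path$unreachable,
                degrees = path$degrees),
    permutation = if (!is.null(permutation))
      list(n_perm = permutation$n_perm, tau = permutation$tau,
           exceed_count = permutation$exceed_count,
           p_value = permutation$p_value),
    warnings = warnings_log
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    safe <- function(s) gsub("[^A-Za-z0-9_.-]", "_", s)
    for (s in stages)
      write_gene_list(layer1$sets[[s]],
                      file.path(out_dir, paste0(safe(s), "_layer1.txt")))
    writeLines(c("stage\tvalue",
                 paste(stages, sprintf("%.17g", as.numeric(pattern)),
                       sep = "\t")),
               file.path(out_dir, "pattern.tsv"))
    utils::write.table(as.data.frame(layer2),
                       file.path(out_dir, "correlated_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_gene_list(layer3, file.path(out_dir, "layer3_tfs.txt"))
    write_edge_list(net, file.path(out_dir, "network_edges.tsv"))
    write_network_graphml(net, file.path(out_dir, "network.graphml"))
    regulatory_path_json(path, file.path(out_dir, "regulatory_path.json"))
    write_path_graphml(path, net, file.path(out_dir, "path.graphml"))
    if (!is.null(permutation))
      writeLines(sprintf("%.17g", permutation$jaccards),
                 file.path(out_dir, "jaccards.txt"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }

  invisible(structure(list(layer1 = layer1, pattern = pattern,
                           layer2 = layer2, layer3 = layer3, network = net,
                           path = path, permutation = permutation,
                           report = report),
                      class = "pipeline_result"))
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("pathdevfate pipeline run (%s mode)\n", r$mode))
  cat(sprintf("  layer 1: %d unique stage-specific gene(s) across %d stage(s)\n",
              r$layer1$total_unique, length(r$stages)))
  cat(sprintf("  layer 2: %d correlated gene(s) (%d TFs)\n",
              r$layer2$n_genes, r$layer2$n_tfs))
  cat(sprintf("  layer 3: %d regulator TF(s); network %d node(s) / %d edge(s)\n",
              r$layer3$n_tfs, r$network$n_nodes, r$network$n_edges))
  cat(sprintf("  influencers (l = %g): %s\n", r$path$l,
              if (length(r$path$influencers))
                paste(r$path$influencers, collapse = ", ") else "(none)"))
  cat(sprintf("  connectors: %s\n",
              if (length(r$path$connectors))
                paste(r$path$connectors, collapse = ", ") else "(none)"))
  if (!is.null(r$permutation))
    cat(sprintf("  permutation: %d/%d shuffles with Jaccard > %g (p = %g)\n",
                r$permutation$exceed_count, r$permutation$n_perm,
                r$permutation$tau, r$permutation$p_value))
  invisible(x)
}
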