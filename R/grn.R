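# Layers 3-4: regulators of the correlated genes are looked up in the curated
# interaction table, and the TF -> target edges terminating in layer-2 genes
# are assembled into a directed regulatory subnetwork (an igraph object with
# node roles and a per-edge mode annotation).

#' Find the regulators of a gene set
#'
#' All distinct TFs having at least one curated interaction whose target is
#' in the input set.
#'
#' @param targets Character vector of target gene symbols.
#' @param interactions An `interaction_table` (see [read_interactions()]).
#' @return Sorted character vector of TF symbols.
#' @export
find_regulators <- function(targets, interactions) {
  sort(unique(interactions$regulator[interactions$target %in% targets]))
}

#' Assemble the TF-target regulatory subnetwork
#'
#' The edge set is every curated interaction whose regulator is a layer-3 TF
#' and whose target is a layer-2 gene. Duplicate TF -> target pairs carrying
#' different modes collapse to one edge with the modes merged (slash-joined);
#' self-loops (autoregulation) are dropped and counted. Node roles are `TF`
#' (layer-3 only), `target` (layer-2 only) or `both`.
#'
#' @param layer2 Character vector of layer-2 gene symbols, or a
#'   `correlated_gene_set`.
#' @param interactions An `interaction_table`.
#' @param layer3 Optional TF set; must equal
#'   `find_regulators(layer2, interactions)` (asserted). Computed when
#'   omitted.
#' @param include_tf_tf If `TRUE`, additionally admit edges between two
#'   layer-3 TFs even when the regulated TF is not a layer-2 member.
#'   Default off.
#' @return A directed igraph with vertex attribute `role`, edge attribute
#'   `mode`, and graph attribute `dropped_self_loops`.
#' @export
build_subnetwork <- function(layer2, interactions, layer3 = NULL,
                             include_tf_tf = FALSE) {
  genes <- if (inherits(layer2, "correlated_gene_set")) layer2$gene
           else as.character(layer2)
  expected <- find_regulators(genes, interactions)
  if (is.null(layer3)) {
    layer3 <- expected
  } else if (!setequal(layer3, expected)) {
    abort_validation("layer3 must equal find_regulators(layer2, interactions)")
  }
  sel <- interactions$regulator %in% layer3 &
    (interactions$target %in% genes |
       (include_tf_tf & interactions$target %in% layer3))
  ed <- interactions[sel, c("regulator", "target", "mode"), drop = FALSE]
  loops <- ed$regulator == ed$target
  dropped <- length(unique(ed$regulator[loops]))
  ed <- ed[!loops, , drop = FALSE]
  if (nrow(ed)) {
    key <- paste(ed$regulator, ed$target, sep = "\r")
    mode <- vapply(split(ed$mode, key), function(m)
      paste(sort(unique(m)), collapse = "/"), "")
    uniq <- !duplicated(key)
    ed <- ed[uniq, , drop = FALSE]
    ed$mode <- unname(mode[paste(ed$regulator, ed$target, sep = "\r")])
    ed <- ed[order(ed$regulator, ed$target), , drop = FALSE]
  }
  net <- igraph::graph_from_data_frame(ed, directed = TRUE)
  vn <- igraph::V(net)$name
  role <- ifelse(vn %in% layer3 & vn %in% genes, "both",
                 ifelse(vn %in% layer3, "TF", "target"))
  igraph::V(net)$role <- role
  net <- igraph::set_graph_attr(net, "dropped_self_loops", dropped)
  net
}

#' Export a regulatory network as an edge-list TSV
#'
#' Three tab-separated columns: regulator, target, mode annotation.
#'
#' @param net A directed igraph from [build_subnetwork()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  ed <- igraph::as_data_frame(net, what = "edges")
  ed <- ed[order(ed$from, ed$to), , drop = FALSE]
  mode <- if ("mode" %in% names(ed)) ed$mode else rep("Unknown", nrow(ed))
  writeLines(c("regulator\ttarget\tmode",
               if (nrow(ed)) paste(ed$from, ed$to, mode, sep = "\t")), path)
  invisible(path)
}

#' Export a regulatory network as GraphML
#'
#' Role (and, for a regulatory path, influencer/connector flags) travel as
#' vertex attributes.
#'
#' @param net A directed igraph.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}
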