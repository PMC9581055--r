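# The regulatory-pathway extraction: target nodes regulated by more than l
# TFs are flagged as influencers, and a minimum set of Steiner connector
# nodes is added so that the influencers form one connected subgraph of the
# (undirected projection of the) regulatory network. The construction
# descends from the minimum connected dominating set idea: the influencer
# set is held fixed while the connector set is minimized.

#' Find influencer nodes by in-degree
#'
#' Nodes with at least one incoming edge whose in-degree strictly exceeds
#' `l` ("regulated by more than `l` TFs").
#'
#' @param net A directed igraph (see [build_subnetwork()]).
#' @param l Non-negative in-degree threshold.
#' @return Lexicographically sorted character vector of node names.
#' @export
find_influencers <- function(net, l) {
  if (!is.numeric(l) || length(l) != 1L || is.na(l) || l < 0)
    abort_validation("l must be a single value >= 0")
  indeg <- igraph::degree(net, mode = "in")
  sort(names(indeg)[indeg >= 1 & indeg > l])
}

#' Find minimal connector (Steiner) nodes joining the influencers
#'
#' Works on the undirected projection of the network. The connected
#' component holding the most influencers is selected (ties broken by
#' component size, then by lexicographically smallest member); influencers
#' in other components are reported as unreachable. Connectors are found by
#' the metric-closure minimum-spanning-tree Steiner approximation, followed
#' by pruning of non-influencer leaves and greedy irredundance pruning
#' (repeatedly removing, in lexicographic order, any connector whose removal
#' preserves connectivity). On small components an exhaustive search over
#' smaller candidate subsets then certifies that no smaller connector set
#' exists, so the reported set is exactly minimum there.
#'
#' @param net A directed igraph.
#' @param influencers Non-empty character vector of node names.
#' @return List with `connectors` (sorted), `reachable` (the influencers in
#'   the selected component), `unreachable`, and `edges` (data.frame of the
#'   directed edges of `net` joining influencers and connectors).
#' @export
find_connectors <- function(net, influencers) {
  influencers <- unique(as.character(influencers))
  if (!length(influencers))
    abort_validation("influencer set must not be empty")
  vn <- igraph::V(net)$name
  missing <- setdiff(influencers, vn)
  if (length(missing))
    abort_validation("influencer(s) not in the network: ",
                     paste(missing, collapse = ", "))

  g <- igraph::as_undirected(net, mode = "collapse")
  comp <- igraph::components(g)
  member <- comp$membership
  names(member) <- igraph::V(g)$name
  ids <- seq_len(comp$no)
  n_inf <- vapply(ids, function(i) sum(member[influencers] == i), 0L)
  csize <- comp$csize
  smallest <- vapply(ids, function(i) min(names(member)[member == i]), "")
  best <- ids[order(-n_inf, -csize, smallest)][1]

  terminals <- sort(influencers[member[influencers] == best])
  unreachable <- sort(setdiff(influencers, terminals))
  comp_vs <- names(member)[member == best]
  gc <- igraph::induced_subgraph(g, comp_vs)

  connected_with <- function(conn) {
    sub <- igraph::induced_subgraph(gc, c(terminals, conn))
    igraph::is_connected(sub)
  }

  connectors <- character(0)
  if (length(terminals) >= 2L) {
    # metric closure over the terminals, then MST, then the union of the
    # shortest paths realizing the MST edges
    pairs <- utils::combn(terminals, 2L)
    d <- igraph::distances(gc, v = terminals, to = terminals)
    closure <- data.frame(from = pairs[1, ], to = pairs[2, ],
                          weight = d[cbind(pairs[1, ], pairs[2, ])],
                          stringsAsFactors = FALSE)
    cg <- igraph::graph_from_data_frame(closure, directed = FALSE)
    tree <- igraph::mst(cg, weights = igraph::E(cg)$weight)
    te <- igraph::as_data_frame(tree, what = "edges")
    nodes <- terminals
    for (i in seq_len(nrow(te))) {
      sp <- igraph::shortest_paths(gc, from = te$from[i], to = te$to[i],
                                   output = "vpath")$vpath[[1]]
      nodes <- union(nodes, igraph::V(gc)$name[as.integer(sp)])
    }
    connectors <- setdiff(nodes, terminals)

    # prune connector leaves of the induced subgraph
    repeat {
      sub <- igraph::induced_subgraph(gc, c(terminals, connectors))
      deg <- igraph::degree(sub)
      drop <- intersect(names(deg)[deg <= 1], connectors)
      if (!length(drop)) break
      connectors <- setdiff(connectors, drop)
    }

    # greedy irredundance pruning, lexicographic order, to a fixpoint
    repeat {
      removed <- FALSE
      for (cnd in sort(connectors)) {
        if (connected_with(setdiff(connectors, cnd))) {
          connectors <- setdiff(connectors, cnd)
          removed <- TRUE
        }
      }
      if (!removed) break
    }

    # exact minimality certificate on small components: try all candidate
    # subsets strictly smaller than the approximate solution
    k <- length(connectors)
    if (k > 0L) {
      cand <- sort(setdiff(comp_vs, terminals))
      budget <- 2e5
      sizes <- 0:(k - 1L)
      total <- sum(choose(length(cand), sizes))
      if (total <= budget) {
        for (s in sizes) {
          found <- NULL
          if (s == 0L) {
            if (connected_with(character(0))) found <- character(0)
          } else if (length(cand) >= s) {
            cm <- utils::combn(cand, s)
            for (j in seq_len(ncol(cm))) {
              if (connected_with(cm[, j])) { found <- cm[, j]; break }
            }
          }
          if (!is.null(found)) { connectors <- found; break }
        }
      }
    }
  }

  connectors <- sort(connectors)
  keep <- c(terminals, connectors)
  sub_net <- igraph::induced_subgraph(net, intersect(vn, keep))
  edges <- igraph::as_data_frame(sub_net, what = "edges")
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  list(connectors = connectors, reachable = terminals,
       unreachable = unreachable, edges = edges)
}

empty_regulatory_path <- function(l) {
  structure(list(l = l, influencers = character(0),
                 connectors = character(0), unreachable = character(0),
                 edges = data.frame(from = character(0), to = character(0),
                                    stringsAsFactors = FALSE),
                 degrees = data.frame(node = character(0), role = character(0),
                                      in_degree = integer(0),
                                      out_degree = integer(0),
                                      stringsAsFactors = FALSE)),
            class = "regulatory_path")
}

#' Extract the regulatory pathway of a network
#'
#' Composes [find_influencers()] and [find_connectors()]: flags target nodes
#' with in-degree above `config$l` as influencers and joins them through a
#' minimal set of connector nodes. When no node exceeds the threshold an
#' empty pathway is returned with a warning (not an error).
#'
#' @param net A directed igraph (see [build_subnetwork()]).
#' @param config A [pipeline_config()]; `config$l` is the in-degree
#'   threshold.
#' @return An object of class `regulatory_path`: list with `l`,
#'   `influencers`, `connectors`, `unreachable`, `edges` and `degrees` (in-
#'   and out-degree of every reported node).
#' @export
extract_regulatory_path <- function(net, config = pipeline_config()) {
  if (igraph::vcount(net) == 0L)
    abort_validation("network is empty")
  influencers <- find_influencers(net, config$l)
  if (!length(influencers)) {
    warning("no node exceeds the in-degree threshold l = ", config$l,
            "; empty regulatory path")
    res <- list(connectors = character(0), reachable = character(0),
                unreachable = character(0),
                edges = data.frame(from = character(0), to = character(0),
                                   stringsAsFactors = FALSE))
  } else {
    res <- find_connectors(net, influencers)
  }
  nodes <- sort(c(res$reachable, res$unreachable, res$connectors))
  degrees <- if (length(nodes)) {
    data.frame(node = nodes,
               role = ifelse(nodes %in% res$connectors, "connector",
                             "influencer"),
               in_degree = unname(igraph::degree(net, v = nodes, mode = "in")),
               out_degree = unname(igraph::degree(net, v = nodes, mode = "out")),
               stringsAsFactors = FALSE)
  } else {
    data.frame(node = character(0), role = character(0),
               in_degree = integer(0), out_degree = integer(0),
               stringsAsFactors = FALSE)
  }
  structure(list(l = config$l,
                 influencers = influencers,
                 connectors = res$connectors,
                 unreachable = res$unreachable,
                 edges = res$edges,
                 degrees = degrees),
            class = "regulatory_path")
}

#' @export
print.regulatory_path <- function(x, ...) {
  cat(sprintf("regulatory_path (l = %g)\n", x$l))
  cat(sprintf("  influencers: %s\n",
              paste(x$influencers, collapse = ", ")))
  cat(sprintf("  connectors:  %s\n",
              if (length(x$connectors)) paste(x$connectors, collapse = ", ")
              else "(none)"))
  if (length(x$unreachable))
    cat(sprintf("  unreachable: %s\n", paste(x$unreachable, collapse = ", ")))
  invisible(x)
}

#' Serialize a regulatory path to JSON
#'
#' Field order and vector ordering are fixed, so identical inputs yield
#' byte-identical serializations.
#'
#' @param path A `regulatory_path`.
#' @param file Optional output path; when omitted the JSON string is
#'   returned.
#' @return The JSON string (invisibly when `file` is given).
#' @export
regulatory_path_json <- function(path, file = NULL) {
  obj <- list(l = path$l,
              influencers = path$influencers,
              connectors = path$connectors,
              unreachable = path$unreachable,
              edges = path$edges,
              degrees = path$degrees)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(js)
}

#' Export a regulatory path as a two-color GraphML
#'
#' Influencers and connectors are distinguished by a `role` vertex
#' attribute and a `color` attribute (influencer = red, connector = blue).
#'
#' @param path A `regulatory_path`.
#' @param net The network the path was extracted from.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_path_graphml <- function(path, net, file) {
  keep <- c(path$influencers, path$connectors)
  keep <- intersect(igraph::V(net)$name, keep)
  sub <- igraph::induced_subgraph(net, keep)
  role <- ifelse(igraph::V(sub)$name %in% path$connectors,
                 "connector", "influencer")
  igraph::V(sub)$role <- role
  igraph::V(sub)$color <- ifelse(role == "connector", "blue", "red")
  igraph::write_graph(sub, file, format = "graphml")
  invisible(file)
}
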