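# I/O layer: expression matrices (TSV/CSV, genes x stages), TF-target
# interaction tables (TRRUST v2 4-column dialect) and lineage topology
# configs (YAML/JSON). Everything is validated into plain, predictable
# containers: a numeric matrix with gene rownames / stage colnames, a
# data.frame of interaction records, and a small `lineage_topology` list.

#' Validate a genes-by-stages expression matrix
#'
#' Checks the invariants every pipeline step relies on: unique canonical gene
#' symbols as rownames, non-empty stage labels as colnames, and all values
#' finite.
#'
#' @param values Numeric matrix, genes in rows, stages in columns.
#' @return The matrix, invisibly, with canonicalized rownames.
#' @export
validate_expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    abort_validation("expression matrix must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    abort_validation("expression matrix needs gene rownames and stage colnames")
  rn <- canonical_symbol(rownames(values))
  if (any(!nzchar(rn)))
    abort_validation("empty gene symbol in expression matrix")
  dup <- unique(rn[duplicated(rn)])
  if (length(dup))
    abort_validation("duplicate gene symbols after case normalization: ",
                     paste(dup, collapse = ", "))
  if (any(!nzchar(colnames(values))))
    abort_validation("empty stage label in expression matrix")
  if (!all(is.finite(values)))
    abort_validation("expression matrix contains non-finite values")
  rownames(values) <- rn
  invisible(values)
}

#' Read an expression matrix from delimited text
#'
#' Expects a header row of stage labels and a first column of gene symbols,
#' followed by a numeric body. Gene symbols are canonicalized
#' (first-letter-uppercase); duplicate rows after canonicalization are
#' rejected. Replicate columns that share a stage label are averaged into a
#' single column, so the result carries exactly one profile per stage.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param log2_transform Apply `log2(x + 1)` to the values after loading.
#' @return Numeric matrix (genes x stages).
#' @export
read_expression <- function(path, dialect = c("tsv", "csv"),
                            log2_transform = FALSE) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  if (!file.exists(path))
    abort_validation("expression file not found: ", path)

  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(first))
    abort_format("expression file is empty: ", path)
  header <- strsplit(first, sep, fixed = TRUE)[[1]]
  if (length(header) < 2L)
    abort_format("expression header must name at least one stage: ", path)
  numeric_like <- !is.na(suppressWarnings(as.numeric(header[-1])))
  if (any(numeric_like))
    abort_format("expression file appears to lack a header row ",
                 "(numeric stage labels): ", path)

  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    abort_format("expression file must have a gene column plus stage columns")
  genes <- raw[[1]]
  body <- as.matrix(raw[, -1, drop = FALSE])
  colnames(body) <- colnames(raw)[-1]  # as.matrix mangles duplicate labels
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body),
                                dimnames = dimnames(body)))
  bad_rows <- which(apply(is.na(num), 1L, any))
  if (length(bad_rows))
    abort_validation("non-numeric expression value(s) at data row(s): ",
                     paste(bad_rows, collapse = ", "))

  rownames(num) <- canonical_symbol(genes)
  dup <- unique(rownames(num)[duplicated(rownames(num))])
  if (length(dup))
    abort_validation("duplicate gene symbols after case normalization: ",
                     paste(dup, collapse = ", "))

  # average replicate columns sharing a stage label, preserving first
  # occurrence order
  labels <- colnames(num)
  if (anyDuplicated(labels)) {
    uniq <- unique(labels)
    num <- vapply(uniq, function(lb)
      rowMeans(num[, labels == lb, drop = FALSE]), numeric(nrow(num)))
    dimnames(num) <- list(canonical_symbol(genes), uniq)
  }
  if (log2_transform) num <- log2(num + 1)
  validate_expression_matrix(num)
  num
}

#' Write an expression matrix to delimited text
#'
#' Values are written with 17 significant digits so that
#' `read_expression(write_expression(m))` round-trips to full double
#' precision and preserves row and column order.
#'
#' @param values Numeric matrix (genes x stages).
#' @param path Output path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(values, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  validate_expression_matrix(values)
  chr <- apply(values, c(1, 2), function(v) sprintf("%.17g", v))
  lines <- c(paste(c("gene", colnames(values)), collapse = sep),
             vapply(seq_len(nrow(values)), function(i)
               paste(c(rownames(values)[i], chr[i, ]), collapse = sep), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read a TF-target interaction table (TRRUST v2 dialect)
#'
#' Four tab-separated columns: TF symbol, target symbol, regulation mode
#' (Activation/Repression/Unknown), and a comma- or semicolon-separated list
#' of publication ids. Symbols are canonicalized; exact duplicate
#' (regulator, target, mode) records are collapsed (their evidence lists are
#' merged).
#'
#' @param path Path to the file.
#' @return A data.frame of class `interaction_table` with columns
#'   `regulator`, `target`, `mode` and list-column `evidence`; attributes
#'   `n_regulators` and `n_records` report unique-regulator and record
#'   counts.
#' @export
read_interactions <- function(path) {
  if (!file.exists(path))
    abort_validation("interaction file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    abort_format("interaction file is empty: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != 4L)
  if (length(bad))
    abort_format("expected 4 tab-separated columns; offending line(s): ",
                 paste(bad, collapse = ", "))
  reg <- canonical_symbol(vapply(parts, `[[`, "", 1L))
  tgt <- canonical_symbol(vapply(parts, `[[`, "", 2L))
  mode <- trimws(vapply(parts, `[[`, "", 3L))
  ev_raw <- vapply(parts, `[[`, "", 4L)
  if (any(!nzchar(reg)) || any(!nzchar(tgt)))
    abort_validation("empty regulator or target symbol in interaction table")
  evidence <- lapply(strsplit(ev_raw, "[,;]"), function(e) {
    e <- trimws(e)
    e[nzchar(e)]
  })

  key <- paste(reg, tgt, mode, sep = "\r")
  keep <- !duplicated(key)
  if (any(!keep)) {
    merged <- split(evidence, key)
    evidence <- lapply(merged[unique(key)], function(e) unique(unlist(e)))
    names(evidence) <- NULL
  } else {
    evidence <- evidence[keep]
  }
  tab <- data.frame(regulator = reg[keep], target = tgt[keep],
                    mode = mode[keep], stringsAsFactors = FALSE)
  tab$evidence <- evidence
  class(tab) <- c("interaction_table", "data.frame")
  attr(tab, "n_regulators") <- length(unique(tab$regulator))
  attr(tab, "n_records") <- nrow(tab)
  tab
}

#' Write a TF-target interaction table in the 4-column dialect
#'
#' @param tab An `interaction_table` (or compatible data.frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(tab, path) {
  ev <- vapply(tab$evidence, paste, "", collapse = ";")
  writeLines(paste(tab$regulator, tab$target, tab$mode, ev, sep = "\t"), path)
  invisible(path)
}

#' Construct a linear lineage topology
#'
#' @param stages Ordered character vector of stage labels, root first.
#' @return A `lineage_topology` object.
#' @export
lineage_linear <- function(stages) {
  stages <- as.character(stages)
  if (length(stages) < 2L)
    abort_validation("a linear lineage needs at least two stages")
  if (anyDuplicated(stages))
    abort_validation("duplicate stage labels in linear lineage")
  edges <- cbind(parent = stages[-length(stages)], child = stages[-1])
  structure(list(kind = "linear", nodes = stages, edges = edges,
                 root = stages[1]),
            class = "lineage_topology")
}

#' Construct a rooted tree lineage topology
#'
#' @param edges Two-column matrix or data.frame of parent -> child relations.
#' @param nodes Optional full node set for validation; every edge endpoint
#'   must belong to it.
#' @return A `lineage_topology` object (kind `"tree"`, or `"linear"` when the
#'   tree happens to be a simple path).
#' @export
lineage_tree <- function(edges, nodes = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L)
    abort_validation("tree edges must have two columns (parent, child)")
  storage.mode(edges) <- "character"
  colnames(edges) <- c("parent", "child")
  all_nodes <- unique(c(edges))
  if (!is.null(nodes)) {
    nodes <- as.character(nodes)
    missing <- setdiff(all_nodes, nodes)
    if (length(missing))
      abort_validation("edge node(s) absent from declared stage set: ",
                       paste(missing, collapse = ", "))
    all_nodes <- union(nodes, all_nodes)
  }
  g <- igraph::graph_from_edgelist(edges, directed = TRUE)
  g <- g + igraph::vertices(setdiff(all_nodes, igraph::V(g)$name))
  if (!igraph::is_dag(g))
    abort_validation("lineage tree contains a cycle")
  indeg <- igraph::degree(g, mode = "in")
  roots <- names(indeg)[indeg == 0]
  if (length(roots) != 1L)
    abort_validation("lineage tree must have exactly one root; found: ",
                     paste(sort(roots), collapse = ", "))
  if (any(indeg > 1L))
    abort_validation("lineage tree node(s) with multiple parents: ",
                     paste(sort(names(indeg)[indeg > 1L]), collapse = ", "))
  if (!igraph::is_connected(g, mode = "weak"))
    abort_validation("lineage tree is not connected")
  outdeg <- igraph::degree(g, mode = "out")
  kind <- if (all(outdeg <= 1L)) "linear" else "tree"
  structure(list(kind = kind, nodes = igraph::V(g)$name, edges = edges,
                 root = roots),
            class = "lineage_topology")
}

#' Read a lineage topology from a YAML or JSON config
#'
#' The config declares `kind: linear` with an ordered `stages` list, or
#' `kind: tree` with an `edges` list of `[parent, child]` pairs (optionally a
#' full `stages` set and an explicit `root`, which must agree with the
#' inferred one).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `lineage_topology` object.
#' @export
read_lineage <- function(path) {
  if (!file.exists(path))
    abort_validation("lineage file not found: ", path)
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
  kind <- tolower(spec$kind %||% "linear")
  topo <- if (kind == "linear") {
    if (is.null(spec$stages))
      abort_format("linear lineage config needs a 'stages' list")
    lineage_linear(unlist(spec$stages))
  } else if (kind == "tree") {
    if (is.null(spec$edges))
      abort_format("tree lineage config needs an 'edges' list")
    el <- spec$edges
    if (is.list(el)) el <- do.call(rbind, lapply(el, unlist))
    lineage_tree(el, nodes = if (!is.null(spec$stages)) unlist(spec$stages))
  } else {
    abort_format("unknown lineage kind: ", kind)
  }
  if (!is.null(spec$root) && !identical(as.character(spec$root), topo$root))
    abort_validation("declared root '", spec$root,
                     "' does not match inferred root '", topo$root, "'")
  topo
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.lineage_topology <- function(x, ...) {
  cat(sprintf("lineage_topology: %s, %d node(s), root %s\n",
              x$kind, length(x$nodes), x$root))
  invisible(x)
}

# igraph view of a topology, for path/leaf queries
lineage_graph <- function(topo) {
  g <- igraph::graph_from_edgelist(topo$edges, directed = TRUE)
  g + igraph::vertices(setdiff(topo$nodes, igraph::V(g)$name))
}

# ordered root -> node path (character vector of stage labels)
lineage_path_to <- function(topo, node) {
  if (!node %in% topo$nodes)
    abort_validation("node '", node, "' is not part of the lineage")
  g <- lineage_graph(topo)
  p <- igraph::shortest_paths(g, from = topo$root, to = node,
                              mode = "out")$vpath[[1]]
  if (!length(p))
    abort_validation("no root-to-'", node, "' path in the lineage")
  igraph::V(g)$name[as.integer(p)]
}

lineage_leaves <- function(topo) {
  g <- lineage_graph(topo)
  names(which(igraph::degree(g, mode = "out") == 0))
}

# all node -> leaf continuations (list of label vectors, each starting at node)
lineage_continuations <- function(topo, node, leaf = NULL) {
  g <- lineage_graph(topo)
  leaves <- lineage_leaves(topo)
  if (node %in% leaves) return(list())
  if (!is.null(leaf)) {
    if (!leaf %in% leaves)
      abort_validation("'", leaf, "' is not a terminal cell of the lineage")
    leaves <- leaf
  }
  paths <- lapply(leaves, function(lf) {
    p <- suppressWarnings(
      igraph::shortest_paths(g, from = node, to = lf, mode = "out")$vpath[[1]])
    if (length(p)) igraph::V(g)$name[as.integer(p)] else NULL
  })
  paths <- Filter(Negate(is.null), paths)
  if (!is.null(leaf) && !length(paths))
    abort_validation("terminal cell '", leaf, "' is not downstream of '",
                     node, "'")
  paths
}

#' Write a one-symbol-per-line gene list
#'
#' @param genes Character vector of gene symbols.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}
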