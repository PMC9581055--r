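# Independent oracles, kept free of the code paths they check.

# explicit average-rank construction (no call to rank())
oracle_rank <- function(x) {
  vapply(seq_along(x), function(i)
    sum(x < x[i]) + (1 + sum(x == x[i])) / 2, 0)
}

# product-moment of the explicit rank vectors
oracle_spearman <- function(x, y) {
  rx <- oracle_rank(x); ry <- oracle_rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# exhaustive minimum number of Steiner connector nodes joining `terminals`
# within the undirected graph `gu` (terminals assumed in one component)
oracle_min_steiner <- function(gu, terminals) {
  cand <- sort(setdiff(igraph::V(gu)$name, terminals))
  for (s in 0:length(cand)) {
    if (s == 0) {
      if (igraph::is_connected(igraph::induced_subgraph(gu, terminals)))
        return(0L)
    } else {
      cm <- utils::combn(cand, s)
      for (j in seq_len(ncol(cm))) {
        sub <- igraph::induced_subgraph(gu, c(terminals, cm[, j]))
        if (igraph::is_connected(sub)) return(s)
      }
    }
  }
  Inf
}

# naive in-degree influencer count straight off the edge list
oracle_influencers <- function(net, l) {
  ed <- igraph::as_data_frame(net, what = "edges")
  cnt <- table(ed$to)
  sort(as.character(names(cnt)[cnt >= 1 & cnt > l]))
}

random_digraph <- function(n, p, label = "n%02d") {
  g <- igraph::sample_gnp(n, p, directed = TRUE)
  igraph::V(g)$name <- sprintf(label, seq_len(n))
  g
}
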