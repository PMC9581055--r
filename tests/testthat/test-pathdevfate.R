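test_that("influencers are the nodes whose in-degree strictly exceeds l", {
  net <- igraph::graph_from_data_frame(
    data.frame(from = c("A", "B", "C"), to = "X"), directed = TRUE)
  expect_identical(find_influencers(net, 2), "X")
  expect_identical(find_influencers(net, 3), character(0))
  hubs <- igraph::graph_from_data_frame(
    data.frame(from = sprintf("T%02d", 1:12),
               to = rep(c("H1", "H2"), each = 6)), directed = TRUE)
  expect_identical(find_influencers(hubs, 5), c("H1", "H2"))
  expect_error(find_influencers(net, -1),
               class = "pathdevfate_validation_error")
})

test_that("connector search handles shared regulators and adjacent influencers", {
  shared <- igraph::graph_from_data_frame(
    data.frame(from = "T1", to = c("G1", "G2")), directed = TRUE)
  res <- find_connectors(shared, c("G1", "G2"))
  expect_identical(res$connectors, "T1")
  adjacent <- igraph::graph_from_data_frame(
    data.frame(from = "G1", to = "G2"), directed = TRUE)
  res2 <- find_connectors(adjacent, c("G1", "G2"))
  expect_identical(res2$connectors, character(0))
  expect_error(find_connectors(shared, character(0)),
               class = "pathdevfate_validation_error")
})

test_that("influencers in other components are reported unreachable", {
  net <- igraph::graph_from_data_frame(
    data.frame(from = c("T1", "T1", "T9"), to = c("G1", "G2", "G9")),
    directed = TRUE)
  res <- find_connectors(net, c("G1", "G2", "G9"))
  expect_identical(res$reachable, c("G1", "G2"))
  expect_identical(res$unreachable, "G9")
  expect_identical(res$connectors, "T1")
})

test_that("connector sets match the exhaustive Steiner minimum on small digraphs", {
  set.seed(202)
  checked <- 0
  while (checked < 40) {
    n <- sample(5:12, 1)
    g <- random_digraph(n, runif(1, 0.2, 0.4))
    gu <- igraph::as_undirected(g, mode = "collapse")
    comp <- igraph::components(gu)
    vs <- igraph::V(gu)$name[comp$membership == which.max(comp$csize)]
    if (length(vs) < 4) next
    infl <- sample(vs, sample(2:min(4, length(vs)), 1))
    res <- find_connectors(g, infl)
    exact <- oracle_min_steiner(igraph::induced_subgraph(gu, vs), sort(infl))
    expect_equal(length(res$connectors), exact)
    # reported subgraph is connected
    sub <- igraph::induced_subgraph(gu, c(sort(infl), res$connectors))
    expect_true(igraph::is_connected(sub))
    checked <- checked + 1
  }
})

test_that("path extraction keeps the influencer set fixed while minimizing connectors", {
  tfs <- sprintf("T%02d", 1:14)
  ed <- data.frame(
    from = c(rep(c("Contf1", "Contf2"), 3), rep(tfs[1:12], 1)),
    to = c(rep(c("Ccnd2", "Pparg", "Ihh"), each = 2),
           rep(c("Ccnd2", "Pparg", "Ihh"), each = 4)))
  net <- igraph::graph_from_data_frame(ed, directed = TRUE)
  cfg <- pipeline_config(l = 5)
  before <- find_influencers(net, cfg$l)
  path <- extract_regulatory_path(net, cfg)
  expect_identical(path$influencers, before)
  expect_identical(path$influencers, c("Ccnd2", "Ihh", "Pparg"))
  expect_true(all(path$connectors %in% c("Contf1", "Contf2")))
  expect_length(path$connectors, 1L)
  expect_identical(
    sort(unique(path$degrees$role)), c("connector", "influencer"))
})

test_that("raising l never enlarges the influencer set; empty result warns", {
  set.seed(77)
  for (i in 1:20) {
    g <- random_digraph(sample(8:20, 1), 0.3)
    prev <- igraph::V(g)$name
    for (l in c(0, 1, 2, 5, 10)) {
      cur <- find_influencers(g, l)
      expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
  net <- igraph::graph_from_data_frame(
    data.frame(from = "A", to = "B"), directed = TRUE)
  expect_warning(path <- extract_regulatory_path(net, pipeline_config(l = 99)),
                 "empty")
  expect_length(path$influencers, 0L)
  expect_length(path$connectors, 0L)
})

test_that("identical inputs give byte-identical path serializations", {
  set.seed(5)
  g <- random_digraph(15, 0.25)
  cfg <- pipeline_config(l = 1)
  j1 <- regulatory_path_json(extract_regulatory_path(g, cfg))
  j2 <- regulatory_path_json(extract_regulatory_path(g, cfg))
  expect_identical(as.character(j1), as.character(j2))
})
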