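test_that("expression files are parsed with dimension bookkeeping", {
  p <- write_tsv_lines(c(
    paste(c("gene", six_stages), collapse = "\t"),
    paste(c("Sox2", 1:6), collapse = "\t"),
    paste(c("Gata1", 6:1), collapse = "\t"),
    paste(c("Tal1", rep(2, 6)), collapse = "\t")))
  m <- read_expression(p)
  expect_identical(dim(m), c(3L, 6L))
  expect_identical(rownames(m), c("Sox2", "Gata1", "Tal1"))
  expect_identical(colnames(m), six_stages)
  expect_equal(unname(m["Sox2", ]), as.numeric(1:6))
})

test_that("duplicate symbols (case-insensitive) and bad cells are rejected", {
  dup <- write_tsv_lines(c("gene\tA\tB", "Sox2\t1\t2", "SOX2\t3\t4"))
  expect_error(read_expression(dup), "Sox2",
               class = "pathdevfate_validation_error")
  bad <- write_tsv_lines(c("gene\tA\tB", "G1\t1\t2", "G2\tNA\t4"))
  expect_error(read_expression(bad), "row\\(s\\): 2",
               class = "pathdevfate_validation_error")
  nohead <- write_tsv_lines(c("G0\t1\t2", "G1\t1\t2"))
  expect_error(read_expression(nohead), "header",
               class = "pathdevfate_format_error")
})

test_that("replicate columns sharing a stage label are averaged", {
  p <- write_tsv_lines(c("gene\tESC\tESC\tMES",
                         "G1\t2\t4\t7",
                         "G2\t1\t1\t9"))
  m <- read_expression(p)
  expect_identical(colnames(m), c("ESC", "MES"))
  expect_equal(unname(m["G1", ]), c(3, 7))
})

test_that("expression write/read round-trips values and order exactly", {
  set.seed(4)
  m <- matrix(rlnorm(24) * pi, 4, 6,
              dimnames = list(c("Zic3", "Esrrb", "Id1", "Onecut1"), six_stages))
  p <- tempfile(fileext = ".tsv")
  write_expression(m, p)
  expect_identical(read_expression(p), m)
  # csv dialect too
  pc <- tempfile(fileext = ".csv")
  write_expression(m, pc, dialect = "csv")
  expect_identical(read_expression(pc, dialect = "csv"), m)
})

test_that("interaction tables parse, dedupe and report malformed lines", {
  tab <- tiny_interactions(c("Msx2\tCcnd2\tUnknown\t12345",
                             "Foxo1\tIhh\tActivation\t1,2;3",
                             "Msx2\tCcnd2\tUnknown\t12345"))
  expect_equal(nrow(tab), 2L)
  expect_identical(tab$regulator[1], "Msx2")
  expect_identical(tab$evidence[[2]], c("1", "2", "3"))
  expect_equal(attr(tab, "n_regulators"), 2L)
  expect_error(tiny_interactions(c("Msx2\tCcnd2\tUnknown\t1", "A\tB")),
               "line\\(s\\): 2", class = "pathdevfate_format_error")
})

test_that("interaction parsing is idempotent under re-serialization", {
  tab <- tiny_interactions(c("MSX2\tccnd2\tUnknown\t1;2",
                             "Foxo1\tIhh\tActivation\t3",
                             "Foxo1\tIhh\tRepression\t4"))
  p <- tempfile()
  write_interactions(tab, p)
  again <- read_interactions(p)
  expect_equal(again, tab, ignore_attr = TRUE)
})

test_that("lineage configs validate path and tree invariants", {
  lin <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(kind = "linear", stages = as.list(six_stages)), lin)
  topo <- read_lineage(lin)
  expect_identical(topo$kind, "linear")
  expect_identical(topo$root, "ESC")
  expect_identical(topo$nodes, six_stages)

  cyc <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(kind = "tree",
                        edges = list(c("B", "A"), c("A", "B"))), cyc)
  expect_error(read_lineage(cyc), "cycle",
               class = "pathdevfate_validation_error")

  two <- tempfile(fileext = ".json")
  jsonlite::write_json(list(kind = "tree",
                            edges = list(c("R1", "A"), c("R2", "B"))),
                       two, auto_unbox = TRUE)
  expect_error(read_lineage(two), "root",
               class = "pathdevfate_validation_error")

  undeclared <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(kind = "tree", stages = list("A", "B"),
                        edges = list(c("A", "B"), c("A", "C"))), undeclared)
  expect_error(read_lineage(undeclared), "C",
               class = "pathdevfate_validation_error")
})

test_that("symbols are canonicalized to the mouse convention", {
  expect_identical(canonical_symbol(c("SOX2", "gata1 ", "Stat5b")),
                   c("Sox2", "Gata1", "Stat5b"))
})
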