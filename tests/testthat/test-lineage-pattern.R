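test_that("pattern integration takes per-stage means of each stage's own genes", {
  expr <- make_expr(list(G1 = c(8, 1, 1, 1, 1, 1),
                         G2 = c(6, 2, 1, 1, 1, 1),
                         G3 = c(1, 7, 1, 1, 1, 1),
                         G4 = c(1, 1, 5, 1, 1, 1),
                         G5 = c(1, 1, 1, 4, 1, 1),
                         G6 = c(1, 1, 1, 1, 3, 1),
                         G7 = c(1, 1, 1, 1, 1, 2)))
  sets <- list(ESC = c("G1", "G2"), MES = "G3", HB = "G4",
               HE = "G5", HP = "G6", MAC = "G7")
  pat <- integrate_lineage_pattern(expr, sets)
  expect_equal(unname(unclass(pat)), c(7, 7, 5, 4, 3, 2))
  # one gene per stage: pattern is the diagonal of peak values
  solo <- integrate_lineage_pattern(expr, lapply(sets, `[`, 1))
  expect_equal(unname(unclass(solo)), c(8, 7, 5, 4, 3, 2))
  sets$HP <- character(0)
  expect_error(integrate_lineage_pattern(expr, sets), "HP",
               class = "pathdevfate_validation_error")
})

test_that("pattern integration is permutation-equivariant in stage order", {
  ge <- generate_expression(per_stage = 4, n_background = 20,
                            n_followers = 0, noise_sigma = 0.1, seed = 12)
  sets <- ge$truth$planted_stage_genes
  pat <- integrate_lineage_pattern(ge$expr, sets)
  perm <- c(3, 1, 6, 2, 5, 4)
  pat_perm <- integrate_lineage_pattern(ge$expr[, perm], sets)
  expect_equal(unclass(pat_perm), unclass(pat)[perm])
})

test_that("spearman_rho matches hand cases and rejects degenerate input", {
  expect_equal(spearman_rho(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_equal(spearman_rho(c(1, 2, 3), c(6, 4, 2)), -1.0)
  expect_error(spearman_rho(c(1, 1, 1), c(1, 2, 3)),
               class = "pathdevfate_validation_error")
  expect_error(spearman_rho(1:3, 1:4), class = "pathdevfate_validation_error")
})

test_that("spearman_rho ties agree with the explicit average-rank oracle", {
  expect_equal(spearman_rho(c(1, 2, 2, 3), c(1, 3, 2, 4)),
               oracle_spearman(c(1, 2, 2, 3), c(1, 3, 2, 4)),
               tolerance = 1e-12)
  set.seed(55)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    x <- sample(1:5, n, replace = TRUE) + ifelse(runif(n) < 0.5, 0, 0.25)
    y <- sample(1:4, n, replace = TRUE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    expect_equal(spearman_rho(x, y), oracle_spearman(x, y), tolerance = 1e-12)
  }
})

test_that("correlated-gene screen records rho, skips constants, orders deterministically", {
  pat <- stats::setNames(c(5, 12, 30, 22, 9, 3), six_stages)
  expr <- make_expr(list(Exact = c(5, 12, 30, 22, 9, 3),
                         Scaled = 2 * c(5, 12, 30, 22, 9, 3),
                         Near = c(5, 13, 30, 22, 8, 3),
                         Anti = rev(c(5, 12, 30, 22, 9, 3)),
                         Flat = rep(4, 6)))
  got <- find_correlated_genes(expr, pat, pipeline_config(),
                               tf_list = c("Near"))
  expect_identical(got$gene, c("Exact", "Near", "Scaled"))
  expect_equal(got$rho, c(1, 1, 1))
  expect_identical(got$is_tf, c(FALSE, TRUE, FALSE))
  expect_equal(attr(got, "skipped_constant"), 1L)
})

test_that("planted pattern followers are recovered exactly among 2000 genes", {
  ge <- generate_expression(per_stage = 5, n_background = 1940,
                            n_followers = 30, noise_sigma = 0.05, seed = 77)
  got <- find_correlated_genes(ge$expr, ge$truth$lineage_profile,
                               pipeline_config())
  expect_setequal(got$gene, ge$truth$planted_followers)
})

test_that("membership under the screen is invariant to positive scaling of a gene", {
  ge <- generate_expression(per_stage = 5, n_background = 100,
                            n_followers = 10, noise_sigma = 0.2, seed = 13)
  cfg <- pipeline_config()
  base <- find_correlated_genes(ge$expr, ge$truth$lineage_profile, cfg)$gene
  scaled <- ge$expr
  scaled["Folw001", ] <- scaled["Folw001", ] * 137.5
  scaled["Bg0001", ] <- scaled["Bg0001", ] * 0.004
  again <- find_correlated_genes(scaled, ge$truth$lineage_profile, cfg)$gene
  expect_setequal(again, base)
})
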