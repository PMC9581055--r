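test_that("peak detection handles unique, tied and constant profiles", {
  expect_identical(detect_peak_stage(c(2, 9, 3, 1, 1, 1)), "2")
  expect_identical(
    detect_peak_stage(stats::setNames(c(2, 9, 3, 1, 1, 1), six_stages)), "MES")
  expect_identical(detect_peak_stage(c(5, 5, 1, 1, 1, 1), strict = TRUE),
                   NA_character_)
  expect_identical(detect_peak_stage(rep(2, 6), strict = TRUE), NA_character_)
  expect_identical(detect_peak_stage(c(5, 5, 1, 1), strict = FALSE), "1")
  expect_error(detect_peak_stage(3), class = "pathdevfate_validation_error")
})

test_that("stage signatures average the peaking regulators", {
  regs <- make_expr(list(R1 = c(10, 2, 1, 1, 1, 1),
                         R2 = c(6, 4, 1, 1, 1, 1),
                         R3 = c(1, 9, 2, 1, 1, 1)))
  sg <- build_stage_signature(regs, "ESC")
  expect_identical(sg$members, c("R1", "R2"))
  expect_equal(unname(sg$profile), c(8, 3, 1, 1, 1, 1))
  # single peaking regulator: signature equals its own profile
  sg3 <- build_stage_signature(regs, "MES")
  expect_equal(sg3$profile, regs["R3", ])
  # signature self-consistency (peak at its own stage)
  expect_identical(detect_peak_stage(sg$profile, strict = TRUE), "ESC")
  expect_error(build_stage_signature(regs, "MAC"), "MAC",
               class = "pathdevfate_validation_error")
})

test_that("stage screen keeps monotone matches and drops antitone ones", {
  sig <- build_stage_signature(
    make_expr(list(R1 = c(9, 4, 3, 2, 1.5, 1))), "ESC")
  expr <- make_expr(list(Same = c(9, 4, 3, 2, 1.5, 1),
                         Scaled = c(90, 40, 30, 20, 15, 10),
                         Rev = c(1, 1.5, 2, 3, 4, 9),
                         Flat = rep(3, 6)))
  got <- find_stage_specific_genes(expr, sig, pipeline_config())
  expect_setequal(got, c("Same", "Scaled"))
})

test_that("stage screen agrees with an explicit rank-correlation oracle on a planted matrix", {
  ge <- generate_expression(per_stage = 50, n_background = 1950,
                            n_followers = 0, noise_sigma = 0.05, seed = 101)
  cfg <- pipeline_config(global_regulators = ge$truth$global_regulators)
  regs <- ge$expr[intersect(cfg$global_regulators, rownames(ge$expr)), ,
                  drop = FALSE]
  for (stage in c("ESC", "HB", "MAC")) {
    sig <- build_stage_signature(regs, stage)
    got <- find_stage_specific_genes(ge$expr, sig, cfg)
    oracle <- vapply(rownames(ge$expr), function(g) {
      v <- ge$expr[g, ]
      if (stats::sd(v) == 0) return(FALSE)
      rho <- oracle_spearman(v, sig$profile)
      pk <- which(v == max(v))
      rho > cfg$rho_min && length(pk) == 1L && six_stages[pk] == stage
    }, TRUE)
    expect_setequal(got, rownames(ge$expr)[oracle])
    expect_gt(length(got), 0)
  }
})

test_that("strict-mode members always peak at the signature stage", {
  ge <- generate_expression(per_stage = 8, n_background = 150,
                            n_followers = 0, noise_sigma = 0.3, seed = 7)
  cfg <- pipeline_config(global_regulators = ge$truth$global_regulators)
  l1 <- find_stage_gene_sets(ge$expr, cfg)
  for (s in six_stages) {
    for (g in l1$sets[[s]])
      expect_identical(detect_peak_stage(ge$expr[g, ], strict = TRUE), s)
  }
})

test_that("tree rules require monotone rise to the target and fall beyond it", {
  tree <- lineage_tree(rbind(c("HSC", "MPP"), c("MPP", "CLP"), c("CLP", "B")))
  expr <- make_expr(list(Up = c(1, 2, 5, 3),
                         Early = c(1, 6, 5, 3),
                         Term = c(1, 2, 3, 9),
                         Tie = c(1, 2, 2, 1)),
                    stages = c("HSC", "MPP", "CLP", "B"))
  expect_identical(find_cell_specific_genes_tree(expr, tree, "CLP"), "Up")
  expect_identical(find_cell_specific_genes_tree(expr, tree, "B"), "Term")
  expect_identical(find_cell_specific_genes_tree(expr, tree, "MPP"), "Early")
  # equal neighboring values fail the strict rule but pass one loosening
  expect_setequal(
    find_cell_specific_genes_tree(expr, tree, "MPP", max_violations = 1),
    c("Early", "Tie", "Up"))
  expect_error(find_cell_specific_genes_tree(expr, tree, "NK"),
               class = "pathdevfate_validation_error")
})

test_that("on a path topology the tree rule selects exactly the strictly unimodal genes", {
  set.seed(31)
  stages <- c("S1", "S2", "S3", "S4", "S5")
  tree <- lineage_tree(cbind(stages[-5], stages[-1]))
  m <- matrix(rlnorm(200 * 5), 200, 5,
              dimnames = list(sprintf("G%03d", 1:200), stages))
  target <- "S3"
  got <- find_cell_specific_genes_tree(m, tree, target)
  unimodal <- vapply(rownames(m), function(g) {
    v <- m[g, ]
    all(diff(v[1:3]) > 0) && all(diff(v[3:5]) < 0)
  }, TRUE)
  expect_setequal(got, rownames(m)[unimodal])
})

test_that("branched targets demand the fall along every continuation unless one leaf is named", {
  tree <- lineage_tree(rbind(c("HSC", "MPP"), c("MPP", "CLP"),
                             c("MPP", "CMP"), c("CLP", "B"), c("CMP", "Mono")))
  stages <- c("HSC", "MPP", "CLP", "CMP", "B", "Mono")
  expr <- make_expr(list(BothDown = c(1, 9, 4, 5, 2, 3),
                         OneDown = c(1, 9, 4, 5, 2, 7)),
                    stages = stages)
  expect_identical(find_cell_specific_genes_tree(expr, tree, "MPP"),
                   "BothDown")
  expect_setequal(find_cell_specific_genes_tree(expr, tree, "MPP", leaf = "B"),
                  c("BothDown", "OneDown"))
})
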