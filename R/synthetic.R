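# Synthetic stage-structured fixtures with planted ground truth. The
# generator emulates the shape of an FPKM matrix along a differentiation
# lineage: unimodal stage-specific genes (including a curated subset playing
# the role of the global regulators), genes following the integrated lineage
# profile, and a right-skewed log-normal background. A companion generator
# plants a TF->target table with hub targets and shared bridging TFs so the
# whole pipeline, through connector search, is testable without downloads.

# asymmetric unimodal shape peaking at stage s (rise and decay rates differ
# so that no two off-peak stages tie exactly)
unimodal_shape <- function(n, s, rate_up = 0.8, rate_down = 1.15) {
  j <- seq_len(n)
  ifelse(j <= s, exp(-rate_up * (s - j)), exp(-rate_down * (j - s)))
}

default_lineage_profile <- function(stages) {
  n <- length(stages)
  p <- max(2L, round(n / 2))
  L <- 30 * ifelse(seq_len(n) <= p, exp(-0.9 * (p - seq_len(n))),
                   exp(-0.63 * (seq_len(n) - p)))
  names(L) <- stages
  L
}

#' Generate a stage-structured expression matrix with planted ground truth
#'
#' Plants three gene populations along a linear lineage:
#' * **stage-specific genes** (`per_stage` per stage): an asymmetric
#'   unimodal profile peaking at their stage, whose peak height tracks a
#'   fixed lineage profile, times a per-gene positive scale. The first
#'   `regulators_per_stage` of each stage double as the curated
#'   global-regulator input.
#' * **pattern followers** (`n_followers`): profiles proportional to the
#'   lineage profile itself, i.e. genes a layer-2 screen should recover.
#' * **background genes** (`n_background`): i.i.d. log-normal draws with no
#'   imposed stage order. A background draw that by rank coincidence
#'   replicates a planted shape (Spearman rho at or above
#'   `background_max_rho` against any ideal stage shape or the lineage
#'   profile) is redrawn, so the planted/background labels are exact ground
#'   truth.
#'
#' Multiplicative Gaussian noise of relative scale `noise_sigma` (standard
#' deviation `noise_sigma` times the signal value, floored at a small
#' positive value) perturbs the planted genes. Output is deterministic under
#' `seed`; the caller's RNG state is preserved.
#'
#' @param stages Ordered stage labels (root first).
#' @param per_stage Planted stage-specific genes per stage (>= 1).
#' @param n_background Background genes (>= 0).
#' @param n_followers Planted lineage-pattern followers (>= 0).
#' @param regulators_per_stage How many stage genes per stage are flagged as
#'   global regulators.
#' @param noise_sigma Relative noise scale for planted genes.
#' @param seed RNG seed.
#' @param lineage_profile Optional named vector of per-stage levels; by
#'   default a fixed unimodal profile peaking mid-lineage.
#' @param scale_sdlog Log-sd of the per-gene scale for stage genes.
#' @param follower_sdlog Log-sd of the per-gene scale for followers.
#' @param background_meanlog,background_sdlog Log-normal background
#'   parameters.
#' @param background_max_rho Redraw threshold for background rank
#'   coincidences.
#' @return List with `expr` (the matrix) and `truth` (class
#'   `synthetic_truth`: planted sets, global regulators, lineage profile,
#'   noise scale, seed).
#' @export
generate_expression <- function(stages = c("ESC", "MES", "HB", "HE", "HP", "MAC"),
                                per_stage = 50L,
                                n_background = 1950L,
                                n_followers = 30L,
                                regulators_per_stage = 3L,
                                noise_sigma = 0.05,
                                seed = 1L,
                                lineage_profile = NULL,
                                scale_sdlog = 0.25,
                                follower_sdlog = 0.5,
                                background_meanlog = 1.5,
                                background_sdlog = 1,
                                background_max_rho = 0.9) {
  n_stage <- length(stages)
  if (n_stage < 2L) abort_validation("need at least two stages")
  if (per_stage < 1L) abort_validation("per_stage must be >= 1")
  if (n_background < 0L || n_followers < 0L)
    abort_validation("counts must be non-negative")
  if (regulators_per_stage < 1L || regulators_per_stage > per_stage)
    abort_validation("regulators_per_stage must be in [1, per_stage]")
  if (noise_sigma < 0) abort_validation("noise_sigma must be >= 0")

  L <- lineage_profile %||% default_lineage_profile(stages)
  if (length(L) != n_stage)
    abort_validation("lineage_profile length must match the stage count")
  names(L) <- stages

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))

  noisy <- function(v) {
    if (noise_sigma == 0) return(v)
    pmax(v * (1 + noise_sigma * stats::rnorm(length(v))), 1e-6)
  }

  cap <- function(s) canonical_symbol(s)
  rows <- list()
  planted_stage <- stats::setNames(vector("list", n_stage), stages)
  regulators <- character(0)

  for (si in seq_len(n_stage)) {
    shape <- unimodal_shape(n_stage, si)
    syms <- cap(sprintf("%sg%02d", stages[si], seq_len(per_stage)))
    planted_stage[[si]] <- syms
    regulators <- c(regulators, syms[seq_len(regulators_per_stage)])
    for (k in seq_len(per_stage)) {
      scale <- exp(stats::rnorm(1, 0, scale_sdlog))
      rows[[syms[k]]] <- noisy(L[si] * scale * shape)
    }
  }

  followers <- character(0)
  if (n_followers > 0L) {
    followers <- cap(sprintf("Folw%03d", seq_len(n_followers)))
    for (k in seq_len(n_followers)) {
      scale <- exp(stats::rnorm(1, 0, follower_sdlog))
      rows[[followers[k]]] <- noisy(scale * as.numeric(L))
    }
  }

  background <- character(0)
  if (n_background > 0L) {
    background <- cap(sprintf("Bg%04d", seq_len(n_background)))
    ideal <- rbind(t(vapply(seq_len(n_stage), function(s)
      unimodal_shape(n_stage, s), numeric(n_stage))), as.numeric(L))
    for (k in seq_len(n_background)) {
      repeat {
        v <- stats::rlnorm(n_stage, background_meanlog, background_sdlog)
        rho <- suppressWarnings(stats::cor(t(ideal), v, method = "spearman"))
        if (all(is.na(rho) | rho < background_max_rho)) break
      }
      rows[[background[k]]] <- v
    }
  }

  expr <- do.call(rbind, rows)
  colnames(expr) <- stages
  validate_expression_matrix(expr)

  truth <- structure(list(stages = stages,
                          planted_stage_genes = planted_stage,
                          global_regulators = regulators,
                          planted_followers = followers,
                          background = background,
                          lineage_profile = L,
                          noise_sigma = noise_sigma,
                          seed = as.integer(seed)),
                     class = "synthetic_truth")
  list(expr = expr, truth = truth)
}

#' Generate a planted TF-target interaction table
#'
#' Designates the first `n_hubs` planted pattern followers as hub targets
#' ("planted influencers"): each receives `k_regulators` distinct TF
#' regulators, among them `n_bridges` bridging TFs shared by every hub (the
#' planted connectors). `n_noise_edges` additional random TF -> background
#' edges are added, avoiding duplicates and never targeting a hub. With
#' `k_regulators` above the pipeline's in-degree threshold, every hub
#' qualifies as an influencer and the bridges connect them.
#'
#' @param truth A `synthetic_truth` from [generate_expression()] (needs at
#'   least `n_hubs` planted followers).
#' @param k_regulators Regulators per hub.
#' @param n_hubs Number of hub targets.
#' @param n_bridges Number of shared bridging TFs (>= 1, < `k_regulators`).
#' @param n_noise_edges Random noise edges.
#' @param seed RNG seed.
#' @return List with `interactions` (an `interaction_table`) and `truth`
#'   extended with `planted_influencers` (named vector of regulator counts)
#'   and `planted_connectors`.
#' @export
generate_interactions <- function(truth, k_regulators = 6L, n_hubs = 3L,
                                  n_bridges = 2L, n_noise_edges = 50L,
                                  seed = 1L) {
  if (n_bridges < 1L || n_bridges >= k_regulators)
    abort_validation("need 1 <= n_bridges < k_regulators")
  if (n_hubs < 1L || n_hubs > length(truth$planted_followers))
    abort_validation("n_hubs must be in [1, number of planted followers]")

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))

  hubs <- truth$planted_followers[seq_len(n_hubs)]
  bridges <- canonical_symbol(sprintf("Contf%d", seq_len(n_bridges)))
  modes <- c("Activation", "Repression", "Unknown")

  reg <- character(0); tgt <- character(0)
  for (i in seq_len(n_hubs)) {
    own <- canonical_symbol(sprintf("Hub%dtf%d",
                                    i, seq_len(k_regulators - n_bridges)))
    reg <- c(reg, bridges, own)
    tgt <- c(tgt, rep(hubs[i], k_regulators))
  }

  if (n_noise_edges > 0L) {
    pool_tf <- canonical_symbol(sprintf("Ntf%03d", seq_len(max(20L, n_noise_edges %/% 2L))))
    pool_tgt <- setdiff(c(truth$background,
                          truth$planted_followers[-seq_len(n_hubs)]), hubs)
    if (!length(pool_tgt))
      abort_validation("no non-hub genes available for noise edges")
    seen <- paste(reg, tgt)
    added <- 0L
    while (added < n_noise_edges) {
      r <- sample(pool_tf, 1L); t <- sample(pool_tgt, 1L)
      if (r == t || paste(r, t) %in% seen) next
      reg <- c(reg, r); tgt <- c(tgt, t)
      seen <- c(seen, paste(r, t))
      added <- added + 1L
    }
  }

  tab <- data.frame(regulator = reg, target = tgt,
                    mode = sample(modes, length(reg), replace = TRUE),
                    stringsAsFactors = FALSE)
  tab$evidence <- as.list(as.character(sample.int(99999999L, nrow(tab))))
  class(tab) <- c("interaction_table", "data.frame")
  attr(tab, "n_regulators") <- length(unique(tab$regulator))
  attr(tab, "n_records") <- nrow(tab)

  truth$planted_influencers <- stats::setNames(rep(k_regulators, n_hubs), hubs)
  truth$planted_connectors <- bridges
  list(interactions = tab, truth = truth)
}

#' Write a complete synthetic fixture to disk
#'
#' Produces the exact file dialects the pipeline consumes: `expression.tsv`,
#' `interactions.tsv` (4-column dialect), `lineage.yaml`, `regulators.txt`
#' and `truth.json`.
#'
#' @param dir Output directory (created if needed).
#' @param ... Passed to [generate_expression()].
#' @param k_regulators,n_hubs,n_bridges,n_noise_edges,interaction_seed Passed
#'   to [generate_interactions()].
#' @return Invisibly, the extended `synthetic_truth`.
#' @export
write_synthetic_fixture <- function(dir, ..., k_regulators = 6L, n_hubs = 3L,
                                    n_bridges = 2L, n_noise_edges = 50L,
                                    interaction_seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ge <- generate_expression(...)
  gi <- generate_interactions(ge$truth, k_regulators = k_regulators,
                              n_hubs = n_hubs, n_bridges = n_bridges,
                              n_noise_edges = n_noise_edges,
                              seed = interaction_seed)
  write_expression(ge$expr, file.path(dir, "expression.tsv"))
  write_interactions(gi$interactions, file.path(dir, "interactions.tsv"))
  yaml::write_yaml(list(kind = "linear", stages = as.list(ge$truth$stages)),
                   file.path(dir, "lineage.yaml"))
  write_gene_list(ge$truth$global_regulators, file.path(dir, "regulators.txt"))
  truth <- gi$truth
  tr <- unclass(truth)
  # named atomic vectors must become lists to keep their names in JSON
  tr$lineage_profile <- as.list(tr$lineage_profile)
  tr$planted_influencers <- as.list(tr$planted_influencers)
  jsonlite::write_json(tr, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(truth)
}
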