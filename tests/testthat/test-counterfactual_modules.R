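test_that("effect-gene filtering applies its expression and quantile
          floors", {
  n <- 50
  E <- structure(list(
    effects = cbind(lowexpr = rnorm(n, 0, 0.5),
                    keeper = rnorm(n, 0, 0.5),
                    flat = rep(0, n)),
    embedding = cbind(rnorm(n), rnorm(n)),
    raw_mean_expr = c(lowexpr = 0.005, keeper = 0.05, flat = 0.5),
    n_samples = c(rep(10L, n - 2), 2L, 1L)),
    class = "EffectMatrix")
  f <- filter_effect_genes(E)
  expect_identical(colnames(f$effects), "keeper")
  expect_equal(nrow(f$effects), n - 2)  # two cells under the sample floor
  E2 <- E; E2$raw_mean_expr[] <- 0.001
  expect_error(filter_effect_genes(E2), "all genes removed")
})

test_that("kNN smoothing is the doubled row-stochastic average:
          constants, linearity and the complete-graph limit", {
  set.seed(1)
  n <- 40; m <- 6
  emb <- cbind(rnorm(n), rnorm(n))
  mk <- function(eff) structure(
    list(effects = eff, embedding = emb,
         raw_mean_expr = rep(1, m), n_samples = rep(10L, n)),
    class = "EffectMatrix")
  const <- mk(matrix(rep(c(1, -2, 0.5, 3, -1, 2), each = n), n, m))
  sm <- smooth_effects(const, k = 5)
  expect_equal(sm$effects,
               2 * const$effects, tolerance = 1e-12)
  # linearity
  E1 <- mk(matrix(rnorm(n * m), n, m))
  E2 <- mk(matrix(rnorm(n * m), n, m))
  lin <- mk(3 * E1$effects - 2 * E2$effects)
  expect_equal(smooth_effects(lin, k = 7)$effects,
               3 * smooth_effects(E1, k = 7)$effects -
                 2 * smooth_effects(E2, k = 7)$effects,
               tolerance = 1e-10)
  # k = n - 1: every row averages all others
  smax <- smooth_effects(E1, k = n - 1)
  oracle <- 2 * (matrix(colSums(E1$effects), n, m, byrow = TRUE) -
                   E1$effects) / (n - 1)
  expect_equal(smax$effects, oracle, tolerance = 1e-10)
})

test_that("smoothing reduces within-module variance on planted data", {
  for (s in 0:4) {
    sim <- simulate_effect_matrix(list(noise_sd = 0.3), seed = s)
    sm <- smooth_effects(sim$effects, k = 15)
    pos <- sim$truth$module_mask
    v_pre <- mean(apply(sim$effects$effects[pos, sim$truth$up_genes], 2,
                        var))
    v_post <- mean(apply(sm$effects[pos, sim$truth$up_genes], 2, var))
    expect_lt(v_post, v_pre)
  }
})

test_that("spectral co-clustering recovers planted blocks exactly and
          is permutation-equivariant", {
  set.seed(2)
  blocks <- rbind(cbind(matrix(2, 30, 20), matrix(0.05, 30, 25)),
                  cbind(matrix(0.05, 25, 20), matrix(-1.5, 25, 25)))
  blocks <- blocks + matrix(rnorm(55 * 45, 0, 0.01), 55, 45)
  mk <- function(eff) structure(
    list(effects = eff, embedding = cbind(rnorm(nrow(eff)),
                                          rnorm(nrow(eff))),
         raw_mean_expr = rep(1, ncol(eff)),
         n_samples = rep(10L, nrow(eff))), class = "EffectMatrix")
  cc <- cocluster_effects(mk(blocks), 2, 2, seed = 0)
  expect_equal(adjusted_rand_index(cc$cell_modules,
                                   rep(1:2, c(30, 25))), 1)
  expect_equal(adjusted_rand_index(cc$gene_modules,
                                   rep(1:2, c(20, 25))), 1)
  # seed change on well-separated blocks: identical partition
  cc2 <- cocluster_effects(mk(blocks), 2, 2, seed = 99)
  expect_equal(adjusted_rand_index(cc$cell_modules, cc2$cell_modules), 1)
  # permuting rows permutes labels identically
  perm <- sample(55)
  cc3 <- cocluster_effects(mk(blocks[perm, ]), 2, 2, seed = 0)
  expect_equal(adjusted_rand_index(cc3$cell_modules,
                                   cc$cell_modules[perm]), 1)
  expect_error(cocluster_effects(mk(matrix(1, 10, 10)), 2, 2),
               "degenerate")
})

test_that("module scores follow their printed definitions", {
  n <- 10
  eff <- matrix(0, n, 40,
                dimnames = list(NULL, sprintf("g%d", 1:40)))
  eff[1, 1:30] <- 0.5           # cell 1: +0.5 on 30 up-markers
  eff[2:6, 1:30] <- 0.4         # module cells defining the markers
  assign <- structure(list(cell_modules = c(1, rep(1, 5), rep(2, 4)),
                           gene_modules = rep(1:2, c(30, 10)),
                           n_cell_modules = 2, n_gene_modules = 2),
                      class = "ModuleAssignment")
  E <- structure(list(effects = eff), class = "EffectMatrix")
  sc <- score_modules(assign, E, top_n_markers = 30)
  expect_equal(sc[["1"]]$scores[1], 15.0)   # 30 x 0.5
  expect_equal(sc[["1"]]$scores[7], 0)      # zero-effect cell
  # scoring is linear: negating the effects negates every score
  for (rule in c("sum_lfc", "weighted_sign_mean"))
    expect_equal(score_cells(-eff, sc[["1"]]$markers, rule),
                 -score_cells(eff, sc[["1"]]$markers, rule))
  # weighted sign mean on the same cell: mean(sign * lfc) = 0.5
  scw <- score_modules(assign, E, score_rule = "weighted_sign_mean",
                       top_n_markers = 30)
  expect_equal(scw[["1"]]$scores[1], 0.5)
})

test_that("the Youden threshold matches exhaustive enumeration", {
  scores <- c(1, 2, 3, 4, 5, 6)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  res <- youden_cutoff_and_transfer(scores, labels)
  oracle <- youden_oracle(scores, labels)
  expect_equal(res$J, 1)
  expect_equal(oracle$J, 1)
  expect_equal(res$threshold, 3.5)
  expect_identical(res$direction, "<")  # in-module cells score lower
  # transfer applies the same cutoff
  res2 <- youden_cutoff_and_transfer(scores, labels,
                                     list(t1 = c(0, 10)))
  expect_identical(unname(res2$masks$t1), c(TRUE, FALSE))
  # random instances against the oracle
  set.seed(3)
  for (i in 1:50) {
    s <- rnorm(30)
    l <- rbinom(30, 1, 0.4) == 1
    if (length(unique(l)) < 2) next
    expect_equal(youden_cutoff_and_transfer(s, l)$J,
                 youden_oracle(s, l)$J, tolerance = 1e-12)
  }
  # identical class distributions: J near zero
  set.seed(4)
  s0 <- rep(rnorm(20), 2)
  l0 <- rep(c(TRUE, FALSE), each = 20)
  expect_lt(youden_cutoff_and_transfer(s0, l0)$J, 0.15)
  expect_error(youden_cutoff_and_transfer(s0, rep(TRUE, 40)),
               "both in-module")
})

test_that("gene-threshold override selects cells by a named gene's
          effect", {
  eff <- matrix(c(-0.1, 0.2, -0.04), 3, 1,
                dimnames = list(NULL, "IL17A"))
  E <- structure(list(effects = eff), class = "EffectMatrix")
  expect_identical(gene_threshold_mask(E, "IL17A", -0.05),
                   c(TRUE, FALSE, FALSE))
  expect_error(gene_threshold_mask(E, "GZMB", -0.05), "not in")
})

test_that("the planted module is recovered end to end with high F1 and
          marker recall", {
  for (s in 0:4) {
    sim <- simulate_effect_matrix(seed = s)
    E <- filter_effect_genes(sim$effects)
    S <- smooth_effects(E, k = 15)
    cc <- cocluster_effects(S, 2, 2, seed = 0)
    sc <- score_modules(cc, S)
    truth <- sim$truth$module_mask
    f1 <- sapply(names(sc), function(m) {
      pred <- cc$cell_modules == as.integer(m)
      2 * sum(pred & truth) / (sum(pred) + sum(truth))
    })
    expect_gte(max(f1), 0.85)
    best <- names(which.max(f1))
    recall <- mean(c(sim$truth$up_genes, sim$truth$down_genes) %in%
                     names(sc[[best]]$markers))
    expect_gte(recall, 0.7)
  }
})

test_that("module validation by relaxed pseudobulk DE finds the planted
          age effect in marker enrichment", {
  genes <- sprintf("G%04d", 381:410)
  cfg <- atlas_config(n_donors = 12, tissue_groups = c("BLO", "JEJ"),
                      cells_per_donor_tissue = 50, n_genes = 440,
                      planted_age_effects =
                        list(list(genes = genes, log2FC = 1.5)))
  sim <- simulate_atlas(cfg, seed = 1)
  mask <- sim$truth$contaminant_labels == "clean" &
    sim$matrix$cell_meta$lineage == "T4"
  res <- validate_module(mask, sim$matrix, markers = genes, seed = 1)
  expect_false(is.null(res$enrichment))
  hit <- res$enrichment[res$enrichment$tissue_group == "BLO", ]
  expect_true(any(hit$nes > 0 & hit$fdr_q < 0.05))
})
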