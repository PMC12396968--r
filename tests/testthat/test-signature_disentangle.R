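test_that("signature gene selection is a strict threshold conjunction", {
  de <- data.frame(
    gene = c("a", "a", "b", "c"),
    unit = "T", tissue_group = c("BLO", "JEJ", "BLO", "BLO"),
    logfc = c(1.2, 0.2, 0.9, 2.0),
    adj_p_val = c(0.04, 0.50, 0.01, 0.04),
    aveexpr = c(2.5, 2.5, 3.0, 1.0))
  z <- select_signature_genes(de)
  expect_identical(sort(attr(z, "selected")), "a")  # b fails lfc, c ave
  expect_error(select_signature_genes(de, adj_p_max = 1e-9), "thresholds")
})

test_that("z-scores are standardized per gene", {
  set.seed(1)
  m <- matrix(rnorm(40, 5, 2), 8, 5,
              dimnames = list(letters[1:8], LETTERS[1:5]))
  de <- data.frame(gene = letters[1:8], unit = "T", tissue_group = "BLO",
                   logfc = 2, adj_p_val = 0.01, aveexpr = 3)
  z <- select_signature_genes(de, expr_means = m)
  expect_equal(unname(rowMeans(z)), rep(0, 8), tolerance = 1e-12)
  expect_equal(unname(apply(z, 1, sd)), rep(1, 8), tolerance = 1e-12)
})

test_that("gene clustering recovers planted blocks deterministically", {
  set.seed(2)
  block1 <- matrix(rnorm(20 * 4, 3), 20, 4)
  block2 <- matrix(rnorm(20 * 4, -3), 20, 4)
  z <- rbind(block1, block2)
  rownames(z) <- sprintf("g%d", 1:40)
  cs <- cluster_signature_genes(z, 2)
  expect_length(cs$clusters, 2)
  ari <- adjusted_rand_index(cs$labels, rep(1:2, each = 20))
  expect_equal(ari, 1)
  # duplicates co-cluster; permutation changes nothing but labels
  z2 <- z; z2["g2", ] <- z2["g1", ]
  cs2 <- cluster_signature_genes(z2, 2)
  expect_equal(cs2$labels[["g1"]], cs2$labels[["g2"]])
  perm <- sample(40)
  cs3 <- cluster_signature_genes(z[perm, ], 2)
  expect_equal(adjusted_rand_index(cs3$labels[rownames(z)], cs$labels), 1)
  expect_error(cluster_signature_genes(z, 1), "n_clusters")
})

test_that("GSEA matches the brute-force running-sum oracle on random
          instances", {
  set.seed(3)
  for (i in 1:100) {
    n <- sample(30:120, 1)
    ranking <- setNames(rnorm(n), sprintf("g%d", seq_len(n)))
    set <- sample(names(ranking), sample(3:10, 1))
    w <- sample(c(0, 1), 1)
    es_pkg <- gsea_preranked(ranking, list(s = set), n_perm = 100,
                             seed = 1, weight = w)$es
    expect_equal(es_pkg, gsea_es_oracle(ranking, set, weight = w),
                 tolerance = 1e-12)
  }
})

test_that("GSEA behaves at the extremes and under score negation", {
  ranking <- setNames(seq(1000, 1, length.out = 1000) / 100,
                      sprintf("g%d", 1:1000))
  top <- names(ranking)[1:10]
  res <- gsea_preranked(ranking, list(top = top), n_perm = 200, seed = 1)
  expect_gt(res$es, 0.9)
  expect_lt(res$p_value, 0.05)
  neg <- gsea_preranked(setNames(-as.numeric(ranking), names(ranking)),
                        list(top = top), n_perm = 200, seed = 1)
  expect_equal(neg$es, -res$es, tolerance = 1e-12)
  expect_error(gsea_preranked(ranking, list(out = c("zz1", "zz2")),
                              n_perm = 100), "no genes")
})

test_that("GSEA agrees with an independent implementation on sign and
          significance", {
  skip_if_not_installed("fgsea")
  set.seed(4)
  ranking <- setNames(rnorm(500), sprintf("g%d", 1:500))
  ranking[1:25] <- ranking[1:25] + 2.5
  sets <- list(hit = sprintf("g%d", 1:25),
               null = sample(names(ranking), 30))
  ours <- gsea_preranked(ranking, sets, n_perm = 500, seed = 1)
  ref <- suppressWarnings(
    fgsea::fgsea(sets, ranking, nPermSimple = 500, scoreType = "std"))
  ref <- ref[match(ours$term, ref$pathway), ]
  expect_equal(sign(ours$es), sign(ref$ES))
  expect_lt(ours$p_value[ours$term == "hit"], 0.01)
  expect_lt(ref$pval[ref$pathway == "hit"], 0.01)
})

test_that("per-donor ADT testing detects a planted shift and respects
          donor floors", {
  set.seed(5)
  n_donor <- 5; n_per <- 120
  donors <- rep(sprintf("D%d", 1:n_donor), each = n_per)
  groups <- rep(rep(c("BLO", "JEJ"), each = n_per / 2), n_donor)
  # planted scenario: marker 1 strongly shifted in JEJ
  lam <- ifelse(groups == "JEJ", 60, 8)
  adt <- cbind(m_shift = rpois(length(donors), lam),
               m_other = rpois(length(donors), 20))
  res <- adt_differential(adt, groups, donors, min_cells = 20,
                          min_donors = 4, seed = 0)
  shift <- res[res$marker == "m_shift", ]
  expect_true(all(shift$p_value < 0.01))
  expect_true(all(shift$delta > 0))
  # null scenario: all markers identically distributed across groups
  adt0 <- cbind(m1 = rpois(length(donors), 20),
                m2 = rpois(length(donors), 40))
  res0 <- adt_differential(adt0, groups, donors, min_cells = 20,
                           min_donors = 4, seed = 0)
  expect_gt(mean(res0$p_value > 0.05), 0.8)
  # min_donors floor: only 2 donors eligible -> skipped
  res2 <- adt_differential(adt[donors %in% c("D1", "D2"), ],
                           groups[donors %in% c("D1", "D2")],
                           donors[donors %in% c("D1", "D2")],
                           min_cells = 20, min_donors = 4, seed = 0)
  expect_equal(nrow(res2), 0)
  expect_true(attr(res2, "audit")$skipped)
})

test_that("composition-versus-expression summaries flag planted
          scenarios", {
  # composition-driven: subset 4x more frequent in BM, no expression shift
  set.seed(6)
  n <- 1200
  tg <- rep(c("BM", "BLO"), each = n / 2)
  subset <- c(sample(c("mono", "dc"), n / 2, TRUE, prob = c(0.8, 0.2)),
              sample(c("mono", "dc"), n / 2, TRUE, prob = c(0.2, 0.8)))
  meta <- data.frame(subset = subset, lineage = "Myeloid",
                     tissue_group = tg)
  expr <- matrix(rnorm(n * 4, 2, 0.1), n, 4,
                 dimnames = list(NULL, sprintf("g%d", 1:4)))
  enr <- data.frame(subset = "mono", tissue_group = "BM", nes = 0.3,
                    fdr_q = 0.8)
  res <- summarize_composition_vs_expression(sprintf("g%d", 1:4), meta,
                                             expr, enr)
  row <- res[res$subset == "mono" & res$tissue_group == "BM", ]
  expect_identical(row$flag, "composition-driven")

  # expression-driven: stable frequencies, significant enrichment
  subset2 <- sample(c("mono", "dc"), n, TRUE)
  meta2 <- data.frame(subset = subset2, lineage = "Myeloid",
                      tissue_group = tg)
  expr2 <- expr
  expr2[tg == "BM" & subset2 == "mono", ] <-
    expr2[tg == "BM" & subset2 == "mono", ] + 2
  enr2 <- data.frame(subset = "mono", tissue_group = "BM", nes = 2.4,
                     fdr_q = 0.001)
  res2 <- summarize_composition_vs_expression(sprintf("g%d", 1:4), meta2,
                                              expr2, enr2)
  row2 <- res2[res2$subset == "mono" & res2$tissue_group == "BM", ]
  expect_identical(row2$flag, "expression-driven")

  # frequencies within lineage x tissue sum to 1
  sums <- tapply(res$freq_in, paste(res$lineage, res$tissue_group), sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-12)
})
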