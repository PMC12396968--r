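test_that("subset frequencies normalize within lineage and respect
          floors", {
  meta <- data.frame(
    donor_id = rep(c("D1", "D2", "D3", "D4", "D5"), each = 100),
    tissue_group = "BLO", lineage = "T",
    subset = rep(c("a", "b"), c(30, 70)))
  ft <- tabulate_subset_frequencies(meta, min_cells = 50, min_donors = 4)
  d1 <- ft[ft$donor_id == "D1", ]
  expect_equal(sort(d1$proportion), c(0.3, 0.7))
  sums <- tapply(ft$proportion,
                 paste(ft$donor_id, ft$tissue_group, ft$lineage), sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)))
  # donor with 49 lineage cells excluded
  meta2 <- rbind(meta, data.frame(donor_id = "D9", tissue_group = "BLO",
                                  lineage = "T",
                                  subset = rep("a", 49)))
  ft2 <- tabulate_subset_frequencies(meta2, min_cells = 50,
                                     min_donors = 4)
  expect_false("D9" %in% ft2$donor_id)
  expect_true(any(grepl("D9", attr(ft2, "audit")$donor_units_dropped)))
})

test_that("the frequency GLM recovers a planted age shift with the
          right sign and a null yields flat log2FC", {
  w <- c(T_a = 1, T_b = 1, T_c = 1, T_d = 1, T_e = 1, T_rm = 0.25)
  cfg <- atlas_config(n_donors = 24, tissue_groups = c("BLO", "JEJ"),
                      lineages = list(T = names(w)),
                      cells_per_donor_tissue = 100, n_genes = 300,
                      subset_base_weights = w,
                      planted_age_composition =
                        list(list(subset = "T_rm", fold = 2)))
  hits <- logical(0); coefs <- lfcs <- numeric(0)
  for (s in 1:5) {
    sim <- simulate_atlas(cfg, seed = s)
    ft <- tabulate_subset_frequencies(sim$matrix$cell_meta,
                                      min_cells = 20)
    res <- glm_frequency_shift(ft)
    hit <- res[res$subset == "T_rm", ]
    hits <- c(hits, hit$adj_p_val < 0.05)
    coefs <- c(coefs, hit$coeff)
    lfcs <- c(lfcs, hit$logfc)
  }
  expect_gte(mean(hits), 0.6)       # detected in most tissue units
  expect_true(all(coefs > 0))       # sign always matches the planted shift
  expect_gt(median(lfcs), 0.5)      # covariate-aware log2FC near log2(2)

  cfg0 <- atlas_config(n_donors = 24, tissue_groups = c("BLO", "JEJ"),
                       lineages = list(T = names(w)),
                       cells_per_donor_tissue = 100, n_genes = 300,
                       subset_base_weights = w)
  sim0 <- simulate_atlas(cfg0, seed = 4)
  ft0 <- tabulate_subset_frequencies(sim0$matrix$cell_meta,
                                     min_cells = 20)
  res0 <- glm_frequency_shift(ft0)
  expect_lt(max(abs(res0$logfc), na.rm = TRUE), 0.6)
})

test_that("majority voting requires strictly more than half of the
          reference choices", {
  set.seed(1)
  counts <- matrix(rpois(6 * 20, 50), 6, 20,
                   dimnames = list(sprintf("s%d", 1:6), NULL))
  grouping <- factor(rep(c("x", "y"), 10))
  # stub backend: flags s1 for exactly half of the references
  half_backend <- function(counts, grouping, reference, fdr)
    if (match(reference, rownames(counts)) <= 3) "s1" else character(0)
  res <- majority_vote_composition(counts, grouping,
                                   backend = half_backend)
  expect_equal(unname(res$votes[["s1"]]), 0.5)
  expect_false("s1" %in% res$credible)
  # backend flagging identically across references reduces to one run
  const_backend <- function(counts, grouping, reference, fdr) "s2"
  res2 <- majority_vote_composition(counts, grouping,
                                    backend = const_backend)
  expect_identical(res2$credible, "s2")
  expect_error(majority_vote_composition(counts[1:2, ], grouping),
               "3 subsets")
})

test_that("the ALR backend finds a planted enrichment and stays quiet
          under the null", {
  set.seed(2)
  n_samp <- 24
  grouping <- factor(rep(c("other", "target"), each = n_samp / 2))
  base <- matrix(rpois(6 * n_samp, 60), 6, n_samp,
                 dimnames = list(sprintf("s%d", 1:6), NULL))
  planted <- base
  planted[1, grouping == "target"] <-
    rpois(n_samp / 2, 180)  # 3-fold enrichment of s1
  res <- majority_vote_composition(planted, grouping)
  expect_true("s1" %in% res$credible)
  expect_false(any(sprintf("s%d", 3:6) %in% res$credible))
  null_hits <- sapply(0:9, function(s) {
    set.seed(100 + s)
    m <- matrix(rpois(6 * n_samp, 60), 6, n_samp,
                dimnames = list(sprintf("s%d", 1:6), NULL))
    length(majority_vote_composition(m, grouping)$credible)
  })
  expect_gte(mean(null_hits == 0), 0.9)
})

test_that("landmark registration aligns peaks across batches and
          preserves ranks", {
  set.seed(3)
  v <- c(rnorm(500, 0.5, 0.12), rnorm(300, 2.0, 0.15),
         rnorm(500, 1.0, 0.12), rnorm(300, 2.5, 0.15))
  b <- rep(c("b1", "b2"), each = 800)
  reg <- landmark_register_adt(v, b)
  for (bb in c("b1", "b2")) {
    d <- density(reg$registered[b == bb])
    pk <- d$x[which(diff(sign(diff(d$y))) == -2) + 1]
    pk <- pk[d$y[which(diff(sign(diff(d$y))) == -2) + 1] >
               0.05 * max(d$y)]
    expect_lt(abs(min(pk) - 0), 0.05)
    expect_lt(abs(max(pk) - 1), 0.05)
    idx <- which(b == bb)
    expect_identical(order(reg$registered[idx]), order(v[idx]))
  }
  # single batch: peaks land on (0, 1) too
  reg1 <- landmark_register_adt(v[1:800], rep("only", 800))
  d1 <- density(reg1$registered)
  pk1 <- d1$x[which(diff(sign(diff(d1$y))) == -2) + 1]
  pk1 <- pk1[d1$y[which(diff(sign(diff(d1$y))) == -2) + 1] >
               0.05 * max(d1$y)]
  expect_lt(abs(min(pk1) - 0), 0.05)
  expect_lt(abs(max(pk1) - 1), 0.05)
  # degenerate constant marker: identity warp, flagged
  regc <- landmark_register_adt(rep(1, 50), rep("b", 50))
  expect_identical(regc$flagged, "b")
  expect_equal(regc$registered, rep(1, 50))
})

test_that("percent positivity covers its boundary cases and feeds the
          GLM", {
  reg <- structure(list(registered = c(-1, -2, -0.5)),
                   class = "RegisteredADT")
  expect_equal(percent_positive(reg, 0.5,
                                rep("g", 3))$percent_positive, 0)
  expect_equal(percent_positive(c(0, 1, 2), -Inf,
                                rep("g", 3))$percent_positive, 100)
  # planted +30-point positivity shift in old donors
  set.seed(4)
  n_donor <- 16
  rows <- list()
  for (d in seq_len(n_donor)) {
    age <- if (d <= 8) "young" else "old"
    p <- if (age == "young") 0.30 else 0.60
    vals <- ifelse(runif(200) < p, 1.1, -0.1)
    rows[[d]] <- data.frame(
      donor_id = sprintf("D%02d", d), age_group = age,
      percent = percent_positive(vals, 0.5, rep("g", 200))$percent_positive,
      n = 200, lineage_total = 200)
  }
  tab <- do.call(rbind, rows)
  tab$subset <- "mac"; tab$tissue_group <- "BM"
  tab$n <- round(tab$percent * 2)  # positives out of 200
  res <- glm_frequency_shift(tab, adjust = character(0))
  expect_true(res$adj_p_val < 0.05 && res$coeff > 0)
  diff_pts <- mean(tab$percent[tab$age_group == "old"]) -
    mean(tab$percent[tab$age_group == "young"])
  expect_lt(abs(diff_pts - 30), 5)
})
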