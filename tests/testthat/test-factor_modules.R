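rank3_counts <- function(seed = 42, M = 100, N = 400) {
  set.seed(seed)
  W0 <- matrix(rgamma(M * 3, 0.5, 1), M, 3)
  W0[1:20, 1] <- W0[1:20, 1] + 3
  W0[21:40, 2] <- W0[21:40, 2] + 3
  W0[41:60, 3] <- W0[41:60, 3] + 3
  H0 <- matrix(rgamma(3 * N, 0.8, 1), 3, N)
  X <- matrix(rpois(M * N, W0 %*% H0), M, N)
  counts <- t(X)
  colnames(counts) <- sprintf("g%d", seq_len(M))
  rownames(counts) <- sprintf("c%d", seq_len(N))
  keep <- prefilter_factorization_genes(counts, 0.01)
  list(counts = counts[, keep], W0 = W0[keep, ])
}

test_that("Poisson factorization recovers planted loadings with
          monotone deviance", {
  fx <- rank3_counts()
  best <- NULL
  for (s in 0:4) {
    f <- fit_poisson_factorization(fx$counts, 3, seed = s,
                                   max_iter = 150)
    expect_true(all(diff(f$deviance_trace) <= 1e-6))
    expect_true(all(f$gene_scores >= 0) && all(f$cell_scores >= 0))
    if (is.null(best) || f$deviance < best$deviance) best <- f
  }
  cc <- cor(best$gene_scores, fx$W0)
  expect_gte(min(apply(cc, 2, max)), 0.8)
  # gene-score columns are normalized (scale convention)
  expect_equal(unname(colSums(best$gene_scores)), rep(1, 3),
               tolerance = 1e-8)
  expect_error(
    fit_poisson_factorization(cbind(fx$counts, zzz = 0), 3, seed = 0),
    "prefilter")
})

test_that("consensus factorization finds the planted rank with
          2-model provenance", {
  fx <- rank3_counts(seed = 7)
  cons <- consensus_factorize(fx$counts, K_range = 3:6, runs_per_K = 3,
                              top_models_per_K = 2, seed = 1,
                              max_iter = 120, tol = 1e-5)
  expect_equal(cons$consensus_K, 3)
  for (p in cons$provenance)
    expect_gte(length(unique(sub("[.]F[0-9]+$", "", p))), 2)
  # agglomerative fallback honors the same contract
  cons2 <- consensus_factorize(fx$counts, K_range = 3:5, runs_per_K = 3,
                               top_models_per_K = 2, seed = 1,
                               method = "agglomerative",
                               max_iter = 120, tol = 1e-5)
  expect_equal(cons2$consensus_K, 3)
  for (p in cons2$provenance)
    expect_gte(length(unique(sub("[.]F[0-9]+$", "", p))), 2)
})

test_that("nuisance flagging uses strict per-list count thresholds", {
  set.seed(1)
  M <- 60
  gm <- data.frame(symbol = sprintf("g%d", 1:M),
                   is_ribo = FALSE, is_hemoglobin = FALSE,
                   is_hsp = FALSE, is_metallothionein = FALSE,
                   is_stress = FALSE)
  gm$is_ribo[1:11] <- TRUE
  gm$is_hemoglobin[30] <- TRUE
  W <- matrix(runif(M * 3, 0, 0.1), M, 3,
              dimnames = list(gm$symbol, c("F1", "F2", "F3")))
  W[1:11, 1] <- 1          # 11 ribosomal in top 30 -> flagged (11 > 10)
  W[c(1:10, 40:59), 2] <- 1  # exactly 10 ribosomal -> not flagged
  W[30, 3] <- 1            # 1 hemoglobin -> flagged (> 0)
  model <- structure(list(gene_scores = W), class = "FactorModel")
  flags <- flag_nuisance_factors(model, gm)
  expect_equal(unname(flags), c(TRUE, FALSE, TRUE), ignore_attr = TRUE)
  cnt <- attr(flags, "counts")
  expect_equal(unname(cnt[1:2, "ribo"]), c(11, 10))
  gm2 <- gm; gm2$is_stress <- NULL
  expect_warning(flag_nuisance_factors(model, gm2), "is_stress")
})

test_that("the 80%-higher tissue-specificity rule is inclusive", {
  H <- rbind(F1 = c(1.9, 1.0, 1.0), F2 = c(1.8, 1.0, 1.0),
             F3 = c(1.2, 1.0, 1.0))
  # one cell per tissue keeps the means exactly at these values
  model <- structure(list(cell_scores = H), class = "FactorModel")
  lab <- select_tissue_specific_factors(model, c("gut", "lng", "ln"))
  expect_equal(unname(lab), c("gut", "gut", NA), ignore_attr = TRUE)
})

test_that("the Fisher-z correlation threshold shrinks with gene count
          and admits ~5% of null pairs", {
  thr <- function(M) tanh(qnorm(0.975) / sqrt(M - 3))
  expect_true(all(diff(sapply(c(10, 100, 1000, 10000), thr)) < 0))
  set.seed(2)
  M <- 2000; nf <- 40
  W <- matrix(rnorm(M * nf), M, nf,
              dimnames = list(sprintf("g%d", 1:M),
                              sprintf("F%d", 1:nf)))
  res <- detect_cross_lineage_modules(list(a = W[, 1:20], b = W[, 21:40]),
                                      min_partners = 1)
  cmat <- res$correlation
  pairs <- cmat[upper.tri(cmat)]
  frac <- mean(abs(pairs) > res$threshold)
  n_pairs <- length(pairs)
  ci <- qbinom(c(0.005, 0.995), n_pairs, 0.05) / n_pairs
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("factors from two lineages sharing a planted program land in
          one module", {
  cfg <- atlas_config(n_donors = 8, tissue_groups = c("BLO", "LN", "JEJ"),
                      cells_per_donor_tissue = 60, n_genes = 500,
                      planted_tissue_programs =
                        list(res_prog = list(tissue_group = "JEJ",
                                             activity_ratio = 5)))
  sim <- simulate_atlas(cfg, seed = 0)
  cm <- sim$matrix
  clean <- sim$truth$contaminant_labels == "clean"
  fits <- list()
  planted_factor <- list()
  for (lin in c("T4", "T8")) {
    sel <- clean & cm$cell_meta$lineage == lin
    counts <- as.matrix(cm$gex_counts[sel, ])
    counts <- counts[, prefilter_factorization_genes(counts)]
    f <- fit_poisson_factorization(counts, 6, seed = 1, max_iter = 150)
    fits[[lin]] <- f
    ov <- apply(f$gene_scores, 2, function(w)
      mean(names(sort(w, decreasing = TRUE))[1:20] %in%
             sim$truth$program_genes$res_prog))
    planted_factor[[lin]] <- paste(lin, names(which.max(ov)), sep = ".")
    # the planted factor is also the tissue-specific one
    lab <- select_tissue_specific_factors(f, cm$cell_meta$tissue_group[sel])
    expect_identical(unname(lab[which.max(ov)]), "JEJ")
  }
  mods <- detect_cross_lineage_modules(fits, n_modules = 2)
  expect_equal(mods$modules[[planted_factor$T4]],
               mods$modules[[planted_factor$T8]])
})

test_that("the factor-covariate mixed model finds the planted factor
          and only it", {
  hits <- 0; clean_others <- 0
  for (s in 1:10) {
    set.seed(s)
    n_donor <- 24; cells_per <- 25; K <- 6
    donors <- rep(sprintf("D%02d", 1:n_donor), each = cells_per)
    age <- rep(rep(c("young", "old"), n_donor / 2), each = cells_per)
    n <- length(donors)
    H <- matrix(rgamma(K * n, 2, 2), K, n,
                dimnames = list(sprintf("F%d", 1:K), NULL))
    donor_re <- rep(rnorm(n_donor, 0, 0.1), each = cells_per)
    H <- H * exp(matrix(donor_re, K, n, byrow = TRUE))
    H[3, age == "old"] <- H[3, age == "old"] * 1.5  # +50% on one factor
    model <- structure(list(cell_scores = H), class = "FactorModel")
    meta <- data.frame(donor_id = donors, age_group = age,
                       sex = rep(c("M", "F"), length.out = n))
    res <- associate_factors_with_covariate(model, meta,
                                            fixed = "sex")
    tab <- res$table
    hits <- hits + (tab$adj_p[3] < 0.05 && tab$coef[3] > 0)
    clean_others <- clean_others + all(tab$adj_p[-3] >= 0.05)
  }
  expect_gte(hits, 9)
  expect_gte(clean_others, 9)
})

test_that("projection is consistent with training scores and transfers
          planted structure", {
  fx <- rank3_counts(seed = 11)
  f <- fit_poisson_factorization(fx$counts, 3, seed = 0, max_iter = 150)
  H <- suppressMessages(project_onto_factors(f, fx$counts[1:80, ]))
  r <- diag(cor(t(H), t(f$cell_scores[, 1:80])))
  expect_true(all(r >= 0.9))
  zero <- matrix(0L, 2, ncol(fx$counts),
                 dimnames = list(c("z1", "z2"), colnames(fx$counts)))
  Hz <- suppressMessages(project_onto_factors(f, zero))
  expect_equal(unname(Hz), matrix(0, 3, 2), tolerance = 1e-8)
  expect_error(suppressMessages(
    project_onto_factors(f, fx$counts[1:5, 1:10])), "overlap")
})
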