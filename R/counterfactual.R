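#' Filter an effect matrix before module discovery
#'
#' Drops genes with raw average expression below `min_raw_expr` or whose
#' 95th percentile of |per-cell log2FC| falls below `lfc_floor`
#' (retaining only genes plausibly affected by the covariate), and
#' drops cells represented in fewer than `min_samples` samples.
#'
#' @param E an `EffectMatrix` (list with `effects`, `embedding`,
#'   `raw_mean_expr`, `n_samples`).
#' @param min_raw_expr raw mean-expression floor.
#' @param lfc_quantile quantile of |log2FC| tested against `lfc_floor`.
#' @param lfc_floor minimum |log2FC| quantile.
#' @param min_samples per-cell sample-representation floor.
#' @return The filtered `EffectMatrix`.
#' @export
filter_effect_genes <- function(E, min_raw_expr = 0.01,
                                lfc_quantile = 0.95, lfc_floor = 0.1,
                                min_samples = 3) {
  stopifnot(lfc_quantile > 0, lfc_quantile < 1)
  q <- apply(abs(E$effects), 2, stats::quantile, probs = lfc_quantile)
  keep_g <- E$raw_mean_expr >= min_raw_expr & q >= lfc_floor
  if (!any(keep_g))
    stop("all genes removed; consider lowering min_raw_expr/lfc_floor")
  keep_c <- E$n_samples >= min_samples
  structure(list(effects = E$effects[keep_c, keep_g, drop = FALSE],
                 embedding = E$embedding[keep_c, , drop = FALSE],
                 raw_mean_expr = E$raw_mean_expr[keep_g],
                 n_samples = E$n_samples[keep_c]),
            class = "EffectMatrix")
}

# kNN affinity (row-normalized); ties broken by index order
.knn_affinity <- function(embedding, k) {
  n <- nrow(embedding)
  stopifnot(k < n)
  d <- as.matrix(stats::dist(embedding))
  diag(d) <- Inf
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ], seq_len(n))[seq_len(k)]
    A[i, nb] <- 1 / k
  }
  A
}

#' Smooth per-cell effects over an embedding neighborhood graph
#'
#' Computes `S = 2 * A * E` where `A` is the row-normalized k-nearest-
#' neighbor affinity matrix of the embedding (row sums 1). The factor of
#' two doubles the neighborhood average; it can be disabled since
#' downstream scores are threshold-calibrated anyway. Smoothing is
#' linear in `E` and reduces within-neighborhood variance.
#'
#' @param E an `EffectMatrix`.
#' @param k neighbors (default 15).
#' @param double apply the factor of 2 (default TRUE).
#' @return The `EffectMatrix` with smoothed `effects`.
#' @export
smooth_effects <- function(E, k = 15, double = TRUE) {
  A <- .knn_affinity(E$embedding, k)
  S <- A %*% E$effects
  if (double) S <- 2 * S
  dimnames(S) <- dimnames(E$effects)
  out <- E
  out$effects <- S
  out
}

#' Spectral co-clustering of a smoothed effect matrix
#'
#' Dhillon's bipartite spectral method: the magnitude matrix |E| is
#' normalized as `D1^(-1/2) |E| D2^(-1/2)`, its leading singular vectors
#' are stacked and k-means partitions cells and genes jointly into the
#' requested grid. Signs are deliberately ignored at this step (a module
#' is a block of coherently affected cells and genes; direction is
#' recovered by [score_modules()]).
#'
#' @param E an `EffectMatrix` (typically smoothed).
#' @param n_gene_modules,n_cell_modules requested grid.
#' @param seed integer seed for k-means.
#' @param minibatch accepted for interface parity; plain k-means is used
#'   at desk scale.
#' @return A `ModuleAssignment`: list with `cell_modules`,
#'   `gene_modules` (integer labels).
#' @export
cocluster_effects <- function(E, n_gene_modules = 4, n_cell_modules = 4,
                              seed = 0, minibatch = FALSE) {
  X <- abs(E$effects)
  if (max(X) - min(X) < 1e-12) stop("degenerate (constant) effect matrix")
  r <- rowSums(X); c <- colSums(X)
  r[r == 0] <- 1e-12; c[c == 0] <- 1e-12
  An <- sweep(sweep(X, 1, sqrt(r), "/"), 2, sqrt(c), "/")
  k <- max(n_gene_modules, n_cell_modules)
  nv <- min(max(1, ceiling(log2(k))), min(dim(X)) - 1)
  sv <- svd(An, nu = nv + 1, nv = nv + 1)
  # drop the trivial first pair, scale back by degree
  U <- sv$u[, 2:(nv + 1), drop = FALSE] / sqrt(r)
  V <- sv$v[, 2:(nv + 1), drop = FALSE] / sqrt(c)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  kmc <- stats::kmeans(U, centers = n_cell_modules, nstart = 20,
                       iter.max = 100)
  kmg <- stats::kmeans(V, centers = n_gene_modules, nstart = 20,
                       iter.max = 100)
  structure(list(cell_modules = kmc$cluster, gene_modules = kmg$cluster,
                 n_cell_modules = n_cell_modules,
                 n_gene_modules = n_gene_modules),
            class = "ModuleAssignment")
}

#' Score cells against effect modules
#'
#' For each cell module, markers are the top `top_n_markers` genes by
#' |mean log2FC| over the module's cells (sign retained). Two score
#' rules are exposed: `sum_lfc` (default) sums each cell's effects over
#' up-markers minus its effects over down-markers; `weighted_sign_mean`
#' averages `sign(marker) * effect` over markers.
#'
#' @param assignment a `ModuleAssignment`.
#' @param E an `EffectMatrix` on the same cells/genes.
#' @param score_rule "sum_lfc" or "weighted_sign_mean".
#' @param top_n_markers marker count per module.
#' @return list per cell module: `markers` (named mean-lfc vector,
#'   signed), `scores` (per-cell), `rule`.
#' @export
score_modules <- function(assignment, E,
                          score_rule = c("sum_lfc", "weighted_sign_mean"),
                          top_n_markers = 50) {
  score_rule <- match.arg(score_rule)
  eff <- E$effects
  out <- list()
  for (m in sort(unique(assignment$cell_modules))) {
    cells <- assignment$cell_modules == m
    mean_lfc <- colMeans(eff[cells, , drop = FALSE])
    ord <- order(abs(mean_lfc), decreasing = TRUE)
    top <- ord[seq_len(min(top_n_markers, length(ord)))]
    markers <- mean_lfc[top]
    if (!length(markers)) next
    out[[as.character(m)]] <- list(markers = markers,
                                   scores = score_cells(eff, markers,
                                                        score_rule),
                                   rule = score_rule)
  }
  out
}

#' @rdname score_modules
#' @param effects cells x genes effect matrix (or an `EffectMatrix`).
#' @param markers named signed marker vector (from a [score_modules()]
#'   entry); signs define the up/down split, values are ignored by
#'   `sum_lfc`.
#' @export
score_cells <- function(effects, markers,
                        score_rule = c("sum_lfc", "weighted_sign_mean")) {
  score_rule <- match.arg(score_rule)
  if (inherits(effects, "EffectMatrix")) effects <- effects$effects
  up <- names(markers)[markers > 0]
  down <- names(markers)[markers < 0]
  if (score_rule == "sum_lfc") {
    rowSums(effects[, up, drop = FALSE]) -
      rowSums(effects[, down, drop = FALSE])
  } else {
    sgn <- sign(markers)
    as.numeric(effects[, names(markers), drop = FALSE] %*% sgn) /
      length(markers)
  }
}

#' Youden-J module threshold and cross-tissue transfer
#'
#' Finds the score cutoff maximizing Youden's J = sensitivity +
#' specificity - 1 over candidate cutoffs (midpoints of sorted unique
#' scores), auto-detecting orientation, then applies the same cutoff to
#' each target tissue's scores. A gene-threshold override selector
#' ("predicted log2FC of gene g below c") is available for modules whose
#' biology is anchored to a single gene.
#'
#' @param scores_source per-cell scores in the source tissue.
#' @param labels_source logical in-module labels in the source.
#' @param scores_targets named list of per-tissue score vectors.
#' @return list: `threshold`, `direction` (">" or "<"), `J`, `masks`
#'   (named list of logical masks, source first).
#' @export
youden_cutoff_and_transfer <- function(scores_source, labels_source,
                                       scores_targets = list()) {
  labels_source <- as.logical(labels_source)
  if (length(unique(labels_source)) < 2)
    stop("source must contain both in-module and out-module cells")
  u <- sort(unique(scores_source))
  cand <- (u[-1] + u[-length(u)]) / 2
  best <- list(J = -Inf)
  for (cut in cand) for (dir in c(">", "<")) {
    pred <- if (dir == ">") scores_source > cut else scores_source < cut
    sens <- sum(pred & labels_source) / sum(labels_source)
    spec <- sum(!pred & !labels_source) / sum(!labels_source)
    J <- sens + spec - 1
    if (J > best$J) best <- list(J = J, threshold = cut, direction = dir)
  }
  apply_cut <- function(s)
    if (best$direction == ">") s > best$threshold else s < best$threshold
  masks <- c(list(source = apply_cut(scores_source)),
             lapply(scores_targets, apply_cut))
  list(threshold = best$threshold, direction = best$direction, J = best$J,
       masks = masks)
}

#' @rdname youden_cutoff_and_transfer
#' @param E an `EffectMatrix`.
#' @param gene gene symbol whose predicted log2FC is thresholded.
#' @param cutoff constant; cells with effect below it are selected.
#' @export
gene_threshold_mask <- function(E, gene, cutoff) {
  if (!gene %in% colnames(E$effects)) stop("gene not in effect matrix")
  E$effects[, gene] < cutoff
}

#' Validate an effect module by pseudobulk DE and enrichment
#'
#' Restricts the cells to the module-positive mask, reruns pseudobulk DE
#' in the relaxed validation mode (samples with at least 5 cells and
#' 1,000 total counts; genes with at least 3 total counts) for the age
#' contrast within each tissue present, and tests the module's marker
#' genes against the resulting log2FC ranking with pre-ranked GSEA.
#'
#' @param mask logical per-cell module mask.
#' @param matrix a [CellMatrix].
#' @param markers character vector of module marker genes.
#' @param unit_key pseudobulk unit column.
#' @param min_donors_per_arm arms below this donor floor are skipped.
#' @param seed GSEA permutation seed.
#' @return list: `de` (DEResult rows) and `enrichment`
#'   (EnrichmentResult rows per tissue); skipped tissues recorded in
#'   `skipped`.
#' @export
validate_module <- function(mask, matrix, markers, unit_key = "lineage",
                            min_donors_per_arm = 2, seed = 0) {
  sub <- subset_cells(matrix, cells = mask)
  pb <- pseudobulk_aggregate(sub, unit_key = unit_key)
  pb <- filter_pseudobulk(pb, min_cells = 5, gene_min_count = 5,
                          gene_min_fraction = 0.10,
                          min_total_counts = 1000, gene_min_total = 3)
  de_all <- list(); enr <- list(); skipped <- character()
  for (tg in unique(pb$sample_meta$tissue_group)) {
    m <- pb$sample_meta[pb$sample_meta$tissue_group == tg, ]
    d_old <- unique(m$donor_id[m$age_group == "old"])
    d_young <- unique(m$donor_id[m$age_group == "young"])
    if (length(d_old) < min_donors_per_arm ||
        length(d_young) < min_donors_per_arm) {
      skipped <- c(skipped, tg); next
    }
    de <- fit_differential_expression(pb, list(type = "age", tissue = tg),
                                      min_samples_per_arm =
                                        min_donors_per_arm)
    if (!nrow(de)) { skipped <- c(skipped, tg); next }
    de_all[[tg]] <- de
    for (u in unique(de$unit)) {
      dd <- de[de$unit == u, ]
      ranking <- stats::setNames(dd$logfc, dd$gene)
      set <- intersect(markers, dd$gene)
      if (length(set) < 3) next
      g <- gsea_preranked(ranking, list(module_markers = set),
                          n_perm = 500, seed = seed)
      g$tissue_group <- tg; g$unit <- u
      enr[[paste(tg, u)]] <- g
    }
  }
  list(de = if (length(de_all)) do.call(rbind, de_all) else NULL,
       enrichment = if (length(enr)) do.call(rbind, enr) else NULL,
       skipped = skipped)
}

#' kNN-contrast stand-in estimator for per-cell effects
#'
#' A deliberately simple per-cell effect estimator for fixtures and
#' demos: for each cell, the difference in mean log-normalized
#' expression between the two covariate groups among its k nearest
#' embedding neighbors. It shares the EffectMatrix contract with
#' counterfactual models but is not equivalent to one.
#'
#' @param matrix a [CellMatrix].
#' @param embedding cells x d matrix.
#' @param covariate two-level cell-metadata column (default
#'   `age_group`).
#' @param k neighbors.
#' @return An `EffectMatrix`.
#' @export
estimate_effects_knn <- function(matrix, embedding,
                                 covariate = "age_group", k = 30) {
  norm <- normalize_counts(matrix$gex_counts)$values
  norm <- as.matrix(norm)
  g <- factor(matrix$cell_meta[[covariate]])
  stopifnot(nlevels(g) == 2)
  n <- nrow(norm)
  d <- as.matrix(stats::dist(embedding))
  diag(d) <- Inf
  eff <- matrix(0, n, ncol(norm), dimnames = dimnames(norm))
  for (i in seq_len(n)) {
    nb <- order(d[i, ], seq_len(n))[seq_len(min(k, n - 1))]
    hi <- nb[g[nb] == levels(g)[2]]
    lo <- nb[g[nb] == levels(g)[1]]
    if (!length(hi) || !length(lo)) next
    eff[i, ] <- (colMeans(norm[hi, , drop = FALSE]) -
                   colMeans(norm[lo, , drop = FALSE])) / log(2)
  }
  structure(list(effects = eff, embedding = embedding,
                 raw_mean_expr = Matrix::colMeans(matrix$gex_counts),
                 n_samples = rep(Inf, n)),
            class = "EffectMatrix")
}
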