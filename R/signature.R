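#' Select tissue-signature genes from lineage-level DE
#'
#' Takes one-vs-rest tissue DE results across all tissue x lineage
#' combinations and keeps the union of genes passing adjusted p,
#' log2FC and average-expression thresholds in at least one
#' combination, returning a per-gene z-score matrix of mean expression
#' over combinations (z-scored within gene).
#'
#' @param lineage_de data.frame of DE results (columns `gene`, `unit`,
#'   `tissue_group`, `logfc`, `adj_p_val`, `aveexpr`) covering all
#'   combinations.
#' @param expr_means gene x combination matrix of mean expression used
#'   for the z-scores (see [mean_expression_by_group()]); when omitted,
#'   the DE table's `aveexpr` is arranged by (tissue_group x unit) as a
#'   coarse stand-in (it only varies across units).
#' @param adj_p_max,min_log2fc,min_ave_expr selection thresholds
#'   (all three must pass in the same combination).
#' @return numeric matrix genes x combinations of z-scores; selected
#'   gene set in `attr(, "selected")`.
#' @export
select_signature_genes <- function(lineage_de, expr_means = NULL,
                                   adj_p_max = 0.05, min_log2fc = 1,
                                   min_ave_expr = 2) {
  pass <- lineage_de$adj_p_val < adj_p_max &
    lineage_de$logfc > min_log2fc &
    lineage_de$aveexpr > min_ave_expr
  sel <- unique(lineage_de$gene[pass])
  if (!length(sel))
    stop("no genes pass the selection thresholds; consider relaxing ",
         "adj_p_max/min_log2fc/min_ave_expr")
  if (is.null(expr_means)) {
    combo <- paste(lineage_de$tissue_group, lineage_de$unit, sep = "|")
    expr_means <- tapply(lineage_de$aveexpr,
                         list(lineage_de$gene, combo), mean)
  }
  m <- expr_means[sel, , drop = FALSE]
  z <- t(scale(t(m)))
  z[is.nan(z)] <- 0  # constant rows
  attr(z, "selected") <- sel
  z
}

#' Mean expression per gene and group
#'
#' Convenience builder for the gene x combination matrix consumed by
#' [select_signature_genes()]: the mean normalized expression of every
#' gene within each group of cells (e.g. tissue group x lineage).
#'
#' @param norm_values cells x genes normalized expression (matrix or
#'   [normalize_counts()] output).
#' @param groups per-cell combination labels.
#' @return genes x groups matrix of means.
#' @export
mean_expression_by_group <- function(norm_values, groups) {
  if (inherits(norm_values, "NormalizedMatrix"))
    norm_values <- norm_values$values
  f <- factor(groups)
  ind <- Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f),
                              x = 1, dims = c(length(f), nlevels(f)))
  ind <- ind %*% Matrix::Diagonal(x = 1 / Matrix::colSums(ind))
  out <- as.matrix(Matrix::t(norm_values) %*% ind)
  colnames(out) <- levels(f)
  out
}

#' Cluster signature genes by expression pattern
#'
#' Agglomerative clustering with Ward's method on Euclidean distances,
#' cut to exactly `n_clusters` groups (maxclust semantics).
#' Deterministic given its input.
#'
#' @param zmatrix genes x combinations z-score matrix.
#' @param n_clusters requested number of gene clusters (>= 2).
#' @return A `GeneClusterSet`: list with `clusters` (named list cluster
#'   id -> gene vector), `labels` (per-gene integer), `zmatrix`,
#'   `linkage` = "ward.D2/euclidean".
#' @export
cluster_signature_genes <- function(zmatrix, n_clusters) {
  if (n_clusters < 2) stop("n_clusters must be >= 2")
  if (nrow(zmatrix) < n_clusters)
    stop("fewer genes than requested clusters")
  hc <- stats::hclust(stats::dist(zmatrix, method = "euclidean"),
                      method = "ward.D2")
  labels <- stats::cutree(hc, k = n_clusters)
  clusters <- split(rownames(zmatrix), labels)
  names(clusters) <- paste0("C", names(clusters))
  structure(list(clusters = clusters, labels = labels, zmatrix = zmatrix,
                 linkage = "ward.D2/euclidean", tree = hc),
            class = "GeneClusterSet")
}

#' @export
print.GeneClusterSet <- function(x, ...) {
  cat(sprintf("GeneClusterSet: %d genes in %d clusters (%s)\n",
              length(x$labels), length(x$clusters), x$linkage))
  invisible(x)
}

#' Summarize whether a tissue signature is compositional or transcriptional
#'
#' For one gene cluster, combines three lines of evidence per
#' subset x tissue: the subset's within-lineage frequency and its log2
#' frequency fold-change versus the other tissues, the within-subset
#' shift in mean cluster expression (in-tissue vs out), and the GSEA
#' enrichment of the cluster in the subset-level DE. A flag is derived
#' from configurable thresholds: "composition-driven" when the frequency
#' shift is large but within-subset expression is flat,
#' "expression-driven" when the enrichment is significant with stable
#' frequencies, otherwise "mixed/unclear". The raw evidence is always
#' returned; the flag is a reporting heuristic.
#'
#' @param cluster_genes character vector (one entry of a
#'   [cluster_signature_genes()] result).
#' @param cell_meta per-cell metadata with `subset`, `lineage`,
#'   `tissue_group`.
#' @param norm_expr cells x genes normalized expression matrix.
#' @param enrichments data.frame from [gsea_preranked()] runs with
#'   columns `subset`, `tissue_group`, `nes`, `fdr_q`.
#' @param freq_fc_min log2 frequency-FC at/above which composition is
#'   implicated (default 1).
#' @param expr_shift_max log2 expression shift below which within-subset
#'   expression is called flat (default 0.25).
#' @param freq_fc_flat log2 frequency-FC below which frequencies are
#'   called stable (default 0.5).
#' @param fdr_max enrichment significance threshold.
#' @return data.frame per subset x tissue with frequencies, shifts, NES
#'   and the `flag`.
#' @export
summarize_composition_vs_expression <- function(cluster_genes, cell_meta,
                                                norm_expr, enrichments,
                                                freq_fc_min = 1,
                                                expr_shift_max = 0.25,
                                                freq_fc_flat = 0.5,
                                                fdr_max = 0.05) {
  genes <- intersect(cluster_genes, colnames(norm_expr))
  score <- Matrix::rowMeans(norm_expr[, genes, drop = FALSE])
  out <- list()
  for (lin in unique(cell_meta$lineage)) {
    lsel <- cell_meta$lineage == lin
    for (tg in unique(cell_meta$tissue_group)) {
      in_t <- lsel & cell_meta$tissue_group == tg
      out_t <- lsel & cell_meta$tissue_group != tg
      if (!any(in_t) || !any(out_t)) next
      for (sub in unique(cell_meta$subset[lsel])) {
        f_in <- mean(cell_meta$subset[in_t] == sub)
        f_out <- mean(cell_meta$subset[out_t] == sub)
        freq_fc <- log2((f_in + 1e-6) / (f_out + 1e-6))
        s_in <- in_t & cell_meta$subset == sub
        s_out <- out_t & cell_meta$subset == sub
        expr_shift <- if (any(s_in) && any(s_out))
          log2((mean(score[s_in]) + 1e-6) / (mean(score[s_out]) + 1e-6))
        else NA_real_
        e <- enrichments[enrichments$subset == sub &
                           enrichments$tissue_group == tg, , drop = FALSE]
        nes <- if (nrow(e)) e$nes[1] else NA_real_
        q <- if (nrow(e)) e$fdr_q[1] else NA_real_
        sig <- !is.na(q) && q < fdr_max
        flag <- if (freq_fc >= freq_fc_min &&
                    (!is.na(expr_shift) && abs(expr_shift) < expr_shift_max))
          "composition-driven"
        else if (sig && freq_fc < freq_fc_flat) "expression-driven"
        else "mixed/unclear"
        out[[length(out) + 1]] <- data.frame(
          lineage = lin, subset = sub, tissue_group = tg,
          freq_in = f_in, freq_out = f_out, log2_freq_fc = freq_fc,
          log2_expr_shift = expr_shift, nes = nes, fdr_q = q,
          flag = flag, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-donor ADT differential abundance between groups
#'
#' Within each donor, cells are subsampled to equal group sizes, counts
#' are depth-equalized across groups ([downsample_equal_depth()]) and
#' each marker is tested with a two-sided Wilcoxon rank-sum test
#' (tie-corrected) on normalized values. Donors contributing fewer than
#' `min_cells` cells in either group are excluded; the analysis is
#' skipped (empty result with an audit attribute) when fewer than
#' `min_donors` donors remain.
#'
#' @param adt_counts cells x markers count matrix.
#' @param groups two-level per-cell grouping (tested as level2 vs
#'   level1).
#' @param donors per-cell donor labels (required when `per_donor`).
#' @param per_donor analyze within donors (default) or pooled.
#' @param min_cells,min_donors eligibility floors.
#' @param seed integer seed for subsampling.
#' @param scale ADT normalization scale (default 1,000).
#' @return data.frame: `donor`, `marker`, `statistic` (W), `p_value`,
#'   `delta` (median difference, level2 - level1), `n_per_group`.
#' @export
adt_differential <- function(adt_counts, groups, donors = NULL,
                             per_donor = TRUE, min_cells = 50,
                             min_donors = 4, seed = 0, scale = 1e3) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  if (per_donor && is.null(donors))
    stop("donor labels required when per_donor = TRUE")
  if (!per_donor) donors <- rep("pooled", nrow(adt_counts))
  donors <- as.character(donors)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  eligible <- character()
  for (d in unique(donors)) {
    n1 <- sum(donors == d & groups == levels(groups)[1])
    n2 <- sum(donors == d & groups == levels(groups)[2])
    if (n1 >= min_cells && n2 >= min_cells) eligible <- c(eligible, d)
  }
  if (per_donor && length(eligible) < min_donors) {
    out <- data.frame(donor = character(), marker = character(),
                      statistic = numeric(), p_value = numeric(),
                      delta = numeric(), n_per_group = integer())
    attr(out, "audit") <- list(skipped = TRUE,
                               eligible_donors = length(eligible),
                               min_donors = min_donors)
    return(out)
  }
  rows <- list()
  for (d in eligible) {
    idx <- which(donors == d)
    g <- groups[idx]
    n_eq <- min(table(g))
    keep <- c(sample(idx[g == levels(groups)[1]], n_eq),
              sample(idx[g == levels(groups)[2]], n_eq))
    sub_counts <- adt_counts[keep, , drop = FALSE]
    sub_g <- groups[keep]
    sub_counts <- downsample_equal_depth(sub_counts, sub_g,
                                         seed = seed + match(d, eligible))
    tot <- Matrix::rowSums(sub_counts)
    ok <- tot > 0
    vals <- normalize_counts(sub_counts[ok, , drop = FALSE],
                             scale = scale)$values
    sub_g <- sub_g[ok]
    for (a in seq_len(ncol(vals))) {
      v <- as.numeric(vals[, a])
      x2 <- v[sub_g == levels(groups)[2]]
      x1 <- v[sub_g == levels(groups)[1]]
      wt <- suppressWarnings(stats::wilcox.test(x2, x1, correct = TRUE))
      rows[[length(rows) + 1]] <- data.frame(
        donor = d,
        marker = colnames(adt_counts)[a],
        statistic = unname(wt$statistic), p_value = wt$p.value,
        delta = stats::median(x2) - stats::median(x1),
        n_per_group = n_eq, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "audit") <- list(skipped = FALSE,
                             eligible_donors = length(eligible))
  out
}
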