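#' Composite per-cell quality scores
#'
#' Sums the available evidence of a low-quality event into one additive
#' score per cell: doublet probabilities (two callers), erythrocyte gene
#' fraction, dual TCR+BCR receptor flag, erythrocyte-classifier flag, and
#' indicator flags for low UMI (total counts < 2,000), low gene count
#' (< 1,200 detected genes), low ADT counts (< 200) and high mitochondrial
#' fraction (> 20%). Probabilities and fractions enter on their 0-1 scale;
#' flags contribute 0 or 1. Every component is reported alongside the
#' total for auditability.
#'
#' @param matrix a [CellMatrix] with `qc_flags` populated (probabilities /
#'   fractions); UMI, gene and ADT totals are computed from the counts and
#'   the mitochondrial fraction is taken from `qc_flags$mito_fraction` or
#'   computed from `gene_meta$is_mito`.
#' @param include_mito whether the high-mito indicator enters the sum
#'   (the flag is always reported).
#' @param low_umi,low_genes,low_adt,high_mito thresholds for the
#'   indicator components.
#' @return data.frame, one row per cell: each component plus `total`.
#' @export
compute_quality_scores <- function(matrix, include_mito = TRUE,
                                   low_umi = 2000, low_genes = 1200,
                                   low_adt = 200, high_mito = 0.20) {
  stopifnot(inherits(matrix, "CellMatrix"))
  qf <- matrix$qc_flags
  required <- c("scrublet_prob", "hashsolo_prob", "erythro_fraction",
                "dual_receptor", "erythro_pred")
  missing_cols <- if (is.null(qf)) required else setdiff(required, names(qf))
  if (length(missing_cols))
    stop("qc_flags missing required columns: ",
         paste(missing_cols, collapse = ", "))
  n <- nrow(matrix$gex_counts)
  umi <- Matrix::rowSums(matrix$gex_counts)
  genes_detected <- Matrix::rowSums(matrix$gex_counts > 0)
  adt_total <- if (!is.null(matrix$adt_counts))
    Matrix::rowSums(matrix$adt_counts) else rep(NA_real_, n)
  mito <- if (!is.null(qf$mito_fraction)) qf$mito_fraction
  else if (!is.null(matrix$gene_meta$is_mito))
    Matrix::rowSums(matrix$gex_counts[, matrix$gene_meta$is_mito,
                                      drop = FALSE]) / pmax(umi, 1)
  else rep(0, n)
  out <- data.frame(
    cell_id = matrix$cell_meta$cell_id,
    scrublet_prob = qf$scrublet_prob,
    hashsolo_prob = qf$hashsolo_prob,
    erythro_fraction = qf$erythro_fraction,
    dual_receptor = as.integer(qf$dual_receptor > 0),
    erythro_pred = as.integer(qf$erythro_pred > 0),
    low_umi = as.integer(umi < low_umi),
    low_genes = as.integer(genes_detected < low_genes),
    low_adt = as.integer(!is.na(adt_total) & adt_total < low_adt),
    high_mito = as.integer(mito > high_mito),
    stringsAsFactors = FALSE)
  comp <- c("scrublet_prob", "hashsolo_prob", "erythro_fraction",
            "dual_receptor", "erythro_pred", "low_umi", "low_genes",
            "low_adt")
  if (include_mito) comp <- c(comp, "high_mito")
  out$total <- rowSums(out[comp])
  out
}

#' Remove clusters of low-quality cells, with rescue rules
#'
#' A cluster is removed when its median composite score is at or above
#' `median_cutoff`, or its mean score is at or above the applicable mean
#' cutoff (per-tissue overrides mirror manually raised thresholds for
#' difficult tissues), unless it matches a rescue rule. Rescue rules name
#' (subset, tissue) pairs of populations whose apparent low quality is
#' biological (mast cells, platelets, plasma cells, ...) and force
#' retention.
#'
#' @param scores data.frame from [compute_quality_scores()] (needs
#'   `total`), or a numeric vector of totals.
#' @param cluster_labels per-cell cluster assignment (any labeling; e.g.
#'   graph clustering on a latent space, or [cluster_cells_kmeans()]).
#' @param median_cutoff,mean_cutoff removal thresholds (>= comparison).
#' @param mean_cutoff_overrides named numeric, tissue_group -> cutoff.
#' @param rescue_rules list of `list(subset=, tissue=)`; `tissue = NULL`
#'   or `"any"` matches all tissues.
#' @param subset_labels,tissue_labels per-cell labels used to match
#'   rescue rules and tissue overrides (required when those are given).
#' @return logical keep-mask per cell, with a per-cluster audit table in
#'   `attr(, "audit")`.
#' @export
filter_low_quality_clusters <- function(scores, cluster_labels,
                                        median_cutoff = 1.0,
                                        mean_cutoff = 0.3,
                                        mean_cutoff_overrides = NULL,
                                        rescue_rules = list(),
                                        subset_labels = NULL,
                                        tissue_labels = NULL) {
  total <- if (is.data.frame(scores)) scores$total else as.numeric(scores)
  stopifnot(median_cutoff >= 0, mean_cutoff >= 0,
            length(cluster_labels) == length(total))
  cluster_labels <- as.character(cluster_labels)
  if (anyNA(cluster_labels)) stop("cluster_labels must cover all cells")
  known_subsets <- unique(as.character(subset_labels))
  rules <- list()
  for (r in rescue_rules) {
    if (!is.null(subset_labels) && !r$subset %in% known_subsets) {
      warning("rescue rule names unknown subset '", r$subset, "'; ignored")
      next
    }
    rules <- c(rules, list(r))
  }
  clusters <- unique(cluster_labels)
  keep <- rep(TRUE, length(total))
  audit <- data.frame(cluster = clusters, n = NA_integer_,
                      median_score = NA_real_, mean_score = NA_real_,
                      removed = FALSE, rescued = FALSE,
                      stringsAsFactors = FALSE)
  for (i in seq_along(clusters)) {
    idx <- which(cluster_labels == clusters[i])
    med <- stats::median(total[idx]); mn <- mean(total[idx])
    tiss <- if (!is.null(tissue_labels))
      unique(as.character(tissue_labels[idx])) else character()
    cutoff_mean <- mean_cutoff
    if (!is.null(mean_cutoff_overrides) && length(tiss) == 1 &&
        tiss %in% names(mean_cutoff_overrides))
      cutoff_mean <- mean_cutoff_overrides[[tiss]]
    remove <- med >= median_cutoff || mn >= cutoff_mean
    rescued <- FALSE
    if (remove && length(rules) && !is.null(subset_labels)) {
      sub_major <- names(sort(table(subset_labels[idx]), decreasing = TRUE))[1]
      for (r in rules) {
        tissue_ok <- is.null(r$tissue) || identical(r$tissue, "any") ||
          any(tiss %in% r$tissue) ||
          (!length(tiss) && is.null(tissue_labels))
        if (r$subset == sub_major && tissue_ok) { rescued <- TRUE; break }
      }
    }
    if (remove && !rescued) keep[idx] <- FALSE
    audit$n[i] <- length(idx); audit$median_score[i] <- med
    audit$mean_score[i] <- mn; audit$removed[i] <- remove && !rescued
    audit$rescued[i] <- rescued
  }
  attr(keep, "audit") <- audit
  keep
}

#' k-means clustering of cells on a provided embedding
#'
#' Lightweight fallback labeling for QC filtering when no graph
#' clustering is available; any per-cell labeling can be used instead.
#'
#' @param embedding cells x d numeric matrix.
#' @param k number of clusters.
#' @param seed integer seed.
#' @return character vector of cluster labels.
#' @export
cluster_cells_kmeans <- function(embedding, k, seed = 0) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  km <- stats::kmeans(embedding, centers = k, nstart = 10, iter.max = 50)
  paste0("c", km$cluster)
}
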