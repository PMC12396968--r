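#' Prefilter genes for Poisson factorization
#'
#' Keeps genes detected in at least `min_cell_fraction` of cells,
#' optionally restricted to a protein-coding surrogate flag and with
#' receptor-cassette/nuisance exclusions.
#'
#' @param counts cells x genes count matrix.
#' @param min_cell_fraction detection floor (default 1% of cells).
#' @param exclude optional character vector of gene symbols to drop
#'   (e.g. TCR/immunoglobulin cassettes).
#' @param coding_flag optional logical per-gene vector; FALSE genes drop.
#' @return logical keep-vector over genes.
#' @export
prefilter_factorization_genes <- function(counts, min_cell_fraction = 0.01,
                                          exclude = NULL,
                                          coding_flag = NULL) {
  frac <- Matrix::colSums(counts > 0) / nrow(counts)
  keep <- frac >= min_cell_fraction
  if (!is.null(coding_flag)) keep <- keep & coding_flag
  if (!is.null(exclude) && !is.null(colnames(counts)))
    keep <- keep & !(colnames(counts) %in% exclude)
  keep
}

.poisson_deviance <- function(X, R) {
  # Poisson negative log-likelihood up to constants: sum(R - X*log R)
  sum(R) - sum(X[X > 0] * log(R[X > 0]))
}

#' Fit a Poisson matrix factorization ("HPF-lite")
#'
#' Nonnegative factorization of a count matrix maximizing the Poisson
#' likelihood via multiplicative (KL) updates: `X ~ W H` with `W` the
#' M x K gene-score matrix and `H` the K x N cell-score matrix. The
#' deviance is non-increasing every iteration; the fit stops when the
#' relative deviance change falls below `tol`. The scale ambiguity is
#' resolved by normalizing gene-score columns to sum to one (cell scores
#' absorb the scale).
#'
#' @param counts cells x genes non-negative integer matrix, prefiltered
#'   (no all-zero genes or cells; see
#'   [prefilter_factorization_genes()]).
#' @param K number of factors (>= 2).
#' @param seed integer seed for the random initialization.
#' @param max_iter,tol stopping rule.
#' @return A `FactorModel`: list with `gene_scores` (M x K,
#'   column-normalized), `cell_scores` (K x N), `K`, `seed`,
#'   `iterations`, `deviance`, `deviance_trace`.
#' @export
fit_poisson_factorization <- function(counts, K, seed = 0,
                                      max_iter = 300, tol = 1e-6) {
  stopifnot(K >= 2)
  X <- t(as.matrix(counts))  # genes x cells
  if (any(X < 0)) stop("counts must be non-negative")
  if (any(rowSums(X) == 0) || any(colSums(X) == 0))
    stop("all-zero genes or cells present; prefilter before fitting")
  M <- nrow(X); N <- ncol(X)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  W <- matrix(stats::rgamma(M * K, 2, 2), M, K)
  H <- matrix(stats::rgamma(K * N, 2, 2), K, N)
  eps <- 1e-12
  trace <- numeric(0)
  prev <- Inf
  it <- 0
  for (it in seq_len(max_iter)) {
    R <- W %*% H + eps
    W <- W * ((X / R) %*% t(H)) / (matrix(rowSums(H), M, K, byrow = TRUE) + eps)
    R <- W %*% H + eps
    H <- H * (t(W) %*% (X / R)) / (matrix(colSums(W), K, N) + eps)
    dev <- .poisson_deviance(X, W %*% H + eps)
    trace <- c(trace, dev)
    if (is.finite(prev) && abs(prev - dev) / (abs(prev) + eps) < tol) break
    prev <- dev
  }
  csum <- colSums(W)
  W <- sweep(W, 2, csum, "/")
  H <- H * csum
  rownames(W) <- rownames(X)
  colnames(W) <- sprintf("F%d", seq_len(K))
  rownames(H) <- colnames(W)
  colnames(H) <- colnames(X)
  structure(list(gene_scores = W, cell_scores = H, K = K, seed = seed,
                 iterations = it, deviance = trace[length(trace)],
                 deviance_trace = trace),
            class = "FactorModel")
}

#' @export
print.FactorModel <- function(x, ...) {
  cat(sprintf("FactorModel: %d genes x %d factors x %d cells (deviance %.1f)\n",
              nrow(x$gene_scores), x$K, ncol(x$cell_scores), x$deviance))
  invisible(x)
}

#' Consensus Poisson factorization over restarts and ranks
#'
#' Runs [fit_poisson_factorization()] `runs_per_K` times for every K in
#' `K_range`, keeps the top models per K by final deviance, builds a
#' factor-similarity graph (Pearson correlation of gene-score vectors,
#' edges above `cor_threshold`) and finds recurrent factor communities
#' by random-walk (walktrap) community detection, or a deterministic
#' agglomerative fallback with the same acceptance contract. Communities
#' containing factors from at least two distinct models become consensus
#' factors; a final model with that many factors is refit seeded at the
#' community medoids.
#'
#' @param counts cells x genes prefiltered count matrix.
#' @param K_range integer vector of ranks (desk scale: e.g. 4:8).
#' @param runs_per_K restarts per rank.
#' @param top_models_per_K models kept per rank (by deviance).
#' @param seed integer seed (per-run seeds are derived from it).
#' @param cor_threshold similarity-graph edge threshold.
#' @param method "walktrap" or "agglomerative".
#' @param max_iter,tol passed to the per-run fits.
#' @return A `ConsensusFactorModel`: a `FactorModel` plus `provenance`
#'   (per consensus factor, the contributing model/factor ids),
#'   `consensus_K`, and slots for downstream annotations.
#' @export
consensus_factorize <- function(counts, K_range = 4:8, runs_per_K = 5,
                                top_models_per_K = 3, seed = 0,
                                cor_threshold = 0.6,
                                method = c("walktrap", "agglomerative"),
                                max_iter = 200, tol = 1e-5) {
  method <- match.arg(method)
  models <- list()
  for (K in K_range) {
    fits <- lapply(seq_len(runs_per_K), function(r)
      fit_poisson_factorization(counts, K,
                                seed = seed * 1000L + K * 10L + r,
                                max_iter = max_iter, tol = tol))
    dev <- vapply(fits, `[[`, numeric(1), "deviance")
    keep <- order(dev)[seq_len(min(top_models_per_K, length(fits)))]
    for (r in keep)
      models[[sprintf("K%d_run%d", K, r)]] <- fits[[r]]
  }
  # stack factors: columns = factors across kept models
  fac_mat <- do.call(cbind, lapply(names(models), function(nm) {
    W <- models[[nm]]$gene_scores
    colnames(W) <- paste(nm, colnames(W), sep = ".")
    W
  }))
  model_of <- sub("\\.F\\d+$", "", colnames(fac_mat))
  cmat <- stats::cor(fac_mat)
  if (method == "walktrap") {
    adj <- cmat
    adj[adj < cor_threshold] <- 0
    diag(adj) <- 0
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             weighted = TRUE)
    comm <- igraph::cluster_walktrap(g)
    membership <- igraph::membership(comm)
  } else {
    # single linkage at 1 - cor_threshold = connected components of the
    # super-threshold similarity graph, mirroring the graph community route
    hc <- stats::hclust(stats::as.dist(1 - cmat), method = "single")
    membership <- stats::cutree(hc, h = 1 - cor_threshold)
  }
  clusters <- split(colnames(fac_mat), membership)
  recurrent <- Filter(function(fs)
    length(unique(model_of[match(fs, colnames(fac_mat))])) >= 2, clusters)
  if (!length(recurrent))
    stop("no recurrent factor communities found; widen K_range or ",
         "lower cor_threshold")
  medoids <- vapply(recurrent, function(fs) {
    idx <- match(fs, colnames(fac_mat))
    if (length(idx) == 1) return(fs)
    tot <- colSums(cmat[idx, idx, drop = FALSE])
    fs[which.max(tot)]
  }, character(1))
  Kc <- length(recurrent)
  # refit seeded at medoid gene-score vectors
  X <- t(as.matrix(counts))
  M <- nrow(X); N <- ncol(X)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  W <- fac_mat[, medoids, drop = FALSE] + 1e-4
  H <- matrix(stats::rgamma(Kc * N, 2, 2), Kc, N)
  eps <- 1e-12
  trace <- numeric(0); prev <- Inf
  for (it in seq_len(max_iter)) {
    R <- W %*% H + eps
    W <- W * ((X / R) %*% t(H)) /
      (matrix(rowSums(H), M, Kc, byrow = TRUE) + eps)
    R <- W %*% H + eps
    H <- H * (t(W) %*% (X / R)) / (matrix(colSums(W), Kc, N) + eps)
    dev <- .poisson_deviance(X, W %*% H + eps)
    trace <- c(trace, dev)
    if (is.finite(prev) && abs(prev - dev) / (abs(prev) + eps) < tol) break
    prev <- dev
  }
  csum <- colSums(W)
  W <- sweep(W, 2, csum, "/"); H <- H * csum
  rownames(W) <- rownames(X)
  colnames(W) <- sprintf("CF%d", seq_len(Kc))
  rownames(H) <- colnames(W); colnames(H) <- colnames(X)
  provenance <- lapply(recurrent, identity)
  names(provenance) <- colnames(W)
  structure(list(gene_scores = W, cell_scores = H, K = Kc, seed = seed,
                 iterations = it, deviance = trace[length(trace)],
                 deviance_trace = trace, consensus_K = Kc,
                 provenance = provenance, n_models = length(models),
                 nuisance_flags = NULL, tissue_labels = NULL),
            class = c("ConsensusFactorModel", "FactorModel"))
}

#' Flag probable nuisance factors
#'
#' A factor is flagged when, among its `top_n` top-weighted genes, the
#' number belonging to a nuisance list exceeds that list's threshold
#' (strict inequalities): heat-shock proteins (> 1, dissociation
#' artifact), ribosomal proteins (> 10, coverage artifact),
#' metallothioneins (> 1, highly inducible), hemoglobin (> 0, red-cell
#' contamination) and a dissociation-stress signature (> 7).
#'
#' @param model a `FactorModel`.
#' @param gene_meta data.frame with `symbol` and logical `is_<list>`
#'   columns for the lists named in `thresholds`.
#' @param top_n number of top-weighted genes inspected.
#' @param thresholds named numeric vector of strict count thresholds.
#' @return logical vector per factor, with a per-factor count table in
#'   `attr(, "counts")`.
#' @export
flag_nuisance_factors <- function(model, gene_meta, top_n = 30,
                                  thresholds = c(hsp = 1, ribo = 10,
                                                 metallothionein = 1,
                                                 hemoglobin = 0,
                                                 stress = 7)) {
  W <- model$gene_scores
  gm <- gene_meta[match(rownames(W), gene_meta$symbol), , drop = FALSE]
  flags <- rep(FALSE, ncol(W))
  names(flags) <- colnames(W)
  counts <- matrix(NA_integer_, ncol(W), length(thresholds),
                   dimnames = list(colnames(W), names(thresholds)))
  for (k in seq_len(ncol(W))) {
    top <- order(W[, k], decreasing = TRUE)[seq_len(min(top_n, nrow(W)))]
    for (lst in names(thresholds)) {
      col <- paste0("is_", lst)
      if (is.null(gm[[col]])) {
        warning("gene_meta lacks nuisance column ", col, "; rule skipped")
        thresholds <- thresholds[names(thresholds) != lst]
        next
      }
      cnt <- sum(gm[[col]][top], na.rm = TRUE)
      counts[k, lst] <- cnt
      if (cnt > thresholds[[lst]]) flags[k] <- TRUE
    }
  }
  attr(flags, "counts") <- counts
  flags
}

#' Label tissue-specific factors
#'
#' A factor is labeled with tissue group t when its mean cell score in t
#' is at least 80% higher than the average of the remaining groups
#' (inclusive boundary: ratio >= 1.8).
#'
#' @param model a `FactorModel`.
#' @param tissue_labels per-cell tissue-group vector (aligned with
#'   `cell_scores` columns).
#' @param ratio specificity ratio (default 1.8).
#' @return character vector per factor: the selected tissue group or NA,
#'   with the per-factor x tissue mean-score matrix in
#'   `attr(, "means")`.
#' @export
select_tissue_specific_factors <- function(model, tissue_labels,
                                           ratio = 1.8) {
  H <- model$cell_scores
  tissue_labels <- as.character(tissue_labels)
  stopifnot(length(tissue_labels) == ncol(H))
  tg <- sort(unique(tissue_labels))
  empty <- tg[!tg %in% tissue_labels]
  if (length(empty)) warning("tissue groups with no cells excluded")
  means <- sapply(tg, function(t)
    rowMeans(H[, tissue_labels == t, drop = FALSE]))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1,
                                           dimnames = list(rownames(H), tg))
  lab <- rep(NA_character_, nrow(H))
  names(lab) <- rownames(H)
  for (k in seq_len(nrow(H))) {
    for (t in tg) {
      rest <- mean(means[k, setdiff(tg, t)])
      if (rest > 0 && means[k, t] >= ratio * rest) { lab[k] <- t; break }
    }
  }
  attr(lab, "means") <- means
  lab
}

#' Detect gene modules shared across lineage-specific factor models
#'
#' Computes pairwise Pearson correlations between the gene-score vectors
#' of factors pooled from several models (intersected gene universe),
#' keeps factors exceeding the two-sided 95% Fisher-z null bound
#' `r* = tanh(z_{0.975} / sqrt(M - 3))` with at least `min_partners`
#' partners, and clusters the retained correlation matrix (Ward on
#' Euclidean distances of correlation rows) into modules.
#'
#' @param factor_models named list of `FactorModel`s (or gene-score
#'   matrices), one per lineage.
#' @param correlation_ci confidence level of the null bound.
#' @param min_partners minimum super-threshold partners to retain a
#'   factor.
#' @param n_modules number of modules to cut (default 2).
#' @return list with `modules` (named integer vector factor -> module;
#'   empty when < 3 factors retained), `correlation`, `threshold`,
#'   `retained`.
#' @export
detect_cross_lineage_modules <- function(factor_models,
                                         correlation_ci = 0.95,
                                         min_partners = 2,
                                         n_modules = 2) {
  mats <- lapply(factor_models, function(m)
    if (inherits(m, "FactorModel")) m$gene_scores else m)
  if (is.null(names(mats))) names(mats) <- sprintf("model%d", seq_along(mats))
  universe <- Reduce(intersect, lapply(mats, rownames))
  if (length(universe) < 4) stop("shared gene universe too small")
  pooled <- do.call(cbind, lapply(names(mats), function(nm) {
    W <- mats[[nm]][universe, , drop = FALSE]
    colnames(W) <- paste(nm, colnames(W), sep = ".")
    W
  }))
  M <- length(universe)
  z <- stats::qnorm(1 - (1 - correlation_ci) / 2)
  threshold <- tanh(z / sqrt(M - 3))
  cmat <- stats::cor(pooled)
  diag(cmat) <- 0
  partners <- rowSums(cmat > threshold)
  retained <- names(partners)[partners >= min_partners]
  if (length(retained) < 3) {
    return(list(modules = stats::setNames(integer(0), character(0)),
                correlation = cmat, threshold = threshold,
                retained = retained))
  }
  sub <- cmat[retained, retained]
  diag(sub) <- 1
  hc <- stats::hclust(stats::dist(sub, method = "euclidean"),
                      method = "ward.D2")
  modules <- stats::cutree(hc, k = min(n_modules, length(retained)))
  list(modules = modules, correlation = cmat, threshold = threshold,
       retained = retained)
}

#' Associate factor cell scores with a donor covariate
#'
#' Fits, per factor, a linear mixed model with the factor's cell scores
#' as the response, the covariate of interest plus the configured fixed
#' effects (and, when available, two tissue-type dummies for mucosal and
#' lymph-node versus blood-rich sites), and donor as a random intercept.
#' Reports the covariate coefficient, its p-value (Satterthwaite) and
#' BH-adjusted p across factors, together with raw and covariate-
#' adjusted (partial-regression: residual plus covariate effect) cell
#' scores for plotting.
#'
#' @param model a `FactorModel`.
#' @param cell_meta per-cell metadata aligned with cell-score columns.
#' @param covariate column tested (default `age_group`).
#' @param fixed additional fixed-effect columns (silently dropped when
#'   absent or single-level).
#' @param tissue_type optional per-cell tissue-type vector (e.g.
#'   mucosal / LN / blood-rich) entered as dummies.
#' @param random grouping column for the random intercept.
#' @param covariate_levels reference/contrast level order; the reported
#'   coefficient is the second level versus the first (defaults to
#'   young -> old for `age_group`, so positive = higher in older
#'   donors).
#' @return list: `table` (factor, coef, se, p, adj_p, skipped) and
#'   `adjusted_scores` (K x N).
#' @export
associate_factors_with_covariate <- function(model, cell_meta,
                                             covariate = "age_group",
                                             fixed = c("chemistry", "sex",
                                                       "site", "cmv"),
                                             tissue_type = NULL,
                                             random = "donor_id",
                                             covariate_levels = NULL) {
  H <- model$cell_scores
  stopifnot(nrow(cell_meta) == ncol(H))
  if (is.null(covariate_levels))
    covariate_levels <- if (covariate == "age_group" &&
                            all(cell_meta[[covariate]] %in%
                                  c("young", "old"))) c("young", "old")
    else sort(unique(as.character(cell_meta[[covariate]])))
  df <- data.frame(cov = factor(cell_meta[[covariate]],
                                levels = covariate_levels),
                   donor = cell_meta[[random]],
                   stringsAsFactors = FALSE)
  keep_fixed <- character()
  for (fx in fixed) {
    if (is.null(cell_meta[[fx]])) next
    if (length(unique(cell_meta[[fx]])) < 2) next
    df[[fx]] <- factor(cell_meta[[fx]])
    keep_fixed <- c(keep_fixed, fx)
  }
  if (!is.null(tissue_type)) {
    df$tissue_type <- factor(tissue_type)
    keep_fixed <- c(keep_fixed, "tissue_type")
  }
  fml <- stats::as.formula(paste(
    "score ~ cov",
    if (length(keep_fixed)) paste("+", paste(keep_fixed, collapse = " + "))
    else "", "+ (1|donor)"))
  rows <- list()
  adj <- H * NA_real_
  for (k in seq_len(nrow(H))) {
    df$score <- H[k, ]
    fit <- tryCatch(suppressMessages(suppressWarnings(
      lmerTest::lmer(fml, data = df))), error = function(e) NULL)
    if (is.null(fit)) {
      rows[[k]] <- data.frame(factor = rownames(H)[k], coef = NA_real_,
                              se = NA_real_, p_value = NA_real_,
                              skipped = TRUE, stringsAsFactors = FALSE)
      next
    }
    sm <- summary(fit)$coefficients
    covrow <- grep("^cov", rownames(sm))[1]
    rows[[k]] <- data.frame(factor = rownames(H)[k],
                            coef = sm[covrow, "Estimate"],
                            se = sm[covrow, "Std. Error"],
                            p_value = sm[covrow, "Pr(>|t|)"],
                            skipped = FALSE, stringsAsFactors = FALSE)
    # partial regression: residual + intercept + covariate effect
    Xc <- stats::model.matrix(~cov, df)
    beta <- lme4::fixef(fit)
    bsel <- c("(Intercept)", grep("^cov", names(beta), value = TRUE))
    adj[k, ] <- stats::residuals(fit) +
      as.numeric(Xc[, bsel, drop = FALSE] %*% beta[bsel])
  }
  tab <- do.call(rbind, rows)
  tab$adj_p <- NA_real_
  ok <- !tab$skipped
  tab$adj_p[ok] <- stats::p.adjust(tab$p_value[ok], "BH")
  rownames(tab) <- NULL
  list(table = tab, adjusted_scores = adj)
}

#' Project new cells onto a fitted factor model
#'
#' Holds the gene scores fixed and runs the multiplicative cell-score
#' updates on the new counts, restricted to the gene overlap (an error
#' below 50% overlap).
#'
#' @param model a `FactorModel`.
#' @param new_counts cells x genes count matrix (gene symbols as
#'   colnames).
#' @param seed integer seed for initialization.
#' @param max_iter,tol stopping rule.
#' @param min_overlap minimum fraction of model genes present.
#' @return K x cells nonnegative cell-score matrix.
#' @export
project_onto_factors <- function(model, new_counts, seed = 0,
                                 max_iter = 200, tol = 1e-6,
                                 min_overlap = 0.5) {
  W <- model$gene_scores
  common <- intersect(rownames(W), colnames(new_counts))
  overlap <- length(common) / nrow(W)
  if (overlap < min_overlap)
    stop(sprintf("gene overlap %.0f%% below the %.0f%% floor",
                 100 * overlap, 100 * min_overlap))
  message(sprintf("projecting with %.0f%% gene overlap", 100 * overlap))
  Wc <- W[common, , drop = FALSE]
  X <- t(as.matrix(new_counts[, common, drop = FALSE]))
  K <- ncol(Wc); N <- ncol(X)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  H <- matrix(stats::rgamma(K * N, 2, 2), K, N)
  eps <- 1e-12
  prev <- Inf
  for (it in seq_len(max_iter)) {
    R <- Wc %*% H + eps
    H <- H * (t(Wc) %*% (X / R)) / (matrix(colSums(Wc), K, N) + eps)
    dev <- .poisson_deviance(X, Wc %*% H + eps)
    if (is.finite(prev) && abs(prev - dev) / (abs(prev) + eps) < tol) break
    prev <- dev
  }
  zero <- colSums(X) == 0
  H[, zero] <- 0
  rownames(H) <- colnames(W)
  colnames(H) <- rownames(new_counts)
  H
}
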