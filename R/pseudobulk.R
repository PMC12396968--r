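#' Aggregate single cells into pseudobulk samples
#'
#' Sums raw counts over cells sharing (donor, tissue group, unit), where
#' the unit is an immune lineage or a fine-grained subset. Each tissue in
#' each donor is treated as a separate sample; covariates are carried
#' over from the cell metadata (they are constant within a donor).
#'
#' @param matrix a [CellMatrix].
#' @param unit_key cell-metadata column defining the unit ("lineage" or
#'   "subset").
#' @return A `PseudobulkTable`: list with `counts` (genes x samples,
#'   exact integer sums) and `sample_meta` (`sample_id`, `donor_id`,
#'   `tissue_group`, `unit`, `n_cells`, covariates).
#' @export
pseudobulk_aggregate <- function(matrix, unit_key = "subset") {
  stopifnot(inherits(matrix, "CellMatrix"))
  cm <- matrix$cell_meta
  if (is.null(cm[[unit_key]])) stop("cell_meta lacks unit column '",
                                    unit_key, "'")
  key <- paste(cm$donor_id, cm$tissue_group, cm[[unit_key]], sep = "|")
  f <- factor(key)
  # indicator (cells x samples); t(gex) %*% ind gives genes x samples sums
  ind <- Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                              dims = c(length(f), nlevels(f)))
  counts <- as.matrix(Matrix::t(matrix$gex_counts) %*% ind)
  colnames(counts) <- levels(f)
  parts <- do.call(rbind, strsplit(levels(f), "|", fixed = TRUE))
  covars <- c("sex", "cmv", "age_group", "site", "chemistry")
  first <- match(levels(f), key)
  sample_meta <- data.frame(sample_id = levels(f),
                            donor_id = parts[, 1],
                            tissue_group = parts[, 2],
                            unit = parts[, 3],
                            n_cells = as.integer(tabulate(f)),
                            stringsAsFactors = FALSE)
  for (cv in covars)
    if (!is.null(cm[[cv]])) sample_meta[[cv]] <- as.character(cm[[cv]][first])
  structure(list(counts = counts, sample_meta = sample_meta,
                 unit_key = unit_key),
            class = "PseudobulkTable")
}

#' @export
print.PseudobulkTable <- function(x, ...) {
  cat(sprintf("PseudobulkTable: %d genes x %d samples (%d units)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$sample_meta$unit))))
  invisible(x)
}

#' Filter pseudobulk samples and genes with poor representation
#'
#' Default mode drops samples with fewer than 50 cells and keeps genes
#' with at least `gene_min_count` counts in at least `gene_min_fraction`
#' of the retained samples (inclusive boundary). Relaxed mode (used to
#' confirm counterfactual findings) lowers the floors to 10 cells and a
#' 10% sample fraction; the validation variant additionally accepts
#' `min_total_counts` per sample and a `gene_min_total` count floor.
#' Gene filtering is applied within each unit; an audit of exclusions is
#' attached as `attr(, "audit")`.
#'
#' @param table a `PseudobulkTable`.
#' @param min_cells per-sample cell floor ("fewer than" is dropped).
#' @param gene_min_count,gene_min_fraction gene representation rule.
#' @param min_samples_per_arm contrast feasibility floor (3 for tissue,
#'   4 for age analyses); recorded for [fit_differential_expression()].
#' @param relaxed use the relaxed floors (10 cells, 10%).
#' @param min_total_counts optional per-sample total-count floor.
#' @param gene_min_total optional per-gene total-count floor.
#' @return Filtered `PseudobulkTable`.
#' @export
filter_pseudobulk <- function(table, min_cells = 50, gene_min_count = 5,
                              gene_min_fraction = 0.40,
                              min_samples_per_arm = 3, relaxed = FALSE,
                              min_total_counts = NULL,
                              gene_min_total = NULL) {
  stopifnot(inherits(table, "PseudobulkTable"))
  if (relaxed) { min_cells <- 10; gene_min_fraction <- 0.10 }
  keep_s <- table$sample_meta$n_cells >= min_cells
  if (!is.null(min_total_counts))
    keep_s <- keep_s & colSums(table$counts) >= min_total_counts
  counts <- table$counts[, keep_s, drop = FALSE]
  meta <- table$sample_meta[keep_s, , drop = FALSE]
  keep_g <- rep(FALSE, nrow(counts))
  for (u in unique(meta$unit)) {
    cols <- meta$unit == u
    if (!any(cols)) next
    frac <- rowMeans(counts[, cols, drop = FALSE] >= gene_min_count)
    keep_g <- keep_g | frac >= gene_min_fraction
  }
  if (!is.null(gene_min_total))
    keep_g <- keep_g & rowSums(counts) >= gene_min_total
  out <- structure(list(counts = counts[keep_g, , drop = FALSE],
                        sample_meta = meta, unit_key = table$unit_key,
                        min_samples_per_arm = min_samples_per_arm),
                   class = "PseudobulkTable")
  attr(out, "audit") <- list(
    samples_dropped = sum(!keep_s), genes_dropped = sum(!keep_g),
    min_cells = min_cells, gene_min_count = gene_min_count,
    gene_min_fraction = gene_min_fraction)
  out
}

.log2cpm <- function(counts) {
  edgeR::cpm(counts, log = TRUE, prior.count = 0.5)
}

.fit_limma_block <- function(y, design, block) {
  cor <- NULL
  mixed <- FALSE
  if (!is.null(block) && length(unique(block)) > 1 &&
      any(duplicated(block))) {
    dc <- tryCatch(limma::duplicateCorrelation(y, design, block = block),
                   error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(dc) && is.finite(dc$consensus.correlation) &&
        abs(dc$consensus.correlation) < 0.99) {
      cor <- dc$consensus.correlation
      mixed <- TRUE
    }
  }
  fit <- if (mixed)
    limma::lmFit(y, design, block = block, correlation = cor)
  else limma::lmFit(y, design)
  attr(fit, "mixed_model") <- mixed
  fit
}

#' Covariate-adjusted pseudobulk differential expression
#'
#' Fits, per unit and per gene, a linear model on log2-CPM (0.5
#' pseudocount) of the pseudobulk counts with empirical-Bayes variance
#' moderation; the within-donor (tissue analysis) or within-batch (age /
#' CMV analysis) dependence is modeled as a shared intra-block
#' correlation (`limma::duplicateCorrelation`), the vectorized equivalent
#' of a random intercept. When the block correlation is unestimable the
#' model falls back to fixed intercepts and is flagged.
#'
#' Contrasts:
#' \describe{
#'   \item{tissue}{one tissue group versus the rest for the same unit,
#'     donor as the random block; positive log2FC = higher in the named
#'     tissue.}
#'   \item{age}{old minus young within one tissue group, controlling for
#'     sex and CMV as fixed effects, chemistry x site as the random
#'     block; positive log2FC = higher in old.}
#'   \item{cmv}{CMV+ minus CMV- within one tissue group, controlling for
#'     age and sex.}
#' }
#'
#' @param table a filtered `PseudobulkTable`.
#' @param contrast list: `type` ("tissue", "age" or "cmv") and `tissue`
#'   (the tissue group tested; for `type = "tissue"` the "one" arm).
#' @param min_samples_per_arm minimum samples per arm (default 3 for
#'   tissue, 4 for age/cmv); units below the floor are skipped and
#'   recorded in `attr(, "skipped")`.
#' @param ebayes apply empirical-Bayes variance shrinkage (default TRUE).
#' @return data.frame (`DEResult`): `gene`, `unit`, `contrast`,
#'   `tissue_group`, `logfc`, `aveexpr`, `t`, `p_value`, `adj_p_val`
#'   (BH within each unit x tissue family), `n_one`/`n_rest` sample
#'   counts, `donors_one`/`donors_rest`, `mixed_model`.
#' @export
fit_differential_expression <- function(table, contrast,
                                        min_samples_per_arm = NULL,
                                        ebayes = TRUE) {
  stopifnot(inherits(table, "PseudobulkTable"))
  type <- match.arg(contrast$type, c("tissue", "age", "cmv"))
  if (is.null(min_samples_per_arm))
    min_samples_per_arm <- if (type == "tissue") 3 else 4
  meta <- table$sample_meta
  results <- list(); skipped <- character()
  for (u in unique(meta$unit)) {
    sel <- meta$unit == u
    m <- meta[sel, , drop = FALSE]
    y <- .log2cpm(table$counts[, sel, drop = FALSE])
    if (type == "tissue") {
      grp <- factor(ifelse(m$tissue_group == contrast$tissue, "one", "rest"),
                    levels = c("rest", "one"))
      n_one <- sum(grp == "one"); n_rest <- sum(grp == "rest")
      if (n_one < min_samples_per_arm || n_rest < min_samples_per_arm) {
        skipped <- c(skipped, u); next
      }
      design <- stats::model.matrix(~grp)
      fit <- .fit_limma_block(y, design, m$donor_id)
      coefn <- "grpone"
      d_one <- unique(m$donor_id[grp == "one"])
      d_rest <- unique(m$donor_id[grp == "rest"])
    } else {
      var <- if (type == "age") "age_group" else "cmv"
      lv <- if (type == "age") c("young", "old") else c("neg", "pos")
      in_t <- m$tissue_group == contrast$tissue
      arm_hi <- in_t & m[[var]] == lv[2]
      arm_lo <- in_t & m[[var]] == lv[1]
      if (sum(arm_hi) < min_samples_per_arm ||
          sum(arm_lo) < min_samples_per_arm) {
        skipped <- c(skipped, u); next
      }
      ta <- factor(paste(m$tissue_group, m[[var]], sep = "."))
      fixed <- if (type == "age") c("sex", "cmv") else c("age_group", "sex")
      fml <- "~0 + ta"
      for (fx in fixed)
        if (length(unique(m[[fx]])) > 1) fml <- paste(fml, "+", fx)
      design <- stats::model.matrix(stats::as.formula(fml),
                                    data = cbind(m, ta = ta))
      colnames(design) <- make.names(colnames(design))
      block <- interaction(m$chemistry, m$site, drop = TRUE)
      fit <- .fit_limma_block(y, design, block)
      cvec <- rep(0, ncol(design))
      hi <- make.names(paste0("ta", contrast$tissue, ".", lv[2]))
      lo <- make.names(paste0("ta", contrast$tissue, ".", lv[1]))
      if (!hi %in% colnames(design) || !lo %in% colnames(design)) {
        skipped <- c(skipped, u); next
      }
      cvec[match(c(hi, lo), colnames(design))] <- c(1, -1)
      fit <- limma::contrasts.fit(fit, cvec)
      coefn <- 1
      n_one <- sum(arm_hi); n_rest <- sum(arm_lo)
      d_one <- unique(m$donor_id[arm_hi]); d_rest <- unique(m$donor_id[arm_lo])
    }
    mixed <- attr(fit, "mixed_model")
    if (isTRUE(ebayes)) {
      eb <- limma::eBayes(fit, trend = TRUE, robust = FALSE)
      tt <- limma::topTable(eb, coef = coefn, number = Inf, sort.by = "none")
    } else {
      fit <- limma::eBayes(fit)  # ordinary t: recompute without shrinkage
      se <- fit$stdev.unscaled[, coefn] * fit$sigma
      tstat <- fit$coefficients[, coefn] / se
      p <- 2 * stats::pt(-abs(tstat), df = fit$df.residual)
      tt <- data.frame(logFC = fit$coefficients[, coefn],
                       AveExpr = fit$Amean, t = tstat, P.Value = p,
                       adj.P.Val = stats::p.adjust(p, "BH"))
    }
    results[[u]] <- data.frame(
      gene = rownames(y), unit = u,
      contrast = paste0(type, ":", contrast$tissue),
      tissue_group = contrast$tissue,
      logfc = tt$logFC, aveexpr = tt$AveExpr, t = tt$t,
      p_value = tt$P.Value,
      adj_p_val = stats::p.adjust(tt$P.Value, "BH"),
      n_one = n_one, n_rest = n_rest,
      donors_one = length(d_one), donors_rest = length(d_rest),
      mixed_model = isTRUE(mixed),
      stringsAsFactors = FALSE)
  }
  out <- if (length(results)) do.call(rbind, results) else
    data.frame(gene = character(), unit = character(),
               contrast = character(), tissue_group = character(),
               logfc = numeric(), aveexpr = numeric(), t = numeric(),
               p_value = numeric(), adj_p_val = numeric(),
               n_one = integer(), n_rest = integer(),
               donors_one = integer(), donors_rest = integer(),
               mixed_model = logical())
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Per-gene variance decomposition over experimental covariates
#'
#' Fits, per gene, a random-effects model on log2-CPM with every
#' covariate as a random intercept (the classic variance-component
#' partition) and reports the fraction of variance attributable to each
#' covariate plus the residual. Fractions are non-negative and sum to 1.
#'
#' @param table a filtered `PseudobulkTable` (typically one unit).
#' @param covariates character vector of sample-metadata columns.
#' @return data.frame: `gene`, one fraction column per usable covariate,
#'   `residual`. Covariates with a single observed level are excluded
#'   with a warning.
#' @export
decompose_variance <- function(table,
                               covariates = c("age_group", "cmv", "sex",
                                              "site", "chemistry",
                                              "tissue_group")) {
  stopifnot(inherits(table, "PseudobulkTable"))
  meta <- table$sample_meta
  usable <- character()
  for (cv in covariates) {
    if (is.null(meta[[cv]])) { warning("covariate absent: ", cv); next }
    if (length(unique(meta[[cv]])) < 2) {
      warning("covariate '", cv, "' has a single level; excluded"); next
    }
    usable <- c(usable, cv)
  }
  if (!length(usable)) stop("no usable covariates")
  y <- .log2cpm(table$counts)
  fml <- stats::as.formula(paste("expr ~",
                                 paste(sprintf("(1|%s)", usable),
                                       collapse = " + ")))
  out <- matrix(NA_real_, nrow(y), length(usable) + 1,
                dimnames = list(rownames(y), c(usable, "residual")))
  df <- meta[usable]
  for (g in seq_len(nrow(y))) {
    df$expr <- y[g, ]
    fit <- tryCatch(suppressMessages(suppressWarnings(
      lme4::lmer(fml, data = df,
                 control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                             check.nobs.vs.nRE = "ignore")))),
      error = function(e) NULL)
    if (is.null(fit)) next
    vc <- as.data.frame(lme4::VarCorr(fit))
    v <- vc$vcov
    names(v) <- vc$grp
    v["Residual"] <- v[vc$grp == "Residual"]
    tot <- sum(v)
    out[g, usable] <- v[usable] / tot
    out[g, "residual"] <- v["Residual"] / tot
  }
  data.frame(gene = rownames(y), out, row.names = NULL,
             check.names = FALSE)
}
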