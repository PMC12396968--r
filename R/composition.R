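#' Tabulate immune-subset frequencies within lineages
#'
#' Counts cells per donor x tissue x subset and expresses each subset as
#' a proportion of its lineage within that donor x tissue. Donors
#' contributing fewer than `min_cells` lineage cells in a tissue are
#' excluded, and tissue x lineage combinations with fewer than
#' `min_donors` remaining donors are excluded; all exclusions are
#' recorded in `attr(, "audit")`.
#'
#' @param cell_meta per-cell metadata with `donor_id`, `tissue_group`,
#'   `subset` and the lineage column.
#' @param lineage_key lineage column name.
#' @param min_cells,min_donors eligibility floors.
#' @return data.frame: `donor_id`, `tissue_group`, `lineage`, `subset`,
#'   `n`, `lineage_total`, `proportion`, plus donor covariates when
#'   present.
#' @export
tabulate_subset_frequencies <- function(cell_meta, lineage_key = "lineage",
                                        min_cells = 50, min_donors = 4) {
  cm <- cell_meta
  cm$lineage <- as.character(cm[[lineage_key]])
  key <- paste(cm$donor_id, cm$tissue_group, cm$lineage, sep = "|")
  tot <- table(key)
  sub_key <- paste(key, cm$subset, sep = "|")
  cnt <- table(sub_key)
  parts <- do.call(rbind, strsplit(names(cnt), "|", fixed = TRUE))
  out <- data.frame(donor_id = parts[, 1], tissue_group = parts[, 2],
                    lineage = parts[, 3], subset = parts[, 4],
                    n = as.integer(cnt), stringsAsFactors = FALSE)
  out$lineage_total <- as.integer(tot[paste(out$donor_id, out$tissue_group,
                                            out$lineage, sep = "|")])
  out$proportion <- out$n / out$lineage_total
  drop_small <- out$lineage_total < min_cells
  audit <- list(donor_units_dropped =
                  unique(paste(out$donor_id, out$tissue_group,
                               out$lineage)[drop_small]))
  out <- out[!drop_small, , drop = FALSE]
  tl <- paste(out$tissue_group, out$lineage)
  nd <- tapply(out$donor_id, tl, function(d) length(unique(d)))
  bad_tl <- names(nd)[nd < min_donors]
  audit$tissue_lineages_dropped <- bad_tl
  out <- out[!tl %in% bad_tl, , drop = FALSE]
  covars <- intersect(c("age_group", "sex", "cmv", "site", "chemistry"),
                      names(cell_meta))
  if (length(covars)) {
    first <- match(out$donor_id, cell_meta$donor_id)
    for (cv in covars) out[[cv]] <- as.character(cell_meta[[cv]][first])
  }
  rownames(out) <- NULL
  attr(out, "audit") <- audit
  out
}

#' Covariate-adjusted GLM test for frequency / positivity shifts
#'
#' For each subset x tissue unit, fits a binomial GLM with logit link on
#' (subset count, lineage total) — or a quasi-binomial model on percent
#' responses — with the covariate of interest plus adjustment covariates
#' as fixed effects. Reports the covariate coefficient with a two-sided
#' Wald p, BH adjustment across units, and a covariate-aware log2FC: the
#' log2 ratio of predicted proportions at reference covariate values
#' with the covariate of interest set to its high versus low level
#' (old / young by default; positive = higher in the older group).
#'
#' @param freq_table output of [tabulate_subset_frequencies()] or a
#'   compatible table; for percent responses supply `percent` in [0,100]
#'   and `response = "percent"`.
#' @param covariate column tested (two levels; default `age_group`).
#' @param covariate_levels low/high level order (log2FC = high vs low).
#' @param adjust adjustment covariate columns (dropped when absent or
#'   single-level within a unit).
#' @param response "proportion" (binomial on counts) or "percent"
#'   (quasi-binomial on percent/100).
#' @return data.frame (`CompositionResult`): `subset`, `tissue_group`,
#'   `coeff`, `std_error`, `z`, `p_value`, `adj_p_val`, `logfc`,
#'   `n_observations`, `donors`; separations/singular fits are flagged
#'   `skipped`.
#' @export
glm_frequency_shift <- function(freq_table, covariate = "age_group",
                                covariate_levels = NULL,
                                adjust = c("sex", "chemistry", "cmv",
                                           "site"),
                                response = c("proportion", "percent")) {
  response <- match.arg(response)
  ft <- freq_table
  if (is.null(covariate_levels))
    covariate_levels <- if (covariate == "age_group") c("young", "old")
    else sort(unique(as.character(ft[[covariate]])))
  adjust <- setdiff(adjust, covariate)
  units <- unique(ft[c("subset", "tissue_group")])
  rows <- list()
  for (i in seq_len(nrow(units))) {
    sub <- units$subset[i]; tg <- units$tissue_group[i]
    d <- ft[ft$subset == sub & ft$tissue_group == tg, , drop = FALSE]
    d$covf <- factor(d[[covariate]], levels = covariate_levels)
    if (length(unique(stats::na.omit(d$covf))) < 2 || nrow(d) < 3) next
    use_adj <- adjust[vapply(adjust, function(a)
      !is.null(d[[a]]) && length(unique(d[[a]])) > 1, logical(1))]
    fml <- stats::as.formula(paste(
      "resp ~ covf",
      if (length(use_adj)) paste("+", paste(use_adj, collapse = " + "))
      else ""))
    fit <- NULL
    if (response == "proportion") {
      d$resp <- cbind(d$n, d$lineage_total - d$n)
      fit <- tryCatch(suppressWarnings(
        stats::glm(fml, family = stats::binomial(), data = d)),
        error = function(e) NULL)
    } else {
      d$resp <- pmin(pmax(d$percent / 100, 0), 1)
      fit <- tryCatch(suppressWarnings(
        stats::glm(fml, family = stats::quasibinomial(), data = d,
                   weights = d$n_total)),
        error = function(e) NULL)
    }
    skipped <- is.null(fit) || !fit$converged ||
      any(is.na(stats::coef(fit)))
    if (skipped) {
      rows[[length(rows) + 1]] <- data.frame(
        subset = sub, tissue_group = tg, coeff = NA_real_,
        std_error = NA_real_, z = NA_real_, p_value = NA_real_,
        logfc = NA_real_, n_observations = nrow(d),
        donors = length(unique(d$donor_id)), skipped = TRUE,
        stringsAsFactors = FALSE)
      next
    }
    sm <- summary(fit)$coefficients
    crow <- grep("^covf", rownames(sm))[1]
    zval <- sm[crow, 3]
    pval <- 2 * stats::pnorm(-abs(zval))
    # covariate-aware log2FC at reference (first-level) adjust covariates
    nd <- d[1, , drop = FALSE]
    for (a in use_adj) nd[[a]] <- sort(unique(d[[a]]))[1]
    nd_hi <- nd; nd_hi$covf <- factor(covariate_levels[2],
                                      levels = covariate_levels)
    nd_lo <- nd; nd_lo$covf <- factor(covariate_levels[1],
                                      levels = covariate_levels)
    p_hi <- stats::predict(fit, newdata = nd_hi, type = "response")
    p_lo <- stats::predict(fit, newdata = nd_lo, type = "response")
    rows[[length(rows) + 1]] <- data.frame(
      subset = sub, tissue_group = tg, coeff = sm[crow, 1],
      std_error = sm[crow, 2], z = zval, p_value = pval,
      logfc = log2(as.numeric(p_hi) / as.numeric(p_lo)),
      n_observations = nrow(d),
      donors = length(unique(d$donor_id)), skipped = FALSE,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out$adj_p_val <- NA_real_
  ok <- !out$skipped
  out$adj_p_val[ok] <- stats::p.adjust(out$p_value[ok], "BH")
  rownames(out) <- NULL
  out
}

#' Reference-robust compositional analysis by majority voting
#'
#' Compositional tests depend on the choice of reference subset. This
#' wrapper runs a credible-effect backend once per choice of reference
#' and reports a subset as credibly changing only when it is flagged in
#' strictly more than half of the runs. The built-in default backend is
#' an additive-log-ratio linear model with BH correction at `fdr`; any
#' backend with the same signature can be plugged in.
#'
#' @param counts subsets x samples count matrix (samples = donor x
#'   tissue or similar).
#' @param grouping two-level factor over samples (the tested condition).
#' @param backend function(counts, grouping, reference, fdr) returning a
#'   character vector of credible subset names.
#' @param fdr backend false-discovery rate.
#' @return list: `credible` (character), `votes` (named vote fractions),
#'   `n_runs`.
#' @export
majority_vote_composition <- function(counts, grouping,
                                      backend = alr_backend, fdr = 0.05) {
  if (nrow(counts) < 3) stop("need at least 3 subsets")
  subsets <- rownames(counts)
  if (is.null(subsets)) stop("counts must have subset rownames")
  votes <- stats::setNames(numeric(length(subsets)), subsets)
  n_runs <- 0
  for (ref in subsets) {
    res <- tryCatch(backend(counts, grouping, reference = ref, fdr = fdr),
                    error = function(e) NULL)
    if (is.null(res)) next  # failed run: vote denominator adjusted
    n_runs <- n_runs + 1
    votes[intersect(res, subsets)] <- votes[intersect(res, subsets)] + 1
  }
  if (n_runs == 0) stop("every backend run failed")
  frac <- votes / n_runs
  list(credible = names(frac)[frac > 0.5], votes = frac, n_runs = n_runs)
}

#' Additive-log-ratio backend for [majority_vote_composition()]
#'
#' Models log((count_s + 0.5) / (count_ref + 0.5)) per non-reference
#' subset as a linear function of the grouping and flags subsets whose
#' BH-adjusted group p falls below `fdr`.
#'
#' @param counts subsets x samples counts.
#' @param grouping factor over samples.
#' @param reference reference subset name.
#' @param fdr BH threshold.
#' @return character vector of credible subsets.
#' @export
alr_backend <- function(counts, grouping, reference, fdr = 0.05) {
  subsets <- setdiff(rownames(counts), reference)
  ref <- counts[reference, ] + 0.5
  ps <- vapply(subsets, function(s) {
    y <- log((counts[s, ] + 0.5) / ref)
    fit <- stats::lm(y ~ grouping)
    stats::anova(fit)[1, "Pr(>F)"]
  }, numeric(1))
  adj <- stats::p.adjust(ps, "BH")
  subsets[adj < fdr]
}

#' Landmark-register ADT intensities across batches
#'
#' Two-landmark registration: per batch and marker, kernel-density peak
#' detection finds the negative and (when present) positive peaks, and a
#' strictly monotone piecewise-linear warp maps negative peak -> 0 and
#' positive peak -> 1 (single-peak batches are shifted so their peak
#' sits at 0). Ranks within a batch are preserved exactly.
#'
#' @param values numeric vector of normalized log intensities for one
#'   marker.
#' @param batch per-cell batch labels.
#' @param bw density bandwidth (passed to [stats::density()]).
#' @param min_peak_height peaks below this fraction of the max density
#'   are ignored.
#' @return A `RegisteredADT`: list with `registered` values, `warps`
#'   (per-batch control points), `peaks` (per-batch detected peaks),
#'   `flagged` (degenerate batches given an identity warp).
#' @export
landmark_register_adt <- function(values, batch, bw = "nrd0",
                                  min_peak_height = 0.05) {
  batch <- as.character(batch)
  stopifnot(length(batch) == length(values))
  registered <- values * NA_real_
  warps <- list(); peaks <- list(); flagged <- character()
  for (b in unique(batch)) {
    idx <- which(batch == b)
    v <- values[idx]
    if (length(unique(v)) < 3 || stats::sd(v) < 1e-9) {
      registered[idx] <- v
      warps[[b]] <- cbind(x = c(0, 1), y = c(0, 1))
      peaks[[b]] <- numeric(0)
      flagged <- c(flagged, b)
      next
    }
    d <- stats::density(v, bw = bw)
    ymax <- max(d$y)
    is_peak <- which(diff(sign(diff(d$y))) == -2) + 1
    is_peak <- is_peak[d$y[is_peak] >= min_peak_height * ymax]
    pk <- d$x[is_peak]
    if (!length(pk)) pk <- d$x[which.max(d$y)]
    if (length(pk) > 2) {
      # keep the two best-supported peaks, in position order
      pk <- sort(pk[order(d$y[is_peak], decreasing = TRUE)[1:2]])
    }
    if (length(pk) == 2) {
      src <- c(min(v) - 1e-9, pk[1], pk[2], max(v) + 1e-9)
      dst <- c(0 - (pk[1] - min(v) + 1e-9) / (pk[2] - pk[1]),
               0, 1,
               1 + (max(v) + 1e-9 - pk[2]) / (pk[2] - pk[1]))
      registered[idx] <- stats::approx(src, dst, xout = v)$y
      warps[[b]] <- cbind(x = src, y = dst)
    } else {
      registered[idx] <- v - pk[1]
      warps[[b]] <- cbind(x = c(pk[1], pk[1] + 1), y = c(0, 1))
    }
    peaks[[b]] <- pk
  }
  structure(list(registered = registered, warps = warps, peaks = peaks,
                 batch = batch, flagged = flagged),
            class = "RegisteredADT")
}

#' Percent positivity of a registered ADT marker
#'
#' Percent of cells above the positive threshold (default 0.5 on the
#' registered scale, the midpoint between the aligned negative and
#' positive peaks) per group.
#'
#' @param registered a `RegisteredADT` or numeric vector of registered
#'   values.
#' @param threshold positive cutoff on the registered scale.
#' @param groups per-cell group key (e.g. donor x tissue x subset).
#' @return data.frame: `group`, `percent_positive` in [0, 100],
#'   `n_cells`; empty groups are absent.
#' @export
percent_positive <- function(registered, threshold = 0.5, groups) {
  v <- if (inherits(registered, "RegisteredADT")) registered$registered
  else as.numeric(registered)
  stopifnot(length(groups) == length(v))
  g <- as.character(groups)
  out <- lapply(unique(g), function(gr) {
    idx <- g == gr
    data.frame(group = gr,
               percent_positive = 100 * mean(v[idx] > threshold),
               n_cells = sum(idx), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
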