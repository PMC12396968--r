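#' Default configuration for the synthetic atlas generator
#'
#' Returns the generator settings emulating a multi-donor, multi-tissue
#' CITE-seq immune atlas: 24 donors (14 male / 10 female, roughly half
#' "old" i.e. >40 years), six tissue groups, four immune lineages with
#' three subsets each, gamma-Poisson gene counts driven by additive gene
#' programs (lineage identity, tissue residency, age response, nuisance),
#' bimodal batch-shifted ADT intensities, and doublet/erythrocyte
#' contamination. All downstream ground truth (program loadings and
#' activities, composition tables, contaminant labels, clone ids) is
#' recorded so recovery can be scored without re-reading the config.
#'
#' @param n_donors number of donors.
#' @param tissue_groups character vector of tissue groups.
#' @param lineages named list: lineage -> character vector of subsets.
#' @param n_genes total genes (program genes are carved out of these).
#' @param cells_per_donor_tissue clean cells drawn per donor x tissue.
#' @param depth_mean,depth_sd log-normal per-cell depth distribution.
#' @param theta negative-binomial dispersion (gamma shape); counts are
#'   gamma-Poisson with variance mu + mu^2/theta.
#' @param genes_per_program,program_strength program size and the loading
#'   mass concentrated on a program's own genes.
#' @param doublet_rate,erythro_rate contamination rates.
#' @param n_adts number of ADT markers.
#' @param adt_batch_shift_sd sd of the additive per-site shift applied to
#'   ADT log intensities (batch effect).
#' @param subset_base_weights optional named vector of baseline
#'   composition weights per subset (normalized within lineage);
#'   defaults to random gamma weights.
#' @param planted_tissue_programs named list: program label ->
#'   `list(tissue_group=, activity_ratio=)`; the program's activity is
#'   multiplied by `activity_ratio` in its home tissue.
#' @param planted_age_effects list of
#'   `list(genes=|program=, subset=NULL, tissue_group=NULL, log2FC=)`;
#'   gene entries multiply the Poisson rate of those genes by `2^log2FC`
#'   in old donors (within subset/tissue when given); program entries
#'   multiply that program's activity.
#' @param planted_tissue_composition list of
#'   `list(subset=, tissue_group=, fold=)` enrichments.
#' @param planted_age_composition list of `list(subset=, fold=)`
#'   old-vs-young frequency shifts.
#' @param clonality_target expected repertoire clonality for T cells.
#' @return A config list (class `atlas_config`).
#' @export
atlas_config <- function(n_donors = 24,
                         tissue_groups = c("BLO", "BM", "SPL", "LN", "LNG", "JEJ"),
                         lineages = list(
                           T4 = c("T4_naive", "T4_mem", "T4_trm"),
                           T8 = c("T8_naive", "T8_em", "T8_emra"),
                           B = c("B_naive", "B_mem", "Plasma"),
                           Myeloid = c("Mono", "Mac", "DC")),
                         n_genes = 600,
                         cells_per_donor_tissue = 50,
                         depth_mean = 5000, depth_sd = 0.25,
                         theta = 10,
                         genes_per_program = 20,
                         program_strength = 8,
                         doublet_rate = 0.03,
                         erythro_rate = 0.02,
                         n_adts = 8,
                         adt_batch_shift_sd = 0.4,
                         subset_base_weights = NULL,
                         planted_tissue_programs = list(),
                         planted_age_effects = list(),
                         planted_tissue_composition = list(),
                         planted_age_composition = list(),
                         clonality_target = 0.3) {
  cfg <- as.list(environment())
  class(cfg) <- "atlas_config"
  cfg
}

.validate_atlas_config <- function(cfg) {
  subsets <- unlist(cfg$lineages, use.names = FALSE)
  for (eff in cfg$planted_age_effects) {
    if (!is.null(eff$subset) && !all(eff$subset %in% subsets))
      stop("planted age effect names unknown subset: ",
           paste(setdiff(eff$subset, subsets), collapse = ", "))
    if (!is.null(eff$tissue_group) &&
        !all(eff$tissue_group %in% cfg$tissue_groups))
      stop("planted age effect names unknown tissue_group")
  }
  for (eff in c(cfg$planted_tissue_composition, cfg$planted_age_composition))
    if (!all(eff$subset %in% subsets))
      stop("planted composition shift names unknown subset: ", eff$subset)
  for (nm in names(cfg$planted_tissue_programs)) {
    tp <- cfg$planted_tissue_programs[[nm]]
    if (!tp$tissue_group %in% cfg$tissue_groups)
      stop("planted tissue program '", nm, "' names unknown tissue_group")
  }
  invisible(cfg)
}

# Nuisance gene lists are carved from the gene universe with recognizable
# symbol prefixes so list-membership flags can also be rebuilt from symbols.
.nuisance_families <- c(hsp = "HSPA", ribo = "RPL",
                        metallothionein = "MT1", hemoglobin = "HB",
                        stress = "FOSB", mito = "MT-ND")

#' Simulate a multi-donor multi-tissue CITE-seq atlas with planted truth
#'
#' Gene counts are gamma-Poisson: each cell's rate vector is its depth
#' times the (row-normalized) product of program activities and gene
#' loadings; planted tissue programs, age effects and composition shifts
#' perturb activities, rates or subset proportions as configured. ADT
#' counts come from a two-component log-normal mixture whose component
#' means are shifted per processing site. Doublets are sums of two random
#' clean cells; erythrocytes carry a hemoglobin-dominated program.
#'
#' @param config an [atlas_config()].
#' @param seed integer seed; identical (config, seed) gives identical output.
#' @return list with `matrix` (a [CellMatrix]) and `truth` (an
#'   `AtlasTruth` list: `program_loadings`, `program_activity`,
#'   `planted_tissue_programs`, `planted_age_effects`,
#'   `composition_table`, `contaminant_labels`, `clone_ids`, `embedding`).
#' @export
simulate_atlas <- function(config = atlas_config(), seed) {
  cfg <- .validate_atlas_config(config)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  subsets <- unlist(cfg$lineages, use.names = FALSE)
  lineage_of <- rep(names(cfg$lineages), lengths(cfg$lineages))
  names(lineage_of) <- subsets
  n_sub <- length(subsets)

  ## ---- gene universe and programs ------------------------------------
  prog_names <- c("housekeeping", paste0("id_", subsets),
                  names(cfg$planted_tissue_programs),
                  paste0("nuis_", names(.nuisance_families)))
  age_prog <- vapply(cfg$planted_age_effects,
                     function(e) !is.null(e$program), logical(1))
  prog_names <- unique(c(prog_names,
    vapply(cfg$planted_age_effects[age_prog], `[[`, "", "program")))
  n_prog <- length(prog_names)
  gpp <- cfg$genes_per_program
  need <- n_prog * gpp
  if (need > cfg$n_genes)
    stop("n_genes too small for the configured programs (need ", need, ")")
  symbols <- sprintf("G%04d", seq_len(cfg$n_genes))
  # nuisance families get recognizable prefixes
  gene_meta <- data.frame(symbol = symbols, stringsAsFactors = FALSE)
  prog_genes <- split(seq_len(need),
                      rep(seq_len(n_prog), each = gpp))
  names(prog_genes) <- prog_names
  for (fam in names(.nuisance_families)) {
    idx <- prog_genes[[paste0("nuis_", fam)]]
    gene_meta$symbol[idx] <- sprintf("%s%d", .nuisance_families[[fam]],
                                     seq_along(idx))
    gene_meta[[paste0("is_", fam)]] <- FALSE
    gene_meta[[paste0("is_", fam)]][idx] <- TRUE
  }
  symbols <- gene_meta$symbol

  L <- matrix(stats::rgamma(cfg$n_genes * n_prog, shape = 0.3, rate = 3),
              nrow = cfg$n_genes, ncol = n_prog,
              dimnames = list(symbols, prog_names))
  for (p in seq_len(n_prog))
    L[prog_genes[[p]], p] <- L[prog_genes[[p]], p] + cfg$program_strength
  L[, "housekeeping"] <- L[, "housekeeping"] + 1  # broad baseline

  ## ---- donors ---------------------------------------------------------
  donors <- sprintf("D%02d", seq_len(cfg$n_donors))
  n_male <- round(cfg$n_donors * 14 / 24)
  donor_meta <- data.frame(
    donor_id = donors,
    sex = sample(rep(c("M", "F"), c(n_male, cfg$n_donors - n_male))),
    age_group = sample(rep(c("young", "old"),
                           length.out = cfg$n_donors)),
    cmv = sample(c("neg", "pos"), cfg$n_donors, replace = TRUE),
    site = rep_len(c("siteA", "siteB"), cfg$n_donors),
    chemistry = sample(c("3prime", "5prime"), cfg$n_donors, replace = TRUE),
    stringsAsFactors = FALSE)

  ## ---- composition table ---------------------------------------------
  if (!is.null(cfg$subset_base_weights)) {
    if (!all(subsets %in% names(cfg$subset_base_weights)))
      stop("subset_base_weights must name every subset")
    base_prop <- cfg$subset_base_weights[subsets]
  } else {
    base_prop <- stats::rgamma(n_sub, shape = 4, rate = 1)
    names(base_prop) <- subsets
  }
  comp <- list()
  for (d in donors) for (tg in cfg$tissue_groups) {
    p <- base_prop * exp(stats::rnorm(n_sub, sd = 0.15))
    for (sh in cfg$planted_tissue_composition)
      if (tg %in% sh$tissue_group) p[sh$subset] <- p[sh$subset] * sh$fold
    if (donor_meta$age_group[donor_meta$donor_id == d] == "old")
      for (sh in cfg$planted_age_composition)
        p[sh$subset] <- p[sh$subset] * sh$fold
    comp[[paste(d, tg)]] <- data.frame(
      donor_id = d, tissue_group = tg, subset = subsets,
      proportion = as.numeric(p / sum(p)), stringsAsFactors = FALSE)
  }
  composition_table <- do.call(rbind, comp)
  rownames(composition_table) <- NULL

  ## ---- clean cells ----------------------------------------------------
  meta_list <- vector("list", cfg$n_donors * length(cfg$tissue_groups))
  k <- 0
  for (d in donors) for (tg in cfg$tissue_groups) {
    k <- k + 1
    pr <- composition_table$proportion[composition_table$donor_id == d &
                                         composition_table$tissue_group == tg]
    cnt <- as.vector(stats::rmultinom(1, cfg$cells_per_donor_tissue, pr))
    meta_list[[k]] <- data.frame(
      donor_id = d, tissue_group = tg,
      subset = rep(subsets, cnt), stringsAsFactors = FALSE)
  }
  cell_meta <- do.call(rbind, meta_list)
  cell_meta$lineage <- unname(lineage_of[cell_meta$subset])
  di <- match(cell_meta$donor_id, donor_meta$donor_id)
  for (col in c("sex", "age_group", "cmv", "site", "chemistry"))
    cell_meta[[col]] <- donor_meta[[col]][di]
  n_clean <- nrow(cell_meta)

  ## ---- program activities ---------------------------------------------
  A <- matrix(stats::rgamma(n_clean * n_prog, shape = 1, rate = 5),
              nrow = n_clean, ncol = n_prog,
              dimnames = list(NULL, prog_names))
  A[, "housekeeping"] <- A[, "housekeeping"] + 2
  id_col <- match(paste0("id_", cell_meta$subset), prog_names)
  A[cbind(seq_len(n_clean), id_col)] <-
    A[cbind(seq_len(n_clean), id_col)] + 3
  for (nm in names(cfg$planted_tissue_programs)) {
    tp <- cfg$planted_tissue_programs[[nm]]
    base <- stats::rgamma(n_clean, shape = 2, rate = 4)
    home <- cell_meta$tissue_group == tp$tissue_group
    A[, nm] <- base * ifelse(home, tp$activity_ratio, 1)
  }
  # nuisance programs: low-level broad activity
  for (fam in names(.nuisance_families))
    A[, paste0("nuis_", fam)] <- stats::rgamma(n_clean, shape = 1.5, rate = 6) *
      if (fam == "hemoglobin") 0.1 else 0.5
  is_old <- cell_meta$age_group == "old"
  for (eff in cfg$planted_age_effects) {
    if (is.null(eff$program)) next
    sel <- is_old
    if (!is.null(eff$subset)) sel <- sel & cell_meta$subset %in% eff$subset
    if (!is.null(eff$tissue_group))
      sel <- sel & cell_meta$tissue_group %in% eff$tissue_group
    A[, eff$program] <- stats::rgamma(n_clean, shape = 2, rate = 4)
    A[sel, eff$program] <- A[sel, eff$program] * 2^eff$log2FC
  }

  ## ---- rates and counts ------------------------------------------------
  depth <- stats::rlnorm(n_clean, log(cfg$depth_mean), cfg$depth_sd)
  mu <- A %*% t(L)
  mu <- mu / rowSums(mu) * depth
  for (eff in cfg$planted_age_effects) {
    if (is.null(eff$genes)) next
    sel <- is_old
    if (!is.null(eff$subset)) sel <- sel & cell_meta$subset %in% eff$subset
    if (!is.null(eff$tissue_group))
      sel <- sel & cell_meta$tissue_group %in% eff$tissue_group
    gi <- match(eff$genes, symbols)
    if (anyNA(gi)) stop("planted age effect names unknown genes")
    mu[sel, gi] <- mu[sel, gi] * 2^eff$log2FC
  }
  disp <- matrix(stats::rgamma(length(mu), shape = cfg$theta,
                               rate = cfg$theta), nrow = nrow(mu))
  counts <- matrix(stats::rpois(length(mu), mu * disp), nrow = nrow(mu),
                   dimnames = list(NULL, symbols))

  contaminant <- rep("clean", n_clean)

  ## ---- erythrocytes ----------------------------------------------------
  n_ery <- round(cfg$erythro_rate * n_clean)
  if (n_ery > 0) {
    hb <- which(gene_meta$is_hemoglobin)
    ery_mu <- matrix(0.02, n_ery, cfg$n_genes)
    ery_mu[, hb] <- 1
    ery_mu <- ery_mu / rowSums(ery_mu) *
      stats::rlnorm(n_ery, log(cfg$depth_mean / 2), cfg$depth_sd)
    ery_counts <- matrix(stats::rpois(length(ery_mu), ery_mu), nrow = n_ery,
                         dimnames = list(NULL, symbols))
    pick <- sample(n_clean, n_ery, replace = TRUE)
    ery_meta <- cell_meta[pick, , drop = FALSE]
    ery_meta$subset <- "Erythro"
    ery_meta$lineage <- "Erythro"
    counts <- rbind(counts, ery_counts)
    cell_meta <- rbind(cell_meta, ery_meta)
    A <- rbind(A, matrix(0, n_ery, n_prog))
    contaminant <- c(contaminant, rep("erythrocyte", n_ery))
  }

  ## ---- doublets --------------------------------------------------------
  n_dbl <- round(cfg$doublet_rate * n_clean)
  if (n_dbl > 0) {
    i1 <- sample(n_clean, n_dbl, replace = TRUE)
    i2 <- sample(n_clean, n_dbl, replace = TRUE)
    dbl_counts <- counts[i1, , drop = FALSE] + counts[i2, , drop = FALSE]
    dbl_meta <- cell_meta[i1, , drop = FALSE]
    counts <- rbind(counts, dbl_counts)
    cell_meta <- rbind(cell_meta, dbl_meta)
    A <- rbind(A, (A[i1, , drop = FALSE] + A[i2, , drop = FALSE]))
    contaminant <- c(contaminant, rep("doublet", n_dbl))
  }
  n_cells <- nrow(cell_meta)
  rownames(cell_meta) <- NULL
  cell_meta$cell_id <- sprintf("cell%05d", seq_len(n_cells))
  rownames(counts) <- cell_meta$cell_id

  ## ---- qc flags --------------------------------------------------------
  clean <- contaminant == "clean"
  qc_flags <- data.frame(
    scrublet_prob = ifelse(contaminant == "doublet",
                           stats::rbeta(n_cells, 12, 3),
                           stats::rbeta(n_cells, 1, 20)),
    hashsolo_prob = ifelse(contaminant == "doublet",
                           stats::rbeta(n_cells, 8, 4),
                           stats::rbeta(n_cells, 1, 30)),
    erythro_fraction = rowSums(counts[, gene_meta$is_hemoglobin,
                                      drop = FALSE]) / rowSums(counts),
    dual_receptor = as.integer(stats::runif(n_cells) <
                                 ifelse(contaminant == "doublet", 0.5, 0.01)),
    erythro_pred = as.integer(contaminant == "erythrocyte" &
                                stats::runif(n_cells) < 0.95),
    mito_fraction = stats::rbeta(n_cells, 2, 38))

  ## ---- ADT counts ------------------------------------------------------
  adt <- NULL
  if (cfg$n_adts > 0) {
    adt_names <- sprintf("ADT%02d", seq_len(cfg$n_adts))
    # each marker positive in a subset of subsets
    pos_map <- matrix(stats::runif(cfg$n_adts * n_sub) < 0.4,
                      nrow = cfg$n_adts,
                      dimnames = list(adt_names, subsets))
    site_shift <- stats::rnorm(2, 0, cfg$adt_batch_shift_sd)
    names(site_shift) <- c("siteA", "siteB")
    sub_idx <- match(cell_meta$subset, subsets)
    adt <- matrix(0L, n_cells, cfg$n_adts,
                  dimnames = list(cell_meta$cell_id, adt_names))
    for (a in seq_len(cfg$n_adts)) {
      pos <- !is.na(sub_idx) & pos_map[a, sub_idx]
      mu_log <- ifelse(pos, 4.5, 2.0) + site_shift[cell_meta$site]
      adt[, a] <- stats::rpois(n_cells, exp(mu_log +
                                              stats::rnorm(n_cells, 0, 0.35)))
    }
  }

  ## ---- clonotypes (T cells, per donor) ---------------------------------
  clone_ids <- rep(NA_character_, n_cells)
  t_cells <- which(cell_meta$lineage %in% c("T4", "T8") & clean)
  for (d in donors) {
    idx <- t_cells[cell_meta$donor_id[t_cells] == d]
    if (length(idx) < 5) next
    ids <- simulate_repertoire(length(idx), cfg$clonality_target,
                               n_clones = max(10, length(idx)),
                               seed = seed + match(d, donors))
    clone_ids[idx] <- paste0(d, "_", ids)
  }

  ## ---- embedding (true-activity latent space + noise) ------------------
  emb_base <- log1p(A[, setdiff(prog_names, "housekeeping"), drop = FALSE])
  ery <- contaminant == "erythrocyte"
  emb_base <- cbind(emb_base, ery_axis = 5 * ery,
                    dbl_axis = 5 * (contaminant == "doublet"))
  embedding <- emb_base + matrix(stats::rnorm(length(emb_base), 0, 0.1),
                                 nrow = n_cells)

  truth <- list(program_loadings = L, program_activity = A,
                planted_tissue_programs = cfg$planted_tissue_programs,
                planted_age_effects = cfg$planted_age_effects,
                composition_table = composition_table,
                contaminant_labels = contaminant,
                clone_ids = clone_ids,
                embedding = embedding,
                program_genes = lapply(prog_genes, function(i) symbols[i]))
  class(truth) <- "AtlasTruth"

  cm <- CellMatrix(counts, cell_meta, gene_meta, adt_counts = adt,
                   qc_flags = qc_flags)
  list(matrix = cm, truth = truth)
}

#' Simulate a per-cell x gene effect matrix with a planted module
#'
#' Emulates the output of a counterfactual model: a dense matrix of
#' predicted per-cell log2 fold changes for one covariate, with a planted
#' block of module-positive cells carrying coherent up/down gene effects,
#' plus a low-dimensional embedding in which the module occupies a
#' contiguous region (so kNN smoothing is meaningful).
#'
#' @param config list with `n_cells`, `n_genes`, `module_fraction`,
#'   `n_up`, `n_down`, `effect_up`, `effect_down`, `noise_sd`,
#'   `embedding_noise`. Missing entries take the defaults shown in
#'   [effect_config()].
#' @param seed integer seed.
#' @return list with `effects` (an `EffectMatrix`: `effects`, `embedding`,
#'   `raw_mean_expr`, `n_samples`) and `truth` (`module_mask`, `up_genes`,
#'   `down_genes`).
#' @export
simulate_effect_matrix <- function(config = effect_config(), seed) {
  cfg <- utils::modifyList(effect_config(), as.list(config))
  if (cfg$module_fraction <= 0 || cfg$module_fraction >= 1)
    stop("module_fraction must be in (0, 1)")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  n <- cfg$n_cells; m <- cfg$n_genes
  genes <- sprintf("G%04d", seq_len(m))
  n_pos <- floor(cfg$module_fraction * n)
  mask <- rep(FALSE, n); mask[sample(n, n_pos)] <- TRUE
  up <- genes[seq_len(cfg$n_up)]
  down <- genes[cfg$n_up + seq_len(cfg$n_down)]
  E <- matrix(stats::rnorm(n * m, 0, cfg$noise_sd), n, m,
              dimnames = list(sprintf("cell%05d", seq_len(n)), genes))
  E[mask, match(up, genes)] <- E[mask, match(up, genes)] + cfg$effect_up
  E[mask, match(down, genes)] <- E[mask, match(down, genes)] + cfg$effect_down
  center <- ifelse(mask, 3, 0)
  embedding <- cbind(center + stats::rnorm(n, 0, cfg$embedding_noise),
                     center + stats::rnorm(n, 0, cfg$embedding_noise))
  raw_mean_expr <- stats::rgamma(m, shape = 2, rate = 10)
  names(raw_mean_expr) <- genes
  eff <- structure(list(effects = E, embedding = embedding,
                        raw_mean_expr = raw_mean_expr,
                        n_samples = rep(10L, n)),
                   class = "EffectMatrix")
  list(effects = eff,
       truth = list(module_mask = mask, up_genes = up, down_genes = down))
}

#' @rdname simulate_effect_matrix
#' @export
effect_config <- function() {
  list(n_cells = 1000, n_genes = 200, module_fraction = 0.2,
       n_up = 30, n_down = 20, effect_up = 0.5, effect_down = -0.5,
       noise_sd = 0.1, embedding_noise = 0.3)
}

#' Simulate a clonotype repertoire with a target clonality
#'
#' Clone frequencies follow a power law `p_r ~ r^(-alpha)` over clone
#' ranks; `alpha` is calibrated by bisection so that the expected
#' clonality score (1 - Pielou evenness, measured on 100-cell subsamples
#' by [clonality_score()]) matches `clonality_target`.
#'
#' @param n_cells number of cells to assign.
#' @param clonality_target real in `[0, 1)`; achievable targets depend on
#'   `n_clones` (an error reports the feasible range otherwise).
#' @param n_clones number of distinct clones in the pool.
#' @param seed integer seed.
#' @return character vector of clone ids, length `n_cells`.
#' @export
simulate_repertoire <- function(n_cells, clonality_target, n_clones, seed) {
  stopifnot(n_clones >= 1, clonality_target >= 0, clonality_target < 1)
  if (n_clones == 1) return(rep("clone1", n_cells))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  expected_clonality <- function(alpha, n_draws = 20) {
    p <- seq_len(n_clones)^(-alpha); p <- p / sum(p)
    n_sub <- min(100, n_cells)
    vals <- vapply(seq_len(n_draws), function(i) {
      cl <- sample.int(n_clones, n_sub, replace = TRUE, prob = p)
      .clonality_of(table(cl))
    }, numeric(1))
    mean(vals)
  }
  lo <- 0; hi <- 12
  c_lo <- expected_clonality(lo); c_hi <- expected_clonality(hi)
  if (clonality_target < c_lo - 0.05 || clonality_target > c_hi) {
    stop(sprintf(
      "clonality_target %.2f unreachable with %d clones (feasible ~[%.3f, %.3f])",
      clonality_target, n_clones, c_lo, c_hi))
  }
  if (clonality_target > c_lo) {
    for (i in 1:18) {
      mid <- (lo + hi) / 2
      if (expected_clonality(mid) < clonality_target) lo <- mid else hi <- mid
    }
    alpha <- (lo + hi) / 2
  } else alpha <- 0
  p <- seq_len(n_clones)^(-alpha); p <- p / sum(p)
  ids <- sample.int(n_clones, n_cells, replace = TRUE, prob = p)
  sprintf("clone%d", ids)
}
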