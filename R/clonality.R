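# clonality of a clone-size table: 1 - H/log2(C), with the C = 1
# convention (total dominance) returning 1.
.clonality_of <- function(sizes) {
  sizes <- as.numeric(sizes)
  sizes <- sizes[sizes > 0]
  C <- length(sizes)
  if (C <= 1) return(1)
  p <- sizes / sum(sizes)
  H <- -sum(p * log2(p))
  1 - H / log2(C)
}

#' Group receptor contigs into clonotypes
#'
#' Applies the sequential clonotype-grouping criteria to a simplified
#' contig table: cells are first partitioned by identical V gene, J gene
#' and CDR3 length on every chain they carry; within a partition, TCR
#' clones require 100% CDR3 nucleotide identity, while BCR clones link
#' any pair of cells with at least 85% CDR3 amino-acid identity
#' (1 - normalized Hamming distance) on every chain and take connected
#' components (single linkage).
#'
#' @param contigs data.frame with columns `cell_id`, `chain` (e.g.
#'   "VDJ"/"VJ"), `v_gene`, `j_gene`, `cdr3_nt`, `cdr3_aa`, `receptor`
#'   ("TCR" or "BCR").
#' @param bcr_identity minimum amino-acid identity for BCR linkage
#'   (inclusive).
#' @return data.frame `cell_id`, `clone_id`; cells with malformed CDR3
#'   records are dropped with a warning.
#' @export
group_clonotypes <- function(contigs, bcr_identity = 0.85) {
  need <- c("cell_id", "chain", "v_gene", "j_gene", "cdr3_nt", "cdr3_aa",
            "receptor")
  miss <- setdiff(need, names(contigs))
  if (length(miss)) stop("contigs missing columns: ",
                         paste(miss, collapse = ", "))
  bad <- nchar(contigs$cdr3_nt) != 3 * nchar(contigs$cdr3_aa)
  if (any(bad)) {
    warning(sum(bad), " contig(s) with CDR3 length mismatch rejected")
    contigs <- contigs[!bad, , drop = FALSE]
  }
  # one record per cell: concatenate chains in a fixed order
  ord <- order(contigs$cell_id, contigs$chain)
  contigs <- contigs[ord, , drop = FALSE]
  agg <- function(col) tapply(contigs[[col]], contigs$cell_id,
                              paste, collapse = "|")
  cells <- sort(unique(contigs$cell_id))
  key <- paste(agg("receptor"), agg("v_gene"), agg("j_gene"),
               nchar(gsub("\\|", "", agg("cdr3_aa"))),
               vapply(strsplit(agg("cdr3_aa"), "\\|"),
                      function(x) paste(nchar(x), collapse = "|"), ""),
               sep = "~")
  cdr3_nt <- agg("cdr3_nt"); cdr3_aa <- agg("cdr3_aa")
  receptor <- vapply(strsplit(agg("receptor"), "\\|"), `[`, "", 1)
  clone <- rep(NA_character_, length(cells))
  names(clone) <- cells
  next_id <- 1L
  for (k in unique(key)) {
    idx <- which(key == k)
    if (receptor[idx[1]] == "TCR") {
      grp <- match(cdr3_nt[idx], unique(cdr3_nt[idx]))
    } else {
      nb <- length(idx)
      aa <- strsplit(cdr3_aa[idx], "")
      adj <- diag(TRUE, nb)
      if (nb > 1) {
        for (i in seq_len(nb - 1)) for (j in (i + 1):nb) {
          a <- aa[[i]]; b <- aa[[j]]
          ident <- mean(a == b)
          adj[i, j] <- adj[j, i] <- ident >= bcr_identity
        }
      }
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      grp <- igraph::components(g)$membership
    }
    clone[idx] <- sprintf("clone%06d", next_id - 1L + grp)
    next_id <- next_id + max(grp)
  }
  data.frame(cell_id = cells, clone_id = unname(clone),
             stringsAsFactors = FALSE)
}

#' Repertoire clonality (1 - Pielou evenness) with subsampling
#'
#' For each group, repeatedly subsamples `subsample_n` cells without
#' replacement and computes `1 - H_s / log2(C)` where `H_s` is the
#' Shannon entropy (bits) of clone frequencies in the subsample and `C`
#' the number of unique clonotypes observed. Reports the mean over draws
#' (`n_draws = 1` reproduces the literal single-subsample procedure).
#' Groups smaller than `subsample_n` are skipped and logged; `C = 1`
#' yields clonality 1 by convention and is flagged.
#'
#' @param clone_ids per-cell clonotype ids (NA = no receptor).
#' @param groups per-cell group key (e.g. donor x subset x tissue);
#'   omit for a single group.
#' @param subsample_n subsample size (default 100 cells).
#' @param n_draws number of subsample draws averaged.
#' @param seed integer seed.
#' @return data.frame per group: `group`, `n_cells`, `C` (mean unique
#'   clonotypes per draw), `clonality`, `clonality_sd`, `n_subsampled`,
#'   `n_draws`, `degenerate` (C = 1 convention used), `skipped`.
#' @export
clonality_score <- function(clone_ids, groups = NULL, subsample_n = 100,
                            n_draws = 25, seed = 0) {
  if (is.null(groups)) groups <- rep("all", length(clone_ids))
  keep <- !is.na(clone_ids)
  clone_ids <- clone_ids[keep]; groups <- as.character(groups)[keep]
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  out <- lapply(unique(groups), function(g) {
    ids <- clone_ids[groups == g]
    n <- length(ids)
    if (n < subsample_n) {
      return(data.frame(group = g, n_cells = n, C = NA_real_,
                        clonality = NA_real_, clonality_sd = NA_real_,
                        n_subsampled = subsample_n, n_draws = 0L,
                        degenerate = FALSE, skipped = TRUE))
    }
    vals <- Cs <- numeric(n_draws)
    for (d in seq_len(n_draws)) {
      sub <- sample(ids, subsample_n)
      tab <- table(sub)
      Cs[d] <- length(tab)
      vals[d] <- .clonality_of(tab)
    }
    data.frame(group = g, n_cells = n, C = mean(Cs),
               clonality = mean(vals),
               clonality_sd = stats::sd(vals),
               n_subsampled = subsample_n, n_draws = n_draws,
               degenerate = any(Cs == 1), skipped = FALSE)
  })
  do.call(rbind, out)
}
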