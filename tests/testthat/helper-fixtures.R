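# Small fixture builders and independent brute-force oracles used across
# the suite. Oracles are written as plain loops, independent of the
# package implementation they check.

random_cell_matrix <- function(n_cells = 10, n_genes = 20, seed = 1,
                               with_adt = FALSE) {
  set.seed(seed)
  counts <- matrix(rpois(n_cells * n_genes, 3), n_cells, n_genes)
  cell_meta <- data.frame(
    cell_id = sprintf("c%03d", seq_len(n_cells)),
    donor_id = sample(c("D1", "D2"), n_cells, replace = TRUE),
    tissue_group = sample(c("BLO", "JEJ"), n_cells, replace = TRUE),
    subset = sample(c("a", "b"), n_cells, replace = TRUE),
    stringsAsFactors = FALSE)
  gene_meta <- data.frame(symbol = sprintf("G%03d", seq_len(n_genes)),
                          stringsAsFactors = FALSE)
  adt <- if (with_adt) matrix(rpois(n_cells * 3, 20), n_cells, 3,
                              dimnames = list(NULL, c("A1", "A2", "A3")))
  CellMatrix(counts, cell_meta, gene_meta, adt_counts = adt)
}

# step-by-step running-sum oracle (plain loop)
gsea_es_oracle <- function(ranking, set, weight = 1) {
  ord <- order(ranking, decreasing = TRUE)
  genes <- names(ranking)[ord]
  scores <- as.numeric(ranking)[ord]
  n <- length(genes)
  hit <- genes %in% set
  nr <- sum(abs(scores[hit])^weight)
  if (nr == 0) nr <- sum(hit)
  best <- 0; run <- 0
  for (i in seq_len(n)) {
    if (hit[i]) {
      w <- if (sum(abs(scores[hit])^weight) == 0) 1 else
        abs(scores[i])^weight
      run <- run + w / nr
    } else {
      run <- run - 1 / (n - sum(hit))
    }
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# direct evaluation of 1 - Pielou evenness from clone sizes
clonality_oracle <- function(sizes) {
  sizes <- sizes[sizes > 0]
  if (length(sizes) <= 1) return(1)
  p <- sizes / sum(sizes)
  H <- -sum(p * log2(p))
  1 - H / log2(length(sizes))
}

# exhaustive Youden-J enumeration over all midpoints and orientations
youden_oracle <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- (u[-1] + u[-length(u)]) / 2
  best <- -Inf; best_cut <- NA
  for (cut in cand) for (dir in c(">", "<")) {
    pred <- if (dir == ">") scores > cut else scores < cut
    J <- sum(pred & labels) / sum(labels) +
      sum(!pred & !labels) / sum(!labels) - 1
    if (J > best) { best <- J; best_cut <- cut }
  }
  list(J = best, cut = best_cut)
}

# set-arithmetic oracle for the DEG-overlap similarity
deg_sim_oracle <- function(up_a, down_a, up_b, down_b) {
  num <- sum(up_a %in% up_b) + sum(down_a %in% down_b)
  den <- length(unique(c(up_a, down_a, up_b, down_b)))
  if (den == 0) 0 else num / den
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}
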