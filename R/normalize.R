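#' Library-size normalize a count matrix
#'
#' Applies the standard single-cell transform `ln(scale * c / T + 1)` per
#' cell, where `c` is the count for one feature, `T` the cell's total and
#' `scale` the target depth (10,000 for gene expression, 1,000 for ADT
#' counts by convention). The log is natural; zero counts stay zero.
#'
#' @param counts cells x features matrix (sparse or dense), non-negative.
#' @param total_per_cell optional per-cell totals; defaults to row sums.
#' @param scale positive target depth. Use `1e4` for GEX, `1e3` for ADT.
#' @return A `NormalizedMatrix`: list with `values` (same shape/class as
#'   input), `scale` and `log_base = "e"`.
#' @export
normalize_counts <- function(counts, total_per_cell = NULL, scale = 1e4) {
  stopifnot(scale > 0)
  if (is.null(total_per_cell)) total_per_cell <- Matrix::rowSums(counts)
  if (length(total_per_cell) != nrow(counts))
    stop("total_per_cell must have one entry per cell")
  bad <- which(total_per_cell <= 0)
  if (length(bad)) {
    ids <- rownames(counts)[bad]
    if (is.null(ids)) ids <- as.character(bad)
    stop("cells with zero total counts (filter first): ",
         paste(utils::head(ids, 10), collapse = ", "))
  }
  if (inherits(counts, "sparseMatrix")) {
    v <- methods::as(methods::as(counts, "generalMatrix"), "CsparseMatrix")
    # cells x features: @i indexes the cell of each nonzero
    v@x <- log(scale * v@x / total_per_cell[v@i + 1L] + 1)
    values <- v
  } else {
    values <- log(scale * counts / total_per_cell + 1)
  }
  structure(list(values = values, scale = scale, log_base = "e"),
            class = "NormalizedMatrix")
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat(sprintf("NormalizedMatrix: %d x %d, ln(%g * c/T + 1)\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' Downsample counts to equalize sequencing depth across groups
#'
#' Equalizes the average number of transcripts per cell across groups
#' (donors, tissues) to avoid coverage bias before factorization or
#' marker testing. Each cell in group g is thinned at rate
#' `min_g(mean depth) / mean depth(g)`; binomial thinning keeps each
#' molecule independently, exact multinomial subsampling draws a fixed
#' per-cell total.
#'
#' @param counts cells x features non-negative integer matrix.
#' @param group_labels per-cell group vector.
#' @param seed integer seed (required; thinning is stochastic).
#' @param method "binomial" (default) or "multinomial".
#' @return Matrix of the same shape with elementwise `out <= in`.
#' @export
downsample_equal_depth <- function(counts, group_labels, seed,
                                   method = c("binomial", "multinomial")) {
  method <- match.arg(method)
  stopifnot(length(group_labels) == nrow(counts))
  group_labels <- as.character(group_labels)
  depths <- Matrix::rowSums(counts)
  mean_depth <- tapply(depths, group_labels, mean)
  if (any(mean_depth == 0)) {
    stop("groups with zero total counts: ",
         paste(names(mean_depth)[mean_depth == 0], collapse = ", "))
  }
  target <- min(mean_depth)
  rate <- target / mean_depth
  if (all(rate >= 1)) return(counts)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  m <- methods::as(methods::as(methods::as(
    Matrix::Matrix(counts, sparse = TRUE), "dMatrix"), "generalMatrix"),
    "CsparseMatrix")
  cell_idx <- m@i + 1L
  p_cell <- rate[group_labels[cell_idx]]
  if (method == "binomial") {
    m@x <- as.double(stats::rbinom(length(m@x), size = as.integer(m@x),
                                   prob = pmin(1, p_cell)))
  } else {
    # per cell draw a fixed total, allocate over that cell's features
    tm <- Matrix::t(m)  # features x cells, columns are cells
    for (j in seq_len(ncol(tm))) {
      r <- rate[group_labels[j]]
      if (r >= 1) next
      idx <- (tm@p[j] + 1L):(tm@p[j + 1L])
      if (tm@p[j + 1L] == tm@p[j]) next
      x <- tm@x[idx]
      n_keep <- round(sum(x) * r)
      tm@x[idx] <- as.double(stats::rmultinom(1, n_keep, prob = x))
    }
    m <- Matrix::t(tm)
  }
  m <- Matrix::drop0(m)
  dimnames(m) <- dimnames(counts)
  m
}
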