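#' Build trending up/down DEG sets per subset x tissue
#'
#' For each (subset, tissue) aging signature, collects the trending
#' up-regulated genes (unadjusted p < `p_max` and log2FC > `lfc`) and
#' down-regulated genes (log2FC < -`lfc`) among genes above the mean
#' log-normalized expression floor. Entities are excluded when their
#' total DEG count is not strictly greater than `min_degs` or when they
#' fail the per-arm donor floor; exclusions are recorded in
#' `attr(, "audit")`.
#'
#' @param de_results data.frame with `gene`, `unit`, `tissue_group`,
#'   `logfc`, `p_value`, and optionally `mean_expr`, `donors_one`,
#'   `donors_rest`.
#' @param p_max,lfc trending thresholds (strict comparisons; |logfc|
#'   exactly at `lfc` is in neither set).
#' @param min_degs strict DEG floor (an entity with exactly `min_degs`
#'   DEGs is excluded).
#' @param min_expr mean log-normalized expression floor.
#' @param min_donors minimum donors per age arm.
#' @return A `TrendingSets`: named list of `list(up=, down=)` keyed by
#'   "subset|tissue".
#' @export
build_trending_sets <- function(de_results, p_max = 0.05, lfc = 0.1,
                                min_degs = 70, min_expr = 0.05,
                                min_donors = 3) {
  d <- de_results
  if (!is.null(d$mean_expr)) d <- d[d$mean_expr > min_expr, , drop = FALSE]
  key <- paste(d$unit, d$tissue_group, sep = "|")
  sets <- list(); audit <- character()
  for (k in unique(key)) {
    e <- d[key == k, , drop = FALSE]
    if (!is.null(e$donors_one) &&
        (e$donors_one[1] < min_donors || e$donors_rest[1] < min_donors)) {
      audit <- c(audit, paste(k, "(donor floor)"))
      next
    }
    trending <- e$p_value < p_max
    up <- e$gene[trending & e$logfc > lfc]
    down <- e$gene[trending & e$logfc < -lfc]
    if (length(up) + length(down) <= min_degs) {
      audit <- c(audit, paste(k, "(DEG floor)"))
      next
    }
    sets[[k]] <- list(up = up, down = down)
  }
  attr(sets, "audit") <- audit
  class(sets) <- "TrendingSets"
  sets
}

#' DEG-overlap similarity between aging signatures
#'
#' The similarity between entities A and B is the number of shared
#' up-regulated genes plus the number of shared down-regulated genes,
#' divided by the union of all four trending sets:
#' `(|up_A n up_B| + |down_A n down_B|) / |up_A u down_A u up_B u down_B|`.
#' Distance is 1 - similarity. Entities with both sets empty are
#' excluded. Entities with more than `cluster_min_degs` DEGs are
#' additionally clustered (Ward.D2 on the distance matrix); a 2-D
#' embedding backend is pluggable (classical MDS by default, excluded
#' from any acceptance contract — the distance matrix is the artifact).
#'
#' @param sets a `TrendingSets` (or plain named list of
#'   `list(up=, down=)`).
#' @param cluster_min_degs DEG count above which entities enter the
#'   clustering (strict >).
#' @param embed_fun NULL, or function(dist) -> n x 2 coordinates.
#' @return list: `similarity`, `distance` (symmetric matrices, unit
#'   diagonal similarity), `clustering` (hclust or NULL), `embedding`.
#' @export
deg_overlap_similarity <- function(sets, cluster_min_degs = 200,
                                   embed_fun = NULL) {
  nonempty <- vapply(sets, function(s)
    length(s$up) + length(s$down) > 0, logical(1))
  sets <- sets[nonempty]
  n <- length(sets)
  if (n < 2) stop("need at least 2 eligible entities")
  nm <- names(sets)
  sim <- matrix(1, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- sets[[i]]; b <- sets[[j]]
    num <- length(intersect(a$up, b$up)) +
      length(intersect(a$down, b$down))
    den <- length(unique(c(a$up, a$down, b$up, b$down)))
    sim[i, j] <- sim[j, i] <- if (den > 0) num / den else 0
  }
  dist_m <- 1 - sim
  degs <- vapply(sets, function(s) length(s$up) + length(s$down),
                 numeric(1))
  big <- names(degs)[degs > cluster_min_degs]
  clustering <- NULL
  if (length(big) >= 3)
    clustering <- stats::hclust(stats::as.dist(dist_m[big, big]),
                                method = "ward.D2")
  embedding <- NULL
  if (!is.null(embed_fun)) embedding <- embed_fun(stats::as.dist(dist_m))
  else if (n >= 3)
    embedding <- stats::cmdscale(stats::as.dist(dist_m), k = 2)
  list(similarity = sim, distance = dist_m, clustering = clustering,
       embedding = embedding)
}
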