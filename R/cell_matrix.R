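#' Construct a CellMatrix
#'
#' A `CellMatrix` bundles a sparse cells x genes count matrix with optional
#' antibody-derived-tag (ADT) counts, per-cell metadata, per-gene metadata
#' and optional per-cell QC flags. It is the common currency of every stage
#' in the package: QC filtering, pseudobulk aggregation, factorization and
#' composition analysis all consume it.
#'
#' @param gex_counts sparse (or dense) non-negative integer matrix,
#'   cells x genes. Coerced to `Matrix::dgCMatrix`.
#' @param cell_meta data.frame with one row per cell. Must contain
#'   `donor_id` and `tissue_group`; typical columns also include `tissue`,
#'   `lineage`, `subset`, `age_group` ("young"/"old"), `sex`, `cmv`,
#'   `site` and `chemistry`.
#' @param gene_meta data.frame with one row per gene; must contain a unique
#'   `symbol` column. Logical nuisance-list columns (`is_hsp`, `is_ribo`,
#'   `is_metallothionein`, `is_hemoglobin`, `is_stress`, `is_mito`) are used
#'   by QC and factor-flagging stages when present.
#' @param adt_counts optional cells x ADT non-negative integer matrix.
#' @param qc_flags optional data.frame (one row per cell) with columns such
#'   as `scrublet_prob`, `hashsolo_prob`, `erythro_fraction`,
#'   `dual_receptor`, `erythro_pred`, `mito_fraction`.
#'
#' @return An object of class `CellMatrix`.
#' @export
CellMatrix <- function(gex_counts, cell_meta, gene_meta,
                       adt_counts = NULL, qc_flags = NULL) {
  gex_counts <- methods::as(methods::as(methods::as(
    Matrix::Matrix(gex_counts, sparse = TRUE), "dMatrix"), "generalMatrix"),
    "CsparseMatrix")
  if (any(gex_counts@x < 0)) stop("gex_counts must be non-negative")
  if (any(gex_counts@x != round(gex_counts@x)))
    stop("gex_counts must be integer-valued")
  cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
  gene_meta <- as.data.frame(gene_meta, stringsAsFactors = FALSE)
  if (nrow(cell_meta) != nrow(gex_counts))
    stop(sprintf("cell_meta has %d rows but gex_counts has %d cells",
                 nrow(cell_meta), nrow(gex_counts)))
  if (nrow(gene_meta) != ncol(gex_counts))
    stop(sprintf("gene_meta has %d rows but gex_counts has %d genes",
                 nrow(gene_meta), ncol(gex_counts)))
  for (col in c("donor_id", "tissue_group")) {
    if (is.null(cell_meta[[col]]) || any(is.na(cell_meta[[col]])) ||
        any(!nzchar(as.character(cell_meta[[col]]))))
      stop(sprintf("cell_meta$%s must be present and non-empty for every cell", col))
  }
  if (is.null(gene_meta$symbol)) stop("gene_meta must contain a 'symbol' column")
  if (anyDuplicated(gene_meta$symbol)) stop("gene symbols must be unique")
  colnames(gex_counts) <- gene_meta$symbol
  if (is.null(rownames(gex_counts))) {
    rn <- if (!is.null(cell_meta$cell_id)) cell_meta$cell_id else
      sprintf("cell%d", seq_len(nrow(gex_counts)))
    rownames(gex_counts) <- rn
  }
  if (is.null(cell_meta$cell_id)) cell_meta$cell_id <- rownames(gex_counts)
  if (!is.null(adt_counts)) {
    adt_counts <- methods::as(methods::as(methods::as(
      Matrix::Matrix(adt_counts, sparse = TRUE), "dMatrix"), "generalMatrix"),
      "CsparseMatrix")
    if (nrow(adt_counts) != nrow(gex_counts))
      stop("adt_counts must have the same number of cells as gex_counts")
    if (any(adt_counts@x < 0)) stop("adt_counts must be non-negative")
    rownames(adt_counts) <- rownames(gex_counts)
  }
  if (!is.null(qc_flags)) {
    qc_flags <- as.data.frame(qc_flags, stringsAsFactors = FALSE)
    if (nrow(qc_flags) != nrow(gex_counts))
      stop("qc_flags must have one row per cell")
  }
  structure(list(gex_counts = gex_counts, adt_counts = adt_counts,
                 cell_meta = cell_meta, gene_meta = gene_meta,
                 qc_flags = qc_flags),
            class = "CellMatrix")
}

#' @export
print.CellMatrix <- function(x, ...) {
  cat(sprintf("CellMatrix: %d cells x %d genes", nrow(x$gex_counts),
              ncol(x$gex_counts)))
  if (!is.null(x$adt_counts)) cat(sprintf(", %d ADTs", ncol(x$adt_counts)))
  cat(sprintf("\n  donors: %d, tissue groups: %s\n",
              length(unique(x$cell_meta$donor_id)),
              paste(sort(unique(as.character(x$cell_meta$tissue_group))),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.CellMatrix <- function(x) dim(x$gex_counts)

#' Subset a CellMatrix by cells and/or genes
#'
#' @param x CellMatrix.
#' @param cells logical, integer or character index over cells.
#' @param genes logical, integer or character index over genes.
#' @return The subsetted CellMatrix.
#' @export
subset_cells <- function(x, cells = NULL, genes = NULL) {
  stopifnot(inherits(x, "CellMatrix"))
  if (is.null(cells)) cells <- seq_len(nrow(x$gex_counts))
  if (is.null(genes)) genes <- seq_len(ncol(x$gex_counts))
  if (is.character(genes)) genes <- match(genes, x$gene_meta$symbol)
  CellMatrix(x$gex_counts[cells, genes, drop = FALSE],
             x$cell_meta[cells, , drop = FALSE],
             x$gene_meta[genes, , drop = FALSE],
             adt_counts = if (!is.null(x$adt_counts))
               x$adt_counts[cells, , drop = FALSE],
             qc_flags = if (!is.null(x$qc_flags))
               x$qc_flags[cells, , drop = FALSE])
}

.known_tissue_groups <- c("BLO", "BM", "SPL", "LN", "LNG", "JEJ")

#' Write a CellMatrix bundle to disk
#'
#' The on-disk bundle is plain text: `matrix.mtx` (Matrix Market,
#' genes in columns), optional `adt.mtx`, `cells.tsv`, `genes.tsv`,
#' optional `qc_flags.tsv`, `adt_names.tsv` and a `levels.json` sidecar
#' recording factor level orderings so a read round-trips categorical
#' columns exactly.
#'
#' @param x CellMatrix.
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_cell_matrix <- function(x, path) {
  stopifnot(inherits(x, "CellMatrix"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$gex_counts, file.path(path, "matrix.mtx"))
  .write_tsv(x$cell_meta, file.path(path, "cells.tsv"))
  .write_tsv(x$gene_meta, file.path(path, "genes.tsv"))
  if (!is.null(x$adt_counts)) {
    Matrix::writeMM(x$adt_counts, file.path(path, "adt.mtx"))
    .write_tsv(data.frame(adt = colnames(x$adt_counts)),
               file.path(path, "adt_names.tsv"))
  }
  if (!is.null(x$qc_flags)) .write_tsv(x$qc_flags, file.path(path, "qc_flags.tsv"))
  lv <- list()
  for (col in names(x$cell_meta))
    if (is.factor(x$cell_meta[[col]])) lv[[col]] <- levels(x$cell_meta[[col]])
  jsonlite::write_json(lv, file.path(path, "levels.json"))
  invisible(path)
}

#' Read a CellMatrix bundle from disk
#'
#' @param path directory containing `matrix.mtx`, `cells.tsv`, `genes.tsv`
#'   and optionally `adt.mtx`, `qc_flags.tsv`, `levels.json`.
#' @return A CellMatrix. Unknown `tissue_group` values (outside
#'   BLO/BM/SPL/LN/LNG/JEJ) pass through with a warning.
#' @export
read_cell_matrix <- function(path) {
  mtx_path <- file.path(path, "matrix.mtx")
  if (!file.exists(mtx_path)) stop("missing matrix.mtx in ", path)
  counts <- methods::as(Matrix::readMM(mtx_path), "CsparseMatrix")
  cell_meta <- .read_tsv(file.path(path, "cells.tsv"))
  gene_meta <- .read_tsv(file.path(path, "genes.tsv"))
  if (nrow(cell_meta) != nrow(counts))
    stop(sprintf("cells.tsv has %d rows but matrix.mtx has %d cells",
                 nrow(cell_meta), nrow(counts)))
  if (nrow(gene_meta) != ncol(counts))
    stop(sprintf("genes.tsv has %d rows but matrix.mtx has %d genes",
                 nrow(gene_meta), ncol(counts)))
  lv_path <- file.path(path, "levels.json")
  if (file.exists(lv_path)) {
    lv <- jsonlite::read_json(lv_path, simplifyVector = TRUE)
    for (col in names(lv))
      if (col %in% names(cell_meta))
        cell_meta[[col]] <- factor(cell_meta[[col]], levels = lv[[col]])
  }
  adt <- NULL
  adt_path <- file.path(path, "adt.mtx")
  if (file.exists(adt_path)) {
    adt <- methods::as(Matrix::readMM(adt_path), "CsparseMatrix")
    nm_path <- file.path(path, "adt_names.tsv")
    if (file.exists(nm_path)) colnames(adt) <- .read_tsv(nm_path)$adt
    if (nrow(adt) != nrow(counts))
      stop(sprintf("adt.mtx has %d rows but matrix.mtx has %d cells",
                   nrow(adt), nrow(counts)))
  }
  qc <- NULL
  qc_path <- file.path(path, "qc_flags.tsv")
  if (file.exists(qc_path)) qc <- .read_tsv(qc_path)
  tg <- as.character(cell_meta$tissue_group)
  unknown <- setdiff(unique(tg), .known_tissue_groups)
  if (length(unknown))
    warning("unknown tissue_group values pass through: ",
            paste(unknown, collapse = ", "))
  CellMatrix(counts, cell_meta, gene_meta, adt_counts = adt, qc_flags = qc)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, fileEncoding = "UTF-8")
}

#' Map fine-grained sampling sites onto coarse tissue groups
#'
#' Pools related sampling sites (e.g. jejunum epithelium and lamina propria
#' into JEJ; lung lavage and parenchyma into LNG; the individual lymph-node
#' stations into LN). The mapping is configuration, not code: pass your own
#' named vector to override.
#'
#' @param tissue character vector of site labels.
#' @param mapping named character vector site -> tissue_group.
#' @return character vector of tissue groups; unmapped sites pass through.
#' @export
map_tissue_groups <- function(tissue,
                              mapping = c(JEL = "JEJ", JLP = "JEJ",
                                          BAL = "LNG", PAR = "LNG",
                                          ILN = "LN", LLN = "LN", MLN = "LN")) {
  tissue <- as.character(tissue)
  hit <- tissue %in% names(mapping)
  tissue[hit] <- unname(mapping[tissue[hit]])
  tissue
}
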