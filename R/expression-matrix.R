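#' Construct an ExpressionMatrix
#'
#' Lightweight container for single-cell expression data: a sparse cells x
#' genes count matrix, optional log-normalized layer, and cell/gene metadata.
#' Rows are cells (barcodes), columns are genes.
#'
#' @param counts Sparse or dense non-negative integer matrix, cells x genes,
#'   with barcode rownames and gene-symbol colnames.
#' @param cell_meta data.frame of per-cell metadata (row order = matrix rows);
#'   a `barcode` column is added if absent.
#' @param gene_meta data.frame of per-gene metadata (`symbol`, optionally
#'   `chrom`, `arm`, `tss`, `strand`); a `mito` flag is derived from
#'   `mito_prefix` if absent.
#' @param normalized Optional cells x genes numeric matrix (log-normalized).
#' @param mito_prefix Gene-symbol prefix marking mitochondrial genes.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(counts, cell_meta = NULL, gene_meta = NULL,
                              normalized = NULL, mito_prefix = "MT-") {
  counts <- methods::as(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                                "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have barcode rownames and gene colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate cell barcodes")
  if (anyDuplicated(colnames(counts))) stop("duplicate gene identifiers")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  if (is.null(cell_meta)) cell_meta <- data.frame(barcode = rownames(counts))
  if (!"barcode" %in% names(cell_meta)) cell_meta$barcode <- rownames(counts)
  stopifnot(nrow(cell_meta) == nrow(counts))
  rownames(cell_meta) <- rownames(counts)
  if (is.null(gene_meta)) gene_meta <- data.frame(symbol = colnames(counts))
  if (!"symbol" %in% names(gene_meta)) gene_meta$symbol <- colnames(counts)
  stopifnot(nrow(gene_meta) == ncol(counts))
  rownames(gene_meta) <- colnames(counts)
  if (!"mito" %in% names(gene_meta))
    gene_meta$mito <- startsWith(gene_meta$symbol, mito_prefix)
  structure(list(counts = counts, normalized = normalized,
                 cell_meta = cell_meta, gene_meta = gene_meta),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d genes%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$normalized)) "" else " (log-normalized layer present)"))
  cat("cell_meta columns:", paste(names(x$cell_meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$counts)

#' Subset an ExpressionMatrix by cells and/or genes
#'
#' @param em An `ExpressionMatrix`.
#' @param cells,genes Index vectors (logical, integer, or names); `NULL`
#'   keeps everything.
#' @return The subset `ExpressionMatrix`.
#' @export
subset_cells <- function(em, cells = NULL, genes = NULL) {
  if (is.null(cells)) cells <- seq_len(nrow(em$counts))
  if (is.null(genes)) genes <- seq_len(ncol(em$counts))
  em$counts <- em$counts[cells, genes, drop = FALSE]
  if (!is.null(em$normalized))
    em$normalized <- em$normalized[cells, genes, drop = FALSE]
  em$cell_meta <- em$cell_meta[cells, , drop = FALSE]
  em$gene_meta <- em$gene_meta[genes, , drop = FALSE]
  em
}

#' Log-normalize counts
#'
#' Per-cell depth normalization followed by `log1p`:
#' `normalized[c, g] = log1p(counts[c, g] / depth_c * scale)` where `depth_c`
#' is the cell's total count. Invariant to multiplying a cell's counts by any
#' positive constant.
#'
#' @param em An `ExpressionMatrix`.
#' @param scale Scale factor (default 10,000).
#' @return The `ExpressionMatrix` with a `normalized` layer.
#' @export
lognormalize <- function(em, scale = 10000) {
  depth <- Matrix::rowSums(em$counts)
  if (any(depth == 0))
    stop("zero-depth cell(s): ",
         paste(head(rownames(em$counts)[depth == 0], 5), collapse = ", "))
  norm <- em$counts / depth * scale
  norm@x <- log1p(norm@x)
  em$normalized <- norm
  em
}

# Dense normalized layer (cells x genes base matrix), computing it if absent.
normalized_dense <- function(em) {
  if (is.null(em$normalized)) stop("normalized layer absent; run lognormalize()")
  as.matrix(em$normalized)
}
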