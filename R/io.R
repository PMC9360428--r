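# Readers/writers for the standard on-disk formats: 10x-style MTX triplet,
# BED-like fragment files, peak BED, GMT gene sets, and plain TSV tables.

#' Read a 10x-style MTX triplet into an ExpressionMatrix
#'
#' Accepts either on-disk orientation (features x barcodes, the 10x
#' convention, or barcodes x features) and returns cells x genes.
#'
#' @param mtx_path Path to `matrix.mtx`.
#' @param barcodes_path Path to a one-column barcodes file.
#' @param features_path Path to a features file (first column = symbol).
#' @param mito_prefix Prefix marking mitochondrial gene symbols.
#' @return An `ExpressionMatrix`.
#' @export
read_counts_bundle <- function(mtx_path, barcodes_path, features_path,
                               mito_prefix = "MT-") {
  for (p in c(mtx_path, barcodes_path, features_path))
    if (!file.exists(p)) stop("file not found: ", p)
  m <- Matrix::readMM(mtx_path)
  barcodes <- readLines(barcodes_path)
  feats <- read.delim(features_path, header = FALSE, stringsAsFactors = FALSE)
  features <- feats[[1]]
  if (nrow(m) == length(features) && ncol(m) == length(barcodes)) {
    m <- Matrix::t(m)                      # 10x convention: features x barcodes
  } else if (!(nrow(m) == length(barcodes) && ncol(m) == length(features))) {
    stop(sprintf(
      "dimension mismatch: matrix %d x %d vs %d barcodes and %d features",
      nrow(m), ncol(m), length(barcodes), length(features)))
  }
  if (anyDuplicated(barcodes)) stop("duplicate barcodes in ", barcodes_path)
  dimnames(m) <- list(barcodes, features)
  expression_matrix(m, mito_prefix = mito_prefix)
}

#' Write an ExpressionMatrix as an MTX triplet
#'
#' Writes `matrix.mtx` (features x barcodes, 10x orientation),
#' `barcodes.tsv`, and `features.tsv` into `dir`.
#'
#' @param em An `ExpressionMatrix`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts_bundle <- function(em, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(em$counts), file.path(dir, "matrix.mtx"))
  writeLines(rownames(em$counts), file.path(dir, "barcodes.tsv"))
  write.table(em$gene_meta, file.path(dir, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read a BED-like fragment file
#'
#' Columns: chrom, start, end, barcode, count (0-based half-open intervals).
#'
#' @param path Fragment TSV path.
#' @return A `data.table` with those columns.
#' @export
read_fragments <- function(path) {
  fr <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "barcode", "count"))
  if (nrow(fr) == 0)
    warning("empty fragment file: ", path)
  fr
}

#' Write fragments to a BED-like TSV
#' @param fragments data.frame/data.table with chrom, start, end, barcode, count.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  data.table::fwrite(fragments, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read/write a peak table (BED, 0-based half-open; 4th column = peak id)
#' @param path File path.
#' @return data.frame with chrom, start, end, peak_id (and extra columns if present).
#' @export
read_peaks <- function(path) {
  pk <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "peak_id") %in% names(pk)))
  pk
}

#' @rdname read_peaks
#' @param peaks Peak data.frame.
#' @export
write_peaks <- function(peaks, path) {
  write.table(peaks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name<TAB>description<TAB>genes...`.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Write a GMT gene-set collection
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Convert fragments to a per-cell peak count matrix
#'
#' Assigns each fragment to the peak containing its midpoint (if any) and
#' accumulates the count column.
#'
#' @param fragments Fragment table (chrom, start, end, barcode, count).
#' @param peaks Peak table (chrom, start, end, peak_id).
#' @param barcodes Optional barcode universe fixing row order.
#' @return Sparse cells x peaks count matrix.
#' @export
fragments_to_peak_counts <- function(fragments, peaks, barcodes = NULL) {
  fr <- data.table::as.data.table(fragments)
  pk <- data.table::as.data.table(peaks)
  fr[, mid := (start + end) %/% 2L]
  fr[, `:=`(qs = mid, qe = mid + 1L)]
  pk2 <- pk[, .(chrom, qs = start, qe = end, peak_id)]
  data.table::setkey(pk2, chrom, qs, qe)
  ov <- data.table::foverlaps(fr[, .(chrom, qs, qe, barcode, count)], pk2,
                              type = "within", nomatch = NULL)
  if (is.null(barcodes)) barcodes <- sort(unique(fragments$barcode))
  agg <- ov[, .(n = sum(count)), by = .(barcode, peak_id)]
  agg <- agg[barcode %in% barcodes]
  Matrix::sparseMatrix(
    i = match(agg$barcode, barcodes),
    j = match(agg$peak_id, pk$peak_id),
    x = agg$n,
    dims = c(length(barcodes), nrow(pk)),
    dimnames = list(barcodes, pk$peak_id))
}

# Coordinate converters: BED (0-based half-open) <-> 1-based inclusive.
bed_to_1based <- function(start0) start0 + 1L
one_based_to_bed <- function(pos1) pos1 - 1L
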