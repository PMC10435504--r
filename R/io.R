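#' Read and write the pipeline's tabular formats
#'
#' Plain-text interchange: variants and segments as TSV (positions 1-based
#' for variants, 0-based half-open for segments), sparse matrices as
#' MatrixMarket (`.mtx`) with sidecar features/barcodes TSVs, fragments and
#' AIRR-style contigs as TSV.
#'
#' @param x table or matrix to write; @param path file path.
#' @name spaceclone_io
NULL

#' @rdname spaceclone_io
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname spaceclone_io
#' @export
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname spaceclone_io
#' @param mat a `cell_feature_matrix`; @param prefix path prefix; writes
#'   `<prefix>.mtx`, `<prefix>_features.tsv`, `<prefix>_cells.tsv`.
#' @export
write_cell_matrix <- function(mat, prefix) {
  Matrix::writeMM(methods::as(mat$counts, "CsparseMatrix"),
                  paste0(prefix, ".mtx"))
  write_tsv(mat$features, paste0(prefix, "_features.tsv"))
  write_tsv(mat$cells, paste0(prefix, "_cells.tsv"))
  invisible(prefix)
}

#' @rdname spaceclone_io
#' @export
read_cell_matrix <- function(prefix) {
  counts <- methods::as(Matrix::readMM(paste0(prefix, ".mtx")),
                        "CsparseMatrix")
  features <- read_tsv(paste0(prefix, "_features.tsv"))
  cells <- read_tsv(paste0(prefix, "_cells.tsv"))
  dimnames(counts) <- list(features$gene, cells$cell)
  structure(list(counts = counts, features = features, cells = cells,
                 modality = cells$modality[1L]),
            class = "cell_feature_matrix")
}

#' @rdname spaceclone_io
#' @param bulk list from [simulate_bulk_reads()]; @param dir directory;
#'   @param site site label used in the file names.
#' @export
write_bulk_site <- function(bulk, dir, site) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- bulk$variants
  out_v <- data.frame(CHROM = v$chrom, POS = v$pos, REF = v$ref, ALT = v$alt,
                      stringsAsFactors = FALSE)
  out_v[[paste0("ALT_READS_", site)]] <- v$alt_reads
  out_v[[paste0("TOTAL_READS_", site)]] <- v$total_reads
  write_tsv(out_v, file.path(dir, paste0("variants_", site, ".tsv")))
  s <- bulk$segments
  write_tsv(data.frame(CHROM = s$chrom, START = s$start, END = s$end,
                       TOTAL_CN = s$total_cn, SEG_CCF = s$seg_ccf,
                       EVENT_ID = s$event_id, stringsAsFactors = FALSE),
            file.path(dir, paste0("segments_", site, ".tsv")))
  invisible(dir)
}
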