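#' Write a count matrix in 10x MatrixMarket convention
#'
#' Stores the matrix as `matrix.mtx` with genes as rows and cells as
#' columns (the on-disk 10x convention), alongside `barcodes.tsv` and
#' `features.tsv`. In memory the matrix is cells x genes; the transpose
#' happens here and in [read_count_matrix()].
#'
#' @param counts cells (barcodes) x genes matrix with dimnames.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_count_matrix <- function(counts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- methods::as(methods::as(Matrix::Matrix(Matrix::t(counts),
                                              sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts) %||% character(0),
             file.path(dir, "features.tsv"))
  writeLines(rownames(counts) %||% character(0),
             file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' @param dir directory holding matrix.mtx, barcodes.tsv, features.tsv.
#' @return sparse cells x genes matrix with barcode rownames and gene
#'   colnames.
#' @export
read_count_matrix <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "barcodes.tsv",
                            "features.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing count matrix file(s): ",
         paste(basename(missing), collapse = ", "))
  }
  m <- tryCatch(Matrix::readMM(paths[1L]), error = function(e) {
    stop("malformed MatrixMarket file ", paths[1L], ": ",
         conditionMessage(e))
  })
  barcodes <- readLines(paths[2L])
  features <- readLines(paths[3L])
  if (nrow(m) != length(features) || ncol(m) != length(barcodes)) {
    stop(sprintf(
      "dimension mismatch: matrix is %d x %d but features.tsv has %d and barcodes.tsv has %d entries",
      nrow(m), ncol(m), length(features), length(barcodes)))
  }
  m <- methods::as(methods::as(Matrix::t(m), "generalMatrix"),
                   "CsparseMatrix")
  dimnames(m) <- list(barcodes, features)
  m
}

#' Write / read tagged reads as (gzipped) TSV
#'
#' Columns: barcode, umi, gene, orientation. A `.gz` suffix triggers
#' gzip compression.
#'
#' @param reads data frame of tagged reads.
#' @param path file path (`.tsv` or `.tsv.gz`).
#' @return for reading, the reads data frame.
#' @export
write_tagged_reads <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(reads, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tagged_reads
#' @export
read_tagged_reads <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = "character")
  required <- c("barcode", "umi", "gene", "orientation")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("tagged-read file lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  df$gene[df$gene == "" | df$gene == "NA"] <- NA_character_
  df
}
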