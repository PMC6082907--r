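#' Read and write FASTQ, count matrices and axis files
#'
#' Thin wrappers over Biostrings (FASTQ, 4-line records, Phred+33) and
#' Matrix (MatrixMarket) used throughout the pipeline.
#'
#' @param path file path.
#' @param ids,seqs,quals read ids, sequences and quality strings; when
#'   `quals` is `NULL` a constant high quality (Q40, "I") is written.
#' @return `read_fastq()` returns a data frame with columns `id`, `seq`,
#'   `qual`; `write_fastq()` returns `path` invisibly.
#' @name fastq_io
NULL

#' @rdname fastq_io
#' @export
write_fastq <- function(ids, seqs, path, quals = NULL) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals))
  invisible(path)
}

#' @rdname fastq_io
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}

#' Write / read a UMI count matrix as MatrixMarket plus axis TSVs
#'
#' The matrix is stored as `counts.mtx` with `genes.tsv` and `cells.tsv`
#' holding the row and column ids, the common exchange layout for sparse
#' gene-by-cell matrices.
#'
#' @param counts gene x cell matrix.
#' @param dir directory to write into / read from.
#' @return `write_counts_mtx()` returns `dir` invisibly;
#'   `read_counts_mtx()` returns the dense integer matrix with dimnames.
#' @export
write_counts_mtx <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
                  file.path(dir, "counts.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "counts.mtx")))
  storage.mode(m) <- "integer"
  dimnames(m) <- list(readLines(file.path(dir, "genes.tsv")),
                      readLines(file.path(dir, "cells.tsv")))
  m
}
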