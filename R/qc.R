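#' Cell- and gene-level quality-control thresholds
#'
#' Bundles the stringent cell filters of the pipeline — at least
#' `min_genes` detected genes, second-maximum pairwise Pearson
#' correlation above `min_second_max_pearson`, and no embedding-space
#' outlier call — together with the detection-based gene filter (TPM
#' strictly above `min_gene_tpm` in at least `min_gene_cells` cells).
#'
#' @param min_genes minimum detected genes per cell (default 3000).
#' @param min_second_max_pearson minimum second-maximum pairwise Pearson
#'   correlation (strictly greater than; default 0.6).
#' @param outlier_method `"robust_pca_mad"` (deterministic PCA-space
#'   median-absolute-deviation rule) or `"none"`.
#' @param outlier_mad_k MAD multiplier of the outlier rule.
#' @param outlier_n_pcs number of principal components used.
#' @param min_gene_tpm gene filter: TPM must exceed this (strictly).
#' @param min_gene_cells gene filter: in at least this many cells.
#' @return an object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 3000L,
                          min_second_max_pearson = 0.6,
                          outlier_method = c("robust_pca_mad", "none"),
                          outlier_mad_k = 5,
                          outlier_n_pcs = 10L,
                          min_gene_tpm = 5,
                          min_gene_cells = 2L) {
  outlier_method <- match.arg(outlier_method)
  stopifnot(min_genes >= 0, is.finite(min_second_max_pearson),
            outlier_mad_k > 0, outlier_n_pcs >= 1,
            is.finite(min_gene_tpm), min_gene_cells >= 0)
  structure(list(min_genes = as.integer(min_genes),
                 min_second_max_pearson = min_second_max_pearson,
                 outlier_method = outlier_method,
                 outlier_mad_k = outlier_mad_k,
                 outlier_n_pcs = as.integer(outlier_n_pcs),
                 min_gene_tpm = min_gene_tpm,
                 min_gene_cells = as.integer(min_gene_cells)),
            class = "qc_thresholds")
}

#' Number of detected genes per cell
#'
#' A gene is detected in a cell when its UMI count is at least 1.
#'
#' @param counts gene x cell UMI count matrix.
#' @return named integer vector, one entry per cell.
#' @export
genes_detected <- function(counts) {
  out <- colSums(counts >= 1L)
  storage.mode(out) <- "integer"
  out
}

#' Second-maximum pairwise Pearson correlation per cell
#'
#' For every cell, computes the Pearson correlation (on log2(TPM+1),
#' optionally restricted to a gene subset) with every other cell and
#' returns the second largest value, self excluded.  A healthy cell in a
#' population has at least two close neighbours, so a low second maximum
#' marks an isolated, likely degraded cell.
#'
#' @param expr gene x cell TPM matrix.
#' @param gene_subset optional gene ids to restrict the correlation to.
#' @param log_transform correlate log2(TPM+1) (default) or raw TPM.
#' @return named numeric vector of second-maximum correlations.
#' @export
second_max_correlation <- function(expr, gene_subset = NULL,
                                   log_transform = TRUE) {
  if (ncol(expr) < 3L) {
    stop("second-maximum correlation is undefined with fewer than 3 cells")
  }
  if (!is.null(gene_subset)) expr <- expr[gene_subset, , drop = FALSE]
  x <- if (log_transform) log2(expr + 1) else expr
  cc <- suppressWarnings(cor(x))
  diag(cc) <- -Inf
  apply(cc, 2, function(v) sort(v, decreasing = TRUE)[2])
}

#' Deterministic PCA-space outlier flags
#'
#' A reproducible surrogate for visual outlier removal on embeddings:
#' cells are projected onto the top principal components of
#' log2(TPM+1), and a cell is flagged when its Euclidean distance from
#' the componentwise median exceeds the median distance by more than
#' `outlier_mad_k` median absolute deviations.
#'
#' @param expr gene x cell TPM matrix.
#' @param thresholds a [qc_thresholds()].
#' @return named logical vector (all `FALSE` when the method is "none").
#' @export
embedding_outliers <- function(expr, thresholds = qc_thresholds()) {
  out <- setNames(rep(FALSE, ncol(expr)), colnames(expr))
  if (thresholds$outlier_method == "none") return(out)
  if (ncol(expr) < 10L) {
    stop("PCA outlier detection needs at least 10 cells")
  }
  x <- t(log2(expr + 1))
  x <- x[, apply(x, 2, function(v) any(v != v[1])), drop = FALSE]
  if (ncol(x) == 0L) {
    warning("degenerate expression matrix; no outliers flagged")
    return(out)
  }
  k <- min(thresholds$outlier_n_pcs, ncol(x), nrow(x) - 1L)
  pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = k)$x
  ctr <- apply(pc, 2, median)
  d <- sqrt(colSums((t(pc) - ctr)^2))
  s <- mad(d)
  if (s == 0) return(out)
  out[] <- d > median(d) + thresholds$outlier_mad_k * s
  out
}

#' Apply the cell quality-control filters
#'
#' A cell passes when it has at least `min_genes` detected genes, its
#' second-maximum pairwise correlation is strictly above
#' `min_second_max_pearson`, and it is not an embedding-space outlier.
#'
#' @param counts gene x cell UMI count matrix.
#' @param expr matching TPM matrix (defaults to `tpm_normalize(counts)`).
#' @param thresholds a [qc_thresholds()].
#' @return list with `cells` (retained cell ids) and `report`, a data
#'   frame (one row per cell: `cell_id`, `genes_detected`,
#'   `second_max_pearson`, `outlier`, `pass`) whose attributes `n_input`
#'   and `n_pass` summarize the run.
#' @export
apply_qc <- function(counts, expr = tpm_normalize(counts),
                     thresholds = qc_thresholds()) {
  stopifnot(identical(dim(counts), dim(expr)))
  gd <- genes_detected(counts)
  smc <- if (thresholds$min_second_max_pearson <= -1 || ncol(expr) < 3L) {
    setNames(rep(NA_real_, ncol(expr)), colnames(expr))
  } else {
    second_max_correlation(expr)
  }
  outl <- embedding_outliers(expr, thresholds)
  pass <- gd >= thresholds$min_genes &
    (is.na(smc) | smc > thresholds$min_second_max_pearson) &
    !outl
  report <- data.frame(cell_id = colnames(counts), genes_detected = gd,
                       second_max_pearson = unname(smc), outlier = unname(outl),
                       pass = unname(pass), row.names = NULL,
                       stringsAsFactors = FALSE)
  attr(report, "n_input") <- ncol(counts)
  attr(report, "n_pass") <- sum(pass)
  list(cells = colnames(counts)[pass], report = report)
}

#' Detection-based gene filter
#'
#' Keeps genes whose TPM is strictly above `min_gene_tpm` in at least
#' `min_gene_cells` cells.
#'
#' @param expr gene x cell TPM matrix (typically restricted to
#'   QC-retained cells first).
#' @param thresholds a [qc_thresholds()].
#' @return character vector of retained gene ids.
#' @export
filter_genes <- function(expr, thresholds = qc_thresholds()) {
  n_over <- rowSums(expr > thresholds$min_gene_tpm)
  rownames(expr)[n_over >= thresholds$min_gene_cells]
}
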