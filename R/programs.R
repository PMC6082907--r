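#' Cell-cycle gene panel
#'
#' Loads the shipped (editable) list of cell-cycle-associated genes,
#' split into a G1/S and a G2/M class, together with the cycling
#' threshold and classification mode.  Two modes are supported because
#' both appear in practice: `"mean_expression"` calls a cell cycling
#' when its average TPM over the whole panel is at least `threshold`
#' (inclusive); `"n_genes_expressed"` calls a cell cycling when the
#' number of panel genes with TPM > 0 strictly exceeds `threshold`.
#'
#' @param path optional TSV with columns `gene`, `phase`
#'   (`G1/S` or `G2/M`); defaults to the shipped list.
#' @param threshold cycling threshold (default 100).
#' @param mode `"mean_expression"` (default) or `"n_genes_expressed"`.
#' @return list with `g1s_genes`, `g2m_genes`, `threshold`, `mode`;
#'   class `cell_cycle_panel`.
#' @export
cell_cycle_panel <- function(path = NULL, threshold = 100,
                             mode = c("mean_expression", "n_genes_expressed")) {
  mode <- match.arg(mode)
  stopifnot(threshold > 0)
  if (is.null(path)) {
    path <- system.file("extdata", "cell_cycle_genes.tsv",
                        package = "villusSC")
  }
  tab <- read.delim(path, stringsAsFactors = FALSE)
  g1s <- tab$gene[tab$phase == "G1/S"]
  g2m <- tab$gene[tab$phase == "G2/M"]
  if (length(intersect(g1s, g2m))) stop("G1/S and G2/M lists overlap")
  structure(list(g1s_genes = g1s, g2m_genes = g2m,
                 threshold = threshold, mode = mode),
            class = "cell_cycle_panel")
}

#' Classify cycling cells
#'
#' In `mean_expression` mode, a cell is cycling when its mean TPM over
#' the union of the G1/S and G2/M panel genes is at least the panel
#' threshold (inclusive).  In `n_genes_expressed` mode, a cell is
#' cycling when it expresses (TPM > 0) strictly more panel genes than
#' the threshold.
#'
#' @param expr gene x cell TPM matrix.
#' @param panel a [cell_cycle_panel()].
#' @return named logical vector, one flag per cell.
#' @export
cycling_cells <- function(expr, panel = cell_cycle_panel()) {
  genes <- intersect(unique(c(panel$g1s_genes, panel$g2m_genes)),
                     rownames(expr))
  if (length(genes) == 0L) stop("no cell-cycle panel gene is in the matrix")
  sub <- expr[genes, , drop = FALSE]
  if (panel$mode == "mean_expression") {
    colMeans(sub) >= panel$threshold
  } else {
    colSums(sub > 0) > panel$threshold
  }
}

#' Fraction of cycling cells per cluster
#'
#' @param flags per-cell logical cycling flags.
#' @param assignment per-cell cluster labels (0 = unassigned, reported
#'   under `"unassigned"`).
#' @return named numeric vector of cycling fractions per cluster.
#' @export
cycling_ratio <- function(flags, assignment) {
  stopifnot(length(flags) == length(assignment))
  grp <- as.character(assignment)
  grp[grp == "0"] <- "unassigned"
  vapply(split(flags, grp), mean, numeric(1))
}

#' Marker genes of one cluster (one-vs-rest Wilcoxon test)
#'
#' Compares every prefiltered gene between the target cluster and all
#' other cells on log2(TPM+1).  Prefilters: the gene must be expressed
#' (TPM > 0) in at least `min_pct` of the cluster's cells, and the
#' absolute difference of mean log2(TPM+1) (the log2 fold change) must
#' reach `min_log2fc`.  Genes passing are tested with the two-sided
#' Wilcoxon rank-sum test, using the exact rank-sum distribution for
#' small tie-free samples and the tie-corrected normal approximation
#' with continuity correction otherwise (the [stats::wilcox.test()]
#' default policy).  Benjamini-Hochberg q-values are computed across
#' the tested genes.  Rows are sorted by q-value, then by decreasing
#' fold change.
#'
#' @param expr gene x cell TPM matrix.
#' @param assignment per-cell cluster labels naming all columns.
#' @param target_cluster cluster to contrast against the rest.
#' @param min_log2fc,min_pct prefilter thresholds.
#' @param alpha significance level recorded in the output attributes
#'   (no row filtering is applied).
#' @return data frame (`gene`, `cluster`, `log2_fold_change`, `pct_in`,
#'   `pct_out`, `p_value`, `fdr_q`).
#' @export
find_markers <- function(expr, assignment, target_cluster,
                         min_log2fc = 0.25, min_pct = 0.10, alpha = 0.05) {
  in_cl <- assignment == target_cluster
  if (sum(in_cl) < 3L || sum(!in_cl) < 3L) {
    stop("target cluster and complement must each have at least 3 cells")
  }
  lx <- log2(expr + 1)
  pct_in <- rowMeans(expr[, in_cl, drop = FALSE] > 0)
  pct_out <- rowMeans(expr[, !in_cl, drop = FALSE] > 0)
  lfc <- rowMeans(lx[, in_cl, drop = FALSE]) -
    rowMeans(lx[, !in_cl, drop = FALSE])
  keep <- pct_in >= min_pct & abs(lfc) >= min_log2fc
  genes <- rownames(expr)[keep]

  p <- vapply(genes, function(g) {
    suppressWarnings(
      wilcox.test(lx[g, in_cl], lx[g, !in_cl])$p.value)
  }, numeric(1))
  q <- p.adjust(p, method = "BH")

  out <- data.frame(gene = genes, cluster = as.character(target_cluster),
                    log2_fold_change = unname(lfc[keep]),
                    pct_in = unname(pct_in[keep]),
                    pct_out = unname(pct_out[keep]),
                    p_value = unname(p), fdr_q = unname(q),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$fdr_q, -out$log2_fold_change), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  out
}

#' Marker genes of every cluster
#'
#' One-vs-rest [find_markers()] for each labelled cluster (label 0 is
#' skipped), concatenated.
#'
#' @inheritParams find_markers
#' @param ... passed to [find_markers()].
#' @return concatenated marker data frame.
#' @export
find_all_markers <- function(expr, assignment, ...) {
  cl <- setdiff(sort(unique(as.character(assignment))), "0")
  do.call(rbind, lapply(cl, function(k) {
    find_markers(expr, assignment, k, ...)
  }))
}

#' Detect expressed genes from a curated panel
#'
#' A panel gene counts as detected when its TPM is strictly above
#' `min_tpm` in at least `min_cells` cells.  A per-subtype mean
#' log2(TPM+1) matrix over the detected genes is returned for
#' heatmap-style summaries.
#'
#' @param expr gene x cell TPM matrix.
#' @param panel_genes character vector of panel gene ids.
#' @param min_tpm detection TPM threshold (strict; default 2).
#' @param min_cells minimum number of cells over threshold (default 30).
#' @param assignment optional per-cell subtype labels for the summary
#'   matrix.
#' @param name panel name carried in the result.
#' @return list (`panel`, `detected_genes`, `n_panel`, `n_detected`,
#'   `subtype_means`), class `gene_panel_result`.
#' @export
panel_detect <- function(expr, panel_genes, min_tpm = 2, min_cells = 30L,
                         assignment = NULL, name = "custom") {
  stopifnot(length(panel_genes) > 0)
  present <- intersect(panel_genes, rownames(expr))
  n_over <- rowSums(expr[present, , drop = FALSE] > min_tpm)
  detected <- present[n_over >= min_cells]

  subtype_means <- NULL
  if (!is.null(assignment) && length(detected)) {
    lx <- log2(expr[detected, , drop = FALSE] + 1)
    grp <- split(seq_along(assignment), assignment)
    subtype_means <- matrix(
      unlist(lapply(grp, function(j) rowMeans(lx[, j, drop = FALSE]))),
      nrow = length(detected),
      dimnames = list(detected, names(grp)))
  }
  structure(list(panel = name, detected_genes = detected,
                 n_panel = length(panel_genes), n_detected = length(detected),
                 subtype_means = subtype_means),
            class = "gene_panel_result")
}

#' @export
print.gene_panel_result <- function(x, ...) {
  cat("gene panel `", x$panel, "`: ", x$n_detected, " of ", x$n_panel,
      " genes detected\n", sep = "")
  invisible(x)
}

#' Load a shipped curated gene panel
#'
#' Ships representative hormone and imprinted gene lists assembled from
#' genes the placental literature names (with a `source` column); the
#' panel composition is input data, not code, and users supply their
#' own curated lists for real analyses.
#'
#' @param name `"hormone"`, `"imprinted"`, or a TSV path with columns
#'   `gene`, `class`, `source`.
#' @return data frame with columns `gene`, `class`, `source`.
#' @export
load_gene_panel <- function(name) {
  path <- if (file.exists(name)) name else {
    system.file("extdata", paste0(name, "_panel.tsv"), package = "villusSC")
  }
  if (!nzchar(path) || !file.exists(path)) stop("unknown panel: ", name)
  read.delim(path, stringsAsFactors = FALSE)
}
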