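#' Run the full analysis pipeline on a UMI count matrix
#'
#' Chains the analysis stages the package implements: TPM
#' normalization, cell QC, gene filtering, Spearman/average-linkage
#' clustering with the dynamic hybrid cut, nested subtype refinement,
#' marker-panel annotation of clusters, cell-cycle classification, and
#' detection of the shipped hormone and imprinted panels.
#'
#' @param counts gene x cell UMI count matrix.
#' @param thresholds a [qc_thresholds()].
#' @param min_cluster_size,deep_split passed to
#'   [dynamic_hybrid_cut()] and [subcluster()].
#' @param panel a [marker_panel()] for cluster annotation.
#' @param cc_panel a [cell_cycle_panel()].
#' @param subtype_pass refine populations into nested subtypes?
#' @return list with elements `expr` (TPM over retained cells and
#'   genes), `qc` (report), `retained_cells`, `retained_genes`,
#'   `populations` (integer labels), `subtypes` (nested labels),
#'   `population_names` (per-cluster annotation), `cycling` (flags) and
#'   `cycling_by_subtype`, `hormone` and `imprinted`
#'   (`gene_panel_result`s).
#' @export
run_placenta_pipeline <- function(counts,
                                  thresholds = qc_thresholds(),
                                  min_cluster_size = 20L,
                                  deep_split = 1L,
                                  panel = marker_panel(),
                                  cc_panel = cell_cycle_panel(),
                                  subtype_pass = TRUE) {
  expr_all <- tpm_normalize(counts)
  qc <- apply_qc(counts, expr_all, thresholds)
  expr <- tpm_normalize(counts[, qc$cells, drop = FALSE])
  genes <- filter_genes(expr, thresholds)
  expr <- expr[genes, , drop = FALSE]

  clus <- cluster_cells(expr, min_cluster_size = min_cluster_size,
                        deep_split = deep_split)
  populations <- clus$labels
  subtypes <- if (subtype_pass) {
    discover_subtypes(expr, populations, min_cluster_size = min_cluster_size,
                      deep_split = deep_split)
  } else {
    setNames(as.character(populations), names(populations))
  }

  scores <- score_cell_types(expr, panel)
  calls <- assign_types(scores)
  population_names <- annotate_clusters(calls, populations)
  population_names <- population_names[names(population_names) != "0"]

  cycling <- cycling_cells(expr, cc_panel)
  cycling_by_subtype <- cycling_ratio(cycling, subtypes)

  hormone <- panel_detect(expr, load_gene_panel("hormone")$gene,
                          assignment = subtypes, name = "hormone")
  imprinted <- panel_detect(expr, load_gene_panel("imprinted")$gene,
                            assignment = subtypes, name = "imprinted")

  list(expr = expr, qc = qc$report, retained_cells = qc$cells,
       retained_genes = genes, populations = populations,
       subtypes = subtypes, population_names = population_names,
       cell_type_calls = calls, cycling = cycling,
       cycling_by_subtype = cycling_by_subtype,
       hormone = hormone, imprinted = imprinted)
}
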