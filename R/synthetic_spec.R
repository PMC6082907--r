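#' Specification for a synthetic tag-based scRNA-seq experiment
#'
#' A `synthetic_spec` captures everything needed to simulate a sorted-cell
#' plate-based 3' tag experiment: the gene universe, the planted subtypes
#' with their marker genes, the negative-binomial noise model, planted
#' cycling and low-quality cells, and the library tag layout (cell barcode
#' + UMI) used when emitting FASTQ.
#'
#' Counts for gene \eqn{g} in cell \eqn{c} are drawn
#' \eqn{NB(\mu_{gc}, size)} with \eqn{Var = \mu + \mu^2/size}.  Baseline
#' gene means are log-normal around `baseline_mean` (spread
#' `gene_mean_sdlog`) so that cells share a realistic mean-expression
#' profile; marker and cycle-panel genes are pinned at exactly
#' `baseline_mean` so planted fold changes are well defined.  Marker genes
#' of a subtype have their mean multiplied by that subtype's
#' `marker_fold` in its cells; cycle-panel genes are multiplied by
#' `cycle_panel_boost` in cycling cells.
#'
#' @param n_genes number of genes in the universe.
#' @param subtypes list of subtype descriptions; each a list with elements
#'   `name`, `n_cells`, `marker_genes` (character vector of gene ids),
#'   `marker_fold` (positive multiplier), and optionally
#'   `cycling_fraction` overriding the global one.
#' @param baseline_mean expected UMI count per gene per cell for marker /
#'   cycle genes, and the mean of the log-normal baseline for the rest.
#' @param gene_mean_sdlog log-scale spread of baseline gene means.
#' @param dispersion negative-binomial size parameter.
#' @param cycling_fraction fraction of each subtype's cells that cycle;
#'   scalar, recycled over subtypes unless a subtype overrides it.
#' @param cycle_genes gene ids forming the planted cell-cycle panel.
#' @param cycle_panel_boost mean multiplier for cycle-panel genes in
#'   cycling cells.
#' @param lowq_fraction fraction of all cells planted as low-quality.
#' @param lowq_gene_cap maximum number of genes with nonzero counts in a
#'   low-quality cell; must stay below the QC detected-gene threshold
#'   (3000) so planted low-quality cells must fail QC.
#' @param barcode_len,umi_len lengths of the cell barcode and UMI carried
#'   on read 2.
#' @param tso_seq template-switch oligo sequence used as read-1
#'   contamination.
#' @param polya_contam_rate fraction of read-1 sequences carrying a 3'
#'   poly(A) contamination tail.
#' @param gene_ids optional character vector of gene ids (length
#'   `n_genes`); invented ids are generated when omitted.
#' @param seed integer seed; identical spec + seed reproduces identical
#'   output from all generators.
#'
#' @return an object of class `synthetic_spec`.
#' @seealso [simulate_counts()], [simulate_fastq()],
#'   [default_placenta_spec()]
#' @export
synthetic_spec <- function(n_genes,
                           subtypes = list(),
                           baseline_mean = 3,
                           gene_mean_sdlog = 2.5,
                           dispersion = 2,
                           cycling_fraction = 0,
                           cycle_genes = character(),
                           cycle_panel_boost = 6,
                           lowq_fraction = 0,
                           lowq_gene_cap = 500,
                           barcode_len = 8L,
                           umi_len = 8L,
                           tso_seq = "AAGCAGTGGTATCAACGCAGAGT",
                           polya_contam_rate = 0,
                           gene_ids = NULL,
                           seed = 1L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 0 ||
      n_genes != floor(n_genes)) {
    stop("`n_genes` must be a single non-negative integer")
  }
  n_genes <- as.integer(n_genes)
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("G%05d", seq_len(n_genes))
  }
  if (length(gene_ids) != n_genes || anyDuplicated(gene_ids)) {
    stop("`gene_ids` must be ", n_genes, " unique ids")
  }

  stopifnot(is.list(subtypes))
  for (st in subtypes) {
    if (is.null(st$name) || is.null(st$n_cells) || is.null(st$marker_genes) ||
        is.null(st$marker_fold)) {
      stop("each subtype needs `name`, `n_cells`, `marker_genes`, `marker_fold`")
    }
    if (!is.numeric(st$n_cells) || st$n_cells < 1 ||
        st$n_cells != floor(st$n_cells)) {
      stop("subtype `", st$name, "`: `n_cells` must be a positive integer")
    }
    if (!is.numeric(st$marker_fold) || st$marker_fold <= 0) {
      stop("subtype `", st$name, "`: `marker_fold` must be positive")
    }
    bad <- setdiff(st$marker_genes, gene_ids)
    if (length(bad)) {
      stop("subtype `", st$name, "`: marker genes outside the gene universe: ",
           paste(head(bad, 5), collapse = ", "))
    }
    if (!is.null(st$cycling_fraction) &&
        (st$cycling_fraction < 0 || st$cycling_fraction > 1)) {
      stop("subtype `", st$name, "`: `cycling_fraction` must be in [0, 1]")
    }
  }
  nm <- vapply(subtypes, function(s) s$name, character(1))
  if (anyDuplicated(nm)) stop("subtype names must be unique")

  check_frac <- function(x, what) {
    if (!is.numeric(x) || any(x < 0) || any(x > 1)) {
      stop("`", what, "` must lie in [0, 1]")
    }
  }
  check_frac(cycling_fraction, "cycling_fraction")
  check_frac(lowq_fraction, "lowq_fraction")
  check_frac(polya_contam_rate, "polya_contam_rate")
  stopifnot(baseline_mean > 0, dispersion > 0, cycle_panel_boost > 0,
            gene_mean_sdlog >= 0)
  bad_cyc <- setdiff(cycle_genes, gene_ids)
  if (length(bad_cyc)) {
    stop("cycle-panel genes outside the gene universe: ",
         paste(head(bad_cyc, 5), collapse = ", "))
  }
  if (lowq_gene_cap < 1 || lowq_gene_cap >= 3000) {
    stop("`lowq_gene_cap` must be a positive integer below 3000 (the QC gene threshold)")
  }
  if (barcode_len < 1 || umi_len < 1) stop("tag lengths must be positive")
  if (!grepl("^[ACGT]*$", tso_seq)) stop("`tso_seq` must be a DNA string")
  seed <- as.integer(seed)

  structure(list(
    n_genes = n_genes, gene_ids = gene_ids, subtypes = subtypes,
    baseline_mean = baseline_mean, gene_mean_sdlog = gene_mean_sdlog,
    dispersion = dispersion, cycling_fraction = cycling_fraction,
    cycle_genes = cycle_genes, cycle_panel_boost = cycle_panel_boost,
    lowq_fraction = lowq_fraction, lowq_gene_cap = as.integer(lowq_gene_cap),
    barcode_len = as.integer(barcode_len), umi_len = as.integer(umi_len),
    tso_seq = tso_seq, polya_contam_rate = polya_contam_rate, seed = seed
  ), class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  n_cells <- sum(vapply(x$subtypes, function(s) s$n_cells, numeric(1)))
  cat("synthetic_spec:", x$n_genes, "genes,", length(x$subtypes),
      "subtypes,", n_cells, "cells\n")
  invisible(x)
}

# pad a vector of real gene symbols with invented ids up to n markers
pad_markers <- function(symbols, prefix, n) {
  extra <- n - length(symbols)
  if (extra <= 0) return(symbols[seq_len(n)])
  c(symbols, sprintf("%s%03d", prefix, seq_len(extra)))
}

#' Default synthetic experiment emulating a sorted-placenta study
#'
#' Builds a [synthetic_spec()] with 7 planted cell populations carrying 14
#' leaf subtypes (three cytotrophoblast, three first-trimester and two
#' second-trimester extravillous trophoblast, one syncytiotrophoblast, two
#' macrophage, two mesenchymal and one blood subtype), 1567 cells in
#' total, about 6% planted low-quality cells, and subtype-specific
#' cycling fractions (highest in the proliferative CTB and EVT subtypes).
#' Each population shares a block of population markers (containing its
#' canonical sorting/annotation genes, e.g. CDH1/EGFR for CTB, HLA-G/MMP2
#' for EVT, CGB/CSH1 for STB, CD14/CD68 for macrophages, THY1/ENG for
#' mesenchymal cells, HBB for blood) and every subtype adds its own
#' marker block.  The shipped hormone and imprinted panel genes are
#' embedded in the relevant marker blocks so panel detection is
#' exercised end to end.
#'
#' @param n_genes size of the gene universe.
#' @param marker_fold planted marker fold change.
#' @param cells_per_subtype optional named integer vector overriding the
#'   default subtype sizes (names must match the 14 subtype names).
#' @param pop_markers,sub_markers number of shared population-level and
#'   subtype-specific marker genes.
#' @param lowq_fraction fraction of planted low-quality cells.
#' @param ... further arguments passed to [synthetic_spec()].
#' @return a `synthetic_spec`.
#' @export
default_placenta_spec <- function(n_genes = 20000,
                                  marker_fold = 8,
                                  cells_per_subtype = NULL,
                                  pop_markers = 200,
                                  sub_markers = 120,
                                  lowq_fraction = 0.061,
                                  ...) {
  sizes <- c(
    CTB_8W_1 = 130, CTB_8W_2 = 120, CTB_8W_3 = 120,
    EVT_8W_1 = 100, EVT_8W_2 = 95,  EVT_8W_3 = 95,
    EVT_24W_1 = 115, EVT_24W_2 = 100,
    STB_8W = 120,
    Macro_1 = 110, Macro_2 = 110,
    Mes_1 = 125, Mes_2 = 125,
    Blood = 102
  )
  if (!is.null(cells_per_subtype)) {
    stopifnot(setequal(names(cells_per_subtype), names(sizes)))
    sizes[names(cells_per_subtype)] <- cells_per_subtype
  }
  cycling <- c(
    CTB_8W_1 = 0.02, CTB_8W_2 = 0.05, CTB_8W_3 = 0.60,
    EVT_8W_1 = 0.50, EVT_8W_2 = 0.10, EVT_8W_3 = 0.02,
    EVT_24W_1 = 0.05, EVT_24W_2 = 0.05,
    STB_8W = 0,
    Macro_1 = 0.05, Macro_2 = 0.05,
    Mes_1 = 0.10, Mes_2 = 0.10,
    Blood = 0.02
  )

  troph <- pad_markers(c("KRT7", "TFAP2C", "GATA3"), "TRO", 40)
  pops <- list(
    CTB = pad_markers(c("CDH1", "EGFR", "TP63", "ITGA6", "PEG3", "PEG10",
                        "MEST", "DNMT1", "TET2"), "CTB", pop_markers),
    EVT8 = pad_markers(c("HLA-G", "MMP2", "ITGA5", "FN1", "TET1", "TET3",
                         "ASCL2", "GRB10", "H19", "IGF2", "GPR1"),
                       "EV8", pop_markers),
    EVT24 = pad_markers(c("HLA-G", "MMP2", "TAC3", "SERPINE1", "PRG2",
                          "JAM2", "PAPPA2", "FSTL1", "FSTL3", "PTHLH",
                          "AICDA"), "E24", pop_markers),
    STB = pad_markers(c("CGA", "CGB", "CGB1", "CGB2", "CGB5", "CGB7",
                        "CGB8", "CSH1", "CSH2", "CSHL1", "GH2", "INSL4",
                        paste0("PSG", 1:9), "LEP", "CRH", "ADM", "KISS1",
                        "GDF15", "INHBA", "ERVFRD-1", "GCM1", "ZNF331",
                        "TFPI2", "PPP1R9A", "ANO1", "RHOBTB3", "RPS6KA5"),
                      "STB", pop_markers),
    Macro = pad_markers(c("CD14", "CD68", "VIM", "HLA-A", "AIF1", "CD53"),
                        "MAC", pop_markers),
    Mes = pad_markers(c("THY1", "ENG", "VIM", "HLA-A", "COL1A1", "COL3A1",
                        "PDGFRB", "ANGPTL1", "ANGPTL2", "ANGPTL4", "CTGF",
                        "ACTN1", "VGF", "NPPB", "EDN1", "RLN2"),
                      "MES", pop_markers),
    Blood = pad_markers(c("HBB", "HBA1", "HBA2", "HBG1", "HBG2", "ALAS2",
                          "GYPA"), "BLD", pop_markers)
  )
  subs <- list(
    CTB_8W_1 = c("ERVFRD-1", "GCM1", "INSL4", "CGA", "SLC1A5", "FZD5", "WNT2"),
    CTB_8W_2 = c("SP1"),
    CTB_8W_3 = c("RRM2", "CCNB1", "CDK1"),
    EVT_8W_1 = c("RRM2", "AURKB", "BUB1", "PPP2CA"),
    EVT_8W_2 = character(),
    EVT_8W_3 = c("TAC3", "SERPINE1", "PRG2", "JAM2", "PRKCD", "KDM4B", "DUSP1"),
    EVT_24W_1 = c("TAC3", "PLAU"),
    EVT_24W_2 = c("CSH1", "PSG3", "PAPPA"),
    STB_8W = character(),
    Macro_1 = c("CD74", "CTSS", "LYZ", "HLA-DRA", "HLA-DRB1"),
    Macro_2 = c("MRC1", "APOE", "C1QC", "CSF1R", "DAB2"),
    Mes_1 = c("CD74", "ITGB1", "CAV1"),
    Mes_2 = c("DLK1", "MEG3", "PLAGL1", "KCNQ1OT1", "PHACTR2", "MEST1", "IGF2"),
    Blood = character()
  )
  pop_of <- c(
    CTB_8W_1 = "CTB", CTB_8W_2 = "CTB", CTB_8W_3 = "CTB",
    EVT_8W_1 = "EVT8", EVT_8W_2 = "EVT8", EVT_8W_3 = "EVT8",
    EVT_24W_1 = "EVT24", EVT_24W_2 = "EVT24",
    STB_8W = "STB", Macro_1 = "Macro", Macro_2 = "Macro",
    Mes_1 = "Mes", Mes_2 = "Mes", Blood = "Blood"
  )
  subs <- lapply(names(subs), function(s) {
    pad_markers(subs[[s]], paste0("S", gsub("[^A-Za-z0-9]", "", s)),
                sub_markers)
  })
  names(subs) <- names(pop_of)

  # remaining imprinted-panel genes expressed broadly across trophoblast
  imprinted_extra <- c("PHLDA2", "CDKN1C", "NNAT", "NDN", "SNRPN", "GNAS",
                       "NAP1L5", "OSBPL5", "SLC22A18", "CD81", "MKRN3",
                       "MAGEL2", "ZIM2")
  troph <- unique(c(troph, imprinted_extra))

  cc <- cell_cycle_panel()
  cycle_genes <- unique(c(cc$g1s_genes, cc$g2m_genes))

  named <- unique(c(troph, unlist(pops), unlist(subs), cycle_genes))
  if (length(named) >= n_genes) {
    stop("`n_genes` too small for the default marker layout")
  }
  gene_ids <- c(named, sprintf("G%05d", seq_len(n_genes - length(named))))

  subtypes <- lapply(names(pop_of), function(s) {
    mk <- unique(c(
      if (pop_of[[s]] %in% c("CTB", "EVT8", "EVT24", "STB")) troph,
      pops[[pop_of[[s]]]], subs[[s]]
    ))
    list(name = s, n_cells = unname(sizes[[s]]), marker_genes = mk,
         marker_fold = marker_fold,
         cycling_fraction = unname(cycling[[s]]))
  })

  synthetic_spec(
    n_genes = n_genes, gene_ids = gene_ids, subtypes = subtypes,
    cycle_genes = cycle_genes, lowq_fraction = lowq_fraction, ...
  )
}
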