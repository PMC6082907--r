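# shared synthetic-spec builders for the test suite

# two well-separated blobs
two_blob_spec <- function(n_cells = 50, n_genes = 600, fold = 8, seed = 1) {
  ids <- sprintf("G%05d", seq_len(n_genes))
  synthetic_spec(
    n_genes = n_genes,
    subtypes = list(
      list(name = "A", n_cells = n_cells, marker_genes = ids[1:60],
           marker_fold = fold),
      list(name = "B", n_cells = n_cells, marker_genes = ids[61:120],
           marker_fold = fold)
    ),
    seed = seed
  )
}

# one homogeneous blob (no planted structure)
null_spec <- function(n_cells = 150, n_genes = 1000, seed = 1) {
  synthetic_spec(
    n_genes = n_genes,
    subtypes = list(list(name = "A", n_cells = n_cells,
                         marker_genes = character(), marker_fold = 1)),
    seed = seed
  )
}

# 7 populations with nested subtypes (14 leaf labels): every population
# shares a 100-gene marker block, every subtype adds its own 50 genes
nested_spec <- function(n_genes = 2000, fold = 8, n_cells = 50, seed = 1) {
  pops <- list(P1 = c("A", "B", "C"), P2 = c("D", "E", "F"),
               P3 = c("G", "H"), P4 = "I", P5 = c("J", "K"),
               P6 = c("L", "M"), P7 = "N")
  ids <- sprintf("G%05d", seq_len(n_genes))
  nxt <- 1L
  take <- function(k) { out <- ids[nxt:(nxt + k - 1L)]; nxt <<- nxt + k; out }
  subtypes <- list()
  for (p in names(pops)) {
    pm <- take(100L)
    for (s in pops[[p]]) {
      subtypes[[length(subtypes) + 1L]] <-
        list(name = paste0(p, "_", s), n_cells = n_cells,
             marker_genes = c(pm, take(50L)), marker_fold = fold)
    }
  }
  synthetic_spec(n_genes = n_genes, subtypes = subtypes, seed = seed)
}

# full-universe spec with planted cycling cells; the planted panel is
# its own gene set, independent of the shipped curated list
cycling_spec <- function(n_cells = 100, cycling_fraction = 0.4,
                         n_genes = 20000, seed = 1) {
  ids <- sprintf("G%05d", seq_len(n_genes))
  panel <- ids[1:90]
  spec <- synthetic_spec(
    n_genes = n_genes,
    subtypes = list(list(name = "A", n_cells = n_cells,
                         marker_genes = character(), marker_fold = 1,
                         cycling_fraction = cycling_fraction)),
    cycle_genes = panel,
    seed = seed
  )
  list(spec = spec, panel = structure(
    list(g1s_genes = panel[1:45], g2m_genes = panel[46:90],
         threshold = 100, mode = "mean_expression"),
    class = "cell_cycle_panel"))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
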