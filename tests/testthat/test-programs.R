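toy_panel <- function(genes, threshold = 100, mode = "mean_expression") {
  half <- length(genes) %/% 2
  structure(list(g1s_genes = genes[seq_len(half)],
                 g2m_genes = genes[(half + 1):length(genes)],
                 threshold = threshold, mode = mode),
            class = "cell_cycle_panel")
}

test_that("cycling classification is inclusive at the mean threshold", {
  genes <- paste0("cc", 1:4)
  expr <- matrix(0, nrow = 6, ncol = 3,
                 dimnames = list(c(genes, "g1", "g2"), paste0("c", 1:3)))
  expr[genes, 2] <- 100       # mean exactly at threshold -> cycling
  expr[genes, 3] <- 99.9
  fl <- cycling_cells(expr, toy_panel(genes))
  expect_identical(unname(fl), c(FALSE, TRUE, FALSE))

  # count mode is strict ("over" the threshold)
  expr2 <- matrix(0, nrow = 8, ncol = 3,
                  dimnames = list(paste0("cc", 1:8), paste0("c", 1:3)))
  expr2[1:3, 2] <- 10       # 3 genes expressed
  expr2[1:4, 3] <- 10       # 4 genes expressed
  fl2 <- cycling_cells(expr2, toy_panel(paste0("cc", 1:8), threshold = 3,
                                        mode = "n_genes_expressed"))
  expect_identical(unname(fl2), c(FALSE, FALSE, TRUE))

  expect_error(cycling_cells(expr[5:6, , drop = FALSE], toy_panel(genes)),
               "no cell-cycle panel gene")
})

test_that("planted cycling cells are classified at >= 98% sens/spec", {
  cs <- cycling_spec(n_cells = 150, cycling_fraction = 0.4, seed = 61)
  sim <- simulate_counts(cs$spec)
  expr <- tpm_normalize(sim$counts)
  fl <- cycling_cells(expr, cs$panel)
  expect_gte(mean(fl[sim$truth$cycling]), 0.98)
  expect_gte(mean(!fl[!sim$truth$cycling]), 0.98)
})

test_that("cycling_ratio reports per-cluster fractions, unassigned apart", {
  flags <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
             FALSE, FALSE, TRUE, FALSE)
  labels <- c(rep(1L, 10), 0L, 0L)
  cr <- cycling_ratio(flags, labels)
  expect_equal(unname(cr["1"]), 0.3)
  expect_equal(unname(cr["unassigned"]), 0.5)
  expect_equal(unname(cycling_ratio(rep(FALSE, 5), rep(2L, 5))["2"]), 0)
})

test_that("an all-or-nothing marker pins the rank-sum statistic", {
  # gene at TPM 100 in all 20 cluster cells, 0 in the other 20
  expr <- matrix(50, nrow = 3, ncol = 40,
                 dimnames = list(paste0("g", 1:3), paste0("c", 1:40)))
  expr["g1", ] <- c(rep(100, 20), rep(0, 20))
  set.seed(30)
  expr["g2", ] <- runif(40, 40, 60)
  grp <- setNames(rep(c("in", "out"), each = 20), colnames(expr))
  mt <- find_markers(expr, grp, "in", min_log2fc = 0.25, min_pct = 0.1)
  row <- mt[mt$gene == "g1", ]
  expect_equal(row$pct_out, 0)
  expect_equal(row$pct_in, 1)
  # statistic at its extremum: the smallest p any gene can reach here
  expect_lt(row$p_value, 1e-8)
  expect_equal(row$p_value, min(mt$p_value))
  expect_identical(mt$gene[1], "g1")               # sorted first by q

  # tie-free analogue at n = 8 + 8: p matches exact enumeration
  set.seed(31)
  x <- rlnorm(8, 5, 0.3); y <- rlnorm(8, 3, 0.3)
  expr2 <- rbind(g1 = c(x, y), g2 = runif(16, 40, 60))
  colnames(expr2) <- paste0("c", 1:16)
  grp2 <- setNames(rep(c("in", "out"), each = 8), colnames(expr2))
  mt2 <- find_markers(expr2, grp2, "in", min_log2fc = 0, min_pct = 0)
  expect_equal(mt2$p_value[mt2$gene == "g1"],
               oracle_wilcox_exact(log2(x + 1), log2(y + 1)))
})

test_that("p-values match exact enumeration for small tie-free groups", {
  set.seed(32)
  for (n in c(5, 8, 10)) {
    x <- matrix(rlnorm(20 * 2 * n, 3, 1), nrow = 20)
    dimnames(x) <- list(paste0("g", 1:20), paste0("c", seq_len(2 * n)))
    grp <- setNames(rep(c("A", "B"), each = n), colnames(x))
    mt <- find_markers(x, grp, "A", min_log2fc = 0, min_pct = 0)
    for (g in mt$gene[1:10]) {
      pe <- oracle_wilcox_exact(log2(x[g, grp == "A"] + 1),
                                log2(x[g, grp == "B"] + 1))
      pa <- mt$p_value[mt$gene == g]
      expect_lt(abs(pa - pe) / pe, 0.10)
    }
  }
})

test_that("type-I error sits near 5% on an exchangeable null", {
  set.seed(33)
  G <- 1000; n <- 50
  counts <- matrix(rnbinom(G * n, size = 2, mu = 3), G, n,
                   dimnames = list(sprintf("g%04d", 1:G), sprintf("c%03d", 1:n)))
  expr <- tpm_normalize(counts)
  grp <- setNames(rep(c("A", "B"), each = n / 2), colnames(expr))
  mt <- find_markers(expr, grp, "A", min_log2fc = 0, min_pct = 0)
  frac <- mean(mt$p_value < 0.05)
  # 3.5 Monte-Carlo standard errors around the nominal level
  expect_gt(frac, 0.05 - 3.5 * sqrt(0.05 * 0.95 / G))
  expect_lt(frac, 0.05 + 3.5 * sqrt(0.05 * 0.95 / G))
})

test_that("BH q-values are monotone in p and never below them", {
  sim <- simulate_counts(two_blob_spec(n_cells = 15, n_genes = 500, seed = 34))
  expr <- tpm_normalize(sim$counts)
  mt <- find_markers(expr, setNames(sim$truth$subtype, sim$truth$cell_id), "A")
  expect_true(all(mt$fdr_q >= mt$p_value - 1e-12))
  o <- order(mt$p_value)
  expect_true(all(diff(mt$fdr_q[o]) >= -1e-12))
})

test_that("planted markers are recovered at q < 0.05 with the right sign", {
  sim <- simulate_counts(two_blob_spec(n_cells = 30, n_genes = 500,
                                       fold = 8, seed = 35))
  expr <- tpm_normalize(sim$counts)
  grp <- setNames(sim$truth$subtype, sim$truth$cell_id)
  mt <- find_markers(expr, grp, "A")
  planted <- sprintf("G%05d", 1:60)
  hits <- mt[mt$gene %in% planted, ]
  expect_identical(nrow(hits), 60L)
  expect_true(all(hits$fdr_q < 0.05))
  expect_true(all(hits$log2_fold_change > 0))
})

test_that("find_all_markers concatenates one-vs-rest runs symmetrically", {
  sim <- simulate_counts(two_blob_spec(n_cells = 20, n_genes = 400, seed = 36))
  expr <- tpm_normalize(sim$counts)
  grp <- setNames(sim$truth$subtype, sim$truth$cell_id)
  all_mt <- find_all_markers(expr, grp)
  a <- find_markers(expr, grp, "A")
  b <- find_markers(expr, grp, "B")
  expect_identical(all_mt, rbind(a, b))
  # two-cluster symmetry: the same genes appear with flipped folds
  shared <- intersect(a$gene, b$gene)
  expect_gt(length(shared), 0)
  expect_equal(a$log2_fold_change[match(shared, a$gene)],
               -b$log2_fold_change[match(shared, b$gene)])
  expect_equal(a$p_value[match(shared, a$gene)],
               b$p_value[match(shared, b$gene)])
})

test_that("panel detection applies the strict TPM > 2 in >= 30 cells rule", {
  n <- 1000
  expr <- matrix(0, nrow = 3, ncol = n,
                 dimnames = list(c("at2", "in30", "in29"), paste0("c", 1:n)))
  expr["at2", ] <- 2                       # exactly 2.0 everywhere
  expr["in30", 1:30] <- 2.1
  expr["in29", 1:29] <- 2.1
  res <- panel_detect(expr, c("at2", "in30", "in29"))
  expect_identical(res$detected_genes, "in30")

  # monotone in both thresholds
  res_lo <- panel_detect(expr, c("at2", "in30", "in29"), min_tpm = 1.5)
  expect_true(all(res$detected_genes %in% res_lo$detected_genes))
  res_fewer <- panel_detect(expr, c("at2", "in30", "in29"), min_cells = 29)
  expect_true(all(res$detected_genes %in% res_fewer$detected_genes))
  expect_true("in29" %in% res_fewer$detected_genes)
})

test_that("per-subtype panel summaries average log expression", {
  expr <- matrix(c(10, 100, 1000, 10, 100, 1000), nrow = 1,
                 dimnames = list("h1", paste0("c", 1:6)))
  expr <- rbind(expr, other = 5)
  res <- panel_detect(expr, "h1", min_tpm = 2, min_cells = 2,
                      assignment = rep(c("s1", "s2"), each = 3))
  expect_equal(res$subtype_means["h1", "s1"],
               mean(log2(c(10, 100, 1000) + 1)))
})

test_that("shipped panels load with provenance columns", {
  hp <- load_gene_panel("hormone")
  ip <- load_gene_panel("imprinted")
  expect_true(all(c("gene", "class", "source") %in% names(hp)))
  expect_gt(nrow(hp), 40)
  expect_gt(nrow(ip), 25)
  expect_error(load_gene_panel("nonexistent"), "unknown panel")
})
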