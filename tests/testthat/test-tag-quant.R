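make_layout <- function(wl = c(cellA = "ACGTACGT", cellB = "TTTTCCCC"),
                        ...) {
  library_layout(whitelist = wl, ...)
}

test_that("extract_tags pulls barcode and UMI at the configured offsets", {
  layout <- make_layout()
  tags <- extract_tags("ACGTACGTTTTTCCCC", layout)
  expect_identical(tags$barcode, "ACGTACGT")
  expect_identical(tags$umi, "TTTTCCCC")

  layout6 <- library_layout(whitelist = c(c1 = "AAAAAA"),
                            barcode_len = 6, umi_len = 6)
  tags6 <- extract_tags("AAAAAACCCCCCGG", layout6)
  expect_identical(tags6$barcode, "AAAAAA")
  expect_identical(tags6$umi, "CCCCCC")
})

test_that("reads too short for the tag intervals are skipped and tallied", {
  layout <- make_layout()
  tags <- extract_tags(c("ACGTACGTTT", "ACGTACGTTTTTCCCC"), layout)
  expect_true(is.na(tags$barcode[1]))
  expect_identical(attr(tags, "too_short"), 1L)
})

test_that("barcode assignment follows exact, rescue and tie rules", {
  wl <- c(cellA = "AAAAAAAA", cellB = "CCCCCCCC")
  exact <- library_layout(whitelist = wl, max_mismatch = 0)
  expect_identical(assign_barcode("AAAAAAAA", exact), "cellA")
  expect_true(is.na(assign_barcode("AAAAAAAT", exact)))

  rescue <- library_layout(whitelist = wl, max_mismatch = 1)
  expect_identical(assign_barcode("AAAAAAAT", rescue), "cellA")
  # equidistant from two entries -> unassigned
  wl2 <- c(x = "AAAAAAAA", y = "AAAAAAAT")
  tie <- library_layout(whitelist = wl2, max_mismatch = 1)
  expect_true(is.na(assign_barcode("AAAAAAAC", tie)))
})

test_that("library_layout validates intervals and whitelist", {
  expect_error(library_layout(whitelist = c(a = "ACGT"), barcode_len = 8),
               "length")
  expect_error(library_layout(whitelist = character(), barcode_len = 8,
                              umi_offset = 4, umi_len = 8), "overlap")
})

test_that("trim_read1 implements the TSO / poly(A) / quality rules", {
  tso <- "AAGCAGTGGTATCAACGCAGAGT"
  clean <- paste0(strrep("ACGT", 12), "CC")  # 50 bp, no TSO, no poly(A)
  expect_identical(unclass(trim_read1(clean))[1], clean)

  # poly(A) tail of 12 removed from an 8-mer core (with padding to pass
  # the length floor disabled via min_len)
  polya <- paste0("ACGTACGT", strrep("A", 12))
  expect_identical(unclass(trim_read1(polya, min_len = 5))[1], "ACGTACGT")

  # exact TSO prefix removed; one mismatch also removed
  body <- strrep("CCGGTT", 10)
  expect_identical(unclass(trim_read1(paste0(tso, body)))[1], body)
  tso_mm <- paste0("T", substr(tso, 2, nchar(tso)))
  expect_identical(unclass(trim_read1(paste0(tso_mm, body)))[1], body)

  # low-quality 3' bases trimmed
  seqq <- paste0(strrep("ACGT", 10), "GGGG")
  qual <- paste0(strrep("I", 40), strrep("#", 4))
  expect_identical(unclass(trim_read1(seqq, qual))[1], strrep("ACGT", 10))

  # reads shorter than min_len after trimming are dropped and tallied
  short <- trim_read1(paste0("ACGTAC", strrep("A", 20)), min_len = 30)
  expect_true(is.na(short[1]))
  expect_identical(attr(short, "dropped"), 1L)
})

test_that("count_umis collapses duplicate UMIs inside each gene only", {
  tab <- data.frame(
    read_id = paste0("r", 1:7),
    cell_id = "c1",
    umi = c("U1", "U1", "U1", "U2", "U2", "U3", "U3"),
    gene_id = c("g1", "g1", "g1", "g1", "g1", "g1", "g2"),
    unique_flag = TRUE, stringsAsFactors = FALSE
  )
  m <- count_umis(tab)
  expect_identical(m["g1", "c1"], 3L)  # U1, U2, U3
  expect_identical(m["g2", "c1"], 1L)  # same UMI, different gene

  tab5 <- tab[1:5, ]
  expect_identical(count_umis(tab5)["g1", "c1"], 2L)
})

test_that("count_umis drops multimapped reads and flags malformed rows", {
  tab <- data.frame(read_id = c("r1", "r2"), cell_id = "c1",
                    umi = c("U1", "U2"), gene_id = "g1",
                    unique_flag = c(TRUE, FALSE), stringsAsFactors = FALSE)
  expect_identical(count_umis(tab)["g1", "c1"], 1L)

  bad <- tab; bad$umi[2] <- NA
  expect_error(count_umis(bad), "row")
})

test_that("count_umis matches the brute-force oracle on random tables", {
  set.seed(7)
  genes <- paste0("g", 1:6); cells <- paste0("c", 1:4)
  for (rep in 1:20) {
    n <- 120
    tab <- data.frame(
      read_id = paste0("r", seq_len(n)),
      cell_id = sample(cells, n, replace = TRUE),
      umi = sample(paste0("U", 1:8), n, replace = TRUE),
      gene_id = sample(genes, n, replace = TRUE),
      unique_flag = sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(.9, .1)),
      stringsAsFactors = FALSE
    )
    expect_identical(count_umis(tab, genes, cells),
                     oracle_count_umis(tab, genes, cells))
  }
})

test_that("adding duplicate reads never changes the UMI counts", {
  set.seed(8)
  n <- 200
  tab <- data.frame(
    read_id = paste0("r", seq_len(n)),
    cell_id = sample(paste0("c", 1:5), n, replace = TRUE),
    umi = sample(paste0("U", 1:10), n, replace = TRUE),
    gene_id = sample(paste0("g", 1:8), n, replace = TRUE),
    unique_flag = TRUE, stringsAsFactors = FALSE
  )
  dup <- tab[sample(n, 80, replace = TRUE), ]
  dup$read_id <- paste0("d", seq_len(nrow(dup)))
  both <- rbind(tab, dup)
  expect_identical(count_umis(tab), count_umis(both))
})

test_that("tpm_normalize rescales each cell to one million", {
  counts <- matrix(c(2L, 3L, 5L, 0L, 0L, 0L, 4L, 0L, 0L), nrow = 3,
                   dimnames = list(paste0("g", 1:3), paste0("c", 1:3)))
  tpm <- tpm_normalize(counts)
  expect_equal(tpm[, "c1"], c(g1 = 2e5, g2 = 3e5, g3 = 5e5))
  expect_equal(tpm["g1", "c3"], 1e6)            # single expressed gene
  expect_identical(attr(tpm, "zero_cells"), "c2")
  expect_true(all(tpm[, "c2"] == 0))

  set.seed(1)
  big <- matrix(rpois(600, 3), nrow = 30,
                dimnames = list(paste0("g", 1:30), paste0("c", 1:20)))
  sums <- colSums(tpm_normalize(big))
  expect_true(all(abs(sums[sums > 0] - 1e6) <= 1e-9 * 1e6))
})

test_that("tpm_normalize preserves within-cell rank order", {
  set.seed(2)
  counts <- matrix(rpois(200, 5), nrow = 20,
                   dimnames = list(paste0("g", 1:20), paste0("c", 1:10)))
  tpm <- tpm_normalize(counts)
  for (j in seq_len(ncol(counts))) {
    expect_identical(order(counts[, j]), order(tpm[, j]))
  }
})

test_that("mito_ratio covers the trivial and hand-tallied cases", {
  counts <- matrix(c(5L, 2L, 3L, 4L, 0L, 0L), nrow = 3,
                   dimnames = list(c("MT-1", "g1", "g2"), c("c1", "c2")))
  r <- mito_ratio(counts, "MT-1")
  expect_equal(unname(r["c1"]), 5 / 10)
  expect_equal(unname(r["c2"]), 1)
  expect_equal(unname(mito_ratio(counts, "g1")["c2"]), 0)
  zero <- counts; zero[, 2] <- 0L
  expect_true(is.na(mito_ratio(zero, "MT-1")["c2"]))

  # 10-row read-level table, hand count: c1 has 4 reads, 1 mito
  tab <- data.frame(
    cell_id = c(rep("c1", 4), rep("c2", 6)),
    gene_id = c("MT-1", "g1", "g2", "g1", rep("MT-1", 3), "g1", "g2", "g2"),
    stringsAsFactors = FALSE
  )
  rr <- mito_ratio(tab, "MT-1")
  expect_equal(unname(rr["c1"]), 1 / 4)
  expect_equal(unname(rr["c2"]), 3 / 6)
})
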