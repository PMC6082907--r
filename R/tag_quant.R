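#' Library tag layout for barcode/UMI demultiplexing
#'
#' Describes where the cell barcode and UMI sit on read 2, together with
#' the barcode whitelist of the library and the mismatch tolerance used
#' when matching observed barcodes against it.
#'
#' @param whitelist named character vector: values are barcode sequences,
#'   names the corresponding cell ids.
#' @param barcode_offset,barcode_len 0-based offset and length of the
#'   cell barcode on read 2.
#' @param umi_offset,umi_len 0-based offset and length of the UMI;
#'   defaults to immediately after the barcode.
#' @param max_mismatch maximum Hamming distance for barcode rescue; 0
#'   (the default) requires exact whitelist matches.
#' @return an object of class `library_layout`.
#' @export
library_layout <- function(whitelist,
                           barcode_offset = 0L, barcode_len = 8L,
                           umi_offset = NULL, umi_len = 8L,
                           max_mismatch = 0L) {
  stopifnot(barcode_offset >= 0, barcode_len >= 1, umi_len >= 1,
            max_mismatch >= 0)
  if (is.null(umi_offset)) umi_offset <- barcode_offset + barcode_len
  b <- c(barcode_offset, barcode_offset + barcode_len)   # [start, end)
  u <- c(umi_offset, umi_offset + umi_len)
  if (max(b[1], u[1]) < min(b[2], u[2])) {
    stop("barcode and UMI intervals overlap")
  }
  if (length(whitelist)) {
    if (any(nchar(whitelist) != barcode_len)) {
      stop("whitelist entries must all have length `barcode_len`")
    }
    if (is.null(names(whitelist))) {
      names(whitelist) <- paste0("cell_", seq_along(whitelist))
    }
    if (anyDuplicated(whitelist)) stop("whitelist barcodes must be unique")
  }
  structure(list(barcode_offset = as.integer(barcode_offset),
                 barcode_len = as.integer(barcode_len),
                 umi_offset = as.integer(umi_offset),
                 umi_len = as.integer(umi_len),
                 whitelist = whitelist,
                 max_mismatch = as.integer(max_mismatch)),
            class = "library_layout")
}

#' Extract the cell barcode and UMI from read 2
#'
#' Pulls the barcode and UMI substrings at the offsets configured in the
#' layout.  Reads too short to contain both intervals yield `NA` tags and
#' are counted in the `too_short` attribute.
#'
#' @param read2_seq character vector of read-2 sequences.
#' @param layout a [library_layout()].
#' @return data frame with columns `barcode` and `umi` (NA for skipped
#'   reads); attribute `too_short` holds the skip tally.
#' @export
extract_tags <- function(read2_seq, layout) {
  need <- max(layout$barcode_offset + layout$barcode_len,
              layout$umi_offset + layout$umi_len)
  ok <- nchar(read2_seq) >= need
  barcode <- ifelse(ok, substr(read2_seq, layout$barcode_offset + 1L,
                               layout$barcode_offset + layout$barcode_len),
                    NA_character_)
  umi <- ifelse(ok, substr(read2_seq, layout$umi_offset + 1L,
                           layout$umi_offset + layout$umi_len),
                NA_character_)
  out <- data.frame(barcode = barcode, umi = umi, stringsAsFactors = FALSE)
  attr(out, "too_short") <- sum(!ok)
  out
}

# vectorized Hamming distance between equal-length strings and one probe
hamming_to <- function(x, probe) {
  L <- nchar(probe)
  d <- integer(length(x))
  for (j in seq_len(L)) {
    d <- d + (substr(x, j, j) != substr(probe, j, j))
  }
  d
}

#' Match an observed barcode against the whitelist
#'
#' An exact whitelist match wins.  Otherwise, when `max_mismatch >= 1`,
#' the unique whitelist entry within Hamming distance `max_mismatch`
#' wins; ties (two entries equally close) leave the read unassigned.
#'
#' @param barcode character vector of observed barcodes.
#' @param layout a [library_layout()].
#' @return character vector of cell ids; `NA` means unassigned.
#' @export
assign_barcode <- function(barcode, layout) {
  wl <- layout$whitelist
  cell <- names(wl)[match(barcode, wl)]
  if (layout$max_mismatch >= 1L) {
    todo <- which(is.na(cell) & !is.na(barcode))
    for (i in todo) {
      d <- hamming_to(wl, barcode[i])
      near <- which(d <= layout$max_mismatch)
      if (length(near) == 1L) cell[i] <- names(wl)[near]
    }
  }
  cell
}

#' Trim TSO, poly(A) and low-quality tails from read 1
#'
#' Removes a TSO prefix (at most one mismatch allowed), then cuts the
#' read at the start of the leftmost run of `A` of length at least
#' `min_polya_run` (everything 3' of the run is discarded with it), then
#' trims trailing bases with Phred quality below `min_qual`.  Reads
#' shorter than `min_len` after trimming are dropped (returned as `NA`
#' and tallied in the `dropped` attribute).
#'
#' @param seq character vector of read-1 sequences.
#' @param quals matching Phred+33 quality strings; `NULL` skips quality
#'   trimming.
#' @param tso TSO sequence to strip from the 5' end.
#' @param min_polya_run minimum A-run length treated as a poly(A) tail.
#' @param min_qual minimum Phred score kept at the 3' end.
#' @param min_len minimum surviving read length.
#' @return character vector of trimmed sequences (`NA` = dropped), with
#'   attribute `dropped` (count) and `qual` (trimmed quality strings).
#' @export
trim_read1 <- function(seq, quals = NULL,
                       tso = "AAGCAGTGGTATCAACGCAGAGT",
                       min_polya_run = 8L, min_qual = 20L, min_len = 30L) {
  n <- length(seq)
  if (is.null(quals)) quals <- strrep("I", nchar(seq))
  stopifnot(length(quals) == n, all(nchar(quals) == nchar(seq)))

  # TSO prefix, allowing <= 1 mismatch
  L <- nchar(tso)
  if (L > 0L) {
    long <- nchar(seq) >= L
    pre <- substr(seq, 1L, L)
    hit <- long & hamming_to(pre, tso) <= 1L
    seq[hit] <- substr(seq[hit], L + 1L, nchar(seq[hit]))
    quals[hit] <- substr(quals[hit], L + 1L, nchar(quals[hit]))
  }

  # leftmost A-run of length >= min_polya_run: cut there
  m <- regexpr(sprintf("A{%d,}", min_polya_run), seq)
  cut <- which(m > 0L)
  seq[cut] <- substr(seq[cut], 1L, m[cut] - 1L)
  quals[cut] <- substr(quals[cut], 1L, m[cut] - 1L)

  # 3' quality trim
  q <- lapply(quals, function(s) utf8ToInt(s) - 33L)
  keep_len <- vapply(q, function(v) {
    n_i <- length(v)
    while (n_i > 0L && v[n_i] < min_qual) n_i <- n_i - 1L
    n_i
  }, integer(1))
  seq <- substr(seq, 1L, keep_len)
  quals <- substr(quals, 1L, keep_len)

  drop <- nchar(seq) < min_len
  seq[drop] <- NA_character_
  quals[drop] <- NA_character_
  attr(seq, "dropped") <- sum(drop)
  attr(seq, "qual") <- quals
  seq
}

#' Count distinct UMIs per gene and cell
#'
#' Discards non-uniquely mapped reads, then counts, for every
#' (cell, gene) pair, the number of distinct UMI sequences among the
#' remaining reads.  Duplicated UMIs inside a gene collapse to one
#' molecule; the same UMI observed on two different genes counts once for
#' each gene.  The operation is idempotent under read duplication.
#'
#' @param assignments data frame with columns `read_id`, `cell_id`,
#'   `umi`, `gene_id`, `unique_flag`.
#' @param genes,cells optional gene / cell universes fixing the matrix
#'   axes (defaults to the ids observed in the table).
#' @return gene x cell integer matrix of distinct-UMI counts.
#' @export
count_umis <- function(assignments, genes = NULL, cells = NULL) {
  need <- c("read_id", "cell_id", "umi", "gene_id", "unique_flag")
  miss <- setdiff(need, names(assignments))
  if (length(miss)) stop("assignment table lacks columns: ",
                         paste(miss, collapse = ", "))
  chr <- assignments[c("read_id", "cell_id", "umi", "gene_id")]
  bad <- which(Reduce(`|`, lapply(chr, function(x) is.na(x) | x == "")) |
               is.na(assignments$unique_flag))
  if (length(bad)) stop("malformed assignment row(s): ",
                        paste(head(bad, 5), collapse = ", "))

  a <- assignments[assignments$unique_flag, , drop = FALSE]
  key <- paste(a$cell_id, a$gene_id, a$umi, sep = "\r")
  a <- a[!duplicated(key), , drop = FALSE]

  if (is.null(genes)) genes <- sort(unique(a$gene_id))
  if (is.null(cells)) cells <- sort(unique(a$cell_id))
  m <- matrix(0L, nrow = length(genes), ncol = length(cells),
              dimnames = list(genes, cells))
  if (nrow(a)) {
    tab <- table(factor(a$gene_id, levels = genes),
                 factor(a$cell_id, levels = cells))
    m[] <- as.integer(tab)
  }
  m
}

#' Quantify a tag-structured FASTQ pair into a UMI count matrix
#'
#' End-to-end demultiplexing: extract barcode and UMI from read 2, match
#' barcodes against the whitelist, optionally trim read 1 (pairs whose
#' read 1 is dropped are discarded), join read ids against the
#' read-to-gene assignment table, and count distinct UMIs per gene and
#' cell.
#'
#' @param read1,read2 FASTQ paths (matching read order).
#' @param assignments read-to-gene table: data frame or TSV path with
#'   columns `read_id`, `gene_id`, `unique_flag`.
#' @param layout a [library_layout()].
#' @param genes optional gene universe for the matrix rows.
#' @param trim apply [trim_read1()] to read 1 before counting?
#' @param ... passed on to [trim_read1()].
#' @return list with `counts` (gene x cell integer matrix over all
#'   whitelist cells) and `stats`, a one-row data frame of drop tallies
#'   (`n_pairs`, `too_short`, `unassigned`, `trim_dropped`,
#'   `unaligned`).
#' @export
quantify_reads <- function(read1, read2, assignments, layout,
                           genes = NULL, trim = TRUE, ...) {
  r1 <- read_fastq(read1)
  r2 <- read_fastq(read2)
  if (!identical(r1$id, r2$id)) stop("read 1 / read 2 ids out of sync")
  if (is.character(assignments)) {
    assignments <- read.delim(assignments, stringsAsFactors = FALSE)
  }

  tags <- extract_tags(r2$seq, layout)
  too_short <- attr(tags, "too_short")
  cell <- assign_barcode(tags$barcode, layout)
  unassigned <- sum(is.na(cell) & !is.na(tags$barcode))

  trim_dropped <- 0L
  keep <- !is.na(cell)
  if (trim) {
    tr <- trim_read1(r1$seq, r1$qual, ...)
    trim_dropped <- sum(keep & is.na(tr))
    keep <- keep & !is.na(tr)
  }

  tab <- data.frame(read_id = r1$id[keep], cell_id = cell[keep],
                    umi = tags$umi[keep], stringsAsFactors = FALSE)
  j <- match(tab$read_id, assignments$read_id)
  unaligned <- sum(is.na(j))
  tab <- cbind(tab[!is.na(j), , drop = FALSE],
               assignments[j[!is.na(j)], c("gene_id", "unique_flag"),
                           drop = FALSE])

  counts <- count_umis(tab, genes = genes,
                       cells = names(layout$whitelist))
  stats <- data.frame(n_pairs = nrow(r1), too_short = too_short,
                      unassigned = unassigned, trim_dropped = trim_dropped,
                      unaligned = unaligned)
  list(counts = counts, stats = stats)
}

#' Normalize UMI counts to UMI-based TPM
#'
#' TPM of gene g in cell c is its UMI count divided by the cell's total
#' UMI count, times 1e6, so every cell column with nonzero total sums to
#' exactly one million.  Cells with zero total stay all-zero and are
#' flagged in the `zero_cells` attribute.
#'
#' @param counts gene x cell UMI count matrix.
#' @return numeric matrix of TPM values with attribute `zero_cells`.
#' @export
tpm_normalize <- function(counts) {
  tot <- colSums(counts)
  zero <- tot == 0
  scale <- ifelse(zero, 0, 1e6 / tot)
  tpm <- sweep(counts, 2, scale, `*`)
  attr(tpm, "zero_cells") <- colnames(counts)[zero]
  tpm
}

#' Fraction of a cell's molecules on mitochondrial genes
#'
#' Computes, per cell, the fraction of kept molecules (UMIs when given a
#' count matrix, reads when given an assignment table with `cell_id` and
#' `gene_id` columns) that map to the mitochondrial gene set.  Cells with
#' nothing counted get `NA`.
#'
#' @param x gene x cell count matrix, or an assignment-style data frame.
#' @param mito_genes character vector of mitochondrial gene ids.
#' @return named numeric vector of per-cell ratios in [0, 1] (or `NA`).
#' @export
mito_ratio <- function(x, mito_genes) {
  if (is.data.frame(x)) {
    stopifnot(all(c("cell_id", "gene_id") %in% names(x)))
    tot <- table(x$cell_id)
    mit <- table(factor(x$cell_id[x$gene_id %in% mito_genes],
                        levels = names(tot)))
    out <- as.numeric(mit) / as.numeric(tot)
    names(out) <- names(tot)
    return(out)
  }
  miss <- setdiff(mito_genes, rownames(x))
  if (length(miss) == length(mito_genes) && length(mito_genes)) {
    warning("none of the mitochondrial genes are in the matrix")
  }
  tot <- colSums(x)
  mit <- colSums(x[intersect(mito_genes, rownames(x)), , drop = FALSE])
  out <- ifelse(tot == 0, NA_real_, mit / tot)
  names(out) <- colnames(x)
  out
}
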