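#' Simulate a UMI count matrix with planted structure
#'
#' Draws gene-by-cell UMI counts under the negative-binomial model of a
#' [synthetic_spec()]: baseline gene means (log-normal across genes,
#' shared by all cells), subtype marker genes multiplied by the subtype's
#' `marker_fold`, cycle-panel genes multiplied by `cycle_panel_boost` in
#' cycling cells, and low-quality cells restricted to at most
#' `lowq_gene_cap` genes with nonzero counts.  Identical spec + seed
#' reproduces the identical matrix.
#'
#' @param spec a [synthetic_spec()].
#' @return a list with `counts` (gene x cell integer matrix) and `truth`,
#'   a data frame with one row per cell: `cell_id`, `subtype`, `cycling`,
#'   `lowq`, `barcode`.
#' @examples
#' sp <- synthetic_spec(
#'   n_genes = 50,
#'   subtypes = list(list(name = "A", n_cells = 5,
#'                        marker_genes = c("G00001", "G00002"),
#'                        marker_fold = 8)),
#'   seed = 1
#' )
#' sim <- simulate_counts(sp)
#' dim(sim$counts)
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, simulate_counts_impl(spec))
}

simulate_counts_impl <- function(spec) {
  G <- spec$n_genes
  sizes <- vapply(spec$subtypes, function(s) as.integer(s$n_cells), integer(1))
  N <- sum(sizes)
  if (N == 0L) {
    counts <- matrix(integer(), nrow = G, ncol = 0,
                     dimnames = list(spec$gene_ids, character()))
    truth <- data.frame(cell_id = character(), subtype = character(),
                        cycling = logical(), lowq = logical(),
                        barcode = character(), stringsAsFactors = FALSE)
    return(list(counts = counts, truth = truth))
  }

  # baseline gene means: log-normal across genes, mean = baseline_mean;
  # marker and cycle-panel genes pinned at baseline_mean exactly so the
  # planted fold changes are well defined
  sdl <- spec$gene_mean_sdlog
  mu_g <- rlnorm(G, meanlog = log(spec$baseline_mean) - sdl^2 / 2, sdlog = sdl)
  names(mu_g) <- spec$gene_ids
  pinned <- unique(c(unlist(lapply(spec$subtypes, `[[`, "marker_genes")),
                     spec$cycle_genes))
  mu_g[pinned] <- spec$baseline_mean

  cell_id <- sprintf("cell_%04d", seq_len(N))
  subtype <- rep(vapply(spec$subtypes, `[[`, character(1), "name"), sizes)
  barcode <- random_dna(N, spec$barcode_len, unique = TRUE)

  cyc_frac <- vapply(spec$subtypes, function(s) {
    if (is.null(s$cycling_fraction)) spec$cycling_fraction[1]
    else s$cycling_fraction
  }, numeric(1))
  cycling <- stats::rbinom(N, 1L, rep(cyc_frac, sizes)) == 1L
  lowq <- stats::rbinom(N, 1L, spec$lowq_fraction) == 1L

  mu <- matrix(mu_g, nrow = G, ncol = N,
               dimnames = list(spec$gene_ids, cell_id))
  col0 <- cumsum(c(0L, sizes))
  for (i in seq_along(spec$subtypes)) {
    st <- spec$subtypes[[i]]
    cols <- (col0[i] + 1L):col0[i + 1L]
    mu[st$marker_genes, cols] <- mu[st$marker_genes, cols] * st$marker_fold
  }
  if (length(spec$cycle_genes) && any(cycling)) {
    mu[spec$cycle_genes, cycling] <-
      mu[spec$cycle_genes, cycling] * spec$cycle_panel_boost
  }

  counts <- matrix(rnbinom(G * N, size = spec$dispersion, mu = mu),
                   nrow = G, ncol = N,
                   dimnames = list(spec$gene_ids, cell_id))
  for (j in which(lowq)) {
    keep <- sample.int(G, spec$lowq_gene_cap)
    drop <- rep(TRUE, G)
    drop[keep] <- FALSE
    counts[drop, j] <- 0L
  }
  storage.mode(counts) <- "integer"

  truth <- data.frame(cell_id = cell_id, subtype = subtype,
                      cycling = cycling, lowq = lowq, barcode = barcode,
                      stringsAsFactors = FALSE)
  list(counts = counts, truth = truth)
}

# n unique random DNA strings of length len
random_dna <- function(n, len, unique = FALSE) {
  if (n == 0L) return(character())
  if (len == 0L) return(rep("", n))
  draw <- function(k) {
    apply(matrix(sample(c("A", "C", "G", "T"), k * len, replace = TRUE),
                 nrow = k), 1, paste, collapse = "")
  }
  out <- draw(n)
  while (unique && anyDuplicated(out)) {
    dup <- which(duplicated(out))
    out[dup] <- draw(length(dup))
  }
  out
}

#' Emit tag-structured FASTQ and a read-to-gene assignment table
#'
#' For every UMI in `counts`, writes at least one read pair: read 1
#' carries (synthetic) cDNA sequence, optionally contaminated with a TSO
#' prefix or a 3' poly(A) tail; read 2 carries the cell barcode followed
#' by the UMI at fixed offsets.  Duplicate read pairs (same cell, gene
#' and UMI) are injected at rate `dup_rate`.  A library-wide barcode
#' whitelist is written alongside the FASTQ files.  Read ids are opaque:
#' nothing about the ground truth is recoverable from them.
#'
#' @param spec the [synthetic_spec()] used to build `counts`.
#' @param counts,truth output of [simulate_counts()].
#' @param out_dir directory to write into (created if missing).
#' @param dup_rate probability that a molecule gains one duplicate read
#'   pair.
#' @param tso_rate fraction of read-1 sequences carrying a TSO prefix.
#' @param read1_len,read2_len read lengths in bases.
#' @return a list with paths `read1`, `read2`, `whitelist`,
#'   `assignments`, and the assignment table itself
#'   (`assignment_table`: read_id, gene_id, unique_flag).
#' @export
simulate_fastq <- function(spec, counts, truth, out_dir,
                           dup_rate = 0, tso_rate = 0,
                           read1_len = 100L, read2_len = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (ncol(counts) != nrow(truth) ||
      !identical(colnames(counts), truth$cell_id)) {
    stop("`counts` and `truth` describe different cells")
  }
  if (is.null(read2_len)) read2_len <- spec$barcode_len + spec$umi_len + 8L
  if (read2_len < spec$barcode_len + spec$umi_len) {
    stop("`read2_len` too short for barcode + UMI")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  withr::with_seed(spec$seed + 1L,
    simulate_fastq_impl(spec, counts, truth, out_dir, dup_rate, tso_rate,
                        as.integer(read1_len), as.integer(read2_len)))
}

simulate_fastq_impl <- function(spec, counts, truth, out_dir, dup_rate,
                                tso_rate, read1_len, read2_len) {
  nz <- which(counts > 0, arr.ind = TRUE)
  k <- counts[nz]
  n_mol <- sum(k)
  gene <- rep(rownames(counts)[nz[, 1]], k)
  cell <- rep(colnames(counts)[nz[, 2]], k)
  pair <- rep(seq_len(nrow(nz)), k)

  # distinct UMIs within each (cell, gene); resample collisions
  umi_space <- 4^spec$umi_len
  umi_int <- sample.int(umi_space, n_mol, replace = TRUE)
  repeat {
    dup <- duplicated(paste(pair, umi_int))
    if (!any(dup)) break
    umi_int[dup] <- sample.int(umi_space, sum(dup), replace = TRUE)
  }
  umi <- int_to_dna(umi_int - 1L, spec$umi_len)

  # duplicate injection: each molecule gains one extra pair w.p. dup_rate
  extra <- stats::rbinom(n_mol, 1L, dup_rate) == 1L
  idx <- c(seq_len(n_mol), which(extra))
  gene <- gene[idx]; cell <- cell[idx]; umi <- umi[idx]
  n_read <- length(idx)
  ord <- sample.int(n_read)            # shuffle so file order leaks nothing
  gene <- gene[ord]; cell <- cell[ord]; umi <- umi[ord]
  read_id <- sprintf("read_%07d", seq_len(n_read))

  barcode <- truth$barcode[match(cell, truth$cell_id)]

  # synthetic cDNA is kept free of poly(A)-like runs (every 6th
  # consecutive A is broken) so that the planted contamination below is
  # the only trimmable signal and the FASTQ -> counts round trip stays
  # exact with the trimmer on
  r1 <- gsub("AAAAAA", "AAAAAC", random_dna(n_read, read1_len))
  tail_a <- strrep("A", 20L)
  is_pa <- runif(n_read) < spec$polya_contam_rate
  r1[is_pa] <- paste0(substr(r1[is_pa], 1L, read1_len - 20L), tail_a)
  is_tso <- runif(n_read) < tso_rate
  r1[is_tso] <- paste0(spec$tso_seq,
                       substr(r1[is_tso], 1L, read1_len - nchar(spec$tso_seq)))
  pad <- random_dna(n_read, read2_len - spec$barcode_len - spec$umi_len)
  r2 <- paste0(barcode, umi, pad)

  r1_path <- file.path(out_dir, "reads_R1.fastq")
  r2_path <- file.path(out_dir, "reads_R2.fastq")
  write_fastq(read_id, r1, r1_path)
  write_fastq(read_id, r2, r2_path)

  wl <- truth[, c("cell_id", "barcode")]
  wl_path <- file.path(out_dir, "whitelist.tsv")
  write.table(wl, wl_path, sep = "\t", quote = FALSE, row.names = FALSE)

  assign_tab <- data.frame(read_id = read_id, gene_id = gene,
                           unique_flag = TRUE, stringsAsFactors = FALSE)
  as_path <- file.path(out_dir, "assignments.tsv")
  write.table(assign_tab, as_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  list(read1 = r1_path, read2 = r2_path, whitelist = wl_path,
       assignments = as_path, assignment_table = assign_tab)
}

int_to_dna <- function(x, len) {
  base <- c("A", "C", "G", "T")
  out <- matrix("", nrow = length(x), ncol = len)
  for (i in seq_len(len)) {
    out[, len - i + 1L] <- base[x %% 4L + 1L]
    x <- x %/% 4L
  }
  apply(out, 1, paste, collapse = "")
}
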