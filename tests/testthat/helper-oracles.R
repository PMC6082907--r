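# independent brute-force oracles the implementation is checked against

# distinct-UMI count per (cell, gene) via explicit per-pair set scan
oracle_count_umis <- function(assignments, genes, cells) {
  a <- assignments[assignments$unique_flag, , drop = FALSE]
  m <- matrix(0L, length(genes), length(cells),
              dimnames = list(genes, cells))
  for (g in genes) for (cc in cells) {
    sel <- a$gene_id == g & a$cell_id == cc
    m[g, cc] <- length(unique(a$umi[sel]))
  }
  m
}

# second-largest pairwise Pearson correlation via explicit double loop
oracle_second_max <- function(expr) {
  x <- log2(expr + 1)
  n <- ncol(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    cors <- vapply(setdiff(seq_len(n), i),
                   function(j) cor(x[, i], x[, j]), numeric(1))
    out[i] <- sort(cors, decreasing = TRUE)[2]
  }
  setNames(out, colnames(expr))
}

# Spearman dissimilarity via explicit mid-rank + Pearson-of-ranks
oracle_spearman_d <- function(expr) {
  r <- apply(expr, 2, rank)   # mid-ranks for ties
  n <- ncol(expr)
  d <- matrix(0, n, n, dimnames = list(colnames(expr), colnames(expr)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- (1 - cor(r[, i], r[, j])) / 2
  }
  diag(d) <- 0
  d
}

# detected genes per cell via explicit column scan
oracle_genes_detected <- function(counts) {
  out <- integer(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    out[j] <- sum(counts[, j] >= 1)
  }
  setNames(out, colnames(counts))
}

# UPGMA by rescanning all cluster pairs each step; returns the height
# sequence and the partition (list of member sets) after every merge
oracle_upgma <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1L)) {
      dd <- mean(D[clusters[[i]], clusters[[j]]])
      if (dd < best_d - 1e-12) { best_d <- dd; best <- c(j, i) }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- c(clusters[-best], list(merged))
    heights <- c(heights, best_d)
    partitions <- c(partitions, list(lapply(clusters, sort)))
  }
  list(heights = heights, partitions = partitions)
}

# partition of 1..n after the first k merges of an hclust tree
hclust_partition_after <- function(hc, k) {
  n <- length(hc$order)
  lab <- cutree(hc, h = hc$height[k] + 1e-12)
  unname(lapply(split(seq_len(n), lab), sort))
}

canonical_partition <- function(p) {
  p <- lapply(p, sort)
  p[order(vapply(p, `[`, numeric(1), 1))]
}

# exact two-sided Wilcoxon rank-sum p-value by full enumeration
oracle_wilcox_exact <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x)
  w_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (length(r) + 1) / 2
  combos <- utils::combn(length(r), n1)
  ws <- colSums(matrix(r[combos], nrow = n1))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}
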