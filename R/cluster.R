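#' Spearman rank-correlation dissimilarity between cells
#'
#' Builds the cell-by-cell dissimilarity d = (1 - beta) / 2, where beta
#' is the Spearman correlation (mid-ranks for ties) of the two cells'
#' expression profiles, so identical rank orders give d = 0 and exactly
#' reversed orders give d = 1.  Being rank-based, the result is
#' invariant to any monotone per-cell transform of the expression
#' values.
#'
#' @param expr gene x cell expression matrix (TPM or counts).
#' @param gene_subset optional gene ids to restrict to.
#' @return symmetric cell x cell dissimilarity matrix in [0, 1] with
#'   zero diagonal.
#' @export
spearman_dissimilarity <- function(expr, gene_subset = NULL) {
  if (!is.null(gene_subset)) expr <- expr[gene_subset, , drop = FALSE]
  if (ncol(expr) < 2L) stop("need at least 2 cells")
  const <- apply(expr, 2, function(v) all(v == v[1]))
  if (any(const)) {
    stop("constant expression vector; Spearman correlation undefined for cell(s): ",
         paste(colnames(expr)[const], collapse = ", "))
  }
  beta <- cor(expr, method = "spearman")
  d <- (1 - beta) / 2
  d[d < 0] <- 0
  d[d > 1] <- 1
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) dendrogram
#'
#' Agglomerative clustering where the distance between two clusters is
#' the unweighted mean of all member pairwise dissimilarities.  Average
#' linkage is reducible, so merge heights are non-decreasing.
#'
#' @param D symmetric dissimilarity matrix (e.g. from
#'   [spearman_dissimilarity()]).
#' @return an object of class `hclust`.
#' @export
average_linkage <- function(D) {
  if (any(!is.finite(as.matrix(D)))) stop("dissimilarity matrix contains non-finite values")
  stats::hclust(stats::as.dist(D), method = "average")
}

# per-node bookkeeping for a dendrogram: sizes, member leaves, and the
# core height — the highest merge in the subtree whose two sides both
# hold at least `core_min` leaves.  Late joins of stragglers (single
# cells absorbed just below the parent merge) do not move the core
# height, which is what makes the detachment gap robust.
dend_nodes <- function(dend, core_min = 3L) {
  n <- length(dend$order)
  mg <- dend$merge
  h <- dend$height
  size <- integer(n - 1L)
  members <- vector("list", n - 1L)
  core_top <- numeric(n - 1L)
  for (i in seq_len(n - 1L)) {
    get <- function(j) if (j < 0L) -j else members[[j]]
    a <- mg[i, 1L]; b <- mg[i, 2L]
    members[[i]] <- c(get(a), get(b))
    size[i] <- length(members[[i]])
    sz <- function(j) if (j < 0L) 1L else size[j]
    ct <- function(j) if (j < 0L) 0 else core_top[j]
    core_top[i] <- max(ct(a), ct(b),
                       if (min(sz(a), sz(b)) >= core_min) h[i] else 0)
  }
  list(size = size, members = members, core_top = core_top)
}

#' Dynamic hybrid tree cut
#'
#' Cuts an average-linkage dendrogram into clusters of variable height,
#' in two stages.  \strong{Stage 1 (tree stage)}: walking down from the
#' root, a merge is split when both sides hold at least
#' `min_cluster_size` leaves and at least one side is \emph{detached} —
#' the gap between the merge height and that side's \emph{core height}
#' (its highest internal merge whose two sides both hold at least three
#' leaves, so late-joining straggler cells do not mask the gap)
#' exceeds a fraction (set by `deep_split`) of the tree's height range
#' (root height minus the 5th percentile of merge heights).  A side
#' smaller than `min_cluster_size` is stripped — its leaves stay
#' unassigned, awaiting stage 2 — and the walk continues on the large
#' side.  A branch that cannot be split becomes one cluster.
#' \strong{Stage 2 (assignment stage, `pam_stage = TRUE`)}: each
#' unassigned cell joins the cluster with the smallest average
#' dissimilarity to its members, provided that distance does not exceed
#' the cluster's radius (the median plus twice the median-to-maximum
#' spread of the members' average within-cluster dissimilarities);
#' cells failing the radius test keep label 0.
#'
#' Labels are renumbered 1..K by decreasing cluster size; 0 means
#' unassigned.
#'
#' @param dend `hclust` object built from `D`.
#' @param D the dissimilarity matrix the dendrogram was built from
#'   (needed for the assignment stage).
#' @param min_cluster_size smallest allowed cluster.
#' @param deep_split split sensitivity, integer 0 (conservative) to 4
#'   (aggressive); sets the detachment gap to 0.30, 0.20, 0.125, 0.075
#'   or 0.04 of the height range.
#' @param pam_stage run the assignment stage?
#' @return integer vector of per-cell labels (named by cell), with
#'   attribute `params`.
#' @export
dynamic_hybrid_cut <- function(dend, D = NULL, min_cluster_size = 20L,
                               deep_split = 1L, pam_stage = TRUE) {
  stopifnot(inherits(dend, "hclust"), deep_split %in% 0:4)
  n <- length(dend$order)
  cells <- if (is.null(dend$labels)) as.character(seq_len(n)) else dend$labels
  labels <- setNames(integer(n), cells)
  params <- list(min_cluster_size = as.integer(min_cluster_size),
                 deep_split = as.integer(deep_split),
                 pam_stage = isTRUE(pam_stage))
  done <- function(lab) {
    attr(lab, "params") <- params
    lab
  }
  if (min_cluster_size > n) {
    warning("`min_cluster_size` exceeds the number of leaves; all cells unassigned")
    return(done(labels))
  }
  if (n == 1L) {
    labels[] <- 1L
    return(done(labels))
  }

  info <- dend_nodes(dend)
  h <- dend$height
  rng <- max(h) - unname(quantile(h, 0.05))
  gap_frac <- c(0.30, 0.20, 0.125, 0.075, 0.04)[deep_split + 1L]
  # strictly positive so a height-degenerate tree stays one cluster
  gap_thresh <- max(gap_frac * rng, .Machine$double.eps)

  node_size <- function(j) if (j < 0L) 1L else info$size[j]
  node_top <- function(j) if (j < 0L) 0 else info$core_top[j]
  node_leaves <- function(j) if (j < 0L) -j else info$members[[j]]

  # a node carries a valid split when both sides can hold a cluster and
  # at least one side is detached from the merge; a subtree has
  # structure when a valid split exists anywhere within it
  split_here <- logical(n - 1L)
  has_structure <- logical(n - 1L)
  str_of <- function(j) if (j < 0L) FALSE else has_structure[j]
  for (i in seq_len(n - 1L)) {
    a <- dend$merge[i, 1L]; b <- dend$merge[i, 2L]
    split_here[i] <-
      node_size(a) >= min_cluster_size && node_size(b) >= min_cluster_size &&
      ((h[i] - node_top(a)) >= gap_thresh ||
       (h[i] - node_top(b)) >= gap_thresh)
    has_structure[i] <- split_here[i] || str_of(a) || str_of(b)
  }

  clusters <- list()
  descend <- function(i) {
    if (i < 0L) {                          # lone leaf: unassigned unless
      if (min_cluster_size <= 1L) {        # singletons are allowed
        clusters[[length(clusters) + 1L]] <<- -i
      }
      return(invisible())
    }
    a <- dend$merge[i, 1L]; b <- dend$merge[i, 2L]
    sa <- node_size(a); sb <- node_size(b)
    if (sa >= min_cluster_size && sb >= min_cluster_size &&
        (split_here[i] || str_of(a) || str_of(b))) {
      descend(a)                           # split (or pass through a
      descend(b)                           # union with deeper structure)
    } else if (sa >= min_cluster_size && (sb < min_cluster_size)) {
      descend(a)                           # strip straggler branch b;
    } else if (sb >= min_cluster_size && (sa < min_cluster_size)) {
      descend(b)                           # its leaves await stage 2
    } else {
      clusters[[length(clusters) + 1L]] <<- node_leaves(i)
    }
    invisible()
  }
  descend(n - 1L)

  for (k in seq_along(clusters)) labels[clusters[[k]]] <- k

  if (isTRUE(pam_stage) && length(clusters) && any(labels == 0L)) {
    if (is.null(D)) stop("`D` is required for the assignment stage")
    D <- as.matrix(D)
    # iterate to a fixed point: newly assigned cells enlarge the
    # clusters, which updates the radii and can admit further cells
    repeat {
      radius <- vapply(clusters, function(mem) {
        dk <- D[mem, mem, drop = FALSE]
        avg <- rowSums(dk) / (length(mem) - 1L)
        # extrapolate past the most peripheral member, so cells stripped
        # just outside a tight core can still join
        median(avg) + 2 * (max(avg) - median(avg))
      }, numeric(1))
      changed <- FALSE
      for (i in which(labels == 0L)) {
        avg <- vapply(clusters, function(mem) mean(D[i, mem]), numeric(1))
        k <- which.min(avg)
        if (avg[k] <= radius[k]) {
          labels[i] <- k
          clusters[[k]] <- c(clusters[[k]], i)
          changed <- TRUE
        }
      }
      if (!changed || !any(labels == 0L)) break
    }
  }

  # renumber by decreasing size
  if (any(labels > 0L)) {
    tab <- sort(table(labels[labels > 0L]), decreasing = TRUE)
    remap <- setNames(seq_along(tab), names(tab))
    labels[labels > 0L] <- remap[as.character(labels[labels > 0L])]
  }
  done(labels)
}

#' Cluster cells end to end
#'
#' Convenience wrapper chaining [spearman_dissimilarity()],
#' [average_linkage()] and [dynamic_hybrid_cut()].
#'
#' @param expr gene x cell expression matrix.
#' @param gene_subset optional gene ids for the dissimilarity.
#' @param ... passed to [dynamic_hybrid_cut()].
#' @return list with `labels`, `dendrogram` and `dissimilarity`.
#' @export
cluster_cells <- function(expr, gene_subset = NULL, ...) {
  D <- spearman_dissimilarity(expr, gene_subset)
  dend <- average_linkage(D)
  labels <- dynamic_hybrid_cut(dend, D, ...)
  list(labels = labels, dendrogram = dend, dissimilarity = D)
}

#' Re-cluster one population into subtypes
#'
#' Re-runs the dissimilarity / average-linkage / dynamic-cut chain
#' inside a single parent cluster, emitting nested labels of the form
#' `"<parent>_<child>"`.  Within a population the genes that separate
#' subtypes are a small fraction of the transcriptome, so by default the
#' nested dissimilarity is computed over the parent's own top `n_hvg`
#' highly variable genes (variance of log2(TPM+1) across the parent's
#' cells); pass `gene_subset` to override.  A parent with no internal
#' structure yields a single child.
#'
#' @param expr gene x cell expression matrix (all cells).
#' @param assignment per-cell labels (integer or character) naming every
#'   column of `expr`.
#' @param parent_label the cluster to refine.
#' @param min_cluster_size,deep_split,pam_stage as in
#'   [dynamic_hybrid_cut()]; `min_cluster_size` defaults to 20.
#' @param gene_subset optional gene ids for the dissimilarity
#'   (overrides the highly-variable-gene default).
#' @param n_hvg number of within-parent highly variable genes used when
#'   `gene_subset` is `NULL`.
#' @return character vector of nested labels for the parent's cells
#'   (unassigned children keep `"<parent>_0"`).
#' @export
subcluster <- function(expr, assignment, parent_label,
                       min_cluster_size = 20L, deep_split = 1L,
                       pam_stage = TRUE, gene_subset = NULL,
                       n_hvg = 2000L) {
  cells <- names(assignment)[assignment == parent_label]
  if (length(cells) < 2L * min_cluster_size) {
    stop("parent cluster has fewer than 2 * min_cluster_size cells")
  }
  sub <- expr[, cells, drop = FALSE]
  if (is.null(gene_subset)) {
    gene_subset <- highly_variable_genes(sub, n_hvg)
  }
  res <- cluster_cells(sub, gene_subset,
                       min_cluster_size = min_cluster_size,
                       deep_split = deep_split, pam_stage = pam_stage)
  child <- res$labels
  if (all(child == 0L)) child[] <- 1L     # homogeneous parent: one child
  setNames(paste0(parent_label, "_", child), cells)
}

#' Refine every population into nested subtypes
#'
#' Applies [subcluster()] to each labelled cluster large enough to be
#' refined; smaller clusters keep a single child.  Unassigned cells
#' (label 0) keep the label `"0"`.
#'
#' @inheritParams subcluster
#' @param assignment per-cell integer labels from
#'   [dynamic_hybrid_cut()].
#' @return character vector of nested labels over all cells.
#' @export
discover_subtypes <- function(expr, assignment, min_cluster_size = 20L,
                              deep_split = 1L, pam_stage = TRUE,
                              gene_subset = NULL, n_hvg = 2000L) {
  out <- setNames(rep("0", length(assignment)), names(assignment))
  for (k in setdiff(sort(unique(assignment)), 0L)) {
    cells <- names(assignment)[assignment == k]
    if (length(cells) >= 2L * min_cluster_size) {
      out[cells] <- subcluster(expr, assignment, k, min_cluster_size,
                               deep_split, pam_stage, gene_subset, n_hvg)
    } else {
      out[cells] <- paste0(k, "_1")
    }
  }
  out
}
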