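#' Highly variable genes by log-expression variance
#'
#' @param expr gene x cell TPM matrix.
#' @param n number of genes to keep.
#' @return character vector of the top-`n` gene ids by variance of
#'   log2(TPM+1).
#' @export
highly_variable_genes <- function(expr, n = 2000L) {
  lx <- log2(expr + 1)
  v <- rowSums((lx - rowMeans(lx))^2)
  names(sort(v, decreasing = TRUE))[seq_len(min(n, nrow(expr)))]
}

#' Two-dimensional embedding of cells for reporting
#'
#' `method = "pca"` projects log2(TPM+1) over the top highly variable
#' genes onto the first two principal components (deterministic;
#' `seed` is ignored).  `method = "tsne"` runs an exact (non
#' Barnes-Hut) t-SNE on the Spearman dissimilarity matrix, matching the
#' per-cell perplexity by binary search and descending the
#' Kullback-Leibler objective with momentum and early exaggeration;
#' identical seeds give identical coordinates.  Embeddings are for
#' visual reporting only — cluster labels never come from them.
#'
#' @param expr gene x cell TPM matrix.
#' @param method `"pca"` or `"tsne"`.
#' @param seed integer seed for the t-SNE initialization.
#' @param perplexity t-SNE perplexity; must be below `n_cells / 3`.
#' @param n_hvg number of highly variable genes for the PCA view.
#' @param max_iter t-SNE gradient-descent iterations.
#' @param D optional precomputed dissimilarity matrix for t-SNE.
#' @return cell x 2 coordinate matrix with attributes `method` and
#'   `seed`.
#' @export
embed_cells <- function(expr, method = c("pca", "tsne"), seed = 0L,
                        perplexity = 30, n_hvg = 2000L, max_iter = 500L,
                        D = NULL) {
  method <- match.arg(method)
  if (method == "pca") {
    hvg <- highly_variable_genes(expr, n_hvg)
    x <- t(log2(expr[hvg, , drop = FALSE] + 1))
    co <- prcomp(x, center = TRUE, rank. = 2L)$x[, 1:2, drop = FALSE]
  } else {
    if (perplexity >= ncol(expr) / 3) {
      stop("perplexity must be below n_cells / 3")
    }
    if (is.null(D)) D <- spearman_dissimilarity(expr)
    co <- withr::with_seed(as.integer(seed),
                           tsne_exact(as.matrix(D), perplexity, max_iter))
    rownames(co) <- colnames(expr)
  }
  colnames(co) <- c("dim1", "dim2")
  attr(co, "method") <- method
  attr(co, "seed") <- as.integer(seed)
  co
}

# conditional Gaussian affinities with per-point precision matched to
# the target perplexity by binary search
tsne_affinities <- function(D2, perplexity, tol = 1e-5) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { H <- 0; p <- w }
      else {
        p <- w / sw
        H <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(H - logU) < tol) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else          { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P[P < .Machine$double.xmin] <- .Machine$double.xmin
  P
}

tsne_exact <- function(D, perplexity, max_iter) {
  n <- nrow(D)
  P <- tsne_affinities(D^2, perplexity)
  Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  G <- matrix(0, n, 2)        # update memory (momentum)
  gains <- matrix(1, n, 2)
  eta <- 200
  exag <- 12
  P_run <- P * exag
  for (iter in seq_len(max_iter)) {
    if (iter == 101L) P_run <- P
    mom <- if (iter < 250L) 0.5 else 0.8
    ss <- rowSums(Y^2)
    num <- 1 / (1 + outer(ss, ss, `+`) - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- num / sum(num)
    W <- (P_run - Q) * num
    grad <- 4 * (diag(rowSums(W)) %*% Y - W %*% Y)
    gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    G <- mom * G - eta * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
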