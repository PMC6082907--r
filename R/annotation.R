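#' Marker panel for placental cell-type annotation
#'
#' A marker panel maps each cell type to positive markers (expected
#' high) and optional negative markers (expected absent).  The default
#' panel covers the sorted-placenta populations: villous stromal core
#' (VIM+, HLA-A+), Hofbauer macrophages (CD14+, CD68+), mesenchymal
#' stromal cells (THY1+), fetal blood (HBB+), generic trophoblast
#' (KRT7+, TFAP2C+, GATA3+), cytotrophoblast (CDH1+, EGFR+, HLA-G-),
#' extravillous trophoblast (HLA-G+, MMP2+) and syncytiotrophoblast
#' (CGB+, CSH1+).  Protein-style aliases (CK7, CD90, E-cadherin) are
#' translated to gene symbols through the shipped alias map.
#'
#' @param path optional panel file: YAML (type -> positive / negative
#'   lists) or TSV with columns `cell_type`, `gene`, `direction`
#'   (`positive` / `negative`).
#' @return a named list of `list(positive =, negative =)` entries, class
#'   `marker_panel`.
#' @export
marker_panel <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "marker_panel.tsv", package = "villusSC")
  }
  if (grepl("\\.ya?ml$", path)) {
    raw <- yaml::read_yaml(path)
    panel <- lapply(raw, function(e) {
      list(positive = as.character(unlist(e$positive)),
           negative = as.character(unlist(e$negative)))
    })
  } else {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    panel <- lapply(split(tab, tab$cell_type), function(d) {
      list(positive = d$gene[d$direction == "positive"],
           negative = d$gene[d$direction == "negative"])
    })
  }
  panel <- lapply(panel, function(e) {
    e$positive <- resolve_aliases(e$positive)
    e$negative <- resolve_aliases(e$negative)
    if (length(intersect(e$positive, e$negative))) {
      stop("positive and negative marker sets overlap")
    }
    e
  })
  structure(panel, class = "marker_panel")
}

# protein name -> gene symbol map (shipped alias table)
resolve_aliases <- function(genes) {
  map_path <- system.file("extdata", "gene_aliases.tsv", package = "villusSC")
  map <- read.delim(map_path, stringsAsFactors = FALSE)
  hit <- match(genes, map$alias)
  ifelse(is.na(hit), genes, map$symbol[hit])
}

#' Score every cell against a marker panel
#'
#' Each gene's log2(TPM+1) is z-scored across cells (constant genes
#' score 0); a cell's score for a type is the mean z-score of the
#' type's positive markers minus the mean z-score of its negative
#' markers.  Markers absent from the matrix are skipped with a warning;
#' a type with no present markers is scored `NA`.
#'
#' @param expr gene x cell TPM matrix.
#' @param panel a [marker_panel()].
#' @return cell x type numeric score matrix.
#' @export
score_cell_types <- function(expr, panel = marker_panel()) {
  all_markers <- unique(unlist(lapply(panel, unlist)))
  present <- intersect(all_markers, rownames(expr))
  if (length(present) == 0L) stop("no panel marker is in the gene universe")
  missing <- setdiff(all_markers, present)
  if (length(missing)) {
    warning("markers absent from the matrix: ",
            paste(missing, collapse = ", "))
  }
  lx <- log2(expr[present, , drop = FALSE] + 1)
  if (ncol(lx) >= 2L) {
    mu <- rowMeans(lx)
    sd_g <- sqrt(rowSums((lx - mu)^2) / (ncol(lx) - 1L))
    z <- (lx - mu) / ifelse(sd_g == 0, Inf, sd_g)  # constant gene -> z = 0
  } else {
    z <- lx    # single cell: no across-cell reference, use log expression
  }

  scores <- vapply(panel, function(e) {
    pos <- intersect(e$positive, present)
    neg <- intersect(e$negative, present)
    if (length(pos) + length(neg) == 0L) {
      return(rep(NA_real_, ncol(expr)))
    }
    s <- if (length(pos)) colMeans(z[pos, , drop = FALSE]) else 0
    if (length(neg)) s <- s - colMeans(z[neg, , drop = FALSE])
    s
  }, numeric(ncol(expr)))
  if (!is.matrix(scores)) {
    scores <- matrix(scores, nrow = ncol(expr),
                     dimnames = list(NULL, names(panel)))
  }
  rownames(scores) <- colnames(expr)
  scores
}

#' Call a cell type per cell from panel scores
#'
#' The argmax type wins when its score beats the runner-up by at least
#' `min_margin`; exact ties and sub-margin leads give `NA`
#' (unassigned).
#'
#' @param scores cell x type matrix from [score_cell_types()].
#' @param min_margin required lead of the top score over the second.
#' @return character vector of per-cell calls (`NA` = unassigned).
#' @export
assign_types <- function(scores, min_margin = 0) {
  apply(scores, 1, function(s) {
    s <- s[!is.na(s)]
    if (length(s) == 0L) return(NA_character_)
    o <- order(s, decreasing = TRUE)
    if (length(s) > 1L && s[o[1]] - s[o[2]] < min_margin) return(NA_character_)
    if (length(s) > 1L && s[o[1]] == s[o[2]]) return(NA_character_)
    names(s)[o[1]]
  })
}

#' Name clusters by majority vote of member-cell calls
#'
#' @param calls per-cell type calls from [assign_types()].
#' @param assignment per-cell cluster labels.
#' @return named character vector, one call per cluster (ties broken
#'   alphabetically; clusters whose cells are all unassigned get `NA`).
#' @export
annotate_clusters <- function(calls, assignment) {
  vapply(split(calls, assignment), function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_character_)
    tab <- sort(table(v), decreasing = TRUE)
    names(tab)[1]
  }, character(1))
}

#' Sorting-purity rates per sorted gate
#'
#' Confronts transcriptome-based cell-type calls with the sorted
#' (e.g. MACS) gate each cell came from.  For a gate P with intended
#' type T: the true rate is the fraction of P's cells called T; the
#' false-positive rate is the fraction of P's cells called some other
#' defined type (unassigned cells count in neither, so true rate +
#' false-positive rate + unassigned fraction = 1); the false-negative
#' rate is the fraction of all cells called T that came from gates
#' other than P.
#'
#' @param calls per-cell type calls (`NA` = unassigned).
#' @param gates per-cell sorted-gate labels, same length/order.
#' @param gate_intent named character vector mapping gate -> intended
#'   type.
#' @return list with `rates` (data frame: gate, n, true_rate,
#'   false_positive_rate, false_negative_rate) and `contingency`
#'   (gate x call table; unassigned column "<unassigned>").
#' @export
purity_rates <- function(calls, gates, gate_intent) {
  stopifnot(length(calls) == length(gates))
  if (any(is.na(gates))) stop("every cell needs a gate label")
  miss <- setdiff(unique(gates), names(gate_intent))
  if (length(miss)) stop("gates without intent: ", paste(miss, collapse = ", "))

  call_f <- ifelse(is.na(calls), "<unassigned>", calls)
  contingency <- table(gate = gates, call = call_f)

  rates <- do.call(rbind, lapply(names(gate_intent), function(g) {
    in_gate <- gates == g
    n <- sum(in_gate)
    if (n == 0L) {
      return(data.frame(gate = g, n = 0L, true_rate = NA_real_,
                        false_positive_rate = NA_real_,
                        false_negative_rate = NA_real_))
    }
    tt <- gate_intent[[g]]
    called_t <- !is.na(calls) & calls == tt
    tr <- sum(in_gate & called_t) / n
    fp <- sum(in_gate & !is.na(calls) & calls != tt) / n
    fn <- if (sum(called_t) == 0L) NA_real_ else
      sum(called_t & !in_gate) / sum(called_t)
    data.frame(gate = g, n = n, true_rate = tr, false_positive_rate = fp,
               false_negative_rate = fn)
  }))
  list(rates = rates, contingency = contingency)
}
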