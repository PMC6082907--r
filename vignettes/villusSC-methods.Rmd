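---
title: "Methods: tag-based single-cell analysis of sorted placental cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tag-based single-cell analysis of sorted placental cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

villusSC analyses plate-based 3' tag single-cell RNA-seq of sorted
placental villus cells — cytotrophoblasts (CTB), syncytiotrophoblast
(STB), extravillous trophoblasts (EVT) and villous stromal cells sorted
by surface markers (HLA-G, CDH1) — and discovers cell populations and
nested subtypes from the transcriptome alone.  This vignette documents
the model and the numerical choices behind every stage, including the
choices we made where the design was genuinely open.

## Tag quantification

Read 2 of each pair carries a cell barcode and a unique molecular
identifier (UMI) at fixed offsets; read 1 carries cDNA.  Demultiplexing
follows fixed, explicit rules:

* **Barcode matching.** An exact whitelist match wins.  With
  `max_mismatch = 1`, a barcode matching a *unique* whitelist entry at
  Hamming distance 1 is rescued; ambiguity leaves the read unassigned.
  The default is `max_mismatch = 0`: rescue is an opt-in because a
  plate-based whitelist is small and collisions are unlikely but not
  impossible.
* **Read-1 trimming.** A template-switch-oligo (TSO) prefix is removed
  allowing one mismatch; the read is cut at the leftmost run of
  `A >= min_polya_run` (default 8) — everything 3' of the run start is
  discarded, so no qualifying run can survive; 3' bases under
  `min_qual = 20` are trimmed; reads shorter than `min_len = 30` are
  dropped and tallied.  All four parameters are configurable; the
  defaults make the trimmer testable rather than claiming to reproduce
  any particular published configuration.
* **UMI counting.** Reads flagged non-unique by the aligner (the
  pipeline takes a pluggable read-to-gene assignment table; alignment
  itself is out of scope) are discarded; the count for a (cell, gene)
  pair is the number of *distinct* UMI strings among its remaining
  reads.  Collapse is exact-string: no Hamming-1 UMI merging, because
  duplicate removal — not error correction — is the operation being
  modelled.  The same UMI on two genes counts once per gene.
* **TPM.** \(\mathrm{TPM}_{gc} = 10^6 \cdot n_{gc} / \sum_g n_{gc}\).
  Columns with nonzero totals sum to exactly $10^6$; zero-total cells
  stay zero and are flagged.

## Quality control

A cell passes when all three hold:

1. at least `min_genes = 3000` detected genes ("detected" means UMI
   count ≥ 1 — the count is the primitive observation, so detection is
   defined on counts, not on normalized values);
2. its *second-largest* pairwise Pearson correlation with any other
   cell exceeds 0.6 — computed on log2(TPM+1) over all genes.  The log
   transform is our choice (untransformed TPM lets a handful of giant
   genes dominate the correlation); it is exposed as `log_transform`;
3. it is not an embedding-space outlier.  Visual outlier removal on
   t-SNE/PCA plots is replaced by a deterministic surrogate: in the
   space of the top 10 principal components of log2(TPM+1), a cell is
   flagged when its Euclidean distance from the componentwise median
   exceeds the median distance by more than `outlier_mad_k = 5` median
   absolute deviations.  `outlier_method = "none"` disables the rule.

Genes are then kept when TPM is *strictly* above 5 in at least 2 cells.
Both boundaries are deliberate: "over 5" is read as a strict
inequality, "at least 2 cells" as inclusive.  The gene filter is
computed on the QC-retained cells (order configurable).

## Dissimilarity, tree, and the dynamic hybrid cut

The cell-cell dissimilarity is \(d_{ij} = (1-\beta_{ij})/2\) with
\(\beta\) the Spearman correlation (mid-ranks for ties — essential
under scRNA-seq zero inflation).  Being rank-based, \(d\) is invariant
to any monotone per-cell transform.  The tree is average-linkage UPGMA
(`stats::hclust`), whose reducibility guarantees monotone merge
heights.

The cut is a two-stage dynamic hybrid implemented from scratch:

* **Core height.** For every internal node we record the highest merge
  in its subtree whose two sides both hold at least 3 leaves.  Late
  joins of straggler cells (singletons absorbed just below a
  population's joining height) therefore do not move a branch's core
  height — without this, a single straggler masks an otherwise clean
  split.
* **Detachment gap.** A merge is *splittable* when both sides hold at
  least `min_cluster_size` (default 20) leaves and at least one side's
  core height sits more than a gap threshold below the merge height.
  The threshold is a fixed fraction of the tree's height range (root
  height minus the 5th percentile of merge heights):
  0.30, 0.20, 0.125, 0.075 or 0.04 for `deep_split` 0-4 (default 1).
  These fractions were calibrated once on planted-partition and
  homogeneous-null simulations: the null must produce at most one
  cluster in ≥ 95% of runs while planted blobs at marker fold 8 split
  reliably.
* **Pass-through of unions.** Walking down from the root, a node is
  split if it is splittable *or* a valid split exists anywhere deeper
  on either side.  This matters because with several populations the
  top of an average-linkage tree is a chain or balanced join of
  *unions* whose local gaps are tiny; terminating there would return
  one giant cluster.  A branch smaller than `min_cluster_size` is
  stripped (its leaves wait for stage 2); a branch with no internal
  structure becomes one cluster.  A height-degenerate tree (zero
  range) is returned as a single cluster.
* **Assignment stage.** Each unassigned cell joins the cluster with
  the smallest average dissimilarity to its members, provided that
  distance is within the cluster's radius — the median plus twice the
  (max − median) spread of members' average within-cluster
  dissimilarities, i.e. an extrapolation just past the most peripheral
  core member.  Assignment iterates to a fixed point: admitted cells
  enlarge the cluster and update its radius.  Cells outside every
  radius keep label 0.

Labels are renumbered by decreasing size, so runs are reproducible up
to nothing — the procedure is fully deterministic given the input
matrix, and label identity is stable under permutations of cell order.

**Nested subtypes.** Each population is re-clustered with the same
chain (`subcluster()`).  Within a population the genes that separate
subtypes are a small fraction of the transcriptome: over the full
filtered gene set the within-population subtype gap is of the order of
the Spearman sampling noise (~\(1/\sqrt{n_\mathrm{genes}}\)) and no
cut can see it.  The nested dissimilarity is therefore computed over
the parent's own top 2,000 highly variable genes (variance of
log2(TPM+1) across the parent's cells).  The main cut deliberately
keeps the full filtered gene set; highly variable genes are otherwise
used only for the PCA view.

**Embeddings** (PCA on the top 2,000 highly variable genes; exact
t-SNE on the dissimilarity matrix with per-cell perplexity matched by
binary search, early exaggeration 12 for 100 iterations, learning rate
200, momentum 0.5 → 0.8, seed-deterministic) are for reporting only —
no label ever derives from an embedding, except the optional QC
outlier surrogate above.

## Annotation and sorting purity

Cell-type scores are contrasts of z-scored log2(TPM+1): the mean
z-score over a type's positive markers minus the mean over its
negative markers; constant genes score 0, missing markers are skipped
with a warning.  The call is the argmax type, with ties and sub-margin
leads unassigned (`min_margin = 0` by default).  With the minimal
canonical panel (one to three genes per type — VIM/HLA-A, CD14/CD68,
THY1, HBB, KRT7/TFAP2C/GATA3, CDH1/EGFR/HLA-G−, HLA-G/MMP2,
CGB/CSH1), single-cell calls are intrinsically noisy because a single
lucky negative-binomial draw can spike a one-marker type; population
naming therefore uses the cluster-level majority vote of member-cell
calls, which is stable.  Single-cell calls are used where they are
needed: the sorting-purity rates.  For a sorted gate \(P\) with
intended type \(T\): true rate \(=|P \cap \mathrm{called}\,T|/|P|\);
false-positive rate \(=|P \cap \mathrm{called\ other}|/|P|\)
(unassigned cells count in neither, so true + FP + unassigned = 1);
false-negative rate \(=|\mathrm{called}\,T \setminus P| /
|\mathrm{called}\,T|\).  These denominators are package definitions —
the rates' exact published definitions are not recoverable — and are
stated here rather than guessed as anyone's intent.

## Cell cycle, markers, panels

* **Cycling cells.** Two classification modes exist because both
  conventions occur: `mean_expression` (default) calls a cell cycling
  when its mean TPM over the whole cycle panel is at least 100
  (inclusive); `n_genes_expressed` calls it cycling when strictly more
  than the threshold number of panel genes have TPM > 0.  The shipped
  panel (42 G1/S + 52 G2/M genes) is an editable data file; the
  package takes any panel.
* **Marker discovery.** One-vs-rest comparisons on log2(TPM+1) with
  prefilters `min_pct = 0.10` (expressed in ≥ 10% of the cluster) and
  `min_log2fc = 0.25` (difference of mean log2(TPM+1)); the test is
  the two-sided Wilcoxon rank-sum via `stats::wilcox.test` defaults —
  exact for small tie-free samples, tie-corrected normal approximation
  with continuity correction otherwise.  The exact small-sample path
  is kept because it is both the classical recommendation and the only
  way the test agrees with the enumerated null to high accuracy at
  small group sizes.  Benjamini-Hochberg q-values are computed across
  the genes actually tested.
* **Gene panels.** A panel gene is detected when TPM is strictly above
  2 in at least 30 cells.  The shipped hormone (48 genes) and
  imprinted (32 genes) lists are *representative* panels assembled
  from genes the placental literature names, with a provenance column;
  panel composition is input data, and real analyses should supply
  their own curated lists.

## The synthetic experiment

`simulate_counts()` draws \(n_{gc} \sim \mathrm{NB}(\mu_{gc},
\mathrm{size})\) with \(\mathrm{Var} = \mu + \mu^2/\mathrm{size}\)
(size = `dispersion`, default 2).  Baseline gene means are log-normal
across genes (`gene_mean_sdlog = 2.5`) with mean `baseline_mean = 3`
UMI per gene per cell, i.e. roughly 60,000 UMIs per cell over the
20,000-gene default universe — deep, plate-based libraries.  These two
values were fixed once so that synthetic cells reproduce the study
conditions the pipeline assumes: 4,000–10,000 detected genes per cell
(the default lands near 7,300) and pairwise log-expression
correlations comfortably above the 0.6 QC cut for healthy cells.
Marker and cycle-panel genes are pinned at exactly `baseline_mean`
before their fold changes, so planted effects are well defined rather
than convolved with the log-normal draw.  Subtype marker genes are
multiplied by `marker_fold` (default 8) in their subtype; cycle-panel
genes by `cycle_panel_boost = 6` in cycling cells (planted mean panel
TPM ≈ 300 vs ≈ 45 baseline, against the threshold of 100); low-quality
cells keep nonzero counts on at most `lowq_gene_cap = 500` genes, far
below the 3,000-gene QC cut.  The default cohort
(`default_placenta_spec()`) plants 1,567 cells in 7 populations
carrying 14 subtypes, with ~6% low-quality cells and
subtype-specific cycling fractions (0.6 in the proliferative CTB
subtype, 0.5 in the proliferative EVT subtype, ≤ 0.1 elsewhere); each
population shares 200 marker genes (containing its canonical sorting
genes) and each subtype adds 120 of its own.

`simulate_fastq()` emits one read pair per counted molecule (UMIs
distinct within each cell-gene pair), injects duplicate pairs at a
configurable rate, adds TSO prefixes and 3' poly(A) tails at
configurable rates, and writes the whitelist and a read-to-gene
assignment table.  Read ids are opaque; ground truth lives only in the
truth table.  Synthetic cDNA is generated free of poly(A)-like runs so
the planted contamination is the only trimmable signal and the
FASTQ → counts round trip is exact with the trimmer on.

**What the generator does not emulate** — and therefore what passing
tests do and do not show about real data: no batch or embryo effects,
no ambient RNA or doublets, no gene-length or GC bias, no mitochondrial
stress signature, no correlated marker modules beyond the planted
blocks, and conditionally independent genes given the cell's type and
state.  Tests on this generator validate the *pipeline's logic*
(counting, filtering rules, tree construction and cutting, test
statistics) under a realistic noise magnitude; they do not certify
performance on tissue with contamination or batch structure.

## Problem sizes and determinism

The test suite runs desk-scale: oracle comparisons on 100 random toy
instances per statistic, planted-partition recovery at 700 cells ×
2,000 genes, null calibration on 20 seeds × 150 cells, QC/cycling
checks at the full 20,000-gene universe with a few hundred cells.  The
acceptance script runs the full default cohort (1,567 cells × 20,000
genes, about 4 minutes end to end).  Every stochastic step flows from
a single integer seed through `withr::with_seed`, so identical inputs
give byte-identical outputs; the clustering stack contains no
randomness at all.

## Known limitations

* The dynamic cut's gap fractions are calibrated for dissimilarities
  in [0, 1] of the Spearman form; radically different metrics may need
  different `deep_split` settings.
* Single-cell type calls with one-marker panels are noisy by
  construction; use cluster-level annotation, or richer panels, for
  per-cell decisions.
* The second-maximum-correlation criterion assumes every real
  population has at least three members in the library; a genuine
  two-cell population would be rejected by design.
* `find_all_markers` on very large cohorts runs one test per gene per
  cluster; prefilters keep this tractable but it is not optimized for
  atlas-scale data.
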