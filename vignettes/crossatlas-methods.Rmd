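---
title: "Methods: cross-species atlas comparison with crossatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species atlas comparison with crossatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`crossatlas` compares single-cell/single-nucleus transcriptomes of two
species connected by a table of orthologous genes. The analysis
proceeds in stages, each a pure function of its inputs, parameters and
seed:

1. **Quality control.** Cells are summarized by genes detected, total
   transcripts, and mitochondrial fraction, and filtered on per-sample
   thresholds. Boundary semantics are inclusive: a cell is removed only
   when a metric is *strictly* outside a limit (the "more than 5%
   mitochondrial" reading), so a cell at exactly 5% is retained.
2. **Normalization.** Counts are library-size normalized and
   variance-stabilized as `log1p(count / cell_total * scale_factor)`
   (scale factor 10,000). Technical covariates (e.g. per-cell rRNA or
   mitochondrial load) can be regressed out per gene by ordinary least
   squares, keeping residual plus gene mean. This is a deliberately
   transparent stand-in for regularized negative-binomial regression
   normalization: the pipeline contract downstream only requires
   variance-stabilized values with covariate trends removed, and the
   OLS form is exactly reproducible and easy to reason about. The
   provenance field of every normalized matrix records the scale factor
   and the covariates removed.
3. **Atlas construction.** Highly variable genes are ranked by
   standardized variance — the variance of z-scores taken against a
   loess mean–variance trend (log10 variance on log10 mean, span 0.3),
   clipped at `sqrt(n_cells)`; ties break by gene id so the ranking is
   deterministic. PCA is computed on centered, unit-scaled genes with a
   fixed sign convention (the largest-magnitude loading of each
   component is positive). The cell graph connects each cell to its
   k = 20 Euclidean nearest neighbors, weighted by the Jaccard overlap
   of the endpoints' neighbor sets, pruning edges below 1/15. Louvain
   community detection at a configurable resolution yields clusters,
   relabeled 0, 1, 2, ... by decreasing size. UMAP is display-only.
4. **Marker detection.** For each cluster, genes expressed in at least
   5% of in-cluster cells with a natural-log fold change of at least
   0.25 versus all other cells (computed on `expm1` of the normalized
   values with pseudocount 1) are tested by the two-sided Wilcoxon
   rank-sum test; p-values are Bonferroni-corrected by the total number
   of genes in the matrix, and rows with adjusted p at most 0.05 are
   reported. Only up-regulated markers are reported by default, since
   the downstream overlap statistics consume positive marker sets. The
   expressed-fraction gate applies to the in-cluster group only — the
   rule is phrased in terms of the cluster's own cells — with a
   both-groups option.
5. **1:1 restriction and integration.** The ortholog table's one2one
   subset must be a bijection; pairs whose genes have nonzero counts in
   at least 2 cells in *both* species are retained, and species-A
   identifiers are converted to their species-B partners so both
   matrices live on one unified gene space. Integration then follows
   the anchor paradigm: shared highly variable features (up to 3000);
   diagonal CCA via a truncated SVD of the cross-product of the two
   standardized feature submatrices, cell loadings L2-normalized;
   anchors as mutual nearest neighbor cell pairs (k = 5) in CCA space,
   scored by the overlap of their k = 30 neighborhoods; per-cell
   correction vectors that map the query dataset onto the reference as
   Gaussian-weighted averages of anchor difference vectors (bandwidth:
   distance to the 50th nearest anchor, weights multiplied by anchor
   scores); then joint PCA (10 dims), the k = 20 SNN graph and Louvain
   at resolution 1 on the corrected composite.
6. **Composition and skew.** Integrated clusters are tabulated against
   origin labels. In the `of_integrated_cluster` direction every cell
   is weighted by the inverse of its species' total cell count, so a
   cluster to which both species contribute equally *per capita* shows
   50/50 regardless of dataset sizes; rows sum to 1. The
   `of_origin_cluster` direction is unweighted ("what share of this
   original cell type landed in this integrated cluster"); each
   origin's column sums to 1. A cluster is called species-skewed when
   its normalized majority fraction reaches 0.90, and well-mixed when
   the minority species contributes at least one third — the two
   operational signatures used to separate candidate species-specific
   states from conserved ones.
7. **Overlap statistics.** For marker sets of sizes `n1`, `n2` from a
   universe of `N` genes sharing `k` members, the representation factor
   is `k / (n1 * n2 / N)` and significance is the hypergeometric upper
   tail `P(X >= k)`, accumulated in log space so that the extreme tails
   (p below 1e-18) are representable. Cross-species comparisons use the
   retained shared-gene count as `N` (the expressed 1:1 universe is the
   natural reference; the identified-but-unexpressed alternative is a
   configuration switch); within-species comparisons default to an
   annotation total of 27,818 genes.
8. **Bulk concordance.** A genes-by-samples count table is quantile
   normalized (each sample's order statistics replaced by cross-sample
   rank means, ties receiving the mean of their target values); samples
   are compared to a reference by Spearman's rho (Kendall's tau
   optionally, since both rank correlations appear in practice) and by
   the per-gene `log2((sample + 1) / (reference + 1))` distribution,
   summarized by mean, sample sd and median. A pseudocount of 1 guards
   the zeros left by count data.

# The anchor consistency filter

Mutual nearest neighbors in CCA space can join cells that are not
biologically equivalent: two cell states each private to one species
correlate through their *mutual absence* of all shared programs and can
become anchors, after which the correction folds one onto the other.
The package therefore filters anchors for consistency in uncorrected
expression space: both endpoints' joint expression-PCA coordinates are
smoothed over their 30 within-dataset nearest neighbors (meta-cell
averaging, suppressing per-cell noise by roughly the square root of the
neighborhood size), and anchors whose smoothed difference norm exceeds
the anchor median by more than 2 MADs are dropped. Because the filter
space is standardized per dataset, a global batch shift of one dataset
cancels exactly and the filter never confuses batch offsets with state
differences. The effect is what the integration contract tests assert:
with the filter in place the planted species-specific types form pure
single-species clusters instead of collapsing onto each other, while
shared-type mixing and shift invariance are unchanged.

# The synthetic generator

The generator emulates the structure the comparative pipeline assumes,
with full ground truth:

- two species with `genes_per_species = 3000` genes each, of which
  `n_one2one = 2000` form a 1:1 bijection (orthologous pairs share their
  baseline expression) and `n_one2many = 200` rows are one-to-many;
- `n_types_shared = 8` shared cell types, each driven by a 25-gene
  program mapped through 1:1 orthologs with `divergence_frac = 0.2` of
  each program rewired per species (so homologous types keep a large
  but incomplete marker overlap), plus one species-specific type per
  species;
- counts drawn as negative binomial with
  `mean = baseline * program_effect^(gene in program) * timepoint_factor
  * libsize_factor` and `dispersion = 0.1` (variance
  `mu + 0.1 mu^2`); baselines are log-normal (`meanlog = log(0.2)`,
  `sdlog = 1`) for realistic mean heterogeneity, so HVG selection has
  something to find; the program effect is 8-fold;
- 100 cells per type per timepoint over 3 timepoints, implemented as
  mild global expression shifts (+/-10% per step) — the atlases pool
  timepoints, so batch structure is deliberately weak;
- log-normal library-size factors (`sigma = 0.35`, mean 1) and 10
  mitochondrial plus 10 rRNA covariate genes calibrated to 2% and 5%
  of counts respectively;
- one RNG stream per dataset keyed by `(seed, species)`, so each
  species' counts are reproducible independently of generation order.

Species-specific programs are drawn, by default, from *unused 1:1
orthologs*: the gene exists in both species but its program is active
in only one. This mirrors the biologically interesting case of a
conserved gene complement deployed species-specifically (or
heterochronically — the state may simply not have arisen yet at the
sampled stages in the other species) and keeps the planted specific
types detectable inside the shared gene space. A configuration switch
(`specific_program_space = "non_orthologous"`) instead places them on
genes without orthologs; note that in that regime the specific types
are *invisible* in the shared space by construction — both species'
private types then look like "no program" cells and co-cluster — so
skew detection cannot, and should not, find them.

The bulk triplet emulates partitioning one embryo culture into three
aliquots: a log-normal expectation vector (`meanlog = log(500)`, deep
bulk coverage so Poisson noise contributes little to log fold-changes),
per-gene log2-normal isolation biases with sds 0.558 (nuclei) and 0.683
(cells) — the two distribution widths the concordance analysis should
recover — and Poisson sampling.

What the generator does **not** emulate: doublets, ambient RNA,
spliced/unspliced structure, gene–gene correlation beyond programs,
per-cell-type library-size differences, and realistic dropout beyond
what the NB law produces. Passing tests therefore demonstrate the
pipeline's statistical machinery on data satisfying its assumptions,
not robustness to every artifact of real droplet data.

# Numerical and design choices

- **Wilcoxon p-values** use the exact U distribution when the pooled
  sample is at most 12 and tie-free, otherwise the normal approximation
  with tie correction and continuity correction; a zero-variance
  (all-tied) comparison returns p = 1.
- **PC count.** The elbow rule (first component contributing under 5%
  of total sd after the decrease flattens below 0.1% of total) is
  implemented and tested, but atlases default to an explicit 10
  components: on data whose trailing eigenvalue spectrum is flat the
  rule can fire very early, and pinning the dimensionality is what
  atlas analyses do in practice anyway (20 or 10 being typical).
- **Cluster labels** are ordered by decreasing size, so "cluster 0" is
  always the largest; Louvain runs under a set seed and labels are
  stable across reruns.
- **Degenerate inputs** are defined, not fatal: zero-total cells
  normalize to zero with a warning; a constant matrix yields a
  lexicographic HVG ordering with a warning; an empty marker table
  after restriction gives an overlap result with k = 0 and p = 1;
  thresholds that remove every cell warn rather than error.
- **Determinism.** Every stochastic step (partial SVD initialization,
  Louvain, UMAP) takes a seed from configuration; fixed seed implies
  bit-identical output, which the tests assert.
- **p-value reporting.** Text output prints overlap p-values as upper
  bounds ("p < 4e-19") to match how such values are conventionally
  quoted; stored values keep full precision.

# Problem sizes

The reference study conditions are 2700 cells per species (5400 total),
3000 genes per species, 2000 shared 1:1 orthologs, and a 20,000-gene
bulk triplet. The test suite re-runs the full comparative pipeline on
these conditions across five seeds, and unit tests use a reduced
configuration (5 types, 640 cells, 600 genes) where the full scale adds
nothing to the property under test.

# Known limitations

- Exactly two datasets integrate at a time; multi-species or
  multi-batch integration would require chaining against a reference.
- One-to-many and many-to-many orthologs are carried in the table but
  excluded from the shared space; paralog-aware comparison is out of
  scope.
- The OLS covariate regression removes linear trends only.
- The composition weights treat each species as one sample; replicate
  structure within species is not modeled.
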