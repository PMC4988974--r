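---
title: "Methods: comparative differential co-expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative differential co-expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conetdiff)
```

This vignette documents the models, parameters and numerical choices
behind `conetdiff`. The package compares weighted gene co-expression
networks built from two related species' multi-tissue expression panels
over a shared ortholog space, and asks which modules are preserved, how
robust each network is to targeted attack, and which hub genes are wired
differently between the species.

## The data model

Inputs are two gene-by-sample matrices of log-scale expression (e.g.
log-transformed FPKM), one per species, with tissues as samples — the
motivating setting is 8 tissues in one species and 6 in the other.
Transcripts are mapped onto shared ortholog identifiers through best-hit
maps (e-value ≤ 1e-5, one best hit per transcript). When several
transcripts of one species map to the same ortholog, the transcript with
the largest sample standard deviation is kept: with so few samples, the
most variable isoform carries the most network-usable signal. Ties break
lexicographically so the collapse is deterministic.

Quality control drops genes with more than 50% missing values (the
threshold is a parameter; there is no universally right value) and genes
whose sample SD is below 1e-8 (constants carry no correlation
information). Sample outliers are flagged when their standardized mean
inter-sample correlation falls below −2.5, a concrete rule for the common
"no outlier present" check. Comparability of the two datasets is
summarized by the Pearson correlation of ranked per-gene mean expression
(a Spearman correlation of averages), which is robust to platform- or
species-level scale differences.

## Differential expression

Each ortholog is tested with an equal-variance two-sample *t* test using
the pooled variance

$$ s_p^2 = \frac{SD_1^2 (n_1 - 1) + SD_2^2 (n_2 - 1)}{n_1 + n_2 - 2}, $$

with $n_1 + n_2 - 2$ degrees of freedom and two-sided p-values by default.
The pooled (not Welch) form is used deliberately: the degrees of freedom
and the variance formula above define the procedure this package
implements. Before testing, genes in the bottom 30th percentile of the
pooled-variance distribution are removed — a percentile (rather than an
absolute variance cutoff) because log-FPKM scales vary between studies.
Benjamini–Hochberg correction is applied to the filtered gene set only, so
the multiplicity equals the number of genes actually tested; genes with
q ≤ 0.05 are called significant. Degenerate genes with zero pooled
variance get p = 1 when the means agree and p = 0 (with a warning) when
they do not.

## Signed networks and topological overlap

Pearson correlations of the significant genes, computed across each
species' samples separately, are transformed by the signed soft threshold

$$ a_{ij} = \left( \frac{1 + \mathrm{cor}_{ij}}{2} \right)^{\beta}, $$

which maps correlation −1 to 0 and +1 to 1, preserving the sign of
co-regulation. The default power is β = 14; `pick_soft_threshold()` can
instead scan candidates and choose the smallest power whose connectivity
distribution fits a power law with R² ≥ 0.8 (log-log regression over 10
connectivity bins). Adjacencies then become topological overlaps

$$ TOM_{ij} = \frac{l_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}},
   \qquad l_{ij} = \sum_{u \neq i,j} a_{iu} a_{uj},
   \qquad k_i = \sum_u a_{iu}, $$

with $u$ excluded from $\{i, j\}$ in the shared-neighbor sum (automatic
with a zero diagonal) and diagonal TOM set to 1. Clustering operates on
DisTOM = 1 − TOM. Isolated node pairs get TOM 0.

## Module detection

Modules come from average-linkage hierarchical clustering of DisTOM with a
two-stage cut:

1. **Core stage.** A static cut at the $0.99 - 0.02 \cdot \mathrm{deepSplit}$
   quantile of merge heights, followed by a recursive split of any branch
   whose merge height exceeds the smaller merge height of its non-leaf
   children by more than $0.25 - 0.05 \cdot \mathrm{deepSplit}$. The
   deepSplit level (0–4, default 2) therefore controls both how low the
   static cut sits and how small a height gap justifies a split. Branches
   below `min_module_size` (default 20, minimum 3) become grey.
2. **kME refinement (optional, recommended).** When the expression matrix
   is supplied, branch cores seed an iterative refinement: module
   eigengenes (first principal component of the gene-standardized member
   expression, oriented so its correlation with the module mean is
   non-negative) are recomputed, every gene is assigned to the module
   whose eigengene it correlates with best if that correlation reaches
   `kme_cut` (default 0.8), other genes go grey, undersized modules
   dissolve, and the loop repeats (3 iterations or convergence).

The refinement stage exists because short sample panels defeat pure tree
cutting: with 8 samples the null distribution of a Pearson correlation has
standard deviation ≈ 0.38, so some background genes genuinely correlate
with any module and average-linkage trees chain through them. On planted
4-module benchmarks (sizes 60/50/40/30 over 300 noise genes) the core
stage alone reaches an adjusted Rand index of roughly 0.2–0.5 while the
refined partition reaches 0.9–0.96; no global `cutree` height recovers the
planted structure at all. The default `kme_cut = 0.8` reflects the same
small-n logic: member genes under the generative model have population
kME ≥ 0.85 or so, while the 0.05-level critical correlation at n = 8 is
about 0.71, so 0.8 trades a small loss of weakly-loaded members for strong
exclusion of chance-correlated background. Genes are sorted before
clustering, so the partition is invariant to input order; colors follow
the conventional size ordering (turquoise, blue, brown, …) with ties
broken by the smallest member gene id.

With all pairwise dissimilarities exactly equal the cut degenerates to a
single module (if the common distance is within the gap tolerance) or to
all-grey; this is documented behavior, not an error.

## Module preservation

`z_summary()` imposes the reference partition on the test dataset and
scores each module with two density statistics (mean intramodule
correlation and mean intramodule adjacency in the test network) and two
connectivity statistics (correlation of intramodular connectivities and of
kME vectors between reference and test, with the test eigengene computed
on the mapped gene set — module definitions are imposed, not re-detected).
Each statistic is standardized against `n_perm` (≥ 50, default 100)
same-size random gene sets drawn without replacement from the shared
universe; `z_density` and `z_connectivity` are medians of their groups and
`z_summary` their mean — a reduced but structurally faithful version of
the published composite preservation statistic, fully specified and fast
at desk scale. Categories use the standard thresholds (< 2 not preserved,
2–10 moderate, > 10 strong). A random "gold" module of `gold_size`
(default 50) runs through the identical machinery as a negative control
and is excluded from preservation claims. Cross-tabulation of two
partitions uses two-sided Fisher exact tests per cell; module pairing for
downstream hub analysis considers only enriched cells (observed overlap
above expectation), since a two-sided p can also be small for depletion.

## Robustness under targeted attack

For attack analysis the weighted network is binarized; the default keeps
the top 5% of off-diagonal weights (a percentile rule, so the two species'
graphs have comparable densities — an absolute τ is available). Nodes are
then deleted one at a time in decreasing order of degree, betweenness,
closeness (computed within components as inverse mean geodesic distance),
or eigenvector centrality (principal eigenvector of the largest
component), with uniform random deletion (25 repetitions averaged,
seeded) as control. Rankings are static by default — the deletion order is
fixed from the intact graph — with re-ranking after every removal
available behind `recalc = TRUE`. After each removal,
$\sigma(i/N)$ records the largest-component size over the *original* node
count, so the last entry is exactly 0, and

$$ R = \frac{1}{N} \sum_{i=1}^{N} \sigma(i/N), \qquad V = \tfrac12 - R,
   \qquad V_{max} = \sqrt{V_k^2 + V_{BC}^2 + V_{CC}^2 + V_{EC}^2 + V_R^2}. $$

$R + V = 1/2$ holds exactly by construction, and a graph that never
fragments yields $R = (N-1)/(2N)$. Ties in centrality break by node id so
trajectories are reproducible.

## Divergent hubs

Within a matched module pair, intramodular connectivity is
$k_i = \sum_{j \in M, j \neq i} a_{ij}$ (adjacency row-sums restricted to
the module) and $K_i = k_i / k_{\max}$, so exactly the most connected
gene(s) reach 1. The hub table holds orthologs in both modules with
$K_i > 0.6$ in at least one species (the strict inequality is the default;
the boundary is configurable), sorted by the reference $K_i$; divergence
is flagged at $|\Delta K_i| \ge 0.2$, a default chosen because it isolates
exactly the three divergent genes in the package's bundled 17-row worked
example. No significance test is attached to $\Delta K_i$ — none is
defined for it — so the flag is a ranking device, not an inference.

## Gene–metabolite networks

Metabolite integration consumes a precomputed gene–metabolite correlation
table. Seed edges are module genes with $|PCC| \ge 0.80$; one hop of
first-neighbor expansion adds every gene connected to a seed metabolite at
the same threshold (the absolute value is thresholded; the sign is kept on
the edge). Networks are compared per metric — gene nodes, metabolite
nodes, edges, density, module genes with a partner — deliberately without
a single scalar "complexity" score.

## The synthetic generator

`generate_paired_datasets()` emulates the paired study design: shared
ortholog baselines (N(5, 1.5²)), per-module latent factors with
per-sample tissue mean shifts, gene loadings uniform on [0.5, 1] (or
fixed per module), Gaussian noise (default SD 0.25 on the log scale),
optional duplicate transcripts (doubled noise SD, exercising the max-SD
collapse), background genes as pure noise, and metabolite profiles
constructed as $r \cdot z(\mathrm{gene}) + \sqrt{1 - r^2}\,\varepsilon$
so the population correlation equals the target.

Three design choices deserve explanation:

* **Orthogonalized factors.** The realized latent factors are
  orthogonalized across modules (and against the intercept) within each
  species. With 6–8 samples, independently drawn factors frequently have
  sample correlations above 0.5, in which case two "distinct" planted
  modules are genuinely one correlated block in the realized data and the
  ground-truth partition is not identifiable by any method. Orthogonal
  factors make planted modules distinct expression programs — the property
  a module-recovery benchmark needs the truth to have.
* **Hub divergence is a correlation-scale decoupling.** A divergent hub
  keeps a pure high-loading module profile in species B, while in species
  A its profile is $(1-\delta) f_M + \sqrt{1-(1-\delta)^2}\, d$ with $d$ a
  gene-specific direction orthogonal to all module factors
  ($\delta$ = `hub_delta`, default 0.3). A pure loading change cannot
  plant a connectivity gap — correlations are scale-invariant, so a
  loading-only gap vanishes at exactly the same rate as the noise —
  whereas mixing in an orthogonal component caps the hub's correlation to
  its module at $1-\delta$ regardless of noise, which the soft-threshold
  power then amplifies into a realized $\Delta K_i$ well above the
  planted floor of `hub_delta`/2.
* **Noise levels per experiment.** The default `noise_sd = 0.25` gives
  within-module correlations around 0.9, a realistic regime for module
  detection and preservation benchmarks. Connectivity-level experiments
  (hub divergence) use `noise_sd = 0.1` in the package's tests: estimating
  per-gene intramodular connectivity from 6–8 samples requires tight
  modules, and at noise 0.25 the between-species $K_i$ sampling noise
  (±0.3 and worse) is of the same order as any plantable effect.

What the generator does *not* emulate: count-level sequencing noise and
normalization artifacts (it generates log-scale values directly),
between-tissue correlation structure beyond mean shifts, overlapping
modules, and realistic gene-length or expression-level biases. Passing
recovery benchmarks on this generator therefore demonstrates correctness
of the pipeline's logic under its own model assumptions, not performance
on real RNA-seq.

## Problem sizes and determinism

The shipped tests and the acceptance script run at desk scale — around
500–2000 genes, 8 + 6 samples, 50–100 permutations, 10–20 seeded
repetitions per property — sizes chosen so the full suite completes in
well under a minute while keeping the statistical assertions stable across
seeds. Every stochastic stage (generator, permutation nulls, random attack
orderings) takes an explicit seed, and seeded helpers restore the caller's
RNG state, so identical inputs and seeds reproduce identical outputs
byte for byte.

## Known limitations

* The tree-cut is a fully specified simplification of the dynamic
  tree-cut family; on real data its module boundaries will differ from
  other implementations, though the deepSplit control behaves analogously.
* The Z-summary uses 4 statistics rather than the full published
  catalogue; thresholds (2, 10) are standard but the score is not
  numerically interchangeable with other implementations.
* Binarization for robustness discards weights; the percentile default is
  a pragmatic density-matching rule, and V_max values depend on it.
* With 6–8 samples, per-gene connectivity estimates are intrinsically
  noisy; divergent-hub flags on real data of this size should be read as
  candidate rankings, not discoveries.
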