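---
title: "Methods: robust multi-dataset subclustering and stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: robust multi-dataset subclustering and stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind `nichecluster`, in the spirit of a methods supplement: it
states what each stage assumes, which knobs matter, and what the synthetic
benchmarks do and do not demonstrate. No empirical claims are made here
beyond what the package's test suite and `scripts/acceptance.R` themselves
compute.

## The problem

Cell subpopulations of a tissue niche — endothelial and mesenchymal stromal
cells of the bone marrow are the motivating case — are profiled by several
scRNA-seq datasets with different sorting strategies and batch structure.
Two failure modes dominate joint analyses: *under-clustering* (one-shot
community detection at moderate resolution merges genuinely distinct
states) and *over-clustering* (high resolution invents splits that are
artifacts of sampling noise). The package treats these asymmetrically:
subclustering is pushed as deep as a high-resolution reference permits, and
a resampling-based classifier then audits every cluster, dissolving those
that do not survive.

## Preprocessing

**QC filtering** is applied per dataset of origin. A cell is kept when its
number of detected features and its total counts both lie within the
`[q_low, q_high]` quantiles of its dataset (defaults 0.10 / 0.90), its
mitochondrial read fraction is at most `mito_max`, and (optionally, the
human convention) its immunoglobulin read fraction is at most `ig_max`.
Defaults follow the two species conventions: mouse 10th/90th quantiles + 5%
mitochondrial; human additionally 10% mitochondrial and 10% immunoglobulin
(`qc_thresholds_human()`), the latter guarding against B-cell
contamination. Quantiles use the common linear-interpolation convention
(type 7) and cells exactly at a bound are retained; the two quantile
filters are intersected, and both are computed on the original dataset (not
sequentially), so their order cannot matter. With the quantile filters
disabled the filter is exactly idempotent; with them enabled a second pass
can remove further cells only because the quantiles themselves move.

**Normalization** is log library-size scaling:
`norm = log(1 + count × scale / total)`, `scale = 10^4`. Variance-
stabilising transformations can be substituted by attaching any externally
computed layer of the same shape (`expression_dataset(norm = ...)`); every
downstream stage consumes only the normalized layer.

**Most variable genes** are ranked by standardized dispersion: per-gene
variance of the normalized values divided by the mean variance of genes in
the same mean-expression bin (20 equal-frequency bins). The binning removes
the mean–variance trend of count noise; a degenerate case worth knowing is
a fixture in which planted markers fill an entire top bin, where they
normalise against themselves — benchmarks therefore use gene universes
large enough that no bin is marker-dominated, which is also the realistic
regime.

## Integration and label transfer

The joint embedding standardizes each gene within each dataset (removing
per-dataset location and scale) and projects the pooled cells onto the top
`n_dims = 20` principal axes. Axis signs are fixed by making each axis's
largest-magnitude loading positive, so the embedding is deterministic.
This is deliberately simple; anchor-based integration is treated as an
external, pluggable step — an embedding computed elsewhere can be imported
from TSV (`read_embedding()`) and used by every downstream function.

Reference labels (e.g. sorted LEPR+ / VE-Cad+ identities) move onto query
cells by k-nearest-neighbor majority vote in the embedding (`k = 30`),
with the majority fraction as score; ties break by smaller mean distance,
then lexicographically, and scores below 0.5 yield `"unassigned"`. The
choice of kNN majority (rather than cluster co-membership) is one concrete
reading of "aligning" query cells with a reference class; `k` and the
cutoff are configuration, not biology.

## Divide-and-conquer clustering

The graph is a shared-nearest-neighbor graph: each cell's neighbor set is
itself plus its `k = 20` nearest cells; kNN edges are weighted by the
Jaccard overlap of the two neighbor sets and pruned below 1/15. Louvain
community detection (igraph) at resolution 1 on the full dataset gives the
**high-resolution reference** — the upper bound on how fine the final
partition may become.

Each node of the tree is then processed as follows:

* nodes smaller than `min_cells = 40` (bootstrap evaluation with 5 folds
  and forest training need tens of cells) or at `max_level = 5` become
  leaves;
* the node's *occupied* reference communities are those with more than
  half of their cells inside the node; at most one occupied community
  means no subdivision exists under the reference — a leaf
  (`highres_single`), the hierarchy's termination criterion;
* otherwise the node is re-embedded on its own most variable genes (the
  within-node signal differs from the global one, which is what makes
  iterative subclustering see more than one-shot clustering), resolutions
  0.1–1.2 are swept, and the candidate with the best mean silhouette wins,
  subject to two constraints: at most as many subclusters as occupied
  reference communities, and mean silhouette at least
  `min_silhouette = 0.1`. The floor exists because modularity optimisation
  returns a partition even on structureless data, where silhouettes sit
  near 0; genuine expression-driven splits in these embeddings score well
  above 0.1. A node failing both constraints is closed as
  `highres_single` — no subdivision found under the bound.

Children are named by the dotted convention (level 1 "A", "B"; level 2
"A1"; deeper "A2.1"). All stochastic steps (Louvain) are seeded from the
configuration, making the tree a pure function of data and config.

## Bootstrap stability

For each unordered cluster pair: per repeat (10 total), each cluster's
cells are split into 5 near-equal folds (fold sizes differ by at most one
cell when sizes are not divisible). For each fold, differential expression
between the two clusters is computed **on the training 80% only** — test
cells never influence feature selection — by Wilcoxon rank-sum over the
configured gene universe; the top 10 genes per direction by average log2
fold change (at most 20 features) train a random forest (ranger, 500
trees, √features per split, seeded) that classifies the held-out fold.
Each cell is thus classified exactly once per repeat.

Summaries follow the three definitions: dominant cluster (assigned in
more than half the runs; an exact 5/5 split has no dominant), recall per
cell, and #Correct. The instability rule is: a cluster is unstable when
more than 50% of its cells have at least one pairwise comparison whose
dominant cluster **is not their own** — either another cluster won more
than half the runs, or no cluster reached a majority. Counting the
no-majority case as a failure is a deliberate reading of "incorrectly
assigned robustly": a cell without a majority for its own cluster was
assigned away from home in at least half the runs. The stricter
alternative (count only outright wrong dominants) was evaluated and has a
blind spot exactly where the rule matters most: for a cluster split into
two statistically identical halves, symmetry caps the outright-wrong
fraction near 0.5 minus half the tie mass, so such splits hover at the
threshold instead of clearing it. Under the implemented reading over-split
halves score well above 0.5 while genuinely distinct clusters score 0.

**Dissolution** iterates: evaluate, dissolve the single worst unstable
cluster (highest failing-cell fraction), reassign its cells among the
remaining clusters with a random forest trained on their cells (features:
union of each remaining cluster's top 10 one-vs-rest DEGs), re-evaluate —
up to 3 dissolutions. One-at-a-time matters: when both halves of an
over-split cluster are unstable, dissolving them simultaneously would
leave no sibling to absorb the cells; sequentially, the first half flows
into the second and the merged cluster then passes.

A practical operating characteristic: detection power grows with cluster
size. The frozen sampling-noise differences between two random halves of a
cluster shrink as 1/√n, so with very small clusters the classifier can
partially learn the split and detection becomes borderline; at the
benchmark size (200 cells per cluster, in line with the hundreds of cells
per cluster typical of the motivating datasets) detection is reliable.

**Dataset-mixing entropy** summarises batch composition per cluster:
`H = −Σ_d p_d ln p_d` over the cluster's dataset-of-origin proportions
(natural log, `0 ln 0 = 0`), reported alongside `H / ln D`. Each cell's
dataset probability is estimated by its cluster's composition, so the
per-cluster average equals the cluster-level entropy — the only estimator
available without a per-cell model.

## Markers, added value, annotation

The Wilcoxon rank-sum test is vectorised over genes: normal approximation
with tie correction and continuity correction in general, exact
enumeration of the rank-sum null when both groups have ≤ 10 cells (the
two-sided exact p is twice the smaller tail, capped at 1). Effect size is
`avg_log2fc = log2((mean(expm1 norm_A)+1) / (mean(expm1 norm_B)+1))` — a
pseudocount of 1 on the de-logged group means; p-values are Benjamini–Hochberg
adjusted over the tested universe. Markers are one-vs-rest DEGs gated at
`p_adj < 0.05` (configurable) and ranked by fold change; top 30/50/100 are
the conventional set sizes.

Added-value rates treat the integrated marker set `I` as truth and a
single dataset's set `S` as the attempt: recovered = `|I∩S|/|I|`,
FN = `|I\S|/|I|`, FP = `|S\I|/|S|` (an empty `S` reports FP 0 with a
flag). The FP denominator is the single-dataset set size — the natural
reading of "fraction of the single-dataset markers that are spurious".
Jaccard matrices compare partitions cluster-by-cluster on the common cell
universe. Signature annotation is one-shot nearest-centroid: each query
cell takes the reference profile (mean normalized expression over the
marker union) with the highest Spearman correlation; iterative
fine-tuning of annotation tools is intentionally out of scope, and at
least half the signature genes must be present in the query.
Over-representation is the upper-tail hypergeometric test; annotation
databases are user-supplied (GMT).

## Cross-species conservation

Mouse symbols map to human by uppercase normalisation ("Cxcl12" ↔
"CXCL12"), overridable pair-by-pair with an explicit two-column table;
mapping precedes intersection (the only order under which cross-species
symbol sets can intersect at all). For cluster *i* with `l_i` DEGs drawn
from the mouse MVG universe, the expected shared count with the human MVG
set is `(|MVG_h ∩ MVG_m| / |MVG_m|) × l_i` and `ES_i` is observed over
expected (NA when the expectation is 0). A permutation companion samples
`l_i` genes uniformly from the mouse universe `n_perm` times; its mean ES
is 1 by construction and the 2.5/97.5% quantiles give an empirical null
band. ES values are conventionally read to two decimals.

## The synthetic-data generator

Counts are negative binomial with a shared dispersion (size 2 by
default) — the standard overdispersed model for UMI counts. The mean of
gene g in cell c is `baseline × 2^(marker effects) × 2^(batch shift)`:
each node of the planted hierarchy carries its own marker genes
(disjoint across nodes, default 20 per node at log2FC 3 — strong,
clean markers) up-regulated in its whole clade, so sibling separation
exists at every level; batch shifts are per-gene, per-dataset normal draws
in log2 units (default sd 0.25, a moderate batch effect; 0 disables).
Mitochondrial and immunoglobulin genes are named by the species prefixes
and their means are rescaled per cell so the expected content fraction
follows a Beta distribution (defaults: mito mean 3%, immunoglobulin 2%) —
enough spread to exercise both QC filters. Baseline mean 0.5
counts/gene/cell gives realistic sparsity (~60–70% zeros). The planted
structure (marker positions, batch shifts) is seeded separately from the
per-cell noise, so `simulate_dataset(spec, noise_seed =)` draws fresh data
from the *same* generative model — what signature-annotation and
label-transfer benchmarks require.

What the simulator does **not** emulate: zero-inflation beyond NB,
doublets, ambient RNA, cell-cycle structure, per-gene dispersion
variation, and correlated gene programs. Passing benchmarks on it
demonstrates the machinery's correctness and calibration under its stated
model, not performance on any real tissue.

## Benchmark problem sizes

The acceptance-level checks run at sizes chosen to be informative yet
desk-scale: hierarchy recovery plants 14 leaves over 3 levels in ~3000
cells × 2000 genes across 3 datasets (71 cells per leaf per dataset);
over-clustering detection uses 3 clusters × 200 cells × 600 genes with one
cluster randomly halved; conservation fixtures use universes of 2000–3000
genes. Metric identities (exact Wilcoxon p, hypergeometric p, entropy
closed forms, ES arithmetic) are checked exactly.

## Known limitations

* The embedding-based integration removes per-dataset location/scale per
  gene but not nonlinear batch structure; strong batch effects may need an
  external integration, imported as an embedding.
* The silhouette floor (0.1) is a heuristic guard against splitting noise;
  extremely subtle but real substructure below it will be merged — the
  stability audit cannot recover structure the tree never proposes.
* Dominance with 10 repeats quantises at 1/10; clusters sitting exactly at
  the 50% instability threshold are decided by the bootstrap seed.
* The case-rule ortholog map is a symbol-level convenience; paralog
  families and non-trivial orthology need the explicit table.
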