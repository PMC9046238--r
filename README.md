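# nichecluster

Robust characterisation of cell subpopulations across multiple single-cell
RNA-seq datasets.

When several scRNA-seq datasets of the same tissue are analysed together —
for example bone-marrow niche populations (endothelial and mesenchymal
stromal cells) profiled by different labs — standard one-shot community
detection either misses fine substructure or invents clusters that do not
survive resampling. `nichecluster` implements a two-stage answer:

1. **Divide-and-conquer subclustering bounded from above.** A Louvain
   clustering at resolution 1 on the shared-nearest-neighbor graph serves as
   a *high-resolution reference*: the finest structure the data supports.
   Clusters are then split recursively — each node is re-embedded on its own
   most variable genes, a resolution sweep is scored by mean silhouette, and
   a node whose cells occupy at most one reference community is never split
   further. Leaves carry dotted names recording the hierarchy ("A", "A2",
   "A2.1").

2. **Bootstrap random-forest stability.** For every pair of clusters, over
   10 repeats, cells are split into 5 folds; on each training 80% the
   top 10 differentially expressed genes per cluster (Wilcoxon rank-sum,
   ranked by average log2 fold change) feed a random forest that classifies
   the held-out fold, so each cell is classified once per repeat. Per cell
   and pair the *dominant cluster* is the one assigned in more than half the
   runs; *recall per cell* is the fraction of correct assignments over all
   pairs and runs, and *#Correct* counts pairs whose dominant matches the
   original cluster. A cluster in which more than 50% of cells have at least
   one comparison whose dominant is not their own cluster is **unstable**:
   it is dissolved and its cells are reassigned to the remaining clusters by
   a random forest, iterating until the partition is stable.

Around this core the package provides dataset-mixing Shannon entropy
(`H_j = -Σ_d p_jd ln p_jd` per cluster, normalised by `ln D`), marker
detection with added-value analysis across datasets (false-negative /
false-positive marker rates of single-dataset analyses against the
integrated result), Jaccard partition comparison, nearest-centroid signature
annotation, hypergeometric over-representation, and a cross-species
conservation **enrichment score**: for mouse cluster *i* with `l_i` DEGs,

    ES_i = |MVG_human ∩ DEG_mouse,i| / ( |MVG_human ∩ MVG_mouse| / |MVG_mouse| × l_i )

i.e. observed shared genes over the count expected at the genome-wide
baseline overlap rate (mouse symbols mapped to human by case normalisation
or an explicit ortholog table).

Everything is testable without downloads: a negative-binomial simulator
plants hierarchical cluster structure, per-gene batch effects and
mitochondrial / immunoglobulin content with known ground truth.

## Worked example

```r
library(nichecluster)

spec <- simulation_spec(
  cluster_tree = sim_hierarchy(list(2, c(2, 2)), n_markers = 20, log2fc = 3),
  n_datasets = 3, cells_per_cluster = 50, n_genes = 1000, seed = 42)
sim <- simulate_dataset(spec)

qc  <- qc_filter(sim$dataset)          # per-dataset 10th/90th quantile + 5% mito
ds  <- normalize_counts(qc$dataset)    # log library-size normalization
tree <- run_divide_and_conquer(ds, nc_config(seed = 42))
print(tree)
#> cluster_tree: 365 cells, 5 nodes, 4 leaves, depth 1
#>   leaves: A(95) B(94) C(89) D(87)

part <- leaf_partition(tree)
stab <- evaluate_stability(ds, part, genes = select_mvg(ds, 300), seed = 42)
tidy(stab)
#> # A tibble: 4 × 6
#>   cluster n_cells mean_recall mean_n_correct frac_wrong_dominant unstable
#> 1 A            95       1.000              3                   0 FALSE
#> 2 B            94       1                  3                   0 FALSE
#> 3 C            89       1                  3                   0 FALSE
#> 4 D            87       0.998              3                   0 FALSE

tidy(dataset_entropy(part, ds))
#> # A tibble: 4 × 4
#>   cluster n_cells entropy entropy_norm
#> 1 A            95    1.10        0.999
#> 2 B            94    1.10        1.000
#> 3 C            89    1.09        0.994
#> 4 D            87    1.10        1.000
```

The four planted level-2 clusters are recovered exactly; every cluster is
robust (all cells' dominant clusters match their own in all pairwise
comparisons, mean recall ≈ 1), and each cluster mixes the three simulated
datasets at near-maximal entropy (`entropy_norm ≈ 1`), i.e. no batch
segregation. `cluster_markers()` then returns each cluster's planted marker
genes at the top of its table (average log2 fold changes ≈ 3, matching the
simulated effect), and `autoplot()` / `plot_cluster_tree()` visualise any of
the result objects.

A command-line wrapper over the same functions ships at
`inst/scripts/nichecluster.R` (subcommands `simulate`, `qc`, `cluster`,
`stability`, `conserve`).

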