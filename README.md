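# uncles

Consensus clustering of gene expression across many heterogeneous datasets,
with the downstream statistics used to turn consensus clusters into
prognostic gene signatures.

## The problem

A single transcriptomic experiment rarely settles which genes are genuinely
co-regulated: platforms differ, conditions differ, and many genes are simply
missing from older arrays. Merging datasets into one matrix imports every
platform's artefacts. This package instead clusters each dataset
independently with several methods and asks which gene groupings *survive
the consensus* — the UNCLES type A strategy built on binarisation of
consensus partition matrices (Bi-CoPaM):

1. **Partition generation.** C clustering methods (k-means with
   deterministic Kaufman initialisation, a self-organising map with bubble
   neighbourhood, Ward hierarchical clustering) run on each of L datasets at
   a fixed K, giving R = C × L hard partitions.
2. **Min-min relabelling.** Cluster labels are aligned across partitions by
   greedily matching the globally best-fitting cluster pairs first (cost =
   symmetric difference of gene sets on shared genes), so the tightest
   clusters are matched well even at the expense of poor ones.
3. **CoPaM averaging.** The relabelled partitions are averaged element by
   element into a fuzzy K × G consensus partition matrix. A gene present in
   only some datasets is averaged only over the partitions that saw it
   (membership weighted by presence), so genes need only appear in L* of
   the L datasets — the extension that roughly doubles usable genome
   coverage on real multi-platform collections.
4. **Difference threshold binarisation (DTB).** A gene is assigned to its
   top cluster only when that fuzzy membership beats every other cluster's
   by at least δ ∈ [0, 1]; contested genes stay unassigned. Larger δ, tighter
   clusters.

Running the pipeline over a grid of K and δ yields hundreds of candidate
clusters. The **M-N scatter plot** scores each candidate by dispersion (a
modified mean-square error, averaged per dataset over the genes present
there) against log₁₀ size, and repeatedly selects the candidate closest to
the top-left corner (tight *and* large), discarding everything that
overlaps it, until the plot is empty.

Around the clustering core the package provides:

- an exact log-space **hypergeometric upper-tail** test for cluster/gene-list
  overlap (accurate down to p ≈ 10⁻³⁰⁰), Venn-region accounting, and
  multi-list consensus counting;
- **clinical signature statistics**: hypoxia scores (per-sample signature
  medians, rank-scaled to [0, 1]), univariate Cox proportional-hazards
  ratios, ROC/AUC at a survival horizon, per-gene and signature-level
  ER-status ANOVA with fold-changes, a random-set tightness test, and
  Spearman-correlation sub-cluster discovery;
- a **synthetic-data generator** that plants known co-expressed clusters
  (optionally anti-correlated), per-dataset missing genes with an L* floor,
  and clinical cohorts with known log-hazard effects and ER fold-changes, so
  the whole pipeline is testable end to end without any downloads.

## Worked example

```r
library(uncles)

design <- planted_design(
  n_genes = 400, n_datasets = 5, samples_per_dataset = c(4, 6, 5, 3, 7),
  clusters = c(60, 80), anticorrelated_pairs = list(c(1, 2)),
  noise_sd = 0.3, min_presence = 4, missing_fraction = 0.1, seed = 42)
coll <- generate_collection(design)
fit  <- uncles(coll, k_values = c(6, 8), seed = 1)
sel  <- mn_select(fit, max_clusters = 5)
sel
#> M-N scatter-plot selection:
#>  rank  distance K delta size       mse
#>     1 0.1447548 8   0.4   80 0.1234477
#>     2 0.1413247 6   0.5   60 0.1039562
#>     3 0.8319972 8   0.3    5 0.5277739
#>     4 0.8270273 8   0.2    3 0.3763224
#>     5 0.8286894 6   0.4    2 0.1028370
```

The first two selections are exactly the planted 80- and 60-gene
anti-correlated clusters (ranks 3–5 are small noise fragments, far from the
corner). Overlap enrichment against the planted truth, and the mean-profile
correlation between the two selections in dataset 1:

```r
truth <- attr(coll, "truth")
overlap_test(sel$clusters[[1]]$genes, truth$clusters[[2]], coll$gene_universe)
#> Hypergeometric overlap: k = 80 of list K = 80 in cluster n = 80 (universe N = 400)
#>   upper-tail p = 2.37e-86
cluster_profile_correlation(sel$clusters[[1]]$genes, sel$clusters[[2]]$genes,
                            coll$datasets[[1]])
#> [1] -0.9986138
```

A synthetic clinical cohort whose hazard depends on the first selected
cluster's activity, scored and fitted:

```r
cohort <- generate_clinical(
  clinical_design(n_samples = 300, signature_effects = c(sig1 = 1.2),
                  n_background_genes = 1000, seed = 1),
  list(sig1 = sel$clusters[[1]]$genes))
hs <- hypoxia_score(sel$clusters[[1]]$genes, cohort, "selected-1")
cox_hr(hs, cohort)
#> Cox PH: HR = 4.039 (beta = 1.396 +/- 0.230), p = 1.24e-09, 240/300 events
roc_auc(hs, cohort, horizon_years = 10)$auc
#> [1] 0.7276134
```

The hazard ratio is per full 0→1 range of the hypoxia score; the fitted
log-hazard 1.40 ± 0.23 brackets the planted 1.2.

A YAML-configured end-to-end run (simulate → normalise → cluster → select →
score) is available through `run_pipeline()` and the thin CLI at
`inst/cli/uncles.R`; every run writes its artefacts plus a JSON manifest
with MD5 checksums, and identical configurations reproduce identical
outputs.

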