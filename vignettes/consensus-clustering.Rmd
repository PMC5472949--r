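---
title: "Consensus clustering across heterogeneous expression datasets: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus clustering across heterogeneous expression datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uncles)
```

# The model

The package answers one question: *which groups of genes are co-expressed
consistently across every dataset in a heterogeneous collection?* Datasets
may come from different microarray platforms, different laboratories and
different experimental designs, and may each be missing different genes, so
the collection is never merged. Instead each dataset is clustered
independently and the partitions are combined.

For a fixed cluster count $K$, $C$ base methods applied to $L$ datasets give
$R = C \times L$ hard partitions. After aligning cluster labels, the
partitions are averaged into the fuzzy consensus partition matrix (CoPaM)
$F \in [0,1]^{K \times G}$, where $F_{kg}$ is the fraction of partitions
assigning gene $g$ to cluster $k$ — with the crucial weighting that the
average for $g$ runs only over the partitions whose dataset measured $g$.
A gene is admitted to the analysis when it appears in at least $L^*$ of the
$L$ datasets; every consensus quantity downstream respects that presence
mask. Difference threshold binarisation (DTB) then assigns $g$ to its
argmax cluster $k^*$ iff $F_{k^*g} - F_{kg} \ge \delta$ for every other $k$,
and leaves it unassigned otherwise. At $\delta = 0$ we additionally require
the maximum to be strict: an exactly tied gene belongs to no cluster. This
keeps $\delta = 0$ meaningful and makes the $\delta$-grid nest: raising
$\delta$ can only shrink clusters, a property the test suite asserts over
the whole grid.

## Base clusterers

* **k-means with Kaufman initialisation.** The first centre is the point
  minimising total Euclidean distance to all points; each further centre is
  the point maximising the summed positive reduction in the other points'
  nearest-centre distances; Lloyd iterations (squared Euclidean, at most 300
  sweeps) follow. The procedure has no random element, so repeated runs are
  identical. A cluster emptied during Lloyd is re-seeded with the point
  farthest from its assigned centre.
* **Self-organising map, bubble neighbourhood.** Units form the most square
  factor-pair grid of $K$ (4×4 at $K=16$, 2×4 at $K=8$, 5×8 at $K=40$); the
  neighbourhood is a hard bubble whose radius decays linearly from
  $\max(\text{dims})/2$ to 1, and units strictly inside the radius move with
  the winner, so the final phase updates the best-matching unit alone. The
  codebook is initialised at Kaufman-seeded data points: random-row
  initialisation can start two units inside one tight cluster, and on small
  grids the shrunken bubble offers no escape, merging distinct clusters.
  The seeded random presentation order (`epochs` passes over the genes,
  default 100) is the method's only stochastic element and is recorded in
  the partition's provenance. Units that end empty are retained as empty
  clusters so that $K$ stays aligned across partitions.
* **Ward hierarchical clustering** on Euclidean distances (`ward.D2`), cut
  into exactly $K$ groups, via `stats::hclust`.

## Relabelling

Cluster labels are aligned to the first generated partition (method 1 on
dataset 1) by *min-min* matching: over the $K \times K$ cost matrix —
cost$(i,j)$ = size of the symmetric difference between reference cluster $i$
and target cluster $j$, restricted to the genes both partitions saw — the
globally minimal open pair is matched repeatedly, ties broken by the lowest
$(i,j)$ row-major. Matching the best-fitting clusters first is exactly what
a pipeline wants when only the few tightest consensus clusters will survive
selection; the cost function itself is not dictated by the consensus
framework, and the symmetric difference is this package's documented choice.
Empty clusters participate with cost equal to the non-empty counterpart's
size, keeping the matrix total.

## M-N selection

Every non-empty binarised cluster from the $(K, \delta)$ grid becomes one
point on the M-N plane: dispersion on the horizontal axis, $\log_{10}$ size
on the vertical. Dispersion is a modified mean-square error: per dataset
$l$, over the subset $C_l$ of the cluster's genes present there,
$\mathrm{MSE}_l = \frac{1}{|C_l| D_l} \sum_{g \in C_l} \lVert x_g - \bar x
\rVert^2$ ($D_l$ = conditions), averaged over the datasets containing at
least one of the genes. Both axes are min-max normalised to $[0,1]$ over the
*current* candidates and the candidate nearest the top-left corner (low
dispersion, large size) wins; everything sharing a gene with the winner
leaves the plot, the axes are re-normalised, and selection repeats. Two
consequences of re-normalisation are deliberate: selection distances are
comparable only within a round (a lone final candidate sits at its own
plot's corner, distance 0), and an axis with no spread contributes nothing.
Distance ties prefer the larger cluster, then the lower $(K, \delta,
\text{index})$ provenance, making selection order-invariant — both are
asserted as tests.

# Enrichment arithmetic

Cluster/gene-list overlap uses the exact hypergeometric upper tail
$P(X \ge k)$ summed in log space from $k$ upward via log-gamma binomial
coefficients, clamped to $[0,1]$ against last-ulp rounding. Lists are first
intersected with the study's gene universe; genes never measured cannot
enrich anything. The test suite checks the tail against R's `phyper` for
random instances and against exact rational arithmetic (numerator/denominator
binomial sums evaluated in unbounded integers, frozen into a fixture) for a
grid covering every universe size up to 60, at $10^{-10}$ relative error.
The implementation is accurate far below double underflow of the naive sum
(printed values around $10^{-52}$ reproduce at two significant figures).

# Clinical statistics

A signature's **hypoxia score** is the per-sample median expression of its
genes, ranked over samples (average ranks on ties) and scaled as
$(\text{rank}-1)/(n-1)$ — the scaling convention is ours; only "ranked then
scaled to $[0,1]$" is inherent. Being rank-based, the score is invariant
under strictly increasing transforms of expression (exactly so for
odd-sized signatures, where the median is a single order statistic).
Downstream:

* **Cox proportional hazards** (`survival::coxph`, Efron ties, Wald
  p-values); the hazard ratio is reported per full $0 \to 1$ score range —
  dichotomisation at a cut-point is the main alternative reading and is
  deliberately not chosen.
* **ROC/AUC** labels a sample positive when death is observed within a
  horizon (default 10 years); samples censored before the horizon have
  unknown labels and are excluded. The AUC is the Mann–Whitney statistic,
  its p-value normal-approximated.
* **ER ANOVA**: per gene, one-way two-group ANOVA on standardised
  expression (the F statistic is location/scale invariant, so
  standardisation is cosmetic for p but stated for fidelity), fold-change as
  the ER+/ER− ratio of group means on the quantile-normalised positive
  scale. Signature-level significance compares member genes against the
  rest of the genome by ANOVA on $\log(-\log p)$ and $\log(\text{fold
  change})$ — both roughly log-normal genome-wide — and the signature
  fold-change is the geometric mean of its members'. Genome-wide per-gene
  statistics use the vectorised two-group identity $F = t^2$; a test pins
  it to `stats::anova` per gene.
* **Tightness test**: observed within-set MSE on per-gene standardised
  expression versus 1000 random same-size sets, a normal fitted to the null
  MSEs, $p = \Phi((\text{obs} - \hat\mu)/\hat\sigma)$. The p-value is
  uniform under the null only when the observed set is exchangeable with
  the comparison draws — both must come from the same gene pool — which the
  acceptance test demonstrates.
* **Sub-cluster discovery**: pairwise Spearman correlation among a gene
  set's members, average-linkage clustering on $1-\rho$, tree cut at
  correlation distance 0.6 (or a target count); constant genes are excluded
  with a warning since Spearman is undefined for them. Linkage and cut are
  exposed because nothing in the consensus framework fixes them.

# The synthetic-data generator

The generator is the package's test bed and defines its study conditions.
A collection design plants clusters whose members share, within each
dataset, a monotone piecewise-linear latent trajectory over conditions
(emulating gradual induction or repression through a time course), negated
for the second member of an anti-correlated pair, plus i.i.d. Gaussian
noise (`noise_sd`); background genes are independent unit-variance noise.
Per-dataset missingness is Bernoulli per (gene, dataset) with rejection
redraws enforcing the $L^*$ floor. Profiles share a common scale: per-gene
baseline offsets would be removed by the z-scoring anyway, but their rank
interactions with quantile normalisation would blur the planted zero-noise
identities that several invariants assert.

Clinical cohorts give each signature a latent activity score uniform on
$[0,1]$ per sample; signature genes multiply a log-normal baseline by
$e^{s-1/2}$, by the signature's ER fold-change in ER-positive samples, and
by log-normal noise, so signature medians track scores monotonically.
Survival is exponential with hazard $\lambda_0 e^{\sum_j \beta_j s_j}$ and
independent uniform censoring on $(0,\tau)$, with $\tau$ solved numerically
so the expected censored fraction matches the design. This model is
deliberately simple — closed-form, fast, parameters recoverable — and does
not emulate batch effects, platform-specific probe artefacts, correlated
censoring, proportional-hazards violations, or the heavy-tailed noise of
real tumour cohorts. Passing tests therefore demonstrate that the
implementation recovers what it plants under its stated noise model, not
that real clinical data would behave as cleanly.

# Numerical choices and degenerate inputs

* Standard deviations use the population convention (denominator $n$)
  everywhere; one convention, stated, testable.
* Quantile normalisation maps each value to the mean, across columns, of
  the values at its rank; a within-column tie group receives the mean of
  the rank means it spans (computed directly; the widely used
  implementation interpolates ties differently for groups spanning more
  than two ranks, and serves as a cross-check on tie-free data). One-column
  and one-row matrices are fixed points / collapse to the row mean.
* Constant one-colour genes cannot reach unit variance: their rows are
  zeroed and flagged. Two-colour (log-ratio) datasets are zero-centred per
  gene only.
* Probe selection (cell-line rule) takes the max coefficient-of-variation
  probe among those above the dataset's first quartile in $\ge 25\%$ of
  samples, falling back to max CV overall; a zero-mean probe with positive
  sd counts as infinite CV, an all-constant one is excluded. The clinical
  rule is identical with variance as the spread measure ("most variable as
  measured by covariance" is read as variance — the covariance of a single
  variable).
* DTB margin comparisons use a $10^{-12}$ tolerance so that grid-nesting is
  robust to averaging round-off; fuzzy memberships are ratios of small
  integers, so this is far below any genuine margin.
* Gene identifiers are trimmed and compared case-insensitively (mixed
  platform symbol tables); missing cells in input files are rejected rather
  than imputed — the unit of missingness is a whole gene absent from a
  dataset.

# Problem sizes in the test suite

The acceptance-level clustering run uses a seeded collection of $L = 16$
datasets (3–7 conditions each) over 2,000 genes with planted anti-correlated
clusters of 120 and 150 genes, noise sd 0.3, 15% missingness with
$L^* = 13$, clustered at $K \in \{8, 12, 16\}$ over the full
$\delta = 0, 0.1, \dots, 1$ grid — sizes chosen to exercise every code path
(missing genes, all three methods, the full grid) while a complete run of
the suite stays in the low minutes. Cox recovery is asserted as the
replicate-averaged estimate over five seeded cohorts of $n = 500$ (a single
draw has standard error $\approx 0.17$, so averaging tests bias rather than
luck); fold-change recovery uses 2,000 background genes so that quantile
normalisation's mild shrinkage of group shifts (it forces identical
per-sample distributions) stays below the assertion width. Module tests run
on collections of a few hundred genes.

# Known limitations

* Only UNCLES type A (consistent co-expression) is implemented; the type B
  contrast between dataset subsets, and binarisation techniques other than
  DTB, are out of scope.
* The M-N plane offers no significance measure; how many selected clusters
  are "good" remains the analyst's judgement (the selection table reports
  the distances).
* The SOM grid for $K$ values that are prime degenerates to $1 \times K$;
  with the bubble neighbourhood this is a harmless one-dimensional map, but
  topology-sensitive uses should pick composite $K$.
* Survival modelling is univariate; clinical covariates, competing risks
  and stratified baselines are out of scope.
* Quantile normalisation slightly attenuates genuine group differences in
  fold-change estimation (it equalises per-sample distributions); with
  signatures a few percent of the genome this bias is within a few percent,
  but it grows with the shifted fraction.
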