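# nichesplit

Integrative tools for detecting and mapping **cryptic diversity** in
narrowly distributed taxa — species complexes whose evolutionary lineages
are morphologically near-identical but genetically distinct, often each
confined to a single watershed. The package implements, as reusable and
tested components, the quantitative pipeline of a combined
molecular/morphometric/niche-modelling assessment:

- a **penalized maximum-entropy niche model** (`maxent()`), fitted
  per geographic region cluster on climate principal components plus
  terrain slope, with replicated leave-out-one-third ROC/AUC evaluation,
  max(sensitivity + specificity) thresholding, and merging of regional
  ranges (`enm()`);
- **range accounting** of the predicted suitable area against forest
  cover, protected areas and D8 watershed basins on exact spherical cell
  areas (`range_account()`, `label_basins()`);
- **16S screening** by uncorrected pairwise distance with pairwise
  deletion, within/among-lineage summaries, 3% threshold clustering into
  candidate lineages, and phased-allele sharing reports
  (`p_distance_matrix()`, `group_divergence()`, `threshold_cluster()`,
  `allele_sharing()`);
- **morphometric diagnosability**: varimax-rotated PCA with a 0.80
  loading screen, ANCOVA (SVL covariate) with Tukey HSD, ratio-based
  Kruskal-Wallis/Wilcoxon comparisons, and the pairwise
  lineage-by-lineage matrix of diagnostic traits
  (`pca_varimax()`, `ancova_tukey()`, `diagnosability_matrix()`);
- a **synthetic-world generator** with known ground truth for every
  stage: correlated low-rank climate fields, niche-driven presences,
  forest/protected masks, watershed partitions, JC69-evolved 16S-like
  alignments and allometric trait tables (`simulate_world()`,
  `simulate_sequences()`, `simulate_traits()`).

## The model in brief

Over background cells $B$, the niche model is the Gibbs distribution
$r(x) = e^{\eta(x)}/Z$ with $\eta(x) = \sum_j w_j f_j(x)$ over linear,
quadratic and hinge features of the predictors, maximizing

$$\frac1m \sum_{i} \eta(x_i) - \log\sum_{x\in B} e^{\eta(x)}
  - \sum_j \beta_j |w_j|, \qquad \beta_j = \lambda s_j / \sqrt m,$$

i.e. the maximum-entropy distribution whose feature means match the
presence sample to within $\beta_j$ (the KKT conditions checked by
`kkt_check()`). Suitability is reported on the logistic scale
$S = e^H r/(1 + e^H r)$, with $H$ the entropy of $r$, so an
uninformative model scores 0.5. See the methods vignette
(`vignettes/methods.Rmd`) for the full construction and all protocol
details.

## Worked example

A complete synthetic study — landscape, occurrences, split-region niche
models, range accounting, and sequence screening:

```r
library(nichesplit)

world <- simulate_world(world_spec())            # 120 x 120 cells, 2 clusters
sites <- cluster_sites(world$sites, radius_km = 1)
fit   <- enm(sites, world$predictors, reps = 50, seed = 42)
fit
#> <enm> 2 region(s): north, south
#>   north: 11 sites, median AUC 0.989, threshold 0.564
#>   south: 20 sites, median AUC 1.000, threshold 0.306
#>   merged binary range: 1007 cells

jaccard_index(fit$merged_binary, world$true_range)
#> [1] 0.8652174

range_account(fit$merged_binary, world$forest, world$protected,
              world$basins, world$area_km2)
#> <range_account> suitable area: 846 km2
#>   forested: 846 km2 (99.9% of suitable)
#>   protected: 214 km2 (25.3% of suitable; 25.4% of forested)
#>   3 basin(s) intersect the range; 3 exceed 100 km2

seqs <- simulate_sequences(lineage_tree_spec(), seed = 7)
group_divergence(p_distance_matrix(seqs))
#> <divergence_summary>
#>   among lineages:  6.45-10.14% (uncorrected p)
#>   within lineages: 0.00-0.12% (max per lineage)

length(unique(threshold_cluster(p_distance_matrix(seqs), cutoff = 0.03)))
#> [1] 9
```

Reading the output: each region's model scores near-perfect held-out
AUC over 50 replicate splits; applying the per-region median
max(sens+spec) thresholds and merging recovers the generator's true
binary range with Jaccard 0.87. The overlay accounting reports how much
of that range is forested, protected, and in which watershed basins.
The simulated nine-lineage 16S alignment shows among-lineage divergences
of 6.5-10.1% against within-lineage divergences of at most 0.1%, and 3%
single-linkage clustering recovers exactly the nine generating lineages.

For real data, point `run_pipeline()` at a directory of `.asc` rasters
and an occurrence CSV (`lon,lat,lineage,cluster`) via `run_config()`;
`write_world()` shows the expected layout.

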