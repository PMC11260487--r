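# ribostates

Quantitative heterogeneity analysis for ensembles of immature large
ribosomal subunit (pre-50S) reconstructions, for structural biologists
studying bacterial ribosome assembly with heterogeneous cryo-EM
reconstruction methods.

When an assembly factor is deleted, pre-50S particles accumulate as a
mixture of folding intermediates. Heterogeneous reconstruction yields a
latent encoding per particle and representative density volumes decoded
from encoding-space clusters. `ribostates` turns that output into an
interpretable state census:

* **Block occupancy** — the reference model is segmented into named
  blocks (rRNA helices, proteins, core); the occupancy of block $b$ in
  volume $v$ is the fraction of the block's atoms whose trilinearly
  interpolated, per-volume z-normalised density reaches a threshold
  $\tau$ (default 1.5 sd):
  $\mathrm{occ}(v,b) = |\{a \in A_b : \tilde\rho_v(x_a) \ge \tau\}| / |A_b|$.
* **Classification** — Ward-linkage hierarchical clustering (Euclidean
  distance on occupancy rows), with the class count chosen at the
  largest relative merge-height gap, plus seeded k-means++ partitioning
  of latent encodings into volume clusters.
* **Maturation-state taxonomy** — each class gets a two-axis state:
  PTC stage 1–4 (core only → CP folded → H73/H90–93 folded → H89
  folded) × H68/69 docking stage A–D (occupancy quartiles), with
  particle-weighted state fractions and between-condition deltas.
* **Gradient quantification** — sucrose-gradient A260 traces are
  baseline-corrected (rubberband / lower convex hull), integrated in
  named sedimentation windows, and summarised as the 50S/30S peak-area
  ratio used to rank assembly mutants by pre-50S accumulation.
* **Synthetic data** — seeded generators for phantom models and block
  libraries, rendered noisy volumes, latent mixtures and multi-peak
  traces, with ground-truth bookkeeping for parameter-recovery tests.

Inputs are the field's standard formats: MRC/CCP4 density maps, PDB or
mmCIF coordinates, YAML block libraries, and two-column CSV/TSV traces.
Results are tibbles that compose with the tidyverse; fitted objects
support `tidy()`/`glance()` and result types have `autoplot()` methods.

## Worked example

```r
library(ribostates)

# a factor-deletion-like synthetic ensemble: 200 000 particles drawn from
# 11 class templates, partitioned into K = 500 volume clusters
tm  <- state_templates("delta_yjga")
ens <- simulate_ensemble(tm, n_particles = 200000, seed = 1)
prt <- kmeans_partition(ens$latent, K = 500, seed = 1)
occ <- partition_occupancy(ens, prt)
cls <- hierarchical_cluster(occ, "auto")
glance(cls)
#> # A tibble: 1 x 5
#>   n_volumes n_classes linkage metric    gap_ratio
#>       <int>     <int> <chr>   <chr>         <dbl>
#> 1       500        11 ward.D2 euclidean      50.3

rules <- default_taxonomy(example_block_library())
sf <- state_fractions(cls, assign_class_states(occ, cls, rules), occ,
                      dataset = "delta_yjga", rules = rules)
ptc_stage_marginal(sf)
#> # A tibble: 4 x 3
#>   ptc_stage particles fraction
#>       <int>     <dbl>    <dbl>
#> 1         1     16143   0.0807
#> 2         2    111811   0.559
#> 3         3     40068   0.200
#> 4         4     31978   0.160
```

The automatic dendrogram cut recovers the 11 planted conformational
classes, and the particle-weighted PTC-stage census matches the planted
mixture (stage 2 ≈ 56 %, stage 3 ≈ 20 %) — the package's core check
that classification and taxonomy do not distort particle bookkeeping.

```r
# a mutant-like gradient trace with a planted 50S/30S area ratio of 1.92
tr <- simulate_gradient_trace(
  data.frame(position = c(30, 54), area = c(1, 1.92), width = c(3, 3.5)),
  drift = c(0.05, 0.002), noise_sd = 0.002, seed = 1)
q <- quantify_profile(baseline_correct(tr))
q
#> # A tibble: 4 x 4
#>   window   peak_position peak_height   area
#>   <chr>            <dbl>       <dbl>  <dbl>
#> 1 30S               29.5     0.135   0.987
#> 2 50S               53.6     0.220   1.91
#> 3 70S               82.5     0.00773 0.0159
#> 4 polysome          84.3     0.00408 0.0115
ratio_50s_30s(q)
#> [1] 1.930798
```

The planted area ratio is recovered to about 1 % despite baseline drift
and noise. See `vignettes/ribostates-methods.Rmd` for the model, the
taxonomy rules, every tunable default and the generator's scope.

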