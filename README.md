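# riverbarrier

Do major rivers act as sex-specific barriers to dispersal in wild
mammal populations? `riverbarrier` answers that question starting from
the messiest data wildlife genetics offers: replicated, error-prone SNP
genotypes of fecal samples, each with nothing but a collection
coordinate. It is aimed at landscape geneticists and wildlife managers
working with non-invasive sampling of elusive species (bears being the
motivating case), where telemetry is impractical and dispersal must be
inferred from relatives' positions.

## What it computes

Given a genotype table (85 autosomal biallelic SNPs plus Y/X sexing
markers per sample) and named river polylines in a projected CRS:

1. **Individuals** — single-linkage clustering of the allele-mismatch
   graph (tolerance ≤ 12 mismatching alleles, samples under 60 typed
   loci excluded), majority-rule consensus genotypes, sex from Y-marker
   positivity, spatial centres as coordinate means.
2. **First-order dyads** — pairwise Lynch–Ritland relatedness

   *r̂* = ½ Σ classes of the locus-weighted regression estimate with
   each individual as reference; pairs with *r̂* > 0.4 become dyads
   (expected first-order *r* = 0.5, second-order 0.25), classed
   MM/FF/MF, annotated with centre distance (km), dispersal angle to
   the reference line, direction class (D1 ≤ 45° "orthogonal to
   rivers", D2 otherwise) and rivers crossed.
3. **Crossing parity** — a river counts as crossed only when the dyad
   segment intersects its polyline an odd number of times (endpoints on
   opposite banks); meander grazes cancel.
4. **Barrier tests** — Yates χ² on MM vs FF crossing proportions;
   conditional-MLE Fisher odds ratio for multiply-sampled individuals;
   ANOVA + Tukey HSD on dyad distances; score z-tests of P(D1) = 0.5;
   Kolmogorov–Smirnov comparisons of angle distributions (all dyads,
   and > 25 km only).
5. **Random-direction null** — 1,000 replicates resampling start points
   from known female dispersers, reusing the exact observed FF distance
   multiset with uniform directions; observed crossing proportion
   tested against the replicate mean (one-sided t) and the empirical
   2.5th percentile.
6. **Spatial PCA** — per sex, eigenanalysis of (1/n)·XᵀWₛX over a
   Delaunay connection network (Wₛ the symmetrised row-normalised
   adjacency), so each axis extremises variance × Moran's I, with
   Monte-Carlo permutation tests for global and local structure.

A synthetic-data module (`generate_landscape`, `generate_population`,
`disperse_and_settle`, `sample_genotypes`) produces landscapes,
pedigrees, sex-specific log-normal dispersal kernels with a
river-crossing aversion parameter, and noisy replicated samples — with
full ground truth, so identification, estimator recovery, null-model
calibration and power are all testable. See the vignette
(`vignettes/barrier-analysis.Rmd`) for the model, parameter defaults
and design choices.

## Worked example

```r
library(riverbarrier)

rivers  <- generate_landscape(landscape_spec(), seed = 1)   # 3 rivers, 400x300 km
truth   <- generate_population(n_families = 150, seed = 2)  # 85-SNP pedigree
truth   <- disperse_and_settle(truth, rivers, dispersal_kernel_spec(), seed = 3)
samples <- sample_genotypes(truth, seed = 4)                # noisy fecal samples
samples
#> <sample_set> 1133 samples, 85 autosomal loci, 2967 missing calls

report <- run_analysis(samples, rivers,
                       pipeline_config(null_reps = 1000,
                                       spca_permutations = 199, seed = 5))
report
#> <analysis_report>
#>   individuals: 600 (303 M / 297 F)
#>   dyads: MM 175, FF 186, MF 359
#>   crossing proportions: MM 0.531, FF 0.118
#>   H1 chi-square = 69.01, p = < 2.22e-16
#>   null simulation mean = 0.197 (observed 0.118)
#>   sPCA male: global p = 0.005, local p = 0.495
#>   sPCA female: global p = 0.005, local p = 1
```

Reading the output: all 1,133 samples clustered back to 600
individuals; female–female dyads crossed rivers in 11.8% of cases
against 53.1% for male–male dyads (the default female crossing
aversion is 0.8). The random-direction null says short female
dispersal distances alone would still have produced 19.7% crossings
(2.5th percentile 14.5%), so the observed 11.8% reflects direction
behaviour, not distance — exactly the signature the pipeline is built
to detect. Mean dyad distances were 75.9 km (MM) vs 22.4 km (FF). The
default-seeded example takes under a minute on one core.

`run_analysis(..., out_dir = "out")` additionally writes `report.json`,
`individuals.csv`, `dyads.csv`, per-sex sPCA scores, and
`genotypes_regions.csv` (consensus genotypes plus river-band region
labels) for external multivariate tools such as DAPC.
`inst/scripts/riverbarrier.R` wraps the same functions as a CLI with
`simulate`, `identify`, `dyads`, `barriers`, `spca` and `all`
subcommands.

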