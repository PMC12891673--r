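Package: riverbarrier
Title: Sex-Specific River-Barrier Effects on Dispersal from Non-Invasive Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for testing whether rivers act as
    sex-specific barriers to dispersal in wild mammal populations sampled
    non-invasively. Collapses replicated, noisy SNP genotypes from fecal
    samples into individuals by mismatch-tolerant matching, estimates
    pairwise Lynch-Ritland relatedness to extract first-order dyads,
    measures dyad dispersal distances, directions and river crossings
    against named river polylines (odd-parity crossing rule), runs the
    hypothesis tests of a barrier analysis (crossing-proportion
    chi-square, Fisher's exact odds ratio, distance ANOVA with Tukey
    contrasts, one-proportion direction tests, Kolmogorov-Smirnov angle
    comparisons), simulates a random-direction Monte-Carlo null for
    female crossing rates, and quantifies spatial genetic structure by
    spatial PCA over a Delaunay connection network with global and local
    permutation tests. Includes a synthetic-data generator (landscapes,
    pedigrees, sex-specific dispersal kernels with crossing aversion,
    genotyping error) providing ground truth for calibration and power
    checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    deldir
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
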