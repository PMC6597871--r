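Package: nmlpe
Title: Landscape Genomics with Nested Maximum-Likelihood Population Effects Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end landscape-genomics toolkit for individual-based
    isolation-by-resistance analysis. Reads multi-sample VCFs into a genotype
    table and applies standard locus filters (quality, depth, minor-allele
    frequency, Hardy-Weinberg exact test, linkage-disequilibrium pruning);
    computes per-cluster diversity summaries (heterozygosities, nucleotide
    diversity, inbreeding, LD-based effective population size) and Tajima's D
    with a coalescent-simulation correction for minor-allele-frequency filter
    bias; estimates Yang genomic relatedness and LOESS spatial autocorrelograms
    with permutation null envelopes; builds resistance surfaces from rasters and
    computes circuit-theory effective resistance between sample points via
    sparse graph-Laplacian solves; and fits maximum-likelihood population
    effects (MLPE) regressions of pairwise relatedness on resistance distances,
    including a nested extension (NMLPE) with random effects for unordered
    pairs of sampling locations that restores calibrated inference under
    clustered sampling designs. Also provides spatial generalized least squares
    for habitat-amount models, environmental-association genome scans with
    genomic-inflation calibration and Benjamini-Hochberg false discovery
    control, and a synthetic-data generator for landscapes, sampling designs
    and genotypes used to validate every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    MASS,
    nlme,
    geosphere,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
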