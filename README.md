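# nmlpe

Individual-based landscape genomics for clustered sampling designs:
isolation-by-resistance (IBR) regression of pairwise genomic relatedness on
circuit-theory resistance distances, with the **nested
maximum-likelihood-population-effects (NMLPE)** correlation structure at its
core, plus the supporting pipeline — VCF filtering, diversity statistics,
Tajima's D with a coalescent bias correction, Yang relatedness, LOESS
spatial autocorrelograms with permutation envelopes, resistance surfaces and
sparse-Laplacian effective resistance, spatial GLS for habitat-amount
effects, and environmental-association genome scans with genomic-inflation
calibration.

It is written for population and landscape geneticists working with
range-wide SNP datasets of organisms sampled as clusters — for instance
stingless bee colonies, several per beekeeper, where daughter colonies
disperse only short distances so landscape resistance governs gene flow.

## The model

For each unordered pair of individuals *(i, j)*, Yang relatedness A_ij is
regressed on standardized resistance distances x_ij:

    y_ij = x_ij' β + u_i + u_j + v_L(i)L(j) + ε_ij

with iid Normal random effects **u** per individual (the MLPE structure:
pairs sharing an individual are correlated, ρ = σ²_u / (2σ²_u + σ²_v + σ²_e)
≤ 1/2) and — the nested extension — **v** per unordered pair of sampling
locations. With several colonies per location, omitting **v** leaves
location-level dependence in the residuals and makes likelihood-ratio tests
anticonservative; the package's validation suite demonstrates the inflation
(≈ 0.3 rejection at nominal 0.05) and its repair (≈ 0.05 under NMLPE, with
never-smaller standard errors). Fitting profiles β and σ²_e analytically and
optimizes the variance ratios by bounded quasi-Newton via a Woodbury
identity, so a 60-individual dataset (1,770 pairs) fits in ~0.1 s.

Resistance distances are two-terminal effective resistances of the raster
graph (8-neighbor mean-conductance edges, diagonals scaled 1/√2), computed
by grounding one focal node and solving the reduced graph Laplacian with a
sparse Cholesky factorization — exact to machine precision against the dense
pseudoinverse.

## Worked example

Simulate a landscape and a clustered design, generate genotypes whose
allele-frequency covariance decays with habitat resistance, and ask which
surface explains relatedness:

```r
library(nmlpe)

land   <- simulate_landscape(25, 25, autocorr_range = 1.2, habitat_prob = 0.5, seed = 42)
surf   <- build_resistance_surface(land$habitat,   "habitat", provenance = "habitat")
ibd    <- build_resistance_surface(land$elevation, "null",    provenance = "geographic_null")
design <- simulate_sampling_design(20, 3, land$habitat, seed = 42)
sim    <- simulate_genotypes_ibr(design, surf, n_loci = 10000, fst_scale = 0.3,
                                 phi = 0.6, seed = 42)

A <- yang_relatedness(sim$gt)
pairs <- build_pair_table(
  A, list(habitat         = pairwise_circuit_resistance(surf, sim$gt$samples),
          geographic_null = pairwise_circuit_resistance(ibd,  sim$gt$samples)),
  sim$gt$samples)

all_subsets_selection(pairs, nested = FALSE)
#>             model k_predictors loglik    aic delta_aic     weight       rho
#> 1         habitat            1   8239 -16469       0.0  1.000e+00 4.182e-01
#> 2 geographic_null            1   7846 -15684     784.7 3.991e-171 1.597e-01
#> 3     (intercept)            0   7114 -14222    2246.7  0.000e+00 1.523e-08
```

The generating habitat surface out-ranks pure geographic distance by ~785
AIC units. Refit the winner with the nested structure for final estimates:

```r
summary(mlpe(relatedness ~ habitat, pairs, nested = TRUE))
#> NMLPE regression (ML), 2701 pairs
#> formula: relatedness ~ habitat
#>
#> Fixed effects:
#>               Estimate Std. Error  z value  Pr(>|z|)
#> (Intercept) -0.0137324  0.0038987  -3.5223 0.0004278 ***
#> habitat     -0.0281969  0.0007049 -40.0014 < 2.2e-16 ***
#>
#> 95% CI:
#>                lower    upper
#> (Intercept) -0.02137 -0.00609
#> habitat     -0.02958 -0.02682
#>
#> Variance components:
#>    individual location_pair      residual
#>      0.000279      0.000016      0.000100
#> rho = 0.4139   logLik = 8312.2085   AIC = -16614.4170
```

Relatedness declines significantly with habitat resistance (β = −0.028 per
SD of resistance distance). The misspecification diagnostic shows why the
nested term matters:

```r
residual_serial_autocorrelation(mlpe(relatedness ~ habitat, pairs, nested = FALSE))
#> [1] 0.117     # location-level dependence left by plain MLPE
residual_serial_autocorrelation(mlpe(relatedness ~ habitat, pairs, nested = TRUE))
#> [1] 0.011     # absorbed by the location-pair random effect
```

`run_pipeline()` chains the full workflow (filter → diversity → relatedness
→ resistance → model selection → scans) from a VCF, a metadata CSV and
ESRI ASCII rasters, writing every stage's tables as CSV/JSON.

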