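---
title: "Models and methods behind nmlpe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nmlpe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nmlpe` implements an individual-based landscape-genomics workflow for
species sampled as clustered colonies across a fragmented range: locus
filtering, diversity summaries, pairwise genomic relatedness, circuit-theory
resistance distances, isolation-by-resistance (IBR) regression with the
nested maximum-likelihood-population-effects (NMLPE) correlation structure,
spatial GLS for habitat-amount effects, and environmental-association genome
scans. This vignette explains the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic-data validation does
and does not demonstrate.

## The pairwise mixed model: MLPE and its nested extension

The centrepiece is a regression for *pairwise* data. The response for an
unordered pair of individuals $(i, j)$ is their Yang genomic relatedness
$A_{ij}$; the predictors $x_{ij}$ are standardized resistance distances
between the two sampling points. Pairwise observations are not independent:
all pairs sharing an individual are correlated. The maximum-likelihood
population effects (MLPE) model captures this with an iid Normal random
effect per individual,

$$y_{ij} = x_{ij}'\beta + u_i + u_j + \varepsilon_{ij}, \qquad
  u \sim N(0, \sigma_u^2),\ \varepsilon \sim N(0, \sigma_e^2),$$

which induces correlation $\rho = \sigma_u^2 / (2\sigma_u^2 + \sigma_e^2)
\le 1/2$ between pairs that overlap in one individual.

When several colonies are sampled per location, pairs that connect the same
two *locations* share landscape history that the individual effects do not
capture. Ignoring it makes fixed-effect inference anticonservative: the
likelihood-ratio test sees hundreds of pairwise rows where only dozens of
location pairs carry independent information. The nested model (NMLPE) adds
an iid Normal effect per unordered location pair,

$$y_{ij} = x_{ij}'\beta + u_i + u_j + v_{L(i)L(j)} + \varepsilon_{ij},
  \qquad v \sim N(0, \sigma_v^2),$$

with within-location pairs receiving their own level $v_{aa}$. The reported
correlation becomes $\rho = \sigma_u^2/(2\sigma_u^2+\sigma_v^2+\sigma_e^2)$.

### Estimation

`mlpe()` profiles the fixed effects and the residual variance analytically
and optimizes the variance *ratios* $\gamma_u = \sigma_u^2/\sigma_e^2$,
$\gamma_v = \sigma_v^2/\sigma_e^2$ on the log scale (bounded L-BFGS-B,
three starts at log-ratios $-2, 0, 2$, convergence tolerance `factr = 1e4`
on the profiled log-likelihood). Each likelihood evaluation uses the
Woodbury identity, reducing the $n_\text{pairs}$-dimensional solve to a
$q \times q$ Cholesky factorization where $q$ = individuals + location
pairs; a 60-individual, 20-location dataset (1,770 pairs) fits in about a
tenth of a second. Wald standard errors come from
$\hat\sigma_e^2 (X'W^{-1}X)^{-1}$; AIC counts fixed effects + residual
variance + one parameter per variance ratio. Likelihood-ratio tests require
ML fits; `likelihood_ratio_test()` refuses REML.

**Identifiability boundary.** With exactly one colony per location every
location pair occurs once and $Z_v Z_v' = I$: $\sigma_v^2$ and
$\sigma_e^2$ are not separately identifiable. Rather than returning an
arbitrary split, `mlpe(nested = TRUE)` detects this, drops the $v$ term,
reports `sigma2_v = NA` and flags `identifiable = FALSE` with a warning.

### Model selection and diagnostics

`all_subsets_selection()` enumerates predictor subsets whose pairwise
|Pearson r| stays below 0.6 (strongly collinear surfaces — e.g. a
temperature-range surface and a forest-cover surface correlated at
r ≈ 0.94 — never co-occur), fits each subset by ML and ranks by AIC with
Akaike weights. Selection is run with the *plain* MLPE structure and the
best models are refitted as NMLPE for final estimates — the same division
of labour as the original protocol, and a necessary one: the location-pair
effect is exactly the level at which competing resistance surfaces differ,
so letting $v$ absorb it during selection erases the contrast the AIC
comparison needs.

`residual_serial_autocorrelation()` is the misspecification diagnostic:
residuals are whitened by the Cholesky factor of the fitted marginal
correlation after sorting rows by location pair, and the lag-1
autocorrelation of the whitened series is returned. Location-level
dependence that plain MLPE ignores shows up as a clearly positive value;
refitting with NMLPE returns it to ≈ 0.

## Yang relatedness

For dosages $g \in \{0, 1, 2\}$ and sample allele frequencies $p_i$,
off-diagonal entries are
$A_{jk} = m_{jk}^{-1} \sum_i (g_{ij}-2p_i)(g_{ik}-2p_i) / (2p_i(1-p_i))$
with pairwise-complete missing-data handling and monomorphic loci excluded;
the diagonal uses the standard self-relatedness form. Because $p_i$ is
estimated from the sample itself, the estimator is implicitly
double-centered: additive per-individual components of any pairwise
structure are absorbed into the frequencies. Two practical consequences are
worth knowing. First, off-diagonals average ≈ 0 by construction, and
parent-offspring pairs approach 0.5 only when the frequency panel is large.
Second, in IBR regression the *additive* part of a resistance matrix (the
"access resistance" around each sampling point) carries no usable signal —
only the genuinely pairwise part does. This shapes the validation design
below.

## Circuit-theory resistance

A resistance raster becomes a resistor network: non-nodata cells are nodes,
8-neighbor edges (diagonals scaled by $1/\sqrt2$; a 4-neighbor mode is
available) have conductance equal to the mean of the two cell conductances
(mean-resistance averaging available; the choice changes values and is
recorded). Effective resistance between focal cells is computed by
grounding one focal node and solving the reduced graph Laplacian with a
sparse Cholesky factorization — one factorization per connected component,
one triangular solve per focal node, exact to machine precision (the test
suite checks agreement with the dense pseudoinverse to 1e-8 and the
series-resistor closed form on chains). A direct factorization was chosen
over an iterative Krylov solver because desk-scale grids (up to a few
hundred thousand cells) factor comfortably and exactness simplifies the
property tests (Rayleigh monotonicity, metric triangle inequality).

Surface construction follows the conventional hypothesis encodings: binary
habitat → 0.1/0.9, inverted continuous cover → max − value, raw
(elevation, roughness, climate), and the uniform 0.5 surface as the
isolation-by-distance null. Surfaces are cropped to the sample extent plus
a one-degree buffer and zero cells are replaced by 0.001 so conductances
stay finite. Rasters in geographic coordinates are used as-is: cell size is
not great-circle-corrected, a documented limitation shared with the common
GIS workflow at these latitudes.

## Diversity, Tajima's D and the MAF-filter correction

Per-cluster summaries use unbiased expected heterozygosity
$2p(1-p)\cdot 2n/(2n-1)$, per-site nucleotide diversity from allele counts
(equal to unbiased $H_E$ for biallelic SNPs), the method-of-moments
inbreeding coefficient per individual, and nonparametric bootstrap over
loci (default 1,000 draws, seeded) for 95% intervals — marker resampling
is the standard for genome-wide summaries when no analytic CI is published.

Tajima's D is computed from the site frequency spectrum with the 1989
constants, treating $2n$ diploid genotypes as haplotype counts (sufficient
under infinite sites). The neutral simulator draws constant-size coalescent
genealogies (exponential waiting times at rate $\binom{k}{2}$) and places
mutations multinomially by branch length, either at rate $\theta/2$ or
conditioned on a fixed number of segregating sites (the default when
matching an observed S).

A minor-allele-frequency filter removes singletons and doubletons and
biases D strongly upward (≈ +1.3 at n = 50, S = 100, MAF ≥ 0.05).
`debias_tajimas_d()` subtracts the mean filtered D of matched neutral
replicates. One subtlety the validation surfaces honestly: the *unfiltered*
neutral mean of D is not exactly 0 but ≈ −0.10 at these settings (the
variance-estimate denominator covaries with the numerator), a property
confirmed against an independent coalescent simulator. The package reports
the statistic faithfully rather than recentering it; the debias correction,
which subtracts a simulated null mean, removes this finite-sample offset
together with the filter bias.

LD-based $N_e$ uses the bias-corrected sample-size expectation of mean
squared dosage correlation and the published inversion formulas, with the
monogamy variant as the default mating model for monandrous bees.
Confidence intervals use a delete-one-locus jackknife — a block jackknife
over the locus pairs sharing each locus — on the $1/N_e$ scale.

## Spatial GLS for habitat amount

Location-level means of diversity within a 2-km buffer (the species'
foraging radius) are regressed on habitat fraction under six correlation
structures (none, linear, exponential, Gaussian, spherical, rational
quadratic) over great-circle distances, with the conventional geostatistical
kernel forms and no nugget by default. Structures are ranked by AICc under
REML; the best is refitted by ML and compared with the intercept-only ML
model by a likelihood-ratio test. Logit transforms of heterozygosities clip
exact 0/1 at a configurable epsilon (default 1e-3) with a warning.

## Genome scans

The environmental-association scan regresses each locus's dosage on a
scaled environmental variable plus the top-k principal components of the
centered dosage matrix — a least-squares latent-factor approximation that
preserves the inferential logic of the latent factor mixed model workflow
(conditioning on k factors, genomic-inflation calibration, BH FDR at
q = 0.05, and intersecting candidates across k − 1, k, k + 1) without its
MCMC sampler. P-values use the t distribution at the regression's residual
degrees of freedom. The genomic inflation factor is
median$(z^2)$/0.4549; adjusted p-values divide $z^2$ by $\lambda$.

The between-cluster outlier scan computes per-locus Weir-Cockerham Fst and
a Lewontin-Krakauer-style statistic $(k-1)\,F_{ST}/\bar F_{ST}$ against
$\chi^2_{k-1}$. Because the ratio statistic is right-skewed, its median sits
below the chi-square median and the estimated $\lambda$ falls below 1;
genomic control is therefore applied only when $\lambda > 1$ (rescaling by
a deflated $\lambda$ would be anticonservative). The statistic's null
distribution is approximate by design and is validated by simulation, not
by distributional assumptions.

## The synthetic-data generator and what the validation shows

`simulate_landscape()` builds Gaussian-random-field layers by circulant
embedding (exponential covariance); habitat is the field thresholded at the
requested cover fraction, roughness is the local standard deviation of
elevation. `simulate_sampling_design()` places locations uniformly on valid
cells with zero-truncated-Poisson colony counts, colonies sharing their
location's coordinates (within-location distance 0 km, as when several
colonies come from one beekeeper). `simulate_genotypes_ibr()` encodes the
IBR hypothesis directly: per-locus location logit-frequencies are drawn
from a multivariate Normal with covariance
$\sigma^2 \exp(-R_{ab}/\varphi)$ in the circuit resistance $R$, clipped to
[0.001, 0.999], with binomial dosages — a frequency-covariance stand-in for
a spatial coalescent, chosen because it instantiates exactly the
covariance-decay assumption the regression tests at negligible cost.
`spike_adaptive_loci()` overwrites a chosen fraction of loci with logistic
clines in an environmental variable.

Validation scenarios and their fixed scales (chosen once, as realistic
desk-scale analogues of a range-wide bee study, and stated here because the
tests depend on them):

- **Generative recovery** (MLPE): 20 locations × 3 colonies, β = −0.5,
  ρ = 0.3; 200 replicates; β within 2 SE ≥ 90% of the time.
- **Anticonservatism contrast**: same design, null predictor, ρ = 0.2,
  location-pair variance 0.25, residual 0.35 (unit total variance);
  500 replicates. Plain MLPE rejects far above nominal (≈ 0.3); NMLPE
  stays at ≈ 0.05 with never-smaller standard errors.
- **End-to-end IBR detection**: 25 × 25 landscape (autocorrelation range
  1.2 map units, 50% habitat), habitat-mode generating surface,
  $\varphi$ = max pairwise resistance (a near-linear decay over the
  observed range), drift scale 0.3, 10,000 loci; the generating surface
  must out-rank the uniform null surface by AIC. Two design facts matter
  here and were established during development: the circuit resistance of
  a patchy surface is dominated by *additive* local-access components that
  the relatedness estimator's double-centering removes, so a large marker
  panel is needed for the remaining pairwise contrast; and selection must
  use plain MLPE, since the nested effect would absorb precisely the
  location-pair-level signal that distinguishes surfaces.
- **Scan calibration**: 5,000 mostly-neutral loci, λ within 0.1 of 1,
  empirical FDR of spiked clines (slope 2, 5% of loci) ≤ 0.10.
- **Envelope coverage**: for 40 scattered individuals with iid relatedness
  noise, the LOESS curve stays inside the 199-permutation envelope at
  ≥ 90% of grid points in ≥ 90% of replicates. The envelope uses exact
  Monte-Carlo order statistics (pointwise level $2k/(B+1)$). This
  criterion is intrinsically borderline: a span-0.5 LOESS has few
  effective degrees of freedom, so its rare excursions beyond a pointwise
  envelope are long, and the nested 90/90 rule sits close to the
  achievable coverage.

What passing these tests does **not** show: the generator has no
recombination map, no explicit coalescent genealogy, no genotyping error,
and its environmental clines are stationary logistic responses; real data
violate all of these. The tests demonstrate internal statistical
correctness and calibration of the machinery, not field realism.

## Numerical and interface conventions

Distances are haversine great-circle kilometres (Earth radius 6,371 km) —
at a 900-km study scale a planar approximation is inadequate. Coordinates
are WGS84 decimal degrees; VCF positions are 1-based. Filter order is
missingness → quality → depth → MAF → HWE (cheap scalar filters first),
then LD pruning and outlier removal on the survivors; the chain is
idempotent and the order is recorded in the report. The HWE test is the
conditional exact test on heterozygote counts (two-sided by summing
configurations no more probable than observed). LD pruning is greedy in map
order against all previously kept loci (reduced-representation loci carry
no meaningful physical windows). Loci with more than 25% missing genotypes
are removed by default, mirroring the common site-coverage rule. All
stochastic functions take explicit seeds; nothing depends on the global RNG
state except through them. Every analysis table is written as plain CSV or
JSON by the pipeline runner (`run_pipeline()`), which validates its
configuration — rejecting unknown keys — before touching any data.
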