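---
title: "Models and numerical choices in adaptscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical choices in adaptscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`adaptscape` chains four analysis stages — population structure,
genotype–environment association (GEA), landscape model competition, and
genetic offset — behind a synthetic-data generator that plants known
truth. This vignette explains the models, the defaults and why they were
chosen, and the numerical decisions that matter when the inputs get
awkward. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## What the generator emulates, and what it does not

The generator is built to resemble a range-wide RAD-seq study of a
montane tree on a subtropical island: about two dozen populations of
eight diploid individuals sampled across a climate-gradient landscape,
roughly two thousand biallelic SNPs with a small adaptive fraction,
multilocus differentiation near *F*~ST~ = 0.1, and ~11% missing
genotypes. The defaults in `sim_config()` encode those conditions
(26 populations × 8 individuals, 1,950 neutral + 50 adaptive loci,
`fst_target = 0.1`, `missing_rate = 0.11`, cline slope `beta = 1.5` on
the logit scale, future shift of one landscape standard deviation).

* **Landscape.** Each environmental layer is a Gaussian random field
  synthesized by circular FFT convolution of white noise with a Gaussian
  kernel (`autocorr_range` cells, default 8 on a 40 × 40 grid, chosen so
  neighboring populations share climate but the range spans several
  independent patches), standardized to mean 0, sd 1 over unmasked
  cells. Wrap-around artifacts of the circular convolution are accepted
  at these desk scales. Cells are square (0.09°, ≈10 km), so grids
  round-trip through ESRI ASCII files, the package's raster format
  (single-`cellsize` headers cannot represent anisotropic cells).
* **Populations.** Placed on a regular lattice with seeded jitter and
  snapped to distinct unmasked cells, so coordinates are reproducible
  and span the landscape.
* **Genotypes.** Neutral locus ℓ draws an ancestral frequency
  p₀ℓ ~ Uniform(0.05, 0.95) and population frequencies from the
  Balding–Nichols Beta(p₀(1−F)/F, (1−p₀)(1−F)/F) with F =
  `fst_target`; the expected multilocus *F*~ST~ is then F itself, which
  the test suite verifies within ±0.03. Adaptive loci shift the drawn
  frequency on the logit scale by β·z, z the driving variable's
  standardized value at the population's cell. Frequencies are clipped
  to [0.001, 0.999] before Binomial(2, p) sampling so no locus is
  degenerate by construction; loci that happen to be monomorphic in the
  realized sample are retained and handled downstream (they carry zero
  evidence in every scan). Missingness is completely at random — the
  missingness mechanism of real RAD data is unknown, and this is the
  only defensible neutral assumption.
* **Ground truth.** The sidecar records the adaptive locus ids, p₀, β,
  driving variable, population cells and per-population frequencies, and
  the per-cell true mean |Δ allele frequency| under the future scenario,
  enabling parameter-recovery tests for every downstream stage.

The generator deliberately omits linkage disequilibrium, coalescent
pedigree structure, spatially autocorrelated drift, selection dynamics
through time, and informative missingness. Passing tests therefore show
that the estimators recover what they claim under drift + clines + CAR
missingness; they do not certify behavior under, e.g., strong LD or
batch-structured missingness.

A note on realized power: because layers are standardized over the
*landscape*, the environmental contrast realized across the ~24 sampled
populations varies between seeds, and association-scan power varies with
it. Recovery rates are therefore always reported as means over several
landscape realizations (3 in the test suite, 5 in the acceptance
script), not from a single draw.

## Structure statistics

*F*~ST~ uses the Weir–Cockerham (1984) variance components a, b, c per
locus, computed from per-population genotype counts with missing data
excluded per locus per population. The multilocus estimate is the ratio
of sums Σa/Σ(a+b+c) — standard practice, and the headline number — with
the mean of per-locus ratios also reported since the two diverge under
heterogeneous locus information. Pairwise entries recompute the
components on the two populations alone. Loci where the components are
undefined (fewer than two populations with data, singleton samples) are
skipped and counted. Population-specific estimates use the Weir–Goudet
allele-matching β formulation (within-population matching of distinct
allele pairs against mean between-population matching). The estimator
may be negative with no among-population variance; `linearized_fst()`
passes negatives through with a flag rather than silently truncating.

PCA mean-imputes missing dosages per locus and centers columns (no
scaling), then takes the SVD; monomorphic columns contribute exactly
zero. Nei (1972) distance caps pairs with no shared alleles
(J~xy~ = 0, infinite distance) at 50 with a flag — large enough to
dominate any real distance, finite enough for neighbor joining.

Neighbor joining is the Saitou–Nei algorithm with the standard Q-matrix.
Ties in Q resolve to the lowest taxon-index pair, making trees
deterministic. Negative branch lengths are clamped to zero with the
deficit moved to the sister branch, preserving the pair's path length —
the usual practical fix. PERMANOVA is delegated to `vegan::adonis2`
(Gower-centered partition, (1+count)/(1+n_perm) p-values), with the
pseudo-F verified against a direct sum-of-squares oracle in the tests.

The site-frequency spectrum is projected to a smaller sample size by
hypergeometric expectation per locus and folded (minor-allele) by
default, since ancestral states are unknown. Mass that becomes
monomorphic after projection is reported separately so locus mass is
conserved exactly.

## Association scans

The LFMM scan uses the ridge closed form rather than MCMC: the latent
factor matrix is the rank-K left singular subspace of the genotype
matrix after shrinking the environmental directions — with the small
default penalty this is the projection onto the orthogonal complement of
the environment — so the factors absorb structure but cannot absorb the
signal being tested. Per-locus z-scores come from the joint regression
of dosage on environment plus factors. Z-scores are calibrated by the
genomic inflation factor λ = median(z²)/qchisq(0.5, 1); under
Balding–Nichols drift with small K, λ sits well above 1 (the drift
covariance is full-rank, not rank-K) and the calibration is what keeps
the test's size nominal — the acceptance script measures it at ≈0.05.
With `n_runs > 1`, additional runs refit on bootstrap resamples of
individuals and per-run z-scores are combined by the median (mean
available); the median was chosen for robustness to the occasional
degenerate resample, and run-to-run variation requires resampling
because the closed form is otherwise deterministic. `K` is always
user-chosen; a scree inspection of `genotype_pca()` is the intended
helper, and no selection is ever applied silently. With K = 0 and
calibration off, p-values reduce exactly to per-locus OLS t-tests (the
uncalibrated reference is Student-t, not normal, so small-sample
behavior is exact).

The pcadapt-style scan regresses each locus on the top-K PC scores,
forms the loci × K z-matrix, and uses robust Mahalanobis distances
(MCD, support fraction 0.75) against χ²~K~ after genomic-inflation
division. For K = 1 the statistic is the squared standardized loading
scaled by a zero-centered MAD, so its rank order equals the |z| order.
Detecting outliers differentiated in arbitrary directions requires K
large enough to span those directions; with r populations, K near r−1
is the informative ceiling.

BH control is `stats::p.adjust(method = "BH")` (tested against an
independent step-up implementation). The intersection rule — GEA hits
(any variable, q < 0.10) ∩ union of *F*~ST~-outlier sets — retains
per-locus provenance; external outlier sets (e.g. from a Bayesian
*F*~ST~ scanner run elsewhere) enter as one-id-per-line text files.

## Model competition

All permutation p-values use the (1+count)/(1+n_perm) convention; the
floor is 1/(n_perm+1). Mantel tests correlate upper triangles and
permute row/column order jointly; `n_perm = "exact"` enumerates all n!
relabelings (n ≤ 8) and then reports the exact permutation p over the
full distribution. The partial Mantel correlates residuals of
`a ~ control` and `b ~ control` and permutes the *residual* matrix of
the response (Legendre's residual-permutation scheme, the recommended
choice for partial tests). A response numerically identical to the
control leaves only floating-point noise as residuals; the partial
correlation is then defined as 0 ("fully explained") rather than left
to the whim of 1e-17-scale noise.

Reciprocal causal modeling scores each ordered model pair by
r(genetic ~ focal | alternative) − r(genetic ~ alternative | focal); the
matrix is antisymmetric by construction. "Fully supported" is
operationalized as all off-diagonal row entries strictly positive — the
natural numeric reading of marking models that beat every competitor in
both reciprocal comparisons.

MLPE regresses vectorized pairwise responses on pairwise predictors
under Clarke's population-effects covariance, parameterized here as
C = (1−ρ)I + ρZZ'/2 with Z the pairs × populations incidence matrix:
C has unit diagonal, correlation ρ/2 between pairs sharing a population
(Clarke's maximum of ½ at ρ = 1), and is positive definite for all
ρ ∈ [0, 1) — no ad-hoc PD repairs needed. ρ is profiled on [0, 0.99]
with an analytic GLS inner solve (Cholesky); estimation is ML, not
REML, because AIC comparisons across different fixed effects require
ML. k counts α, slope, ρ, σ². ΔAIC > 2 marks distinct fits. At ρ = 0
the estimates equal OLS on the vectorized pairs, which the tests check
to 1e-6.

PCNM is delegated to `vegan::pcnm` (truncation at the longest
minimum-spanning-tree edge, exceedances set to 4× truncation); the
conventional "half of the positive axes" subset uses floor for odd
counts. The three-set RDA partition computes Ezekiel-adjusted R² for
all seven subset models and derives pure, pairwise-joint and three-way
fractions by inclusion–exclusion (fractions can be negative, as
adjusted R² differences legitimately are); pure fractions are tested by
permutation in partial RDA with the other two sets as `Condition`, the
full model by row permutation. Predictor-set collinearity falls back to
vegan's pseudoinverse path with its rank warnings.

Collinearity pruning drops the highest-VIF variable iteratively until
all VIF ≤ 10, then resolves remaining |r| > 0.8 pairs greedily, keeping
the member less correlated with everything else; with fewer sites than
variables the VIF system is singular and the function degrades to
correlation-only pruning with a warning. Niche overlap computes
Schoener's D and Hellinger-based I on renormalized density grids; the
equivalency test pools occurrence points, permutes labels, rebuilds
kernel densities on a fixed common grid, and reports a two-sided
permutation p. The TSS threshold scans all unique scores and takes the
lowest maximizer.

Geographic distance is always great-circle (haversine, Earth radius
6,371 km) — at a 500-km island scale planar approximations already bias
long pairs — and bearings are initial great-circle bearings, 0° = north,
clockwise.

## Genetic offset

**RONA.** Population allele frequency is regressed on each variable
across populations (not individual dosages: the quantity RONA predicts
is a population frequency shift), per-locus RONA at a population is
|slope|·|Δe|, and the population value is the R²-weighted mean over that
variable's significant loci. Variables are ranked by significant-locus
count with the top three flagged. Under the clinal generator the
weighted RONA tracks the true mean |Δp| within ±20% — the linear
approximation to a logistic cline, evaluated away from the cline center,
is the dominant error source.

**Gradient forest.** Each adaptive locus gets a random-forest regression
of population frequency on the environmental variables (500 trees by
default, tree size capped at 2^d terminal nodes with
d = ⌈log₂(0.368·n/2)⌉, n the individual count — the conventional
small-sample depth rule). Loci with out-of-bag R² ≤ 0 are dropped.
Turnover functions are built by the package's own aggregation: every
split location of a variable, across all trees of a locus, receives
weight R²(locus) × importance-share(variable within locus), importances
from permutation importance clipped at zero; cumulative sums along each
variable's range give monotone turnover functions whose total masses are
the per-variable importances, normalized so all variables together carry
the mean retained R². This reproduces the defining properties of
gradient-forest turnover (monotone, bounded by importance, split-located)
from what `randomForest` exposes — per-split improvement values are not
available, so splits within a locus-variable pair are weighted equally.
The reference implementation's band-width correlation threshold
(r = 0.5) is recorded in the model object for provenance but plays no
role in this aggregation. The offset between scenarios is the Euclidean
distance between turnover-transformed environment vectors per cell; the
RGB composition maps the first three PCs of transformed space to
channels, zero-padding (with a warning) below three effective
dimensions.

**GDM.** Dissimilarities d ∈ [0,1) are modeled as d = 1 − exp(−η),
η = β₀ + Σ β·|I(x_i) − I(x_j)| with three monotone I-splines per
predictor (order 2, knots at min/median/max; interior knots at
quantiles for more splines) and optional geographic-distance splines
anchored at distance 0. The basis is evaluated by integrating M-splines
on a fine cached grid (2,048 points, ~1e-5 accuracy), which keeps the
code general in the spline count. Coefficients are fitted by iteratively
reweighted non-negative least squares (`pracma::lsqnonneg`) on the
complementary-log working response with binomial-type weights, to
|Δdeviance| < 1e-8 or 100 iterations; deviance explained is reported
against the intercept-only fit. A constant predictor yields an all-zero
basis column and hence a zero coefficient, not an error.

**Offsets.** Local offset is the predicted dissimilarity between a
cell's current and future environment; forward is the minimum over all
unmasked future cells; reverse the minimum over all current cells seen
from a future cell — no dispersal limitation, with the suitability mask
(shared by both scenarios; when masks differ upstream, suitable-at-
future is the intended candidate set) defining the candidates. All
offset predictions drop the intercept: β₀ absorbs the dissimilarity
between replicate samples of *identical* environments (sampling noise),
so identical climates must map to exactly zero offset — this is what
makes the null scenario (future = current) return exact zeros, and the
focal cell's membership in both candidate sets guarantees
forward ≤ local and reverse ≤ local everywhere. Argmin ties break by
smallest great-circle distance, then lowest cell index, so surfaces are
deterministic; migration distance is 0 iff the best target is the focal
cell. Scenario layers are assumed to be already averaged across climate
models upstream.

## Problem sizes and limitations

The test suite and acceptance script run on deliberately modest sizes —
24 populations × 8 individuals with ~1,000 loci for calibration and
recovery (20 and 5 realizations respectively), 200 replicates for test
size, 3 × 3 grids for brute-force offset oracles — sizes at which every
claim is checked against an independent oracle or planted truth in
seconds. The estimators themselves are vectorized and comfortably handle
the ~2,000-SNP, ~200-individual scale the generator emulates; the
quadratic-in-cells forward/reverse offset search is the practical
ceiling (a few thousand unmasked cells).

Known limitations: the LFMM bootstrap-median combination is a pragmatic
surrogate for algorithmic run-to-run variation in stochastic solvers;
GF turnover weighting approximates per-split importance; GDM offsets
ignore the geographic spline term by construction (a migration cost
model would need it back); BayeScan-style Bayesian outlier scans are not
reimplemented — their output enters as external outlier sets; and raster
I/O is ESRI ASCII only, with square cells.
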