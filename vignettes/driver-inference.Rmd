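---
title: "Coupling bacterioplankton composition and environment to community function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupling bacterioplankton composition and environment to community function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codriver)
```

## The scientific problem

Heterotrophic bacterioplankton drive the degradation and assimilation of
dissolved organic matter (DOM) in coastal waters, but which specific
populations or environmental conditions govern measurable community
functions — extracellular enzyme activities, growth efficiency, substrate
utilization capacity — is rarely clear. A natural design samples two
contrasting coastal systems monthly over a year, characterizes the total
(16S rDNA) and active (16S rRNA) community fractions at OTU resolution,
measures a panel of environmental covariates, and asks which predictors
couple to each community function.

The statistical obstacle is dimensionality: thousands of OTU relative
abundances plus tens of environmental variables against about twelve
monthly observations per site (p >> n). `codriver` implements the full
analysis chain for this design: OTU-table processing, Biolog EcoPlate
scoring, bacterial rate derivations, permutation statistics, and the core
inference — per-site LASSO regression followed by cross-site consensus
filtering.

## The driver-inference model

For one community function $y$ at one site, predictors $x_j$ (OTU percent
abundances of both fractions plus environmental covariates) enter the
lasso

$$\hat\beta(\lambda) = \arg\min_\beta \frac{1}{2n}\lVert y - X\beta\rVert_2^2
 + \lambda \lVert\beta\rVert_1 ,$$

whose $\ell_1$ penalty embodies the "bet on sparsity": only a few
coefficients are assumed nonzero, which curbs spurious correlation in the
p >> n regime. Columns are standardized to unit (population) standard
deviation inside the solver and the response is centered; coefficients
are reported back on the original scale with an intercept.

A predictor selected at one site may still be noise. The consensus rule
retains a predictor only if

1. it is selected by the lasso in **both** sites, and
2. its per-site Pearson correlations with the function share a sign.

Agreement between two independent systems is the method's error control;
functions whose consensus set is empty are reported as having *no model*.
For each retained driver we report the per-site correlations, a common
$R^2$ (squared Pearson correlation of the pooled per-site standardized
predictor–response pairs), and a root mean squared prediction error
(RMSPE) from the pooled single-predictor regression. $R^2 > 0.4$
classifies a driver as *strong*.

Two definitional choices here were genuinely open and are package
decisions, exposed as arguments:

* *Common $R^2$* is computed on per-site standardized pairs, so
  site-level mean and scale offsets do not masquerade as a shared
  relationship.
* *RMSPE in function units*: the pooled regression runs on standardized
  pairs, and each residual is mapped back through its own site's response
  standard deviation. This keeps the error interpretable in the
  function's units while remaining consistent with the pooled fit.

### Choosing the penalty

No single $\lambda$ is canonical in this design. The default is k-fold
cross-validation (k = min(5, n−1)) over a log-spaced path from
$\lambda_{\max}$ (the smallest penalty with an all-zero solution) down
two decades, choosing the CV-minimum; the one-standard-error rule is
available via `rule = "1se"` and is markedly more conservative under
pure-noise responses. Fold assignment is a deterministic function of the
supplied seed.

### Statistical reality at monthly resolution

Support recovery in sparse regression requires on the order of
$2 s \log p$ observations for $s$ true drivers among $p$ predictors —
roughly 36 rows for 3 drivers among ~435 predictors, versus the 12
monthly observations a one-year design provides. There is also a hard
cap: for $s$ equally strong, mutually uncorrelated drivers the marginal
correlation of each with the response cannot exceed $1/\sqrt{s}$ (the
squared correlations sum to at most 1), while the largest *chance*
correlation among hundreds of predictors at n = 12 is typically larger.
The practical consequence, which the package's own validation
quantifies, is that the per-site lasso frequently misses planted drivers
at these dimensions, so the consensus stage inherits low sensitivity.
What the cross-site filter does deliver — and what the null-model tests
verify — is strong control of false consensus drivers: with no planted
signal the mean number of consensus selections per function is well
below one. Interpreted on real data: a reported consensus driver is
credible; an absent one is weak evidence of absence.

## The synthetic data generator

`simulate_dataset()` emits everything the pipeline consumes, with the
statistical structure the analysis assumes, plus the planted ground
truth needed to score recovery. Its defaults mirror the study design the
package targets:

* **Design**: 2 sites × 12 months × 2 fractions (rDNA/rRNA), 3,009 OTUs,
  35 environmental covariates, 8 community functions (five extracellular
  enzymes, BGE, BP, bacterial abundance).
* **Communities**: latent log-normal abundances with AR(1) month-to-month
  correlation ρ = 0.6 (seasonal smoothness), shared latent means across
  sites (the same taxa dominate both systems), multinomial read sampling
  at per-sample depths drawn from 16,500–24,000. The depth floor exceeds
  the 16,000-read rarefaction depth by enough to absorb the ~2% of reads
  removed with rare OTUs, so the emitted data are always rarefiable —
  mirroring a real study whose smallest retained sample slightly exceeds
  the rarefaction depth.
* **Environment**: sinusoidal seasonal components with site-shared
  amplitude and phase plus site-specific offsets and noise, giving the
  correlated covariate structure typical of field data.
* **Responses**: $y = \sum_j \beta_j z_j + \varepsilon$ over planted
  standardized predictors, by default 2 OTUs (either fraction) + 1
  environmental variable per function, identical (predictor, sign) sets
  at both sites with site-specific magnitudes within ±20%, effect size 2
  and noise SD 0.5 (effect/noise = 4). Function observations are removed
  completely at random at rate 0.25, matching the several assay-free
  months of a typical field year.
* **Identifiability constraint**: planted OTUs are drawn from a
  high-but-not-dominant abundance band (latent-mean ranks ~3–15%), and
  candidate driver sets are rejection-sampled until their pairwise
  correlations stay below 0.35 in every site. Without this, compositional
  closure among dominant taxa and chance seasonal correlation at n = 12
  can flip the marginal sign of a planted effect, making "recovery"
  ill-defined. This constrains only the planted truth, never the
  surrounding predictor space.
* **Auxiliary series**: logistic EcoPlate color kinetics with replicate
  noise, exponential DOC decay, linear O₂ drawdown in replicate bottles,
  log-normal production/respiration values, and an exponential CDOM
  spectrum.

What the generator does **not** emulate: taxonomic structure and
phylogeny, overdispersion beyond multinomial sampling, time-lagged
predictor–response couplings, rDNA–rRNA mechanistic coupling (dormancy
dynamics), or real substrate chemistry on the plates. Passing tests on
synthetic data therefore demonstrate correctness of the computations and
calibrated behavior under the assumed model, not performance guarantees
on field data.

## Module-level conventions and numerics

**OTU processing.** OTUs occurring in at most one sample or with fewer
than 10 reads in total are excluded; samples are never dropped.
Rarefaction subsamples reads uniformly *without replacement* to a common
depth (default 16,000) and requires an explicit seed. Bray–Curtis
dissimilarity for a pair of all-zero samples is 0/0; we define it as 0
with a warning (identical emptiness treated as identity). Hierarchical
clustering defaults to complete linkage — the default of the clustering
routine this field uses — with average and single linkage exposed;
dendrograms export to Newick with branch lengths from merge heights.

**EcoPlates.** The average well color development,
AWCD $= \sum(R - C)/93$ over the 93 substrate wells, uses the
replicate-matched water blank by default (a plate-mean blank is
available); negative blank-corrected values are retained through AWCD,
which sums signed values, but floored at zero before Bray–Curtis, which
requires non-negativity. The reading whose AWCD is closest to 0.5 is
used for normalization, ties resolved to the earliest reading (less
evaporation and edge artifact). Normalization divides by the AWCD, so
the plate mean is exactly 1 and the presence threshold "normalized
absorbance ≥ 1 in at least one replicate" reads as "at least average
color development"; division rather than subtraction is used because the
threshold only makes sense on a ratio scale.

**Rates.** BGE = BP/(BP+BR)·100 requires commensurate carbon units and
refuses mixed ones (units are carried as the caller's responsibility,
never converted silently). Respiration is the pooled OLS slope across
replicate bottles (per-bottle slopes also reported); a respiratory
quotient of 1 maps O₂ consumption to carbon mole-for-mole. The DOC decay
fit DOC(t) = RDOC + BDOC·e^(−D_t·t) uses bounded Levenberg–Marquardt
with starts RDOC₀ = min(DOC), BDOC₀ = range(DOC), D_t₀ = ln 2/(span/2);
an exactly constant series is a degenerate case returning BDOC = 0,
RDOC = mean, D_t = NA rather than a spurious rate, and non-convergence
is flagged, never silently replaced. The bioavailable percentage uses
the initial total (RDOC+BDOC) as denominator. CDOM spectral slopes use
log-linear OLS by default (simple, reproducible), with a nonlinear
exponential fit behind a flag.

**Permutation statistics.** The Mantel statistic is the Pearson
correlation of strict lower triangles; PERMANOVA Gower-centers squared
dissimilarities and partitions tr(G) by the group-mean projector. Both
tests permute whole samples, use the one-sided (greater) alternative,
and report add-one p-values, p = (1 + #{stat_perm ≥ stat_obs})/(1 +
n_perm); identical seeds give identical p-values. The pipeline's
PERMANOVA on monthly substrate profiles groups months into quarters,
since a month factor with one profile per month leaves no residual
degrees of freedom.

**Lasso numerics.** Cyclic coordinate descent with soft-threshold
updates in fixed input order (a deterministic tie-break), warm starts
along the decreasing λ path, active-set iteration with a full verifying
sweep, and convergence when no coefficient moves more than 1e-7 in a
full sweep. Every converged fit carries its KKT residual; the test suite
holds it below 1e-6 and checks the closed-form soft-threshold solution
on orthonormal designs to 1e-8.

## Problem sizes used in validation

The packaged tests exercise: the full default design (3,009 OTUs × 2
fractions × 2 sites) for end-to-end determinism; 200-OTU instances (435
predictors) over 30 seeds for consensus recovery and null safety; 500
replicates × 999 permutations for the Mantel type-I rate; 200
replicates for the PERMANOVA null mean R² (expectation (a−1)/(n−1));
50-seed batches for KKT optimality and DOC decay recovery. These sizes
are the package's validation design and are restated in the acceptance
script, which recomputes every quantity from scratch.

## Known limitations

* One grouping factor only in PERMANOVA; no strata, no dispersion test.
* No time-lagged predictor–response relationships are considered.
* The consensus procedure tests association, not causation, and its
  sensitivity at monthly resolution is intrinsically low (see above);
  it is best read as a high-precision screen.
* Rate derivations assume the stated conversion constants (1.4×10¹⁸
  cells mol⁻¹ thymidine; RQ = 1); both are exposed as arguments.
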