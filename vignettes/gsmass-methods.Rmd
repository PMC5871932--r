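---
title: "Methods: genomic vs phenotypic mass selection in an allogamous crop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic vs phenotypic mass selection in an allogamous crop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gsmass` simulates and analyses recurrent mass selection in a
self-incompatible, fully outcrossing diploid crop — the setting of common
buckwheat (*Fagopyrum esculentum*, 2n = 16), where selfing is blocked by the
S-locus and the breeding unit is an open-pollinated population rather than a
line. The package covers the full experimental loop: a forward-in-time
population simulator, a yield-predictive selection index, per-trait G-BLUP
genomic prediction, a two-cycle-per-year genomic selection (GS) scheme run
against a one-cycle-per-year phenotypic selection (PS) control, and the
ex-post diagnostics (LD decay, effective population size, accuracy decay of
frozen prediction models).

This vignette records the models, the tunable parameters and their defaults,
the design choices made where the design was genuinely open, and what the
test suite does and does not establish. No empirical claim is made here that
the tests or `scripts/acceptance.R` do not themselves compute.

## The selection index

Seed yield per unit area cannot be measured on a single plant in an
outcrossing species without clonal propagation, so selection acts on a
scalar index
$$ s_i = \sum_j b_j u_{ij}, $$
where $u_{ij}$ is the observed, expected (fitted) or predicted value of
secondary trait $j$ for plant $i$, and the weights $b_j$ come from a
principal component regression (PCR) of cultivar-mean yield on seven
single-plant traits. `fit_pcr()` chooses the number of components by
leave-one-out cross-validation (literal refitting per fold), taking the
smallest $k$ whose RMSE is within `1e-12` of the minimum (parsimony
tie-break), and back-transforms the coefficients to the original trait
scale.

Two decisions here were open:

* **Predictor scaling.** Predictors are mean-centered but *not* unit-scaled
  by default (`scale = FALSE`), with a switch. The relative magnitudes of
  the published weights (e.g. 0.0306 on test weight, whose values are
  around 600 g/l) are consistent with unscaled predictors.
* **Intercept.** The index as printed has no intercept; `fit_pcr()` carries
  one internally so predictions are on the yield scale. Selection uses only
  rankings, so the intercept never changes who is selected;
  `compute_index(..., intercept = FALSE)` gives the pure weighted sum. The
  bundled evaluation table's printed index means sit about 0.3 kg/a above
  the weighted sum of the printed trait means, a gap the package surfaces
  rather than hides (both values are computable).

Transferability of the trait correlation structure between the historical
field trial and the breeding population is checked with a Mantel test
(`mantel_test()`): Pearson correlation of upper-triangle entries, p-value
from simultaneous row/column permutations with the identity permutation in
the null set, 9,999 permutations and a two-sided comparison by default.

## Genomic prediction (G-BLUP)

Each index trait gets a univariate mixed model
$$ y = 1\mu + g + e, \qquad g \sim N(0, K\sigma_g^2), \quad
   e \sim N(0, I\sigma_e^2), $$
with $K = ZZ'/c$ the genomic relationship from column-centered genotypes
($Z$), $c$ a trace normalization making the mean diagonal 1. Codominant
markers enter as dosage 0/1/2 and dominant markers as presence 0/1, both
centered and unscaled; the published experiment mixed the two marker types
without stating a coding, so this is logged as a package decision. The
variance ratio $\delta = \sigma_e^2/\sigma_g^2$ is estimated by REML on the
spectral decomposition of the projected kinship (a one-dimensional search on
$\log\delta$, tolerance `1e-8`); the test suite verifies the optimum against
a 50-point grid.

Every model also carries the equivalent ridge (RR-BLUP) marker-effect
representation $a = Z'(K+\delta I)^{-1}(y-1\hat\mu)/c$, so predictions for
new genotypes are marker products; kinship-space and marker-space
predictions agree to machine precision and are cross-checked against an
independent ridge solve in the tests. Markers absent from a later panel are
imputed at training means (contributing zero), which is exactly the
situation created by marker-panel attrition.

**LOOCV convention.** `loocv_accuracy()` estimates $\mu$ and $\delta$ once
on the full data and re-solves only the genetic effects per fold (fast
linear-smoother path and literal refit, identical to machine precision). If
instead $\mu$ were re-estimated inside every fold, the held-out prediction
would collapse to the leave-one-out mean whenever REML lands on the
$h^2 = 0$ boundary — which happens in roughly half of pure-noise fits — and
the Pearson correlation would then be exactly $-1$, destroying the null
calibration the accuracy statistic is supposed to have. Fixing the mean is
the standard genomic-prediction CV convention and keeps the null accuracy
centred at zero.

"Expected" index values at a training cycle are fitted (train-on-self)
GEBVs, not LOOCV values; the much higher expected-vs-observed correlations
compared with LOOCV accuracies in the motivating experiment support this
reading. Traits with negative LOOCV accuracy stay in the index — no
accuracy-based trait dropping.

## The breeding schemes

One breeding year is either one PS cycle or two GS cycles:

* **GS cycle 1** (192 plants): genotype, phenotype, train (or update) the
  per-trait models, rank by expected index, select 12 seed parents *after*
  pollination — the pollen cloud is the whole population, so selection acts
  on dams only. Offspring population: 48.
* **GS cycle 2** (48 plants, off-season): genotype only, rank by predicted
  index, select 12 *before* pollination — both dam and sire are selected,
  doubling the expected response at equal intensity and accuracy. Offspring:
  192 (the next year's cycle-1 population).
* **PS cycle** (192 plants): observed index from phenotypes, 12 dams after
  pollination, whole-population pollen.

Model updating is annual by default (`update_policy = "annual"`; `"never"`
freezes the first year's models — the comparison behind the accuracy-decay
analysis). Markers monomorphic in the current population are dropped from
the panel at each update (`update_marker_panel()`), mirroring the published
panel attrition. A mortality contingency (`apply_mortality()`) fills the
selected set by rank order, skipping dead plants.

Open points resolved as package decisions: offspring draw their dam
uniformly from the selected set (honeybee open pollination gives no family
structure); the 48 cycle-2 plants are random offspring of the 12 cycle-1
seed parents open-pollinated by the full population; ties in truncation
selection break by individual id (reproducibility); seed-stock samples
(36 by default) are drawn from every post-cycle mating and phenotyped at
the end in one shared simulated environment, mirroring a common-garden
evaluation; PS season effects are not modelled, since evaluating all
populations together removes them by design.

## The synthetic world

The simulator's defaults are the stated conditions of the motivating
experiment wherever those are stated, and a documented assumption elsewhere:

* **Map:** 2,000 markers on 8 linkage groups of 100 cM (2n = 16), a
  desk-scale stand-in for the real 14,598-marker panel; `dominant_fraction`
  defaults to 0.5 because the real panel mixes marker types in unstated
  proportions.
* **Meiosis:** crossovers are a Poisson process on map length per linkage
  group (Haldane, no interference), giving closed-form recombination
  fractions the tests verify at 10,000 meioses.
* **Founders:** linkage equilibrium, allele frequencies uniform on
  (0.1, 0.9). The route to initial LD is the stated 40-plant bottleneck
  expanded to 192. Note a quantitative gap this creates: one generation of
  mating among 40 plants from LE founders yields $r^2 \approx 1/(2k)
  \approx 0.013$ at *all* distances (drift LD needs recurrent generations
  to build the distance dependence), whereas the real initial population
  showed $r^2 \approx 0.08$ at 1 cM — its base population evidently carried
  prior LD. The package asserts the verifiable directions (LD inflation,
  Ne reduction), not the unreproducible absolute values.
* **Traits:** eight traits (seed yield + the seven index traits) share one
  set of 100 QTL; per-locus effect vectors are multivariate normal with
  covariance equal to the published field-trial correlation matrix
  (PSD-repaired by eigenvalue clipping). When a reference population is
  given, effects are re-whitened against the realized QTL genotypes so the
  genetic covariance in that population equals the target exactly; trait
  baselines (means, phenotypic SDs) come from the initial population of the
  bundled 2014 evaluation table. Seed yield, never measured on single
  plants, borrows the selection-index scale as an explicitly synthetic
  stand-in. Heritability defaults to 0.5 for every trait — the paper
  reports no per-trait heritabilities, so a single mid-range value is
  assumed, documented, and used consistently (it is also the value the
  scheme-level acceptance checks stipulate).
* **Seeds:** every stochastic operation takes an explicit seed;
  `run_program()` derives per-stage seeds deterministically from the master
  seed, so trajectories are bit-reproducible.
* **Missing genotypes:** default rate 0; when present, column-mean imputed
  before modelling.

Out of scope by design: mutation, epistasis and dominance variance, spatial
field effects, sequence-level simulation.

## LD and effective population size

Pairwise $r^2$ within linkage groups (≤ 50 cM) uses the direct
haplotype-frequency estimator for codominant pairs and a two-locus EM for
any pair involving a dominant marker. The EM distributes each observed
genotype class over its compatible haplotype-pair configurations under
Hardy-Weinberg proportions, starts from linkage-equilibrium products of the
marginal allele-frequency estimates, and stops when the largest haplotype-
frequency change drops below `1e-4` (the published stopping rule), capped
at 1,000 iterations with a non-convergence flag. The observed-data
log-likelihood is non-decreasing across iterations (asserted in tests) and
the converged solution matches an exhaustive simplex grid search to
`1e-3` — noting that the production stopping rule may halt a few `1e-3`
short of the optimum on flat ridges, a stopping-rule effect the tests
separate from estimator error.

Effective population size comes from least squares of observed $r^2$
against the Hill–Weir drift expectation
$$ E[r^2] \approx \frac{10 + C}{(2 + C)(11 + C)}
   \left(1 + \frac{(3 + C)(12 + 12C + C^2)}{n(2+C)(11+C)}\right),
   \qquad C = 4 N_e c, $$
with $c$ from map distance via the Haldane inverse. The exact published
formula combination is not printed in the source experiment, so the
sampling term is switchable (`variant = "drift_floor"` gives the drift term
plus an additive $1/n$). Pairs with minor allele frequency < 0.05 are
excluded; observations are averaged in 1-cM bins and the fit weights bins
by pair count. The drift expectation assumes drift–recombination
equilibrium, reached after roughly $1/(2c)$ generations; when the time
horizon is known, `min_distance` restricts the fit to the equilibrated
window (the parameter-recovery check uses $c \ge 1/(2t)$), which removes
the upward bias from tightly linked, not-yet-equilibrated pairs.

## Evaluation statistics

Populations are compared per trait by Welch's t-test (summary-statistic and
raw-vector paths agree to `1e-10`) with Bonferroni correction over the
pairwise family *within* one trait — matching per-column letter groupings
in evaluation tables; `letter_display()` is presentation only. SDs are
sample SDs ($n-1$). Percent-of-initial values are computed from
full-precision means; two published percentage entries (111.04%, 120.94%)
are not exactly reproducible from the printed means and the package reports
the printed-mean arithmetic (111.39%, 120.95%) rather than matching them.

## What a green test establishes — and what it does not

The synthetic generator emulates the *structure* of the experiment
(population sizes, selection timing, marker observation, correlated traits,
bottleneck history), not its data. Green acceptance checks therefore
establish: internal numerical identities (G-BLUP ≡ RR-BLUP, LOOCV fast ≡
refit, EM ≡ grid search), exact reproduction of the arithmetic recomputable
from the published tables (15.0% PS gain, 1.65-day flowering delay, 10.4%
mapped markers), and qualitative reproduction of the scheme-level findings
(positive GS gains, frozen-model accuracy decay, Ne decline across cycles)
under the stated world. They do not establish the paper's absolute
accuracies (Table-3 values), its Ne series, or its r² levels, which depend
on undeposited genotype and phenotype data.

Compute-bound replicate counts in the test suite (e.g. 30 scheme-level
programs instead of 100) are scaled down only for the test-run budget; the
thresholds are the criteria's own.
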