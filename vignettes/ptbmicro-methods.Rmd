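---
title: "Models and methods in ptbmicro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in ptbmicro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptbmicro)
```

## Scientific setting

Spontaneous preterm birth (sPTB, delivery before 37 weeks) is strongly
associated with the composition of the vaginal microbiome, particularly in
cohorts of predominantly African ancestry: term deliveries tend to follow
*Lactobacillus crispatus*-dominated communities, while preterm deliveries are
associated with diverse anaerobe-rich communities carrying taxa such as
Lachnospiraceae BVAB1, *Sneathia amnii*, *Prevotella* cluster 2 and TM7-H1.
`ptbmicro` implements a complete analysis chain for longitudinal case-control
cohorts of this design — 45 PTB cases matched 2:1 to 90 term (≥ 39 week)
controls on ethnicity, age and household income — together with a synthetic
cohort generator so that every stage can be validated against known ground
truth.

## Data model and quality control

Taxonomic profiles travel as an `abundance_table`: a samples × taxa matrix of
relative abundances (rows sum to 1) plus the per-sample classified read
depth. Counts are normalized row-wise on ingestion; proportion input must sum
to 1 within `1e-6` (renormalized) or it is rejected. Samples need at least
1,000 classified reads (`filter_min_reads`, boundary inclusive) to enter any
analysis. Gestational age is carried in integer days everywhere; weeks appear
only at I/O boundaries. Metadata rows (`SampleRecord`s) are plain data frames
keyed by `sample_id`, with the ethnicity indicator coded 0 for African
ancestry and 1 otherwise.

Case-control matching (`match_controls`) is greedy and multi-pass: pass 0
requires exact ethnicity, age within ±2 years and the same income bracket;
the age tolerance widens by 2 years per pass up to ±10, then income is
dropped, then age, leaving ethnicity-only matching. Controls are consumed
without replacement and ties among equally close controls are broken by a
seeded shuffle, so matching is deterministic under a fixed seed. The pass
schedule itself is a package convention: published descriptions of such
designs state only that criteria were "loosened at each pass".

## Vagitypes

A sample's vagitype (community state type) is the taxon with the largest
proportion of reads, provided that proportion reaches 30%; otherwise the
sample is `UNASSIGNED` (`assign_vagitype`). Exact ties break to the
lexicographically first taxon label, with a warning. The predominant-taxon
rule is preferred over clustering because it is not population or dataset
dependent. For transition modeling, unassigned and non-focal vagitypes map to
an `"Other"` state.

## Abundance filtering and transforms

`filter_low_abundance` retains a taxon when (1) at least 5% of profiles show
abundance ≥ 1%, or (2) at least 15% show ≥ 0.1%. All four cutoffs are read
inclusively — "at least" is explicit for the inner thresholds and the outer
ones are treated symmetrically.

The shared response/feature transform is the soft-threshold log
(`soft_threshold_log`): subtract 0.001, floor at 0, then
`log10((x + 0.001)/0.001)`. It maps proportions onto [0, 3], flattens
sub-0.001 noise to exactly 0, and preserves order above the threshold. The
same transform supplies the response of the longitudinal model and the
features of the predictive model, keeping scales coherent across modules.

## Differential screening

Per taxon, a two-sided Mann-Whitney U test compares PTB against TB samples
(earliest sample per subject), after rounding abundances below `1e-5` to
zero. The p-value is exact by enumeration when the pooled sample size is at
most 12 with no ties, otherwise a tie-corrected normal approximation with
continuity correction is used (the switch is internal and recorded in the
result). Benjamini-Hochberg step-up adjustment flags taxa at q < 0.05.
Group medians and 75th percentiles are computed on the floored values with
linear interpolation, matching the test input. Fisher's exact test (two-sided
by the "at most as probable" convention; doubling conventions exist and give
different values) contrasts *L. crispatus* vagitype frequency by outcome.

## The two-step predictive model

The classifier minimizes the penalized logistic objective

$$\sum_i \ln\!\left(1 + e^{-y_i(\mathbf{w}^\top \mathbf{x}_i + b)}\right) + C\,\lVert\mathbf{w}\rVert_1,$$

with an unpenalized intercept. Note that `C` multiplies the **penalty**:
larger `C` means more shrinkage, the reverse of a common library convention,
and equal to `n * lambda` in glmnet's parameterization. The solver is
proximal-gradient (FISTA) with exact soft-thresholding, objective tolerance
`1e-8` and a 20,000-iteration cap; at `C = 0` on separable data no finite
minimizer exists and the solver stops at the cap with a warning rather than
an error, so resampling loops are never aborted.

Training is two-step (`two_step_train`): features are first filtered by a
univariate Mann-Whitney test at p ≤ 0.05, then the L1 model is fitted on the
survivors with `C` chosen by stratified 5-fold grid search over 13 log-spaced
points in $[10^{-3}, 10^3]$ maximizing cross-validated AUROC (ties resolve
toward the larger, sparser `C`). Both the fold count and the grid are package
defaults — source descriptions state only "grid search and nested
cross-validation".

Evaluation is leave-one-out: the **entire** two-step procedure reruns without
the held-out subject, whose decision value is recorded. Sensitivity and
specificity are read at decision threshold 0 and AUROC from the tie-corrected
rank statistic. By default the univariate filter runs inside every fold
(leakage-free); `filter_mode = "whole-cohort"` reproduces pipelines that
filtered once on the full cohort, since published descriptions are ambiguous
on this point. Permutation significance retrains the full procedure on
label-shuffled data and uses the add-one estimator
`p = (1 + #{null ≥ observed})/(1 + n_perm)`, so p is never 0. The
`eval = "apparent"` statistic (in-sample AUROC of one trained model per
permutation) is offered for large replication studies; observed and permuted
statistics are always computed identically, so exchangeability — and hence
validity — holds for either choice.

One behavior worth knowing: when a leave-one-out fold selects no features,
its intercept-only decision value depends on the training class ratio, and a
held-out case then scores slightly *lower* than a held-out control. Under
null data this drives LOO AUROC well below 0.5. It is a known artifact of
leave-one-out with near-empty models, is conservative in direction, and does
not affect the permutation test (both sides of the comparison carry it).

The published four-taxon risk score
`0.775·stl(Samn) + 0.751·stl(BVAB1) + 0.116·stl(TM7) + 0.011·stl(Pcl2)`
ships as a frozen scoring profile (`ptb_score`); its coefficients derive from
a controlled-access cohort and are deliberately not re-estimated.

The clinical comparator applies the identical two-stage pipeline to 11
clinical variables (short cervix, cerclage, vaginal pH, BMI, progesterone,
gravidity, parity, gravidity − parity, history of miscarriage/stillbirth,
history of PTB, recent antibiotics), YES/NO coded 1/0 and continuous features
min-max normalized **inside each training fold**; constant features map to 0
with a warning.

## Vagitype dynamics: a panel-data CTMC

Vagitype trajectories are modeled as a continuous-time Markov chain over
{*L. crispatus*, *L. iners*, BVAB1, *G. vaginalis*, Other} with per-day
intensities and a log-linear outcome covariate,
$q_{rs}(z) = q^0_{rs} e^{\beta_{rs} z}$ with $z = 1$ for PTB. The likelihood
is interval-censored (states are seen only at visit days; transition times
are never assumed), evaluated through matrix exponentials
(scaling-and-squaring). Transitions with fewer than 4 observed between-visit
changes (pooled over outcomes by default; per-group counting is available)
are excluded from the model — without this restriction the MLE routinely
fails to converge on sparse panels. Optimization is BFGS on log-intensities
with three seeded starts; standard errors come from the observed information
matrix.

Derived summaries: stationary distributions evaluated as a row of
`P(100000 days)` and verified against the null-space solution `πQ = 0`
(residual < 1e-6, reducible chains reported per starting state with a
warning); and a dynamic-balance table at the one-trimester horizon, taken as
91 days (13 weeks — the day count is a package convention). Both
`P_ij(t) − P_ji(t)` and the detailed-balance flux `π_i P_ij − π_j P_ji` are
emitted, since either reading of "forward minus reverse" is defensible.

## Longitudinal trajectories: penalized-spline mixed model

Per taxon, the soft-threshold log abundance is modeled as

$$y_{ij} = \beta_0 + \beta_1 \mathrm{PO}_i + \beta_2 \mathrm{BMI}_{ij} + \beta_3 \mathrm{pH}_{ij} + \beta_4 I_{\mathrm{ethnicity}} + f(\mathrm{ga}_{ij}) \times \mathrm{PO}_i + \gamma_i + \varepsilon_{ij},$$

with a penalized cubic B-spline smoother of gestational age per outcome level
(basis dimension 10, second-difference penalty, one smoothing parameter
shared across levels) and a random subject intercept, estimated by REML via
`mgcv`. The P-spline basis is a standard penalized-spline representation
standing in for other smoother families; this is a model-class approximation,
recorded in the output. Effect contributions are tested with ANOVA-style
approximate F tests, and fitted trajectories carry 98% pointwise bands from
the coefficient covariance. Ancestry × outcome stratified fits drop the
constant terms and flag strata under 5 subjects as low-power. With the
smoothing parameter fixed at 0 and no random effect the fit reduces exactly
to least squares on the expanded basis (a tested invariant).

## Cytokines and sparse CCA

Nine cytokines (IL-1β, IL-6, IL-8, eotaxin, TNF-α, IL-17A, MIP-1β,
IP-10/CXCL10, RANTES) are retained when fewer than 30% of readings are out of
range; remaining out-of-range values are imputed at the relevant limit of
detection. One sample per subject per trimester is used (earliest gestational
age; trimester boundaries < 98, 98–195, > 195 days are a documented
convention).

Sparse CCA follows the penalized-matrix-decomposition scheme: alternating
soft-thresholded power iterations maximize `u'X'Yv` under
`‖u‖₂ ≤ 1, ‖v‖₂ ≤ 1` and l1 budgets `(cx, cy)` (defaults 2.0), with later
components computed on the deflated cross-covariance. The objective is
asserted non-decreasing at every iteration; the sign convention makes each
component's largest-magnitude taxon weight positive, and results are
invariant to sample/column order. Within-block covariance is treated as
identity, so at unconstrained penalties on orthonormalized blocks the first
component coincides with classical CCA (a tested oracle). Correlation-circle
coordinates are the Pearson correlations of each variable with its own
block's canonical variates; an axis-flip flag aligns orientations across
separately fitted groups. Two caveats: cytokine blocks are analyzed on
per-swab normalized concentrations by default, and the *null* canonical
correlation grows with the l1 budget (at n = 100 with 9 × 12 blocks, loose
penalties overfit to ≈ 0.45–0.5 even for independent blocks; the sparsest
setting stays below 0.35). Penalty choice should therefore be reported with
any result.

## The synthetic cohort generator

`simulate_cohort` emulates the study conditions end to end: case and
control-pool subjects with realistic covariates (ancestry ~78% African,
age ≈ 26 ± 5.5, low-income-skewed brackets, PTB-enriched clinical history
rates taken from the cohort description, e.g. previous PTB 31% vs 10%); 2:1
matching through the real `match_controls`; delivery days uniform on
[161, 258] (23w0d–36w6d) for PTB and [273, 294] (≥ 39 w) for TB; visits every
28 days from day 60 truncated at delivery; latent vagitype paths simulated
exactly (exponential holding times) from outcome-specific generators with
PTB-shifted initial frequencies; per-visit compositions
Dirichlet-multinomial around vagitype templates (dominant-taxon mass ≥ 0.5,
precision 40) over a 27-taxon panel; negative-binomial read depths (mean
50,000, size 12) with a 2% assay-failure rate producing sub-1,000-read
samples for the QC rule to catch; visit pH elevated under dysbiotic states;
and LOD-censored cytokines whose proinflammatory members (eotaxin, IL-1β,
IL-6, MIP-1β) load positively on dysbiotic taxa.

The PTB composition effect multiplies template concentrations by
`exp(log-fold)` for BVAB1 (+0.8), *S. amnii* (+0.8), *Prevotella* cluster 2
(+0.6), TM7-H1 (+0.6) and *L. crispatus* (−0.5). These defaults were
calibrated once so the default cohort's leave-one-out AUROC lands in the
0.65–0.85 band that matches reported performance on real data of this design,
while still flagging all four signature taxa; they are frozen thereafter.
Ground truth (config, latent states, delivery days) is retained for recovery
tests.

What the generator does **not** emulate: read-level noise (no sequencing
errors, chimeras or primer bias — profiles are drawn directly), taxonomic
misclassification, visit-schedule irregularity or missed visits, within-
subject covariate drift (BMI is constant per subject), batch effects in
cytokine assays, and any coupling between clinical flags and the microbiome.
Passing tests therefore demonstrate correctness of the statistical machinery
under the assumed generative model, not robustness to real-world measurement
artifacts.

## Numerical conventions and degenerate inputs

Lexicographic `sample_id`/taxon-label tie-breaks wherever a deterministic
choice is needed (earliest-sample selection, vagitype ties, duplicate-day
collapsing); all randomized steps accept seeds and restore the caller's RNG
state. FISTA tolerance `1e-8` on the objective; sCCA weight-change tolerance
`1e-7`; matrix-exponential row sums checked to `1e-10` and entries clipped to
[0, 1]; stationary residual `1e-6`. All-tied Mann-Whitney inputs return
p = 1; empty feature sets yield flagged intercept-only models; zero-depth
samples, non-compositional rows and all-zero contingency tables are errors.
Percentages in cohort summaries round half-up to one decimal (base R's
`round` is round-half-even, which is not the reporting convention).

## Validation problem sizes

The test suite validates against independent oracles (exhaustive permutation
enumeration, hypergeometric enumeration, closed-form 2-state chains,
eigendecompositions, OLS normal equations, classical CCA, an independent
coordinate-descent L1 solver) and recovers generating parameters at the
following scales, chosen to exercise each estimator's asymptotics at
interactive cost: 200 subjects × 8 monthly visits for the CTMC (log-
intensities within 3 SE); 100 subjects × 7 visits for the mixed model (fixed
effects within 3 SE, subject SD within 20%); n = 100 for sCCA support
recovery (≥ 80% of first-component l1 mass on loaded variables); 200
simulated null cohorts of 135 subjects for the differential false-discovery
check; and 200 replicates of 99 permutations for the permutation test's
type-I calibration.

## Known limitations

* The CTMC assumes time-homogeneous intensities and no misclassification of
  the observed vagitype; the mixed model assumes Gaussian residuals on the
  transformed scale, which is an approximation for proportions piled near 0.
* The two-step model's univariate filter ignores between-taxon correlation;
  the L1 step mitigates but does not remove this.
* Sparse CCA treats within-block covariance as identity (diagonal-penalized
  CCA); its "canonical correlations" are not classical canonical correlations
  unless blocks are internally uncorrelated.
* The frozen risk score is reported as published and cannot be recalibrated
  without the original controlled-access cohort.
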