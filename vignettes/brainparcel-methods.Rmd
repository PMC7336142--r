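---
title: "Methods: parcel-wise morphometry inference and the BrainAGE ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parcel-wise morphometry inference and the BrainAGE ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind each stage of the
package, the tunable parameters and their defaults, the design choices made
where several faithful implementations were possible, and what the synthetic
cohorts do and do not tell you about behaviour on real imaging data.

## The synthetic generative model

All tests and calibration runs operate on cohorts from `sim_config()` /
`simulate_reference_cohort()` / `simulate_study_cohort()`. The parcel volume
of subject $i$ in parcel $p$ is additive Gaussian:

$$v_{ip} = b_p + s_p\,\big(a_i - 55\big) + u_{\text{site}(i),p} + \varepsilon_{ip},$$

where $a_i$ is the subject's *effective brain age* (see below), baselines
$b_p \sim N(800, 100^2)$ volume units, slopes
$s_p \sim N(-0.5, 0.1^2)$ units/year, site offsets
$u \sim N(0, 2^2)$ and noise $\varepsilon \sim N(0, 4^2)$. Linearity in age
with independent Gaussian noise is the minimal structure that both the
ANOVA stage and the linear SVR stage assume; nothing richer is claimed.

**Effective age.** For the reference cohort $a_i$ is chronological age: the
reference defines the normative aging trajectory. Study subjects carry two
extra terms:

* an individual biological brain-age deviation
  $\tau_i \sim N(0, \texttt{brainage\_sd}^2)$ with default SD 4 years —
  healthy brains genuinely differ in apparent age, and without this term
  group-mean confidence intervals become unrealistically narrow (dominated
  by shared site noise rather than subject-level variation);
* a diagnosis effect expressed in **years of excess brain aging**
  ($0$ for HC, $4$ for MCI, $9.2$ for AD by default, preserving the
  characteristic $\approx 2.3$ AD:MCI severity ratio of dementia
  brain-aging studies), concentrated on an affected parcel subset.

**Concentration.** With affected fraction $f$ (default 0.15, the
"temporal-like" subset taken from the start of the parcel list — no
anatomical semantics are simulated), an affected parcel of a group-$g$
subject loses $-s_p\,\delta_g/f$ volume units. The $1/f$ normalization makes
the *whole-brain-average* excess aging equal $\delta_g$ years regardless of
how concentrated the atrophy is, so a linear age-reader recovers
$\approx\delta_g$, and with $f = 1$ exactly $\delta_g$. Parameter-recovery
runs therefore use $f = 1$ (clinically defensible: dementia atrophy is
widespread, not confined to one lobe), while detection-power runs use the
concentrated default.

The reference cohort deliberately carries **no** biological brain-age
scatter. Real reference cohorts do, and that scatter produces the
well-known regression-to-the-mean attenuation of BrainAGE estimates; the
generator isolates the ensemble machinery from that bias so that tests
check the machinery, not a bias-correction scheme (which the package does
not implement).

Other emulated features: deliberately unequal site, sex and age-bracket
frequencies in the reference pool (the imbalance stratified subsampling
must absorb); study ages $N(74.4, 7.4^2)$ truncated to $[56, 92]$ across 48
sites; covariates drawn identically in both SDB arms; BMI/education entries
masked missing completely at random at rate `missing_rate` (default 1%,
matching the order of sporadic missingness in dementia registries). With
`sdb_effect = 0` (the default and the null scenario) the volume code path
never reads `sdb_status`, so the arms are exchangeable *by construction*.

## Parcellation

`build_default_atlas()` tessellates a grid into exactly 673 contiguous
Voronoi cells partitioned 600/36/37 into cortical, subcortical and
cerebellar compartments; it is a structural stand-in with the right label
counts, not an anatomical atlas. `aggregate_voxels_to_parcels()` defaults to
`sum` scaled by the voxel volume because modulated gray-matter segments
represent actual tissue volume, and summation preserves it; `mean` is
offered for sensitivity checks. Whether real studies used sums or means of
modulated voxels is usually unstated — the choice is flagged here as an
assumption. Overlapping (probabilistic) atlases are rejected: labels must
partition the grid.

## Cohort assembly

*Imputation.* Only BMI and education may be missing. Chained regression over
sex, age, cognitive status and the respective other covariate, with
posterior-noise draws, five sweeps, `m = 5` imputations. Because matching
runs once, the completed tables are pooled per cell (mean across
imputations) — the simplest rule consistent with a single matching pass.

*Propensity and matching.* Logistic regression of SDB status on age, sex,
education, BMI, cognitive status, APOE4 count and protocol.
Treatment history (CPAP/BiPAP) is excluded between arms because it occurs
only among the exposed and would separate the classes perfectly. The
matching algorithm is greedy nearest-neighbour on the logit of the score,
without replacement, exact on cognitive status, caliper 0.2 SD of the logit
scores, processing order randomized by seed — the simplest faithful
instantiation of "1:1 propensity matching"; all knobs are arguments. One
record per subject enters the matching. Balance is reported as standardized
mean differences (positive = higher in the exposed arm) with Welch t tests
for numeric covariates and chi-square tests for categorical ones; these
mirror the descriptive two-arm tables such studies print, and none of the
p-values gates the pipeline.

## Parcel-wise inference

One linear model per parcel: `volume ~ age + diagnosis * sdb_status`, age
continuous. Each factor's statistic is the **Type-II partial F** — the
model-comparison F for dropping that term from the model containing every
term not containing it, with the error term always taken from the complete
model. A single joint model with partial tests was chosen over four
separate one-factor models because it is the standard reading of an n-way
ANOVA and does not attribute confounded variance to whichever factor is
tested; any other design is available by passing a different `formula`
(e.g. `~ sdb_status` for a marginal test).

The permutation scheme shuffles the tested factor's labels uniformly across
subjects, leaving all other columns fixed, exactly as the procedure is
usually described. This simple shuffle is known to be anticonservative when
strong nuisance effects are present (a Freedman–Lane scheme would permute
residuals instead); the package implements the simple scheme because it is
the procedure under study, and its calibration under the global null is
what the acceptance suite verifies. The interaction is permuted within
diagnosis strata, which preserves exchangeability under the interaction
null while leaving both main effects intact; whether to permute freely
instead is exposed via `permute_var`/`strata`.

Numerical details: p-values use the add-one estimator
$(1 + \#\{\text{null} \ge \text{obs}\})/(n_{\text{perm}} + 1)$, so they can
never be zero and live in $[1/(n_{\text{perm}}+1),\, 1]$; the FWE threshold
is the 95th percentile of the max-F sample with linear interpolation
(quantile type 7); zero-variance parcels are flagged, get `NA` statistics,
and are excluded from the set-wise maximum (with a warning) rather than
poisoning it; rank-deficient designs abort naming the aliased term; model
fits use pivoted QR, so collinearity short of exact aliasing degrades
gracefully. Nuisance covariates (total intracranial volume, sex) are not
included by default — the default model mirrors the four-factor design; add
them to the formula if wanted.

## The BrainAGE ensemble

Each of `n_replicates` replicates draws a stratified subsample of the
reference pool — at most 30 subjects per age-bracket × sex × site cell
(5-year brackets tiling 55–85), then the larger sex down-sampled to the
smaller within each bracket — and fits a weak learner: features
standardized to zero mean/unit variance *on that subsample only*
(parameters stored with the learner, keeping train/test separation honest),
then linear epsilon-SVR with $C = 1$, $\varepsilon = 0.1$. "Similar numbers
across age brackets" is operationalized as the equalize-within-bracket rule;
the whole stratified pool is used per replicate
(`per_replicate_fraction = 1`) since the cell caps and sex equalization
already randomize membership. Linear SVR is the standard weak learner for
parcel-level brain age, is deterministic, and at these problem sizes is
nearly unbiased (prediction-vs-age slope ≈ 1 on held-out data); kernel,
cost and epsilon are arguments for anyone wanting otherwise. For the linear
kernel predictions use the collapsed primal weight vector, which makes
scoring hundreds of learners cheap; a unit test pins its equality to the
kernel expansion.

Replicate $r$ derives its seed as `seed + r` (counter scheme), so replicates
are independent and individually reproducible. Bagged prediction is the
plain mean across learners; `n_replicates` defaults to 200 — bagging
variance decays as $1/R$, so beyond a few hundred replicates the bagged
mean moves by far less than the subject-level noise — while production runs
of such ensembles use $10^4$.

`evaluate_groups()` reports per-diagnosis MAE and mean BrainAGE with
t-based 95% CIs (omitted below 2 subjects; width 0 with a notice when
degenerate), and a permutation ANOVA of BrainAGE on diagnosis, SDB and
interaction — literally the parcel-wise engine run on a single "parcel".

## Problem sizes used by the tests

The suite runs everything at desk scale, chosen so the full battery
completes in minutes while every Monte-Carlo check retains resolution: FWE
calibration on 200 null datasets of 60 subjects × 50 parcels with 500
permutations each; p-uniformity on 100 datasets with 200 permutations;
detection power and SDB specificity on 330-subject cohorts with 60 parcels
and 1,000 permutations; ensemble recovery with a 1,500-subject reference,
100 parcels and 200 replicates. The acceptance script reruns the FWE
calibration from scratch under a caller-supplied seed.

## What passing tests do and do not show

The synthetic cohorts share the analysis' own assumptions: parcels are
independent given the design (no spatial covariance), effects are linear
and additive, noise is Gaussian and homoskedastic, missingness is MCAR, and
site effects are additive offsets. Passing tests therefore demonstrate that
the machinery is correct and calibrated *under those assumptions*. They do
not certify behaviour under correlated parcels (where max-statistic
correction becomes conservative), non-linear aging, informative
missingness, scanner effects that rescale rather than shift volumes, or a
self-reported exposure label with misclassification — all of which real
cohorts exhibit. The reference-without-scatter choice likewise means the
package's recovery results do not speak to BrainAGE attenuation bias on
real reference pools.

## Known limitations

No voxel-wise inference, cluster statistics or TFCE; no optimal or
full matching and no inverse-probability weighting; no deep-learning age
predictors; no bias-corrected BrainAGE; atlas labels must be hard
(non-overlapping). The pipeline starts from parcel or voxel *values* —
segmentation, normalization and modulation of raw images are upstream of
this package.
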