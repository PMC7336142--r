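# brainparcel

Parcel-based gray-matter morphometry statistics, permutation inference with
max-statistic family-wise error control, and a bagged support-vector
brain-age ("BrainAGE") ensemble — the statistical machinery behind studies
asking whether a clinical exposure (here: self-reported sleep-disordered
breathing, SDB) is associated with regional gray-matter volume or advanced
brain aging across cognitive groups (healthy controls, mild cognitive
impairment, Alzheimer's disease).

The package is aimed at neuroimaging statisticians who want the full
pipeline — cohort assembly through inference — as reusable, tested R
functions, exercised end-to-end on synthetic cohorts so every stage is
verifiable without access to any imaging repository.

## What it implements

**Parcellation.** Voxel-wise modulated gray-matter maps are compressed to a
673-parcel representation (600 cortical + 36 subcortical + 37 cerebellar
labels). A synthetic label atlas with that structure is built on demand;
real NIfTI label images with a label table are accepted too.

**Cohort assembly.** Multiple imputation (chained regression over sex, age,
cognitive status, BMI, education) for sporadically missing covariates,
logistic propensity scores for the exposure, greedy 1:1 nearest-neighbour
matching on the logit scale — exact on cognitive status, caliper 0.2 SD —
and Table-1-style balance diagnostics (standardized mean differences, t and
chi-square tests).

**Parcel-wise inference.** Per parcel, an n-way linear model
`volume ~ age + diagnosis * sdb` yields each factor's partial F (Type-II
sums of squares) as the reference statistic. The tested factor's labels are
shuffled (the interaction within diagnosis strata) and the model refit;
per-parcel null F values give uncorrected permutation p-values, and the
per-replication **set-wise maximum** F across all parcels gives the null
distribution for family-wise error correction:

    p_FWE(parcel) = (1 + #{ max-F >= F_parcel }) / (n_perm + 1)

with the significance threshold at the empirical 95th percentile of the
max-F sample.

**BrainAGE.** A reference cohort spanning ages 55–85 across heterogeneous
sites is repeatedly subsampled — at most 30 subjects per age-bracket × sex ×
site cell, sexes equalized within brackets — and each subsample trains a
linear epsilon-SVR of age on the parcel volumes (weak learner). Bagged
prediction is the mean over learners, and

    BrainAGE = bagged predicted age − chronological age

is summarized per group (MAE, mean, 95% CI) and tested for diagnosis, SDB
and interaction effects with the same permutation ANOVA engine.

**Synthetic cohorts.** `sim_config()` controls a generative model with
linear age-related volume decline, diagnosis-graded atrophy expressed as
years of excess brain aging on an affected parcel subset, per-subject
biological brain-age scatter, site offsets, an SDB effect that defaults to
zero (the null scenario), and missing covariates.

## Worked example

```r
library(brainparcel)
cfg <- sim_config(n_reference = 800, n_parcels = 80,
                  n_study_per_cell = c(HC = 30, MCI = 111, AD = 24),
                  seed = 42)
reference <- simulate_reference_cohort(cfg)
study <- simulate_study_cohort(cfg)

cohort <- impute_missing(study$cohort, m = 5, seed = 1)$pooled
matched <- match_pairs(cohort, estimate_propensity(cohort), seed = 1)
matched
#> <matched_cohort>
#>   130 pairs, 70 discarded, caliper 0.0523 logit units

cohort_m <- matched_subjects(matched, cohort)
parcels_m <- study$parcels[match(cohort_m$subject_id, study$parcels$subject_id), ]

run_parcelwise_analysis(parcels_m, cohort_m, n_perm = 1000, seed = 2)
#> <parcelwise_analysis> 80 parcels, 1000 permutations per factor
#>   age                      F_crit =  10.975  significant: 80
#>   diagnosis                F_crit =   7.489  significant: 12
#>   sdb_status               F_crit =  11.686  significant: 0
#>   diagnosis:sdb_status     F_crit =   7.411  significant: 0

ens <- train_brainage(reference$parcels, reference$cohort,
                      stratification_config(n_replicates = 50, seed = 3))
evaluate_groups(predict(ens, parcels_m), cohort_m, n_perm = 1000, seed = 4)
#>   diagnosis     n   mae mean_brainage ...  ci_low ci_high
#> 1 HC           36  3.12        -0.236 ...   -1.54    1.07
#> 2 MCI         184  4.90         4.07  ...    3.45    4.69
#> 3 AD           40  8.23         8.23  ...    7.02    9.43
#> group inference (permutation ANOVA on BrainAGE):
#>   diagnosis               39.4   p = 0.000999
#>   sdb_status               1.21  p = 0.298
#>   diagnosis:sdb_status     0.917 p = 0.359
```

Reading the output: age-related decline is detected in every parcel and the
implanted diagnosis atrophy in exactly the 12 affected parcels, while the
SDB factor (whose generating effect is zero) is significant nowhere. The
ensemble predicts healthy-control age with an MAE of 3.1 years, and the
group-mean BrainAGE confidence intervals recover the implanted excess-aging
offsets (0 / +4 / +9.2 years); SDB shows no BrainAGE effect. `autoplot()`
on either result object draws the corresponding figure, and `tidy()` /
`glance()` return the underlying tables.

The whole pipeline can also be driven from one configuration:
`run_pipeline(pipeline_config(seed = 1), "runs/demo")` writes every stage
table plus a JSON manifest, and `render_report("runs/demo")` renders the
summary tables.

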