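#' @title Synthetic cohort generators
#' @description
#' Generators for the two cohorts the pipeline consumes: a heterogeneous
#' reference cohort used to train the age-prediction ensemble, and a
#' diagnosis-by-SDB study cohort on which parcel-wise inference and BrainAGE
#' scoring are run.  Both are fully determined by a [sim_config()]: the same
#' configuration yields the same parcel "anatomy" (baselines, age slopes,
#' affected subset) in both cohorts, which is what makes a reference-trained
#' model transferable to the study cohort.
#' @name simulate_cohorts
NULL

# Seed arithmetic: sub-streams are offset from the master seed, kept inside
# the 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + k) %% (.Machine$integer.max - 1))
}

# Parcel-level generating parameters shared by reference and study cohorts.
parcel_params <- function(config) {
  set.seed(derive_seed(config$seed, 0))
  p <- config$n_parcels
  list(
    parcel_id = sprintf("p%04d", seq_len(p)),
    baseline = rnorm(p, config$baseline_volume_mean, config$baseline_volume_sd),
    slope = rnorm(p, config$age_slope_mean, config$age_slope_sd),
    affected = seq_len(p) <= ceiling(config$affected_parcel_fraction * p)
  )
}

ref_age_breaks <- function(config, width = 5) {
  seq(config$age_range_reference[1], config$age_range_reference[2], by = width)
}

volumes_tibble <- function(values, subject_id, parcel_id) {
  colnames(values) <- parcel_id
  bind_cols(tibble(subject_id = subject_id), as_tibble(values))
}

#' Generate the synthetic reference (training) cohort
#'
#' Draws `n_reference` subjects with deliberately unequal site, sex and
#' age-bracket frequencies -- the imbalance that stratified subsampling is
#' designed to absorb -- and parcel volumes following the linear-in-age model
#' described in [sim_config()].  The reference cohort carries no diagnosis or
#' SDB structure: it defines the normative aging trajectory.
#'
#' @param config A [sim_config()].
#' @return A list with elements `cohort` (tibble, one row per subject) and
#'   `parcels` (tibble: `subject_id` plus one numeric column per parcel,
#'   row-aligned with `cohort`).
#' @export
#' @examples
#' ref <- simulate_reference_cohort(sim_config(n_reference = 100, n_parcels = 10))
#' dim(ref$parcels)
simulate_reference_cohort <- function(config) {
  stopifnot(inherits(config, "bp_sim_config"))
  breaks <- ref_age_breaks(config)
  n_brackets <- length(breaks) - 1
  min_n <- 2L * 2L * n_brackets
  if (config$n_reference < min_n) {
    abort(sprintf(
      paste0("n_reference = %d is too small: stratified subsampling needs at ",
             "least 2 subjects per age-bracket x sex cell (>= %d subjects for ",
             "%d brackets)."),
      config$n_reference, min_n, n_brackets
    ))
  }
  pp <- parcel_params(config)
  set.seed(derive_seed(config$seed, 1))

  n <- config$n_reference
  k <- config$n_sites_reference
  site_probs <- 2^(-(seq_len(k)) / 1.5)
  site <- sample(sprintf("ref_site%02d", seq_len(k)), n, TRUE, prob = site_probs)
  # female proportion varies by site, sex imbalance by design
  p_female <- 0.25 + 0.5 * (match(site, sort(unique(site))) - 1) / max(k - 1, 1)
  sex <- ifelse(runif(n) < p_female, "female", "male")
  # age brackets increasingly sparse at older ages
  bracket <- sample(seq_len(n_brackets), n, TRUE, prob = rev(seq_len(n_brackets)) + 1)
  age <- runif(n, breaks[bracket], breaks[bracket + 1])

  cohort <- tibble(
    subject_id = sprintf("ref%05d", seq_len(n)),
    age = age,
    sex = sex,
    diagnosis = "HC",
    sdb_status = NA_character_,
    bmi = rnorm(n, 27, 4.5),
    education_years = pmax(round(rnorm(n, 15, 3)), 6),
    apoe4_count = sample(0:2, n, TRUE, prob = c(0.6, 0.3, 0.1)),
    site = site,
    protocol = sample(c("MP-RAGE", "IR-SPGR"), n, TRUE, prob = c(0.75, 0.25)),
    treatment_flag = FALSE
  )

  u_site <- matrix(rnorm(k * config$n_parcels, 0, config$site_offset_sd),
                   nrow = k)
  site_idx <- match(site, sprintf("ref_site%02d", seq_len(k)))
  a0 <- config$age_range_reference[1]
  values <- rep(1, n) %o% pp$baseline +
    (age - a0) %o% pp$slope +
    u_site[site_idx, , drop = FALSE] +
    matrix(rnorm(n * config$n_parcels, 0, config$noise_sd), nrow = n)

  list(cohort = cohort,
       parcels = volumes_tibble(values, cohort$subject_id, pp$parcel_id))
}

#' Generate the synthetic study cohort
#'
#' Draws the six diagnosis-by-SDB cells with the configured sizes.  Covariates
#' are drawn from the same distributions in both SDB arms (exchangeable), so
#' with `sdb_effect = 0` the volume model never touches `sdb_status` and the
#' two arms are distributionally identical given covariates -- the null
#' scenario.  Diagnosis-graded atrophy is expressed as excess brain aging
#' concentrated on the affected parcel subset (see [sim_config()]), and each
#' subject additionally carries an individual brain-age deviation.
#' A `missing_rate` fraction of BMI and education entries is masked as
#' missing, completely at random.
#'
#' @inheritParams simulate_reference_cohort
#' @return As [simulate_reference_cohort()]: list of `cohort` and `parcels`.
#' @export
#' @examples
#' st <- simulate_study_cohort(sim_config(
#'   n_study_per_cell = c(HC = 5, MCI = 5, AD = 5), n_parcels = 8))
#' dplyr::count(st$cohort, diagnosis, sdb_status)
simulate_study_cohort <- function(config) {
  stopifnot(inherits(config, "bp_sim_config"))
  pp <- parcel_params(config)
  set.seed(derive_seed(config$seed, 2))

  cells <- tidyr::expand_grid(
    diagnosis = c("HC", "MCI", "AD"),
    sdb_status = c("negative", "positive")
  )
  diagnosis <- rep(cells$diagnosis, times = config$n_study_per_cell[cells$diagnosis])
  sdb_status <- rep(cells$sdb_status, times = config$n_study_per_cell[cells$diagnosis])
  n <- length(diagnosis)

  rtnorm <- function(n, mean, sd, lo, hi) {
    x <- rnorm(n, mean, sd)
    while (any(bad <- x < lo | x > hi)) x[bad] <- rnorm(sum(bad), mean, sd)
    x
  }
  age <- rtnorm(n, config$study_age_mean, config$study_age_sd,
                config$age_range_study[1], config$age_range_study[2])
  site <- sample(sprintf("study_site%02d", seq_len(config$n_sites_study)), n, TRUE)

  cohort <- tibble(
    subject_id = sprintf("stu%04d", seq_len(n)),
    age = age,
    sex = ifelse(runif(n) < 0.33, "female", "male"),
    diagnosis = diagnosis,
    sdb_status = sdb_status,
    bmi = rnorm(n, 29, 5.7),
    education_years = pmax(round(rnorm(n, 16.1, 2.7)), 6),
    apoe4_count = sample(0:2, n, TRUE, prob = c(0.52, 0.37, 0.11)),
    site = site,
    protocol = sample(c("MP-RAGE", "IR-SPGR"), n, TRUE, prob = c(0.73, 0.27)),
    treatment_flag = sdb_status == "positive" & runif(n) < 0.34
  )

  k <- config$n_sites_study
  u_site <- matrix(rnorm(k * config$n_parcels, 0, config$site_offset_sd), nrow = k)
  site_idx <- match(site, sprintf("study_site%02d", seq_len(k)))
  tau <- rnorm(n, 0, config$brainage_sd)
  # excess aging in years, concentrated on the affected subset
  excess <- config$diagnosis_effects[diagnosis] / config$affected_parcel_fraction
  a0 <- config$age_range_reference[1]

  values <- rep(1, n) %o% pp$baseline +
    (age + tau - a0) %o% pp$slope +
    excess %o% (pp$slope * pp$affected) +
    u_site[site_idx, , drop = FALSE] +
    matrix(rnorm(n * config$n_parcels, 0, config$noise_sd), nrow = n)
  if (config$sdb_effect != 0) {
    values <- values + config$sdb_effect * (cohort$sdb_status == "positive")
  }

  if (config$missing_rate > 0) {
    cohort$bmi[runif(n) < config$missing_rate] <- NA_real_
    cohort$education_years[runif(n) < config$missing_rate] <- NA_real_
  }

  list(cohort = cohort,
       parcels = volumes_tibble(values, cohort$subject_id, pp$parcel_id))
}

#' Paint parcel values into a voxel image
#'
#' Spreads each parcel's value uniformly over that parcel's voxels (so that
#' sum-aggregation with the same atlas returns the input exactly when
#' `voxel_noise_sd = 0`), optionally adding voxel-level Gaussian noise.
#' Background voxels are 0.  Primarily a fixture generator for exercising
#' [aggregate_voxels_to_parcels()] on known ground truth.
#'
#' @param parcel_values Numeric vector, one value per atlas label, in
#'   label-table order.
#' @param atlas A [build_default_atlas()] result (or [read_atlas()]).
#' @param voxel_noise_sd SD of additive voxel noise (0 = exact painting).
#' @return A 3D numeric array with the atlas grid dimensions.
#' @export
paint_voxel_image <- function(parcel_values, atlas, voxel_noise_sd = 0) {
  stopifnot(inherits(atlas, "parcel_atlas"))
  labs <- atlas$label_table$label
  if (length(parcel_values) != length(labs)) {
    abort(sprintf("`parcel_values` has length %d but the atlas has %d labels.",
                  length(parcel_values), length(labs)))
  }
  voxel_noise_sd <- check_nonneg(voxel_noise_sd, "voxel_noise_sd")
  counts <- tabulate(atlas$labels[atlas$labels > 0], nbins = max(labs))
  empty <- labs[counts[labs] == 0]
  if (length(empty) > 0) {
    abort(sprintf("atlas label(s) with zero voxels: %s.",
                  paste(empty, collapse = ", ")))
  }
  img <- array(0, dim = dim(atlas$labels))
  inside <- atlas$labels > 0
  lab_in <- atlas$labels[inside]
  per_voxel <- parcel_values[match(lab_in, labs)] /
    (counts[lab_in] * atlas$voxel_volume)
  if (voxel_noise_sd > 0) {
    per_voxel <- per_voxel + rnorm(length(per_voxel), 0, voxel_noise_sd)
  }
  img[inside] <- per_voxel
  img
}
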