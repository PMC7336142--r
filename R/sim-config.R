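#' Simulation settings for synthetic reference and study cohorts
#'
#' Bundles every knob of the synthetic-cohort generator.  The defaults emulate
#' the statistical structure of a multi-site dementia morphometry study: a
#' heterogeneous reference cohort of 2,089 adults aged 55-85 used to train the
#' age-prediction ensemble, and a 330-subject study cohort laid out in six
#' diagnosis-by-SDB cells (30 HC / 111 MCI / 24 AD per arm), with linear
#' age-related parcel-volume decline, diagnosis-graded atrophy concentrated in
#' an affected ("temporal-like") parcel subset, configurable sleep-disordered
#' breathing (SDB) effect (zero by default, the null scenario), per-site volume
#' offsets, and sporadic missing covariates.
#'
#' The parcel volume model is additive Gaussian.  For reference subject `i`
#' and parcel `p`:
#' \deqn{v_{ip} = b_p + s_p (age_i - 55) + u_{site(i),p} + \epsilon_{ip}}
#' with baselines `b_p ~ N(baseline_volume_mean, baseline_volume_sd^2)`,
#' slopes `s_p ~ N(age_slope_mean, age_slope_sd^2)` (negative on average),
#' site offsets `u ~ N(0, site_offset_sd^2)` and noise
#' `\epsilon ~ N(0, noise_sd^2)`.  Study subjects additionally carry an
#' individual biological brain-age deviation `\tau_i ~ N(0, brainage_sd^2)`
#' and a diagnosis effect expressed in years of excess brain aging: group `g`
#' loses `s_p * diagnosis_effects[g] / affected_parcel_fraction` on each
#' affected parcel, so the whole-brain-average excess aging equals
#' `diagnosis_effects[g]` years regardless of how concentrated the atrophy is.
#'
#' @param n_reference Number of reference (training) subjects.
#' @param n_study_per_cell Named counts per diagnosis for each SDB arm;
#'   each diagnosis cell appears once per arm.
#' @param n_parcels Number of gray-matter parcels (673 for the default atlas).
#' @param age_range_reference,age_range_study Admissible age ranges in years.
#' @param study_age_mean,study_age_sd Normal parameters (years) for study ages,
#'   truncated to `age_range_study`.
#' @param n_sites_reference,n_sites_study Number of acquisition sites; site
#'   frequencies are deliberately unequal in the reference cohort.
#' @param baseline_volume_mean,baseline_volume_sd Parcel baseline volume
#'   distribution (volume units).
#' @param age_slope_mean,age_slope_sd Per-parcel age slope distribution
#'   (volume units per year; mean must be negative).
#' @param diagnosis_effects Named numeric `c(HC=, MCI=, AD=)`: mean excess
#'   brain aging in years per diagnosis.  HC must be exactly 0.
#' @param affected_parcel_fraction Fraction of parcels (taken from the start of
#'   the parcel list) expressing the diagnosis effect, in (0, 1].
#' @param sdb_effect Additive volume shift applied to every parcel of
#'   SDB-positive subjects (volume units; default 0, the null scenario).
#' @param brainage_sd SD (years) of the per-subject biological brain-age
#'   deviation in the study cohort.  The reference cohort defines the
#'   normative trajectory and carries none.
#' @param site_offset_sd SD of per-site, per-parcel volume offsets.
#' @param noise_sd SD of the per-observation Gaussian noise (volume units).
#' @param missing_rate Probability that a BMI or education entry of a study
#'   subject is masked as missing (missingness is completely at random).
#' @param seed Integer seed; together with the other fields it fully
#'   determines both cohorts.
#'
#' @return An object of class `bp_sim_config` (a validated named list).
#' @seealso [simulate_reference_cohort()], [simulate_study_cohort()]
#' @export
#' @examples
#' cfg <- sim_config(n_reference = 200, n_parcels = 20, seed = 1)
#' cfg
sim_config <- function(n_reference = 2089,
                       n_study_per_cell = c(HC = 30, MCI = 111, AD = 24),
                       n_parcels = 673,
                       age_range_reference = c(55, 85),
                       age_range_study = c(56, 92),
                       study_age_mean = 74.4,
                       study_age_sd = 7.4,
                       n_sites_reference = 6,
                       n_sites_study = 48,
                       baseline_volume_mean = 800,
                       baseline_volume_sd = 100,
                       age_slope_mean = -0.5,
                       age_slope_sd = 0.1,
                       diagnosis_effects = c(HC = 0, MCI = 4, AD = 9.2),
                       affected_parcel_fraction = 0.15,
                       sdb_effect = 0,
                       brainage_sd = 4,
                       site_offset_sd = 2,
                       noise_sd = 4,
                       missing_rate = 0.01,
                       seed = 1L) {
  n_reference <- check_count(n_reference, "n_reference")
  n_parcels <- check_count(n_parcels, "n_parcels")
  n_sites_reference <- check_count(n_sites_reference, "n_sites_reference")
  n_sites_study <- check_count(n_sites_study, "n_sites_study")
  seed <- check_count(seed, "seed", min = 0)

  if (!all(c("HC", "MCI", "AD") %in% names(n_study_per_cell))) {
    abort("`n_study_per_cell` must be named with HC, MCI and AD.")
  }
  n_study_per_cell <- vapply(
    c("HC", "MCI", "AD"),
    function(g) check_count(n_study_per_cell[[g]], paste0("n_study_per_cell[", g, "]")),
    integer(1)
  )

  for (rng in list(age_range_reference = age_range_reference,
                   age_range_study = age_range_study)) {
    if (length(rng) != 2 || !is.numeric(rng) || rng[1] >= rng[2]) {
      abort("age ranges must be numeric length-2 with min < max.")
    }
  }
  for (nm in c("baseline_volume_sd", "age_slope_sd", "site_offset_sd",
               "noise_sd", "brainage_sd", "study_age_sd")) {
    assign(nm, check_nonneg(get(nm), nm))
  }
  if (age_slope_mean >= 0) {
    abort("`age_slope_mean` must be negative: parcel volumes decline with age.")
  }
  if (!all(c("HC", "MCI", "AD") %in% names(diagnosis_effects))) {
    abort("`diagnosis_effects` must be named with HC, MCI and AD.")
  }
  if (diagnosis_effects[["HC"]] != 0) {
    abort("`diagnosis_effects[HC]` must be exactly 0.")
  }
  if (!is.numeric(affected_parcel_fraction) ||
      affected_parcel_fraction <= 0 || affected_parcel_fraction > 1) {
    abort("`affected_parcel_fraction` must lie in (0, 1].")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("`missing_rate` must lie in [0, 1).")
  }

  structure(
    list(
      n_reference = n_reference,
      n_study_per_cell = n_study_per_cell,
      n_parcels = n_parcels,
      age_range_reference = as.numeric(age_range_reference),
      age_range_study = as.numeric(age_range_study),
      study_age_mean = as.numeric(study_age_mean),
      study_age_sd = study_age_sd,
      n_sites_reference = n_sites_reference,
      n_sites_study = n_sites_study,
      baseline_volume_mean = as.numeric(baseline_volume_mean),
      baseline_volume_sd = baseline_volume_sd,
      age_slope_mean = as.numeric(age_slope_mean),
      age_slope_sd = age_slope_sd,
      diagnosis_effects = diagnosis_effects[c("HC", "MCI", "AD")],
      affected_parcel_fraction = affected_parcel_fraction,
      sdb_effect = as.numeric(sdb_effect),
      brainage_sd = brainage_sd,
      site_offset_sd = site_offset_sd,
      noise_sd = noise_sd,
      missing_rate = as.numeric(missing_rate),
      seed = seed
    ),
    class = "bp_sim_config"
  )
}

#' @export
print.bp_sim_config <- function(x, ...) {
  cat("<bp_sim_config>\n")
  cat(sprintf("  reference: n = %d, ages %g-%g, %d sites\n",
              x$n_reference, x$age_range_reference[1],
              x$age_range_reference[2], x$n_sites_reference))
  cat(sprintf("  study: %s per SDB arm (%d subjects), %d sites\n",
              paste(sprintf("%s=%d", names(x$n_study_per_cell), x$n_study_per_cell),
                    collapse = "/"),
              2L * sum(x$n_study_per_cell), x$n_sites_study))
  cat(sprintf("  parcels: %d (affected fraction %.2f), noise sd %g, site sd %g\n",
              x$n_parcels, x$affected_parcel_fraction, x$noise_sd, x$site_offset_sd))
  cat(sprintf("  diagnosis effects (yr): HC=%g MCI=%g AD=%g; sdb effect %g; seed %d\n",
              x$diagnosis_effects[["HC"]], x$diagnosis_effects[["MCI"]],
              x$diagnosis_effects[["AD"]], x$sdb_effect, x$seed))
  invisible(x)
}
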