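#' Configuration for an end-to-end pipeline run
#'
#' A single validated object that fully determines a run: simulation
#' settings, matching settings, permutation count, brain-age stratification
#' and a master seed from which every stage seed is derived.
#'
#' @param simulation A [sim_config()].  Its seed is overridden by `seed`.
#' @param stratification A [stratification_config()].  Seed likewise derived.
#' @param m_imputations Imputations for missing covariates.
#' @param caliper_sd Matching caliper in SDs of the logit propensity score.
#' @param n_perm Permutations per factor in the parcel-wise analysis.
#' @param cost,epsilon SVR hyperparameters for the brain-age learners.
#' @param stages Stages to execute, in pipeline order.
#' @param seed Master seed.
#' @return A `bp_pipeline_config` list.
#' @export
pipeline_config <- function(simulation = sim_config(),
                            stratification = stratification_config(),
                            m_imputations = 5,
                            caliper_sd = 0.2,
                            n_perm = 500,
                            cost = 1, epsilon = 0.1,
                            stages = c("simulate", "match", "inference",
                                       "brainage"),
                            seed = 1L) {
  stopifnot(inherits(simulation, "bp_sim_config"),
            inherits(stratification, "bp_strat_config"))
  seed <- check_count(seed, "seed", min = 0)
  stages <- match.arg(stages, several.ok = TRUE)
  simulation$seed <- derive_seed(seed, 11)
  stratification$seed <- derive_seed(seed, 22)
  structure(
    list(simulation = simulation, stratification = stratification,
         m_imputations = check_count(m_imputations, "m_imputations"),
         caliper_sd = caliper_sd,
         n_perm = check_count(n_perm, "n_perm"),
         cost = cost, epsilon = epsilon,
         stages = stages, seed = seed),
    class = "bp_pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [pipeline_config()] arguments; `simulation` and
#' `stratification` are nested maps passed to their constructors.  Unknown
#' keys are rejected.
#'
#' @param path YAML file path.
#' @return A `bp_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(pipeline_config)), c("simulation", "stratification"))
  extra <- setdiff(names(raw), c(known, "simulation", "stratification"))
  if (length(extra) > 0) {
    abort(sprintf("unknown pipeline config key(s): %s.", paste(extra, collapse = ", ")))
  }
  args <- raw[intersect(names(raw), known)]
  if (!is.null(raw$simulation)) {
    sim <- raw$simulation
    if (!is.null(sim$n_study_per_cell)) sim$n_study_per_cell <- unlist(sim$n_study_per_cell)
    if (!is.null(sim$diagnosis_effects)) sim$diagnosis_effects <- unlist(sim$diagnosis_effects)
    args$simulation <- do.call(sim_config, sim)
  }
  if (!is.null(raw$stratification)) {
    args$stratification <- do.call(stratification_config, raw$stratification)
  }
  do.call(pipeline_config, args)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

safe_term <- function(term) gsub(":", "_x_", term, fixed = TRUE)

#' Execute the end-to-end pipeline
#'
#' Runs the enabled stages in order -- simulate cohorts, impute and match,
#' parcel-wise permutation inference on the matched cohort, brain-age
#' ensemble training and scoring -- writing every stage artifact as TSV into
#' `out_dir` together with a machine-readable JSON manifest.  A failing
#' stage halts the run with the stage name; artifacts of completed stages
#' are preserved.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.  Artifacts written: cohort and parcel
#'   tables, matched pairs and balance tables, per-factor parcel-wise result
#'   tables with their null max-F samples, BrainAGE tables and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "bp_pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  stages <- config$stages

  manifest <- list(
    package_version = as.character(utils::packageVersion("brainparcel")),
    seed = config$seed,
    stages = stages,
    n_perm = config$n_perm,
    m_imputations = config$m_imputations,
    caliper_sd = config$caliper_sd,
    svr = list(cost = config$cost, epsilon = config$epsilon),
    simulation = unclass(config$simulation),
    stratification = unclass(config$stratification)
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  reference <- study <- NULL
  if ("simulate" %in% stages) {
    run_stage("simulate", {
      reference <- simulate_reference_cohort(config$simulation)
      study <- simulate_study_cohort(config$simulation)
      write_cohort_tsv(reference$cohort, p("reference_cohort.tsv"))
      write_parcels_tsv(reference$parcels, p("reference_parcels.tsv"))
      write_cohort_tsv(study$cohort, p("study_cohort.tsv"))
      write_parcels_tsv(study$parcels, p("study_parcels.tsv"))
    })
  } else {
    run_stage("load", {
      reference <- list(cohort = read_cohort_tsv(p("reference_cohort.tsv")),
                        parcels = read_parcels_tsv(p("reference_parcels.tsv")))
      study <- list(cohort = read_cohort_tsv(p("study_cohort.tsv")),
                    parcels = read_parcels_tsv(p("study_parcels.tsv")))
    })
  }

  cohort_m <- study$cohort
  parcels_m <- study$parcels
  if ("match" %in% stages) {
    run_stage("match", {
      imp <- impute_missing(study$cohort, m = config$m_imputations,
                            seed = derive_seed(config$seed, 33))
      write_cohort_tsv(imp$pooled, p("study_cohort_imputed.tsv"))
      ps <- estimate_propensity(imp$pooled)
      matched <- match_pairs(imp$pooled, ps, caliper_sd = config$caliper_sd,
                             seed = derive_seed(config$seed, 44))
      readr::write_tsv(matched$pairs, p("matched_pairs.tsv"))
      readr::write_tsv(balance_table(imp$pooled), p("balance_unmatched.tsv"))
      readr::write_tsv(balance_table(imp$pooled, matched), p("balance_matched.tsv"))
      cohort_m <- matched_subjects(matched, imp$pooled)
      parcels_m <- study$parcels[match(cohort_m$subject_id,
                                       study$parcels$subject_id), ]
    })
  }

  if ("inference" %in% stages) {
    run_stage("inference", {
      fit <- run_parcelwise_analysis(parcels_m, cohort_m,
                                     n_perm = config$n_perm,
                                     seed = derive_seed(config$seed, 55))
      for (term in names(fit$terms)) {
        r <- fit$terms[[term]]
        readr::write_tsv(r$table, p(sprintf("parcelwise_%s.tsv", safe_term(term))))
        readr::write_tsv(tibble(max_f = r$null_max),
                         p(sprintf("null_max_%s.tsv", safe_term(term))))
      }
      readr::write_tsv(glance(fit), p("parcelwise_summary.tsv"))
    })
  }

  if ("brainage" %in% stages) {
    run_stage("brainage", {
      ens <- train_brainage(reference$parcels, reference$cohort,
                            config$stratification,
                            cost = config$cost, epsilon = config$epsilon)
      preds <- predict(ens, parcels_m)
      res <- suppressWarnings(evaluate_groups(
        preds, cohort_m, n_perm = config$n_perm,
        seed = derive_seed(config$seed, 66)
      ))
      readr::write_tsv(res$subjects, p("brainage_subjects.tsv"))
      readr::write_tsv(res$groups, p("brainage_groups.tsv"))
      if (!is.null(res$anova)) {
        readr::write_tsv(res$anova, p("brainage_anova.tsv"))
      }
    })
  }
  invisible(out_dir)
}

report_file <- function(run_dir, name) {
  path <- file.path(run_dir, name)
  if (!file.exists(path)) {
    abort(sprintf("missing stage output '%s' in %s.", name, run_dir))
  }
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Summarize a completed pipeline run
#'
#' Renders publication-style summary tables from the stage artifacts without
#' recomputation: the matched balance table, per-factor significant-parcel
#' counts, and per-group BrainAGE summaries (with the identity
#' mean predicted = mean chronological + mean BrainAGE).
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return Named list of tibbles (also written as `report_*.tsv` into
#'   `run_dir`).
#' @export
render_report <- function(run_dir) {
  balance <- report_file(run_dir, "balance_matched.tsv")
  summary_tbl <- report_file(run_dir, "parcelwise_summary.tsv")
  counts <- summary_tbl[, c("term", "n_parcels", "n_significant",
                            "fwe_threshold")]
  subjects <- report_file(run_dir, "brainage_subjects.tsv")
  groups <- report_file(run_dir, "brainage_groups.tsv") %>%
    left_join(
      subjects %>%
        group_by(.data$diagnosis) %>%
        summarise(mean_age = mean(.data$age),
                  mean_predicted = mean(.data$predicted_age),
                  .groups = "drop"),
      by = "diagnosis"
    )
  out <- list(balance = balance, significant_counts = counts, groups = groups)
  for (nm in names(out)) {
    readr::write_tsv(out[[nm]], file.path(run_dir, sprintf("report_%s.tsv", nm)))
  }
  out
}
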