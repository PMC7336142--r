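#' Stratification and ensemble settings for brain-age training
#'
#' The reference pool is heterogeneous across sites, sexes and age brackets;
#' each ensemble replicate therefore trains on a stratified subsample: within
#' every age-bracket x sex x site cell at most `max_per_stratum` subjects are
#' drawn without replacement, and within every age bracket the larger sex is
#' down-sampled to the smaller, so each weak learner sees a balanced slice of
#' the pool.
#'
#' @param age_bracket_width Bracket width in years (default 5, tiling the
#'   reference age range).
#' @param age_range Age range tiled by the brackets (years).
#' @param max_per_stratum Cap per age-bracket x sex x site cell (default 30).
#' @param n_replicates Number of weak learners.  At production scale this is
#'   10,000; the default 200 is a desk-scale setting -- bagging variance
#'   shrinks as 1/n_replicates, so additional replicates mainly polish the
#'   bagged mean.
#' @param per_replicate_fraction Fraction of the stratified pool drawn per
#'   replicate (1 = use the whole stratified pool).
#' @param seed Master seed; replicate r uses the derived seed `seed + r`.
#' @return A `bp_strat_config` list.
#' @export
stratification_config <- function(age_bracket_width = 5,
                                  age_range = c(55, 85),
                                  max_per_stratum = 30,
                                  n_replicates = 200,
                                  per_replicate_fraction = 1,
                                  seed = 1L) {
  if (age_bracket_width <= 0) abort("`age_bracket_width` must be > 0.")
  max_per_stratum <- check_count(max_per_stratum, "max_per_stratum")
  n_replicates <- check_count(n_replicates, "n_replicates")
  if (per_replicate_fraction <= 0 || per_replicate_fraction > 1) {
    abort("`per_replicate_fraction` must lie in (0, 1].")
  }
  structure(
    list(age_bracket_width = as.numeric(age_bracket_width),
         age_range = as.numeric(age_range),
         max_per_stratum = max_per_stratum,
         n_replicates = n_replicates,
         per_replicate_fraction = per_replicate_fraction,
         seed = check_count(seed, "seed", min = 0)),
    class = "bp_strat_config"
  )
}

#' Draw one stratified subsample of the reference cohort
#'
#' @param cohort Reference cohort tibble (needs age, sex, site).
#' @param config A [stratification_config()].
#' @param replicate_seed Seed for this replicate's draws.
#' @return Character vector of subject ids (no duplicates).
#' @export
stratified_subsample <- function(cohort, config = stratification_config(),
                                 replicate_seed = 1) {
  assert_cohort(cohort, need = c("subject_id", "age", "sex", "site"))
  if (nrow(cohort) == 0) abort("reference cohort is empty.")
  if (length(unique(cohort$sex)) < 2) {
    abort("reference cohort must contain both sexes.")
  }
  breaks <- seq(config$age_range[1], config$age_range[2],
                by = config$age_bracket_width)
  if (max(breaks) < config$age_range[2]) breaks <- c(breaks, config$age_range[2])
  bracket <- cut(cohort$age, breaks, include.lowest = TRUE)
  if (length(unique(stats::na.omit(bracket))) < 2) {
    abort("reference cohort must span at least 2 age brackets.")
  }
  set.seed(derive_seed(replicate_seed, 0))

  keep_bracket <- !is.na(bracket)
  dat <- tibble(subject_id = cohort$subject_id[keep_bracket],
                sex = cohort$sex[keep_bracket],
                site = cohort$site[keep_bracket],
                bracket = bracket[keep_bracket])
  sexes <- sort(unique(dat$sex))
  # cap each bracket x sex x site cell
  cell <- interaction(dat$bracket, dat$sex, dat$site, drop = TRUE)
  capped_rows <- unlist(lapply(split(seq_len(nrow(dat)), cell), function(rows) {
    rows[sample.int(length(rows), min(length(rows), config$max_per_stratum))]
  }), use.names = FALSE)
  dat <- dat[sort(capped_rows), ]
  # equalize the sexes within each bracket
  eq_rows <- unlist(lapply(split(seq_len(nrow(dat)), dat$bracket),
                           function(rows) {
    by_sex <- split(rows, factor(dat$sex[rows], levels = sexes))
    n_keep <- min(lengths(by_sex))
    unlist(lapply(by_sex, function(r) r[sample.int(length(r), n_keep)]),
           use.names = FALSE)
  }), use.names = FALSE)
  ids <- dat$subject_id[sort(eq_rows)]
  if (config$per_replicate_fraction < 1) {
    ids <- sample(ids, ceiling(length(ids) * config$per_replicate_fraction))
  }
  stopifnot(!anyDuplicated(ids))
  ids
}

#' Fit one support-vector-regression weak learner
#'
#' Standardizes features to zero mean / unit variance using the training
#' subsample's own statistics (stored with the learner, so test subjects are
#' standardized identically) and fits epsilon-insensitive support-vector
#' regression of age on the parcel features.
#'
#' @param x Numeric matrix (training subjects x parcels).
#' @param age Numeric vector of chronological ages (years).
#' @param cost,epsilon,kernel SVR hyperparameters (linear kernel, C = 1,
#'   epsilon = 0.1 by default).
#' @return A `bp_weak_learner` with stored standardization parameters.
#' @export
fit_weak_learner <- function(x, age, cost = 1, epsilon = 0.1,
                             kernel = "linear") {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) != length(age)) abort("`x` rows and `age` must align.")
  if (nrow(x) < 20) {
    abort(sprintf("need >= 20 training subjects, got %d.", nrow(x)))
  }
  if (anyNA(x) || anyNA(age)) abort("training data must be complete.")
  center <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  floored <- scale_ < 1e-8
  if (any(floored)) {
    warn(sprintf("%d constant feature(s); variance floored to 1.", sum(floored)))
    scale_[floored] <- 1
  }
  z <- scale(x, center, scale_)
  fit <- e1071::svm(z, age, type = "eps-regression", kernel = kernel,
                    cost = cost, epsilon = epsilon, scale = FALSE)
  # for the linear kernel the decision function collapses to a primal
  # weight vector, which makes ensemble prediction cheap
  linear_w <- if (kernel == "linear") drop(crossprod(fit$SV, fit$coefs))
  structure(
    list(fit = fit, linear_w = linear_w, center = center, scale = scale_,
         features = colnames(x), n_train = nrow(x),
         hyper = list(cost = cost, epsilon = epsilon, kernel = kernel)),
    class = "bp_weak_learner"
  )
}

#' @export
predict.bp_weak_learner <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$center)) {
    abort(sprintf("learner expects %d features, got %d.",
                  length(object$center), ncol(newdata)))
  }
  if (!is.null(object$features) && !is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object$features)) {
    abort("feature columns are not in the learner's training order.")
  }
  z <- scale(newdata, object$center, object$scale)
  if (!is.null(object$linear_w)) {
    return(unname(drop(z %*% object$linear_w) - object$fit$rho))
  }
  unname(predict(object$fit, z))
}

#' Train the bagged brain-age ensemble
#'
#' Repeats, `n_replicates` times: draw a stratified subsample of the
#' reference cohort, fit an SVR weak learner on its parcel volumes.  The
#' ensemble's bagged prediction is the arithmetic mean over learners.
#'
#' @param parcels Reference parcel table (`subject_id` + parcel columns).
#' @param cohort Reference cohort tibble, row-aligned with `parcels`.
#' @param config A [stratification_config()].
#' @param cost,epsilon,kernel SVR hyperparameters passed to each learner.
#' @return A `brainage_ensemble`.  Supports [predict()] and [glance()].
#' @export
train_brainage <- function(parcels, cohort, config = stratification_config(),
                           cost = 1, epsilon = 0.1, kernel = "linear") {
  assert_parcels(parcels)
  assert_cohort(cohort, need = c("subject_id", "age", "sex", "site"))
  if (!identical(parcels$subject_id, cohort$subject_id)) {
    abort("`parcels` and `cohort` must have identical subject_id order.")
  }
  Y <- parcel_matrix(parcels)
  ages <- setNames(cohort$age, cohort$subject_id)
  learners <- vector("list", config$n_replicates)
  train_ids <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    ids <- stratified_subsample(cohort, config,
                                replicate_seed = derive_seed(config$seed, r))
    learners[[r]] <- fit_weak_learner(Y[ids, , drop = FALSE], ages[ids],
                                      cost = cost, epsilon = epsilon,
                                      kernel = kernel)
    train_ids[[r]] <- ids
  }
  structure(
    list(learners = learners, train_ids = train_ids, config = config,
         features = colnames(Y),
         hyper = list(cost = cost, epsilon = epsilon, kernel = kernel)),
    class = "brainage_ensemble"
  )
}

#' @export
print.brainage_ensemble <- function(x, ...) {
  cat(sprintf("<brainage_ensemble> %d weak learners, %d features, mean train n = %.0f\n",
              length(x$learners), length(x$features),
              mean(vapply(x$train_ids, length, numeric(1)))))
  invisible(x)
}

#' @method glance brainage_ensemble
#' @export
glance.brainage_ensemble <- function(x, ...) {
  tibble(
    n_learners = length(x$learners),
    n_features = length(x$features),
    mean_train_n = mean(vapply(x$train_ids, length, numeric(1))),
    cost = x$hyper$cost, epsilon = x$hyper$epsilon, kernel = x$hyper$kernel
  )
}

#' Bagged age prediction for new subjects
#'
#' @param object A [train_brainage()] ensemble.
#' @param parcels Parcel table for the subjects to score; parcel columns
#'   must match the training features.
#' @param ... Unused.
#' @return Tibble: `subject_id`, `predicted_age` (mean over weak learners).
#' @export
predict.brainage_ensemble <- function(object, parcels, ...) {
  assert_parcels(parcels)
  Y <- parcel_matrix(parcels)
  if (!identical(colnames(Y), object$features)) {
    abort("parcel columns do not match the ensemble's training features.")
  }
  preds <- vapply(object$learners, function(l) predict(l, Y),
                  numeric(nrow(Y)))
  if (nrow(Y) == 1) preds <- matrix(preds, nrow = 1)
  tibble(subject_id = parcels$subject_id,
         predicted_age = rowMeans(preds))
}

#' BrainAGE scores
#'
#' The brain-age gap estimate: bagged predicted age minus chronological age,
#' in years; positive values mean an older-appearing brain.
#'
#' @param predicted,chronological Aligned numeric vectors (years).
#' @return Numeric vector of per-subject BrainAGE scores.
#' @export
#' @examples
#' brainage_scores(c(80, 70), c(74, 71))  # +6, -1
brainage_scores <- function(predicted, chronological) {
  if (length(predicted) != length(chronological)) {
    abort("`predicted` and `chronological` must have the same length.")
  }
  predicted - chronological
}

#' Group-level BrainAGE evaluation
#'
#' Per-diagnosis mean absolute error, mean BrainAGE with t-based 95%
#' confidence interval, and a permutation ANOVA of BrainAGE on diagnosis,
#' SDB status and their interaction (the single-response analogue of the
#' parcel-wise engine).
#'
#' @param predictions Tibble from [predict.brainage_ensemble()]
#'   (`subject_id`, `predicted_age`).
#' @param cohort Study cohort tibble with `age`, `diagnosis`, `sdb_status`.
#' @param n_perm Permutations for the group-inference ANOVA (0 skips it).
#' @param seed Seed for the permutation ANOVA.
#' @param conf_level Confidence level of the group CIs.
#' @return A `brainage_result`: `subjects` (per-subject table with
#'   `brainage`), `groups` (per-diagnosis summary), `anova` (term table with
#'   permutation p-values).  Supports [tidy()], [glance()], [autoplot()].
#' @export
evaluate_groups <- function(predictions, cohort, n_perm = 1000, seed = 1,
                            conf_level = 0.95) {
  assert_cohort(cohort, need = c("subject_id", "age", "diagnosis", "sdb_status"))
  subjects <- left_join(
    cohort[, c("subject_id", "age", "diagnosis", "sdb_status")],
    predictions[, c("subject_id", "predicted_age")],
    by = "subject_id"
  )
  if (anyNA(subjects$predicted_age)) {
    abort("`predictions` must cover every cohort subject.")
  }
  subjects$brainage <- brainage_scores(subjects$predicted_age, subjects$age)

  groups <- subjects %>%
    group_by(diagnosis = factor(.data$diagnosis, c("HC", "MCI", "AD"))) %>%
    summarise(
      n = dplyr::n(),
      mae = mean(abs(.data$brainage)),
      mean_brainage = mean(.data$brainage),
      sd_brainage = sd(.data$brainage),
      .groups = "drop"
    ) %>%
    mutate(
      note = dplyr::case_when(
        n < 2 ~ "fewer than 2 subjects: CI omitted",
        sd_brainage == 0 ~ "degenerate variance: CI width 0",
        TRUE ~ NA_character_
      ),
      half = ifelse(n >= 2,
                    qt(1 - (1 - conf_level) / 2, n - 1) * sd_brainage / sqrt(n),
                    NA_real_),
      ci_low = .data$mean_brainage - .data$half,
      ci_high = .data$mean_brainage + .data$half
    ) %>%
    select(-"half")
  if (any(!is.na(groups$note))) {
    inform(paste(stats::na.omit(groups$note), collapse = "; "))
  }

  anova_tbl <- NULL
  if (n_perm > 0 && length(unique(subjects$sdb_status)) > 1 &&
      sd(subjects$brainage) > 0) {
    ba_parcels <- tibble(subject_id = subjects$subject_id,
                         brainage_score = subjects$brainage)
    fit <- run_parcelwise_analysis(
      ba_parcels, subjects, formula = ~ diagnosis * sdb_status,
      n_perm = n_perm, seed = seed
    )
    anova_tbl <- tidy(fit) %>%
      select("term", "statistic", p_value = "p_uncorrected")
  }

  structure(
    list(subjects = subjects, groups = groups, anova = anova_tbl,
         conf_level = conf_level, n_perm = n_perm),
    class = "brainage_result"
  )
}

#' @export
print.brainage_result <- function(x, ...) {
  cat("<brainage_result>\n")
  print(x$groups)
  if (!is.null(x$anova)) {
    cat("group inference (permutation ANOVA on BrainAGE):\n")
    print(x$anova)
  }
  invisible(x)
}

#' @method tidy brainage_result
#' @export
tidy.brainage_result <- function(x, ...) as_tibble(x$subjects)

#' @method glance brainage_result
#' @export
glance.brainage_result <- function(x, ...) {
  hc <- x$groups[x$groups$diagnosis == "HC", ]
  tibble(
    n = nrow(x$subjects),
    hc_mae = if (nrow(hc) == 1) hc$mae else NA_real_,
    mean_brainage = mean(x$subjects$brainage),
    sdb_p = if (!is.null(x$anova) && "sdb_status" %in% x$anova$term) {
      x$anova$p_value[x$anova$term == "sdb_status"]
    } else {
      NA_real_
    }
  )
}
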