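#' Multiple imputation of missing BMI and education
#'
#' Chained-regression multiple imputation for the two covariates that may be
#' missing in a study cohort (body-mass index and education years), using
#' sex, age, cognitive status and the respective other covariate as
#' predictors.  Observed entries are never modified.  Alongside the `m`
#' completed tables, a pooled table (per-entry mean of the imputations) is
#' returned for downstream single-run matching.
#'
#' @param cohort Cohort tibble; missingness must be confined to `bmi` and
#'   `education_years`.
#' @param m Number of imputations.
#' @param seed Integer seed.
#' @param n_sweeps Chained-equation sweeps per imputation.
#' @return List with `imputations` (list of `m` completed tibbles), `pooled`
#'   (single completed tibble) and `m`.
#' @export
impute_missing <- function(cohort, m = 5, seed = 1, n_sweeps = 5) {
  assert_cohort(cohort, need = c("subject_id", "age", "sex", "diagnosis",
                                 "bmi", "education_years"))
  m <- check_count(m, "m")
  targets <- c("bmi", "education_years")
  others <- setdiff(names(cohort), targets)
  bad <- others[vapply(cohort[others], anyNA, logical(1))]
  bad <- intersect(bad, c("age", "sex", "diagnosis"))
  if (length(bad) > 0) {
    abort(sprintf("missingness must be confined to bmi/education_years; found NA in: %s.",
                  paste(bad, collapse = ", ")))
  }
  if (any(!complete.cases(cohort[, c("age", "sex", "diagnosis")]))) {
    abort("some rows are missing all imputation predictors (age, sex, diagnosis).")
  }

  miss <- lapply(cohort[targets], is.na)
  if (!any(unlist(miss))) {
    return(list(imputations = rep(list(cohort), m), pooled = cohort, m = m))
  }

  impute_once <- function(k) {
    set.seed(derive_seed(seed, 100 + k))
    dat <- cohort
    for (v in targets) dat[[v]][miss[[v]]] <- mean(cohort[[v]], na.rm = TRUE)
    for (sweep in seq_len(n_sweeps)) {
      for (v in targets) {
        if (!any(miss[[v]])) next
        preds <- c("age", "sex", "diagnosis", setdiff(targets, v))
        preds <- preds[vapply(dat[preds], function(x) length(unique(x)) > 1,
                              logical(1))]
        fit <- lm(as.formula(paste(v, "~", paste(preds, collapse = "+"))),
                  data = dat[!miss[[v]], , drop = FALSE])
        mu <- predict(fit, newdata = dat[miss[[v]], , drop = FALSE])
        dat[[v]][miss[[v]]] <- mu + rnorm(sum(miss[[v]]), 0, summary(fit)$sigma)
      }
    }
    dat
  }
  imputations <- lapply(seq_len(m), impute_once)

  pooled <- cohort
  for (v in targets) {
    stacked <- vapply(imputations, function(d) d[[v]], numeric(nrow(cohort)))
    pooled[[v]] <- rowMeans(stacked)
  }
  list(imputations = imputations, pooled = pooled, m = m)
}

#' Fit a propensity model for SDB status
#'
#' Logistic regression of SDB-positive status on the matching covariate set.
#' Treatment history (CPAP/BiPAP) is deliberately absent from the default
#' covariates: by construction it occurs only in the SDB-positive arm and
#' would separate the classes perfectly.
#'
#' @param cohort Complete cohort tibble (impute first if needed).
#' @param covariates Character vector of covariate column names.
#' @return A `propensity_model`: list with the `glm` fit, the covariates and
#'   `scores` (tibble: subject_id, score, logit).  Supports [tidy()] and
#'   [glance()].
#' @export
estimate_propensity <- function(cohort,
                                covariates = c("age", "sex", "bmi",
                                               "education_years", "diagnosis",
                                               "apoe4_count", "protocol")) {
  assert_cohort(cohort, need = c("subject_id", "sdb_status", covariates))
  if (anyNA(cohort[covariates])) {
    abort("covariates contain missing values; run impute_missing() first.")
  }
  classes <- unique(cohort$sdb_status)
  if (length(classes) < 2) {
    abort("both SDB classes must be present to fit a propensity model.")
  }
  dat <- cohort
  dat$.sdb <- as.integer(dat$sdb_status == "positive")
  keep <- covariates[vapply(dat[covariates],
                            function(x) length(unique(x)) > 1, logical(1))]
  fml <- as.formula(paste(".sdb ~", paste(keep, collapse = "+")))
  fit <- withCallingHandlers(
    glm(fml, family = binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        abort(paste0("perfect separation in the propensity model; remove the ",
                     "offending covariate or use a penalized fit."))
      }
      invokeRestart("muffleWarning")
    }
  )
  p <- unname(fitted(fit))
  if (any(p < 1e-10 | p > 1 - 1e-10)) {
    abort(paste0("perfect separation in the propensity model; remove the ",
                 "offending covariate or use a penalized fit."))
  }
  structure(
    list(fit = fit, covariates = keep,
         scores = tibble(subject_id = cohort$subject_id, score = p,
                         logit = qlogis(p))),
    class = "propensity_model"
  )
}

#' @export
print.propensity_model <- function(x, ...) {
  cat("<propensity_model>\n")
  cat(sprintf("  n = %d, covariates: %s\n", nrow(x$scores),
              paste(x$covariates, collapse = ", ")))
  cat(sprintf("  score range: %.3f - %.3f\n",
              min(x$scores$score), max(x$scores$score)))
  invisible(x)
}

#' @method tidy propensity_model
#' @export
tidy.propensity_model <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @method glance propensity_model
#' @export
glance.propensity_model <- function(x, ...) {
  tibble(
    n = nrow(x$scores),
    prevalence = mean(x$fit$y),
    null.deviance = x$fit$null.deviance,
    deviance = x$fit$deviance,
    AIC = x$fit$aic
  )
}

#' Greedy 1:1 propensity matching, exact on diagnosis
#'
#' Pairs each SDB-positive subject with the nearest unused SDB-negative
#' subject of the same diagnosis on the logit of the propensity score,
#' without replacement, discarding candidates beyond the caliper.  The
#' processing order of treated subjects is randomized by `seed`.  Because
#' matching is exact on diagnosis, the matched cohort has identical
#' per-diagnosis counts in both arms.
#'
#' @param cohort Cohort tibble with `sdb_status` and `diagnosis`.
#' @param scores A `propensity_model`, or a tibble with `subject_id` and
#'   `score`, or a numeric vector aligned to `cohort` rows.
#' @param caliper_sd Caliper as a multiple of the SD of the logit scores
#'   (0.2 is the common convention; `Inf` disables the caliper).
#' @param seed Integer seed for the processing order.
#' @return A `matched_cohort`: `pairs` (tibble: pair_id, treated_id,
#'   control_id, diagnosis, distance), `discarded` (unmatched subject ids)
#'   and the absolute `caliper` in logit units.
#' @export
match_pairs <- function(cohort, scores, caliper_sd = 0.2, seed = 1) {
  assert_cohort(cohort, need = c("subject_id", "sdb_status", "diagnosis"))
  if (inherits(scores, "propensity_model")) scores <- scores$scores
  if (is.numeric(scores) && is.null(dim(scores))) {
    if (length(scores) != nrow(cohort)) {
      abort("numeric `scores` must align with cohort rows.")
    }
    scores <- tibble(subject_id = cohort$subject_id, score = scores)
  }
  if (!all(cohort$subject_id %in% scores$subject_id)) {
    abort("`scores` must cover every cohort subject.")
  }
  dat <- left_join(cohort[, c("subject_id", "sdb_status", "diagnosis")],
                   scores[, c("subject_id", "score")], by = "subject_id")
  if (any(dat$score <= 0 | dat$score >= 1)) {
    abort("propensity scores must lie strictly in (0, 1).")
  }
  dat$logit <- qlogis(dat$score)
  caliper <- if (is.finite(caliper_sd)) caliper_sd * sd(dat$logit) else Inf
  if (is.na(caliper)) caliper <- Inf  # single subject: sd undefined

  set.seed(derive_seed(seed, 0))
  pairs <- list()
  used_controls <- character(0)
  for (dx in unique(dat$diagnosis)) {
    treated <- dat[dat$sdb_status == "positive" & dat$diagnosis == dx, ]
    controls <- dat[dat$sdb_status == "negative" & dat$diagnosis == dx, ]
    if (nrow(treated) == 0 || nrow(controls) == 0) {
      warn(sprintf("diagnosis stratum '%s' has an empty arm; no pairs formed.", dx))
      next
    }
    treated <- treated[sample.int(nrow(treated)), ]
    avail <- setNames(controls$logit, controls$subject_id)
    for (i in seq_len(nrow(treated))) {
      if (length(avail) == 0) break
      d <- abs(avail - treated$logit[i])
      j <- which.min(d)
      if (d[j] <= caliper) {
        pairs[[length(pairs) + 1]] <- tibble(
          treated_id = treated$subject_id[i],
          control_id = names(avail)[j],
          diagnosis = dx,
          distance = unname(d[j])
        )
        avail <- avail[-j]
      }
    }
  }
  pairs <- if (length(pairs) > 0) {
    mutate(bind_rows(pairs), pair_id = row_number(), .before = 1)
  } else {
    tibble(pair_id = integer(), treated_id = character(),
           control_id = character(), diagnosis = character(),
           distance = numeric())
  }
  matched_ids <- c(pairs$treated_id, pairs$control_id)
  stopifnot(!anyDuplicated(matched_ids))  # matching without replacement
  structure(
    list(pairs = pairs,
         discarded = setdiff(dat$subject_id, matched_ids),
         caliper = caliper, caliper_sd = caliper_sd, seed = seed),
    class = "matched_cohort"
  )
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat("<matched_cohort>\n")
  cat(sprintf("  %d pairs, %d discarded, caliper %.4g logit units\n",
              nrow(x$pairs), length(x$discarded), x$caliper))
  if (nrow(x$pairs) > 0) print(count(x$pairs, .data$diagnosis))
  invisible(x)
}

#' Subset a cohort to its matched subjects
#'
#' @param matched A [match_pairs()] result.
#' @param cohort The cohort the matching was run on.
#' @return The cohort rows belonging to a matched pair.
#' @export
matched_subjects <- function(matched, cohort) {
  stopifnot(inherits(matched, "matched_cohort"))
  filter(cohort, .data$subject_id %in%
           c(matched$pairs$treated_id, matched$pairs$control_id))
}

smd_numeric <- function(pos, neg) {
  pooled <- sqrt((var(pos) + var(neg)) / 2)
  if (!is.finite(pooled) || pooled == 0) return(0)
  (mean(pos) - mean(neg)) / pooled
}

smd_binary <- function(p1, p0) {
  pooled <- sqrt((p1 * (1 - p1) + p0 * (1 - p0)) / 2)
  if (pooled == 0) return(0)
  (p1 - p0) / pooled
}

#' Covariate balance between SDB arms
#'
#' Standardized mean differences and two-arm tests for each covariate,
#' positive SMD meaning higher in the SDB-positive arm.  Numeric covariates
#' get a Welch two-sample t test; categorical covariates get a chi-square
#' test (no continuity correction) and, as SMD, the proportion-based value
#' (largest level-wise value for multi-level factors).  Constant covariates
#' get SMD 0 and the test is skipped with a note.
#'
#' @param cohort Cohort tibble.
#' @param matched Optional [match_pairs()] result; if given, balance is
#'   computed on the matched subjects only.
#' @param covariates Covariates to report, in output order.
#' @return Tibble: covariate, type, mean or proportion per arm, smd,
#'   statistic, df, p_value, test, note.
#' @export
balance_table <- function(cohort, matched = NULL,
                          covariates = c("age", "sex", "bmi",
                                         "education_years", "apoe4_count",
                                         "diagnosis", "protocol")) {
  assert_cohort(cohort, need = c("subject_id", "sdb_status"))
  covariates <- intersect(covariates, names(cohort))
  if (!is.null(matched)) cohort <- matched_subjects(matched, cohort)
  pos <- cohort[cohort$sdb_status == "positive", ]
  neg <- cohort[cohort$sdb_status == "negative", ]
  if (nrow(pos) < 2 || nrow(neg) < 2) {
    abort("balance_table() needs at least 2 subjects per arm.")
  }

  one <- function(v) {
    xp <- pos[[v]]; xn <- neg[[v]]
    if (is.numeric(xp)) {
      if (length(unique(c(xp, xn))) == 1) {
        return(tibble(covariate = v, type = "numeric",
                      mean_negative = mean(xn), mean_positive = mean(xp),
                      smd = 0, statistic = NA_real_, df = NA_real_,
                      p_value = NA_real_, test = "none",
                      note = "constant in both arms"))
      }
      tt <- t.test(xp, xn)
      tibble(covariate = v, type = "numeric",
             mean_negative = mean(xn), mean_positive = mean(xp),
             smd = smd_numeric(xp, xn),
             statistic = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value, test = "welch_t", note = NA_character_)
    } else {
      lev <- sort(unique(c(as.character(xp), as.character(xn))))
      if (length(lev) == 1) {
        return(tibble(covariate = v, type = "categorical",
                      mean_negative = NA_real_, mean_positive = NA_real_,
                      smd = 0, statistic = NA_real_, df = NA_real_,
                      p_value = NA_real_, test = "none",
                      note = "constant in both arms"))
      }
      tab <- rbind(table(factor(xn, lev)), table(factor(xp, lev)))
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      smds <- vapply(lev, function(l) {
        smd_binary(mean(xp == l), mean(xn == l))
      }, numeric(1))
      smd <- smds[which.max(abs(smds))]
      tibble(covariate = v, type = "categorical",
             mean_negative = if (length(lev) == 2) mean(xn == lev[2]) else NA_real_,
             mean_positive = if (length(lev) == 2) mean(xp == lev[2]) else NA_real_,
             smd = unname(smd),
             statistic = unname(ct$statistic), df = unname(ct$parameter),
             p_value = ct$p.value, test = "chi_square", note = NA_character_)
    }
  }
  bind_rows(lapply(covariates, one))
}
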