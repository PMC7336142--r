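test_that("imputation is the identity on complete cohorts", {
  cohort <- random_cohort(40, seed = 1)
  out <- impute_missing(cohort, m = 3, seed = 1)
  expect_length(out$imputations, 3)
  for (d in out$imputations) expect_identical(d, cohort)
  expect_identical(out$pooled, cohort)
})

test_that("imputation touches exactly the originally-missing cells", {
  cohort <- random_cohort(60, seed = 2)
  holes_bmi <- c(3, 17, 41)
  holes_edu <- c(8, 52)
  cohort$bmi[holes_bmi] <- NA
  cohort$education_years[holes_edu] <- NA
  out <- impute_missing(cohort, m = 5, seed = 9)
  for (d in out$imputations) {
    expect_false(anyNA(d))
    expect_identical(d$bmi[-holes_bmi], cohort$bmi[-holes_bmi])
    expect_identical(d$education_years[-holes_edu],
                     cohort$education_years[-holes_edu])
  }
  # the five imputed subjects differ across imputations (stochastic draws)
  imputed_bmi <- sapply(out$imputations, function(d) d$bmi[holes_bmi])
  expect_gt(min(apply(imputed_bmi, 1, sd)), 0)
  # pooled = per-cell mean of the imputations
  expect_equal(out$pooled$bmi[holes_bmi], rowMeans(imputed_bmi))
})

test_that("MCAR imputation recovers the generating BMI mean", {
  set.seed(33)
  n <- 2000
  cohort <- random_cohort(n, seed = 33)
  true_mean <- mean(cohort$bmi)
  masked <- cohort
  masked$bmi[sample.int(n, n * 0.2)] <- NA
  out <- impute_missing(masked, m = 5, seed = 7)
  band <- 1.96 * sd(cohort$bmi) / sqrt(n)
  expect_lt(abs(mean(out$pooled$bmi) - true_mean), band)
})

test_that("imputation rejects missingness outside BMI/education", {
  cohort <- random_cohort(30, seed = 3)
  cohort$age[2] <- NA
  expect_error(impute_missing(cohort), "confined")
})

test_that("null-model propensity scores average to the prevalence with calm coefficients", {
  cohort <- random_cohort(5000, seed = 4)
  ps <- estimate_propensity(cohort)
  # with an intercept, mean fitted probability equals the prevalence exactly
  expect_equal(mean(ps$scores$score), mean(cohort$sdb_status == "positive"),
               tolerance = 1e-8)
  expect_true(all(ps$scores$score > 0 & ps$scores$score < 1))
  z <- tidy(ps)$statistic[-1]
  expect_lt(max(abs(z)), 4)
  expect_equal(glance(ps)$n, 5000)
})

test_that("perfect separation and single-class inputs raise errors", {
  cohort <- random_cohort(100, seed = 5)
  cohort$treatment_flag <- cohort$sdb_status == "positive"
  expect_error(
    estimate_propensity(cohort, covariates = c("age", "treatment_flag")),
    "separation"
  )
  onearm <- dplyr::filter(random_cohort(100, seed = 6), sdb_status == "positive")
  expect_error(estimate_propensity(onearm), "both SDB classes")
})

test_that("duplicating every row leaves propensity coefficients unchanged", {
  cohort <- random_cohort(200, seed = 7)
  doubled <- dplyr::bind_rows(
    cohort, dplyr::mutate(cohort, subject_id = paste0(subject_id, "_b"))
  )
  c1 <- coef(estimate_propensity(cohort)$fit)
  c2 <- coef(estimate_propensity(doubled)$fit)
  expect_equal(c1, c2, tolerance = 1e-6)
})

test_that("identical score multisets per diagnosis match every treated subject", {
  base <- random_cohort(60, seed = 8)
  cohort <- base
  cohort$sdb_status <- rep(c("positive", "negative"), each = 30)
  cohort$diagnosis <- rep(rep(c("HC", "MCI", "AD"), each = 10), 2)
  scores <- rep(seq(0.2, 0.8, length.out = 30), 2)
  m <- match_pairs(cohort, scores, caliper_sd = 0.2, seed = 1)
  expect_equal(nrow(m$pairs), 30)
  expect_length(m$discarded, 0)
  expect_true(all(m$pairs$distance < 1e-12))
})

test_that("scores separated beyond the caliper yield zero pairs", {
  cohort <- random_cohort(40, seed = 9)
  cohort$sdb_status <- rep(c("positive", "negative"), each = 20)
  cohort$diagnosis <- "MCI"
  scores <- c(rep(0.9, 20), rep(0.1, 20))
  scores <- scores + rep(seq(0, 0.01, length.out = 20), 2) # nonzero sd
  m <- match_pairs(cohort, scores, caliper_sd = 0.2, seed = 1)
  expect_equal(nrow(m$pairs), 0)
  expect_length(m$discarded, 40)
})

test_that("matching a 200-subject cohort balances per-diagnosis counts across arms", {
  cohort <- random_cohort(200, seed = 10)
  ps <- estimate_propensity(cohort)
  m <- match_pairs(cohort, ps, seed = 3)
  expect_gt(nrow(m$pairs), 0)
  matched <- matched_subjects(m, cohort)
  tab <- table(matched$diagnosis, matched$sdb_status)
  expect_equal(unname(tab[, "positive"]), unname(tab[, "negative"]))
  expect_true(all(m$pairs$diagnosis ==
                    cohort$diagnosis[match(m$pairs$control_id, cohort$subject_id)]))
  ids <- c(m$pairs$treated_id, m$pairs$control_id)
  expect_false(any(duplicated(ids)))
})

test_that("an empty diagnosis stratum warns rather than errors", {
  cohort <- random_cohort(40, seed = 11)
  cohort$diagnosis <- rep(c("HC", "AD"), each = 20)
  cohort$sdb_status[cohort$diagnosis == "AD"] <- "positive"
  cohort$sdb_status[cohort$diagnosis == "HC"] <-
    rep(c("positive", "negative"), 10)
  expect_warning(m <- match_pairs(cohort, runif(40, 0.3, 0.7)), "empty arm")
  expect_true(all(m$pairs$diagnosis == "HC"))
})

test_that("balance on identical arms is exactly zero SMD with p = 1", {
  half <- random_cohort(30, seed = 12)
  cohort <- dplyr::bind_rows(
    dplyr::mutate(half, sdb_status = "positive"),
    dplyr::mutate(half, sdb_status = "negative",
                  subject_id = paste0(subject_id, "_n"))
  )
  bal <- balance_table(cohort)
  expect_true(all(bal$smd == 0))
  expect_true(all(bal$p_value[!is.na(bal$p_value)] == 1))
})

test_that("a one-pooled-SD shift yields SMD 1 and tests match textbook formulas", {
  cohort <- random_cohort(400, seed = 13)
  pos <- cohort$sdb_status == "positive"
  pooled <- sqrt((var(cohort$age[pos]) + var(cohort$age[!pos])) / 2)
  # shift so the arm difference is exactly one pooled SD
  shift <- pooled - (mean(cohort$age[pos]) - mean(cohort$age[!pos]))
  cohort$age[pos] <- cohort$age[pos] + shift
  shift <- pooled
  bal <- balance_table(cohort, covariates = c("age", "sex"))
  # SMD recomputed after the shift (variances unchanged by a constant shift)
  expect_equal(bal$smd[bal$covariate == "age"],
               (mean(cohort$age[pos]) - mean(cohort$age[!pos])) / shift,
               tolerance = 1e-12)
  expect_equal(bal$smd[bal$covariate == "age"], 1, tolerance = 1e-6)

  # Welch t oracle
  x <- cohort$age[pos]; y <- cohort$age[!pos]
  se <- sqrt(var(x) / length(x) + var(y) / length(y))
  expect_equal(bal$statistic[bal$covariate == "age"],
               (mean(x) - mean(y)) / se, tolerance = 1e-10)
  # chi-square oracle without continuity correction
  tab <- table(cohort$sdb_status, cohort$sex)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(bal$statistic[bal$covariate == "sex"],
               sum((tab - expected)^2 / expected), tolerance = 1e-10)
})

test_that("constant covariates are reported but not tested", {
  cohort <- random_cohort(40, seed = 14)
  cohort$protocol <- "MP-RAGE"
  bal <- balance_table(cohort, covariates = c("protocol"))
  expect_equal(bal$smd, 0)
  expect_true(is.na(bal$p_value))
  expect_match(bal$note, "constant")
})

test_that("matching does not worsen mean absolute SMD on overlapping cohorts", {
  st <- simulate_study_cohort(tiny_config(
    n_study_per_cell = c(HC = 30, MCI = 40, AD = 20), seed = 404L
  ))
  cohort <- st$cohort
  ps <- estimate_propensity(cohort)
  m <- match_pairs(cohort, ps, seed = 2)
  before <- balance_table(cohort)
  after <- balance_table(cohort, m)
  expect_lte(mean(abs(after$smd)), mean(abs(before$smd)) + 1e-12)
})
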