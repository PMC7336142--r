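linear_age_data <- function(n, p, noise_sd = 0, seed = 1) {
  set.seed(seed)
  age <- runif(n, 55, 85)
  slopes <- rnorm(p, -0.5, 0.1)
  x <- outer(age, slopes) + outer(rep(1, n), rnorm(p, 800, 50)) +
    matrix(rnorm(n * p, 0, noise_sd), n, p)
  colnames(x) <- sprintf("p%04d", seq_len(p))
  list(x = x, age = age)
}

test_that("stratified subsampling caps cells, equalizes sexes and never repeats", {
  set.seed(41)
  cohort <- tibble::tibble(
    subject_id = sprintf("s%04d", 1:300),
    age = runif(300, 55, 85),
    sex = sample(c("female", "male"), 300, TRUE, prob = c(0.7, 0.3)),
    site = sample(c("a", "b"), 300, TRUE)
  )
  # one overfull cell: 45 eligible women aged 55-60 at site a
  cohort$age[1:45] <- runif(45, 55.1, 59.9)
  cohort$sex[1:45] <- "female"
  cohort$site[1:45] <- "a"
  cfg <- stratification_config(max_per_stratum = 30)
  ids <- stratified_subsample(cohort, cfg, replicate_seed = 1)
  expect_false(any(duplicated(ids)))
  sub <- cohort[match(ids, cohort$subject_id), ]
  drawn_cell <- sum(sub$age < 60 & sub$sex == "female" & sub$site == "a" &
                      sub$subject_id %in% cohort$subject_id[1:45])
  expect_lte(drawn_cell, 30)
  # sexes equal within every bracket
  bracket <- cut(sub$age, seq(55, 85, 5), include.lowest = TRUE)
  tab <- table(bracket, sub$sex)
  expect_equal(unname(tab[, "female"]), unname(tab[, "male"]))
})

test_that("inclusion within a cell is exchangeable across replicates", {
  cohort <- tibble::tibble(
    subject_id = sprintf("s%04d", 1:80),
    # two brackets x two sexes, 20 subjects per cell
    age = rep(c(57, 62), each = 40),
    sex = rep(rep(c("female", "male"), each = 20), 2),
    site = "a"
  )
  cfg <- stratification_config(max_per_stratum = 10)
  n_rep <- 400
  freq <- integer(80)
  for (r in seq_len(n_rep)) {
    ids <- stratified_subsample(cohort, cfg, replicate_seed = r)
    hit <- match(ids, cohort$subject_id)
    freq[hit] <- freq[hit] + 1
  }
  p_hat <- freq / n_rep # each subject competes for 10 of 20 cell slots
  mc <- 4 * sqrt(0.25 / n_rep)
  expect_true(all(abs(p_hat - 0.5) < mc))
})

test_that("weak learners interpolate noise-free linear age signal within epsilon", {
  d <- linear_age_data(60, 15, noise_sd = 0, seed = 43)
  l <- fit_weak_learner(d$x, d$age)
  pred <- predict(l, d$x)
  expect_lt(max(abs(pred - d$age)), 0.1 + 1e-6)
})

test_that("weak learners are invariant to pre-standardization feature rescaling", {
  d <- linear_age_data(50, 10, noise_sd = 2, seed = 44)
  l1 <- fit_weak_learner(d$x, d$age)
  x2 <- d$x
  x2[, 3] <- x2[, 3] * 10
  l2 <- fit_weak_learner(x2, d$age)
  newd <- linear_age_data(20, 10, noise_sd = 2, seed = 45)
  new2 <- newd$x
  new2[, 3] <- new2[, 3] * 10
  expect_equal(predict(l1, newd$x), predict(l2, new2), tolerance = 1e-8)
})

test_that("weak-learner fitting is deterministic and guards its inputs", {
  d <- linear_age_data(40, 8, noise_sd = 1, seed = 46)
  l1 <- fit_weak_learner(d$x, d$age)
  l2 <- fit_weak_learner(d$x, d$age)
  expect_equal(predict(l1, d$x), predict(l2, d$x))
  expect_error(fit_weak_learner(d$x[1:10, ], d$age[1:10]), ">= 20")
  xc <- d$x
  xc[, 2] <- 3
  expect_warning(fit_weak_learner(xc, d$age), "constant")
})

test_that("bagging averages learners and cannot be worse than their mean MAE", {
  d <- linear_age_data(80, 10, noise_sd = 3, seed = 47)
  cohort <- tibble::tibble(
    subject_id = sprintf("s%04d", 1:80), age = d$age,
    sex = rep(c("female", "male"), 40),
    site = rep(c("a", "b"), each = 40)
  )
  parcels <- dplyr::bind_cols(tibble::tibble(subject_id = cohort$subject_id),
                              tibble::as_tibble(d$x))
  ens <- train_brainage(parcels, cohort,
                        stratification_config(n_replicates = 5,
                                              max_per_stratum = 10, seed = 2))
  test_d <- linear_age_data(40, 10, noise_sd = 3, seed = 48)
  test_parcels <- dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("t%03d", 1:40)),
    tibble::as_tibble(test_d$x)
  )
  bagged <- predict(ens, test_parcels)$predicted_age
  indiv <- sapply(ens$learners, function(l) predict(l, test_d$x))
  expect_equal(bagged, rowMeans(indiv), tolerance = 1e-12)
  mae_bag <- mean(abs(bagged - test_d$age))
  mae_ind <- mean(colMeans(abs(indiv - test_d$age)))
  expect_lte(mae_bag, mae_ind + 1e-12)

  # a singleton ensemble is its learner; learner order is irrelevant
  ens1 <- ens
  ens1$learners <- ens$learners[1]
  expect_equal(predict(ens1, test_parcels)$predicted_age,
               unname(indiv[, 1]), tolerance = 1e-12)
  ens_rev <- ens
  ens_rev$learners <- rev(ens$learners)
  expect_equal(predict(ens_rev, test_parcels)$predicted_age, bagged,
               tolerance = 1e-12)
})

test_that("the collapsed linear weight vector reproduces the kernel prediction", {
  d <- linear_age_data(60, 12, noise_sd = 2, seed = 52)
  l <- fit_weak_learner(d$x, d$age)
  newd <- linear_age_data(25, 12, noise_sd = 2, seed = 53)
  z <- scale(newd$x, l$center, l$scale)
  expect_equal(predict(l, newd$x),
               unname(predict(l$fit, z)), tolerance = 1e-10)
})

test_that("BrainAGE scores are the signed prediction gap", {
  expect_equal(brainage_scores(c(80, 70), c(74, 71)), c(6, -1))
  expect_equal(brainage_scores(c(60, 61), c(60, 61)), c(0, 0))
  set.seed(49)
  pred <- rnorm(100, 70, 5)
  chron <- rnorm(100, 70, 5)
  expect_equal(mean(brainage_scores(pred, chron)) + mean(chron), mean(pred),
               tolerance = 1e-12)
  expect_error(brainage_scores(1:3, 1:2), "length")
})

test_that("perfect predictions give zero MAE and degenerate CIs with a notice", {
  cohort <- random_cohort(30, seed = 50)
  preds <- tibble::tibble(subject_id = cohort$subject_id,
                          predicted_age = cohort$age)
  expect_message(
    res <- evaluate_groups(preds, cohort, n_perm = 0),
    "degenerate"
  )
  expect_true(all(res$groups$mae == 0))
  expect_true(all(res$groups$mean_brainage == 0))
  expect_true(all(res$groups$ci_low == res$groups$ci_high))
})

test_that("t-based group CIs agree with a bootstrap percentile CI", {
  set.seed(51)
  n <- 150
  cohort <- random_cohort(n, seed = 51)
  cohort$diagnosis <- "MCI"
  scores <- rnorm(n, 2, 4)
  preds <- tibble::tibble(subject_id = cohort$subject_id,
                          predicted_age = cohort$age + scores)
  res <- suppressWarnings(evaluate_groups(preds, cohort, n_perm = 0))
  g <- res$groups[res$groups$diagnosis == "MCI", ]
  boot <- replicate(10000, mean(sample(scores, n, TRUE)))
  boot_ci <- quantile(boot, c(0.025, 0.975))
  t_width <- g$ci_high - g$ci_low
  b_width <- diff(boot_ci)
  expect_lt(abs(t_width - b_width) / b_width, 0.1)
  expect_lt(abs(mean(c(g$ci_low, g$ci_high)) - mean(boot)), 0.2)
})

test_that("group summaries satisfy the prediction identity and flag the SDB null", {
  cfg <- tiny_config(n_study_per_cell = c(HC = 15, MCI = 15, AD = 15),
                     n_parcels = 30, seed = 77L)
  ref <- simulate_reference_cohort(tiny_config(n_reference = 400,
                                               n_parcels = 30, seed = 77L))
  st <- simulate_study_cohort(cfg)
  ens <- train_brainage(ref$parcels, ref$cohort,
                        stratification_config(n_replicates = 8, seed = 3))
  preds <- predict(ens, st$parcels)
  res <- suppressWarnings(evaluate_groups(preds, st$cohort, n_perm = 200,
                                          seed = 4))
  agg <- dplyr::summarise(
    dplyr::group_by(res$subjects, diagnosis),
    gap = abs(mean(predicted_age) - mean(age) - mean(brainage))
  )
  expect_true(all(agg$gap < 1e-10))
  expect_setequal(res$anova$term,
                  c("diagnosis", "sdb_status", "diagnosis:sdb_status"))
  expect_true(all(res$anova$p_value >= 1 / 201 & res$anova$p_value <= 1))
})
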