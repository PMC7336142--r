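# Fixture builders shared across the test files.  Everything is generated in
# code; sizes are desk-scale so the whole suite stays fast.

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(
    n_reference = 300,
    n_study_per_cell = c(HC = 10, MCI = 15, AD = 8),
    n_parcels = 12,
    n_sites_reference = 3,
    n_sites_study = 6,
    missing_rate = 0,
    seed = 11L
  )
  do.call(sim_config, utils::modifyList(defaults, args))
}

# subjects x parcels tibble of iid Gaussian values
random_parcels <- function(n, p, seed = 1, ids = sprintf("s%04d", seq_len(n))) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("p%04d", seq_len(p))))
  dplyr::bind_cols(tibble::tibble(subject_id = ids), tibble::as_tibble(m))
}

# a cohort with no structure: factors independent of everything
random_cohort <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    subject_id = sprintf("s%04d", seq_len(n)),
    age = runif(n, 55, 85),
    sex = sample(c("female", "male"), n, TRUE),
    diagnosis = sample(c("HC", "MCI", "AD"), n, TRUE),
    sdb_status = sample(c("negative", "positive"), n, TRUE),
    bmi = rnorm(n, 28, 5),
    education_years = round(runif(n, 8, 20)),
    apoe4_count = sample(0:2, n, TRUE),
    site = sample(c("s1", "s2", "s3"), n, TRUE),
    protocol = sample(c("MP-RAGE", "IR-SPGR"), n, TRUE),
    treatment_flag = FALSE
  )
}

# independent brute-force Type-II partial F via explicit least squares on
# column subsets (lm.fit), used as the sums-of-squares oracle
brute_force_partial_f <- function(y, data, formula) {
  mt <- stats::terms(formula)
  labels <- attr(mt, "term.labels")
  fac <- attr(mt, "factors")
  X <- stats::model.matrix(mt, stats::model.frame(mt, data))
  asgn <- attr(X, "assign")
  rss_of <- function(terms_keep) {
    keep <- asgn == 0 | labels[pmax(asgn, 1)] %in% terms_keep & asgn > 0
    fit <- stats::lm.fit(X[, keep, drop = FALSE], y)
    list(rss = sum(fit$residuals^2), rank = fit$rank)
  }
  complete <- rss_of(labels)
  df2 <- length(y) - complete$rank
  out <- lapply(labels, function(t) {
    vars_t <- rownames(fac)[fac[, t] > 0]
    containing <- labels[vapply(labels, function(j) {
      j != t && all(fac[vars_t, j] > 0)
    }, logical(1))]
    keep <- setdiff(labels, c(t, containing))
    w <- rss_of(c(keep, t))
    wo <- rss_of(keep)
    df1 <- w$rank - wo$rank
    data.frame(term = t, statistic = ((wo$rss - w$rss) / df1) /
                 (complete$rss / df2))
  })
  do.call(rbind, out)
}
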