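#' @title Parcel-wise permutation ANOVA with max-statistic FWE correction
#' @description
#' The inference engine fits, per parcel, one linear model with the study
#' factors (age as a continuous covariate, diagnosis, SDB status and their
#' interaction) and computes each factor's partial F statistic from Type-II
#' sums of squares.  Nonparametric p-values come from refitting under random
#' relabelings of the tested factor; family-wise error control across the
#' parcel set uses the permutation distribution of the set-wise maximum F.
#' @name parcelwise_inference
NULL

default_design_formula <- ~ age + diagnosis * sdb_status

# Term bookkeeping for Type-II tests: for each term t, the "with" model
# contains every term not containing t plus t itself; the "without" model
# drops t as well.  The error term always comes from the complete model.
term_plan <- function(mt) {
  labels <- attr(mt, "term.labels")
  fac <- attr(mt, "factors")
  plan <- lapply(labels, function(t) {
    vars_t <- rownames(fac)[fac[, t] > 0]
    containing <- labels[vapply(labels, function(j) {
      j != t && all(fac[vars_t, j] > 0)
    }, logical(1))]
    keep <- setdiff(labels, c(t, containing))
    list(term = t, vars = vars_t, with = c(keep, t), without = keep)
  })
  setNames(plan, labels)
}

# residual sum of squares of Y against the column subset of X given by terms
# in `keep` (intercept always included); returns rss vector and model rank
rss_fit <- function(X, asgn, keep_terms, term_index, Y, yss) {
  cols <- asgn == 0 | term_index[asgn + 1L] %in% keep_terms
  Xs <- X[, cols, drop = FALSE]
  q <- qr(Xs)
  r <- q$rank
  qty <- qr.qty(q, Y)[seq_len(r), , drop = FALSE]
  list(rss = yss - colSums(qty^2), rank = r)
}

# Partial F statistics for the requested terms on response matrix Y.
# Returns F as a terms x parcels matrix plus degrees of freedom.
partial_f_core <- function(Y, X, asgn, plan, terms_to_test = names(plan)) {
  n <- nrow(Y)
  yss <- colSums(Y^2)
  term_index <- c("(intercept)", names(plan))
  complete <- rss_fit(X, asgn, names(plan), term_index, Y, yss)
  df2 <- n - complete$rank
  if (df2 <= 0) abort("no residual degrees of freedom in the complete model.")
  mse <- complete$rss / df2

  out_f <- matrix(NA_real_, nrow = length(terms_to_test), ncol = ncol(Y),
                  dimnames = list(terms_to_test, colnames(Y)))
  df1 <- setNames(integer(length(terms_to_test)), terms_to_test)
  for (t in terms_to_test) {
    w <- rss_fit(X, asgn, plan[[t]]$with, term_index, Y, yss)
    wo <- rss_fit(X, asgn, plan[[t]]$without, term_index, Y, yss)
    d1 <- w$rank - wo$rank
    if (d1 <= 0) {
      abort(sprintf("term '%s' is aliased with the remaining design columns.", t))
    }
    df1[t] <- d1
    out_f[t, ] <- ((wo$rss - w$rss) / d1) / mse
  }
  list(F = out_f, df1 = df1, df2 = df2)
}

prepare_design <- function(parcels, cohort, formula) {
  assert_parcels(parcels)
  assert_cohort(cohort, need = "subject_id")
  if (!identical(parcels$subject_id, cohort$subject_id)) {
    abort("`parcels` and `cohort` must have identical subject_id order.")
  }
  vars <- all.vars(formula)
  missing_vars <- setdiff(vars, names(cohort))
  if (length(missing_vars) > 0) {
    abort(sprintf("formula variable(s) not in cohort: %s.",
                  paste(missing_vars, collapse = ", ")))
  }
  dat <- cohort[vars]
  dat[] <- lapply(dat, function(x) if (is.character(x)) factor(x) else x)
  for (v in vars) {
    if (is.factor(dat[[v]]) && nlevels(droplevels(dat[[v]])) < 2) {
      abort(sprintf("factor '%s' has fewer than 2 observed levels.", v))
    }
  }
  if (anyNA(dat)) abort("design variables contain missing values.")
  mt <- terms(formula)
  mf <- model.frame(mt, dat)
  X <- model.matrix(mt, mf)
  Y <- parcel_matrix(parcels)
  flagged <- apply(Y, 2, var) <= .Machine$double.eps * pmax(colMeans(Y^2), 1)
  list(Y = Y, X = X, asgn = attr(X, "assign"), mf = mf, mt = mt,
       plan = term_plan(mt), flagged = flagged)
}

#' Per-parcel, per-factor reference F statistics
#'
#' Fits the n-way model to every parcel and returns each factor's Type-II
#' partial F -- the reference statistics against which the permutation null
#' distributions are compared.
#'
#' @param parcels Wide parcel table (`subject_id` + one column per parcel),
#'   row-aligned with `cohort`.
#' @param cohort Cohort tibble.
#' @param formula RHS model formula over cohort columns; the default is
#'   `~ age + diagnosis * sdb_status`.
#' @return Tibble: `term`, `parcel_id`, `statistic` (partial F), `df1`,
#'   `df2`, `flagged` (TRUE for zero-variance parcels, whose F is NA).
#' @export
fit_reference_anova <- function(parcels, cohort,
                                formula = default_design_formula) {
  d <- prepare_design(parcels, cohort, formula)
  core <- partial_f_core(d$Y, d$X, d$asgn, d$plan)
  if (any(d$flagged)) {
    warn(sprintf("%d zero-variance parcel(s) flagged; their F is NA.",
                 sum(d$flagged)))
    core$F[, d$flagged] <- NA_real_
  }
  tidyr::pivot_longer(
    bind_cols(tibble(term = rownames(core$F)), as_tibble(core$F)),
    -"term", names_to = "parcel_id", values_to = "statistic"
  ) %>%
    mutate(
      df1 = unname(core$df1[.data$term]),
      df2 = core$df2,
      flagged = unname(d$flagged[.data$parcel_id])
    )
}

strata_permutation <- function(n, strata) {
  if (is.null(strata)) return(sample.int(n))
  idx <- seq_len(n)
  for (lev in unique(strata)) {
    rows <- which(strata == lev)
    idx[rows] <- rows[sample.int(length(rows))]
  }
  idx
}

#' Permutation null distribution for one factor
#'
#' Shuffles the tested factor's labels uniformly at random across subjects
#' (other design columns fixed), refits the model, and records the per-parcel
#' partial F and the set-wise maximum F per replication.  For the
#' SDB-by-diagnosis interaction the SDB labels are permuted within diagnosis
#' strata, preserving exchangeability under the interaction null.
#'
#' @inheritParams fit_reference_anova
#' @param term Term label to test (e.g. `"diagnosis"` or
#'   `"diagnosis:sdb_status"`).
#' @param n_perm Number of permutations (>= 100; a smaller null is too
#'   coarse to estimate tail probabilities).
#' @param seed Integer seed.
#' @param permute_var Variable whose labels are shuffled; defaults to the
#'   term itself (main effects) or the last variable of an interaction.
#' @param strata Optional cohort column name: permute within its levels.
#'   Defaults to the other interaction variable(s) for interaction terms.
#' @return List: `null_F` (n_perm x parcels matrix), `max_F` (length n_perm;
#'   set-wise maximum over non-flagged parcels), `term`, `n_perm`, `seed`.
#' @export
permutation_null <- function(parcels, cohort, term,
                             formula = default_design_formula,
                             n_perm = 1000, seed = 1,
                             permute_var = NULL, strata = NULL) {
  n_perm <- check_count(n_perm, "n_perm", min = 1)
  if (n_perm < 100) {
    abort("n_perm must be >= 100: fewer permutations give too coarse a null.")
  }
  d <- prepare_design(parcels, cohort, formula)
  if (!term %in% names(d$plan)) {
    abort(sprintf("term '%s' is not in the model (%s).", term,
                  paste(names(d$plan), collapse = ", ")))
  }
  vars_t <- d$plan[[term]]$vars
  if (is.null(permute_var)) permute_var <- vars_t[length(vars_t)]
  if (is.null(strata) && length(vars_t) > 1) {
    strata <- setdiff(vars_t, permute_var)
  }
  strata_values <- if (is.null(strata)) {
    NULL
  } else {
    interaction(cohort[strata], drop = TRUE)
  }

  n <- nrow(d$Y)
  set.seed(derive_seed(seed, 0))
  null_F <- matrix(NA_real_, nrow = n_perm, ncol = ncol(d$Y),
                   dimnames = list(NULL, colnames(d$Y)))
  mf <- d$mf
  base_col <- mf[[permute_var]]
  for (r in seq_len(n_perm)) {
    mf[[permute_var]] <- base_col[strata_permutation(n, strata_values)]
    Xp <- model.matrix(d$mt, mf)
    core <- partial_f_core(d$Y, Xp, attr(Xp, "assign"), d$plan,
                           terms_to_test = term)
    null_F[r, ] <- core$F[1, ]
  }
  if (any(d$flagged)) null_F[, d$flagged] <- NA_real_
  max_F <- apply(null_F[, !d$flagged, drop = FALSE], 1, max)
  list(null_F = null_F, max_F = max_F, term = term, n_perm = n_perm,
       seed = seed, flagged = d$flagged)
}

#' Family-wise error correction against the max-F null
#'
#' Converts reference F statistics into permutation p-values with the
#' add-one estimator: the uncorrected p compares each parcel's F to that
#' parcel's own null Fs, the FWE p compares it to the null distribution of
#' the set-wise maximum.  The FWE significance threshold is the empirical
#' 95th percentile (linear interpolation) of the max-F sample.
#'
#' @param reference Output of [fit_reference_anova()] (only rows of the
#'   null's term are used), or a named numeric vector of per-parcel F.
#' @param null Output of [permutation_null()] for the same design and term.
#' @param alpha Family-wise error level for the threshold.
#' @return A `parcelwise_term_result`: list with `table` (tibble: parcel_id,
#'   statistic, p_uncorrected, p_fwe, significant), `threshold`, `null_max`,
#'   `term`, `n_perm`.
#' @export
fwe_correct <- function(reference, null, alpha = 0.05) {
  if (is.data.frame(reference)) {
    ref <- reference[reference$term == null$term, ]
    f <- setNames(ref$statistic, ref$parcel_id)
  } else {
    f <- reference
  }
  pids <- colnames(null$null_F)
  if (!setequal(names(f), pids)) {
    abort("reference and null cover different parcel sets.")
  }
  f <- f[pids]
  n_perm <- null$n_perm
  p_unc <- vapply(seq_along(f), function(j) {
    (1 + sum(null$null_F[, j] >= f[j])) / (n_perm + 1)
  }, numeric(1))
  p_fwe <- (1 + vapply(f, function(x) sum(null$max_F >= x), numeric(1))) /
    (n_perm + 1)
  p_unc[is.na(f)] <- NA_real_
  p_fwe[is.na(f)] <- NA_real_
  threshold <- unname(quantile(null$max_F, 1 - alpha, type = 7))
  structure(
    list(
      table = tibble(
        parcel_id = pids,
        statistic = unname(f),
        p_uncorrected = unname(p_unc),
        p_fwe = unname(p_fwe),
        significant = !is.na(f) & f > threshold
      ),
      threshold = threshold,
      null_max = null$max_F,
      term = null$term,
      n_perm = n_perm,
      alpha = alpha
    ),
    class = "parcelwise_term_result"
  )
}

#' @export
print.parcelwise_term_result <- function(x, ...) {
  cat(sprintf("<parcelwise_term_result> term '%s': %d/%d parcels significant (F > %.3f, P_FWE < %.2f, %d permutations)\n",
              x$term, sum(x$table$significant), nrow(x$table), x$threshold,
              x$alpha, x$n_perm))
  invisible(x)
}

#' Run the full parcel-wise permutation analysis
#'
#' Orchestrates, for every factor of the design, the reference fit, the
#' label-permutation null and the max-statistic FWE correction.  Warns when
#' the cohort does not look 1:1 matched (unequal per-diagnosis counts across
#' SDB arms), since the procedure is intended to run on a matched cohort.
#'
#' @inheritParams fit_reference_anova
#' @param n_perm Permutations per factor.
#' @param seed Master seed; each factor uses a derived sub-seed.
#' @param alpha Family-wise error level.
#' @return A `parcelwise_analysis`: named list of per-term
#'   `parcelwise_term_result`s plus the reference table, formula, `n_perm`
#'   and `seed`.  Supports [tidy()], [glance()] and [autoplot()].
#' @export
run_parcelwise_analysis <- function(parcels, cohort,
                                    formula = default_design_formula,
                                    n_perm = 1000, seed = 1, alpha = 0.05) {
  if (all(c("diagnosis", "sdb_status") %in% names(cohort))) {
    tab <- table(cohort$diagnosis, cohort$sdb_status)
    if (ncol(tab) == 2 && any(tab[, 1] != tab[, 2])) {
      warn("cohort does not look 1:1 matched; results assume a matched design.")
    }
  }
  reference <- fit_reference_anova(parcels, cohort, formula)
  terms_all <- unique(reference$term)
  results <- lapply(seq_along(terms_all), function(i) {
    nl <- suppressWarnings(permutation_null(
      parcels, cohort, terms_all[i], formula,
      n_perm = n_perm, seed = derive_seed(seed, 1000L * i)
    ))
    fwe_correct(reference, nl, alpha = alpha)
  })
  names(results) <- terms_all
  structure(
    list(terms = results, reference = reference, formula = formula,
         n_perm = n_perm, seed = seed, alpha = alpha),
    class = "parcelwise_analysis"
  )
}

#' @export
print.parcelwise_analysis <- function(x, ...) {
  cat(sprintf("<parcelwise_analysis> %d parcels, %d permutations per factor\n",
              length(unique(x$reference$parcel_id)), x$n_perm))
  for (r in x$terms) {
    cat(sprintf("  %-24s F_crit = %7.3f  significant: %d\n",
                r$term, r$threshold, sum(r$table$significant)))
  }
  invisible(x)
}

#' @method tidy parcelwise_analysis
#' @export
tidy.parcelwise_analysis <- function(x, ...) {
  bind_rows(lapply(x$terms, function(r) {
    mutate(r$table, term = r$term, .before = 1)
  }))
}

#' @method glance parcelwise_analysis
#' @export
glance.parcelwise_analysis <- function(x, ...) {
  bind_rows(lapply(x$terms, function(r) {
    tibble(term = r$term, n_parcels = nrow(r$table),
           n_significant = sum(r$table$significant),
           fwe_threshold = r$threshold, n_perm = r$n_perm, alpha = r$alpha)
  }))
}
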