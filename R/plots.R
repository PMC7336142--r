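#' Plot methods
#'
#' `autoplot()` methods for the two main result types, plus a covariate
#' balance ("love") plot.  All return ggplot objects.
#'
#' @name brainparcel-plots
NULL

#' @param object A `parcelwise_analysis`.
#' @param ... Unused.
#' @describeIn brainparcel-plots Per-parcel F statistics by factor with the
#'   FWE threshold line; significant parcels highlighted.
#' @method autoplot parcelwise_analysis
#' @export
autoplot.parcelwise_analysis <- function(object, ...) {
  dat <- tidy(object) %>%
    mutate(index = as.integer(factor(.data$parcel_id,
                                     unique(.data$parcel_id))))
  thr <- glance(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$index, y = .data$statistic)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 0.8) +
    ggplot2::geom_hline(data = thr,
                        ggplot2::aes(yintercept = .data$fwe_threshold),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "parcel", y = "partial F",
                  colour = expression(P[FWE] < .05)) +
    ggplot2::theme_minimal()
}

#' @describeIn brainparcel-plots Predicted versus chronological age by
#'   diagnosis, with the identity line (the BrainAGE scatter view).
#' @method autoplot brainage_result
#' @export
autoplot.brainage_result <- function(object, ...) {
  ggplot2::ggplot(object$subjects,
                  ggplot2::aes(x = .data$age, y = .data$predicted_age,
                               colour = .data$diagnosis)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "chronological age (years)",
                  y = "bagged predicted age (years)",
                  colour = "diagnosis") +
    ggplot2::theme_minimal()
}

#' @param cohort Cohort tibble.
#' @param matched Optional [match_pairs()] result; if given, SMDs before and
#'   after matching are contrasted.
#' @param covariates Covariates to display.
#' @describeIn brainparcel-plots Absolute standardized mean differences per
#'   covariate, before and (optionally) after matching.
#' @export
plot_balance <- function(cohort, matched = NULL,
                         covariates = c("age", "sex", "bmi",
                                        "education_years", "apoe4_count",
                                        "diagnosis", "protocol")) {
  before <- balance_table(cohort, covariates = covariates) %>%
    mutate(stage = "before matching")
  dat <- if (is.null(matched)) {
    before
  } else {
    bind_rows(before,
              balance_table(cohort, matched, covariates = covariates) %>%
                mutate(stage = "after matching"))
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = abs(.data$smd),
                                    y = .data$covariate,
                                    colour = .data$stage)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = 0.1, linetype = "dotted") +
    ggplot2::labs(x = "|standardized mean difference|", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}
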