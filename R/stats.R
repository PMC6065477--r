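#' Pearson and partial correlation
#'
#' `pearson_corr()` is the product-moment correlation with input validation;
#' `partial_corr()` partials one covariate out of both variables (residuals
#' of each regressed on the control, then correlated).
#'
#' @param x,y Equal-length numeric vectors, length >= 3, no missing values.
#' @param control Numeric covariate to partial out.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_corr <- function(x, y) {
  check_corr_inputs(x, y)
  cor(x, y)
}

#' @rdname pearson_corr
#' @export
partial_corr <- function(x, y, control) {
  check_corr_inputs(x, y)
  if (length(control) != length(x) || anyNA(control)) {
    mm_stop("`control` must match `x` in length with no missing values",
            "mm_value_error")
  }
  rx <- resid(lm(x ~ control))
  ry <- resid(lm(y ~ control))
  if (sd(rx) == 0 || sd(ry) == 0) {
    mm_stop("zero residual variance after partialling", "mm_domain_error")
  }
  cor(rx, ry)
}

check_corr_inputs <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    mm_stop("`x` and `y` must have equal length >= 3", "mm_value_error")
  }
  if (anyNA(x) || anyNA(y)) {
    mm_stop("missing values are not allowed; subset first", "mm_value_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    mm_stop("zero variance input", "mm_domain_error")
  }
  invisible(TRUE)
}

#' Paired contrast with effect size
#'
#' Paired t statistic, mean difference and Cohen's d (mean difference over
#' the SD of the paired differences) for two matched samples, e.g. each
#' subject's rest- versus movie-scan motion rate.
#'
#' @param a,b Equal-length paired samples, n >= 2.
#' @return An object of class `paired_contrast`: `t`, `df`, `p_value`,
#'   `mean_diff`, `cohen_d`, `n`.
#' @export
paired_contrast <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L) {
    mm_stop("`a` and `b` must be equal-length with n >= 2", "mm_value_error")
  }
  if (anyNA(a) || anyNA(b)) {
    mm_stop("missing values are not allowed", "mm_value_error")
  }
  d <- a - b
  s <- sd(d)
  n <- length(d)
  if (s == 0) {
    if (all(d == 0)) {
      # identical samples: no difference at all, degenerate but well defined
      return(structure(
        list(t = 0, df = n - 1L, p_value = 1, mean_diff = 0, cohen_d = 0,
             n = n),
        class = "paired_contrast"
      ))
    }
    mm_stop("paired differences have zero variance", "mm_domain_error")
  }
  t_stat <- mean(d) / (s / sqrt(n))
  structure(
    list(t = t_stat, df = n - 1L,
         p_value = 2 * pt(-abs(t_stat), df = n - 1L),
         mean_diff = mean(d), cohen_d = mean(d) / s, n = n),
    class = "paired_contrast"
  )
}

#' @export
print.paired_contrast <- function(x, digits = 4, ...) {
  cat(sprintf(
    "<paired_contrast> t(%d) = %s, p = %s, mean diff = %s, Cohen's d = %s\n",
    x$df, format(x$t, digits = digits),
    format.pval(x$p_value, digits = digits),
    format(x$mean_diff, digits = digits),
    format(x$cohen_d, digits = digits)
  ))
  invisible(x)
}

#' Correlation block for a cohort table
#'
#' The descriptive statistics of the motion analysis: correlations of age
#' with rest- and movie-scan motion and between the scans, correlations of
#' BMI with age and with motion together with their age-partialled versions
#' (on the BMI-complete subset), and the paired rest-versus-movie contrast.
#'
#' @param cohort A cohort `data.frame` (see [read_cohort()]).
#' @return An object of class `cohort_correlations` (a list of named
#'   coefficients plus the [paired_contrast()]).
#' @export
cohort_correlations <- function(cohort) {
  need <- c("age_years", "motion_rest_mm_min", "motion_movie_mm_min")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    mm_stop(sprintf("cohort lacks column(s): %s",
                    paste(missing_cols, collapse = ", ")), "mm_schema_error")
  }
  age <- cohort$age_years
  rest <- cohort$motion_rest_mm_min
  movie <- cohort$motion_movie_mm_min
  out <- list(
    n = nrow(cohort),
    r_age_rest = pearson_corr(age, rest),
    r_age_movie = pearson_corr(age, movie),
    r_rest_movie = pearson_corr(rest, movie),
    contrast = paired_contrast(rest, movie)
  )
  if (!is.null(cohort$bmi_kg_m2) && sum(!is.na(cohort$bmi_kg_m2)) >= 3) {
    ok <- !is.na(cohort$bmi_kg_m2)
    bmi <- cohort$bmi_kg_m2[ok]
    out$n_bmi <- sum(ok)
    out$r_age_bmi <- pearson_corr(age[ok], bmi)
    out$r_bmi_rest <- pearson_corr(bmi, rest[ok])
    out$r_bmi_movie <- pearson_corr(bmi, movie[ok])
    out$rp_bmi_rest_age <- partial_corr(bmi, rest[ok], age[ok])
    out$rp_bmi_movie_age <- partial_corr(bmi, movie[ok], age[ok])
  }
  structure(out, class = "cohort_correlations")
}

#' @export
print.cohort_correlations <- function(x, digits = 3, ...) {
  cat(sprintf("<cohort_correlations> n = %d\n", x$n))
  cat(sprintf("  r(age, rest) = %.3f  r(age, movie) = %.3f  r(rest, movie) = %.3f\n",
              x$r_age_rest, x$r_age_movie, x$r_rest_movie))
  if (!is.null(x$r_age_bmi)) {
    cat(sprintf("  BMI subset n = %d: r(age, BMI) = %.3f\n", x$n_bmi, x$r_age_bmi))
    cat(sprintf("  r(BMI, rest) = %.3f (partial | age %.3f)  r(BMI, movie) = %.3f (partial | age %.3f)\n",
                x$r_bmi_rest, x$rp_bmi_rest_age,
                x$r_bmi_movie, x$rp_bmi_movie_age))
  }
  cat("  rest vs movie: ")
  print(x$contrast)
  invisible(x)
}
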