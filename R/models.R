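# Hierarchical regression comparison: eight nested-and-rival linear models of
# a morphology outcome on age, BMI, motion and AES, ranked by BIC.

outcome_column <- function(outcome) {
  switch(outcome,
         thickness = "thickness_mm",
         fd = "fd_cortical",
         gyrification = "gyrification",
         mm_stop(sprintf("unknown outcome '%s'", outcome), "mm_value_error"))
}

term_column <- function(term) {
  switch(term,
         age = "age_years",
         bmi = "bmi_kg_m2",
         motion_rest = "motion_rest_mm_min",
         motion_movie = "motion_movie_mm_min",
         aes_axial = "aes_axial",
         mm_stop(sprintf("unknown model term '%s'", term), "mm_value_error"))
}

#' The eight-model comparison set
#'
#' Returns the fixed specification of the hierarchical comparison: age
#' first, BMI with and without age, then each motion estimate added to age,
#' with age to interaction terms for the movie-motion and axial-AES models.
#'
#' @return A list of 8 entries, each with `model_id`, `label` and `terms`.
#' @export
model_specs <- function() {
  list(
    list(model_id = 1L, label = "Age", terms = "age"),
    list(model_id = 2L, label = "BMI", terms = "bmi"),
    list(model_id = 3L, label = "Age + BMI", terms = c("age", "bmi")),
    list(model_id = 4L, label = "Age + Movement(Rest)",
         terms = c("age", "motion_rest")),
    list(model_id = 5L, label = "Age + Movement(Movie)",
         terms = c("age", "motion_movie")),
    list(model_id = 6L,
         label = "Age + Movement(Movie) + Age x Movement(Movie)",
         terms = c("age", "motion_movie", "age:motion_movie")),
    list(model_id = 7L, label = "Age + AES(axial)",
         terms = c("age", "aes_axial")),
    list(model_id = 8L, label = "Age + AES(axial) + Age x AES(axial)",
         terms = c("age", "aes_axial", "age:aes_axial"))
  )
}

#' Fit one linear model of a morphology outcome
#'
#' Ordinary least squares of `outcome` on the requested terms plus an
#' intercept. Interaction terms (written `"a:b"`) are products of the
#' mean-centered main effects, centered within the fitting rows, which keeps
#' them nearly orthogonal to the mains. Rows with missing values in any used
#' column are dropped.
#'
#' @param cohort A cohort `data.frame`.
#' @param outcome `"thickness"`, `"fd"` or `"gyrification"`.
#' @param terms Character vector of terms from `age`, `bmi`, `motion_rest`,
#'   `motion_movie`, `aes_axial` and the interactions `age:motion_movie`,
#'   `age:aes_axial`.
#' @param model_id Optional integer id recorded with the fit.
#' @return An object of class `morph_fit`: `coefficients` (with intercept),
#'   `r2`, `rss`, `n`, `p` (number of mean-model parameters), `bic`
#'   (see [bic_ls()]), plus `outcome`, `terms`, `model_id` and the row index
#'   used.
#' @export
fit_linear <- function(cohort, outcome, terms, model_id = NA_integer_) {
  ycol <- outcome_column(outcome)
  if (!ycol %in% names(cohort)) {
    mm_stop(sprintf("cohort lacks outcome column '%s'", ycol),
            "mm_schema_error")
  }
  main_terms <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  cols <- vapply(main_terms, term_column, character(1))
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols)) {
    mm_stop(sprintf("cohort lacks column(s): %s",
                    paste(missing_cols, collapse = ", ")), "mm_schema_error")
  }
  rows <- which(complete.cases(cohort[, c(ycol, cols), drop = FALSE]))
  dat <- cohort[rows, , drop = FALSE]
  X <- matrix(1, nrow(dat), 1, dimnames = list(NULL, "(Intercept)"))
  centered <- lapply(setNames(main_terms, main_terms), function(tm) {
    v <- dat[[term_column(tm)]]
    v - mean(v)
  })
  for (tm in terms) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    col <- if (length(parts) == 1L) {
      dat[[term_column(tm)]]
    } else {
      Reduce(`*`, centered[parts])
    }
    X <- cbind(X, setNames(data.frame(col), tm))
  }
  X <- as.matrix(X)
  y <- dat[[ycol]]
  p <- ncol(X)
  if (length(y) <= p) {
    mm_stop("need more rows than parameters", "mm_value_error")
  }
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    mm_stop(sprintf("design is rank deficient; collinear column(s): %s",
                    paste(bad, collapse = ", ")), "mm_rank_error")
  }
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  n <- length(y)
  structure(
    list(model_id = model_id, outcome = outcome, terms = terms,
         coefficients = beta, r2 = 1 - rss / tss, rss = rss,
         n = n, p = p, bic = bic_ls(n, rss, p), rows = rows),
    class = "morph_fit"
  )
}

#' @export
print.morph_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<morph_fit> %s ~ %s\n", x$outcome,
              paste(x$terms, collapse = " + ")))
  cat(sprintf("  n = %d, p = %d, R^2 = %s, BIC = %s\n", x$n, x$p,
              format(x$r2, digits = digits), format(x$bic, digits = digits)))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' Least-squares BIC
#'
#' `BIC = n * ln(RSS / n) + p * ln(n)` with `p` counting the intercept and
#' slope terms. The error-variance parameter is constant across compared
#' models and therefore omitted; any such shared constant cancels in
#' delta-BIC, which is the quantity used for model ranking. Two models with
#' identical RSS but one extra parameter differ by exactly `ln(n)`.
#'
#' @param n Number of rows (or a `morph_fit`, in which case `rss` and `p`
#'   are taken from it).
#' @param rss Residual sum of squares.
#' @param p Number of mean-model parameters including the intercept.
#' @return BIC value.
#' @export
bic_ls <- function(n, rss = NULL, p = NULL) {
  if (inherits(n, "morph_fit")) {
    fit <- n
    return(bic_ls(fit$n, fit$rss, fit$p))
  }
  if (rss <= 0) mm_stop("`rss` must be positive", "mm_domain_error")
  n * log(rss / n) + p * log(n)
}

#' Rank a set of model fits by BIC
#'
#' Attaches `delta_bic` (BIC minus the set minimum; 0 for the best model)
#' and an `equivalent` flag (`delta_bic < 2`, the conventional equivalence
#' band) to each fit. BIC values are only comparable between models fit to
#' the same rows, so the fits must share outcome and n.
#'
#' @param fits List of `morph_fit` objects on identical rows.
#' @return The list with `delta_bic` and `equivalent` added, classed
#'   `morph_model_set`.
#' @export
compare_models <- function(fits) {
  if (!length(fits) || !all(vapply(fits, inherits, logical(1), "morph_fit"))) {
    mm_stop("`fits` must be a list of morph_fit objects", "mm_type_error")
  }
  ns <- vapply(fits, `[[`, numeric(1), "n")
  outs <- vapply(fits, `[[`, character(1), "outcome")
  rows_same <- all(vapply(fits, function(f) identical(f$rows, fits[[1]]$rows),
                          logical(1)))
  if (length(unique(ns)) != 1L || length(unique(outs)) != 1L || !rows_same) {
    mm_stop("BIC is only comparable across fits on the same outcome rows",
            "mm_value_error")
  }
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  for (i in seq_along(fits)) {
    fits[[i]]$delta_bic <- bics[i] - min(bics)
    fits[[i]]$equivalent <- fits[[i]]$delta_bic < 2
  }
  structure(fits, class = "morph_model_set")
}

#' Eight-model comparison table for one outcome
#'
#' Fits the eight models of [model_specs()] to a cohort and ranks them by
#' delta-BIC. The two BMI models can only be fit to the BMI-complete subset;
#' because BIC is not comparable across differing row sets, delta-BIC is
#' computed within the full-row model set (models 1, 4--8) and separately
#' within the BMI-subset set (models 2--3), which the table flags. With
#' `combine_subsets = TRUE` a single delta-BIC column is computed across all
#' eight models regardless (with a warning when the row sets differ), which
#' reproduces the conventional all-in-one table layout.
#'
#' @param cohort A cohort `data.frame` with the required columns.
#' @param outcome `"thickness"`, `"fd"` or `"gyrification"`.
#' @param combine_subsets Compute one delta-BIC set across all eight models.
#' @return An object of class `morph_model_table`: a `data.frame` with one
#'   row per model (`model_id`, `predictors`, `n`, `r2`, `bic`, `delta_bic`,
#'   `equivalent`, `subset`), with the fits in `attr(, "fits")`.
#' @export
#' @examples
#' co <- simulate_cohort(n = 200, seed = 1)
#' model_table(co, "thickness")
model_table <- function(cohort, outcome = c("thickness", "fd", "gyrification"),
                        combine_subsets = FALSE) {
  outcome <- match.arg(outcome)
  specs <- model_specs()
  uses_bmi <- vapply(specs, function(s) "bmi" %in% s$terms, logical(1))
  if ("bmi_kg_m2" %in% names(cohort) &&
      sum(!is.na(cohort$bmi_kg_m2)) < 10) {
    mm_stop("fewer than 10 BMI-complete records", "mm_value_error")
  }
  fits <- lapply(specs, function(s) {
    fit_linear(cohort, outcome, s$terms, model_id = s$model_id)
  })
  same_rows <- all(vapply(fits, function(f) identical(f$rows, fits[[1]]$rows),
                          logical(1)))
  if (combine_subsets || same_rows) {
    if (combine_subsets && !same_rows) {
      warning("delta-BIC compared across models fit on different subsets; ",
              "BIC values are not strictly comparable across differing n")
    }
    bics <- vapply(fits, `[[`, numeric(1), "bic")
    for (i in seq_along(fits)) {
      fits[[i]]$delta_bic <- bics[i] - min(bics)
      fits[[i]]$equivalent <- fits[[i]]$delta_bic < 2
    }
  } else {
    full <- compare_models(fits[!uses_bmi])
    sub <- compare_models(fits[uses_bmi])
    fits[!uses_bmi] <- full
    fits[uses_bmi] <- sub
  }
  tab <- data.frame(
    model_id = vapply(specs, `[[`, integer(1), "model_id"),
    predictors = vapply(specs, `[[`, character(1), "label"),
    n = vapply(fits, `[[`, numeric(1), "n"),
    r2 = vapply(fits, `[[`, numeric(1), "r2"),
    bic = vapply(fits, `[[`, numeric(1), "bic"),
    delta_bic = vapply(fits, `[[`, numeric(1), "delta_bic"),
    equivalent = vapply(fits, `[[`, logical(1), "equivalent"),
    subset = uses_bmi & !same_rows,
    stringsAsFactors = FALSE
  )
  structure(tab, fits = fits, outcome = outcome,
            combine_subsets = combine_subsets,
            class = c("morph_model_table", "data.frame"))
}

#' @export
print.morph_model_table <- function(x, digits = 3, ...) {
  cat(sprintf("Eight-model comparison, outcome: %s\n", attr(x, "outcome")))
  df <- as.data.frame(x)
  df$r2 <- round(df$r2, digits)
  df$bic <- round(df$bic, 2)
  df$delta_bic <- round(df$delta_bic, 2)
  print(df, row.names = FALSE)
  if (any(x$subset)) {
    cat("Note: BMI models are fit on the BMI-complete subset;\n",
        "their delta-BIC is ranked within that subset only.\n", sep = "")
  }
  invisible(x)
}
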