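test_that("correlations validate inputs and match known structure", {
  x <- rnorm(50)
  expect_equal(pearson_corr(x, x), 1, tolerance = 1e-12)
  expect_error(pearson_corr(rep(1, 10), rnorm(10)), class = "mm_domain_error")
  expect_error(pearson_corr(1:2, 1:2), class = "mm_value_error")

  # independence: r shrinks toward 0 at large n
  set.seed(61)
  expect_lt(abs(pearson_corr(rnorm(5000), rnorm(5000))), 0.05)

  # partialling out a common cause removes the induced correlation
  set.seed(62)
  z <- rnorm(2000)
  a <- 0.8 * z + 0.6 * rnorm(2000)
  b <- 0.7 * z + 0.7 * rnorm(2000)
  expect_gt(pearson_corr(a, b), 0.3)
  expect_lt(abs(partial_corr(a, b, z)), 0.08)
})

test_that("paired contrast matches t.test and the effect-size construction", {
  set.seed(63)
  a <- rnorm(40, 1)
  b <- rnorm(40)
  pc <- paired_contrast(a, b)
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(pc$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(pc$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(pc$mean_diff, unname(tt$estimate), tolerance = 1e-12)
  expect_equal(pc$cohen_d, mean(a - b) / sd(a - b), tolerance = 1e-12)

  same <- paired_contrast(a, a)
  expect_identical(same$mean_diff, 0)
  expect_identical(same$cohen_d, 0)
  expect_error(paired_contrast(rep(5, 10), rep(3, 10)),
               class = "mm_domain_error")

  # differences drawn N(1.528, 1.55): d = 1.528 / 1.55 = 0.986 by design
  set.seed(64)
  ds <- replicate(20, {
    d <- rnorm(640, 1.528, 1.55)
    paired_contrast(d, rep(0, 640))$cohen_d
  })
  expect_equal(mean(ds), 1.528 / 1.55, tolerance = 0.03)
})

test_that("linear fits recover exact and noisy structure", {
  set.seed(65)
  co <- simulate_cohort(n = 300, seed = 65)
  co$thickness_mm <- 3 - 0.004 * co$age_years -
    0.01 * co$motion_movie_mm_min
  fit <- fit_linear(co, "thickness", c("age", "motion_movie"))
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(unname(fit$coefficients["age"]), -0.004, tolerance = 1e-9)
  expect_equal(unname(fit$coefficients["motion_movie"]), -0.01,
               tolerance = 1e-9)

  # pure-noise outcome: R^2 near 0 at large n
  big <- simulate_cohort(n = 10000, seed = 66)
  big$thickness_mm <- rnorm(10000)
  expect_lt(fit_linear(big, "thickness", "age")$r2, 0.01)

  # duplicated predictor makes the design rank deficient
  co$aes_axial <- co$age_years
  expect_error(fit_linear(co, "thickness", c("age", "aes_axial")),
               "collinear", class = "mm_rank_error")
})

test_that("least-squares BIC has its closed-form behaviour", {
  # one extra parameter at identical RSS costs exactly ln(n)
  expect_equal(bic_ls(100, 12.5, 3) - bic_ls(100, 12.5, 2), log(100),
               tolerance = 1e-12)
  expect_error(bic_ls(100, 0, 2), class = "mm_domain_error")

  # delta-BIC agrees with the stats::BIC ranking on identical lm fits
  set.seed(67)
  co <- simulate_cohort(n = 400, seed = 67)
  f1 <- fit_linear(co, "thickness", "age")
  f5 <- fit_linear(co, "thickness", c("age", "motion_movie"))
  l1 <- lm(thickness_mm ~ age_years, co)
  l5 <- lm(thickness_mm ~ age_years + motion_movie_mm_min, co)
  expect_equal(f5$bic - f1$bic, BIC(l5) - BIC(l1), tolerance = 1e-8)
})

test_that("model comparison ranks fits and enforces common rows", {
  co <- simulate_cohort(n = 300, seed = 68,
                        params = sim_params(bmi_missing_frac = 0))
  fits <- lapply(model_specs()[c(1, 4, 5, 6)], function(s) {
    fit_linear(co, "thickness", s$terms, s$model_id)
  })
  ranked <- compare_models(fits)
  deltas <- vapply(ranked, `[[`, numeric(1), "delta_bic")
  expect_true(all(deltas >= 0))
  expect_identical(sum(deltas == 0), 1L)

  co_miss <- simulate_cohort(n = 300, seed = 68)
  f_all <- fit_linear(co_miss, "thickness", "age")
  f_sub <- fit_linear(co_miss, "thickness", "bmi")
  expect_error(compare_models(list(f_all, f_sub)), class = "mm_value_error")
})

test_that("the eight-model table respects subsets and nesting", {
  co <- simulate_cohort(n = 640, seed = 69)
  tab <- model_table(co, "thickness")
  expect_identical(nrow(tab), 8L)
  expect_equal(tab$n[tab$model_id %in% c(2, 3)],
               rep(sum(!is.na(co$bmi_kg_m2)), 2))
  expect_equal(tab$n[!tab$model_id %in% c(2, 3)], rep(640, 6))
  expect_true(all(tab$subset == (tab$model_id %in% c(2, 3))))
  # one best model per comparison set
  expect_identical(sum(tab$delta_bic[!tab$subset] == 0), 1L)
  expect_identical(sum(tab$delta_bic[tab$subset] == 0), 1L)
  # R^2 non-decreasing along nested chains on identical rows
  r2 <- setNames(tab$r2, tab$model_id)
  expect_gte(r2["4"], r2["1"])
  expect_gte(r2["5"], r2["1"])
  expect_gte(r2["6"], r2["5"])
  expect_gte(r2["8"], r2["7"])

  # all-BMI-present cohort: a single comparison set across all eight
  co_full <- simulate_cohort(n = 640, seed = 69,
                             params = sim_params(bmi_missing_frac = 0))
  tab_full <- model_table(co_full, "thickness")
  expect_false(any(tab_full$subset))
  expect_identical(sum(tab_full$delta_bic == 0), 1L)

  expect_warning(model_table(co, "thickness", combine_subsets = TRUE),
                 "not strictly comparable")
})

test_that("a noise-free motion effect makes the generating model win", {
  p <- sim_params(sd_thickness = 1e-6, bmi_missing_frac = 0)
  co <- simulate_cohort(n = 640, seed = 70, params = p)
  tab <- model_table(co, "thickness")
  r2_15 <- tab$r2[tab$model_id %in% 1:5]
  expect_identical(which.max(r2_15), 5L)
  expect_identical(tab$model_id[tab$delta_bic == 0], 5L)
})

test_that("cohort correlation block reproduces the generator's structure", {
  co <- simulate_cohort(n = 3000, seed = 71)
  cc <- cohort_correlations(co)
  expect_gt(cc$r_age_rest, 0.2)
  expect_gt(cc$r_age_movie, cc$r_age_rest - 0.15)
  expect_lt(abs(cc$r_rest_movie - 0.45), 0.08)
  expect_lt(abs(cc$contrast$mean_diff - 1.528), 0.2)
  expect_gt(cc$rp_bmi_rest_age, 0.2)
  expect_identical(cc$n_bmi, sum(!is.na(co$bmi_kg_m2)))
})
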