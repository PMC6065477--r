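test_that("geometric phantoms have the expected occupancy", {
  expect_identical(sum(make_cube(16)$data), 4096)
  for (r in c(10, 14)) {
    count <- sum(make_sphere(r)$data)
    expect_lt(abs(count - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3), 0.02)
  }
  sphere <- make_sphere(10)
  shell <- make_shell(10, 1)
  expect_true(all(sphere$data[shell$data == 1] == 1)) # shell within ball
  expect_lt(sum(shell$data), sum(sphere$data))
  expect_error(make_sphere(-1), class = "mm_value_error")
  expect_error(make_shell(5, 6), class = "mm_value_error")
})

test_that("Menger sponge construction is exactly self-similar", {
  for (L in 0:3) {
    expect_identical(sum(make_menger(L)$data), 20^L)
  }
  expect_identical(dim(make_menger(0)$data), c(1L, 1L, 1L))
  m3 <- make_menger(3)
  counts <- vapply(c(1, 3, 9, 27), function(s) {
    as.numeric(grid_box_count(m3, s))
  }, numeric(1))
  expect_identical(counts, c(8000, 400, 20, 1))
  expect_error(make_menger(-1), class = "mm_value_error")
  expect_error(make_menger(5), class = "mm_value_error")
})

test_that("trace simulation is deterministic and respects its contracts", {
  a <- simulate_trace(seed = 9, spike_times_s = c(280, 360))
  b <- simulate_trace(seed = 9, spike_times_s = c(280, 360))
  expect_identical(a$params, b$params)

  still <- simulate_trace(base_scale_mm = 0, seed = 1)
  expect_true(all(still$params == 0))
  expect_identical(mean_motion_rate(still)$mean_rate_mm_per_min, 0)

  expect_error(simulate_trace(spike_times_s = 600, seed = 1),
               class = "mm_value_error")
  expect_error(simulate_trace(duration_s = 5, seed = 1),
               class = "mm_value_error")
})

test_that("trace base scale controls the group mean rate proportionally", {
  rate_at <- function(scale, n = 30) {
    mean(vapply(seq_len(n), function(i) {
      mean_motion_rate(simulate_trace(base_scale_mm = scale,
                                      seed = 1000 + i))$mean_rate_mm_per_min
    }, numeric(1)))
  }
  young <- rate_at(0.017)
  old <- rate_at(0.034)
  expect_equal(old / young, 2, tolerance = 0.15)
})

test_that("cohort generator is reproducible and respects ranges", {
  a <- simulate_cohort(n = 100, seed = 4)
  b <- simulate_cohort(n = 100, seed = 4)
  expect_identical(a, b)
  expect_true(all(a$age_years >= 18 & a$age_years <= 88))
  expect_true(all(a$motion_rest_mm_min > 0 & a$motion_movie_mm_min > 0))
  expect_equal(sum(is.na(a$bmi_kg_m2)), round(81 / 640 * 100))
  expect_identical(nrow(a), 100L)
})

test_that("noise-free cohorts recover the generating slopes exactly", {
  p <- sim_params(sd_thickness = 1e-9, sd_fd = 1e-9, sd_gi = 1e-9,
                  bmi_missing_frac = 0)
  co <- simulate_cohort(n = 200, seed = 8, params = p)
  fit <- fit_linear(co, "thickness", c("age", "motion_movie"))
  expect_equal(unname(fit$coefficients["age"]), -0.00432, tolerance = 1e-7)
  expect_equal(unname(fit$coefficients["motion_movie"]), -0.0135,
               tolerance = 1e-7)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
})

test_that("cohort correlations land near their targets at large n", {
  co <- simulate_cohort(n = 5000, seed = 12)
  # log-scale targets; raw-scale correlations are mildly attenuated
  expect_lt(abs(cor(log(co$motion_rest_mm_min),
                    log(co$motion_movie_mm_min)) - 0.484), 0.05)
  expect_lt(abs(cor(co$age_years, log(co$motion_movie_mm_min)) - 0.43), 0.05)
  ok <- !is.na(co$bmi_kg_m2)
  expect_lt(abs(cor(co$age_years[ok], co$bmi_kg_m2[ok]) - 0.274), 0.05)
  expect_lt(abs(mean(co$motion_rest_mm_min) -
                  mean(co$motion_movie_mm_min) - 1.528), 0.15)
})

test_that("impossible correlation structures are rejected", {
  expect_error(sim_params(load_age_rest = 0.9, load_bmi_rest = 0.5),
               class = "mm_value_error")
  # inter-scan correlation below the product of shared loadings
  expect_error(sim_params(r_rest_movie = 0), class = "mm_value_error")
  expect_error(sim_params(sd_thickness = 0), class = "mm_value_error")
  expect_error(sim_params(n_subjects = 5), class = "mm_value_error")
})
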