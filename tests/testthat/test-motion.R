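test_that("angular displacement conversion matches closed forms", {
  expect_identical(angular_to_mm(0, "radians"), 0)
  expect_identical(angular_to_mm(0, "degrees"), 0)
  expect_equal(angular_to_mm(pi / 2, "radians"), 25 * pi, tolerance = 1e-12)
  expect_equal(angular_to_mm(1, "degrees"), 50 * pi / 180, tolerance = 1e-12)
  expect_equal(angular_to_mm(-1, "degrees"), -50 * pi / 180,
               tolerance = 1e-12) # sign preserved
  expect_error(angular_to_mm(Inf, "radians"), class = "mm_value_error")
})

test_that("framewise displacement matches simple cases and the oracle", {
  expect_identical(framewise_displacement(flat_trace(8)), rep(0, 7))

  p <- matrix(0, 10, 6)
  p[7:10, 2] <- 1 # 1 mm step between frames 6 and 7
  fd <- framewise_displacement(
    realignment_trace(p, "radians", tr_seconds = 2))
  expect_equal(fd, c(rep(0, 5), 1, rep(0, 3)))

  set.seed(17)
  for (i in 1:10) {
    m <- matrix(rnorm(60), 10, 6)
    unit <- sample(c("radians", "degrees"), 1)
    tr <- realignment_trace(m, unit, tr_seconds = 2)
    expect_equal(framewise_displacement(tr), fd_oracle(m, unit),
                 tolerance = 1e-12)
  }
})

test_that("framewise displacement depends only on differences", {
  set.seed(23)
  m <- matrix(rnorm(60, sd = 0.1), 10, 6)
  tr <- realignment_trace(m, "radians", tr_seconds = 2)
  shifted <- realignment_trace(sweep(m, 2, rnorm(6), "+"), "radians",
                               tr_seconds = 2)
  expect_equal(framewise_displacement(tr), framewise_displacement(shifted),
               tolerance = 1e-9)
  # symmetric under time reversal
  reversed <- realignment_trace(m[10:1, ], "radians", tr_seconds = 2)
  expect_equal(framewise_displacement(tr),
               rev(framewise_displacement(reversed)), tolerance = 1e-12)
})

test_that("mean motion rate applies the drop rule and TR normalization", {
  expect_identical(mean_motion_rate(flat_trace(20))$mean_rate_mm_per_min, 0)

  # uniform 0.05 mm per transition at TR 2 s -> 0.05 / 2 * 60 = 1.5 mm/min
  p <- matrix(0, 30, 6)
  p[, 1] <- seq(0, by = 0.05, length.out = 30)
  rate <- mean_motion_rate(realignment_trace(p, "radians", tr_seconds = 2))
  expect_equal(rate$mean_rate_mm_per_min, 1.5, tolerance = 1e-12)

  # motion confined to the first five frames is fully removed by drop 5,
  # including the transition crossing the drop boundary
  p2 <- matrix(0, 20, 6)
  p2[1:5, ] <- matrix(rnorm(30, sd = 5), 5, 6)
  ms <- mean_motion_rate(realignment_trace(p2, "radians", tr_seconds = 2),
                         drop_initial = 5)
  expect_identical(ms$mean_rate_mm_per_min, 0)
  expect_identical(ms$fd_series, rep(0, 14))

  expect_error(mean_motion_rate(flat_trace(6), drop_initial = 5),
               class = "mm_value_error")
})

test_that("motion rate scales linearly with the trace amplitude", {
  set.seed(41)
  m <- matrix(rnorm(120, sd = 0.05), 20, 6)
  m <- sweep(m, 2, colMeans(m)) # zero-mean
  r1 <- mean_motion_rate(realignment_trace(m, "radians", 2))
  r3 <- mean_motion_rate(realignment_trace(3 * m, "radians", 2))
  expect_equal(r3$mean_rate_mm_per_min, 3 * r1$mean_rate_mm_per_min,
               tolerance = 1e-9)
})

test_that("group time-courses average correctly with sane bands", {
  set.seed(53)
  m <- matrix(rnorm(120, sd = 0.1), 20, 6)
  tr <- realignment_trace(m, "radians", tr_seconds = 2)
  same <- group_timecourse(list(tr, tr, tr))
  expect_equal(same$group_mean, framewise_displacement(
    realignment_trace(m[6:20, ], "radians", 2)), tolerance = 1e-12)
  expect_equal(same$ci_low, same$group_mean, tolerance = 1e-12)
  expect_equal(same$time_s, (5 + seq_along(same$group_mean)) * 2)

  m2 <- matrix(rnorm(120, sd = 0.1), 20, 6)
  tr2 <- realignment_trace(m2, "radians", tr_seconds = 2)
  two <- group_timecourse(list(tr, tr2))
  fd1 <- mean_motion_rate(tr)$fd_series
  fd2 <- mean_motion_rate(tr2)$fd_series
  expect_equal(two$group_mean, (fd1 + fd2) / 2, tolerance = 1e-12)
  expect_true(all(two$ci_low <= two$group_mean + 1e-12))
  expect_true(all(two$group_mean <= two$ci_high + 1e-12))

  tr_short <- realignment_trace(m[1:15, ], "radians", tr_seconds = 2)
  expect_error(group_timecourse(list(tr, tr_short)),
               class = "mm_value_error")
  tr_othertr <- realignment_trace(m, "radians", tr_seconds = 1)
  expect_error(group_timecourse(list(tr, tr_othertr)),
               class = "mm_value_error")
})
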