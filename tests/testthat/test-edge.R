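test_that("intensity normalization is scale invariant and clips at 1", {
  set.seed(21)
  v <- voxel_volume(array(runif(10^3, 0, 5), c(10, 10, 10)))
  n1 <- normalize_intensity(v)
  n2 <- normalize_intensity(voxel_volume(v$data * 10))
  expect_equal(n1$data, n2$data, tolerance = 1e-12)
  expect_equal(max(n1$data), 1)
  expect_true(all(n1$data >= 0 & n1$data <= 1))
  expect_error(normalize_intensity(voxel_volume(array(0, c(3, 3, 3)))),
               class = "mm_domain_error")
})

test_that("slice edge strength matches the unit-step closed form", {
  expect_identical(slice_edge_strength(matrix(0.5, 8, 8)), c(0, 0))
  # central difference across a 0 -> 1 step is (1 - 0) / 2 = 0.5
  res <- slice_edge_strength(step_slice())
  expect_equal(res[1], 0.5, tolerance = 1e-12)
  expect_gt(res[2], 0)
  # pre-blurring the step strictly lowers edge contrast
  blurred <- apply_blur(
    voxel_volume(array(rep(step_slice(), 3), c(16, 16, 3))), 2)
  res_blur <- slice_edge_strength(blurred$data[, , 2])
  expect_lt(res_blur[1], res[1])
  expect_error(slice_edge_strength(matrix(1, 2, 5)), class = "mm_dim_error")
})

test_that("plane averages reduce to the slice value for identical slices", {
  vol <- voxel_volume(array(rep(step_slice(), 6), c(16, 16, 6)))
  single <- slice_edge_strength(step_slice())[1]
  expect_equal(average_edge_strength(vol, "axial"), single,
               tolerance = 1e-12)
  expect_equal(average_edge_strength(vol, "axial",
                                     slice_weighting = "uniform"),
               single, tolerance = 1e-12)
  expect_identical(average_edge_strength(
    voxel_volume(array(1, c(8, 8, 8))), "axial"), 0)
  expect_error(average_edge_strength(vol, "oblique"),
               class = "mm_value_error")
})

test_that("plane selection follows the axis labels", {
  vol <- voxel_volume(array(rep(step_slice(), 6), c(16, 16, 6)),
                      axis_labels = c("coronal", "axial", "sagittal"))
  # slices of the sagittal plane are indexed by the third array axis here
  expect_equal(average_edge_strength(vol, "sagittal"),
               slice_edge_strength(step_slice())[1], tolerance = 1e-12)
  res <- edge_strength(vol, normalize = FALSE)
  expect_equal(res$aes_sagittal, slice_edge_strength(step_slice())[1],
               tolerance = 1e-12)
  expect_identical(unname(res$slices_used["sagittal"]), 6L)
})

test_that("AES is invariant to global intensity scaling", {
  sh <- make_shell(10, 2)
  blurred <- apply_blur(sh, 1)
  scaled <- voxel_volume(blurred$data * 37.5)
  for (plane in c("axial", "coronal", "sagittal")) {
    expect_equal(
      average_edge_strength(normalize_intensity(blurred), plane),
      average_edge_strength(normalize_intensity(scaled), plane),
      tolerance = 1e-12)
  }
})

test_that("blurring strictly lowers AES on a shell phantom", {
  sh <- make_shell(10, 2)
  aes <- vapply(c(0, 1, 2), function(s) {
    average_edge_strength(normalize_intensity(apply_blur(sh, s)), "axial")
  }, numeric(1))
  expect_true(all(diff(aes) < 0))
  expect_true(all(aes > 0))
})

test_that("Gaussian blur conserves mass and sigma 0 is the identity", {
  set.seed(31)
  v <- voxel_volume(array(runif(8^3), c(8, 8, 8)))
  expect_identical(apply_blur(v, 0)$data, v$data)
  spike <- array(0, c(11, 11, 11))
  spike[6, 6, 6] <- 3
  for (s in c(0.8, 1, 2)) {
    out <- apply_blur(voxel_volume(spike), s)
    expect_equal(sum(out$data), 3, tolerance = 1e-6)
  }
  expect_error(apply_blur(v, -1), class = "mm_value_error")
})

test_that("AES of pure noise is finite and seed-reproducible", {
  make_noise <- function() {
    voxel_volume(array(runif(12^3), c(12, 12, 12)))
  }
  set.seed(123)
  a <- edge_strength(make_noise())
  set.seed(123)
  b <- edge_strength(make_noise())
  expect_identical(a$aes_axial, b$aes_axial)
  expect_true(is.finite(a$aes_axial) && a$aes_axial > 0)
  expect_identical(a$edge_pixels, b$edge_pixels)
})
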