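# Independent oracles and fixture builders shared across the test files.

# Random binary volume with arbitrary (non-cubic) dimensions.
random_binary_volume <- function(dims, p = 0.3) {
  voxel_volume(array(rbinom(prod(dims), 1, p), dim = dims), binary = TRUE)
}

# Brute-force offset mean: average grid box count over every possible offset.
offset_mean_oracle <- function(vol, size) {
  offs <- expand.grid(o1 = 0:(size - 1), o2 = 0:(size - 1), o3 = 0:(size - 1))
  mean(apply(offs, 1, function(o) grid_box_count(vol, size, as.integer(o))))
}

# Brute-force framewise displacement: explicit double loop over transitions
# and parameters, independent of the vectorized implementation.
fd_oracle <- function(params, angle_unit, radius_mm = 50) {
  conv <- params
  scale <- if (angle_unit == "degrees") radius_mm * pi / 180 else radius_mm
  conv[, 4:6] <- conv[, 4:6] * scale
  out <- numeric(nrow(conv) - 1)
  for (t in seq_len(nrow(conv) - 1)) {
    acc <- 0
    for (j in 1:6) acc <- acc + abs(conv[t + 1, j] - conv[t, j])
    out[t] <- acc
  }
  out
}

# A 16 x 16 unit-step slice: left half 0, right half 1 along the row axis.
step_slice <- function(n = 16) {
  m <- matrix(0, n, n)
  m[(n / 2 + 1):n, ] <- 1
  m
}

# Constant-parameter realignment trace helper.
flat_trace <- function(n_frames = 10, tr = 2, value = 0) {
  realignment_trace(matrix(value, n_frames, 6), angle_unit = "radians",
                    tr_seconds = tr)
}
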