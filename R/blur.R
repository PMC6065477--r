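# Separable Gaussian smoothing with a reflective (mirror) boundary.
# The kernel is normalized to unit sum and reflected weights are folded back
# inside the support, so total intensity is conserved exactly.

gauss_weights <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  w <- exp(-(seq.int(-r, r))^2 / (2 * sigma^2))
  w / sum(w)
}

# n x n smoothing matrix for one axis (half-sample symmetric reflection).
blur_matrix <- function(n, sigma) {
  w <- gauss_weights(sigma)
  r <- (length(w) - 1L) / 2L
  K <- matrix(0, n, n)
  idx <- seq_len(n)
  for (k in -r:r) {
    j <- idx + k
    j[j < 1L] <- 1L - j[j < 1L]
    j[j > n] <- 2L * n + 1L - j[j > n]
    j[j < 1L] <- 1L            # guard for kernels wider than the axis
    j[j > n] <- n
    K[cbind(idx, j)] <- K[cbind(idx, j)] + w[k + r + 1L]
  }
  K
}

smooth_slice <- function(m, sigma) {
  if (sigma == 0) return(m)
  blur_matrix(nrow(m), sigma) %*% m %*% t(blur_matrix(ncol(m), sigma))
}

smooth_array3d <- function(a, sigma) {
  if (sigma == 0) return(a)
  d <- dim(a)
  x <- array(blur_matrix(d[1], sigma) %*% matrix(a, d[1]), d)
  x <- aperm(array(blur_matrix(d[2], sigma) %*%
                     matrix(aperm(x, c(2, 1, 3)), d[2]), d[c(2, 1, 3)]),
             c(2, 1, 3))
  aperm(array(blur_matrix(d[3], sigma) %*%
                matrix(aperm(x, c(3, 1, 2)), d[3]), d[c(3, 1, 2)]),
        c(2, 3, 1))
}

#' Isotropic Gaussian smoothing of a volume
#'
#' Smooths with standard deviation `sigma` voxels along each axis (separable
#' kernel, reflective boundary, unit-sum weights, so total intensity is
#' conserved). `sigma = 0` is the identity. This is the package's surrogate
#' for motion blurring when studying how blur degrades edge strength.
#'
#' @param vol A [voxel_volume()] or 3D array.
#' @param sigma Non-negative smoothing SD in voxels.
#' @return A `voxel_volume` with the same geometry (scalar, even if the input
#'   was binary).
#' @seealso [edge_strength()], [average_edge_strength()]
#' @export
apply_blur <- function(vol, sigma) {
  vol <- as_volume(vol)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma < 0) {
    mm_stop("`sigma` must be a single non-negative number", "mm_value_error")
  }
  if (sigma == 0) return(vol)
  voxel_volume(smooth_array3d(vol$data, sigma),
               voxel_size_mm = vol$voxel_size_mm,
               axis_labels = vol$axis_labels)
}
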