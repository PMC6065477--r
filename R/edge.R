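# Average edge strength (AES): mean intensity-gradient magnitude at detected
# edges of 2D image planes. Blurring (e.g. from head motion) lowers tissue
# contrast at edges, so lower AES indicates a more degraded image.

# Central-difference gradient of a 2D slice, one-sided at the borders.
slice_gradient <- function(m) {
  n1 <- nrow(m)
  n2 <- ncol(m)
  div1 <- matrix(c(1, rep(2, n1 - 2), 1), n1, n2)
  div2 <- matrix(c(1, rep(2, n2 - 2), 1), n1, n2, byrow = TRUE)
  gx <- (m[c(2:n1, n1), , drop = FALSE] -
           m[c(1, 1:(n1 - 1)), , drop = FALSE]) / div1
  gy <- (m[, c(2:n2, n2), drop = FALSE] -
           m[, c(1, 1:(n2 - 1)), drop = FALSE]) / div2
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

# Canny-style edge mask: Gaussian smoothing (sigma), gradient magnitude,
# non-maximum suppression along the quantized gradient direction (ties kept),
# then double-threshold hysteresis. With threshold_mode = "relative" the
# low/high thresholds are fractions of the slice's peak suppressed-gradient
# magnitude; "absolute" applies them directly on normalized-intensity units.
canny_edges <- function(m, sigma = 1, thresholds = c(0.1, 0.2),
                        threshold_mode = c("relative", "absolute")) {
  threshold_mode <- match.arg(threshold_mode)
  n1 <- nrow(m)
  n2 <- ncol(m)
  g <- slice_gradient(smooth_slice(m, sigma))
  mag <- g$mag
  # gradients at round-off scale are numerical noise, not contrast
  if (max(mag) <= 1e-8) return(matrix(FALSE, n1, n2))
  ang <- atan2(g$gy, g$gx) %% pi
  dir <- floor((ang + pi / 8) / (pi / 4)) %% 4 # 0: x, 1: diag, 2: y, 3: anti
  off <- list(c(1L, 0L), c(1L, 1L), c(0L, 1L), c(-1L, 1L))
  pad <- matrix(0, n1 + 2L, n2 + 2L)
  pad[2:(n1 + 1L), 2:(n2 + 1L)] <- mag
  ii <- as.vector(row(mag)) + 1L
  jj <- as.vector(col(mag)) + 1L
  keep <- matrix(TRUE, n1, n2)
  for (d in 0:3) {
    o <- off[[d + 1L]]
    nb1 <- matrix(pad[cbind(ii + o[1], jj + o[2])], n1, n2)
    nb2 <- matrix(pad[cbind(ii - o[1], jj - o[2])], n1, n2)
    keep[dir == d & (mag < nb1 | mag < nb2)] <- FALSE
  }
  nms <- mag * keep
  ref <- if (threshold_mode == "relative") max(nms) else 1
  strong <- nms >= thresholds[2] * ref
  if (!any(strong)) return(matrix(FALSE, n1, n2))
  weak <- nms >= thresholds[1] * ref
  lab <- EBImage::bwlabel(weak)
  matrix(weak & (as.vector(lab) %in% unique(lab[strong])), n1, n2)
}

#' Normalize volume intensities
#'
#' Divides intensities by the 99th percentile of the nonzero voxels and clips
#' to `[0, 1]`. The percentile (rather than the maximum) makes the
#' normalization robust to isolated hot voxels, and the ratio cancels any
#' global intensity scaling, which is what makes AES scanner-gain invariant.
#'
#' @param vol A scalar [voxel_volume()] or 3D array with at least one
#'   positive voxel.
#' @return A `voxel_volume` with intensities in `[0, 1]`.
#' @export
normalize_intensity <- function(vol) {
  vol <- as_volume(vol)
  pos <- vol$data[vol$data > 0]
  if (length(pos) == 0L) {
    mm_stop("cannot normalize an all-zero volume", "mm_domain_error")
  }
  q <- quantile(pos, 0.99, names = FALSE)
  voxel_volume(pmin(vol$data / q, 1),
               voxel_size_mm = vol$voxel_size_mm,
               axis_labels = vol$axis_labels)
}

#' Edge strength of a single 2D slice
#'
#' Detects edges with a Canny-style detector (Gaussian smoothing at
#' `sigma = 1` pixel, non-maximum suppression, hysteresis thresholds 0.1/0.2)
#' and returns the mean central-difference gradient magnitude of the *raw*
#' slice over the detected edge pixels, together with the edge-pixel count.
#' A slice with no detected edges yields `c(0, 0)`.
#'
#' @param slice 2D numeric matrix (normalized intensities), at least 3 x 3.
#' @param sigma Smoothing SD (pixels) used for edge detection.
#' @param thresholds Length-2 hysteresis thresholds (low, high).
#' @param threshold_mode `"relative"` (default): thresholds are fractions of
#'   the slice's peak suppressed-gradient magnitude, so edges remain
#'   detectable in heavily blurred images; `"absolute"`: thresholds apply
#'   directly on normalized-intensity gradient units.
#' @return Numeric vector `c(mean_gradient_at_edges, n_edges)`.
#' @export
#' @examples
#' step <- matrix(0, 16, 16); step[9:16, ] <- 1
#' slice_edge_strength(step)[1] # 0.5: central difference across a unit step
slice_edge_strength <- function(slice, sigma = 1, thresholds = c(0.1, 0.2),
                                threshold_mode = c("relative", "absolute")) {
  slice <- as.matrix(slice)
  if (nrow(slice) < 3L || ncol(slice) < 3L) {
    mm_stop("slice must be at least 3 x 3", "mm_dim_error")
  }
  e <- canny_edges(slice, sigma = sigma, thresholds = thresholds,
                   threshold_mode = match.arg(threshold_mode))
  if (!any(e)) return(c(0, 0))
  mag <- slice_gradient(slice)$mag
  c(mean(mag[e]), sum(e))
}

#' Average edge strength over one anatomical plane
#'
#' Applies [slice_edge_strength()] to every slice of the requested plane and
#' averages. With `slice_weighting = "edges"` (default) the average is
#' weighted by each slice's edge-pixel count, so background-only slices with
#' few or no edges do not dilute the metric; `"uniform"` averages the
#' edge-bearing slices equally. Slices without detected edges are always
#' excluded. Returns 0 when no slice has edges.
#'
#' @param vol A normalized [voxel_volume()] (see [normalize_intensity()]).
#' @param plane `"axial"`, `"coronal"` or `"sagittal"`; resolved through the
#'   volume's `axis_labels`.
#' @param slice_weighting `"edges"` or `"uniform"`.
#' @inheritParams slice_edge_strength
#' @return Non-negative scalar AES value.
#' @export
average_edge_strength <- function(vol, plane,
                                  slice_weighting = c("edges", "uniform"),
                                  sigma = 1, thresholds = c(0.1, 0.2),
                                  threshold_mode = c("relative", "absolute")) {
  vol <- as_volume(vol)
  slice_weighting <- match.arg(slice_weighting)
  threshold_mode <- match.arg(threshold_mode)
  axis <- plane_axis(vol, plane)
  res <- plane_slice_stats(vol, axis, sigma, thresholds, threshold_mode)
  if (res$edge_pixels == 0L) return(0)
  if (slice_weighting == "edges") {
    sum(res$means * res$counts) / sum(res$counts)
  } else {
    mean(res$means[res$counts > 0])
  }
}

plane_slice_stats <- function(vol, axis, sigma, thresholds, threshold_mode) {
  n <- dim(vol$data)[axis]
  means <- numeric(n)
  counts <- numeric(n)
  for (k in seq_len(n)) {
    sl <- switch(axis,
                 vol$data[k, , , drop = TRUE],
                 vol$data[, k, , drop = TRUE],
                 vol$data[, , k, drop = TRUE])
    r <- slice_edge_strength(sl, sigma = sigma, thresholds = thresholds,
                             threshold_mode = threshold_mode)
    means[k] <- r[1]
    counts[k] <- r[2]
  }
  list(means = means, counts = counts,
       slices_used = sum(counts > 0), edge_pixels = sum(counts))
}

#' Average edge strength in all three planes
#'
#' Convenience wrapper: normalizes the volume (unless `normalize = FALSE`)
#' and computes [average_edge_strength()] for the axial, coronal and sagittal
#' planes, with per-plane slice and edge-pixel counts.
#'
#' @inheritParams average_edge_strength
#' @param normalize Normalize intensities first (see [normalize_intensity()]).
#' @return An object of class `edge_strength_result` with fields
#'   `aes_axial`, `aes_coronal`, `aes_sagittal`, `slices_used` and
#'   `edge_pixels` (both named per plane).
#' @export
edge_strength <- function(vol, slice_weighting = c("edges", "uniform"),
                          sigma = 1, thresholds = c(0.1, 0.2),
                          threshold_mode = c("relative", "absolute"),
                          normalize = TRUE) {
  vol <- as_volume(vol)
  slice_weighting <- match.arg(slice_weighting)
  threshold_mode <- match.arg(threshold_mode)
  if (normalize) vol <- normalize_intensity(vol)
  planes <- c("axial", "coronal", "sagittal")
  aes <- numeric(3)
  used <- integer(3)
  npix <- numeric(3)
  for (i in seq_along(planes)) {
    axis <- plane_axis(vol, planes[i])
    res <- plane_slice_stats(vol, axis, sigma, thresholds, threshold_mode)
    used[i] <- res$slices_used
    npix[i] <- res$edge_pixels
    aes[i] <- if (res$edge_pixels == 0) 0 else if (slice_weighting == "edges") {
      sum(res$means * res$counts) / sum(res$counts)
    } else {
      mean(res$means[res$counts > 0])
    }
  }
  structure(
    list(aes_axial = aes[1], aes_coronal = aes[2], aes_sagittal = aes[3],
         slices_used = setNames(used, planes),
         edge_pixels = setNames(npix, planes),
         slice_weighting = slice_weighting),
    class = "edge_strength_result"
  )
}

#' @export
print.edge_strength_result <- function(x, digits = 4, ...) {
  cat("<edge_strength_result>\n")
  print(data.frame(
    plane = c("axial", "coronal", "sagittal"),
    aes = format(c(x$aes_axial, x$aes_coronal, x$aes_sagittal),
                 digits = digits),
    slices_used = as.integer(x$slices_used),
    edge_pixels = as.integer(x$edge_pixels)
  ), row.names = FALSE)
  invisible(x)
}
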