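#' Voxel volumes
#'
#' A `voxel_volume` is the in-memory representation of a 3D image: a numeric
#' array plus the physical voxel size and a label for each array axis saying
#' which anatomical slice plane that axis indexes (an "axial" axis runs
#' inferior--superior, so stepping along it enumerates axial slices).
#'
#' Array indices are treated as 0-based for all geometric operations: voxel
#' `(i, j, k)` (0-based) spans the half-open cube
#' `[i, i+1) x [j, j+1) x [k, k+1)` in voxel units. This makes box-grid
#' definitions in [grid_box_count()] unambiguous.
#'
#' @param data 3D numeric array. For binary volumes all values must be 0 or 1.
#' @param voxel_size_mm Positive numeric triple, physical edge lengths of one
#'   voxel in millimetres.
#' @param axis_labels Character triple, a permutation of
#'   `c("sagittal", "coronal", "axial")`, giving the slice plane indexed by
#'   each array axis.
#' @param binary Logical; if `NULL` (default), detected from the data.
#'
#' @return An object of class `voxel_volume`: a list with elements `data`,
#'   `voxel_size_mm`, `axis_labels` and `binary`.
#' @seealso [read_volume()], [make_cube()], [compute_fd()], [edge_strength()]
#' @export
#' @examples
#' v <- voxel_volume(array(1, dim = c(4, 4, 4)))
#' v$binary
voxel_volume <- function(data,
                         voxel_size_mm = c(1, 1, 1),
                         axis_labels = c("sagittal", "coronal", "axial"),
                         binary = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    mm_stop("`data` must be a 3D array", "mm_dim_error")
  }
  if (any(dim(data) < 1L)) {
    mm_stop("all three dimensions must be >= 1", "mm_dim_error")
  }
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0)) {
    mm_stop("`voxel_size_mm` must be three positive finite numbers",
            "mm_value_error")
  }
  axis_labels <- as.character(axis_labels)
  if (length(axis_labels) != 3L ||
      !setequal(axis_labels, c("sagittal", "coronal", "axial"))) {
    mm_stop(
      "`axis_labels` must be a permutation of sagittal/coronal/axial",
      "mm_value_error"
    )
  }
  is_bin <- all(data == 0 | data == 1)
  if (isTRUE(binary) && !is_bin) {
    mm_stop("volume flagged binary contains values other than 0 and 1",
            "mm_type_error")
  }
  structure(
    list(
      data = data,
      voxel_size_mm = voxel_size_mm,
      axis_labels = axis_labels,
      binary = if (is.null(binary)) is_bin else isTRUE(binary)
    ),
    class = "voxel_volume"
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<voxel_volume> %d x %d x %d voxels (%s), voxel size %s mm\n",
    d[1], d[2], d[3],
    if (x$binary) sprintf("binary, %d occupied", sum(x$data != 0)) else "scalar",
    paste(format(x$voxel_size_mm, digits = 4), collapse = " x ")
  ))
  cat("  axes:", paste(x$axis_labels, collapse = ", "), "\n")
  invisible(x)
}

# Coerce an array to voxel_volume, pass voxel_volume through.
as_volume <- function(x) {
  if (inherits(x, "voxel_volume")) return(x)
  if (is.array(x) && length(dim(x)) == 3L) return(voxel_volume(x))
  mm_stop("expected a voxel_volume or a 3D array", "mm_type_error")
}

# Array axis that indexes slices of the given anatomical plane.
plane_axis <- function(vol, plane) {
  plane <- as.character(plane)
  ax <- match(plane, vol$axis_labels)
  if (length(plane) != 1L || is.na(ax)) {
    mm_stop(sprintf("unknown plane label '%s'", paste(plane, collapse = ",")),
            "mm_value_error")
  }
  ax
}

require_binary <- function(vol) {
  if (!vol$binary || !all(vol$data == 0 | vol$data == 1)) {
    mm_stop("operation requires a binary (0/1) volume", "mm_type_error")
  }
  invisible(vol)
}

#' Binarize a scalar volume
#'
#' Thresholds intensities to produce a binary occupancy volume, the substrate
#' for box counting.
#'
#' @param vol A [voxel_volume()] or 3D array.
#' @param threshold Voxels strictly greater than this are set to 1.
#' @return A binary `voxel_volume` with the same geometry.
#' @export
binarize <- function(vol, threshold = 0.5) {
  vol <- as_volume(vol)
  voxel_volume((vol$data > threshold) * 1,
               voxel_size_mm = vol$voxel_size_mm,
               axis_labels = vol$axis_labels, binary = TRUE)
}
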