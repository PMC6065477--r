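#' Read a 3D NIfTI volume
#'
#' Reads a NIfTI-1 image (`.nii` or `.nii.gz`) into a [voxel_volume()].
#' Voxel sizes come from the header `pixdim`; the anatomical axis labels are
#' derived from the header orientation codes (L/R = sagittal, A/P = coronal,
#' S/I = axial). When the image carries no qform/sform, the conventional
#' (sagittal, coronal, axial) order is assumed and a warning is issued.
#'
#' @param path Path to an existing NIfTI-1 file.
#' @return A [voxel_volume()].
#' @export
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' write_volume(make_cube(8), f)
#' v <- read_volume(f)
#' dim(v$data)
read_volume <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    mm_stop(sprintf("file not found: %s", path), "mm_io_error")
  }
  img <- tryCatch(
    RNifti::readNifti(path),
    error = function(e) {
      mm_stop(sprintf("cannot read NIfTI file '%s': %s",
                      path, conditionMessage(e)), "mm_format_error")
    }
  )
  d <- dim(img)
  if (length(d) != 3L) {
    mm_stop(sprintf("expected a 3D image, got %d dimensions", length(d)),
            "mm_dim_error")
  }
  hdr <- RNifti::niftiHeader(img)
  vox <- RNifti::pixdim(img)[seq_len(3)]
  if (hdr$qform_code == 0 && hdr$sform_code == 0) {
    warning("no qform/sform in header; assuming (sagittal, coronal, axial) axes")
    labels <- c("sagittal", "coronal", "axial")
  } else {
    letters3 <- strsplit(RNifti::orientation(img), "")[[1]]
    labels <- c(R = "sagittal", L = "sagittal",
                A = "coronal", P = "coronal",
                S = "axial", I = "axial")[letters3]
    if (anyNA(labels) || !setequal(labels, c("sagittal", "coronal", "axial"))) {
      mm_stop("unreadable orientation in NIfTI header", "mm_format_error")
    }
  }
  voxel_volume(array(as.numeric(img), dim = d),
               voxel_size_mm = vox, axis_labels = unname(labels))
}

#' Write a 3D volume to NIfTI
#'
#' Writes the array, voxel sizes and an sform affine encoding the axis labels
#' so that [read_volume()] recovers the same geometry.
#'
#' @param vol A [voxel_volume()] or 3D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  vol <- as_volume(vol)
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$voxel_size_mm
  aff <- matrix(0, 4, 4)
  aff[4, 4] <- 1
  world_row <- c(sagittal = 1L, coronal = 2L, axial = 3L)[vol$axis_labels]
  for (i in 1:3) aff[world_row[i], i] <- vol$voxel_size_mm[i]
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Rigid-body realignment traces
#'
#' A `realignment_trace` holds the per-frame six-parameter rigid-body series
#' produced by fMRI volume realignment: columns 1--3 are translations in mm,
#' columns 4--6 rotations in `angle_unit`. Because a silent radian/degree mix-up
#' scales rotational displacement by a factor of ~57, the angle unit is a
#' required argument everywhere a trace enters the package.
#'
#' @param params Numeric T x 6 matrix, T >= 2, all values finite.
#' @param angle_unit `"radians"` or `"degrees"` for columns 4--6.
#' @param tr_seconds Repetition time in seconds (> 0).
#' @param label Free-text label (e.g. `"rest"`, `"movie"`).
#' @return An object of class `realignment_trace`.
#' @seealso [read_realignment()], [framewise_displacement()]
#' @export
realignment_trace <- function(params, angle_unit = c("radians", "degrees"),
                              tr_seconds, label = "") {
  angle_unit <- match.arg(angle_unit)
  params <- as.matrix(params)
  if (ncol(params) != 6L) {
    mm_stop("realignment parameters must have 6 columns", "mm_format_error")
  }
  if (nrow(params) < 2L) {
    mm_stop("a realignment trace needs at least 2 frames", "mm_value_error")
  }
  if (!all(is.finite(params))) {
    bad <- which(!is.finite(params), arr.ind = TRUE)[1, ]
    mm_stop(sprintf("non-finite parameter at frame %d, column %d",
                    bad[1], bad[2]), "mm_value_error")
  }
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L ||
      !is.finite(tr_seconds) || tr_seconds <= 0) {
    mm_stop("`tr_seconds` must be a single positive number", "mm_value_error")
  }
  storage.mode(params) <- "double"
  colnames(params) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  structure(
    list(params = params, angle_unit = angle_unit,
         tr_seconds = as.numeric(tr_seconds), label = as.character(label)),
    class = "realignment_trace"
  )
}

#' @export
print.realignment_trace <- function(x, ...) {
  cat(sprintf(
    "<realignment_trace> %d frames, TR %.3f s, rotations in %s%s\n",
    nrow(x$params), x$tr_seconds, x$angle_unit,
    if (nzchar(x$label)) paste0(" [", x$label, "]") else ""
  ))
  invisible(x)
}

#' Read an SPM-style rp_*.txt realignment file
#'
#' Parses whitespace-delimited text with exactly six numeric columns per
#' non-empty row (the SPM `rp_*.txt` dialect). The rotation unit of such files
#' is not self-describing, so it must be stated explicitly.
#'
#' @inheritParams realignment_trace
#' @param path Path to the text file.
#' @return A [realignment_trace()], rows in file order.
#' @export
read_realignment <- function(path, angle_unit = c("radians", "degrees"),
                             tr_seconds, label = "") {
  angle_unit <- match.arg(angle_unit)
  if (!file.exists(path)) {
    mm_stop(sprintf("file not found: %s", path), "mm_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) {
    mm_stop("realignment file contains no data rows", "mm_format_error")
  }
  tokens <- strsplit(trimws(lines[keep]), "[[:space:]]+")
  nf <- lengths(tokens)
  if (any(nf != 6L)) {
    bad <- which(nf != 6L)[1]
    mm_stop(sprintf("row %d has %d fields (expected 6)", keep[bad], nf[bad]),
            "mm_format_error")
  }
  vals <- suppressWarnings(as.numeric(unlist(tokens)))
  if (anyNA(vals)) {
    bad <- ceiling(which(is.na(vals))[1] / 6)
    mm_stop(sprintf("non-numeric token in row %d", keep[bad]),
            "mm_parse_error")
  }
  realignment_trace(matrix(vals, ncol = 6, byrow = TRUE),
                    angle_unit = angle_unit, tr_seconds = tr_seconds,
                    label = label)
}

#' Write a realignment trace as rp-style text
#'
#' @param trace A [realignment_trace()] or T x 6 matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_realignment <- function(trace, path) {
  params <- if (inherits(trace, "realignment_trace")) trace$params else
    as.matrix(trace)
  if (ncol(params) != 6L) {
    mm_stop("realignment parameters must have 6 columns", "mm_format_error")
  }
  writeLines(apply(params, 1, function(r) {
    paste(sprintf("% .10e", r), collapse = "  ")
  }), path)
  invisible(path)
}

# Columns a cohort table may carry; id and age_years are mandatory.
cohort_columns <- function() {
  c("id", "age_years", "sex", "bmi_kg_m2",
    "motion_rest_mm_min", "motion_movie_mm_min",
    "thickness_mm", "fd_cortical", "gyrification",
    "aes_axial", "aes_coronal", "aes_sagittal")
}

#' Read a cohort table from CSV
#'
#' Reads an RFC-4180 CSV with a header row. `id` and `age_years` are
#' mandatory; empty BMI cells are kept as missing values (`NA`), never zero,
#' because height/weight are typically available only for a subset of a
#' cohort and BMI models must run on the BMI-complete subset.
#'
#' @param path Path to a CSV file.
#' @return A `data.frame` with one row per subject.
#' @seealso [simulate_cohort()], [model_table()]
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    mm_stop(sprintf("file not found: %s", path), "mm_io_error")
  }
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  missing_cols <- setdiff(c("id", "age_years"), names(df))
  if (length(missing_cols)) {
    mm_stop(sprintf("cohort table lacks mandatory column(s): %s",
                    paste(missing_cols, collapse = ", ")), "mm_schema_error")
  }
  if (nrow(df) > 0 && !is.numeric(df$age_years)) {
    mm_stop("`age_years` must be numeric", "mm_schema_error")
  }
  df
}

#' Write a cohort table to CSV
#'
#' Missing values are written as empty cells; `read_cohort()` restores them
#' as `NA`.
#'
#' @param cohort A cohort `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  if (!is.data.frame(cohort)) {
    mm_stop("`cohort` must be a data.frame", "mm_type_error")
  }
  missing_cols <- setdiff(c("id", "age_years"), names(cohort))
  if (length(missing_cols)) {
    mm_stop(sprintf("cohort table lacks mandatory column(s): %s",
                    paste(missing_cols, collapse = ", ")), "mm_schema_error")
  }
  write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}
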