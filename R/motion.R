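#' Convert an angular displacement to millimetres
#'
#' Rotational realignment parameters are converted to a translation-like
#' displacement as the arc length swept on the surface of a sphere
#' approximating the head: `radius_mm * angle_in_radians`. The conventional
#' radius is 50 mm. Sign is preserved.
#'
#' @param angle Finite angle (vectorized).
#' @param unit `"radians"` or `"degrees"`.
#' @param radius_mm Sphere radius in millimetres (default 50).
#' @return Displacement in millimetres.
#' @export
#' @examples
#' angular_to_mm(1, "degrees") # 50 * pi / 180 = 0.8727 mm
angular_to_mm <- function(angle, unit = c("radians", "degrees"),
                          radius_mm = 50) {
  unit <- match.arg(unit)
  if (any(!is.finite(angle))) {
    mm_stop("`angle` must be finite", "mm_value_error")
  }
  if (!is.numeric(radius_mm) || length(radius_mm) != 1L || radius_mm <= 0) {
    mm_stop("`radius_mm` must be a single positive number", "mm_value_error")
  }
  rad <- if (unit == "degrees") angle * pi / 180 else angle
  radius_mm * rad
}

#' Framewise displacement of a realignment trace
#'
#' For each transition between consecutive frames, the sum over the six
#' rigid-body parameters of the absolute first difference, with the three
#' rotation columns first converted to millimetres via [angular_to_mm()].
#' Depends only on frame-to-frame differences, so adding a constant offset to
#' every frame leaves it unchanged.
#'
#' @param trace A [realignment_trace()].
#' @param radius_mm Sphere radius for the rotation conversion (default 50).
#' @return Numeric vector of length `T - 1`, all values >= 0, in mm.
#' @export
framewise_displacement <- function(trace, radius_mm = 50) {
  if (!inherits(trace, "realignment_trace")) {
    mm_stop("`trace` must be a realignment_trace", "mm_type_error")
  }
  p <- trace$params
  if (!all(is.finite(p))) {
    bad <- which(!is.finite(p), arr.ind = TRUE)[1, ]
    mm_stop(sprintf("non-finite parameter at frame %d, column %d",
                    bad[1], bad[2]), "mm_value_error")
  }
  p[, 4:6] <- angular_to_mm(p[, 4:6], trace$angle_unit, radius_mm)
  rowSums(abs(diff(p)))
}

#' Summary motion rate from a realignment trace
#'
#' Framewise displacement is substantially elevated over the first few
#' volumes of a scan run, so `drop_initial` frames (default 5) are excluded
#' before summarizing; the transition crossing the drop boundary is also
#' discarded so excluded frames contribute no displacement at all. The rate
#' is the mean per-transition displacement divided by the repetition time,
#' expressed per minute (`mm/min`), which makes scans of different TR
#' directly comparable.
#'
#' @inheritParams framewise_displacement
#' @param drop_initial Number of initial frames to exclude (default 5).
#' @return An object of class `motion_summary` with fields `fd_series`
#'   (post-drop, mm per transition), `mean_rate_mm_per_min`, `frames_dropped`,
#'   `sphere_radius_mm`, `tr_seconds` and `label`.
#' @export
mean_motion_rate <- function(trace, drop_initial = 5, radius_mm = 50) {
  if (!inherits(trace, "realignment_trace")) {
    mm_stop("`trace` must be a realignment_trace", "mm_type_error")
  }
  drop_initial <- as.integer(drop_initial)
  if (drop_initial < 0L) {
    mm_stop("`drop_initial` must be >= 0", "mm_value_error")
  }
  n <- nrow(trace$params)
  if (n - drop_initial < 2L) {
    mm_stop(sprintf(
      "only %d frame(s) remain after dropping %d; need at least 2",
      max(n - drop_initial, 0L), drop_initial), "mm_value_error")
  }
  kept <- realignment_trace(
    trace$params[(drop_initial + 1L):n, , drop = FALSE],
    angle_unit = trace$angle_unit, tr_seconds = trace$tr_seconds,
    label = trace$label
  )
  fd <- framewise_displacement(kept, radius_mm = radius_mm)
  structure(
    list(fd_series = fd,
         mean_rate_mm_per_min = mean(fd) / trace$tr_seconds * 60,
         frames_dropped = drop_initial,
         sphere_radius_mm = radius_mm,
         tr_seconds = trace$tr_seconds,
         label = trace$label),
    class = "motion_summary"
  )
}

#' @export
print.motion_summary <- function(x, ...) {
  cat(sprintf(
    "<motion_summary>%s %d transitions, %.4f mm/min (dropped %d initial frames)\n",
    if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
    length(x$fd_series), x$mean_rate_mm_per_min, x$frames_dropped
  ))
  invisible(x)
}

#' Group-averaged motion time-course with confidence band
#'
#' Averages the post-drop framewise-displacement series of several subjects
#' frame by frame and attaches a 95% confidence band (normal approximation
#' `mean +/- 1.96 SE` by default, or Student-t quantiles). Timestamps are the
#' scan times of the later frame of each transition, counted from the start
#' of the run (dropped frames included in the clock), so stimulus-locked
#' events appear at their true scan time.
#'
#' @param traces List of [realignment_trace()] objects with identical frame
#'   counts and TR (at least 2).
#' @param drop_initial Initial frames to exclude per trace.
#' @param radius_mm Sphere radius for rotation conversion.
#' @param ci `"normal"` or `"t"`.
#' @param conf Confidence level (default 0.95).
#' @param group_label Label stored with the result.
#' @return An object of class `timecourse_summary` with fields `time_s`,
#'   `group_mean`, `ci_low`, `ci_high`, `n_traces`, `group_label`.
#' @export
group_timecourse <- function(traces, drop_initial = 5, radius_mm = 50,
                             ci = c("normal", "t"), conf = 0.95,
                             group_label = "") {
  ci <- match.arg(ci)
  if (!is.list(traces) || length(traces) < 2L ||
      !all(vapply(traces, inherits, logical(1), "realignment_trace"))) {
    mm_stop("`traces` must be a list of >= 2 realignment_trace objects",
            "mm_type_error")
  }
  lens <- vapply(traces, function(t) nrow(t$params), integer(1))
  trs <- vapply(traces, function(t) t$tr_seconds, numeric(1))
  if (length(unique(lens)) != 1L || length(unique(trs)) != 1L) {
    mm_stop("all traces must share the same length and TR", "mm_value_error")
  }
  fd <- t(vapply(traces, function(t) {
    mean_motion_rate(t, drop_initial = drop_initial,
                     radius_mm = radius_mm)$fd_series
  }, numeric(lens[1] - drop_initial - 1L)))
  m <- colMeans(fd)
  se <- apply(fd, 2, sd) / sqrt(nrow(fd))
  z <- if (ci == "normal") qnorm(1 - (1 - conf) / 2) else
    qt(1 - (1 - conf) / 2, df = nrow(fd) - 1)
  structure(
    list(time_s = (drop_initial + seq_along(m)) * trs[1],
         group_mean = m, ci_low = m - z * se, ci_high = m + z * se,
         n_traces = nrow(fd), group_label = group_label),
    class = "timecourse_summary"
  )
}

#' @export
print.timecourse_summary <- function(x, ...) {
  cat(sprintf(
    "<timecourse_summary>%s %d traces, %d transitions, %.1f-%.1f s, mean FD %.4f mm\n",
    if (nzchar(x$group_label)) paste0(" [", x$group_label, "]") else "",
    x$n_traces, length(x$time_s), min(x$time_s), max(x$time_s),
    mean(x$group_mean)
  ))
  invisible(x)
}

#' Plot a group motion time-course with its confidence band
#'
#' @param x A `timecourse_summary` from [group_timecourse()].
#' @param col Line colour; the band uses a transparent version.
#' @param ... Passed to [plot()].
#' @export
plot.timecourse_summary <- function(x, col = "firebrick", ...) {
  plot(x$time_s, x$group_mean, type = "n",
       ylim = range(x$ci_low, x$ci_high),
       xlab = "time (s)", ylab = "framewise displacement (mm)", ...)
  polygon(c(x$time_s, rev(x$time_s)), c(x$ci_low, rev(x$ci_high)),
          col = grDevices::adjustcolor(col, alpha.f = 0.25), border = NA)
  lines(x$time_s, x$group_mean, col = col)
  invisible(x)
}
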