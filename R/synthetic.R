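# Synthetic generators: analytic fractal phantoms, realignment traces with
# known structure, and a cohort emulator with age-, BMI- and motion-linked
# morphology outcomes. Every generator is bit-reproducible from its seed.

phantom_volume <- function(occ, pad) {
  if (pad > 0) {
    d <- dim(occ)
    padded <- array(0, d + 2L * pad)
    padded[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- occ
    occ <- padded
  }
  voxel_volume(occ, binary = TRUE)
}

#' Solid geometric phantoms
#'
#' Centered binary solids in a (optionally padded) array, used to validate
#' box counting and edge strength: a filled cube of a given edge, a digitized
#' ball (voxel centers within `radius`), and a spherical shell (ball minus a
#' concentric smaller ball).
#'
#' @param edge,radius,thickness Positive dimensions in voxels.
#' @param pad Zero-voxel margin added on every side. The cube defaults to
#'   `pad = 0` so that it stays aligned with the box grid (a padded cube
#'   straddles extra boxes and no longer yields exact power-law counts).
#' @return A binary [voxel_volume()].
#' @export
#' @examples
#' sum(make_cube(16)$data)  # 4096
make_cube <- function(edge, pad = 0) {
  edge <- as.integer(edge)
  if (is.na(edge) || edge < 1L) {
    mm_stop("`edge` must be a positive integer", "mm_value_error")
  }
  phantom_volume(array(1, dim = rep(edge, 3)), pad)
}

#' @rdname make_cube
#' @export
make_sphere <- function(radius, pad = 2) {
  if (!is.numeric(radius) || radius <= 0) {
    mm_stop("`radius` must be positive", "mm_value_error")
  }
  n <- 2L * ceiling(radius) + 1L
  cc <- (n + 1) / 2
  ax2 <- (seq_len(n) - cc)^2
  d2 <- outer(outer(ax2, ax2, "+"), ax2, "+")
  phantom_volume((d2 <= radius^2) * 1, pad)
}

#' @rdname make_cube
#' @export
make_shell <- function(radius, thickness, pad = 2) {
  if (!is.numeric(radius) || radius <= 0 ||
      !is.numeric(thickness) || thickness <= 0 || thickness > radius) {
    mm_stop("need 0 < thickness <= radius", "mm_value_error")
  }
  n <- 2L * ceiling(radius) + 1L
  cc <- (n + 1) / 2
  ax2 <- (seq_len(n) - cc)^2
  d2 <- outer(outer(ax2, ax2, "+"), ax2, "+")
  inner <- radius - thickness
  phantom_volume((d2 <= radius^2 & d2 > inner^2) * 1, pad)
}

#' Menger sponge phantom
#'
#' The standard level-`level` Menger sponge on a `3^level` grid: recursively
#' remove the seven center-cross subcubes of every 3 x 3 x 3 block. The
#' construction has exactly `20^level` occupied voxels and analytic
#' box-counting dimension `log(20) / log(3) = 2.7268`, making it the
#' reference phantom for validating the box-count estimator on a triadic
#' size ladder.
#'
#' @param level Integer recursion depth, 0--4 (level 4 is an 81-cube).
#' @param pad Zero-voxel margin added on every side.
#' @return A binary [voxel_volume()].
#' @export
#' @examples
#' sum(make_menger(2)$data)  # 400
make_menger <- function(level, pad = 0) {
  level <- as.integer(level)
  if (is.na(level) || level < 0L) {
    mm_stop("`level` must be a non-negative integer", "mm_value_error")
  }
  if (level > 4L) {
    mm_stop("`level` must be <= 4", "mm_value_error")
  }
  n <- 3L^level
  idx <- seq_len(n) - 1L
  keep <- array(TRUE, dim = rep(n, 3))
  for (m in seq_len(level) - 1L) {
    digit <- (idx %/% 3L^m) %% 3L
    is_mid <- digit == 1L
    mids <- outer(outer(is_mid, is_mid, "+"), is_mid, "+")
    keep <- keep & (mids < 2)
  }
  phantom_volume(keep * 1, pad)
}

#' Simulate a realignment trace
#'
#' Generates a six-parameter rigid-body random walk emulating the motion
#' structure seen in fMRI realignment output: per-parameter increments with
#' half-normal magnitude and random sign scaled by `base_scale_mm`
#' (rotations are generated at the equivalent 50 mm arc scale and stored in
#' radians), increments into the first five frames inflated by
#' `initial_factor` (the settling-in effect that motivates dropping initial
#' volumes), and a transient `spike_factor` increment across all parameters
#' at each requested spike time (stimulus-evoked motion).
#'
#' @param duration_s Scan duration in seconds (>= 10 TR).
#' @param tr_seconds Repetition time in seconds.
#' @param base_scale_mm Scale of the per-transition increments, mm.
#' @param spike_times_s Numeric vector of spike times, seconds.
#' @param seed Integer seed; the full draw is reproducible from it.
#' @param label Trace label.
#' @param initial_factor,spike_factor Inflation factors for the initial
#'   frames and the spikes.
#' @return A [realignment_trace()] (rotations in radians).
#' @export
simulate_trace <- function(duration_s = 520, tr_seconds = 2.470,
                           base_scale_mm = 0.017, spike_times_s = numeric(),
                           seed = NULL, label = "",
                           initial_factor = 5, spike_factor = 10) {
  if (duration_s < 10 * tr_seconds) {
    mm_stop("`duration_s` must be at least 10 repetition times",
            "mm_value_error")
  }
  if (base_scale_mm < 0) {
    mm_stop("`base_scale_mm` must be >= 0", "mm_value_error")
  }
  n_frames <- floor(duration_s / tr_seconds)
  if (length(spike_times_s) &&
      (any(spike_times_s <= 0) || any(spike_times_s > duration_s))) {
    mm_stop("spike times must lie within (0, duration_s]", "mm_value_error")
  }
  spike_rows <- if (length(spike_times_s)) {
    pmin(pmax(round(spike_times_s / tr_seconds), 1L), n_frames - 1L)
  } else {
    integer()
  }
  with_seed(seed, {
    inc <- matrix(sign(rnorm((n_frames - 1L) * 6L)) *
                    abs(rnorm((n_frames - 1L) * 6L)) * base_scale_mm,
                  nrow = n_frames - 1L, ncol = 6L)
    early <- seq_len(min(4L, n_frames - 1L)) # transitions within frames 0-4
    inc[early, ] <- inc[early, ] * initial_factor
    inc[spike_rows, ] <- inc[spike_rows, ] * spike_factor
    inc[, 4:6] <- inc[, 4:6] / 50 # mm-equivalent arc -> radians at r = 50
    params <- rbind(0, apply(inc, 2, cumsum))
    realignment_trace(params, angle_unit = "radians",
                      tr_seconds = tr_seconds, label = label)
  })
}

#' Cohort simulation parameters
#'
#' Bundles the generating parameters of [simulate_cohort()]. Defaults encode
#' the statistical structure reported for a large adult lifespan cohort
#' (ages 18--88): morphology declining linearly with age at
#' -0.00432 mm/yr (thickness), -0.00097/yr (fractal dimensionality) and
#' -0.00372/yr (gyrification); movie-scan motion lowering thickness by
#' 0.0135 mm per mm/min; rest motion exceeding movie motion by 1.528 mm/min
#' on average; and log-scale motion correlations of .351/.430 with age,
#' .484 between scans, with BMI loadings that reproduce the age-partialled
#' BMI-motion correlations (.340 rest, .249 movie). BMI is correlated .274
#' with age and missing for a fraction 81/640 of subjects.
#'
#' @param n_subjects Default cohort size.
#' @param age_range Uniform age range in years.
#' @param bmi_mean,bmi_sd,r_age_bmi BMI marginal and its age correlation.
#' @param load_age_rest,load_age_movie Age loadings of log-motion.
#' @param load_bmi_rest,load_bmi_movie Loadings on the age-independent BMI
#'   component.
#' @param r_rest_movie Target log-scale inter-scan motion correlation.
#' @param motion_rest_mean Mean rest motion, mm/min.
#' @param movie_rest_mean_diff Mean rest - movie difference, mm/min.
#' @param log_sd_rest,log_sd_movie Log-scale SDs of motion.
#' @param slope_thickness,slope_fd,slope_gi Age slopes per year.
#' @param motion_effect_thickness,motion_effect_fd,motion_effect_gi Movie
#'   motion effects per mm/min.
#' @param intercept_thickness,intercept_fd,intercept_gi Outcome intercepts
#'   (value at age 0, motion 0).
#' @param sd_thickness,sd_fd,sd_gi Residual SDs of the outcomes.
#' @param aes_means,aes_sd,aes_age_r AES marginal means, SD, and target age
#'   correlations per plane (axial, coronal, sagittal). AES is generated as
#'   an age-loaded variable with no direct motion loading, emulating an
#'   image-quality metric that tracks age-related tissue contrast rather
#'   than fMRI-scan motion.
#' @param bmi_missing_frac Fraction of subjects with missing BMI.
#' @return An object of class `sim_params` (a validated list).
#' @export
sim_params <- function(n_subjects = 640,
                       age_range = c(18, 88),
                       bmi_mean = 26.5, bmi_sd = 4.4, r_age_bmi = 0.274,
                       load_age_rest = 0.351, load_age_movie = 0.430,
                       load_bmi_rest = 0.3184, load_bmi_movie = 0.2248,
                       r_rest_movie = 0.484,
                       motion_rest_mean = 3.52,
                       movie_rest_mean_diff = 1.528,
                       log_sd_rest = 0.45, log_sd_movie = 0.55,
                       slope_thickness = -0.00432,
                       slope_fd = -0.00097,
                       slope_gi = -0.00372,
                       motion_effect_thickness = -0.0135,
                       motion_effect_fd = -0.0030,
                       motion_effect_gi = -0.0116,
                       intercept_thickness = 2.706,
                       intercept_fd = 2.657,
                       intercept_gi = 3.170,
                       sd_thickness = 0.10, sd_fd = 0.020, sd_gi = 0.16,
                       aes_means = c(axial = 0.28, coronal = 0.26,
                                     sagittal = 0.30),
                       aes_sd = 0.03,
                       aes_age_r = c(axial = -0.43, coronal = -0.25,
                                     sagittal = -0.43),
                       bmi_missing_frac = 81 / 640) {
  p <- as.list(environment())
  if (p$n_subjects < 10) {
    mm_stop("`n_subjects` must be >= 10", "mm_value_error")
  }
  sds <- c(p$bmi_sd, p$log_sd_rest, p$log_sd_movie, p$sd_thickness,
           p$sd_fd, p$sd_gi, p$aes_sd)
  if (any(sds <= 0)) {
    mm_stop("all noise SDs must be > 0", "mm_value_error")
  }
  if (abs(p$r_age_bmi) >= 1 || any(abs(p$aes_age_r) >= 1)) {
    mm_stop("requested correlation >= 1 is not attainable", "mm_value_error")
  }
  shared2 <- p$r_rest_movie - p$load_age_rest * p$load_age_movie -
    p$load_bmi_rest * p$load_bmi_movie
  res_rest2 <- 1 - p$load_age_rest^2 - p$load_bmi_rest^2 - shared2
  res_movie2 <- 1 - p$load_age_movie^2 - p$load_bmi_movie^2 - shared2
  if (shared2 < 0 || res_rest2 <= 0 || res_movie2 <= 0) {
    mm_stop(paste0("requested correlation structure is not attainable ",
                   "(loadings imply a correlation >= 1)"), "mm_value_error")
  }
  p$shared_loading <- sqrt(shared2)
  p$res_rest <- sqrt(res_rest2)
  p$res_movie <- sqrt(res_movie2)
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "<sim_params> n = %d, ages %g-%g; age slopes %g / %g / %g per yr;\n",
    x$n_subjects, x$age_range[1], x$age_range[2],
    x$slope_thickness, x$slope_fd, x$slope_gi))
  cat(sprintf(
    "  motion: rest %g mm/min, rest-movie diff %g; thickness motion effect %g\n",
    x$motion_rest_mean, x$movie_rest_mean_diff, x$motion_effect_thickness))
  invisible(x)
}

#' Simulate a cohort table
#'
#' Draws a synthetic cohort emulating the joint structure of age, BMI,
#' per-scan head motion, AES and three cortical morphology outcomes:
#'
#' * age uniform over `age_range`;
#' * BMI linear in age (target correlation `r_age_bmi`) plus noise, with a
#'   fraction `bmi_missing_frac` set missing;
#' * log-motion for the rest and movie scans sharing a latent subject factor
#'   (target inter-scan correlation `r_rest_movie`) plus age and BMI
#'   loadings; raw motion is lognormal (positive and right-skewed, as motion
#'   rates are), with the movie mean lower than rest by
#'   `movie_rest_mean_diff`;
#' * thickness, fractal dimensionality and gyrification each
#'   `intercept + age slope * age + motion effect * movie motion + noise`;
#' * AES per plane loaded on age only, essentially uncorrelated with motion.
#'
#' Correlation targets are specified on the log-motion scale; raw-scale
#' correlations are attenuated by a factor
#' `s / sqrt(exp(s^2) - 1)` (about 7% at the default log-SDs).
#'
#' @param n Number of subjects (defaults to `params$n_subjects`).
#' @param seed Integer seed; fixes the entire draw.
#' @param params A [sim_params()] object.
#' @return A cohort `data.frame` (see [read_cohort()] for the columns).
#' @export
#' @examples
#' co <- simulate_cohort(n = 100, seed = 1)
#' cor(co$age_years, co$thickness_mm)
simulate_cohort <- function(n = params$n_subjects, seed = NULL,
                            params = sim_params()) {
  if (!inherits(params, "sim_params")) {
    mm_stop("`params` must come from sim_params()", "mm_type_error")
  }
  if (n < 10) mm_stop("`n` must be >= 10", "mm_value_error")
  with_seed(seed, {
    age <- runif(n, params$age_range[1], params$age_range[2])
    mid <- mean(params$age_range)
    sd_age <- diff(params$age_range) / sqrt(12)
    z_age <- (age - mid) / sd_age

    eps_bmi <- rnorm(n)
    bmi <- params$bmi_mean + params$bmi_sd *
      (params$r_age_bmi * z_age + sqrt(1 - params$r_age_bmi^2) * eps_bmi)

    shared <- rnorm(n)
    log_rest <- params$load_age_rest * z_age +
      params$load_bmi_rest * eps_bmi +
      params$shared_loading * shared + params$res_rest * rnorm(n)
    log_movie <- params$load_age_movie * z_age +
      params$load_bmi_movie * eps_bmi +
      params$shared_loading * shared + params$res_movie * rnorm(n)

    mean_movie <- params$motion_rest_mean - params$movie_rest_mean_diff
    if (mean_movie <= 0) {
      mm_stop("movie motion mean implied by the parameters is not positive",
              "mm_value_error")
    }
    rest <- exp(log(params$motion_rest_mean) - params$log_sd_rest^2 / 2 +
                  params$log_sd_rest * log_rest)
    movie <- exp(log(mean_movie) - params$log_sd_movie^2 / 2 +
                   params$log_sd_movie * log_movie)

    outcome <- function(intercept, slope, effect, sd) {
      intercept + slope * age + effect * movie + rnorm(n, 0, sd)
    }
    thickness <- outcome(params$intercept_thickness, params$slope_thickness,
                         params$motion_effect_thickness, params$sd_thickness)
    fd <- outcome(params$intercept_fd, params$slope_fd,
                  params$motion_effect_fd, params$sd_fd)
    gi <- outcome(params$intercept_gi, params$slope_gi,
                  params$motion_effect_gi, params$sd_gi)

    aes <- vapply(c("axial", "coronal", "sagittal"), function(pl) {
      r <- params$aes_age_r[[pl]]
      params$aes_means[[pl]] + params$aes_sd *
        (r * z_age + sqrt(1 - r^2) * rnorm(n))
    }, numeric(n))

    if (params$bmi_missing_frac > 0) {
      n_miss <- round(params$bmi_missing_frac * n)
      bmi[sample.int(n, n_miss)] <- NA_real_
    }

    data.frame(
      id = sprintf("S%04d", seq_len(n)),
      age_years = age,
      sex = sample(c("F", "M"), n, replace = TRUE),
      bmi_kg_m2 = bmi,
      motion_rest_mm_min = rest,
      motion_movie_mm_min = movie,
      thickness_mm = thickness,
      fd_cortical = fd,
      gyrification = gi,
      aes_axial = aes[, "axial"],
      aes_coronal = aes[, "coronal"],
      aes_sagittal = aes[, "sagittal"],
      stringsAsFactors = FALSE
    )
  })
}
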