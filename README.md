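# morphmotion

Head motion during MRI scanning blurs structural images and can masquerade
as "brain aging": older adults move more, and motion-degraded scans yield
thinner-looking, smoother-looking cortex. **morphmotion** is an R package
for quantifying that entanglement. It implements, as tested reusable
components, the computational chain needed to relate cortical morphology to
age, body-mass index and head motion:

- **Fractal dimensionality (FD)** of a 3D binary structure by box counting.
  For box sizes *s*, occupied-box counts *N(s)* follow
  *FD = −Δlog₂N / Δlog₂s*, estimated as the negated OLS slope of
  log₂ *N* on log₂ *s* (default sizes {1, 2, 4, 8, 16}). Besides the
  grid-aligned count, the package provides the *dilation* variant — the
  exact mean of the grid count over all *s*³ grid offsets, computed in
  closed form by dilating the structure with an *s*-cube — which removes
  the grid-alignment variability that plagues plain box counting.
- **Framewise displacement (FD motion)** from six-parameter rigid-body
  realignment traces (SPM `rp_*.txt` dialect): per-transition sum of
  absolute parameter differences, rotations converted to arc length on a
  50 mm sphere, the first five volumes excluded, summarized as mm/min so
  scans with different repetition times are comparable.
- **Average edge strength (AES)**, an image-derived quality metric: the
  edge-pixel-weighted mean intensity-gradient magnitude at Canny-detected
  edges of each 2D slice, per anatomical plane (axial, coronal, sagittal).
  Blur — e.g. from motion — lowers AES.
- **Hierarchical model comparison**: eight linear models of each morphology
  outcome (age, BMI, motion from rest and movie scans, AES, and age
  interactions), ranked by *R²* and ΔBIC with
  `BIC = n ln(RSS/n) + p ln(n)` and a ΔBIC < 2 equivalence band.
- **Synthetic generators** for everything the pipeline consumes: analytic
  fractal phantoms (cube, sphere, shell, Menger sponge with exact
  dimensionality log 20 / log 3), realignment traces with elevated initial
  frames and stimulus-locked spikes, and a 640-subject cohort emulator
  whose age slopes, motion effects, correlations and rest-vs-movie
  contrast follow the published statistical structure of a large adult
  lifespan cohort (ages 18–88).

The package is aimed at researchers who want to audit motion effects in
morphometry pipelines, or to validate FD / AES / motion code against
phantoms with known ground truth, without access to restricted imaging
data.

## Worked example

```r
library(morphmotion)

# 1. fractal dimensionality of an exactly self-similar phantom
compute_fd(make_menger(3), sizes = c(1, 3, 9, 27), method = "grid")
#> <boxcount> method = grid, fd = 2.727 (R^2 = 1)
#>  size count
#>     1  8000
#>     3   400
#>     9    20
#>    27     1
```

The level-3 Menger sponge occupies 20³ = 8000 voxels; counts fall by a
factor 20 per triadic size step, so the fitted dimensionality is
log 20 / log 3 ≈ 2.7268 — the analytic value, recovered exactly.

```r
# 2. head motion from a simulated movie-watching scan
tr <- simulate_trace(duration_s = 520, tr_seconds = 2.47,
                     base_scale_mm = 0.017, spike_times_s = c(280, 360),
                     seed = 1, label = "movie")
mean_motion_rate(tr)
#> <motion_summary> [movie] 204 transitions, 2.2027 mm/min (dropped 5 initial frames)

# 3. cohort-level statistics on the synthetic cohort
co <- simulate_cohort(n = 640, seed = 1)
cohort_correlations(co)
#> <cohort_correlations> n = 640
#>   r(age, rest) = 0.383  r(age, movie) = 0.433  r(rest, movie) = 0.478
#>   BMI subset n = 559: r(age, BMI) = 0.246
#>   r(BMI, rest) = 0.367 (partial | age 0.307)  r(BMI, movie) = 0.278 (partial | age 0.199)
#>   rest vs movie: <paired_contrast> t(639) = 23.19, p = < 2.2e-16, mean diff = 1.483, Cohen's d = 0.9168

model_table(co, "thickness")
#> Eight-model comparison, outcome: thickness
#>  model_id                                    predictors   n    r2      bic delta_bic equivalent subset
#>         1                                           Age 640 0.390 -2839.50      9.89      FALSE  FALSE
#>         2                                           BMI 559 0.025 -2209.20    243.03      FALSE   TRUE
#>         3                                     Age + BMI 559 0.376 -2452.24      0.00       TRUE   TRUE
#>         4                          Age + Movement(Rest) 640 0.391 -2834.11     15.28      FALSE  FALSE
#>         5                         Age + Movement(Movie) 640 0.406 -2849.39      0.00       TRUE  FALSE
#>         6 Age + Movement(Movie) + Age x Movement(Movie) 640 0.407 -2844.50      4.89      FALSE  FALSE
#>         7                              Age + AES(axial) 640 0.390 -2833.05     16.34      FALSE  FALSE
#>         8           Age + AES(axial) + Age x AES(axial) 640 0.393 -2829.90     19.49      FALSE  FALSE
```

Reading the table: adding movie-scan motion to age (model 5) raises *R²*
from .390 to .406 and wins the BIC contest among the full-sample models
(ΔBIC = 0); the age-only model sits 9.89 BIC points behind, so motion
explains real additional variance — about 1.5% here — exactly the pattern
the cohort was generated to emulate. The BMI models are fit on the
559-subject BMI-complete subset and ranked separately, because BIC values
are not comparable across different row sets.

A command-line wrapper with the same functionality (subcommands
`simulate`, `fd`, `aes`, `motion`, `motion-group`, `cohort-stats`,
`report`) is installed at `inst/cli/morphmotion.R`:

```sh
Rscript inst/cli/morphmotion.R report --n 640 --seed 1 --out report.md
```

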