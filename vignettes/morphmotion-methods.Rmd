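---
title: "Methods: fractal dimensionality, motion metrics and model comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fractal dimensionality, motion metrics and model comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphmotion)
```

This vignette documents the models and procedures the package implements,
the parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic generators do and do not emulate.

## Box-counting fractal dimensionality

A binary voxel structure's fractal dimensionality summarizes how its bulk
scales with resolution. For a ladder of box edges $s$, the number $N(s)$ of
grid boxes containing at least one occupied voxel follows
$N(s) \propto s^{-\mathrm{FD}}$ for self-similar structures, so

$$\mathrm{FD} = -\frac{\Delta \log_2 N(s)}{\Delta \log_2 s},$$

estimated here as the negated ordinary-least-squares slope of $\log_2 N$ on
$\log_2 s$ over all provided sizes. OLS equals the two-point log-ratio
exactly when the points are collinear, and is the standard multi-point
estimator otherwise; `fit_r2` of the regression is reported as a fit
diagnostic. A constant count series is a perfect fit with slope 0, so it is
returned as `fd = 0`, `fit_r2 = 1` rather than an undefined ratio.

Geometric conventions, fixed to make counts unambiguous: array indices are
0-based for geometry, voxel $(i,j,k)$ spans the half-open cube
$[i,i+1)\times[j,j+1)\times[k,k+1)$, and the box grid tiles *all* of space,
so partially overlapping border boxes count whenever they contain an
occupied voxel. This makes counts independent of zero padding — though not
of *translation*, which is precisely the grid-alignment problem: a filled
16-cube needs $4^3 = 64$ boxes of edge 4 when aligned, but
$\lceil 17/4\rceil^3 = 125$ when shifted one voxel diagonally.

The *dilation* method removes this variability by averaging the grid count
over all $s^3$ offsets. The package treats the offset-mean identity as the
normative definition and computes it in closed form: each occupied box of
each shifted grid corresponds to exactly one voxel of the structure dilated
by an $s$-cube, so the mean count is the dilated voxel count divided by
$s^3$. The dilation is implemented as three separable 1-D sweeps, and the
tests verify the identity against brute-force offset enumeration to
$10^{-9}$.

Default sizes are $\{1, 2, 4, 8, 16\}$ (powers of two suit structures tens
of voxels across). Sizes are configurable so that triadic ladders can be
used with exactly self-similar phantoms: the level-3 Menger sponge yields
counts $\{8000, 400, 20, 1\}$ at sizes $\{1, 3, 9, 27\}$ and the analytic
dimensionality $\log 20/\log 3 \approx 2.7268$, which the test suite
asserts to $10^{-9}$. Only filled structures are supported; surface-only
dimensionality is out of scope. Count monotonicity in $s$ is guaranteed for
multiplicatively nested ladders (each coarse box is a union of fine boxes);
for non-nested ladders a grid count can occasionally increase, which
`compute_fd()` flags with a warning.

## Framewise displacement and motion rates

Rigid-body realignment yields six parameters per frame: three translations
(mm) and three rotations. Framewise displacement for the transition
$t \to t+1$ is the sum of absolute first differences over the six
parameters, with rotations first converted to millimetres as arc length on
a sphere of radius 50 mm (the conventional head-size approximation):
$d_{\mathrm{mm}} = r\,\theta_{\mathrm{rad}}$, sign preserved, so 1° maps to
$50\pi/180 \approx 0.8727$ mm.

Two deliberate choices:

- **The angle unit is a mandatory argument.** rp-style text files do not
  record whether rotations are radians or degrees, and a silent mix-up
  scales rotational displacement by a factor of about 57. Nothing in the
  package guesses.
- **Motion rates are mm/min.** The summary rate is the mean per-transition
  displacement divided by the repetition time, times 60. Scans with
  different TRs (1.970 s rest vs 2.470 s movie in the emulated design) are
  then directly comparable. Whether a per-minute motion figure means
  "mean per transition per unit time" or "sum per minute" is a genuine
  dialect question; the mean-per-transition reading is used and documented
  because it is invariant to scan duration.

Displacement is substantially elevated while the scanner and subject settle
in, so the first `drop_initial = 5` frames are excluded, *including* the
transition that crosses the drop boundary — excluded frames contribute no
displacement at all. Group time-courses average the post-drop series across
subjects with a 95% confidence band (normal approximation by default;
Student-t quantiles optional — group sizes in this design are large enough
that the two are indistinguishable). Timestamps count from the start of the
run including dropped frames, so stimulus-locked events appear at their
true scan time.

## Average edge strength

AES treats edge contrast as an image-quality proxy: motion blurs the image,
blur lowers the intensity gradient at tissue boundaries, so lower AES
means a more degraded scan. The pipeline is:

1. **Normalization**: intensities divided by the 99th percentile of
   nonzero voxels, clipped to $[0,1]$. The percentile (not the maximum)
   resists isolated hot voxels; the ratio cancels global intensity
   scaling, making AES scanner-gain invariant.
2. **Edge detection per 2-D slice**: Gaussian smoothing at $\sigma = 1$
   pixel, central-difference gradient, non-maximum suppression along the
   quantized gradient direction (ties kept, which preserves the two-pixel
   ridge of an ideal step edge), then double-threshold hysteresis with
   low/high thresholds 0.1/0.2. Connected weak-edge components are kept
   when they touch a strong pixel (connected-component labelling via
   EBImage).
3. **Measurement**: the mean central-difference gradient magnitude of the
   *raw* slice over the detected edge pixels. An ideal unit step yields
   exactly $(1-0)/2 = 0.5$.
4. **Aggregation**: per anatomical plane (resolved through the volume's
   axis labels), the edge-pixel-count-weighted mean over slices. Slices
   with no detected edges are skipped, not averaged as zeros — background
   slices must not dilute the metric. Uniform slice weighting is available
   as a flag since the convention is a dialect choice.

**Threshold mode.** The hysteresis thresholds default to *fractions of the
slice's peak suppressed-gradient magnitude* (the classic Canny
convention), not absolute gradient values. The reason is robustness of the
metric's operative property — blur must lower AES, not zero it out: once an
edge has been smeared to an effective width of a few voxels, its peak
gradient on normalized units falls below any fixed absolute threshold near
0.2 and detection collapses, turning a graded quality metric into a cliff.
With relative thresholds the blur ladder $\sigma \in \{0,1,2,3,4\}$ on a
spherical-shell phantom yields strictly decreasing AES in all three planes,
while the constant-slice, unit-step and scale-invariance contracts are
unaffected. An `threshold_mode = "absolute"` switch provides the literal
fixed-threshold behaviour. Gradients at round-off magnitude
($\le 10^{-8}$) are treated as no contrast, so constant slices never
produce spurious "edges" from floating-point noise.

The AES definition here is a deterministic dialect, not a bit-level
replication of any particular toolbox: published descriptions pin down the
idea (mean edge-contrast per plane) but not the detector internals, so the
package fixes one reproducible choice and documents it.

The blur operator itself (`apply_blur`) is a separable Gaussian with
unit-sum weights and half-sample-symmetric reflection at the borders, so
total intensity is conserved to machine precision; $\sigma = 0$ is the
identity. It serves as the package's surrogate for motion degradation.

## The synthetic cohort generator

`simulate_cohort()` emulates the joint statistical structure of a large
adult lifespan cohort so that the inferential layer can be exercised with
known ground truth. Per subject:

- age $\sim$ uniform(18, 88) years;
- BMI $= 26.5 + 4.4\,(0.274\,z_{\mathrm{age}} + \sqrt{1-0.274^2}\,\varepsilon)$
  kg/m², i.e. population age–BMI correlation .274; a fraction
  $81/640 \approx 12.7\%$ of BMI values is set missing, mirroring a cohort
  where height/weight exist only for a subset;
- log-scale motion for rest and movie scans built from standardized
  loadings: age loadings .351/.430, loadings .318/.225 on the
  age-independent BMI component (calibrated to reproduce the published
  age-partialled BMI–motion correlations of .340 and .249), and a shared
  subject factor sized so the inter-scan correlation is .484. Raw motion
  is lognormal — positive and right-skewed, as motion-rate distributions
  are — with means 3.52 (rest) and 1.992 (movie) mm/min and log-SDs
  0.45/0.55. Those four numbers were solved jointly so that the
  rest−movie mean difference is 1.528 mm/min, the paired Cohen's *d* is
  ≈ 0.99, and the movie-motion SD (≈ 1.18 mm/min) is the value implied by
  a motion partial $R^2$ of about .021 in the thickness model. Because
  the correlation targets live on the log scale, raw-scale correlations
  are attenuated by $s/\sqrt{e^{s^2}-1}$, about 7% at these log-SDs;
- outcomes: thickness, fractal dimensionality and gyrification are each
  linear in age (slopes −0.00432 mm/yr, −0.00097/yr, −0.00372/yr) and in
  movie-scan motion (−0.0135 mm per mm/min for thickness; the other two
  scaled by the ratio of their age slopes), plus Gaussian noise (SDs
  0.10 mm, 0.020, 0.16 — chosen so the age-only models explain roughly
  .43–.50, .50 and .19 of variance, matching the published pattern). The
  motion effect is attached to movie-scan motion because that is the
  motion estimate the published model selection favours;
- AES per plane is age-loaded only (target age correlations −.43 axial
  and sagittal, −.25 coronal) with no direct motion loading, emulating a
  quality metric that tracks age-related tissue contrast rather than
  fMRI-scan motion.

`simulate_trace()` generates six-parameter random walks with half-normal
increment magnitudes, a 5× inflation of the increments into the first five
frames (so the drop rule has something to drop) and 10× transient
increments at requested spike times (stimulus-evoked motion; the emulated
movie design spikes near 280 s and 360 s). Rotations are generated at the
equivalent 50 mm arc scale. Every generator is bit-reproducible from its
seed, which is applied without disturbing the caller's RNG stream.

**What the generator does not emulate**: anatomy (phantoms are geometric
solids, not brains), k-space motion artifacts (blur is a Gaussian
surrogate), scanner noise spectra, sex effects, and any nonlinearity in
the age trends. Passing tests therefore demonstrate that the estimators
recover known structure of the *statistical* kind; they do not certify
behaviour on real scans.

## The eight-model comparison

For each outcome, eight linear models are fit: age; BMI; age + BMI;
age + rest motion; age + movie motion; the latter plus its age
interaction; age + axial AES; and that plus its age interaction.
Interaction columns are products of mean-centered main effects (centering
within the fitting rows) to limit collinearity. Fits are ranked by

$$\mathrm{BIC} = n \ln(\mathrm{RSS}/n) + p \ln n,$$

with $p$ counting the intercept and slope terms. The error variance is a
shared constant across compared models and is omitted; any such constant
cancels in $\Delta$BIC, and the tests verify that $\Delta$BIC agrees with
`stats::BIC` on identical fits to $10^{-8}$. Two models with identical RSS
and one extra parameter differ by exactly $\ln n$. $\Delta$BIC is reported
relative to the best model of a comparison set and $\Delta\mathrm{BIC} < 2$
is flagged as equivalence.

Because the BMI models can only be fit to the BMI-complete subset and BIC
is not comparable across differing row sets, `model_table()` ranks models
1, 4–8 (full rows) and models 2–3 (subset rows) separately, annotating each
fit's $n$. A `combine_subsets` flag reproduces the conventional all-in-one
table, with a warning.

**Model recovery at the emulated effect size.** The motion effect the
generator encodes is deliberately small — about 2% partial $R^2$ beyond
age, the magnitude the emulated study itself reports. At $n = 640$ this
puts the age-plus-movie-motion model's expected BIC advantage over the
age-only model near 7–8 points, but with a noncentral-$\chi^2_1$ spread
wide enough that the generating model wins the contest in only roughly
80–85% of simulated cohorts (the acceptance script computes this rate).
That is a property of BIC at this signal-to-noise, not an estimator
defect: inflating the motion effect or shrinking the residual noise would
push the rate toward 1 at the cost of no longer emulating the study. The
package keeps the faithful calibration.

## Numerical choices and degenerate inputs

- Exactness tolerances: analytic FD values are asserted to $10^{-9}$ or
  tighter; the dilation/offset-mean identity to $10^{-9}$; closed-form
  BIC and displacement identities to $10^{-12}$.
- Degenerate inputs are errors with classed conditions (`mm_*_error`):
  empty volumes for dilation counting, all-zero volumes for
  normalization, zero-variance inputs for correlations, non-finite
  realignment parameters (named by frame and column), rank-deficient
  designs (named by column), BIC across differing row sets. Two
  exceptions return well-defined values instead: a constant box-count
  series (`fd = 0`), and a paired contrast of identical samples
  (zero difference, $t = 0$, $d = 0$).
- Ties in non-maximum suppression are kept (`>=` comparison), so
  symmetric edges are not half-suppressed.
- Missing BMI is `NA`, never zero.

## Problem sizes

The test suite and acceptance script run at desk scale, chosen so the full
suite completes in seconds while keeping estimator standard errors well
inside the asserted tolerances: phantoms up to $64^3$ voxels, blur ladders
on a $37^3$ shell, 30–50 random volumes/traces for oracle equivalence, 100
simulated cohorts of $n = 640$ for parameter and model recovery, and
100-trace groups for the time-course summaries.

## Known limitations

- AES values are comparable only within the package's own dialect;
  absolute values from other edge-strength implementations will differ.
- The grid box count is exact but alignment-sensitive by design; use the
  dilation method for reported dimensionalities.
- The cohort emulator's lognormal motion family is a modeling choice
  (motivated by the right-skew and log-scaled displays typical of motion
  data), not an empirical fit to any dataset.
- The CLI is a thin wrapper over the R functions; concurrent runs writing
  to the same output path are not guarded.
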