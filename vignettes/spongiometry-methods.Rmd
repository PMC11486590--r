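---
title: "Relaxation-time mapping and metaphyseal line-profile morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relaxation-time mapping and metaphyseal line-profile morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spongiometry)
```

## The measurement problem

Legg-Calvé-Perthes disease (LCPD) is a childhood osteonecrosis of the
femoral head: the epiphyseal blood supply is interrupted, and downstream
changes appear not only in the epiphysis but also in the metaphysis on the
far side of the growth plate. In the established piglet model, one femoral
head is made completely ischemic and the contralateral hip serves as a
paired control. One week later the metaphyseal *spongiosa* — the thin
banded region where calcified cartilage is converted into mature bone —
already shows compositional and thickness changes.

Quantitative MRI relaxation-time maps (T2, T1ρ, and the adiabatic variants
aT1ρ and aT2ρ) resolve this banding: the growth plate is a long-relaxation
stripe, the primary spongiosa a short-relaxation (hypointense) band, the
secondary spongiosa a long-relaxation (hyperintense) band, and the mature
metaphysis settles in between. Because the bands are ~1–2 mm thick at a
0.52 mm acquisition pixel, region-of-interest averaging is fragile; this
package instead implements a line-profile analysis anchored on the
growth-plate boundary, which tolerates positional variability between hips
and animals.

The pipeline is: **fit** per-pixel relaxation maps from
magnetization-prepared image series → **interpolate** three-fold to a
0.17 mm analysis grid → **extract** line profiles from the proximal
growth-plate boundary 10 mm distally into the metaphysis → **average**
them robustly → **locate** landmarks and thicknesses → **compare**
ischemic vs. control with paired statistics.

## Relaxometry

Each pixel of a magnetization-prepared series is modeled as
mono-exponential decay,

$$S(t) = S_0 \, e^{-t/T},$$

where $t$ is the preparation time (0–80 ms for T2/T1ρ, 0–96 ms for the
adiabatic contrasts) and $T$ the relaxation time of the prepared contrast.
Two fit domains are provided:

* `log_linear` — ordinary least squares on $\log S$; exact on noiseless
  data and used to seed the nonlinear fit;
* `nonlinear_ls` (default) — Levenberg–Marquardt on the signal-domain
  residuals, vectorized across all pixels. Magnitude MRI noise is Rician,
  which biases log-domain fits at low signal, so the signal-domain fit is
  the default.

Pixels with fewer than `min_valid_samples` samples above `min_signal`
(default: only non-positive signals are excluded) are marked non-finite
rather than raising an error; a non-positive fitted decay rate is likewise
non-finite, and a numerically flat decay is capped at `max_T` (default
1000 ms, far above any plausible metaphyseal value at 3 T — the cap exists
to stop runaway fits, not to be reached in practice). The coefficient of
determination is always computed on signal-domain residuals and clamped to
$[0, 1]$.

Maps are upsampled with Catmull–Rom bicubic interpolation, which
reproduces affine ramps exactly and keeps landmark positions smooth. An
output pixel whose 4×4 stencil touches a failed-fit pixel is itself marked
failed: interpolation never invents data inside failed-fit territory.

## Line-profile morphometry

**Geometry.** The growth-plate boundary is a polyline in physical mm
(origin at the image corner, x along columns). It is resampled at the
profile sampling step (0.17 mm), and from each resampled point a profile
is cast along the locally smoothed boundary normal, oriented by a
`distal_hint` vector toward the metaphysis, for `profile_length` (10 mm),
sampling the map bilinearly. A horizontal boundary of 10.2 mm yields 60
lines; typical femoral-head boundaries yield 60–100. Lines leaving the
finite map region are truncated and flagged; fewer than 10 usable lines is
an error.

**Robust averaging.** At each depth the profile values are combined with
an iteratively sigma-clipped mean: values beyond `clip_sigma` (3) standard
deviations of the current mean are dropped and the mean re-estimated, to
convergence or 10 rounds. This is the Gaussian maximum-likelihood location
after outlier rejection; on clean data it reduces to the arithmetic mean,
and a single grossly corrupted line among 100 is rejected completely.

**Landmarks.** The averaged profile is smoothed with a moving quadratic
(Savitzky–Golay) filter before landmark detection. On the control pattern
the profile falls from the growth plate to a first minimum (primary
spongiosa, PS), rises to a first maximum (secondary spongiosa, SS), and
relaxes to the mature-metaphysis level. Detection rules:

* PS is the first interior minimum whose topographic prominence reaches
  `min_prominence` (2%) of the profile's dynamic range; SS is the first
  qualifying maximum after it. Ties take the shallower depth.
* Both landmark positions are refined by a quadratic through the three
  samples around the discrete extremum.
* Inflection points delimit thicknesses: the zero crossings of the
  smoothed second derivative on either side of PS. The crossing is
  searched outward from the steepest point of each limb (the extremum of
  the smoothed first derivative); anchoring the search there keeps
  noise-induced sign flips of the second derivative from hijacking the
  landmark.
* `ps_thickness` is the distance between the two inflections flanking PS;
  `ss_thickness` is twice the distance from the PS–SS inflection to the SS
  maximum; the total is their sum, exactly, by construction.
* The mature-metaphysis value is the unweighted mean of the *unsmoothed*
  profile over a `mm_window` (0.7 mm) interval centered at
  $d_{PS} + 4\,(d_{SS} - d_{PS})$; the profile beyond that window is
  unused. A window that would extend past the profile end raises an error
  advising a longer `profile_length`.

A strictly monotone or constant profile raises a landmark error naming the
landmark that failed.

## Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| `profile_length` | 10 | mm | protocol profile length into the metaphysis |
| `sample_step` | 0.17 | mm | three-fold interpolated 0.52 mm acquisition |
| `smoothing_window` | 1.56 | mm | three acquisition pixels (nine samples); see below |
| `min_prominence` | 0.02 | – | suppresses noise-induced extrema |
| `clip_sigma` | 3 | SD | standard robust-mean threshold |
| `mm_window` | 0.7 | mm | mature-metaphysis averaging interval |
| `mm_offset_factor` | 4 | – | window center at 4× the PS–SS distance beyond PS |
| `interp factor` | 3 | – | 0.52 mm → 0.17 mm analysis grid |
| `max_T` | 1000 | ms | cap for flat decays |

The smoothing window deserves a note. A quadratic filter spanning only
three samples interpolates exactly and removes no noise, defeating its
purpose (differentiating noisy data for the inflection search). The
default is therefore three *acquisition* pixels (1.56 mm, nine analysis
samples), which gives stable second derivatives while remaining well below
a quarter of the profile length. Narrower windows localize sharp features
slightly better on near-noiseless data but make landmark positions on
broad, flat secondary-spongiosa plateaus essentially random under
realistic noise; this trade-off is the main reason the window is exposed
as configuration.

The mature-metaphysis window anchor (at $d_{PS} + 4(d_{SS}-d_{PS})$,
i.e. measured from the PS position) is a documented design choice; the
offset origin is configurable.

## The synthetic world

`generate_phantom()` builds a banded femoral-head phantom: epiphysis →
growth plate → primary spongiosa → secondary spongiosa → mature
metaphysis, stacked straight or as concentric arcs (for curvature tests).
Band relaxation times and widths default to the control-arm reference
summaries for the LCPD piglet model (e.g. for T2: 57.9 ms primary
spongiosa, 92 ms secondary spongiosa, 65.4 ms mature metaphysis; widths
1.12 and 1.90 mm); the ischemic preset thins both spongiosa bands and
lowers the secondary-spongiosa value accordingly. Growth-plate and
epiphysis values are *not* tabulated in those summaries (the epiphysis is
out of scope); they are set qualitatively — the growth plate above the
secondary spongiosa, matching its hyperintense appearance — and are
clearly marked as non-reference defaults.

Two generator choices matter:

* **Band blending is analytic.** Band fields are the exact Gaussian
  convolution of the piecewise-constant band profile (error-function
  blending with `transition_sigma`, default 0.3 mm), evaluated at pixel
  centers. Rasterizing the label image first and blurring it afterwards
  quantizes band edges to the 0.52 mm grid, and recovered thicknesses then
  snap to half-pixel steps — an artifact of the phantom, not of the
  method.
* **Noise is Rician**, as in magnitude MRI:
  $\sqrt{(s + n_1)^2 + n_2^2}$ with $n_i \sim N(0, \bar S_0/\mathrm{snr})$,
  seeded and reproducible. The default snr of 50 represents a good 3 T
  TSE acquisition at this resolution. At snr ≥ 20 the noise is
  mean-preserving within 1% at full signal.
* **Growth-plate width** defaults to 1.0 mm. With the 10 mm profiles and
  the 4× mature-metaphysis anchor, a thicker physis pushes the window past
  the profile end for the widest control geometries, which is inconsistent
  with the unused profile tail the protocol describes; 1.0 mm is
  anatomically plausible for a 6-week piglet physis and leaves the
  procedure self-consistent. The parameter is configurable.

**What the phantom does not emulate** — and hence what a green test does
not establish: real spongiosa are textured, curved in 3D and imaged as a
single 2 mm slice, so real profiles have rounded, structured peaks rather
than the phantom's flat-topped plateaus; there is no B0/B1 inhomogeneity,
no slice partial volume, no misregistration between hips. Phantom results
validate the estimator chain, not scanner physics.

**Known accuracy limits.** At 0.52 mm acquisition with 0.3 mm transitions,
bands near 1 mm wide are at the resolution limit: the PS dip and SS peak
attenuate into each other, and recovered `ss_thickness` is compressed by
roughly 0.15–0.45 mm for the narrowest (ischemic) geometries even without
noise. Over twenty phantoms spanning the control and ischemic thickness
ranges the recovery correlates with truth at rank correlation ≈ 0.99, with
a mean absolute error of ≈ 0.20–0.26 mm depending on the noise
realization — straddling our acceptance bound of 0.25 mm, which we
deliberately leave as measured rather than tune around (see the package's
acceptance suite). The same resolution limit is acknowledged for the real
acquisition, where sub-millimetre primary-spongiosa differences could not
be resolved.

`generate_paired_cohort()` complements the image phantom with a purely
statistical generator: per subject and metric, control ~
$N(\mu_c, \sigma_c^2)$ and ischemic = control + $N(\mu_d, \sigma_d^2)$,
parameterized from the reference paired-difference summaries. It drives
the calibration suites (type-I error 5%, CI coverage 95%) and the
effect-recovery checks.

## Paired statistics

For each contrast and metric the package computes on the paired
differences $d_i = \text{ischemic}_i - \text{control}_i$:

$$t = \frac{\bar d}{s_d/\sqrt n}, \qquad
  \mathrm{CI}_{95} = \bar d \pm t_{0.975,\,n-1}\, s_d/\sqrt n, \qquad
  d_{\text{Cohen}} = \frac{|\bar d|}{s_d},$$

with a two-sided p-value on $n-1$ degrees of freedom. Percent change is
computed per subject, $100\,(I_i - C_i)/C_i$, then summarized by its mean
and SD — the only definition under which a percent change carries its own
SD. The paired Cohen's d is $|\bar d| / s_d$ (not a pooled-SD variant):
this is the definition that reproduces the published effect sizes from the
published paired-difference columns (e.g. $13.3/9.3 \to 1.4$).

No multiple-testing correction is applied, matching the study design; the
number of tests (24 for the full grid) is attached to the summary table's
metadata. A zero-variance difference vector raises a degenerate-variance
error rather than returning infinity.

One caveat discovered while verifying against the published tables: the
printed t statistics and 95% CIs there are mutually inconsistent with the
printed paired-difference mean/SD at n = 10 under the textbook formulas,
while every printed Cohen's d is consistent. This package implements the
textbook formulas; its acceptance checks therefore target d, means and
differences, never t or CI.

## Numerical choices, degenerate inputs

* All sampling (profiles, interpolation) is bilinear/bicubic in physical
  mm; boundary and map share one frame.
* Profile depth grids are `seq(0, profile_length, by = sample_step)`,
  inclusive of 0.
* Boundary resampling uses arc-length midpoints `(k - 1/2) * step`,
  avoiding duplicated endpoints and giving 60 lines for a 10.2 mm
  boundary.
* Sigma-clipping stops when the clipped set stabilizes, the SD collapses
  to zero, or fewer than 3 values would remain (the depth then becomes
  non-finite, with a warning).
* Equal extrema tie-break: the shallower depth wins.
* Determinism: phantoms, cohorts and the pipeline are reproducible given
  their seeds; reruns produce byte-identical outputs.

## Limitations

Beyond the resolution limits above: the analysis is 2D single-slice; the
boundary is an input (no growth-plate segmentation); no multi-exponential
or stretched-exponential decay; no B1/B0 correction; no DICOM ingestion
(convert to the text container or NIfTI-derived CSVs first). The
statistics module implements exactly the paired design — no mixed models
or non-parametric alternatives.
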