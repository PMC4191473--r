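---
title: "Methods: Fourier retinotopy, map metrics and visual electrophysiology scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Fourier retinotopy, map metrics and visual electrophysiology scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retmap)
```

# The measurement problem

In periodic-stimulation intrinsic-signal imaging, a bar drifts across the
visual field at a fixed temporal frequency while the cortex is imaged through
the skull. Each cortical location responds when the bar crosses its receptive
field, so the reflectance at every pixel oscillates at the stimulus frequency
with a phase that encodes the pixel's preferred position in visual space —
plus a hemodynamic delay that is unknown but identical for both sweep
directions. `retmap` implements the analysis chain that turns a pair of
opposite-direction image stacks into an absolute (delay-free) retinotopic map
in visual degrees, and the three quality metrics used to compare such maps
across animals: the tilt of the zero-phase line, the local phase scatter, and
the cortical magnification factor. A second arm of the package scores visual
evoked potentials (VEPs) and electroretinograms (ERGs) and provides the group
statistics used with such measurements.

Because no raw recordings accompany this kind of experiment, every stage is
validated closed-loop against a synthetic-data generator whose ground truth
is known exactly.

# The mapping model

## Signal model and Fourier extraction

At pixel $(r, c)$ inside the responsive region, the generator (and, by
assumption, the cortex) produces

$$x_{rc}(t) = A\cos\!\big(2\pi f t + \varphi_d + \varphi_{rc}\big) + \varepsilon$$

for the forward sweep, and with $-\varphi_{rc}$ for the reverse sweep, where
$f$ is the stimulus frequency, $\varphi_d$ the hemodynamic delay and
$\varphi_{rc}$ the position phase. The analysis chain is:

1. **Boxcar high-pass** (`highpass_boxcar`): each pixel's time series has its
   centered moving average over two stimulus cycles subtracted. The mean of a
   sinusoid over a whole number of cycles is zero, so the stimulus-locked
   component passes untouched while constants and slow drift are removed.
   Edge frames where the window is truncated are dropped, not padded —
   padding would leak spectral energy into the stimulus bin. With an
   even-length window the center sits half a sample forward, which leaves a
   constant offset of `slope/(2 * frame rate)` on a linear ramp; this DC
   residue never reaches the stimulus bin.
2. **Fundamental component** (`extract_fundamental`): the single-frequency
   Fourier component at $f$, computed on the largest whole-cycle run of
   filtered frames, normalized so a noiseless tone $A\cos(2\pi f t+\varphi)$
   returns amplitude $A$ and phase $\varphi$. Phases are referenced to the
   acquisition clock so the two directions are comparable. Sessions are
   required to contain an integer number of stimulus cycles and an integer
   number of frames per cycle; off-bin frequencies are rejected rather than
   interpolated.
3. **Bias removal** (`remove_bias`): the mean cosine/sine vector over a
   caller-supplied reference region (away from evoked activity, free of
   vascular artifacts) is subtracted from every pixel. No automatic artifact
   detection is attempted — region choice is an experimenter decision.
4. **Opposite-direction combination** (`combine_opposite`): per pixel,
   $\varphi_{\text{out}} = \mathrm{wrap}(\varphi_{\text{fwd}} -
   \varphi_{\text{rev}})/2$, so the delay cancels algebraically and exactly;
   amplitudes are averaged. The visual angle is the phase in degrees divided
   by the conversion factor (default 7.2, i.e. one 360° cycle per 50° sweep
   of visual field). Halving before conversion is required to preserve the
   position scale after the subtraction doubles it.

All phase arithmetic uses phase-degrees on the principal interval
$(-180°, 180°]$, with the wrap applied after subtraction and before halving,
which keeps the monitor's central line at zero. The phase subtraction is
unambiguous only while $2\varphi_{rc}$ stays inside one cycle, i.e. while the
mapped region spans less than $\pm 12.5°$ of visual field at the default
conversion factor; the generator's default geometry respects this.

## Map metrics

* **Map tilt** (`compute_map_tilt`): pixels whose visual angle lies within
  2% of the map's range around zero are fit with a total-least-squares
  (principal-axis) line; the tilt is the acute angle, in $[0°, 90°]$, between
  that line and the reference axis — mediolateral (columns) for elevation
  maps, anteroposterior (rows) for azimuth maps. TLS is used because it is
  symmetric in the two image axes; the nominal band is widened minimally when
  it falls between pixel centers on coarse grids. The sign of the tilt is
  discarded. On noiseless planar maps the recovery error is dominated by the
  pixel-lattice discretization of the zero band and stays below about 0.5°
  across orientations.
* **Phase scatter** (`compute_phase_scatter`): for each selected pixel, the
  deviation of its visual angle from the mean over all integer offsets within
  Euclidean radius 2.9 (exactly the 5×5 square, 25 pixels, center included);
  the metric is the SD of these deviations. Centers are the up-to-20,000
  highest-amplitude ROI pixels whose complete footprint lies inside the map;
  ranking ties are broken by row-major order for determinism. Scatter is
  computed with plain (non-circular) arithmetic on the visual-angle field,
  which is delay-free and far from the wrap boundary — a stated limitation:
  the statistic is not meaningful for fields approaching $\pm 12.5°$.
  Footprints are constrained to the map, not to the ROI, so centers within
  two pixels of a responsive/unresponsive boundary mix in outside pixels;
  select the analysis region accordingly.
* **Magnification factor** (`compute_magnification`): along the
  steepest-ascent line (perpendicular to the fitted zero line, through its
  centroid), the sub-pixel positions where the field attains $-5°$ and $+5°$
  are located by bilinear interpolation; the magnification is 10° divided by
  their separation in mm. The 10° span is configurable (`span_deg`). The
  profile is sampled at quarter-pixel steps and each level's crossing nearest
  the centroid is used, which makes the measure robust to noise far from the
  zero line. Flat maps and unattained levels are hard errors, not NA.

# The synthetic-data generator

The generator is first-class, tested code: it defines the conditions under
which every closed-loop claim holds.

* The position field is **planar** — a linear phase gradient whose zero line
  makes a configurable angle with the reference axis and whose gradient
  magnitude is the magnification. A plane is the minimal structure that
  exercises a line-angle metric, a local-deviation metric and a gradient
  metric; real maps curve at area boundaries, which no test here probes.
* Noise is i.i.d. Gaussian per pixel and frame; drift is a per-pixel
  quadratic polynomial; an optional spatially uniform oscillation at the
  stimulus frequency models the constant bias that reference-region
  subtraction removes; an optional high-amplitude stripe outside the ROI
  models a surface vessel. Breathing, eye movements and hemodynamic
  nonlinearity are deliberately not modelled, so passing tests demonstrate
  algorithmic correctness, not robustness to every physiological artifact.
* Acquisition geometry defaults — 64×64 pixels at 0.01 mm/pixel, 10 Hz frame
  rate, 0.125 Hz stimulus (80 frames/cycle), 6 cycles, a centered disk ROI of
  radius 24 pixels, 50° sweep per cycle, 40 phase-degrees of hemodynamic
  delay — are configuration, not claims: the experimental literature does not
  fix them, and they were chosen once as a realistic mouse-imaging geometry
  whose ROI stays inside the unambiguous $\pm 12.5°$ phase range at
  magnifications near 45 deg/mm. Tests use a 32×32, 3-cycle variant of the
  same geometry to keep runtimes in seconds.
* VEP epochs use a negative-then-positive difference-of-Gaussians template
  (trough 80 ms, peak 160 ms) normalized to unit peak-to-trough, so the
  average of noiseless trials recovers the requested amplitude exactly. ERG
  traces place an a-wave trough (20 ms) and b-wave peak (80 ms) after the
  flash; component weights are calibrated by a small fixed-point iteration so
  the realized baseline-to-trough depth and trough-to-peak rise equal the
  requested amplitudes to machine precision, with the depth measured against
  the same 50 ms pre-flash baseline the scorer uses. Under the trough-to-peak
  convention a request with `b_amp < a_amp > 0` is geometrically infeasible
  (the trace must return toward baseline) and is rejected.

# Electrophysiology scoring

VEP amplitude is `max - min` of the trial-averaged trace over a 0–250 ms
post-reversal window (configurable; the convention is not standardized).
The contralateral bias index is the contralateral/ipsilateral amplitude
ratio per animal; response curves are normalized to a reference condition
(lowest spatial frequency, or 100% contrast), and the blank-screen condition
provides the noise floor. Note that peak-to-trough scoring of a noisy
average is positively biased by the extreme-value statistics of the residual
noise — the bias shrinks as $1/\sqrt{n_\text{trials}}$ and is bounded by the
envelope $2\,(\sigma/\sqrt{n})\sqrt{2\log n_\text{samples}}$, which is what
the recovery tests assert.

ERG a-wave amplitude is baseline-to-trough; b-wave amplitude is
trough-to-peak by default (the standard convention), with a
`baseline_to_peak` switch since published reports do not always state their
choice. The baseline is the mean over the 50 ms before the flash. A flat
trace scores (0, 0) with an `NA` a/b ratio and a warning rather than a hard
error, so degenerate conditions remain representable in feature tables.

# Group statistics

`t_from_summary` computes $t = (m_1 - m_2)/\sqrt{\mathrm{SEM}_1^2 +
\mathrm{SEM}_2^2}$ with $df = n_1 + n_2 - 2$. This SEM-quadrature form (not
the pooled-variance form, available via `pooled = TRUE`) is the one that
reproduces published t/df pairs computed from per-group SEMs.
`t_from_raw` computes the summaries and delegates, so the two are exactly
equal by construction.

`rm_anova_linear` implements the split-plot decomposition for a balanced
group × subject × ordered-condition table: the between-group F on subject
mean scores, and the within-subject linear trend tested by projecting each
subject's profile onto orthonormal linear-contrast coefficients
(`contr.poly`) and testing the squared grand mean of the projections against
their within-group variance — the contrast-specific error term, as in
standard repeated-measures contrast tables, not the pooled within-subject
error that `aov`'s polynomial split reports. Conditions are treated as
equally spaced ranks. A df = 1 contrast needs no sphericity correction.
p-values are reported from the t and F distributions, but comparisons across
groups should be made on the statistics.

# Numerical choices and limitations

* Determinism: all generators take explicit seeds and restore the caller's
  RNG state; amplitude-ranking ties break by row-major order; rerunning a
  pipeline stage on the same inputs is byte-identical.
* Degenerate inputs: zero traces report phase 0 by convention; an empty
  reference region, a missing zero crossing, a flat map, and off-bin
  frequencies are explicit errors with named causes.
* The scatter statistic is reported in visual degrees. Published scatter
  values of similar magnitude often omit their unit; no attempt is made to
  match any particular printed scatter value, and the SD uses the $n-1$
  denominator.
* Imaging stacks are stored as 32-bit float multi-page TIFF rescaled to
  [0, 1] with scale/offset in the YAML sidecar; round-trip error is at the
  float-precision level (~1e-7 of the intensity range) and does not affect
  any metric at the tolerances tested.
* Problem sizes: tests run 32×32 sessions with 3 stimulus cycles;
  closed-loop acceptance checks use the full 64×64, 6-cycle default
  geometry. Both complete in seconds on one core.

# A worked closed loop

```{r closed-loop}
gt <- imaging_ground_truth(tilt_deg = 25.7, magnification_deg_per_mm = 44.8)
ses <- simulate_imaging_session(gt)
map <- retinotopic_map(ses)
map_metrics(map, disk_mask(64, 64, 24))
```

The recovered tilt and magnification match the generating parameters to the
sub-degree / sub-percent level, and the scatter of the noiseless planar map
is at numerical zero.
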