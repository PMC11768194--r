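---
title: "Methods: crumb imaging, colour difference and MixoLab parameterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crumb imaging, colour difference and MixoLab parameterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crumblab)
```

crumblab packages the computational workflow of composite-flour bread
studies. This vignette explains each model, the conventions and tunable
parameters, what the synthetic generators do and do not emulate, and the
design choices made where the methodology was genuinely open.

## 1. Crumb cell structure

### Model

A bread-slice photograph is reduced to a grey matrix (BT.601 luminance
for RGB input) plus a *slice mask* separating bread from the removed
background. Background removal is emulated, not re-implemented: the mask
is taken from an alpha channel when present, or from near-white pixels
(`white_cutoff`, default 250 of 255) left behind by manual background
removal, matching slices photographed on a white matte surface.

Pores are darker than the crumb matrix, so segmentation is a global
intensity threshold chosen by **between-class variance maximization
(Otsu)** over the within-mask histogram. Two numerical details matter:

* The histogram is restricted to the mask, so the white background cannot
  bias the threshold.
* The threshold is *computed* on a 3 × 3 box-denoised copy but *applied*
  to raw pixels. Without denoising, a scene with few pores and strong
  sensor noise gives the degenerate Otsu solution that splits the matrix
  noise itself (between-class variance of splitting a Gaussian at its
  mode grows with its SD, and with a ~1 % pore fraction the true split
  no longer dominates). Classifying raw pixels keeps clean images
  pixel-exact. A 2-means threshold is available via
  `size_class_config(method = "kmeans")`.

Connected components are labelled at 8-connectivity by default
(diagonal-touching pores merge; configurable to 4), components below
`min_area` (default 2 px², a single-pixel noise floor) are discarded, and
the survivors are counted in three area bands. The band boundaries are
**explicit configuration** — `small_max` 100 px² and `medium_max`
1000 px² at the reference resolution — because no physical calibration is
assumed; they are reported inside every `pore_statistics` object. Pixel
units are primary; px-per-mm is optional metadata. Border-touching pores
are counted and flagged, not excluded.

Density descriptions: porosity = pore area / slice area, mean pore area,
and pores per 10⁴ slice px². The colourmap render maps each region's area
through a per-image min–max normalization onto a 256-entry palette, so a
region of a given area can legitimately receive different colours on
images with different area ranges; all-equal areas map to the midpoint
colour.

### What a green test establishes

The generator (`generate_crumb_image()`) plants non-overlapping disks
with lognormal radii (median 8 px, σ = 0.4) inside an elliptical slice,
with matrix/pore intensities 200/120, optional linear illumination
gradient, and additive Gaussian noise clipped to [0, 255], applied inside
the slice only. Non-overlap enforces centre distance ≥ r₁ + r₂ + 3 px;
the 3 px margin guarantees that *rasterized* disks are never 8-adjacent,
otherwise two planted pores could merge into one true component and exact
count recovery would be ill-posed. Ground truth is derived from the
noise-free label mask, so pore-area conservation is exact by
construction.

Real crumb is not a Boolean disk model: cells are anisotropic, walls have
texture, illumination is uneven, and pore intensity overlaps matrix
intensity. A green segmentation test therefore establishes that the
*algorithmic chain* (threshold → labelling → region analysis → bands) is
correct and noise-robust within the stated regime (intensity gap ≥ 60
grey levels, noise SD ≤ 10), not that any photograph of bread will be
segmented perfectly.

## 2. Colour difference

Replicate sensor readings are averaged channel-wise per measurement
group. The total colour difference is CIE76,
\[ \Delta E = \sqrt{\Delta L^{*2} + \Delta a^{*2} + \Delta b^{*2}}, \]
against the 0 %-substitution control of the same material. CIE76 is the
primary implementation because it is the formula the workflow defines;
CIEDE2000 (Sharma–Wu–Dalal formulation, validated against the published
reference pairs) is offered behind `method = "ciede2000"` and is never
the default.

The five perceptual bands are implemented half-open,
[0,1), [1,2), [2,3.5), [3.5,5), [5,∞) — imperceptible, slight,
noticeable, substantial, distinct — with **boundary values assigned to
the upper band**. The prose convention writes open intervals on both
sides and leaves boundary membership undefined; a total, disjoint cover
of [0, ∞) requires a choice, and "upper band" is the conservative one
(a boundary difference is treated as the more visible class).

Substitution-level trends (`fit_color_trend()`) are ordinary least
squares with the slope standard error and Pearson *r*; exactly constant
responses return slope 0 with *r* defined as 0 (the sample correlation is
otherwise undefined there).

## 3. MixoLab curve parameterization

### Phases and landmarks

The Chopin+ protocol is modelled as constant-temperature kneading
(default 8 min at 30 °C), a heating ramp (2 °C/min mixer program) to
90 °C, a hold, and cooling to 45 min total. The extractor detects phases
from the **recorded temperature column**, so a curve from any protocol
variant parameterizes correctly as long as the column shows the ramp and
hold.

The raw torque trace oscillates with the kneading action, so landmarks
are read from a rolling-mean envelope (default 30 s) of a lightly
denoised trace (7 s running mean). Envelope smoothing biases extrema and
crossings in a way that is *known*: a box filter of variance *v* maps
*f* to *f + f″v/2* to first order. All refinements therefore use local
polynomial fits with this bias subtracted — peak values are raised by
*f″v/2*, crossing times solved at the adjusted level. This keeps every
torque landmark within ±0.01 Nm and every time within ±0.1 min on
noiseless synthetic curves while remaining stable under 0.01 Nm noise.

Conventions, each configurable in `extraction_config()`:

* **T_hydr** — the instrument literature names but does not define it;
  implemented as the first crossing of `hydration_fraction` (default
  0.5) of C1, flagged in the printed output.
* **Stability** — time the envelope stays ≥ (1 − `stability_tolerance`)
  · C1, default tolerance 0.11 (the Chopin convention; the band depth is
  not otherwise documented). The window is the contiguous interval
  around T1 and may extend past heating onset: published parameter sets
  (e.g. T_hydr 3.6 min, stability 7.0 min, heating at 8 min) are
  arithmetically impossible inside the mixing phase alone, and on the
  instrument the dough does hold its consistency into early heating.
* **Amplitude** — dough elasticity, the peak-to-peak width of the mixing
  oscillation, estimated as 2√2 × RMS of the raw-minus-envelope residual
  over the minute before T1, with the noise floor measured on the
  oscillation-free cooling segment subtracted. A plain upper-minus-lower
  envelope difference is biased upward by roughly twice the extreme
  value of the noise per window (≈ +0.04 Nm at 0.01 Nm noise), which
  would dominate the quantity itself; the RMS estimator is exact for a
  sinusoid and nearly unbiased under noise.
* **Slope-α / slope-β** — least-squares slopes of the envelope from
  heating onset to t(C2) and from t(C2) to T3, in Nm/min (table
  convention; an Nm/s figure appearing in running text is treated as a
  unit slip). Full-interval least squares is used instead of two-point
  differences for noise robustness.
* **Gelling mid-point** — temperature at the first crossing of torque
  level (C2 + C3)/2 between t(C2) and T3, i.e. where the gelatinization
  rise is half complete.
* **C5** — a local linear fit of the raw torque over the final window
  evaluated at the last sample (the centered envelope is truncated at
  the record edge and would read low on a rising tail).
* **Water absorption** is the instrument's dosing to reach the target C1
  and cannot be recovered from a torque trace; it is metadata.

Degenerate input degrades gracefully: a flat zero-torque record reports
C1 = 0 with T_hydr absent; a record with no temperature rise reports
only mixing-phase features, with the heating-phase fields `NA`.

### The generator and the temperature warp

`generate_torque_curve()` inverts those definitions: a shape-preserving
piecewise-cubic (PCHIP, Fritsch–Carlson slopes with zeroed derivatives at
interior extrema — R's `monoH.FC` overshoots at direction changes and
cannot be used) passes through anchors at the start torque, the T_hydr
crossing, the stability band crossings (placed at T1 − 0.2·stability and
T1 + 0.8·stability), C1 at T1, C2, the (C2+C3)/2 crossing, C3 at T3, C4
at the hold midpoint, and C5 at the end. Shoulder anchors after T1 and
T3 mirror the left-side slope of each peak so that the smoothed argmax is
not dragged onto a one-sided plateau, and an approach anchor before the
stability down-crossing guarantees a clear slope there (a near-flat
tangent would make stability hypersensitive to tiny torque errors). The
mixing oscillation is a 0.5 min sinusoid, full amplitude during kneading
and cosine-tapered over the last 30 s before heating onset.

One deliberate deviation: published parameter tables print gelling
mid-points of 66–70 °C together with T3 ≈ 22 min, which a literal 30 °C +
2 °C/min mixer schedule cannot reach before T3 (57 °C at 22 min). The
recorded dough temperature lags the mixer program, so the generator's
temperature column follows the protocol schedule *warped through one
anchor*: it passes through (t, gelling_mid) exactly where the torque
path crosses (C2+C3)/2, staying piecewise linear and monotone during
heating. Slope-α and slope-β are consequences of the anchor geometry
rather than round-trip inputs: a curve cannot in general pass through all
torque anchors *and* realize two prescribed least-squares slopes, so the
generator accepts them as metadata and the round-trip contract covers
torque values, times, stability, amplitude and the gelling mid-point.

Generator preconditions (C2 ≤ C1 and below the stability band, C2 < C3,
T1 inside kneading, the stability window fitting between T_hydr and T3,
gelling mid-point between start and peak temperature) are checked with
errors naming the violated ordering. One bundled reference row (5 %
Cavendish) prints T_hydr > T1 and is rejected by design — hydration
completing after the development peak is not representable by a monotone
rise.

## 4. Group statistics

`one_way_anova()` is the classical between/within decomposition;
`tukey_letters()` computes studentized-range adjusted p-values (exact
balanced Tukey HSD; Tukey–Kramer standard errors applied automatically
when group sizes differ, n = 3 throughout the intended use) and a
compact letter display via insert-and-absorb. The letter invariant —
two groups share a letter *iff* their adjusted p ≥ α — holds exactly and
is tested exhaustively against the pairwise matrix. Letters are ordered
by descending group mean ("a" = highest), matching the usual table
style. With zero within-group variance everywhere the F statistic is
undefined: a warning is emitted and p is reported as 0 when means differ
(the difference is then exact) and 1 when all observations are
identical, so an all-constant dataset letters every group "a".

## 5. Pipeline and I/O

`run_pipeline()` ties the stages together from a JSON/YAML config:
per-sample pore statistics + MixoLab vectors + colourmap renders,
group-level ΔE against the reference group, and one mean ± SD + letters
table per metric. Per-sample failures are isolated and reported; the CLI
exits non-zero when any occurred. Outputs are bit-identical across
re-runs with the same config and inputs, except the timestamp line in
`run.log`; every output records the seed. Floats are serialized with 12
significant digits.

Formats: PNG and JPEG images (plus plain ASCII PGM/PPM so fixtures can
be text); TIFF is not supported in this build because no TIFF codec is
available. Label masks are 16-bit ASCII PGM — the available PNG writer
quantizes to 8 bits, which would corrupt label ids above 255. Torque
curves are CSV with header `time_min,torque_nm,temp_c`; colour readings
CSV with `group,replicate,L,a,b`.

## 6. Known limitations

* The Boolean disk model understates the difficulty of real crumb
  segmentation (anisotropic cells, shading, texture); robustness claims
  hold for the stated intensity-gap/noise regime only.
* Torque curves are phenomenological anchor interpolations; no dough
  viscosity or heat transfer is simulated, and slope-α/β are emergent
  rather than controlled.
* The Mixolab sampling rate is not documented; 1 s is assumed and
  configurable.
* Otsu assumes a bimodal within-mask histogram; heavily under- or
  over-proofed crumb with a continuous pore-size gradient may need the
  k-means alternative or manual thresholds.
* Water absorption, being instrument dosing, is carried through
  unchanged; the package cannot validate it.
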