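---
title: "Quantifying T-tubule architecture and L-type calcium channel activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying T-tubule architecture and L-type calcium channel activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttquant)
```

Cardiomyocyte T-tubules form a near-periodic lattice of membrane
invaginations spaced roughly 2 µm apart along the Z-lines. L-type calcium
channels (LTCCs) cluster at their openings, where they face ryanodine
receptors across the junctional membrane complex. `ttquant` quantifies this
architecture from four kinds of raw data — stained images, scanning ion
conductance microscopy (SICM) height maps, cell-attached and whole-cell
patch-clamp sweeps, and proximity ligation assay (PLA) images — and carries
the group comparisons that studies of this system publish. This vignette
explains the models and procedures behind each stage, the tunable
parameters, what the synthetic-data generator does and does not emulate,
and the numerical choices made where the field's conventions leave room.

## Striation density and the power of regularity

A stained image is analysed inside a rectangular region of interest,
conventionally 5 × 40 µm with the long side along the cell's long axis
(`select_roi()` refuses out-of-bounds regions rather than clipping
silently). The ROI is binarized — Otsu's threshold by default, a fixed
threshold as an override, and an `invert` flag because whether stain
renders bright or dark depends on the acquisition; the threshold actually
used is always recorded in the result. Two metrics follow:

* **Density**: the fraction of pixels on the stained phase, in [0, 1].
* **Power of regularity**: the binary mask is collapsed to a longitudinal
  waveform (the mean of the mask across the short axis — averaging the full
  width smooths over local stripe interruptions, and makes the waveform's
  mean equal the density exactly), the mean is subtracted, and the waveform
  is Fourier-transformed. The regularity power is the maximum spectral
  power in a band around the sarcomeric spatial frequency f₀.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| `f0` | 0.5 cycles/µm | reciprocal of the ~2 µm transverse tubule spacing |
| `band_halfwidth` | 0.1 cycles/µm | the spacing is only approximately 2 µm; a band maximum is robust to period jitter |
| window | rectangular | no taper keeps peak power comparable across cells; Hann available for spectra with strong leakage |
| normalization | power = \|X\|²/n², one-sided | the one-sided power sums to the profile's population variance (Parseval), which the tests verify against an O(n²) direct transform |

Mean (DC) removal matters: without it the DC bin dominates and the band
maximum near f₀ can pick up leakage from it. A profile must cover at least
one period of f₀ (4 µm at the default; the conventional 40 µm ROI gives a
frequency resolution of 0.025 cycles/µm).

## T-tubule openings in SICM topography

SICM yields a height grid (nm) of the live cell surface; T-tubule openings
appear as well-shaped depressions. Published work reports the opening count
per 100 µm² (a 10 × 10 µm scan) and whether openings are organized in
regular rows. The detection procedure here is:

1. **Reference surface**: a rolling median (window 2 µm) of the height map.
   Detection against this reference is invariant to constant offsets and
   insensitive to tilt and slow curvature of the cell surface.
2. **Matched smoothing**: the depth map (reference − height) is averaged
   with a box filter about the size of an opening (0.3 µm default) before
   thresholding. A well several pixels wide keeps nearly its full depth
   while single-pixel roughness spikes are suppressed; without this step a
   lone noise pixel occasionally crosses the depth threshold and inflates
   the count.
3. **Threshold and label**: connected regions deeper than
   `depth_threshold_nm` (50 nm default — well below the hundreds of nm of a
   true opening, well above membrane roughness) with area of at least
   `min_area_um2` (0.01 µm²) become openings; regions with centroids closer
   than `min_separation_um` (0.5 µm) merge, since a single mouth can
   fragment at threshold.

Each opening carries its centroid (µm from the scan's top-left corner, x
rightward, y downward), depth (scan median height minus region minimum) and
area. Density is `count × 100 / scan area`.

**Regularity** follows the "at least four aligned openings" rule: a scan is
regular when some subset of ≥ 4 openings fits a straight line with every
member within `lateral_tol_um` (0.35 µm default, about one opening radius)
of it. The search in `classify_regular()` is exact, not heuristic: a
maximal set of points inside a strip of width 2·tol can always be realized
by a strip with two points on one boundary (candidate direction = the pair
direction) or one point on each boundary (the two orientations where a
pair spans the strip exactly); scanning those O(k²) candidate orientations
with a sliding window over normal projections therefore finds the true
maximum. The test suite confirms agreement with an exhaustive
subset-enumeration oracle. An optional `spacing_tol` additionally demands
roughly even spacing along the line; it is off by default because the
published rule is about alignment only.

## Single-channel analysis

**Pipette geometry.** For a conical tip, pipette resistance and tip inner
diameter are linked by R = (π · d/2 · tan(φ/2) · p)⁻¹ with cone angle
φ = 3.8° and pipette-solution conductivity p = 1.8 S/m as defaults.
`pipette_diameter()` and `pipette_resistance()` are exact algebraic
inverses (the tests check the round trip at machine precision); a 100 MΩ
pipette has d ≈ 0.107 µm and a flat-disc patch area of π(d/2)² ≈ 0.0089 µm².

**Idealization** (`idealize_trace()`) uses the field-standard multi-level
half-amplitude rule: the baseline (median of the pre-step segment) is
subtracted and each sample is assigned the integer open-channel level whose
current k·i is nearest — thresholds at (k + ½)·i. The unitary current i is
taken from metadata when known, otherwise estimated as the spacing of the
two lowest-|current| modes of the all-points histogram of the step segment.
Dwells shorter than `min_dwell_samples` (2) are absorbed into the preceding
level, which removes noise flicker; at a signal-to-noise ratio of 5 this
lifts per-sample agreement with the simulated ground truth above 99%. When
|i| does not exceed 3× the baseline noise SD (estimated by MAD), the result
is flagged `low_confidence` with a warning rather than silently returned.

**Channel count and open probability.** N is the maximum simultaneous open
level across sweeps — it never exceeds the true count, and reaches it with
probability → 1 as recording length grows (for 5 channels at Po = 0.5 over
20 s, the closed-loop test observes no misses in 100 recordings). Po at the
step potential is NPo/N: the summed open counts over all step samples
divided by N times the number of step samples.

**Channel density.** Densities pool patches: ΣN over the total membrane
sampled. Two normalization conventions circulate — per summed tip *area*
(flat-disc π(d/2)², giving channels/µm², the units in which densities are
reported) and per summed tip *diameter* (channels/µm, the literal reading
of some methods texts). The two differ by a factor with units of length,
so they are not interchangeable; `channel_density()` defaults to the area
convention for unit consistency with published channels/µm² values and
implements the diameter convention as an explicit option, recording the
convention in its output. The inclusion rule for Po statistics is N ≥ 1
(patches with at least one channel).

**Whole-cell I–V.** Per step voltage, the peak inward current is the
minimum of the baseline-subtracted step segment; dividing by the measured
capacitance (always an input, never estimated) gives pA/pF. No leak
subtraction or liquid-junction correction is attempted.

## PLA density

PLA staining density is the area covered by signal normalized to the cell
area. The threshold (Otsu by default, fixed as override) is computed from
the intensities *inside* the supplied cell mask only, so bright debris
outside the cell cannot shift it, and it is applied per image. Note that
Otsu assumes a bimodal intensity distribution: an image with no true signal
still gets split somewhere inside its noise, so for signal-free controls a
fixed threshold is the right tool. Thresholding per image (rather than one
global threshold across conditions) is the default and is recorded in the
output.

## The statistical layer

Group results are means ± SEM with n; the SD is reconstructable as
SEM·√n, which is what makes tests from printed summaries possible.

* `ttest_from_summary()` — unpaired two-tailed t-test from two summaries.
  Default is the pooled-variance Student form (df = n₁ + n₂ − 2), matching
  the convention of the studies this package serves; Welch–Satterthwaite is
  available and labelled in the output. When summaries are computed from
  raw samples the Student path reproduces `t.test(var.equal = TRUE)` to
  10⁻¹⁰.
* `anova_mc()` — one-way ANOVA from raw vectors or summaries (raw groups
  are reduced to summaries; the F statistic depends on the data only
  through means, SDs and sizes, so the two routes agree exactly). Post hoc:
  Tukey–Kramer via the studentized range (matches `TukeyHSD()` on raw
  data), or Bonferroni for selected comparisons (raw p × number of
  comparisons, capped at 1). The family-wise type-I error of the Tukey path
  calibrates at the nominal 0.05 in a 5,000-replicate null simulation.
* `fold_change()`, `significance_stars()` — the stars follow the figure
  convention *, **, *** at 0.05, 0.01, 0.0001.

The analysis unit is whatever the caller passes; studies in this area
typically average about five cells per isolation and compare per-isolation
means, and the summary-based interface supports exactly that without any
hierarchical modelling (mixed-effects models are out of scope).

## The synthetic-data generator

Every input modality has a generator, a pure function of its parameters
and one integer seed (bit-identical output, caller's RNG untouched). The
generators exist to close the loop: the core test surface of the package
is that each analysis module recovers the parameter that generated its
input.

* **Striated images** (`gen_striation_image()`): transverse stripes of
  period 2 µm (the tubule spacing) and width 0.6 µm on an 80 × 20 µm,
  0.1 µm/px canvas, so the 5 × 40 µm ROI always fits. The remodelling
  parameter deletes stripe segments block-wise (1 µm blocks), mimicking the
  patchy loss of striation in cultured myocytes while preserving the
  remaining stripes' intensity; `remodel_fraction` 0 → perfect periodicity,
  1 → pure background. Mean regularity power decreases strictly across
  remodelling fractions {0, 0.25, 0.5, 0.75, 1} (50 seeds each in the
  tests), mirroring the fresh > overexpressing > control ordering of
  published groups.
* **Topography** (`gen_topography()`): a rough surface (SD 10 nm — smooth
  sarcolemma) with parabolic wells 150 nm deep and 0.3 µm in radius. Well
  count is Poisson with mean rate × area/100; `regular_rows` places wells
  on a jittered lattice (rows 2 µm apart — the Z-line spacing — and 1.5 µm
  along rows), `random` uses hard-core uniform placement. The detector
  recovers programmed counts exactly across seeds and rates 2–20 per
  100 µm², the span of published fresh vs cultured values.
* **Gating currents** (`gen_patch_trace()`): each channel is an independent
  two-state (closed ↔ open) continuous-time Markov chain — the minimal
  scheme that exposes Po and N to estimation; the kinetic scheme is not
  itself a claim about LTCC gating. Dwell times are sampled exactly from
  their exponential distributions and the state is then read at the sample
  instants, avoiding the bias of per-sample transition simulation at
  coarse rates; a warning fires when mean dwell falls under two samples.
  Channels gate only during the activating step (holding −96.7 mV, step
  −6.7 mV defaults) and superpose linearly: unitary current −1.2 pA, noise
  SD 0.15 pA. Stationary per-channel Po is open_rate/(open_rate +
  close_rate); simulated traces start closed at step onset, and the
  relaxation transient biases the time-averaged Po by ~Po/(λT), negligible
  for the 10–20 s test sweeps.
* **PLA images** (`gen_pla_image()`): an elliptical cell (semi-axes
  25 × 8 µm) with non-overlapping bright puncta of radius 0.25 µm whose
  centres keep whole discs inside the mask, so programmed coverage equals
  the pixelized disc area exactly in the noise-free case.

What the generators deliberately do **not** emulate: optics (no point
spread function, no depth blur), photobleaching or uneven illumination,
SICM scan artefacts (line noise, pipette convolution), multi-state or
voltage-dependent gating kinetics, channel rundown, and spatial
correlation between modalities in one cell. Passing closed-loop tests
therefore demonstrates that the estimators are correct and calibrated on
data satisfying their assumptions — not that those assumptions hold on any
particular microscope or rig.

## Numerical choices and degenerate inputs

* Otsu on a constant image is an error that names the fix (use a fixed
  threshold); blank PLA controls likewise need a fixed threshold.
* An all-flat scan yields an empty opening table, not an error; density 0.
* A patch with no channels returns Po = NA (a no-channel marker), never 0.
* `enforce_min_dwell()` resolves ties by absorbing short runs into the
  *preceding* level, iterating to a fixed point; a leading short run is
  kept since it has no predecessor.
* Problem sizes in the shipped tests: 40 µm (400-sample) profiles, 10 × 10
  µm (100 × 100 px) scans, 10–20 s sweeps at 2–5 kHz, 50–200 seeds per
  closed loop, 5,000 ANOVA null replicates — sizes at which every sampling
  oracle's 3·SE bound is tight enough to catch estimator bias of a few
  percent.

## Known limitations

The opening detector and the alignment rule are stand-ins for judgments
that published work often made manually; they are validated against
synthetic ground truth, not against any study's raw scans. The area
normalization for channel density treats the patch as a flat disc spanned
by the tip — a geometric idealization; the diameter convention is provided
for comparability with texts that use it. Striation analysis assumes the
ROI's long side is already aligned with the cell's long axis (no automatic
orientation detection), and the PLA module reports area fraction only — no
puncta counting or colocalization statistics.
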