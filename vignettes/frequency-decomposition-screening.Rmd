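---
title: "Frequency-decomposition screening from breast-surface vibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-decomposition screening from breast-surface vibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietdx)
```

## The screening problem

Digital Image Elasto Tomography (DIET) screens for breast cancer by shaking
the free-hanging breast sinusoidally at a known actuation frequency and
reconstructing the motion of ~14,000 surface reference points from camera
images. Tumors are 4--10 times stiffer than healthy tissue, and the natural
frequency of a vibrating element scales as $\omega = \sqrt{k/m}$, so tissue
over a lesion responds with spectral content elevated by
$\sqrt{k_\mathrm{tumor}/k_\mathrm{healthy}} \in [2, 3.16]$ relative to
healthy tissue — a far larger contrast than the 5--10% radiodensity contrast
mammography relies on. `dietdx` implements the complete decision pipeline on
top of reconstructed surface displacement data:

1. **Spectral reduction** (`extract_foi()`): each point's 3-D trajectory is
   projected onto its first principal axis, Fourier-transformed, and reduced
   to a *frequency of interest* (FoI).
2. **Segmentation** (`assign_segments()`, `segment_table()`): the surface is
   cut into 4 radial quadrants × 4 vertical (z) bands = 16 segments; FoIs
   are averaged per segment and across usable 20--23 Hz runs.
3. **Diagnosis** (`diagnose()`): within each z-band one radial segment acts
   as the control; any other segment deviating from it by more than a
   percentage tolerance calls the breast positive. Twelve control
   *configurations* probe robustness to lesion position.
4. **Evaluation** (`bootstrap_points()`, `fit_exponential_roc()`): a
   tolerance sweep traces a discrete ROC; resampling 50 breasts with
   replacement 200 times pools ROC points that are summarised by fitting
   $y = 1 - e^{-ax}$ by total least squares, with closed-form AUC
   $1 - (1 - e^{-a})/a$.

Because the diagnostic compares segments *within* one breast, it is
self-normalising: rescaling every frequency in a breast changes nothing, so
naturally stiff breasts are not penalised.

## The frequency-of-interest rule

At steady state the dominant spectral peak sits at the actuation frequency
and carries no diagnostic information; the second-dominant peak carries the
tissue response. The selection rule is:

* if the dominant peak differs from the actuation frequency by more than
  `match_tolerance` (default `max(0.5 Hz, one bin)` — the source method
  says "equivalent" without quantifying it), the point is *irregular* and
  its dominant frequency is used directly;
* otherwise the second-dominant peak is used, provided its magnitude is at
  least 15% of the dominant's; weaker second peaks mean the spectrum is too
  diffuse and the point is discarded.

Peaks are local maxima ranked by magnitude, with bins within
`exclusion_halfwidth = 2` of a selected peak ineligible so spectral leakage
shoulders of the actuation tone are never mistaken for the tissue response.
Ties rank the lower frequency first. The DC bin and (for even lengths) the
Nyquist bin are excluded as rigid-body-drift and aliasing guards. Zero or
constant trajectories are flagged degenerate, excluded and counted.

Whether the clinical pipeline transformed one Cartesian component, the
magnitude, or a projection is not stated in the source; the signed
principal-axis projection is this package's choice. It is well-posed here
because each point's motion is dominated by one direction, and the
projection keeps both tones of a two-tone signal (a property the test suite
checks against a direct-DFT oracle).

Runs are then filtered: a segment whose mean *dominant* frequency differs
from the actuation frequency by more than 2 Hz is irregular, and a run with
10% or more irregular segments is dropped. Only actuation frequencies in
the 20--23 Hz band enter the analysis.

## Segmentation conventions

* The top and bottom 5% of points by height are trimmed before
  segmentation (nearest-rank convention: exactly `floor(0.05 N)` at each
  end), removing the noisy chest-wall and actuator fringes.
* Radial quadrants come from the clock angle about the centroid axis with
  boundaries at the half-hour positions (1:30 / 4:30 / 7:30 / 10:30), so
  quadrant 0 contains 12 o'clock. Right-breast angles are mirrored so
  outer/inner quadrants compare consistently across sides.
* Z-bands split the retained points into four *equal-count* bands rather
  than equal-extent slices. The source does not say which; equal count is
  robust to the strong height gradient of point density on a pendant
  surface, and it is the convention all counts in the tests assume.
* Segments whose points were all excluded are missing, not zero; averaging
  across runs is cell-wise over present cells only, and a cell is missing
  only when missing in every usable run.

## The tolerance classifier

Deviation is measured relative to the control cell,
$|f_s - f_c| / f_c$, matching the published tolerance-band plots with the
control on the x-axis; a symmetric alternative (normalising by the pair
mean) is selectable. Default tolerances ship as the published optima:
0.34 for the optimal configuration and 0.33 for its opposite partner.

The twelve preset configurations are: ids 1--4 hold the control quadrant
fixed across bands; 5--8 advance it one quadrant per band; 9--12 retreat
one per band. The actual clinical layouts are not recoverable from the
published text, so this enumeration is a documented stand-in, and
`preset_configurations(file)` replaces it verbatim from YAML. A z-band
whose control cell is missing contributes no comparisons and is recorded
as indeterminate — never silently negative; a breast with all four
controls missing is indeterminate as a whole. OR-combination across
configurations ignores indeterminate outcomes unless all are.

## ROC evaluation

The bootstrap draws 50 breasts with replacement, 200 times, sweeping each
resample over the tolerance grid (default 0 to 1 in steps of 0.05).
A resample lacking one class contributes only its defined rate; such trials
are counted, and a redraw policy is deliberately not the default because
the resampling distribution should reflect the cohort.

The curve $y = 1 - e^{-ax}$ is fitted by total least squares: the sum of
squared *perpendicular* distances from the pooled points to the curve is
minimised over $a \in (0, 50]$. Each point's orthogonal projection onto
the curve is solved to ~1e-10 by a bracketing grid plus golden-section
refinement, and the outer problem by a deterministic log-spaced grid plus
bounded scalar minimisation. Whether the original fit anchored or weighted
the endpoints is unstated; this fit does neither.

The fitted AUC has the closed form $1-(1-e^{-a})/a$ — computed from the
curve, never from the discrete staircase. Note the family crosses the
chance diagonal at $a \approx 1.594$ (AUC 0.5) and tends to 0 as
$a \to 0$, so "AUC near 0.5" is the no-information regime. Operating
points:

* **optimal** — the point closest (Euclidean) to the ideal corner (0, 1),
  from the stationarity condition $x = a e^{-2ax}$ solved by bisection.
  This choice, rather than the Youden point, reproduces the published
  optimal sensitivity/specificity pairs from the published AUCs (for AUC
  0.85: 81%/75%), and is therefore taken as the intended definition;
* **at 80% specificity** — sensitivity $1 - e^{-0.2a}$ (criterion: ≥ 60%);
* **at 80% sensitivity** — specificity $1 - \ln(5)/a$ (criterion: ≥ 65%);
* the AUC criterion is strictly greater than the mammography benchmark
  0.73 (an AUC of exactly 0.73 fails).

## The synthetic phantom

The clinical recordings are access-restricted, so `synth_cohort()` builds
cohorts with the statistical structure the diagnostic assumes, giving every
downstream stage well-defined ground truth:

* **Geometry** — a pendant half-ellipsoid of revolution with height
  1.2 × equatorial radius, sampled quasi-uniformly; z = 0 at the chest
  wall. Volumes are drawn from the clinical spread (239.5--1057 cm³).
* **Signal** — per point, a primary tone at the actuation frequency
  (amplitude tapering with height) plus a secondary tone at
  `healthy_secondary_ratio` (default 1.5) × the actuation frequency,
  scaled by $\sqrt{1 + w(p)\,(k_\mathrm{ratio} - 1)}$ where $w(p)$ is the
  lesion's surface footprint weight. The secondary amplitude fraction
  defaults to 0.3, comfortably above the 15% retention threshold; setting
  it below 0.15 produces the "filtered out" regime. The source never
  states what physical signal the second-dominant frequency is; the
  two-tone model is an explicit assumption that directly instantiates the
  square-root stiffness scaling.
* **Noise** — Gaussian displacement noise everywhere, tripled inside the
  outer 5% height fringes to emulate the noisy chest-wall/actuator zones
  and exercise the trimming rule; per-point motion directions carry ≤ 10%
  off-axis jitter so the principal-axis projection is non-trivial.
* **Lesions** — one per cancerous breast, with stiffness ratio drawn
  uniformly from [4, 10]. `tumor_extent = "table1"` draws diameters from
  the clinical 7--48 mm range; `tumor_extent = "segment"` instead sizes
  the footprint to cover the segment containing the lesion centre (and
  snaps the centre into a quadrant), guaranteeing at least one segment
  sees the full $\sqrt{k_\mathrm{ratio}} \ge 2$ elevation while remote
  quadrants stay at baseline. The conditioned mode exists because a small
  lesion in a large segment dilutes the segment mean below detectability —
  with "table1" diameters the phantom reproduces exactly the
  small-tumor-miss behaviour one would expect, which is informative but
  not a controlled test of the decision logic.

What the phantom does **not** emulate: harmonic ladders or broadband
spectral content (the true clinical spectrum is unknown), damping and
hysteresis, wave reflection, breast concavities, camera/reconstruction
artifacts, or inter-breast correlation within a patient. Passing tests on
the phantom therefore validate the decision pipeline given the stiffness
model's assumptions — they are not evidence about clinical recordings.

## Problem sizes and reproducibility

The package's working defaults are 1,000 surface points per breast, 1 s
runs at 500 Hz sampling (1 Hz spectral resolution; Nyquist comfortably
above the highest synthesized tone at ~109 Hz), four runs at 20--23 Hz,
and a 13 + 13 cohort — small enough that a full simulate → evaluate cycle
runs in well under a minute while leaving ≥ 20 points per segment after
trimming. Clouds of 14,000 points are supported but not the default.
Every source of randomness descends from one integer seed through a
deterministic seed-derivation chain, so identical seeds give bit-identical
recordings, manifests, bootstrap draws and artifacts.

## Known limitations

* The 12 preset configurations are a reconstruction, not the published
  layouts; conclusions that depend on a specific configuration id should
  treat the id as a label, not an anatomical claim.
* The one-parameter curve cannot represent asymmetric ROC shapes — two
  cohorts with identical fitted AUC can differ in their sensitive/specific
  tails; richer forms are deliberately out of scope as they overfit small
  cohorts.
* The exponential ROC family maps AUC values below ~0.5 to parameters
  near 0; fits are only meaningful for better-than-chance classifiers.
* Tolerance sweeps are only as fine as their grid: when the deviations
  being classified are all smaller than the first non-zero grid step
  (e.g. a no-contrast cohort), the pooled points collapse onto the ROC
  corners and the fit degenerates; resolve the grid to the deviation scale
  of interest.
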