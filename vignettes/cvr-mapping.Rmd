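---
title: "Methods: cerebrovascular reactivity mapping with cvrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cerebrovascular reactivity mapping with cvrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvrkit)
```

## The measurement

Cerebrovascular reactivity (CVR) is the fractional BOLD signal change per
mmHg change in arterial CO2, an index of the vasodilatory reserve of the
cerebral vasculature. In a CO2-inhalation experiment the subject alternates
between breathing room air and a hypercapnic gas mixture in 60 s blocks
while BOLD fMRI is acquired and a capnograph records the CO2 content of
respired air at the mouth. `cvrkit` turns those two recordings into CVR
maps in three stages, plus a resting-state mode when no gas challenge is
available.

## Stage 1 — EtCO2 extraction from the capnogram

The capnogram oscillates once per breath; its upper envelope is the
end-tidal CO2 (EtCO2), the proxy for arterial CO2. The raw recording
(10–200 Hz depending on the monitor) is smoothed with a 100 ms moving
average and resampled to 10 Hz — breathing is slower than 0.3 Hz, so 10 Hz
over-resolves every breath while averaging sensor noise.

Two peak detectors with complementary failure modes run independently:

* **Scale-space**: all local maxima by the three-point criterion
  `v(n) = max[v(n-1), v(n), v(n+1)]`, re-detected after smoothing at 30
  progressively coarser scales (centered moving average of width `2k+1`
  samples at scale `k`). A maximum surviving a scale credits the nearest
  original candidate within ±2 samples; candidates scoring at least 15 of
  30 scales are kept. Noise spikes die after the first few scales; breath
  peaks persist.
* **Smooth-cross**: the trace is compared with its own 10 s moving
  average; each maximal run where the trace lies at or above the average
  brackets one breath, and the run's argmax is the breath's peak.

Each detector's peak values pass through a five-point median filter
(partial, shallow breaths produce isolated low peaks — replacing the value
rather than deleting the peak preserves the breath-time grid needed for
interpolation) and are then linearly interpolated to a uniform 1 Hz grid.
The final EtCO2 curve takes the *higher* of the two values at every grid
point, since the envelope is an upper bound and each algorithm can locally
undershoot it.

Summary statistics: `mean_etco2` is the arithmetic mean of the curve, and
`baseline_etco2` is the average of the lowest ⌈25%⌉ of values — a robust
stand-in for the room-air level that a single deep breath cannot drag down.
A baseline below 25 mmHg (strict) raises the *CO2-switching* warning: when
lung CO2 responds too slowly to the challenge, exhaled CO2 can transiently
fall below the inhaled level and the envelope no longer means end-tidal
CO2. This inversion cannot be detected automatically; the package only
warns and never auto-corrects.

### Numerical choices

* Moving averages shrink their window at the array ends, so constants are
  preserved everywhere.
* Plateaus of exactly equal samples count as one maximum, credited to
  their earliest sample; the first and last samples of the recording are
  never peaks.
* Before scale-space scoring the trace is extended by *point reflection*
  (antisymmetric) about its endpoints, by slightly more than the widest
  smoothing half-width. An even (mirror) extension merges a
  boundary-adjacent peak with its mirror image under wide smoothing and
  the pair's maximum migrates to the boundary itself, so real peaks within
  ~3 s of the recording edges would be scored down; the antisymmetric
  extension continues the breathing oscillation instead and scores
  boundary peaks exactly like interior ones.
* The scale-space score threshold (15/30) is exposed as a parameter. With
  a centered moving-average scale family, a peak of breathing period `T`
  stops being credited once the window exceeds `T` (the running mean
  inverts the oscillation), so breaths faster than ~3 s can fall below
  the default threshold in this detector alone; the smooth-cross detector
  and the max-combination cover that regime.
* The 1 Hz grid starts at the recording's first timestamp, shifted to 0,
  so temporal shifts are recording-relative seconds.

## Stage 2 — temporal alignment

EtCO2 is measured at the mouth and BOLD in the brain; the transit and
hemodynamic delay between them is found by shifting the EtCO2 curve
against the whole-brain mean BOLD time course under the linear model

    BOLD_t = beta1 * etco2(t + s)~ + beta2 * ell_t + beta0

where `~` denotes zero-meaning, and `ell` is the linearly ascending ramp
`-(N-1)/2, ..., (N-1)/2` absorbing scanner drift. BOLD frame `i` (0-based)
is assigned time `i * TR` (frame onset) and regressed on the EtCO2 value
at recorder time `s + i*TR`, by linear interpolation of the 1 Hz curve.

The search is two-step: a coarse 1 s scan over every feasible shift (0 to
recording duration minus BOLD duration; smallest shift wins ties), then a
0.1 s scan over ±5 s around the coarse optimum. The fine residual profile
is summarised by a second-degree polynomial and the vertex of a convex fit
is the final shift, giving sub-grid resolution.

The polynomial is fitted to the ±2 s band around the fine-grid argmin
rather than to the full ±5 s window. The residual-vs-shift profile is
approximately quadratic only near its minimum and V-shaped farther out;
fitting the whole window lets the asymmetric far field bias the vertex by
several tenths of a second, which a local fit avoids (the local fit also
measurably reduces the median shift error under noise). If the local fit
is not convex, the grid argmin is used with a warning. The fine window is
clipped at shift 0; candidate shifts beyond the recording end reuse its
terminal value, with a warning, and if fewer than five fine-grid points
are feasible the coarse optimum is returned.

The *partial correlation* between BOLD and the shifted EtCO2 — both
residualised against intercept and drift, consistently with the model —
is reported as the dataset quality index. Note that because the search
maximises the association over ~100 candidate shifts, its null
distribution is that of a maximum: values up to ~0.3 can occur on data
with no CO2 dependence at all.

A recording shorter than the BOLD series is an error by default; an
explicit opt-in (`allow_short_co2`) forces a zero-shift fit with the curve
end-padded by its final value, loudly logged.

## Stage 3 — CVR quantification

With the aligned regressor, coefficients convert to CVR in % BOLD change
per mmHg:

    CVR = beta1 / (beta0 - beta1 * (mean(EtCO2) - baseline(EtCO2))) * 100

The denominator is the modelled signal level at *baseline* CO2 (the
intercept refers to the mean of the zero-meaned regressor), so CVR is the
percent change per mmHg referenced to the room-air state. Denominators
that are non-positive or smaller than `1e-9 * |beta0|` give `NA` with a
warning (near-zero-signal voxels). No statistical thresholding is applied
to maps — CVR is reported as an effect size, not a test statistic.

* **Whole-brain**: model at the optimal global shift of the whole-brain
  mean time course.
* **Regional**: the EtCO2 curve is re-aligned to each ROI's mean time
  course with the full two-step search (white matter lags gray matter),
  then converted per ROI. ROIs under 10 voxels are flagged, not dropped.
* **Voxel-wise (global shift)**: one fit per voxel against the globally
  shifted regressor.
* **Voxel-wise (per-voxel shift)**: starting from the global shift, each
  voxel's shift is refined over an additional −5..+30 s at 1 s steps
  (earliest delta wins ties; the window is kept narrow so noise cannot
  pull the fit into distant local minima, and the step matches the 1 Hz
  EtCO2 rate — no polynomial refinement at voxel level, where SNR does
  not support it). The winning delta forms the *temporal shift map*, the
  analogue of a bolus-arrival-time map; deltas at the window edge carry a
  boundary flag.
* **Relative maps**: any map divided by its in-mask mean (`NA` voxels
  excluded), so the result has in-mask mean 1.

Because the model is linear with free intercept and drift, CVR is exactly
invariant to global intensity scaling and to adding any multiple of the
drift ramp; the test suite asserts both to 1e-6.

## Resting-state relative CVR

Without a challenge, spontaneous low-frequency CO2 fluctuations still
modulate BOLD. The whole-brain mean time course is linearly detrended,
low-pass filtered at 0.1164 Hz, and rescaled to zero mean and 2-norm
`sqrt(N)/2`; this *reference signal* replaces EtCO2 in a per-voxel model
with six zero-meaned motion covariates (when supplied), a linear trend and
an intercept. Relative reactivity is `100 * beta1 / beta0`; only the
relative map (divided by the in-mask mean) is meaningful in this mode, and
per-voxel scale conventions cancel in it. We therefore regress the raw
voxel series rather than a pre-normalised one: the two readings differ
only by per-voxel scale, which the normalisation removes.

The low-pass filter is an ideal frequency-domain projection: Fourier bins
with frequency magnitude at or below the cutoff are kept (cutoff bin
inclusive), the rest zeroed. A projection is exactly idempotent and
exactly testable — a passband sine on a bin passes bit-identically, a
stopband sine is annihilated. If less than 5% of the detrended RMS
survives the filter the build fails: valid resting-state data keep
essentially all their detrended power below 0.1164 Hz (>99% on the
package's phantoms), while degenerate inputs whose content lies entirely
above the cutoff retain only spectral leakage (~1%), so the guard
separates the two regimes by nearly two orders of magnitude. Motion
columns are zero-meaned so the intercept keeps its baseline-signal
meaning; constant columns are dropped, and a rank-deficient design is an
error.

## Preprocessing

Only what the pipeline needs: per-frame separable Gaussian smoothing
(FWHM in mm, default 8; `sigma = FWHM / sqrt(8 ln 2)` converted to voxels
per axis; reflective boundaries so edges are not darkened; FWHM 0 is the
identity), an intensity-based brain mask (threshold at half the 98th
percentile of the temporal mean, largest 6-connected component, interior
holes filled), and masked mean time courses. The mask is computed from the
smoothed series, matching the processing order of the map computations. A
user-supplied mask overrides the heuristic — the original pipelines build
the mask from tissue segmentation, which is out of scope here; for
whole-brain averaging and relative normalisation only the brain/background
split matters. Motion correction, slice timing, distortion correction and
any registration are likewise out of scope: the package consumes
motion-corrected series, optional motion parameters, and label images
already on the BOLD grid. ANALYZE images carry no orientation, so the
voxel grid is taken as stored and never re-oriented.

## The synthetic phantoms

`phantom_spec()` fixes the emulated study conditions: 64×64×10 voxels,
TR 2 s, 210 frames (a 7 min acquisition); 60 s alternating blocks at
40 mmHg (room air) and 48 mmHg (hypercapnia, a typical +8 mmHg challenge);
breath periods of mean 4 s truncated to the physiological 3–8 s range;
capnograph at 100 Hz with troughs at the inspired level (~1 mmHg);
a global lung-to-brain shift of 15 s; CVR 0.3 %/mmHg (a typical
gray-matter value); baseline signal 1000 inside a central brain box over a
background of ~10. Breaths are symmetric `sin(pi*phase)^0.5` bumps whose
plateau follows the block level; partial breaths halve the bump amplitude.
The contrast-to-noise parameter `snr` is the BOLD block contrast
`a*(cvr/100)*(hyper-baseline)` over the white-noise SD.

Two generator choices deserve emphasis because they determine what is
identifiable at all:

* **The gas paradigm is tied to the scan.** The capnograph starts before
  the scanner and the subject breathes room air until the paradigm begins
  at the BOLD start, returning to room air afterwards — as experiments
  are actually run. A phantom whose blocks alternate over the whole
  recording is periodic, and a periodic regressor makes the global shift
  identifiable only modulo the block cycle, with sign-flipped aliases at
  half-cycle offsets; the room-air lead-in/out breaks that symmetry.
* **Wash-in dynamics** (`washin_tau_s`). With instantaneous block
  transitions, a 1 Hz truth curve and TR 2 s, all shifts within a 1 s
  interval can produce bit-identical regressor samples, so sub-second
  shift recovery is ill-posed by construction. The default keeps
  transitions instantaneous (the truth stays an exact square wave, which
  the envelope-recovery checks rely on); studies of shift recovery set
  `washin_tau_s = 8` s, a few breaths' physiological equilibration, which
  makes the residual profile strictly convex around the true shift.

The resting-state phantom modulates every brain voxel by a latent
low-frequency signal (six sinusoids over 0.01–0.105 Hz with 1/f
amplitudes plus a small pink-noise floor, ~1% fractional amplitude) with a
per-voxel gain field as ground truth.

What the phantoms deliberately do **not** model: vascular dispersion of
the CO2 bolus (the shift is a pure delay), nonlinear hemodynamics,
anatomical structure, physiological noise spectra, and spatially
correlated noise. Passing recovery tests therefore demonstrates the
correctness of the estimators under the stated forward model, not
robustness to everything real data can do.

## Validation problem sizes

The test-suite and acceptance studies use: the full 64×64×10×210 phantom
at SNR 10 for voxel-wise CVR recovery (median relative error ~1%);
150-frame time-course phantoms for shift recovery across true shifts
{10, 47, 60.35, 90} s (noiseless error < 0.03 s; at SNR 5 the
within-1-second rate is ~90% over 400 independent repetitions — the
estimator is unbiased with median error ~0.37 s, and that rate is the
information limit of the residual profile at this noise level rather than
an implementation ceiling); 12×12 grids for the two-compartment shift-map
and resting-state recoveries, where recovery is exact respectively within
a few percent.

## Known limitations

* The intensity-based mask is a stand-in for tissue segmentation; supply
  a segmentation-derived mask for real data.
* Shifts are pure delays; dispersion mismatch biases CVR slightly
  downward on real data in a way the phantoms cannot reveal.
* The CO2-switching heuristic is a warning, not a detector: a genuinely
  low-baseline subject also trips it, and a switching subject with a
  normal baseline would not.
* The EtCO2 curve is interpolated between breath peaks, so a run of
  shallow (partial) breaths immediately before a block transition can be
  median-filtered to the wrong block's level and bias that block's mean
  by over 1 mmHg — an inherent limitation of breath-sparse interpolation
  at transitions.
* Absolute (mmHg-scaled) resting-state CVR is out of scope; only relative
  maps are produced in that mode.
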