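---
title: "Methods: burst-density signal strength and implant geometry for endovascular BCIs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burst-density signal strength and implant geometry for endovascular BCIs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

An endovascular brain-computer interface records field potentials from a
stent-mounted electrode array deployed in the superior sagittal sinus
(SSS), the large midline vein over the interhemispheric fissure. Because
the device cannot be placed surgically on a chosen gyrus, *where it ends
up* relative to motor cortex varies across users, and so does the motor
signal it picks up. This package implements the analysis chain that
quantifies that variability and asks which user-specific factors predict
motor signal strength:

1. a **motor signal strength** statistic from cued move/rest recordings
   (`neural_signal` functions),
2. **implant geometry** relative to the cortical surface
   (`fit_stent_line()`, `stent_to_cortex()`, `roi_overlap()`,
   `sinus_width()`, `cortical_thickness()`),
3. a **slice-based targeting** analysis of pre-implant functional
   activation (`center_of_gravity()`, `stent_slice_span()`,
   `stent_m1_slice_overlap()`),
4. a small-cohort **predictor screen** (`screen_factors()`,
   `lasso_select()`, `rank_tests()`), and
5. a **synthetic cohort generator** with planted ground truth
   (`generate_cohort()` and friends) that makes every stage testable
   without clinical data, which are not publicly available for this kind
   of study.

# The motor signal strength statistic

Participants are cued to attempt a movement for 10 s and then rest for
10 s, ten repetitions per test block. The statistic is computed per
block:

1. **High-gamma isolation.** Every channel is band-passed to
   100–200 Hz. The filter is a 4th-order Butterworth band-pass applied
   *zero-phase*: the squared magnitude response is applied in the
   frequency domain, which is the exact magnitude equivalent of a
   forward–backward (filtfilt) pass and preserves burst timing. Design
   uses `signal::butter()`; application is a DFT multiplication, chosen
   because blocks are long (200 s) and many channels are filtered.
2. **Burst detection.** The per-channel envelope is a centred moving RMS
   (window 20 ms). A burst is an envelope excursion above
   `median + k * robust SD` of the *baseline* envelope, lasting at least
   20 ms; excursions separated by less than 10 ms are merged. The
   baseline is the concatenated REST epochs of the same block, so each
   block is self-referenced and robust to slow drift; the robust SD is
   `1.4826 * MAD`. Default `k = 3`. These four constants are exposed in
   `signal_config()` — the underlying publication record does not fix
   them, so they are deliberately configuration, not constants.
   (Implementation note: baseline quantiles are estimated on a
   half-window stride of the baseline samples; the envelope is smooth at
   that scale, so the estimate is unchanged while large blocks stay
   cheap.)
3. **Epoch densities.** Each burst is assigned to the epoch containing
   its *onset*, with half-open `[start, end)` intervals so boundary
   events are counted exactly once. Density = count / epoch duration
   (bursts/s). Channel aggregation defaults to **pooled** (counts summed
   over active channels), since the index is computed across all live
   channels; `mean` and `best_channel` are available.
4. **Sensitivity index.** For move densities $m$ and rest densities $r$:
   $$d' = \frac{\bar m - \bar r}{\sqrt{(s_m^2 + s_r^2)/2}}$$
   with $n-1$ sample variances. If both variances vanish, $d'$ is 0 when
   the means agree and flagged infinite otherwise; flagged values are
   excluded from downstream correlations with a warning.

A participant's summary value is the **maximum** $d'$ over all blocks of
all sessions (`best_session_strength()`, ties to the earliest session):
the best block is the least contaminated by protocol drift across
sessions. `strength_vs_zero_test()` provides the per-participant exact
Wilcoxon signed-rank test against zero and refuses fewer than five
usable sessions, for which an exact test is uninformative.

# Implant geometry

The device is approximated by a **25 mm centerline**: starting at the
vessel-centerline point nearest (rostro-caudally) to the most rostral
point of the device segmentation, the line follows the centerline
caudally until its arc length reaches 25 mm, resampled at 0.5 mm
(51 points — sub-millimetre quadrature error). This models the device
centre, not individual electrodes, so distances are mean
device-to-cortex separations, not minimal electrode clearances.

* **Distances** (`stent_to_cortex()`): per line point, the nearest
  pial-vertex distance is found in each hemisphere separately — cortical
  folding can hide one hemisphere locally, so the two per-hemisphere
  nearest distances are averaged at each station; the minimum is global.
  Nearest-*vertex* (not point-to-triangle) distance is used; at the
  synthetic mesh resolution (1 mm) the difference is below the reported
  precision.
* **ROI overlap** (`roi_overlap()`): defined on the rostro-caudal axis
  only. ROI intervals come from labeled vertices within 15 mm of the
  midline (the "dorsal band"; configurable — no published value fixes
  the strip width). Vertex stations are treated as centres of axial
  cells and intervals extended by half the station spacing, so bands
  laid out on a cell-centre grid are recovered exactly and exhaustive
  disjoint bands sum to 100%.
* **Sinus width** (`sinus_width()`): twice the lumen radius sampled at
  the 51 line points, averaged.
* **Cortical thickness** (`cortical_thickness()`): mean per-vertex
  pial-to-white Euclidean distance over an ROI, both hemispheres.

# Slice-based targeting

The volume analysis works on coronal slices: half-open mm bins along the
rostro-caudal axis. The dorsal-strip activity profile is the mean
activation per slice; its **center of gravity** is the activity-weighted
mean station, with negative statistic values clamped to zero first (mass
must be non-negative; thresholding at z = 2.3 first is available as the
alternative). The stent's slice span is every bin its interval
intersects with positive measure; its midpoint maps to the slice whose
centre is nearest the interval midpoint, with a midpoint exactly on a
bin edge going to the even index (this reduces to "the bin containing
the midpoint" in all non-degenerate cases). The CoG-to-stent distance is
signed, positive when the activation centroid lies rostral of the
device. Overlap with M1 on the slice grid is a counting ratio over the
stent's slices.

# Predictor screen

The default predictor matrix has **16 factors** per participant: years
since diagnosis, residual muscle strength, active channel count; mean
fMRI activation and suprathreshold spread (z > 2.3, strict) in M1, S1
and SMA; mean stent-to-cortex distance, mean stent-to-M1 distance, SSS
width; rostro-caudal overlap with SMA, M1 and S1; and M1 thickness. The
original factor list is not published item by item; this set
reconstructs it from the quantities the analysis computes, and is
configurable.

* `spearman_cor()` uses midranks; for $n \le 9$ the two-sided p-value is
  **exact by full permutation enumeration** (valid under ties,
  conditioning on the observed midranks), above that the t
  approximation. The screen applies **no multiple-testing correction**
  by default — it is exploratory; Benjamini–Hochberg is a flag.
* `lasso_select()` standardises features to zero mean / unit variance,
  centres the response, and fits the L1 path with `glmnet`; the penalty
  is chosen by **leave-one-out** cross-validation (the cohort is tiny)
  with the one-standard-error rule. Zero-variance factors get
  coefficient zero; a constant response yields an all-zero report.
* `rank_tests()` wraps the exact/corrected-normal Wilcoxon signed-rank
  and Mann-Whitney tests. The normal approximation uses the continuity
  correction, which keeps it within 0.02 of the exact p at n = 12.

# The synthetic cohort

`generate_cohort()` creates, per participant: a folded two-hemisphere
surface (height-field sheets, sinusoidal folds, white surface offset
inward along the analytic normal so per-vertex thickness is exact by
construction); a midline sinus riding an attenuated version of the fold
profile with a stent segmentation scattered on the lumen wall; a
multichannel recording (pink 1/f noise with a white floor; active
channels carry Gaussian-windowed 150 Hz tone bursts of 80 ms at 5 times
the in-band noise SD, inserted at Poisson times whose rate switches
between rest and move epochs); an activation map; and covariates drawn
from the printed cohort ranges (years since diagnosis uniform 1–12,
integer muscle score 0–50, active channels uniform 9–16, lumen radius
around 3.55 mm so sinus width centres on 7.1 mm).

Two aspects of the generator's anatomy matter for the screen:

* **Per-participant band layout.** The M1 band's centre and width, the
  width of S1, and the premotor strip (labeled OTHER) separating M1
  from SMA all vary across participants. With one fixed layout, SMA
  overlap would be an exact deterministic complement of M1 overlap for
  every rostrally shifted placement and the screen could not
  distinguish cause from proxy even in principle.
* **Vertical anatomy.** The lumen centre sits 3–9 mm above the dorsal
  pial profile, varying across participants. This is what decouples the
  stent-to-cortex distance factors from rostro-caudal placement; with a
  fixed clearance, distance would be a pure function of placement and
  hence of overlap.

The **planted relation** is
`strength = a + b * (M1 overlap %) + noise`, mapped to the recording as
`move rate = rest rate + strength` (clamped at the rest rate). Defaults
`a = -0.5`, `b = 0.035`, `noise_sd = 0.1` over placements spanning the
full 0–100% coverage range (on both the rostral and the caudal side)
put minimal-coverage participants at the signal floor — move rate equal
to rest rate — and strong-coverage participants at a robust
~3 bursts/s contrast. This calibration makes the measured
overlap-to-strength rank correlation sit near 0.8–0.9, the association
structure the cohort is meant to emulate; with a visibly weaker planted
effect the ten-epoch sampling noise of $d'$ (relative SD roughly 20%
per block) dominates and no screen could recover the factor at n = 10.

Even so, the stent-to-M1 distance factor remains geometrically coupled
to M1 overlap (rank correlation around −0.9 across cohorts): both
measure proximity of the same device to the same band. In a minority of
cohorts that proxy — not the planted factor — tops the ranking; this is
a property of the geometry, not a defect of the screen, and the same
coupling exists in the real measurement problem.

What the generator does **not** emulate: anatomically realistic
gyrification or vascular tortuosity, hemodynamics, nonstationary or
artifact-laden recordings, referencing differences across devices, and
disease progression over time. Tests passing on this cohort therefore
validate the *analysis chain* — statistics, geometry, recovery of a
planted effect under realistic noise — not the clinical claims
themselves.

# Numerical choices and degenerate inputs

* Coordinates are RAS millimetres; rostro-caudal = y, anterior positive;
  slices are 0-based half-open mm bins.
* All generators take explicit integer seeds; a master seed fans out via
  `child_seed()` (a fixed Lehmer-style affine map below $2^{31}$), so
  any module can be re-run in isolation and full runs are bitwise
  reproducible (`run_end_to_end()` writes an md5 manifest).
* Degenerate cases: constant signals flag the channel rather than
  divide by a zero MAD; zero-mass profiles, empty ROIs, zero-duration
  epochs and exhausted centerlines raise informative errors;
  `validate_inputs()` reports structural violations without raising.
* Problem sizes: the default cohort is 10 participants with 16-channel,
  1 kHz, 200 s blocks. Property-style tests use scaled-down recordings
  (4 channels, 500 Hz, 4 repetitions) where only the statistical
  structure matters; oracle-agreement tests keep the full block
  structure. The end-to-end recovery check uses 50 seeded cohorts
  (plus null cohorts with `b = 0`).

# Known limitations

* The stent line models the device centre; per-electrode localisation
  is out of scope (as it is for the CT-based original).
* Vertex-based distances slightly overestimate point-to-surface
  distances at coarse mesh resolution.
* The burst detector's constants (threshold, window, merge gap) are
  conventions, not identified parameters; conclusions should be checked
  across a small grid of them for real data.
* With n = 10 and 16 screened factors, uncorrected exploratory p-values
  carry the usual multiplicity caveat — mirrored from the original
  analysis and flagged there too.
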