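---
title: "Models and methods behind capspec"
author: "capspec authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind capspec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(capspec)
```

This vignette explains the science and the numerical choices inside
`capspec`: the optical model, the kymograph velocimetry, the vasomotion
spectral analysis, the statistical tail, and the forward simulator that
validates all of them. It also records the design decisions that were
genuinely open and why they were settled the way they were.

## The optical model

Thin skeletal muscle can be transilluminated with negligible scatter, so
transmitted intensity follows Beer–Lambert attenuation:

$$\mathrm{OD}(\lambda) = \varepsilon(\lambda)\, L\, C, \qquad
I = I_0\, 10^{-\mathrm{OD}},$$

with $\varepsilon$ the hemoglobin extinction coefficient (per mM per
cm), $L$ the optical path (cm) and $C$ the hemoglobin concentration
(mM). Two consequences drive the whole package:

1. **At an isosbestic wavelength** ($\varepsilon_{HbO_2} =
   \varepsilon_{Hb}$) the OD is independent of oxygen saturation, so the
   change in OD relative to the first sample,
   $\Delta\mathrm{OD}(t) = \log_{10} I(t_1)/I(t)$, tracks microvascular
   hemoglobin content alone. The sign convention is chosen so that
   rising hemoglobin (darker image) gives rising $\Delta$OD.
2. **Across a saturation-dependent / isosbestic wavelength pair**
   (438/450 nm), the OD ratio of a single RBC is an affine function of
   its SO₂. `rbc_so2()` maps
   $R = \mathrm{OD}_{438}/\mathrm{OD}_{450}$ linearly between the
   calibration endpoints `ratio_deoxy` (SO₂ = 0) and `ratio_oxy`
   (SO₂ = 1) and clips to $[0,1]$. The endpoint values in a live
   preparation come from an in-vivo calibration; the package defaults
   (0.6 and 1.2) are configurable placeholders used *symmetrically* by
   the simulator and the analysis, so closed-loop recovery tests are
   meaningful regardless of their absolute accuracy.

The packaged extinction table
(`inst/extdata/hb_extinction_synthetic.csv`) holds approximate
literature-compilation values at 438, 450 nm and the six visible-band
isosbestic wavelengths (452, 500, 530, 545, 570, 584 nm). It is a
synthetic stand-in adequate for the forward model and unit checks, not a
reference dataset; users can substitute their own via
`hb_extinction(path)`.

Two $\Delta$OD routes are supported and deliberately kept at their
native sampling:

- **MFI**: mean over all pixels of each 450 nm video frame (1 min at 21
  frames/s). Saturated pixels (≥ 4095 at 12 bits) are excluded with a
  reported count.
- **CWS**: spectrometer intensities averaged within a 2-nm bandpass
  around each isosbestic wavelength (realized as the unweighted mean of
  grid samples within ±1 nm inclusive), converted to $\Delta$OD per
  wavelength, then averaged across the six. Averaging six bands with
  independent noise reduces the OD noise by about $\sqrt 6$, which the
  test suite verifies by Monte Carlo.

CWS timing jitters around 10–11 samples/s, so series are linearly
interpolated onto a uniform grid (`resample_uniform()`, default
10.5 Hz, no extrapolation) before Fourier analysis.

## Kymograph construction and velocimetry

`build_sti()` samples each frame bilinearly at equal arc-length steps
(default: one pixel, 0.6466 μm) along the capillary centerline,
arteriolar end first; each frame contributes one column. Moving RBCs
absorb strongly at both wavelengths and appear as dark sloped tracts.

**Incident intensity.** The light level *entering* each RBC is taken
from the plasma gaps between RBCs: a 90th-percentile surface computed on
a 1-s × 10-μm block grid and bilinearly interpolated to the full STI.
A true rolling-window percentile was the obvious alternative; the
block-and-interpolate estimator is the standard cheap approximation,
and it reproduces a known two-level gap/tract fixture within ±2%, which
is the accuracy that matters downstream.

**Tract segmentation.** The STI is divided by the incident surface and
thresholded with Otsu's method; connected components under 5 px are
discarded as noise. A degenerate STI whose normalized 5–95% spread is
below 0.05 is reported as tract-free with a warning — an all-dark STI is
indistinguishable from a dark-illumination all-plasma STI without an
external reference, so no attempt is made to distinguish them.

**Orientation search.** Within tiled windows (default 0.5 s, ≥ 3
frames) the dominant tract slope is found by shearing the demeaned
binary mask along candidate slopes (0.5° angle grid from −89.5° to
89.5°) and scoring the count-weighted variance of the projection
profile, $\sum_b S_b^2 / C_b$. Two numerical points deserve emphasis:

- *Null-centering.* The raw score is exactly degenerate: an extreme
  shear that scatters the window into near-singleton bins attains the
  same score, $N p(1-p)$, as perfect tract alignment. Subtracting the
  expected random-mask contribution $p(1-p)$ per occupied bin removes
  this bias while leaving the alignment peak untouched.
- *Continuous refinement.* Near ±90° one 0.5° step spans hundreds of
  μm/s, so the coarse grid alone cannot meet a 5% accuracy goal at
  500 μm/s. The winning grid angle is therefore refined with
  `optimize()` over ±1 grid step using linear fractional binning, which
  makes the objective continuous in the slope.

Velocity is $v = \tan\theta \cdot \Delta x / \Delta t$, positive for
arteriolar→venular motion; time-reversing an STI negates it (a property
test). Windows whose best speed falls below 10 μm/s, or that contain no
tracts, are assigned exactly 0 — the stopped-flow convention. The
10 μm/s threshold is a noise-robustness choice: it is far below the
slowest flows of interest (≈50 μm/s) and above the angle-grid noise
floor around zero slope.

**Derived quantities.** Lineal density counts mask runs per time
column over the segment length; partial tracts at the segment ends are
counted (the cheaper convention; at 100+ μm segments the end bias is
negligible). Tube hematocrit uses a cylindrical geometry with rat RBC
volume 55 fL and capillary diameter 5 μm — both configurable, since the
conversion constants are preparation-specific. Supply rate is
$|v| \cdot \mathrm{LD}/1000$. Tract SO₂ uses a *shared* segmentation
from the 450 nm STI applied to both wavelength STIs, so tracts match
across wavelengths by construction; per-tract OD is measured on the
darker half of each tract's pixels to suppress partial-volume dilution
at anti-aliased edges.

## Flow classification and functional capillary density

Over a 30-s window, a capillary is **stopped** if velocity is 0
throughout; **intermittent** if any maximal zero run strictly exceeds
3 s (measured as sample count × sampling interval, so an exactly-3.0-s
stop does not qualify) or any reversal against the dominant direction is
sustained ≥ 0.5 s; otherwise **continuous**. The 0.5-s reversal
persistence is a noise-robustness choice — single-window sign flips at
the estimator's resolution should not relabel a capillary.

Functional capillary density divides total crossings of three
horizontal test lines (at 1/4, 1/2, 3/4 of the field height) by the
total line length (3 × field width, default 450 μm). A capillary
crossing two lines counts twice — crossings, not unique capillaries —
and each (capillary, line) pair counts at most once.

## Vasomotion spectral analysis

`power_spectrum()` removes the mean and applies a plain FFT — no taper,
no zero-padding, no detrending beyond the mean. The one-sided amplitude
is $A_k = 2|X_k|/N$ (DC and Nyquist unhalved) so a bin-aligned sinusoid
of amplitude $A$ has Power exactly $A^2$; Parseval's identity
($\sum_k A_k^2 / 2 = \operatorname{var}$) is a test. The vasomotion
band is $[0.03, 0.06]$ Hz inclusive (periods 16–32 s);
`peak_power_in_band()` returns the argmax with ties resolved to the
lower frequency, and errors with the minimum duration when no bin falls
inside the band. A 120-s recording at 10.5 Hz gives
$\Delta f \approx 0.0083$ Hz — four bins in the band — so injected
periods are recoverable to within one bin, never better; tests assert
exactly that.

## The statistical tail

**ROUT, constant model.** The published ROUT procedure addresses curve
fits; applied to a single column of values the "curve" degenerates to a
robust center. The center is fit by iteratively reweighted least squares
with Lorentzian weights $1/(1+(r/\mathrm{RSDR})^2)$; the robust scale
RSDR is the 68.27th percentile of absolute residuals times the
small-sample correction $n/(n-1)$. Each $|r|/\mathrm{RSDR}$ becomes a
two-tailed t-tail P value (df $= n-1$), and points are tested
outward-in: the $i$-th most extreme against the threshold
$Q\,(n-i+1)/n$, stopping at the first failure. This step-down direction
is what gives the method its documented behavior — a lone gross outlier
is tested at level $Q$ itself (not $Q/n$), so detection of a 5σ point is
essentially certain, while the average flagged fraction on clean normal
data stays near $Q$. Default $Q = 1\%$.

**Matched-field exclusion.** A field of view flagged in *any* imaging
period is removed from *all* periods, preserving matched data across
time. When masks are not supplied, ROUT runs within each
(period × group) cell — outliers are judged against their own group's
distribution, as in a per-column outlier analysis — falling back to the
pooled period when a group has fewer than 10 values. The per-group unit
matters: in a cohort where most treated fields oscillate, pooling groups
puts the robust scale's 68th percentile on the boundary between the
oscillatory and quiet subpopulations, and the exclusion set becomes an
all-or-nothing coin flip on the realized oscillatory fraction.

**ANOVA.** `two_way_anova()` fits the fixed-effects group × period model
with sum-to-zero contrasts and type-III sums of squares (identical to
the textbook partition when balanced; a brute-force oracle test enforces
agreement to 1e-9). The response is internally standardized before
fitting — F and P are scale-invariant, and band Power values of order
$10^{-8}$–$10^{-4}$ otherwise sit below generic zero-residual guards. A
constant table short-circuits to $F = 0,\ P = 1$. The post-hoc contrasts
compare groups within each period using the pooled residual mean square,
with Bonferroni multiplier 3 (the number of periods) capped at 1.
Repeated-measures or mixed-effects modeling is deliberately out of
scope; the plain two-factor model is the implemented surface.

## The forward simulator

The generator's defaults *are* the study conditions of the reference
acquisition: 696 × 520 px at 0.6466 μm/px (450 μm across 696 px), 21
frames/s, 12-bit counts, 1-min videos at 438/450 nm; CWS over
450–650 nm at 10.5 recordings/s for 2 min (≈1200 profiles + timing
jitter of ±20 ms). RBCs are rendered as 6 × 5 μm rectangles aligned to
the centerline tangent with one-pixel anti-aliased edges — an invented
but conventional geometry — separated by plasma gaps drawn uniformly in
[0.5, 1.5] × the mean spacing (floored at 1.2 × RBC length). The
bounded-uniform gap law keeps realized lineal density within a few
percent of 1/spacing for a single seeded run while staying aperiodic
enough that the orientation search never sees a repeating texture.

Attenuation is Beer–Lambert throughout: the tissue background carries a
baseline OD (default 0.3 at 450 nm) whose hemoglobin-borne part
oscillates when vasomotion is enabled,
$C(t) = C_0(1 + m \sin 2\pi t/T + \varphi)$ (defaults $T = 28.8$ s,
$m = 0.05$, i.e. ~2 cycles/min at a few-percent modulation); each RBC
multiplies in its own OD (0.35 at 450 nm by default, and at 438 nm that
value times the SO₂-interpolated calibration ratio, so the forward model
and the SO₂ inversion share one calibration). Vasomotion couples
hemoglobin content and capillary velocity with the same phase by
default (`couple_velocity`), reflecting that both are driven by the
same upstream arteriolar tone; the coupling can be switched off. Noise
is additive Gaussian on counts (default 1% of background), not full
photon shot noise — simpler, and sufficient for recovery testing; counts
are rounded and clipped to the 12-bit range. Identical configurations
and seeds give bit-identical stacks.

`generate_cohort()` emulates the two-group study design: control fields
never oscillate; 70% of FIP fields (configurable) develop vasomotion
from imaging period 2 onward with per-field periods drawn uniformly in
16–32 s and depths in 0.03–0.07, the rest staying quiet — mirroring the
observation that dysfunction is spatially heterogeneous. Cohorts
generate CWS recordings by default; per-field videos are available via
`include_video = TRUE` and are intended for small frame shapes, since a
full-size 1-min dual-wavelength stack is a ~3.6 GB array.

**What the simulator does not emulate** — and hence what passing tests
do not show about real data: optical scatter and depth-dependent blur,
motion artifacts and focus drift, RBC deformation and overlap in the
tube, photon (Poisson) noise statistics, spatially varying illumination
beyond the rendered tube, out-of-focus capillaries crossing the
centerline, and physiological covariation beyond a single shared
vasomotion phase. Estimator accuracy on real recordings must be
established against manual or reference measurements; the closed loop
here establishes correctness of the implementations, not field
performance.

## Problem sizes in the test suite

Validation runs use deliberately reduced problem sizes chosen to keep
the closed loop statistically meaningful while fast: velocity-recovery
fixtures render a ~110-μm capillary in 32 × 180 px frames for 10 s;
flow-classification runs use 24 × 118 px for 30 s (the classification
window) at the full 21 frames/s, 100 seeded runs; spectral fixtures use
the full 2-min CWS duration, where the frequency resolution lives; the
end-to-end cohort check runs 20 replicates of the full 5 animals ×
8 fields × 2 groups × 3 periods design through the CWS pipeline. These
sizes are the package's own validation choices and are independent of
the simulator defaults, which remain at the acquisition geometry.

## Known limitations

- The 438/450 nm calibration constants are placeholders; absolute SO₂
  on real data requires the user's in-vivo calibration.
- Velocity aliasing: above roughly 1500 μm/s (slope ≈ tan 89.5°) the
  angle grid saturates; capillary RBC velocities rarely approach this,
  but arteriolar flows would.
- Lineal density counts partial tracts at segment ends; for very short
  segments this biases density upward.
- The incident-intensity surface assumes plasma gaps are visible within
  every 1-s × 10-μm block; a capillary packed wall-to-wall with RBCs
  for longer than a block has its incident level interpolated from
  neighbors.
- `matched_field_exclusion()` assumes fields are identifiable across
  periods by `fov_id`; re-registration of drifting fields is upstream
  of this package.
- Hyperemic-capillary detection and automatic centerline tracing are
  out of scope; centerlines are inputs.
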