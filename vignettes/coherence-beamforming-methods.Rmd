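---
title: "Methods: coherence beamforming, lag weighting, and the synthetic acquisition regimes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coherence beamforming, lag weighting, and the synthetic acquisition regimes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models implemented in `bonebeam`, the
assumptions behind them, the tunable parameters and their defaults, what the
synthetic-data generators do and do not emulate, and the numerical choices
made where the design was genuinely open. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## 1. Image formation model

### Focusing

All beamformers consume the same time-aligned aperture cube. For a pixel at
$(x, z)$ and element $i$ at $(x_i, z_i)$, the receive delay is
$|r_{px} - r_i| / c$; pulse-echo (two-way) data add a transmit path equal to
the pixel depth $z/c$ — the standard approximation for an unsteered focused
or plane transmit. The true transmit sequence of a scanner is rarely known
in detail; the depth-based transmit term is therefore a documented,
configurable assumption rather than a claim about any particular system.
Samples are read by linear (fractional-sample) interpolation — adequate at
the ≥4× oversampling used throughout — out-of-window samples are zeroed and
flagged, and the per-channel DC level over the line is removed, because the
coherence definition below presumes zero-mean signals.

No receive apodization and no f-number aperture growth are applied by
default; both would interact with the lag axis of the coherence stack and
the reference acquisitions specify neither.

### Spatial coherence and SLSC

The coherence of the time-aligned signals $s_i(n)$ at element lag $m$ is the
average over all $N - m$ element pairs of their zero-lag normalized
correlation over an axial kernel centred on the pixel. Pairs whose kernel
energy vanishes contribute zero; the divisor stays $N - m$, so an all-zero
neighbourhood yields exactly 0. Every entry is bounded by 1 in magnitude
(Cauchy–Schwarz), and the test suite asserts this on random inputs. The
axial kernel length is given in wavelengths (1–2 λ in the shipped presets)
and converted to samples at the data's sampling rate, minimum 2 samples;
kernels are truncated symmetrically at the image edges, which leaves the
normalized correlation unbiased because numerator and denominators share
the same window.

An SLSC image is the partial sum of the first $M$ lags. Coherence sums can
be negative; the amplitude image clamps them at zero — log compression is
undefined for negative values and the displayed images are nonnegative —
while the signed values remain accessible in `$raw`.

### LW-SLSC

For each moving kernel of the coherence stack (sizes given in mm, converted
as `round(size/spacing)` with a 2-pixel minimum; top-left anchored; stride
`round(size·(1−overlap))`; trailing kernels shifted to abut the image edge
so coverage is complete), the lag-weight program

$$\hat w = \arg\min_w \; \|B R w\|_2^2 + \alpha^2 \|D w\|_2^2
\quad\text{s.t.}\quad \textstyle\sum w = 1,\; 0 \le w \le 1$$

is reduced to the quadratic form $w^T H w$ with
$H = (BR)^T(BR) + \alpha^2 D^T D$; the reduction is exact and is asserted to
$10^{-10}$ relative on random instances. $D$ is the $(N_L-1)\times N_L$
first-difference operator across lags; $B$ stacks all vertical differences
(column-major) then all horizontal differences of the column-major-reshaped
kernel, giving $2 k_z k_x - k_z - k_x$ rows. Any fixed row ordering yields
the same $B^TB$; this one is documented so intermediate arrays are
reproducible.

Numerical choices:

* **Ridge.** $(BR)^T(BR)$ is rank-deficient for flat kernels, so
  $10^{-10}\,\mathrm{tr}(H)/N_L$ is added to the diagonal before solving.
* **Solver.** A primal-dual interior-point method written for this simplex
  QP: block elimination of the bound multipliers, one symmetric solve per
  iteration, fraction-to-the-boundary steps, centering $\sigma = 0.1$,
  duality-gap tolerance $10^{-10}$ relative to the problem scale, at most
  200 iterations. Non-convergence falls back to `quadprog::solve.QP` with a
  logged warning. The tests cross-check the interior-point solutions against
  `quadprog` and against exhaustive simplex grid search on 3-lag instances.
* **Degenerate kernels.** An all-zero kernel has objective identically zero;
  uniform weights are returned as the reproducible tie-break.
* **Stacking.** Each pixel's value is the median over all overlapping
  weighted kernel images (full kernel extent). The median is order-free, so
  kernel processing order cannot affect the image.

The behavioural consequence of the TV objective is worth stating plainly:
weight goes to the lags at which the kernel looks *flat*. In speckle that is
the low lags (bright, smooth) — contrast; on resolved structure the high
lags — resolution. A feature survives LW-SLSC robustly only if it remains
coherent across the whole lag range, which is precisely the acoustic
signature of a strong specular/point-like reflector such as a bone surface
or a photoacoustic fiber tip. That is why the simulator designs below pay
close attention to where coherence lives along the lag axis.

## 2. Parameters and presets

| Parameter | Meaning | Presets |
|---|---|---|
| `M` | SLSC lag cutoff (lags) | 9 (caprine US); 5 (cadaver US); 15 (cadaver PA) |
| `n_lags` (`N_L`) | lags in the stack | 28; 15; 25 |
| `axial_kernel_wavelengths` | correlation kernel (λ) | 2; 1; 1 |
| kernel (mm), `overlap` | LW-SLSC moving kernel | 1.20×1.92, 50%; 2.0×3.1, 60% |
| `alpha` | lag-gradient regularization | 0.12; 1; 1 |
| `threshold` | segmentation fraction of max | 0.5 (boundary); 0.3 (landmarks) |
| `open_mm`/`close_mm` | morphology SE sizes | 0.38 / 0.63 mm |
| `roi_mm`, `background_offset_mm` | SNR/area ROI scheme | 10 mm, 25 mm |
| `snr_threshold` | out-of-plane boundary | 3 (≤ 3 discarded) |
| `dynamic_range_db` | display range | 25 dB (PA); 50 dB (US default) |

`alpha` is applied to coherence on its raw $[-1, 1]$ scale; the preset
values are interpreted on that scale.

**Aperture scaling.** The presets above belong to 128-element acquisitions.
The simulations in the tests and the acceptance script use a 48-element
truncation of the same array so they run in seconds, and scale the *lag*
parameters by the aperture ratio (e.g. $N_L: 15 \to 6$, $M: 5 \to 2$ for the
ultrasound set; $N_L: 25 \to 9$, $M: 15 \to 6$ for the photoacoustic set) so
that lags span the same fractions of the aperture. Millimetre-valued
parameters (kernels, structuring elements, ROIs) and `alpha` are kept
verbatim. Problem sizes used by the end-to-end checks: 191×71-pixel
ultrasound grids, 141×121 photoacoustic grids, 10 frames per contact group,
100 out-of-plane frames, 100 registration trials.

## 3. What the simulator emulates — and what it does not

All generators are pure functions of their arguments and seed, built from
far-field superposition of Gaussian-modulated sinusoids (4 MHz, 60%
fractional bandwidth by default; 1/r amplitude decay). They model the
*coherence structure* each acquisition regime presents to the beamformers,
which is what this toolchain is sensitive to. They do **not** model
attenuation, element directivity, nonlinear propagation, or full-wave
scattering, and no claim is made that absolute image amplitudes match any
scanner.

* **Point source** (cortical contact): one coherent emitter; every channel
  records the same pulse at its geometric one-way delay, plus white channel
  noise (default 5% of peak).
* **Diffuse target** (cancellous contact): a compact coherent direct wave
  (`direct_fraction = 0.2` of the source amplitude) plus `n_sub = 60`
  reverberant sub-sources in a 2 mm disk whose per-channel arrival times
  carry independent ±0.1 µs jitter. The jitter is the defining feature:
  reflections inside porous, blood-rich bone misalign the delayed signals,
  so the reverberant energy spreads in an amplitude image while carrying
  little spatial coherence. With `radius = 0` and `jitter_us = 0` the
  generator collapses to the point-source limit.
* **Bone scene** (ultrasound): a line-by-line focused-transmit acquisition
  (`per_line` channel data; Gaussian transmit beam, σ = 0.8 mm at the
  surface). The focused transmit matters: under an unfocused model the whole
  surface acts as one wide incoherent source and — by van Cittert–Zernike —
  decorrelates within a few lags, which no parameter choice can undo. Bone
  facets are strong random-phase point-like backscatterers at λ/2 spacing
  (a perfect mirror would *decorrelate* under point-focusing, since its
  planar echo violates the spherical delay law; rough-surface backscatter is
  the physically relevant model). Soft-tissue speckle sits above the
  surface; bright but per-channel-jittered multipath clutter fills the whole
  field including the acoustic shadow — the in vivo mechanism that degrades
  amplitude imaging of bone while remaining invisible to coherence imaging.
  Channel noise defaults to 5% of peak.
* **Out-of-plane**: white channel noise plus a few weak wavefronts with
  random per-channel delays, so nothing focuses anywhere; at defaults the
  beamformed frames fail the SNR > 3 test and are discarded.
* **Vertebra phantom**: a binary annulus-plus-processes volume with named
  landmarks under a known rigid pose, for exact registration round trips. It
  is a synthetic stand-in for a CT volume, labelled as such.

Because the generators reproduce coherence structure rather than anatomy,
passing tests demonstrate that the pipeline's *contrasts and orderings*
(coherence beamformers vs DAS, diffuse vs compact targets, in-plane vs
out-of-plane) behave as the underlying acoustics predicts — not that any
particular clinical gCNR or area value would be reproduced on real tissue.

## 4. Metrics and statistics

gCNR uses 256 equal-width bins spanning the pooled range of both ROIs
(bins are specified by the definition; the shared range makes the measure
exactly gain-invariant); a degenerate pooled range is defined as gCNR 0.
CNR and SNR use population standard deviations on linear amplitude. The
−6 dB area is the area of the 8-connected suprathreshold region *containing
the ROI peak* — satellite lobes elsewhere in the ROI do not inflate it —
with the threshold at $10^{-6/20} \approx 0.501$ of the ROI maximum, inside
a 10 mm × 10 mm ROI centred on the LW-SLSC-estimated target (its brightest
pixel; the estimate is clamped so target and background ROIs fit the image,
which out-of-plane frames would otherwise violate). The peak–to–CoM
compactness measure optionally restricts the centre of mass to the
8-connected suprathreshold component containing the peak (30% in the
pipeline), mirroring how landmark centres of mass are computed from
segmented components; without the restriction the CoM of a mostly-empty
coherence image is dominated by the clamped noise floor.

The bone-contact comparison uses Welch's two-sided *t*-test: the two groups
typically have very unequal spreads, and nothing in the measurement design
justifies assuming equal variances. Box-plot summaries report median,
quartiles, min/max and outliers by the 1.5·IQR rule.

Segmentation uses 8-connected labeling (thin diagonal bone boundaries must
not split), square structuring elements with per-axis mm→pixel conversion
(minimum 1 pixel), and image-wide maxima for fractional thresholds.
Nearest-contour ties go to the lowest label and are logged.

Rigid landmark registration is the closed-form SVD (Kabsch) solution with a
determinant guard that sign-corrects the smallest singular vector, so the
recovered rotation is always proper. The noisy-registration test compares
RMS FRE against the classical expectation
$E[\mathrm{FRE}^2] = 3\sigma^2(1 - 2/N)$ for isotropic per-coordinate noise.

## 5. Known limitations

* The transmit model for pulse-echo focusing is depth-based; steered or
  multi-focal sequences are out of scope.
* Scan conversion assumes radial beams from the arc centre of a convex
  array; vendor-specific beam steering is not modelled.
* LW-SLSC inherits the TV objective's tendency to suppress thin structures
  whose coherence does not extend to high lags; with lag ranges scaled to
  the aperture (as in the shipped presets) bone surfaces are preserved, but
  aggressive `n_lags` on small apertures will erode them.
* The interior-point solver is tuned for the small (≤ 28-variable) QPs this
  method produces; it is not a general-purpose QP code.
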