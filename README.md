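# bonebeam

Coherence-based ultrasound and photoacoustic beamforming for imaging bone —
aimed at image guidance of spinal pedicle cannulation, where two questions
matter: *where are the bony landmarks* (for registering ultrasound to CT),
and *is the drill tip about to breach the cortical wall* (photoacoustic
sensing of the fiber tip's bone contact).

The package implements the full toolchain in R:

* **Beamformers.** Conventional delay-and-sum (DAS); short-lag spatial
  coherence (SLSC); and locally weighted SLSC (LW-SLSC), a regularized
  coherence beamformer that solves a small quadratic program per image
  kernel.
* **Image-quality metrics.** Generalized contrast-to-noise ratio (gCNR),
  CNR, SNR, −6 dB contour areas, and a peak–to–centre-of-mass compactness
  measure.
* **Bone-contact discrimination.** The SNR > 3 out-of-plane filter, −6 dB
  area measurement around the photoacoustic target, and a Welch *t*-test
  between cancellous- and cortical-contact frame groups.
* **Segmentation and landmarks.** Fractional-maximum thresholding,
  morphological cleanup, 8-connected components with amplitude-weighted
  centres of mass, contour selection, integrated-thickness profiles, and
  closed-form (SVD) rigid landmark registration with fiducial registration
  error (FRE) reporting.
* **A simulator** for the four acquisition regimes the pipeline must
  distinguish: compact coherent point sources (fiber on cortical bone),
  diffuse partially-incoherent targets (fiber in cancellous bone), specular
  bone surfaces in cluttered soft tissue (line-by-line focused transmit),
  and out-of-plane noise-only frames — plus a synthetic vertebra CT phantom
  for registration round trips.

## The algorithms

With time-delayed, zero-mean aperture signals `s_i(n)` (channel `i`, depth
sample `n`), the normalized spatial coherence at element lag `m` over an
axial kernel `n1..n2` is

    R(m) = 1/(N-m) * sum_{i=1..N-m}
           sum_n s_i(n) s_{i+m}(n) / sqrt( sum_n s_i(n)^2 * sum_n s_{i+m}(n)^2 )

An SLSC image integrates the first `M` lags: `SLSC(M) = sum_{m=1..M} R(m)`.

LW-SLSC replaces the fixed cutoff with per-kernel adaptive lag weights. For
each `kz x kx` kernel of the coherence stack, reshaped to a matrix
`R ∈ R^{(kz·kx) × N_L}`, the weights solve

    w* = argmin_w  || B R w ||² + α² || D w ||²
         subject to  sum(w) = 1,  0 ≤ w ≤ 1

where `B` is the 2-D first-difference (total-variation) operator on the
kernel, `D` the 1-D difference operator across lags, and `α` the
regularization factor. Substituting `H = (BR)ᵀ(BR) + α² DᵀD` turns this into
the quadratic program `argmin_w wᵀHw` on the simplex, solved here by a
primal-dual interior-point method (with `quadprog` as the fallback). The
final image is the per-pixel **median** of all overlapping weighted kernel
images. Intuition: kernels in flat regions put weight on low lags (contrast),
kernels on resolved structure keep high lags (resolution), and structure
that is coherent across *all* lags — bone — survives every weighting.

Other implemented definitions: `gCNR = 1 − Σ min(p_i, p_o)` over 256
shared-range histogram bins; `CNR = |S_i − S_o| / sqrt(σ_i² + σ_o²)`;
`SNR = µ_t / σ_b` — all on linear (pre-log-compression) amplitude.

## Worked example

Bone-surface scene, all three beamformers, gCNR/CNR for a surface-band ROI
against the acoustic shadow:

```r
library(bonebeam)

geom  <- sim_geometry(48)                      # 48-el, 0.3 mm pitch, 4 MHz
xmax  <- max(abs(geom$element_positions[, "x"]))
scene <- simulate_bone_scene(
  surface = data.frame(x = seq(-xmax, xmax, 0.1), z = 22),
  geometry = geom, depth_mm = 35, seed = 7)

cfg <- run_config(M = 2, n_lags = 6, axial_kernel_wavelengths = 1,
                  kernel_lateral_mm = 2.0, kernel_axial_mm = 3.1,
                  overlap = 0.6, alpha = 1)
rep <- run_beamform(scene$data, scene$grid, cfg,
                    roi_in  = roi(c(-5, 5), c(21.4, 22.6)),   # bone band
                    roi_out = roi(c(-5, 5), c(26, 32)))       # shadow
rep$metrics
#>   frame beamformer metric value
#> 1     1        DAS   gcnr 0.626
#> 2     1        DAS    cnr 0.838
#> 3     1       SLSC   gcnr 0.775
#> 4     1       SLSC    cnr 1.370
#> 5     1     LWSLSC   gcnr 0.784
#> 6     1     LWSLSC    cnr 1.336
```

Both coherence beamformers separate bone from shadow better than DAS
(higher gCNR/CNR), with LW-SLSC on top — the clutter filling the shadow is
bright in amplitude but spatially incoherent.

Bone-contact discrimination on ten simulated photoacoustic frames per
condition (a couple of minutes on one core):

```r
canc <- simulate_diffuse_target(c(0, 33), geometry = geom,
                                n_frames = 10, seed = 11)   # fiber in cancellous bone
cort <- simulate_point_source(c(0, 33), geom,
                              n_frames = 10, seed = 12)     # fiber on cortical bone
pa_cfg <- run_config(M = 6, n_lags = 9, axial_kernel_wavelengths = 1,
                     kernel_lateral_mm = 2.0, kernel_axial_mm = 3.1,
                     overlap = 0.6, alpha = 1, roi_mm = 10,
                     background_offset_mm = 25)
grid <- image_grid(seq(-7, 7, by = 0.2), seq(4, 42, by = 0.2))
run_bone_contact(canc, cort, grid, pa_cfg)
#> <bone_contact_report> DAS areas; 0 + 0 frames discarded as out-of-plane
#> <bone_contact_test> mean difference 1.072 mm^2, t = 3.286, p = 0.00943
#>   group          n median    q1    q3   min   max
#> 1 cancellous    10  1.70  0.980 2.97  0.680 3.28
#> 2 cortical      10  0.840 0.840 0.840 0.840 0.840
```

The diffuse (cancellous-contact) frames produce significantly larger −6 dB
contour areas than the compact (cortical-contact) frames — the discriminator
a surgeon would watch while advancing the pedicle probe.

A thin CLI over the same functions ships at `inst/cli/bonebeam`
(subcommands `simulate`, `beamform`, `segment`, `bone-contact`,
`register-landmarks`).

## HDF5 channel-data container

No community standard exists for raw RF channel data, so the container is
defined here. Datasets: `/rf` (float64, time × element × frame), `/fs`
(MHz), `/c` (m/s), `/modality` (`ultrasound_two_way` |
`photoacoustic_one_way`), `/acquisition` (`frame` | `per_line`),
`/start_time` (µs) and a `/geometry` group (`n_elements`, `pitch` (mm),
`kerf` (mm), `center_frequency` (MHz), `curvature_radius` (mm, −1 = linear
array). Axis order is time, element, frame; axial depth increases away from
the array face.

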