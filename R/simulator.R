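#' @title Synthetic channel-data simulator
#' @description Generators for the four acquisition regimes the analysis
#' pipeline must distinguish: a compact coherent point source (optical fiber
#' tip in contact with cortical bone), a diffuse multi-reflection target
#' (fiber tip surrounded by porous cancellous bone), a specular bone surface
#' over soft-tissue speckle with an acoustic shadow beneath (for ultrasound
#' segmentation and contrast testing), and out-of-plane noise-only frames.
#' All generators are pure functions of their arguments and `seed`:
#' re-running with the same seed reproduces the samples exactly. The acoustic
#' model is far-field point-source superposition of Gaussian-modulated
#' sinusoids (default 4 MHz centre frequency, 60% fractional bandwidth);
#' element directivity and attenuation are not modelled.
#' @name simulator
NULL

# evaluate expr under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Default simulation geometry
#'
#' A 64-element, 0.3 mm pitch, 0.06 mm kerf linear array at 4 MHz — a
#' truncated version of a typical 128-element linear probe, kept small so
#' end-to-end simulations run quickly.
#'
#' @param n_elements number of elements.
#' @return An [array_geometry()].
#' @export
sim_geometry <- function(n_elements = 64) {
  array_geometry(n_elements, pitch = 0.3, kerf = 0.06, center_frequency = 4)
}

# Gaussian-modulated sinusoid; t in us, fc in MHz, fractional FWHM bandwidth
gauss_pulse <- function(t, fc, bandwidth = 0.6, phase = 0) {
  sigma_f <- bandwidth * fc / (2 * sqrt(2 * log(2)))  # FWHM -> sd, MHz
  sigma_t <- 1 / (2 * pi * sigma_f)                   # us
  exp(-t^2 / (2 * sigma_t^2)) * cos(2 * pi * fc * t + phase)
}

pulse_halfwidth_us <- function(fc, bandwidth) {
  sigma_f <- bandwidth * fc / (2 * sqrt(2 * log(2)))
  4 / (2 * pi * sigma_f)
}

# accumulate windowed pulses from point scatterers into a [n_time x N] panel;
# jitter_us > 0 adds independent per-channel arrival-time jitter (uniform on
# +-jitter_us), destroying cross-channel coherence as multiple reflections do;
# accept_mm < Inf restricts each scatterer's contribution to elements within
# that lateral distance (specular-lobe / directivity acceptance cone)
add_scatterers <- function(sig, times, fs, positions, amplitudes, phases,
                           geometry, sound_speed, modality, fc, bandwidth,
                           jitter_us = 0, accept_mm = Inf) {
  ep <- geometry$element_positions
  c_mm_us <- sound_speed / 1000
  hw <- ceiling(pulse_halfwidth_us(fc, bandwidth) * fs)
  woff <- -hw:hw
  nt <- nrow(sig); ne <- ncol(sig)
  t0 <- times[1]; dt <- 1 / fs
  for (s in seq_len(nrow(positions))) {
    d <- sqrt((ep[, "x"] - positions[s, 1])^2 + (ep[, "z"] - positions[s, 2])^2)
    tau <- d / c_mm_us
    if (modality == "ultrasound_two_way") tau <- tau + positions[s, 2] / c_mm_us
    if (jitter_us > 0) tau <- tau + stats::runif(ne, -jitter_us, jitter_us)
    ctr <- round((tau - t0) / dt) + 1
    idx_t <- outer(ctr, woff, "+")                       # ne x nw
    tt <- (idx_t - 1) * dt + t0 - tau                    # time rel. to arrival
    amp <- amplitudes[s] / pmax(d, 1e-3)
    if (is.finite(accept_mm)) {
      amp <- amp * (abs(ep[, "x"] - positions[s, 1]) <= accept_mm)
    }
    vals <- amp * gauss_pulse(tt, fc, bandwidth, phases[s])
    ok <- idx_t >= 1 & idx_t <= nt
    lin <- idx_t[ok] + (rep.int(seq_len(ne), length(woff))[ok] - 1) * nt
    sig[lin] <- sig[lin] + vals[ok]
  }
  sig
}

sim_frame_base <- function(geometry, fs, depth_mm, modality) {
  c_mm_us <- geometry$sound_speed / 1000
  tmax <- (if (modality == "ultrasound_two_way") 2.6 else 1.6) * depth_mm / c_mm_us
  n_time <- ceiling(tmax * fs)
  list(times = (seq_len(n_time) - 1) / fs, n_time = n_time)
}

check_fov <- function(position, geometry, depth_mm) {
  xmax <- max(abs(geometry$element_positions[, "x"]))
  if (position[2] <= 0 || position[2] > depth_mm || abs(position[1]) > xmax) {
    stop("simulator: source position outside the field of view", call. = FALSE)
  }
}

#' Simulate a compact photoacoustic point source
#'
#' One coherent source: every channel records the same Gaussian pulse at its
#' one-way geometric delay, amplitude decaying as 1/distance, plus i.i.d.
#' Gaussian channel noise. Emulates the well-defined compact signal of a
#' fiber tip against cortical bone.
#'
#' @param position `(x, z)` source position in mm.
#' @param geometry an [array_geometry()].
#' @param fs sampling frequency in MHz.
#' @param depth_mm recorded depth in mm.
#' @param amplitude source amplitude.
#' @param noise_level channel-noise standard deviation relative to the peak
#'   clean signal.
#' @param bandwidth fractional pulse bandwidth.
#' @param n_frames number of frames (independent noise per frame).
#' @param seed integer seed; same seed gives identical output.
#' @return A [channel_data()] with `modality = "photoacoustic_one_way"`.
#' @export
simulate_point_source <- function(position, geometry = sim_geometry(),
                                  fs = 16, depth_mm = 45, amplitude = 1,
                                  noise_level = 0.05, bandwidth = 0.6,
                                  n_frames = 1, seed = NULL) {
  check_fov(position, geometry, depth_mm)
  base <- sim_frame_base(geometry, fs, depth_mm, "photoacoustic_one_way")
  fc <- geometry$center_frequency
  clean <- add_scatterers(matrix(0, base$n_time, geometry$n_elements),
                          base$times, fs, rbind(position), amplitude, 0,
                          geometry, geometry$sound_speed,
                          "photoacoustic_one_way", fc, bandwidth)
  with_seed(seed, {
    samples <- array(0, c(base$n_time, geometry$n_elements, n_frames))
    sd_n <- noise_level * max(abs(clean))
    for (f in seq_len(n_frames)) {
      samples[, , f] <- clean + matrix(stats::rnorm(length(clean), sd = sd_n),
                                       nrow(clean))
    }
    channel_data(samples, fs, geometry$sound_speed, "photoacoustic_one_way",
                 geometry)
  })
}

#' Simulate a diffuse multi-reflection photoacoustic target
#'
#' Emulates a fiber tip surrounded by porous cancellous bone: a compact
#' coherent direct wave from the nominal centre, plus many reverberant
#' sub-sources spread over a disk whose per-channel arrival times carry
#' independent jitter. The jitter is the defining feature of the regime —
#' reflections inside the porous structure compromise the alignment of the
#' delayed signals, so the reverberant energy spreads in an amplitude image
#' but carries little spatial coherence, while the direct wave stays compact
#' and coherent.
#'
#' @inheritParams simulate_point_source
#' @param center nominal target centre `(x, z)` in mm.
#' @param radius disk radius containing the reverberant sub-sources, mm.
#' @param n_sub number of sub-sources (>= 10).
#' @param direct_fraction fraction of the source amplitude carried by the
#'   coherent direct wave (the rest is reverberant).
#' @param jitter_us half-width of the uniform per-channel delay jitter of the
#'   reverberant sub-sources, in microseconds (~2 periods at 4 MHz by
#'   default; 0 makes the sub-sources coherent).
#' @return A [channel_data()] with `modality = "photoacoustic_one_way"`.
#' @export
simulate_diffuse_target <- function(center, radius = 2, n_sub = 60,
                                    direct_fraction = 0.2, jitter_us = 0.1,
                                    geometry = sim_geometry(), fs = 16,
                                    depth_mm = 45, amplitude = 1,
                                    noise_level = 0.05, bandwidth = 0.6,
                                    n_frames = 1, seed = NULL) {
  stopifnot(n_sub >= 10, radius >= 0,
            direct_fraction >= 0, direct_fraction <= 1, jitter_us >= 0)
  check_fov(center, geometry, depth_mm)
  base <- sim_frame_base(geometry, fs, depth_mm, "photoacoustic_one_way")
  fc <- geometry$center_frequency
  with_seed(seed, {
    samples <- array(0, c(base$n_time, geometry$n_elements, n_frames))
    for (f in seq_len(n_frames)) {
      clean <- add_scatterers(matrix(0, base$n_time, geometry$n_elements),
                              base$times, fs, rbind(center),
                              direct_fraction * amplitude, 0, geometry,
                              geometry$sound_speed, "photoacoustic_one_way",
                              fc, bandwidth)
      rr <- radius * sqrt(stats::runif(n_sub))
      th <- stats::runif(n_sub, 0, 2 * pi)
      pos <- cbind(center[1] + rr * cos(th), center[2] + rr * sin(th))
      amps <- (1 - direct_fraction) * amplitude *
        abs(stats::rnorm(n_sub, 1, 0.3)) / sqrt(n_sub) * 3
      phases <- stats::runif(n_sub, 0, 2 * pi)
      clean <- add_scatterers(clean, base$times, fs, pos, amps, phases,
                              geometry, geometry$sound_speed,
                              "photoacoustic_one_way", fc, bandwidth,
                              jitter_us = jitter_us)
      sd_n <- noise_level * max(abs(clean))
      samples[, , f] <- clean + matrix(stats::rnorm(length(clean), sd = sd_n),
                                       nrow(clean))
    }
    channel_data(samples, fs, geometry$sound_speed, "photoacoustic_one_way",
                 geometry)
  })
}

#' Simulate a specular bone surface in soft tissue (pulse-echo)
#'
#' Emulates a line-by-line focused-transmit acquisition of a bone surface.
#' Each image line is an independent transmit event whose Gaussian beam
#' (lateral standard deviation `tx_sigma_mm`) insonifies only a narrow strip
#' around the line — the property that preserves the spatial coherence of a
#' specular surface to useful lags; under an unfocused transmit the whole
#' surface would act as a wide source and decorrelate within a few lags.
#' Three acoustic populations make up the scene: (1) bone facets along the
#' surface polyline — strong, random-phase point-like backscatterers spaced
#' half a wavelength, as from a rough cortical interface; (2) weak
#' sub-resolution soft-tissue speckle above the surface; and (3) multipath
#' clutter spread over the whole field of view, shadow included, whose
#' per-channel arrival times carry independent jitter so it is bright in
#' amplitude images yet spatially incoherent — the reverberant haze that
#' degrades amplitude imaging of bone in vivo. Returns the channel data
#' (acquisition `"per_line"`) with a ground-truth surface band mask.
#'
#' @inheritParams simulate_point_source
#' @param surface data frame with columns `x`, `z` (mm) tracing the bone
#'   surface; the default is a gentle lamina-like arc at ~22 mm depth
#'   spanning the aperture.
#' @param tx_sigma_mm lateral standard deviation of the focused transmit
#'   beam at the surface, mm.
#' @param speckle_level speckle scatterer amplitude relative to the bone
#'   facets.
#' @param speckle_density speckle scatterers per mm^2 of soft tissue.
#' @param clutter_level clutter scatterer amplitude relative to the bone
#'   facets.
#' @param clutter_density clutter scatterers per mm^2 of field of view.
#' @param clutter_jitter_us half-width of the uniform per-channel delay
#'   jitter of clutter arrivals, microseconds.
#' @param grid optional [image_grid()] defining both the transmit lines and
#'   the truth-mask raster (default: half-wavelength grid over the aperture
#'   down to `depth_mm`).
#' @param band_mm half-thickness of the ground-truth surface band in mm.
#' @return List with `data` (a [channel_data()], two-way, `"per_line"`),
#'   `truth_mask` (a `binary_mask` on `grid`), `surface` (the polyline) and
#'   `grid`.
#' @export
simulate_bone_scene <- function(surface = NULL, geometry = sim_geometry(),
                                fs = 16, depth_mm = 35, tx_sigma_mm = 0.8,
                                speckle_level = 0.15, speckle_density = 2,
                                clutter_level = 0.5, clutter_density = 1,
                                clutter_jitter_us = 0.5,
                                noise_level = 0.05, bandwidth = 0.6,
                                grid = NULL, band_mm = NULL, seed = NULL) {
  xmax <- max(abs(geometry$element_positions[, "x"]))
  lam <- geometry$wavelength
  if (is.null(surface)) {
    xs <- seq(-xmax, xmax, by = lam / 4)
    surface <- data.frame(x = xs, z = 22 + 6 * (xs / xmax)^2)
  }
  if (is.null(grid)) {
    grid <- image_grid(seq(-xmax, xmax, by = lam / 2),
                       seq(2, depth_mm, by = lam / 2))
  }
  if (is.null(band_mm)) band_mm <- lam / 2
  base <- sim_frame_base(geometry, fs, depth_mm, "ultrasound_two_way")
  fc <- geometry$center_frequency
  ne <- geometry$n_elements
  surf_fun <- stats::approxfun(surface$x, surface$z, rule = 2)
  with_seed(seed, {
    # scatterer populations (drawn once; shared by all transmit events)
    bx <- seq(min(surface$x), max(surface$x), by = lam / 2)
    bone <- list(pos = cbind(bx, surf_fun(bx)),
                 amp = abs(stats::rnorm(length(bx), 1, 0.3)),
                 ph = stats::runif(length(bx), 0, 2 * pi), jit = 0)
    area <- 2 * xmax * (mean(surf_fun(seq(-xmax, xmax, length.out = 64))) - 2)
    n_spk <- max(10, round(speckle_density * area))
    sx <- stats::runif(n_spk, -xmax, xmax)
    spk <- list(pos = cbind(sx, stats::runif(n_spk, 2, surf_fun(sx) - 1)),
                amp = speckle_level * abs(stats::rnorm(n_spk, 1, 0.5)),
                ph = stats::runif(n_spk, 0, 2 * pi), jit = 0)
    n_cl <- max(10, round(clutter_density * 2 * xmax * (depth_mm - 2)))
    clut <- list(pos = cbind(stats::runif(n_cl, -xmax, xmax),
                             stats::runif(n_cl, 2, depth_mm)),
                 amp = clutter_level * abs(stats::rnorm(n_cl, 1, 0.5)),
                 ph = stats::runif(n_cl, 0, 2 * pi), jit = clutter_jitter_us)
    samples <- array(0, c(base$n_time, ne, grid$nx))
    peak <- 0
    for (ix in seq_len(grid$nx)) {
      x0 <- grid$lateral[ix]
      panel <- matrix(0, base$n_time, ne)
      for (pop in list(bone, spk, clut)) {
        w <- exp(-(pop$pos[, 1] - x0)^2 / (2 * tx_sigma_mm^2))
        keep <- w > 0.01
        if (!any(keep)) next
        panel <- add_scatterers(panel, base$times, fs,
                                pop$pos[keep, , drop = FALSE],
                                pop$amp[keep] * w[keep], pop$ph[keep],
                                geometry, geometry$sound_speed,
                                "ultrasound_two_way", fc, bandwidth,
                                jitter_us = pop$jit)
      }
      samples[, , ix] <- panel
      peak <- max(peak, max(abs(panel)))
    }
    samples <- samples + array(stats::rnorm(length(samples),
                                            sd = noise_level * peak),
                               dim(samples))
    data <- channel_data(samples, fs, geometry$sound_speed,
                         "ultrasound_two_way", geometry,
                         acquisition = "per_line")
    zsurf <- surf_fun(grid$lateral)
    truth <- abs(outer(grid$axial, zsurf, "-")) <= band_mm
    list(data = data, truth_mask = binary_mask(truth, grid),
         surface = surface, grid = grid)
  })
}

#' Simulate an out-of-plane (noise-only) acquisition
#'
#' Spatially incoherent channel noise plus a few weak wavefronts whose
#' per-channel delays are random (so they never focus), emulating frames
#' whose photoacoustic source lies outside the imaging plane. At default
#' settings the beamformed frame fails the SNR > 3 in-plane test.
#'
#' @inheritParams simulate_point_source
#' @param noise_sd channel noise standard deviation.
#' @param n_wavefronts number of weak incoherent wavefronts per frame.
#' @param wavefront_amplitude wavefront amplitude relative to `noise_sd`.
#' @return A [channel_data()] with `modality = "photoacoustic_one_way"`.
#' @export
simulate_out_of_plane <- function(geometry = sim_geometry(), fs = 16,
                                  depth_mm = 45, noise_sd = 1,
                                  n_wavefronts = 3, wavefront_amplitude = 0.2,
                                  bandwidth = 0.6, n_frames = 1, seed = NULL) {
  base <- sim_frame_base(geometry, fs, depth_mm, "photoacoustic_one_way")
  fc <- geometry$center_frequency
  ne <- geometry$n_elements
  nt <- base$n_time
  with_seed(seed, {
    samples <- array(0, c(nt, ne, n_frames))
    hw <- ceiling(pulse_halfwidth_us(fc, bandwidth) * fs)
    woff <- -hw:hw
    for (f in seq_len(n_frames)) {
      sig <- matrix(stats::rnorm(nt * ne, sd = noise_sd), nt)
      for (k in seq_len(n_wavefronts)) {
        ctr <- sample.int(nt, ne, replace = TRUE)     # random delay per channel
        idx_t <- outer(ctr, woff, "+")
        tt <- sweep(idx_t, 1, ctr) / fs
        vals <- wavefront_amplitude * noise_sd * gauss_pulse(tt, fc, bandwidth)
        ok <- idx_t >= 1 & idx_t <= nt
        lin <- idx_t[ok] + (rep.int(seq_len(ne), length(woff))[ok] - 1) * nt
        sig[lin] <- sig[lin] + vals[ok]
      }
      samples[, , f] <- sig
    }
    channel_data(samples, fs, geometry$sound_speed, "photoacoustic_one_way",
                 geometry)
  })
}
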