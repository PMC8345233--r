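#' Beamform one frame with a chosen beamformer
#'
#' End-to-end image formation for a single frame: receive focusing, then the
#' requested beamformer. DAS images are envelope-detected; SLSC and LW-SLSC
#' images are coherence images (clamped at zero). The axial correlation
#' kernel length is `axial_kernel_wavelengths * wavelength`, converted to
#' samples at the data's sampling rate; LW-SLSC kernel sizes in mm are
#' converted to pixels as `round(size / spacing)` with a minimum of 2.
#'
#' @param data a [channel_data()].
#' @param grid an [image_grid()].
#' @param method `"das"`, `"slsc"` or `"lwslsc"`.
#' @param config a [run_config()].
#' @param frame frame index.
#' @param focused optional precomputed [focus_frame()] output (reused across
#'   beamformers).
#' @param stack optional precomputed [coherence_stack()].
#' @return A [bimage()].
#' @export
beamform_frame <- function(data, grid, method = c("das", "slsc", "lwslsc"),
                           config = run_config(), frame = 1,
                           focused = NULL, stack = NULL) {
  method <- match.arg(method)
  if (is.null(focused)) focused <- focus_frame(data, grid, frame)
  if (method == "das") {
    return(envelope_detect(das_rf(focused), grid, tag = "DAS"))
  }
  if (is.null(stack)) stack <- frame_coherence(data, focused, config)
  if (method == "slsc") return(slsc_image(stack, config$M))
  kz <- max(2L, round(config$kernel_axial_mm / grid$dz))
  kx <- max(2L, round(config$kernel_lateral_mm / grid$dx))
  lwslsc_image(stack, kz = kz, kx = kx, overlap = config$overlap,
               alpha = config$alpha)
}

#' Coherence stack for a focused frame under a configuration
#'
#' @inheritParams beamform_frame
#' @param focused a [focus_frame()] result.
#' @return A [coherence_stack()].
#' @export
frame_coherence <- function(data, focused, config = run_config()) {
  lam <- data$geometry$wavelength                     # mm
  c_mm_us <- data$sound_speed / 1000
  kl <- max(2L, round(config$axial_kernel_wavelengths * lam / c_mm_us *
                        data$sampling_frequency))
  coherence_stack(focused, n_lags = config$n_lags, kernel_length = kl)
}

#' Run the beamforming workflow over a recording
#'
#' Forms DAS, SLSC and/or LW-SLSC images for each requested frame (focusing
#' and the coherence stack are computed once per frame and shared), computes
#' gCNR and CNR for the supplied ROI pair, and optionally writes everything
#' via [save_results()].
#'
#' @param data a [channel_data()] or path to an HDF5 container.
#' @param grid an [image_grid()].
#' @param config a [run_config()].
#' @param beamformers subset of `c("das", "slsc", "lwslsc")`.
#' @param roi_in,roi_out optional [roi()]s for the image-quality metrics.
#' @param frames frame indices (default: all).
#' @param out_dir optional output directory; when given, images, a metrics
#'   CSV and a manifest are written.
#' @return Object of class `beamform_report`: list with `images` (nested
#'   list `[[frame]][[beamformer]]`), `metrics` (tibble: frame, beamformer,
#'   metric, value) and `manifest` (tibble or NULL).
#' @export
run_beamform <- function(data, grid, config = run_config(),
                         beamformers = c("das", "slsc", "lwslsc"),
                         roi_in = NULL, roi_out = NULL, frames = NULL,
                         out_dir = NULL) {
  if (is.character(data)) data <- read_channel_h5(data)
  beamformers <- match.arg(beamformers, several.ok = TRUE)
  if (is.null(frames)) frames <- seq_len(n_frames(data))
  images <- list()
  rows <- list()
  for (f in frames) {
    focused <- focus_frame(data, grid, f)
    stack <- if (any(beamformers != "das")) {
      frame_coherence(data, focused, config)
    }
    per <- list()
    for (b in beamformers) {
      img <- beamform_frame(data, grid, b, config, f, focused, stack)
      per[[b]] <- img
      if (!is.null(roi_in) && !is.null(roi_out)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          frame = f, beamformer = toupper(b),
          metric = c("gcnr", "cnr"),
          value = c(gcnr(img, roi_in, roi_out), cnr(img, roi_in, roi_out)))
      }
    }
    images[[as.character(f)]] <- per
  }
  metrics <- if (length(rows)) do.call(rbind, rows) else
    tibble::tibble(frame = integer(), beamformer = character(),
                   metric = character(), value = numeric())
  manifest <- NULL
  if (!is.null(out_dir)) {
    flat <- list()
    for (f in names(images)) {
      for (b in names(images[[f]])) flat[[paste0("frame", f, "_", b)]] <- images[[f]][[b]]
    }
    manifest <- save_results(images = flat, masks = list(), metrics = metrics,
                             out_dir = out_dir)
  }
  structure(list(images = images, metrics = metrics, manifest = manifest,
                 config = config),
            class = "beamform_report")
}

#' Cortical-versus-cancellous bone-contact discrimination
#'
#' Full discrimination workflow on two groups of photoacoustic frames: for
#' each frame, DAS and LW-SLSC images are formed; the per-frame SNR is
#' computed on the DAS amplitude with a square target ROI centred at the
#' LW-SLSC-estimated target centre (its brightest pixel) and an equal
#' background ROI `background_offset_mm` above it; frames with SNR at or
#' below the threshold are discarded as out-of-plane; the -6 dB contour
#' area around the target centre is measured on each surviving frame; and a
#' Welch t-test compares the per-frame areas between the two groups.
#'
#' @param frames_a,frames_b [channel_data()] objects (multi-frame) for the
#'   two contact conditions, e.g. cancellous (diffuse) and cortical
#'   (compact).
#' @param grid an [image_grid()].
#' @param config a [run_config()].
#' @param labels group labels.
#' @param beamformer image used for the area measurement (`"das"` by
#'   default, the discriminating choice; `"slsc"`/`"lwslsc"` supported).
#' @return Object of class `bone_contact_report`: the
#'   [compare_bone_contact()] `test`, per-frame tibble `areas`, and counts of
#'   discarded frames per group.
#' @export
run_bone_contact <- function(frames_a, frames_b, grid,
                             config = run_config(),
                             labels = c("cancellous", "cortical"),
                             beamformer = "das") {
  analyze_group <- function(data, label) {
    nf <- n_frames(data)
    out <- vector("list", nf)
    for (f in seq_len(nf)) {
      focused <- focus_frame(data, grid, f)
      stack <- frame_coherence(data, focused, config)
      das <- beamform_frame(data, grid, "das", config, f, focused, stack)
      lw <- beamform_frame(data, grid, "lwslsc", config, f, focused, stack)
      ctr <- brightest_pixel(lw)
      # clamp the estimated centre so target and background ROIs both fit:
      # out-of-plane frames put the brightest pixel anywhere in the image
      half <- config$roi_mm / 2
      ctr[1] <- min(max(ctr[1], grid$lateral[1] + half),
                    grid$lateral[grid$nx] - half)
      ctr[2] <- min(max(ctr[2], grid$axial[1] + half +
                          config$background_offset_mm),
                    grid$axial[grid$nz] - half)
      t_roi <- roi_square(ctr, config$roi_mm)
      b_roi <- roi_square(c(ctr[1], ctr[2] - config$background_offset_mm),
                          config$roi_mm)
      s <- snr(das, t_roi, b_roi)
      img <- switch(beamformer, das = das, lwslsc = lw,
                    slsc = beamform_frame(data, grid, "slsc", config, f,
                                          focused, stack))
      area <- if (s > config$snr_threshold) {
        contour_area_6db(img, center = ctr, roi_size_mm = config$roi_mm)
      } else {
        NA_real_
      }
      out[[f]] <- tibble::tibble(group = label, frame = f, snr = s,
                                 kept = s > config$snr_threshold,
                                 area_mm2 = area)
    }
    do.call(rbind, out)
  }
  tab <- rbind(analyze_group(frames_a, labels[1]),
               analyze_group(frames_b, labels[2]))
  kept <- tab[tab$kept, ]
  na <- sum(kept$group == labels[1]); nb <- sum(kept$group == labels[2])
  if (na < 2 || nb < 2) {
    stop("run_bone_contact: fewer than 2 in-plane frames in a group after ",
         "SNR filtering", call. = FALSE)
  }
  test <- compare_bone_contact(kept$area_mm2[kept$group == labels[1]],
                               kept$area_mm2[kept$group == labels[2]],
                               labels = labels)
  structure(list(test = test, areas = tab,
                 n_discarded = c(sum(!tab$kept[tab$group == labels[1]]),
                                 sum(!tab$kept[tab$group == labels[2]])),
                 beamformer = toupper(beamformer), config = config),
            class = "bone_contact_report")
}

#' @export
print.bone_contact_report <- function(x, ...) {
  cat(sprintf("<bone_contact_report> %s areas; %d + %d frames discarded as out-of-plane\n",
              x$beamformer, x$n_discarded[1], x$n_discarded[2]))
  print(x$test)
  invisible(x)
}

#' Write images, masks and metrics to disk
#'
#' Images are written both as 16-bit grayscale TIFF (linear amplitude,
#' normalized to the image maximum) and as NIfTI-1; masks as 8-bit PNG and
#' NIfTI; metrics as a CSV with one row per (frame, beamformer, metric).
#' Re-running with the same inputs overwrites deterministically and returns
#' an identical manifest.
#'
#' @param images named list of [bimage()]s.
#' @param masks named list of `binary_mask`s.
#' @param metrics data frame of metric rows (may be empty).
#' @param out_dir output directory (created if needed).
#' @return Tibble manifest with columns `file` and `kind`.
#' @export
save_results <- function(images = list(), masks = list(),
                         metrics = NULL, out_dir = ".") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0) {
    stop("save_results: output directory is not writable: ", out_dir,
         call. = FALSE)
  }
  files <- character(); kinds <- character()
  add <- function(path, kind) {
    files <<- c(files, path); kinds <<- c(kinds, kind)
  }
  for (nm in names(images)) {
    img <- images[[nm]]
    mx <- max(img$linear_amplitude)
    norm <- if (mx > 0) img$linear_amplitude / mx else img$linear_amplitude
    p <- file.path(out_dir, paste0(nm, ".tiff"))
    tiff::writeTIFF(norm, p, bits.per.sample = 16)
    add(p, "image_tiff")
    p <- file.path(out_dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(img$linear_amplitude), p)
    add(p, "image_nifti")
  }
  for (nm in names(masks)) {
    m <- masks[[nm]]
    p <- file.path(out_dir, paste0(nm, "_mask.png"))
    png::writePNG(m$pixels * 1, p)
    add(p, "mask_png")
    p <- file.path(out_dir, paste0(nm, "_mask.nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(m$pixels * 1), p)
    add(p, "mask_nifti")
  }
  if (!is.null(metrics)) {
    p <- file.path(out_dir, "metrics.csv")
    utils::write.csv(as.data.frame(metrics), p, row.names = FALSE)
    add(p, "metrics_csv")
  }
  manifest <- tibble::tibble(file = files, kind = kinds)
  utils::write.csv(as.data.frame(manifest),
                   file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}
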