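#' Raw per-element channel data
#'
#' Container for radio-frequency (RF) channel data prior to beamforming:
#' a `n_time x n_elements x n_frames` array of real samples together with the
#' acquisition metadata all downstream stages need. The `modality` field
#' selects the delay model: `"photoacoustic_one_way"` for receive-only
#' acoustic sources (one-way travel) and `"ultrasound_two_way"` for
#' pulse-echo data (transmit path + receive path).
#'
#' @param samples numeric array `[n_time, n_elements, n_frames]` (a matrix is
#'   promoted to a single frame).
#' @param sampling_frequency sampling rate in MHz; must exceed twice the
#'   array's centre frequency.
#' @param sound_speed assumed speed of sound in m/s.
#' @param modality `"ultrasound_two_way"` or `"photoacoustic_one_way"`.
#' @param geometry an [array_geometry()]; its element count must match the
#'   second dimension of `samples`.
#' @param start_time time of the first sample in microseconds.
#' @param acquisition `"frame"` when each slice of the third dimension is an
#'   independent full-field acquisition (plane/unfocused transmit,
#'   photoacoustic receive), or `"per_line"` when slices are successive
#'   line-by-line focused-transmit events of a single frame (slice `i`
#'   belongs to image line `i`).
#' @return An object of class `channel_data`.
#' @export
channel_data <- function(samples, sampling_frequency, sound_speed,
                         modality = c("ultrasound_two_way", "photoacoustic_one_way"),
                         geometry, start_time = 0,
                         acquisition = c("frame", "per_line")) {
  modality <- match.arg(modality)
  acquisition <- match.arg(acquisition)
  if (is.matrix(samples)) dim(samples) <- c(dim(samples), 1L)
  stopifnot(length(dim(samples)) == 3, is.numeric(samples))
  if (dim(samples)[2] != geometry$n_elements) {
    stop(sprintf("channel_data: geometry has %d elements but samples have %d channels",
                 geometry$n_elements, dim(samples)[2]), call. = FALSE)
  }
  if (!(sampling_frequency > 2 * geometry$center_frequency)) {
    stop("channel_data: sampling_frequency must exceed 2 x center_frequency",
         call. = FALSE)
  }
  if (dim(samples)[3] < 1) stop("channel_data: need at least one frame", call. = FALSE)
  structure(list(samples = samples, sampling_frequency = sampling_frequency,
                 sound_speed = sound_speed, modality = modality,
                 start_time = start_time, geometry = geometry,
                 acquisition = acquisition),
            class = "channel_data")
}

n_frames <- function(data) {
  if (data$acquisition == "per_line") 1L else dim(data$samples)[3]
}

#' @export
print.channel_data <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("<channel_data> %d samples x %d elements x %d frame(s), fs %g MHz, c %g m/s, %s\n",
              d[1], d[2], d[3], x$sampling_frequency, x$sound_speed, x$modality))
  invisible(x)
}

#' @export
dim.channel_data <- function(x) dim(x$samples)

#' Read / write channel data as HDF5
#'
#' The on-disk layout is defined by this package (there is no community
#' standard for raw RF): datasets `/rf` (time x element x frame, float64),
#' `/fs` (MHz), `/c` (m/s), `/modality` (string), `/start_time` (us) and a
#' `/geometry` group holding `n_elements`, `pitch`, `kerf`, `center_frequency`
#' (all per [array_geometry()] units) plus `curvature_radius` (mm; `-1`
#' encodes a linear array).
#'
#' @param data a [channel_data()] object.
#' @param path file path of the HDF5 container.
#' @return `write_channel_h5()` returns `path` invisibly;
#'   `read_channel_h5()` returns a [channel_data()].
#' @export
write_channel_h5 <- function(data, path) {
  stopifnot(inherits(data, "channel_data"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::H5close(), add = TRUE)
  rhdf5::h5write(data$samples, path, "rf")
  rhdf5::h5write(data$sampling_frequency, path, "fs")
  rhdf5::h5write(data$sound_speed, path, "c")
  rhdf5::h5write(data$modality, path, "modality")
  rhdf5::h5write(data$acquisition, path, "acquisition")
  rhdf5::h5write(data$start_time, path, "start_time")
  rhdf5::h5createGroup(path, "geometry")
  g <- data$geometry
  rhdf5::h5write(as.integer(g$n_elements), path, "geometry/n_elements")
  rhdf5::h5write(g$pitch, path, "geometry/pitch")
  rhdf5::h5write(g$kerf, path, "geometry/kerf")
  rhdf5::h5write(g$center_frequency, path, "geometry/center_frequency")
  rhdf5::h5write(if (is.null(g$curvature_radius)) -1 else g$curvature_radius,
                 path, "geometry/curvature_radius")
  invisible(path)
}

#' @rdname write_channel_h5
#' @export
read_channel_h5 <- function(path) {
  if (!file.exists(path)) stop("read_channel_h5: no such file: ", path, call. = FALSE)
  on.exit(rhdf5::H5close(), add = TRUE)
  present <- rhdf5::h5ls(path)
  have <- file.path(ifelse(present$group == "/", "", present$group), present$name)
  have <- sub("^/", "", gsub("^//", "", have))
  need <- c("rf", "fs", "c", "modality", "start_time",
            "geometry/n_elements", "geometry/pitch", "geometry/kerf",
            "geometry/center_frequency", "geometry/curvature_radius")
  missing <- setdiff(need, have)
  if (length(missing)) {
    stop("read_channel_h5: malformed container, missing dataset(s): ",
         paste0("/", missing, collapse = ", "), call. = FALSE)
  }
  rd <- function(nm) rhdf5::h5read(path, nm)
  rcurv <- as.numeric(rd("geometry/curvature_radius"))
  c_ms <- as.numeric(rd("c"))
  geom <- array_geometry(n_elements = as.integer(rd("geometry/n_elements")),
                         pitch = as.numeric(rd("geometry/pitch")),
                         kerf = as.numeric(rd("geometry/kerf")),
                         center_frequency = as.numeric(rd("geometry/center_frequency")),
                         curvature_radius = if (rcurv < 0) NULL else as.numeric(rcurv),
                         sound_speed = c_ms)
  rf <- rd("rf")
  if (length(dim(rf)) == 2) dim(rf) <- c(dim(rf), 1L)
  acq <- if ("acquisition" %in% have) as.character(rd("acquisition")) else "frame"
  channel_data(samples = rf, sampling_frequency = as.numeric(rd("fs")),
               sound_speed = c_ms, modality = as.character(rd("modality")),
               geometry = geom, start_time = as.numeric(rd("start_time")),
               acquisition = acq)
}
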