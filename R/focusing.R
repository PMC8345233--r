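#' Per-pixel receive delay table
#'
#' Computes the time (in microseconds) at which each element's recording
#' must be sampled to focus at each image pixel. In photoacoustic (one-way)
#' mode the delay is the receive path `|r_pixel - r_element| / c`; in
#' pulse-echo ultrasound (two-way) mode a transmit path equal to the pixel
#' depth is added, the standard approximation for an unsteered focused or
#' plane-wave transmit.
#'
#' @param geometry an [array_geometry()].
#' @param grid an [image_grid()].
#' @param sound_speed speed of sound in m/s.
#' @param modality `"photoacoustic_one_way"` or `"ultrasound_two_way"`.
#' @return A `n_pixels x n_elements` matrix of delays in microseconds, pixels
#'   in column-major image order (`nz` fastest); attribute `image_dim` holds
#'   `c(nz, nx)`.
#' @export
compute_delays <- function(geometry, grid,
                           sound_speed = geometry$sound_speed,
                           modality = c("photoacoustic_one_way", "ultrasound_two_way")) {
  modality <- match.arg(modality)
  stopifnot(sound_speed > 0)
  if (any(grid$axial < 0)) {
    stop("compute_delays: grid contains pixels behind the array face", call. = FALSE)
  }
  c_mm_us <- sound_speed / 1000  # mm per microsecond
  px <- rep(grid$lateral, each = grid$nz)
  pz <- rep(grid$axial, times = grid$nx)
  ex <- geometry$element_positions[, "x"]
  ez <- geometry$element_positions[, "z"]
  # n_pixels x n_elements receive distance
  rx <- sqrt(outer(px, ex, "-")^2 + outer(pz, ez, "-")^2)
  tau <- rx / c_mm_us
  if (modality == "ultrasound_two_way") tau <- tau + pz / c_mm_us
  attr(tau, "image_dim") <- c(grid$nz, grid$nx)
  tau
}

#' Time-align one image line of channel data
#'
#' Extracts, for one lateral image line, the per-depth time-aligned
#' aperture-domain samples `s_i(n)` that all beamformers consume. Samples are
#' read by linear (fractional-sample) interpolation at the focusing delays;
#' samples requested outside the recorded window are set to exactly zero and
#' flagged invalid; the per-channel DC level over the line's valid samples is
#' then removed so each channel is zero-mean.
#'
#' @param data a [channel_data()].
#' @param delays delay table from [compute_delays()] (microseconds).
#' @param line_index lateral image-line index (1-based).
#' @param frame frame index.
#' @return An object of class `delayed_aperture`: list with `values`
#'   (`nz x n_elements`), logical `valid` of the same shape, and `line_index`.
#' @export
delay_channels <- function(data, delays, line_index, frame = 1) {
  stopifnot(inherits(data, "channel_data"))
  dims <- attr(delays, "image_dim")
  if (is.null(dims)) stop("delay_channels: delays lack an image_dim attribute", call. = FALSE)
  nz <- dims[1]; nx <- dims[2]
  stopifnot(line_index >= 1, line_index <= nx)
  if (!all(is.finite(delays))) stop("delay_channels: delays must be finite", call. = FALSE)
  rows <- (line_index - 1) * nz + seq_len(nz)
  tau <- delays[rows, , drop = FALSE]                      # nz x N, us
  fs <- data$sampling_frequency                            # MHz -> samples/us
  s <- data$samples[, , frame]
  nt <- nrow(s)
  pos <- (tau - data$start_time) * fs + 1                  # fractional sample index
  lo <- floor(pos)
  frac <- pos - lo
  valid <- lo >= 1 & lo + 1 <= nt
  lo_c <- pmin(pmax(lo, 1), nt - 1)
  ne <- ncol(s)
  colidx <- rep(seq_len(ne), each = nz)
  v0 <- s[cbind(as.vector(lo_c), colidx)]
  v1 <- s[cbind(as.vector(lo_c) + 1L, colidx)]
  vals <- matrix((1 - as.vector(frac)) * v0 + as.vector(frac) * v1, nz, ne)
  vals[!valid] <- 0
  # per-channel DC removal over the line's valid samples
  nv <- colSums(valid)
  mu <- ifelse(nv > 0, colSums(vals) / pmax(nv, 1), 0)
  vals <- sweep(vals, 2, mu)
  vals[!valid] <- 0
  structure(list(values = vals, valid = valid, line_index = line_index),
            class = "delayed_aperture")
}

#' Focus a whole frame
#'
#' Runs [delay_channels()] over every lateral line of the grid and returns
#' the aperture cube shared by the DAS and coherence beamformers.
#'
#' @inheritParams delay_channels
#' @param grid an [image_grid()].
#' @param delays optional precomputed delay table; computed from the data's
#'   modality when `NULL`.
#' @return List with `values` (`nz x n_elements x nx` array), `valid`
#'   (same shape, logical) and the `grid`.
#' @details For `"per_line"` acquisitions (line-by-line focused transmit)
#'   each image line is focused on its own transmit event, so the third
#'   sample dimension must match the grid's line count and `frame` is
#'   ignored.
#' @export
focus_frame <- function(data, grid, frame = 1, delays = NULL) {
  if (is.null(delays)) {
    delays <- compute_delays(data$geometry, grid, data$sound_speed, data$modality)
  }
  per_line <- data$acquisition == "per_line"
  if (per_line && dim(data$samples)[3] != grid$nx) {
    stop("focus_frame: per-line acquisition has ", dim(data$samples)[3],
         " transmit events but the grid has ", grid$nx, " lines", call. = FALSE)
  }
  ne <- data$geometry$n_elements
  vals <- array(0, c(grid$nz, ne, grid$nx))
  ok <- array(FALSE, c(grid$nz, ne, grid$nx))
  for (ix in seq_len(grid$nx)) {
    ap <- delay_channels(data, delays, ix, if (per_line) ix else frame)
    vals[, , ix] <- ap$values
    ok[, , ix] <- ap$valid
  }
  list(values = vals, valid = ok, grid = grid)
}
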