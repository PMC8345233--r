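#' Synthetic vertebra-like CT phantom
#'
#' Builds a binary 3-D volume containing a vertebra-like cross-section — a
#' vertebral-body annulus enclosing a foramen, a posterior spinous process
#' and two lateral transverse processes — extruded along the third axis, with
#' a set of anatomically named landmarks and a known rigid pose. The phantom
#' is a synthetic stand-in for a bone-windowed CT volume; it exists so the
#' landmark-registration utilities can be exercised end to end with exact
#' ground truth.
#'
#' @param dims volume dimensions in voxels (>= 32 each).
#' @param voxel_mm isotropic voxel size in mm.
#' @param max_angle_deg magnitude bound of the random Euler angles of the
#'   true pose.
#' @param max_shift_mm magnitude bound of the random translation.
#' @param seed integer seed (pose and nothing else is random).
#' @return List with `volume` (binary 0/1 array), `landmarks` (canonical
#'   [landmark_set()], frame `"phantom"`), `landmarks_posed` (the same
#'   points under the true pose, frame `"ct"`), `rotation`, `translation`
#'   and `voxel_mm`.
#' @export
synth_vertebra_phantom <- function(dims = c(64, 64, 48), voxel_mm = 1,
                                   max_angle_deg = 10, max_shift_mm = 5,
                                   seed = NULL) {
  stopifnot(all(dims >= 32))
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  cx <- nx / 2; cy <- ny * 0.4
  r_out <- nx * 0.22; r_in <- nx * 0.11
  x <- seq_len(nx); y <- seq_len(ny)
  d2 <- outer((x - cx)^2, (y - cy)^2, "+")
  slice <- (d2 <= r_out^2 & d2 >= r_in^2)                       # body annulus
  sp_w <- round(nx * 0.06)
  slice[(cx - sp_w):(cx + sp_w), round(cy + r_out):min(ny, round(cy + r_out + ny * 0.25))] <- TRUE
  tp_h <- round(ny * 0.05)
  ty <- round(cy + r_out * 0.6) + (-tp_h:tp_h)
  slice[max(1, round(cx - r_out - nx * 0.18)):round(cx - r_out * 0.5), ty] <- TRUE
  slice[round(cx + r_out * 0.5):min(nx, round(cx + r_out + nx * 0.18)), ty] <- TRUE
  vol <- array(0L, dims)
  zb <- round(nz * 0.25):round(nz * 0.75)
  for (k in zb) vol[, , k] <- slice * 1L
  zmid <- mean(range(zb)) * voxel_mm
  lm <- data.frame(
    label = c("body_center", "foramen_center", "spinous_tip",
              "transverse_left", "transverse_right",
              "body_superior", "body_inferior"),
    x = voxel_mm * c(cx, cx, cx, cx - r_out - nx * 0.18, cx + r_out + nx * 0.18,
                     cx, cx),
    y = voxel_mm * c(cy, cy, cy + r_out + ny * 0.25, cy + r_out * 0.6,
                     cy + r_out * 0.6, cy - r_out, cy + r_out),
    z = c(zmid, zmid, zmid, zmid, zmid,
          zb[1] * voxel_mm, zb[length(zb)] * voxel_mm))
  canonical <- landmark_set(lm, frame = "phantom")
  with_seed(seed, {
    ang <- stats::runif(3, -max_angle_deg, max_angle_deg) * pi / 180
    Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
                c(0, sin(ang[1]), cos(ang[1])))
    Ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0),
                c(-sin(ang[2]), 0, cos(ang[2])))
    Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0),
                c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
    R <- Rz %*% Ry %*% Rx
    tr <- stats::runif(3, -max_shift_mm, max_shift_mm)
    posed <- apply_rigid_transform(
      list(rotation = R, translation = tr, fixed_frame = "ct"), canonical)
    list(volume = vol, landmarks = canonical, landmarks_posed = posed,
         rotation = R, translation = tr, voxel_mm = voxel_mm)
  })
}

#' Write a phantom (or any) volume as NIfTI-1
#'
#' @param volume 3-D numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_mm isotropic voxel size recorded in the header.
#' @return The path, invisibly.
#' @export
write_volume_nifti <- function(volume, path, voxel_mm = 1) {
  img <- RNifti::asNifti(volume, pixdim = rep(voxel_mm, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  as.array(RNifti::readNifti(path))
}
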