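#' Labeled landmark set
#'
#' A set of labeled 3-D points (mm) in a named coordinate frame, e.g. the
#' amplitude-weighted component centres of mass from segmented ultrasound /
#' photoacoustic images, or their manually identified counterparts in a CT
#' volume.
#'
#' @param points data frame with columns `label`, `x`, `y`, `z` (mm);
#'   a matrix with rownames is also accepted.
#' @param frame character frame tag (e.g. `"ultrasound"`, `"ct"`).
#' @return Object of class `landmark_set`.
#' @export
landmark_set <- function(points, frame = "ultrasound") {
  if (is.matrix(points)) {
    points <- data.frame(label = rownames(points) %||% as.character(seq_len(nrow(points))),
                         x = points[, 1], y = points[, 2], z = points[, 3])
  }
  stopifnot(all(c("label", "x", "y", "z") %in% names(points)), nrow(points) >= 1)
  if (anyDuplicated(points$label)) {
    stop("landmark_set: labels must be unique", call. = FALSE)
  }
  structure(list(points = tibble::as_tibble(points), frame = frame),
            class = "landmark_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

lm_matrix <- function(ls) {
  m <- as.matrix(ls$points[, c("x", "y", "z")])
  rownames(m) <- ls$points$label
  m
}

#' Least-squares rigid landmark registration
#'
#' Closed-form (SVD-based) rigid registration of two labeled point sets
#' matched by label: finds the proper rotation `R` (det = +1, enforced by
#' sign-correcting the smallest singular vector) and translation `t`
#' minimizing `sum ||R m_j + t - f_j||^2`. Reports the fiducial registration
#' error (FRE) per point and its RMS.
#'
#' @param moving,fixed [landmark_set()]s sharing at least 3 non-collinear
#'   labels.
#' @return Object of class `rigid_transform`: list with `rotation` (3x3),
#'   `translation` (length 3, mm), `fre` (tibble label/error), `fre_rms`
#'   (mm) and the frame tags.
#' @export
rigid_landmark_transform <- function(moving, fixed) {
  stopifnot(inherits(moving, "landmark_set"), inherits(fixed, "landmark_set"))
  common <- intersect(moving$points$label, fixed$points$label)
  if (length(common) < 3) {
    stop("rigid_landmark_transform: need at least 3 matched landmark pairs",
         call. = FALSE)
  }
  M <- lm_matrix(moving)[common, , drop = FALSE]
  F_ <- lm_matrix(fixed)[common, , drop = FALSE]
  mc <- colMeans(M); fc <- colMeans(F_)
  M0 <- sweep(M, 2, mc); F0 <- sweep(F_, 2, fc)
  if (svd(M0)$d[2] < 1e-9 * max(svd(M0)$d[1], 1)) {
    stop("rigid_landmark_transform: landmarks are collinear", call. = FALSE)
  }
  s <- svd(t(M0) %*% F0)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- fc - drop(R %*% mc)
  resid <- F_ - (M %*% t(R) + matrix(tr, nrow(M), 3, byrow = TRUE))
  fre <- sqrt(rowSums(resid^2))
  structure(list(rotation = R, translation = tr,
                 fre = tibble::tibble(label = common, error_mm = fre),
                 fre_rms = sqrt(mean(fre^2)),
                 moving_frame = moving$frame, fixed_frame = fixed$frame),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> %s -> %s, RMS FRE %.4g mm over %d landmarks\n",
              x$moving_frame, x$fixed_frame, x$fre_rms, nrow(x$fre)))
  invisible(x)
}

#' Apply a rigid transform to a landmark set
#'
#' @param transform a [rigid_landmark_transform()] result (or a list with
#'   `rotation`, `translation`).
#' @param landmarks a [landmark_set()].
#' @return A transformed [landmark_set()] in the fixed frame.
#' @export
apply_rigid_transform <- function(transform, landmarks) {
  M <- lm_matrix(landmarks)
  P <- M %*% t(transform$rotation) +
    matrix(transform$translation, nrow(M), 3, byrow = TRUE)
  landmark_set(data.frame(label = landmarks$points$label,
                          x = P[, 1], y = P[, 2], z = P[, 3]),
               frame = transform$fixed_frame %||% "fixed")
}

#' Distances from a fiducial to a set of manual markers
#'
#' Euclidean distances (mm) between a fiducial point (e.g. the registered
#' photoacoustic fiber-tip centre of mass) and each manually placed marker,
#' with the minimum-distance marker highlighted and the mean and standard
#' deviation across markers.
#'
#' @param fiducial length-3 `(x, y, z)` point in mm.
#' @param markers a [landmark_set()] of manual markers.
#' @return List with `distances` (tibble label/distance_mm/is_minimum),
#'   `mean_mm`, `sd_mm` and `closest` (label of the minimum-distance marker).
#' @export
marker_distances <- function(fiducial, markers) {
  stopifnot(length(fiducial) == 3, inherits(markers, "landmark_set"))
  M <- lm_matrix(markers)
  d <- sqrt(rowSums(sweep(M, 2, fiducial)^2))
  imin <- which.min(d)
  list(distances = tibble::tibble(label = markers$points$label,
                                  distance_mm = unname(d),
                                  is_minimum = seq_along(d) == imin),
       mean_mm = mean(d),
       sd_mm = stats::sd(d),
       closest = markers$points$label[imin])
}

#' Write / read landmark CSV
#'
#' Columns: label, x, y, z (mm), frame.
#'
#' @param landmarks a [landmark_set()].
#' @param path CSV path.
#' @return `write_landmarks_csv()` the path invisibly; `read_landmarks_csv()`
#'   a [landmark_set()].
#' @export
write_landmarks_csv <- function(landmarks, path) {
  df <- cbind(as.data.frame(landmarks$points), frame = landmarks$frame)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks_csv
#' @export
read_landmarks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  landmark_set(df[, c("label", "x", "y", "z")],
               frame = df$frame[1] %||% "unknown")
}
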