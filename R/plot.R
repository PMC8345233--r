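#' Plot a beamformed image
#'
#' Log-compressed display with the conventional grayscale map, depth
#' increasing downwards. Requires ggplot2.
#'
#' @param object a [bimage()].
#' @param dynamic_range_db display dynamic range in dB.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.bimage <- function(object, dynamic_range_db = 25, ...) {
  db <- log_compress(object, dynamic_range_db)
  df <- data.frame(x = rep(object$grid$lateral, each = object$grid$nz),
                   z = rep(object$grid$axial, times = object$grid$nx),
                   db = as.vector(db))
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = z, fill = db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(-dynamic_range_db, 0),
                                 name = "dB") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "lateral (mm)", y = "depth (mm)",
                  title = object$beamformer_tag) +
    ggplot2::theme_minimal()
}

#' Box plot of bone-contact areas
#'
#' Median, interquartile box, whiskers and crosses for values beyond 1.5
#' interquartile ranges, per contact group.
#'
#' @param object a [compare_bone_contact()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.bone_contact_test <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = group, y = area_mm2)) +
    ggplot2::geom_boxplot(coef = 1.5, outlier.shape = 4) +
    ggplot2::labs(x = NULL, y = expression("-6 dB contour area (mm"^2 * ")")) +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("x", "z", "db", "group", "area_mm2"))
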