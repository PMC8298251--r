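# ggplot2 views of the main result types.

#' Plot a segmented slice
#'
#' @param object a `slice_contours`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.slice_contours <- function(object, ...) {
  df <- tidy.slice_contours(object)
  ggplot2::ggplot(df, ggplot2::aes(x_mm, y_mm, colour = region)) +
    ggplot2::geom_polygon(fill = NA) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("slice %d", object$slice_id),
                  x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

#' Plot a lumen profile
#'
#' PWS, PWSn and FSS against the lumen point index.
#'
#' @param object a `lumen_profile`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.lumen_profile <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            cols = dplyr::any_of(c("PWS_kPa", "PWSn",
                                                   "FSS_dyncm2")),
                            names_to = "quantity", values_to = "value")
  df <- dplyr::filter(df, is.finite(value))
  ggplot2::ggplot(df, ggplot2::aes(point_index, value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "lumen point (CCW from +x ray)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a cohort comparison report
#'
#' Per-patient relative errors by model pair and quantity.
#'
#' @param object a [cohort_report()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.cohort_report <- function(object, ...) {
  ggplot2::ggplot(object$per_patient,
                  ggplot2::aes(patient_id, relative_error, fill = quantity)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~pair, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "relative error (%)") +
    ggplot2::theme_minimal()
}

#' Plot a mesh
#'
#' @param x a `mesh2d`.
#' @param ... unused.
#' @return A ggplot (corner-triangle wireframe coloured by region).
#' @export
autoplot.mesh2d <- function(x, ...) {
  tri <- x$tri
  df <- tibble::tibble(
    element = rep(seq_len(nrow(tri)), each = 3),
    region = rep(x$region, each = 3),
    xx = x$nodes[t(tri[, 1:3]), 1],
    yy = x$nodes[t(tri[, 1:3]), 2])
  ggplot2::ggplot(df, ggplot2::aes(xx, yy, group = element, fill = region)) +
    ggplot2::geom_polygon(colour = "grey30", linewidth = 0.1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}
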