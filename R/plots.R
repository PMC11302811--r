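#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an abutment profile with its extrema and boundaries
#'
#' Draws the interpolated normalized intensity profile of one leaf pair and
#' marks the valley, the flanking peaks and the half-level boundaries used
#' by the FWHM method.
#'
#' @param object An [extract_profile()] result.
#' @param prominence Passed to [find_extrema()]; set `NULL` to skip the
#'   markers.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mlc_profile <- function(object, prominence = 0.02, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(position_mm, value)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(
      x = "Position along leaf motion (mm at isocenter)",
      y = "Normalized intensity",
      title = sprintf("Abutment profile, strip %s / leaf pair %s",
                      attr(object, "strip"), attr(object, "pair"))
    ) +
    ggplot2::theme_minimal()
  if (!is.null(prominence)) {
    marks <- tryCatch({
      ex <- find_extrema(object, prominence)
      fw <- profile_fwhm(object, ex)
      tibble::tibble(
        kind = c("valley", "left peak", "right peak", "left boundary",
                 "right boundary"),
        x = c(ex$valley$position, ex$left_peak$position,
              ex$right_peak$position, fw$boundary_left, fw$boundary_right),
        y = c(ex$valley$value, ex$left_peak$value, ex$right_peak$value,
              (ex$left_peak$value + ex$valley$value) / 2,
              (ex$right_peak$value + ex$valley$value) / 2)
      )
    }, mlcqa_error = function(e) NULL)
    if (!is.null(marks)) {
      p <- p + ggplot2::geom_point(
        data = marks, ggplot2::aes(x, y, colour = kind), size = 2) +
        ggplot2::labs(colour = NULL)
    }
  }
  p
}

#' Plot a calibration curve with its points
#'
#' @param object An [fit_calibration_curve()] result.
#' @param points Optional tibble with `w_feature`, `w_abutment` to overlay
#'   (e.g. the point set the curve was fitted to).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mlc_curve <- function(object, points = NULL, ...) {
  grid <- tibble::tibble(
    w_feature = seq(object$fit_domain[1], object$fit_domain[2],
                    length.out = 200))
  grid$w_abutment <- estimate_width(object, grid$w_feature)
  p <- ggplot2::ggplot(grid, ggplot2::aes(w_feature, w_abutment)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(
      x = sprintf("Feature (%s)", object$method),
      y = "Abutment width (mm)",
      title = sprintf("Calibration curve: %s, scheme %s", object$method,
                      object$scheme)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(points)) {
    p <- p + ggplot2::geom_point(data = points, size = 1.6)
  }
  p
}

#' Per-leaf-pair QA error chart
#'
#' Shows the signed leaf-position error of every analyzed leaf against the
#' log-derived actual position, by method, with the action levels marked.
#'
#' @param object An [analyze_field()] result.
#' @param value `"error"` (vs log) or `"deviation"` (vs nominal layout).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mlc_qa <- function(object, value = "error", ...) {
  df <- tibble::as_tibble(object)
  df$.err <- df[[value]]
  levels <- attr(object, "action_levels") %||% c(0.1, 0.2)
  ggplot2::ggplot(df[!is.na(df$.err), ],
                  ggplot2::aes(pair, .err, colour = side)) +
    ggplot2::geom_hline(yintercept = c(-levels, levels),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(strip ~ method) +
    ggplot2::labs(x = "Leaf pair", y = sprintf("Leaf position %s (mm)", value),
                  colour = "Leaf") +
    ggplot2::theme_minimal()
}
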