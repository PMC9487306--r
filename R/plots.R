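#' Plot an MCI heatmap
#'
#' Control points (gantry order) on x, collimator angle on y, MCI as fill.
#' When a sub-arc plan is supplied, its per-sub-arc collimator angles are
#' overlaid as black horizontal segments with vertical boundaries, the usual
#' way sub-arc collimator choices are displayed on these maps.
#'
#' @param object An `mci_heatmap`.
#' @param plan Optional `subarc_plan` overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mci_heatmap <- function(object, plan = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$cp, y = .data$theta,
                                        fill = .data$mci)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "MCI", limits = c(NA, 1)) +
    ggplot2::labs(x = "control point (gantry order)",
                  y = "collimator angle (deg)") +
    ggplot2::coord_cartesian(expand = FALSE) +
    ggplot2::theme_minimal()
  if (!is.null(plan)) {
    seg <- tidy(plan)
    p <- p +
      ggplot2::geom_segment(
        data = seg, inherit.aes = FALSE, linewidth = 1, colour = "black",
        ggplot2::aes(x = .data$cp_start - 0.5, xend = .data$cp_end + 0.5,
                     y = .data$collimator, yend = .data$collimator)) +
      ggplot2::geom_vline(xintercept = seg$cp_end[-nrow(seg)] + 0.5,
                          colour = "black", linetype = 2)
  }
  p
}

#' Plot a BEV mask with its fitted aperture
#'
#' @param bev A `bev_mask`.
#' @param aperture Optional `mlc_aperture` to overlay (open leaf rectangles
#'   and the jaw rectangle).
#' @return A ggplot.
#' @export
plot_bev <- function(bev, aperture = NULL) {
  stopifnot(inherits(bev, "bev_mask"))
  idx <- which(bev$pixels, arr.ind = TRUE)
  df <- tibble(u = bev$u_centers[idx[, 1]], v = bev$v_centers[idx[, 2]])
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$u, .data$v)) +
    ggplot2::geom_tile(width = bev$pixel_spacing, height = bev$pixel_spacing,
                       fill = "steelblue") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "u, leaf travel (mm)", y = "v, leaf stacking (mm)") +
    ggplot2::theme_minimal()
  if (!is.null(aperture)) {
    op <- aperture[aperture$open, ]
    jaw <- attr(aperture, "jaw")
    p <- p +
      ggplot2::geom_rect(data = op, inherit.aes = FALSE, fill = NA,
                         colour = "grey30",
                         ggplot2::aes(xmin = .data$u_left, xmax = .data$u_right,
                                      ymin = .data$v_low, ymax = .data$v_high)) +
      ggplot2::annotate("rect", xmin = jaw["u_min"], xmax = jaw["u_max"],
                        ymin = jaw["v_min"], ymax = jaw["v_max"],
                        colour = "red", fill = NA, linewidth = 0.8)
  }
  p
}

#' Plot a cumulative DVH curve
#'
#' @param object A `dvh_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dvh_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$dose, 100 * .data$volume_frac)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "dose (Gy)", y = "volume (%)") +
    ggplot2::theme_minimal()
}
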