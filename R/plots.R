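#' Plot a normalised eyelid margin
#'
#' Margin polyline in the pupil-centred frame with the ten multiple-MRD1
#' sampling positions and the marginal peak point marked.
#'
#' @param eye A `normalized_eye` (or margin data frame with `x`, `y`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_normalized_eye <- function(eye, ...) {
  m <- margin_of(eye)
  prof <- contour_profile(eye)
  pk <- peak_point(eye)
  ggplot2::ggplot(m, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted", colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted", colour = "grey50") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_segment(
      data = dplyr::filter(prof, !is.na(.data$height_mm)),
      ggplot2::aes(x = .data$x_mm, xend = .data$x_mm, y = 0,
                   yend = .data$height_mm),
      inherit.aes = FALSE, colour = "grey40", linewidth = 0.3
    ) +
    ggplot2::geom_point(
      data = dplyr::filter(prof, !is.na(.data$height_mm)),
      ggplot2::aes(x = .data$x_mm, y = .data$height_mm),
      inherit.aes = FALSE, size = 1.8
    ) +
    ggplot2::geom_point(data = pk, ggplot2::aes(x = .data$x_mm, y = .data$y_mm),
                        inherit.aes = FALSE, colour = "firebrick", size = 2.5,
                        shape = 17) +
    ggplot2::labs(x = "horizontal distance from pupil centre (mm, temporal +)",
                  y = "height above pupil centre (mm)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.normalized_eye <- function(object, ...) plot_normalized_eye(object, ...)

#' Plot a cohort contour-change table
#'
#' Group-mean contours of the preoperative, postoperative and fellow
#' eyelids across the ten grid positions; positions with a significant
#' postoperative elevation are marked with an asterisk.
#'
#' @param table A [contour_change_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_contour_change <- function(table, ...) {
  stopifnot(inherits(table, "contour_change_table"))
  long <- tibble::as_tibble(table) |>
    dplyr::select(dplyr::all_of(c("position", "x_mm", "mean_pre", "mean_post",
                                  "mean_fellow"))) |>
    tidyr::pivot_longer(dplyr::starts_with("mean_"), names_to = "group",
                        names_prefix = "mean_", values_to = "mean_mm") |>
    dplyr::mutate(group = factor(.data$group,
                                 levels = c("pre", "post", "fellow"),
                                 labels = c("preoperative", "postoperative",
                                            "fellow eyelid")))
  stars <- tibble::as_tibble(table) |>
    dplyr::filter(.data$sig_change) |>
    dplyr::mutate(y = pmax(.data$mean_pre, .data$mean_post,
                           .data$mean_fellow, na.rm = TRUE) + 0.3)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$x_mm, y = .data$mean_mm,
                                          colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = MRD_X, labels = MRD_LABELS) +
    ggplot2::labs(x = "position", y = "mean margin height (mm)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (nrow(stars) > 0) {
    p <- p + ggplot2::geom_text(data = stars,
                                ggplot2::aes(x = .data$x_mm, y = .data$y,
                                             label = "*"),
                                inherit.aes = FALSE, size = 5)
  }
  p
}

#' @export
autoplot.contour_change_table <- function(object, ...) {
  plot_contour_change(object, ...)
}

#' Plot peak-point shifts
#'
#' Group-mean marginal peak points (pre, post, fellow) in the
#' pupil-centred plane, joined in chronological order.
#'
#' @param summary A [peak_shift_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_peak_shift <- function(summary, ...) {
  stopifnot(inherits(summary, "peak_shift_summary"))
  wide <- tibble::as_tibble(summary) |>
    dplyr::select(dplyr::all_of(c("coordinate", "mean_pre", "mean_post",
                                  "mean_fellow"))) |>
    tidyr::pivot_longer(-"coordinate", names_to = "group",
                        names_prefix = "mean_") |>
    tidyr::pivot_wider(names_from = "coordinate", values_from = "value") |>
    dplyr::mutate(group = factor(.data$group,
                                 levels = c("pre", "post", "fellow")))
  ggplot2::ggplot(wide, ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$group)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_path(data = dplyr::filter(wide, .data$group != "fellow"),
                       colour = "grey60",
                       arrow = ggplot2::arrow(length = ggplot2::unit(3, "mm"))) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "peak x (mm, temporal +)", y = "peak y (mm)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.peak_shift_summary <- function(object, ...) plot_peak_shift(object, ...)
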