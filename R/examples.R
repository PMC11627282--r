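#' Example group-mean contour profiles
#'
#' Illustrative group-mean multiple-MRD1 heights (mm) for a cohort of
#' unilateral ptosis patients treated with external levator advancement:
#' the ptotic eyelid before and 6 months after surgery, and the
#' non-ptotic fellow eyelid.  A piecewise-linear contour through any of
#' these rows is a convenient worked example for [peak_point()] and
#' [mrd1()].
#'
#' @return A tibble with columns `group` (`"preoperative"`,
#'   `"postoperative"`, `"fellow"`), `position`, `x_mm`, `height_mm`.
#' @examples
#' means <- example_group_means()
#' fellow <- dplyr::filter(means, group == "fellow")
#' peak_point(data.frame(x = fellow$x_mm, y = fellow$height_mm))
#' @export
example_group_means <- function() {
  g <- mrd_grid()
  tibble::tibble(
    group = rep(c("preoperative", "postoperative", "fellow"), each = 10),
    position = rep(g$position, 3),
    x_mm = rep(g$x_mm, 3),
    height_mm = c(
      0.08, 0.75, 1.20, 1.40, 1.46, 1.29, 0.90, 0.39, -0.24, -1.14,
      0.23, 1.23, 1.90, 2.34, 2.43, 2.19, 1.72, 0.93, 0.02, -1.00,
      0.61, 1.64, 2.31, 2.82, 2.88, 2.78, 2.51, 1.90, 1.06, -0.17
    )
  )
}
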