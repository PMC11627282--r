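# The fixed multiple-MRD1 sampling grid: 2 mm steps, 8 mm nasal to
# 10 mm temporal of the pupil centre.  The x = 0 position is the MRD1.
MRD_LABELS <- c("N8", "N6", "N4", "N2", "MRD1", "T2", "T4", "T6", "T8", "T10")
MRD_X <- seq(-8, 10, by = 2)

#' The multiple-MRD1 sampling grid
#'
#' Ten positions along the upper-eyelid margin at 2 mm intervals in a
#' pupil-centred frame: 8 mm nasal (`N8`--`N2`, negative x) to 10 mm
#' temporal (`T2`--`T10`, positive x) of the pupil centre.  The height at
#' `x = 0` is the classical margin reflex distance (MRD1).
#'
#' @return A tibble with columns `position` (factor, levels `N8` ... `T10`)
#'   and `x_mm` (numeric, -8 to 10).
#' @examples
#' mrd_grid()
#' @export
mrd_grid <- function() {
  tibble::tibble(
    position = factor(MRD_LABELS, levels = MRD_LABELS),
    x_mm = MRD_X
  )
}
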