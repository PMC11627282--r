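#' Measure one annotated photograph
#'
#' Normalises both eyes ([normalize_photo()]) and measures the
#' multiple-MRD1 contour profile and the marginal peak point of each,
#' labelling each eye as `"ptotic"` or `"fellow"` according to the
#' photograph's `ptotic_side`.
#'
#' @param photo A [photo_annotation()].
#' @param interp Interpolation mode for [height_at()].
#' @param calibration Calibration source for [normalize_photo()].
#' @return A list with
#'   `profiles` (tibble: `patient_id`, `timepoint`, `side`, `eye_role`,
#'   `position`, `x_mm`, `height_mm`),
#'   `peaks` (tibble: `patient_id`, `timepoint`, `side`, `eye_role`,
#'   `x_mm`, `y_mm`), and
#'   `log` (one-row tibble of normalisation parameters: tilt and the two
#'   scales).
#' @export
measure_photo <- function(photo, interp = c("linear", "monotone"),
                          calibration = c("per_eye", "mean")) {
  interp <- match.arg(interp)
  calibration <- match.arg(calibration)
  norm <- normalize_photo(photo, calibration = calibration)
  one_side <- function(side) {
    eye <- norm[[side]]
    role <- if (side == photo$ptotic_side) "ptotic" else "fellow"
    prof <- contour_profile(eye, interp = interp) |>
      dplyr::mutate(patient_id = photo$patient_id,
                    timepoint = photo$timepoint,
                    side = side, eye_role = role, .before = 1)
    pk <- peak_point(eye) |>
      dplyr::mutate(patient_id = photo$patient_id,
                    timepoint = photo$timepoint,
                    side = side, eye_role = role, .before = 1)
    list(prof = prof, pk = pk)
  }
  res <- lapply(c("right", "left"), one_side)
  list(
    profiles = dplyr::bind_rows(purrr::map(res, "prof")),
    peaks = dplyr::bind_rows(purrr::map(res, "pk")),
    log = tibble::tibble(
      patient_id = photo$patient_id, timepoint = photo$timepoint,
      tilt_deg = norm$tilt_deg,
      scale_right_mm_per_px = norm$right$scale_mm_per_px,
      scale_left_mm_per_px = norm$left$scale_mm_per_px
    )
  )
}

#' Measure a collection of photographs
#'
#' Applies [measure_photo()] to every photograph and row-binds the
#' results.  Accepts a list of [photo_annotation()] objects or a
#' [synth_cohort()].
#'
#' @param photos List of `photo_annotation`s, or a `synth_cohort`.
#' @param arms Optional named character vector mapping `patient_id` to
#'   arm; for a `synth_cohort` the arm is taken from the cohort itself.
#' @inheritParams measure_photo
#' @return A list with long tibbles `profiles`, `peaks`, and `log` (see
#'   [measure_photo()]), each with an `arm` column when arms are known.
#' @export
measure_cohort <- function(photos, arms = NULL,
                           interp = c("linear", "monotone"),
                           calibration = c("per_eye", "mean")) {
  if (inherits(photos, "synth_cohort")) {
    arms <- setNames(rep(photos$arm, length(photos$patients)),
                     vapply(photos$patients, `[[`, "", "patient_id"))
    photos <- cohort_photos(photos)
  }
  stopifnot(is.list(photos), length(photos) > 0)
  res <- lapply(photos, measure_photo, interp = interp,
                calibration = calibration)
  out <- list(
    profiles = dplyr::bind_rows(purrr::map(res, "profiles")),
    peaks = dplyr::bind_rows(purrr::map(res, "peaks")),
    log = dplyr::bind_rows(purrr::map(res, "log"))
  )
  if (!is.null(arms)) {
    out$profiles <- dplyr::mutate(out$profiles,
                                  arm = unname(arms[.data$patient_id]),
                                  .after = "patient_id")
    out$peaks <- dplyr::mutate(out$peaks,
                               arm = unname(arms[.data$patient_id]),
                               .after = "patient_id")
  }
  out
}
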