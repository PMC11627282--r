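#' Sex-specific white-to-white calibration constant
#'
#' Horizontal corneal (white-to-white) diameter used as the in-image
#' metric standard: 11.77 mm for men, 11.64 mm for women.
#'
#' @param sex `"male"` or `"female"`.
#' @return The white-to-white diameter in millimetres.
#' @export
wtw_mm <- function(sex) {
  sex <- match.arg(sex, c("male", "female"))
  if (sex == "male") 11.77 else 11.64
}

rotate_about <- function(p, theta_deg, center) {
  th <- theta_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  as.numeric(R %*% (p - center) + center)
}

#' Head-tilt angle from the inter-canthal line
#'
#' Signed angle, in degrees, of the line joining the two lateral canthi
#' relative to the image horizontal, in the raster coordinate system
#' (y grows downward).  The result is in (-90, 90] and is independent of
#' which canthus is taken first; rotating the photograph by its negation
#' (see [apply_rotation()]) makes the inter-canthal line horizontal.
#'
#' @param photo A [photo_annotation()].
#' @return Angle in degrees.
#' @export
tilt_angle <- function(photo) {
  stopifnot(inherits(photo, "photo_annotation"))
  p1 <- photo$eyes$right$lateral_canthus
  p2 <- photo$eyes$left$lateral_canthus
  d <- p2 - p1
  if (sqrt(sum(d^2)) == 0) {
    stop("lateral canthi coincide; tilt angle undefined", call. = FALSE)
  }
  ang <- atan2(d[2], d[1]) * 180 / pi
  if (ang > 90) ang <- ang - 180
  if (ang <= -90) ang <- ang + 180
  ang
}

#' Rigidly rotate all landmarks of a photograph
#'
#' Rotates every landmark of both eyes by `-angle` degrees about the
#' inter-canthal midpoint, so that `apply_rotation(photo, tilt_angle(photo))`
#' levels the inter-canthal line (tilt correction).  The transform is
#' rigid: all pairwise distances are preserved.
#'
#' @param photo A [photo_annotation()].
#' @param angle Angle in degrees (typically the output of [tilt_angle()]).
#' @return A new `photo_annotation` with rotated landmarks.
#' @export
apply_rotation <- function(photo, angle) {
  stopifnot(inherits(photo, "photo_annotation"))
  if (!is.finite(angle)) stop("`angle` must be finite", call. = FALSE)
  center <- (photo$eyes$right$lateral_canthus +
             photo$eyes$left$lateral_canthus) / 2
  rot_eye <- function(eye) {
    m <- cbind(eye$margin$x, eye$margin$y)
    th <- -angle * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    mc <- sweep(m, 2, center) %*% t(R)
    mc <- sweep(mc, 2, center, `+`)
    eye_annotation(
      side = eye$side,
      pupil_center = rotate_about(eye$pupil_center, -angle, center),
      limbus_nasal = rotate_about(eye$limbus_nasal, -angle, center),
      limbus_temporal = rotate_about(eye$limbus_temporal, -angle, center),
      lateral_canthus = rotate_about(eye$lateral_canthus, -angle, center),
      margin = tibble::tibble(x = mc[, 1], y = mc[, 2]),
      pupil_diameter = eye$pupil_diameter
    )
  }
  photo_annotation(
    patient_id = photo$patient_id,
    timepoint = photo$timepoint,
    sex = photo$sex,
    ptotic_side = photo$ptotic_side,
    eyes = lapply(photo$eyes, rot_eye),
    image_path = photo$image_path,
    metadata = photo$metadata
  )
}

#' Millimetres-per-pixel scale from the white-to-white distance
#'
#' Metric calibration of one eye: the sex-specific white-to-white
#' diameter ([wtw_mm()]) divided by the pixel distance between the nasal
#' and temporal limbus landmarks.
#'
#' @param eye An [eye_annotation()].
#' @param sex `"male"` or `"female"`.
#' @return Scale in mm per pixel.
#' @export
mm_scale <- function(eye, sex) {
  stopifnot(inherits(eye, "eye_annotation"))
  d <- sqrt(sum((eye$limbus_temporal - eye$limbus_nasal)^2))
  if (d == 0) stop("limbus points coincide; scale undefined", call. = FALSE)
  wtw_mm(sex) / d
}

#' Map a tilt-corrected eye into the pupil-centred millimetre frame
#'
#' Expresses the eyelid margin in the measurement frame of the contour
#' metrics: origin at the pupil centre, units millimetres, y up (positive
#' heights above the pupil centre), and x temporal-positive -- the x axis
#' is oriented so the eye's own lateral canthus has positive x, which
#' makes nasal positions negative for either eye.  Margin points are
#' re-sorted by increasing x and consecutive duplicate x are collapsed to
#' their mean y, so the margin is a function of x.
#'
#' @param eye A tilt-corrected [eye_annotation()].
#' @param scale Scale in mm per pixel (see [mm_scale()]).
#' @param tilt_deg Tilt correction that was applied, recorded for
#'   provenance (does not affect the transform).
#' @return An object of class `normalized_eye`: a list with `side`,
#'   `margin` (tibble `x`, `y` in mm, x strictly increasing),
#'   `scale_mm_per_px`, `tilt_deg`, and `canthus_x_mm` (> 0).
#' @export
to_pupil_frame <- function(eye, scale, tilt_deg = 0) {
  stopifnot(inherits(eye, "eye_annotation"))
  if (!is.numeric(scale) || length(scale) != 1 || !is.finite(scale) ||
      scale <= 0) {
    stop("`scale` must be a single positive number (mm/px)", call. = FALSE)
  }
  pc <- eye$pupil_center
  tsign <- sign(eye$lateral_canthus[1] - pc[1])
  if (tsign == 0) {
    stop("lateral canthus is vertically aligned with the pupil; temporal direction undefined",
         call. = FALSE)
  }
  x <- tsign * (eye$margin$x - pc[1]) * scale
  y <- -(eye$margin$y - pc[2]) * scale
  ord <- order(x)
  m <- tibble::tibble(x = x[ord], y = y[ord]) |>
    dplyr::summarise(y = mean(.data$y), .by = "x")
  if (nrow(m) < 2) {
    stop("margin has fewer than 2 distinct x positions after collapsing duplicates",
         call. = FALSE)
  }
  structure(
    list(
      side = eye$side,
      margin = m,
      scale_mm_per_px = scale,
      tilt_deg = tilt_deg,
      canthus_x_mm = tsign * (eye$lateral_canthus[1] - pc[1]) * scale
    ),
    class = "normalized_eye"
  )
}

#' @export
print.normalized_eye <- function(x, ...) {
  cat(sprintf("<normalized_eye> %s eye, %d margin points, x in [%.2f, %.2f] mm, scale %.4f mm/px, tilt %.2f deg\n",
              x$side, nrow(x$margin), min(x$margin$x), max(x$margin$x),
              x$scale_mm_per_px, x$tilt_deg))
  invisible(x)
}

#' Normalise both eyes of a photograph
#'
#' Full normalisation chain: measure the head tilt from the inter-canthal
#' line, rotate it away, calibrate pixels to millimetres from the
#' white-to-white distance, and map each eye into its pupil-centred
#' temporal-positive frame.
#'
#' @param photo A [photo_annotation()].
#' @param calibration `"per_eye"` (each eye calibrated from its own
#'   limbus landmarks, the default) or `"mean"` (both eyes use the mean
#'   of the two scales).
#' @return A list with elements `right` and `left`
#'   ([to_pupil_frame()] results) plus `tilt_deg`.
#' @export
normalize_photo <- function(photo, calibration = c("per_eye", "mean")) {
  calibration <- match.arg(calibration)
  ang <- tilt_angle(photo)
  ph <- apply_rotation(photo, ang)
  scales <- vapply(ph$eyes, mm_scale, numeric(1), sex = photo$sex)
  if (calibration == "mean") scales[] <- mean(scales)
  list(
    right = to_pupil_frame(ph$eyes$right, scales[["right"]], tilt_deg = ang),
    left = to_pupil_frame(ph$eyes$left, scales[["left"]], tilt_deg = ang),
    tilt_deg = ang
  )
}
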