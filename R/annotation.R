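ANNOTATION_SCHEMA_VERSION <- "1.0"

as_margin <- function(margin, name = "margin") {
  if (is.matrix(margin) && ncol(margin) == 2) {
    margin <- tibble::tibble(x = margin[, 1], y = margin[, 2])
  }
  if (!is.data.frame(margin) || !all(c("x", "y") %in% names(margin))) {
    stop(sprintf("`%s` must be a two-column matrix or a data frame with columns x and y",
                 name), call. = FALSE)
  }
  m <- tibble::tibble(x = as.numeric(margin$x), y = as.numeric(margin$y))
  if (nrow(m) < 2) {
    stop(sprintf("`%s` must contain at least 2 points", name), call. = FALSE)
  }
  if (!all(is.finite(m$x)) || !all(is.finite(m$y))) {
    stop(sprintf("`%s` contains non-finite coordinates", name), call. = FALSE)
  }
  m
}

#' Single-eye landmark annotation
#'
#' Bundles the manually placed landmarks of one eye in raw pixel
#' coordinates (raster convention: y grows downward): pupil centre, nasal
#' and temporal limbus (the white-to-white endpoints used for metric
#' calibration), the lateral canthus, and the traced upper-eyelid-margin
#' polyline.
#'
#' @param side `"right"` or `"left"`.
#' @param pupil_center,limbus_nasal,limbus_temporal,lateral_canthus
#'   Length-2 numeric `(x, y)` in pixels.
#' @param margin Upper-eyelid margin polyline: a data frame with columns
#'   `x`, `y` (pixels) or a two-column matrix; at least 2 points.
#' @param pupil_diameter Optional pupil diameter in pixels (> 0).
#' @return An object of class `eye_annotation`.
#' @seealso [photo_annotation()]
#' @export
eye_annotation <- function(side, pupil_center, limbus_nasal, limbus_temporal,
                           lateral_canthus, margin, pupil_diameter = NULL) {
  side <- match.arg(side, c("right", "left"))
  pupil_center <- check_point(pupil_center, "pupil_center")
  limbus_nasal <- check_point(limbus_nasal, "limbus_nasal")
  limbus_temporal <- check_point(limbus_temporal, "limbus_temporal")
  lateral_canthus <- check_point(lateral_canthus, "lateral_canthus")
  if (identical(limbus_nasal, limbus_temporal)) {
    stop("`limbus_nasal` and `limbus_temporal` must be distinct points",
         call. = FALSE)
  }
  if (!is.null(pupil_diameter)) {
    pupil_diameter <- as.numeric(pupil_diameter)
    if (length(pupil_diameter) != 1 || !is.finite(pupil_diameter) ||
        pupil_diameter <= 0) {
      stop("`pupil_diameter` must be a single positive finite number",
           call. = FALSE)
    }
  }
  structure(
    list(
      side = side,
      pupil_center = pupil_center,
      pupil_diameter = pupil_diameter,
      limbus_nasal = limbus_nasal,
      limbus_temporal = limbus_temporal,
      lateral_canthus = lateral_canthus,
      margin = as_margin(margin)
    ),
    class = "eye_annotation"
  )
}

#' Whole-photograph landmark annotation
#'
#' One frontal photograph of a unilateral-ptosis patient: landmark sets
#' for both eyes, patient sex (which selects the white-to-white
#' calibration constant), the ptotic side, and the study timepoint.
#'
#' @param patient_id Non-empty string.
#' @param timepoint `"preop"` or `"postop6m"`.
#' @param sex `"male"` or `"female"`.
#' @param ptotic_side `"right"` or `"left"`.
#' @param eyes Named list with elements `right` and `left`, each an
#'   [eye_annotation()] whose `side` matches its name.
#' @param image_path Optional path of the underlying raster image.
#' @param metadata Free-form named list (e.g. levator function); not used
#'   computationally.
#' @return An object of class `photo_annotation`.
#' @export
photo_annotation <- function(patient_id, timepoint, sex, ptotic_side, eyes,
                             image_path = NULL, metadata = list()) {
  if (!is.character(patient_id) || length(patient_id) != 1 ||
      !nzchar(patient_id)) {
    stop("`patient_id` must be a non-empty string", call. = FALSE)
  }
  timepoint <- match.arg(timepoint, c("preop", "postop6m"))
  sex <- match.arg(sex, c("male", "female"))
  ptotic_side <- match.arg(ptotic_side, c("right", "left"))
  if (!is.list(eyes) || !setequal(names(eyes), c("right", "left"))) {
    stop("`eyes` must be a named list with exactly the elements \"right\" and \"left\"",
         call. = FALSE)
  }
  for (s in c("right", "left")) {
    if (!inherits(eyes[[s]], "eye_annotation")) {
      stop(sprintf("`eyes$%s` must be an eye_annotation", s), call. = FALSE)
    }
    if (!identical(eyes[[s]]$side, s)) {
      stop(sprintf("`eyes$%s` has side \"%s\"; sides must match their names",
                   s, eyes[[s]]$side), call. = FALSE)
    }
  }
  if (!is.list(metadata)) stop("`metadata` must be a list", call. = FALSE)
  structure(
    list(
      schema_version = ANNOTATION_SCHEMA_VERSION,
      patient_id = patient_id,
      timepoint = timepoint,
      sex = sex,
      ptotic_side = ptotic_side,
      eyes = eyes[c("right", "left")],
      image_path = image_path,
      metadata = metadata
    ),
    class = "photo_annotation"
  )
}

#' @export
print.photo_annotation <- function(x, ...) {
  cat(sprintf("<photo_annotation> patient %s, %s, %s, ptotic side: %s\n",
              x$patient_id, x$timepoint, x$sex, x$ptotic_side))
  for (s in c("right", "left")) {
    cat(sprintf("  %s eye: %d margin points\n", s, nrow(x$eyes[[s]]$margin)))
  }
  invisible(x)
}

eye_to_list <- function(eye) {
  out <- list(
    side = eye$side,
    pupil_center = eye$pupil_center,
    limbus_nasal = eye$limbus_nasal,
    limbus_temporal = eye$limbus_temporal,
    lateral_canthus = eye$lateral_canthus,
    margin = list(x = eye$margin$x, y = eye$margin$y)
  )
  if (!is.null(eye$pupil_diameter)) out$pupil_diameter <- eye$pupil_diameter
  out
}

#' Write a photo annotation to a JSON file
#'
#' Serialises a [photo_annotation()] to the package's versioned JSON
#' annotation schema (full double precision, so [read_photo_annotation()]
#' restores every coordinate bit-exactly).
#'
#' @param photo A `photo_annotation`.
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_photo_annotation <- function(photo, path) {
  stopifnot(inherits(photo, "photo_annotation"))
  doc <- list(
    schema_version = ANNOTATION_SCHEMA_VERSION,
    patient_id = photo$patient_id,
    timepoint = photo$timepoint,
    sex = photo$sex,
    ptotic_side = photo$ptotic_side,
    eyes = lapply(photo$eyes, eye_to_list),
    image_path = photo$image_path,
    metadata = photo$metadata
  )
  # 17 significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

require_field <- function(doc, field, where = "annotation") {
  if (is.null(doc[[field]])) {
    stop(sprintf("annotation schema error: missing field `%s` in %s",
                 field, where), call. = FALSE)
  }
  doc[[field]]
}

eye_from_list <- function(doc, where) {
  for (f in c("side", "pupil_center", "limbus_nasal", "limbus_temporal",
              "lateral_canthus", "margin")) {
    require_field(doc, f, where)
  }
  margin <- doc$margin
  if (is.null(margin$x) || is.null(margin$y)) {
    stop(sprintf("annotation schema error: `margin` in %s must have x and y arrays",
                 where), call. = FALSE)
  }
  eye_annotation(
    side = doc$side,
    pupil_center = unlist(doc$pupil_center),
    limbus_nasal = unlist(doc$limbus_nasal),
    limbus_temporal = unlist(doc$limbus_temporal),
    lateral_canthus = unlist(doc$lateral_canthus),
    margin = tibble::tibble(x = unlist(margin$x), y = unlist(margin$y)),
    pupil_diameter = doc$pupil_diameter
  )
}

#' Read a photo annotation from a JSON file
#'
#' Parses and fully validates an annotation file written by
#' [write_photo_annotation()] (or by any tool following the same schema).
#' Missing fields raise a schema error naming the field; invalid values
#' (an absent eye, non-finite coordinates, a non-positive pupil diameter)
#' raise validation errors.
#'
#' @param path Path to a JSON annotation file.
#' @return A validated [photo_annotation()].
#' @export
read_photo_annotation <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  require_field(doc, "schema_version")
  for (f in c("patient_id", "timepoint", "sex", "ptotic_side", "eyes")) {
    require_field(doc, f)
  }
  if (is.null(doc$eyes$right) || is.null(doc$eyes$left)) {
    stop("validation error: both `eyes$right` and `eyes$left` must be present",
         call. = FALSE)
  }
  eyes <- list(
    right = eye_from_list(doc$eyes$right, "eyes$right"),
    left = eye_from_list(doc$eyes$left, "eyes$left")
  )
  photo_annotation(
    patient_id = doc$patient_id,
    timepoint = doc$timepoint,
    sex = doc$sex,
    ptotic_side = doc$ptotic_side,
    eyes = eyes,
    image_path = doc$image_path,
    metadata = if (is.null(doc$metadata)) list() else doc$metadata
  )
}

#' Write a table of contour profiles to CSV
#'
#' Serialises measured multiple-MRD1 profiles, one row per
#' (patient, timepoint, eye role), with the ten positions as columns in
#' fixed nasal-to-temporal order `N8, N6, N4, N2, MRD1, T2, T4, T6, T8,
#' T10`.  Missing heights (positions outside the traced margin) are
#' written as empty cells.
#'
#' @param profiles Long tibble with columns `patient_id`, `timepoint`,
#'   `eye_role`, `position`, `height_mm` (as produced by
#'   [measure_photo()] / [measure_cohort()], where `eye_role` is
#'   `"ptotic"` or `"fellow"`).
#' @param path File to write.
#' @return The wide tibble that was written, invisibly.
#' @export
write_profile_table <- function(profiles, path) {
  stopifnot(is.data.frame(profiles))
  needed <- c("patient_id", "timepoint", "eye_role", "position", "height_mm")
  missing_cols <- setdiff(needed, names(profiles))
  if (length(missing_cols)) {
    stop(sprintf("`profiles` lacks columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(profiles) == 0) stop("`profiles` is empty", call. = FALSE)
  dup <- profiles |>
    dplyr::count(.data$patient_id, .data$timepoint, .data$eye_role,
                 .data$position) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate (patient_id, timepoint, eye_role) profile entries",
         call. = FALSE)
  }
  wide <- profiles |>
    dplyr::mutate(position = factor(as.character(.data$position),
                                    levels = MRD_LABELS)) |>
    tidyr::pivot_wider(id_cols = c("patient_id", "timepoint", "eye_role"),
                       names_from = "position",
                       values_from = "height_mm",
                       names_expand = TRUE) |>
    dplyr::select(dplyr::all_of(c("patient_id", "timepoint", "eye_role",
                                  MRD_LABELS)))
  readr::write_csv(wide, path, na = "")
  invisible(wide)
}

#' Read a contour-profile CSV back into long form
#'
#' Inverse of [write_profile_table()]; empty cells become `NA`.
#'
#' @param path CSV file written by [write_profile_table()].
#' @return Long tibble with columns `patient_id`, `timepoint`,
#'   `eye_role`, `position`, `x_mm`, `height_mm`.
#' @export
read_profile_table <- function(path) {
  wide <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    timepoint = readr::col_character(),
    eye_role = readr::col_character(),
    .default = readr::col_double()
  ))
  wide |>
    tidyr::pivot_longer(dplyr::all_of(MRD_LABELS), names_to = "position",
                        values_to = "height_mm") |>
    dplyr::mutate(position = factor(.data$position, levels = MRD_LABELS),
                  x_mm = MRD_X[as.integer(.data$position)]) |>
    dplyr::select(dplyr::all_of(c("patient_id", "timepoint", "eye_role",
                                  "position", "x_mm", "height_mm")))
}
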