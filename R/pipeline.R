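#' Study configuration
#'
#' Bundles the analysis options of [run_study()] / [run_simulation()].
#'
#' @param alpha Significance level in (0, 1).
#' @param interp Margin interpolation: `"linear"` (default) or
#'   `"monotone"`.
#' @param calibration White-to-white calibration source: `"per_eye"` or
#'   `"mean"` of the two eyes.
#' @param correction Multiplicity handling across the ten positions:
#'   `"none"` (default) or `"holm"`.
#' @param symmetry Post-vs-fellow comparison: `"paired"` or
#'   `"independent"`.
#' @param fellow_from Photograph supplying the fellow-eye reference:
#'   `"postop"` or `"preop"`.
#' @param out_dir Optional output directory for CSV/JSON report files.
#' @param seed Integer seed for simulation subcommands.
#' @return A list of class `study_config`.
#' @export
study_config <- function(alpha = 0.05,
                         interp = c("linear", "monotone"),
                         calibration = c("per_eye", "mean"),
                         correction = c("none", "holm"),
                         symmetry = c("paired", "independent"),
                         fellow_from = c("postop", "preop"),
                         out_dir = NULL, seed = 1L) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  structure(list(
    alpha = alpha,
    interp = match.arg(interp),
    calibration = match.arg(calibration),
    correction = match.arg(correction),
    symmetry = match.arg(symmetry),
    fellow_from = match.arg(fellow_from),
    out_dir = out_dir,
    seed = as.integer(seed)
  ), class = "study_config")
}

load_manifest_photos <- function(manifest) {
  if ("photo" %in% names(manifest)) {
    photos <- manifest$photo
  } else if ("path" %in% names(manifest)) {
    photos <- lapply(manifest$path, read_photo_annotation)
  } else {
    stop("`manifest` needs a `photo` list-column or a `path` column",
         call. = FALSE)
  }
  photos
}

#' Run a full contour study
#'
#' End-to-end orchestration: load (or take) the annotated photographs,
#' normalise and measure every eye, assemble per-patient
#' pre/post/fellow triplets, and produce per-arm cohort comparison
#' tables and peak-shift summaries.  Patients lacking one of the two
#' timepoints are excluded with a warning and listed in the report.
#' When `config$out_dir` is set, the profile table, per-arm cohort
#' tables, the peak summary JSON, and a log of every normalisation
#' parameter are written there.
#'
#' @param manifest A tibble with one row per photograph: either a `path`
#'   column (JSON annotation files) or a `photo` list-column of
#'   [photo_annotation()] objects, plus an `arm` column.  A
#'   [synth_cohort()] is also accepted.
#' @param config A [study_config()].
#' @return A list of class `lid_study`: `profiles`, `peaks`,
#'   `change_tables` (one [contour_change_table()] per arm),
#'   `peak_summaries` (one [peak_shift_summary()] per arm),
#'   `normalization_log`, `excluded` (patient ids), and `config`.
#' @export
run_study <- function(manifest, config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  if (inherits(manifest, "synth_cohort")) {
    meas <- measure_cohort(manifest, interp = config$interp,
                           calibration = config$calibration)
  } else {
    stopifnot(is.data.frame(manifest))
    if (!"arm" %in% names(manifest)) {
      stop("`manifest` must have an `arm` column", call. = FALSE)
    }
    photos <- load_manifest_photos(manifest)
    arms <- setNames(manifest$arm,
                     vapply(photos, `[[`, "", "patient_id"))
    meas <- measure_cohort(photos, arms = arms, interp = config$interp,
                           calibration = config$calibration)
  }

  # exclude patients without both timepoints
  tp_count <- meas$profiles |>
    dplyr::distinct(.data$patient_id, .data$timepoint) |>
    dplyr::count(.data$patient_id)
  excluded <- tp_count$patient_id[tp_count$n < 2]
  if (length(excluded) > 0) {
    warning(sprintf("excluding %d patient(s) lacking a timepoint: %s",
                    length(excluded), paste(excluded, collapse = ", ")),
            call. = FALSE)
  }
  profiles <- dplyr::filter(meas$profiles, !.data$patient_id %in% excluded)
  peaks <- dplyr::filter(meas$peaks, !.data$patient_id %in% excluded)

  arms_present <- if ("arm" %in% names(profiles))
    sort(unique(profiles$arm)) else "all"

  per_arm <- function(arm) {
    pr <- if (arm == "all" && !"arm" %in% names(profiles)) profiles
          else dplyr::filter(profiles, .data$arm == !!arm)
    pk <- if (arm == "all" && !"arm" %in% names(peaks)) peaks
          else dplyr::filter(peaks, .data$arm == !!arm)
    list(
      change = contour_change_table(
        triplet_profiles(pr, fellow_from = config$fellow_from),
        alpha = config$alpha, correction = config$correction,
        symmetry = config$symmetry),
      peak = peak_shift_summary(
        triplet_peaks(pk, fellow_from = config$fellow_from),
        alpha = config$alpha, symmetry = config$symmetry)
    )
  }
  by_arm <- lapply(setNames(arms_present, arms_present), per_arm)

  result <- structure(list(
    profiles = profiles,
    peaks = peaks,
    change_tables = purrr::map(by_arm, "change"),
    peak_summaries = purrr::map(by_arm, "peak"),
    normalization_log = meas$log,
    excluded = excluded,
    config = config
  ), class = "lid_study")

  if (!is.null(config$out_dir)) write_study_report(result, config$out_dir)
  result
}

write_study_report <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_profile_table(study$profiles, file.path(out_dir, "profiles.csv"))
  readr::write_csv(study$normalization_log,
                   file.path(out_dir, "normalization_log.csv"))
  for (arm in names(study$change_tables)) {
    readr::write_csv(tibble::as_tibble(study$change_tables[[arm]]),
                     file.path(out_dir,
                               sprintf("contour_change_%s.csv", arm)))
  }
  peak_doc <- list(
    alpha = study$config$alpha,
    excluded_patients = as.list(study$excluded),
    arms = lapply(study$peak_summaries, function(s)
      lapply(split(tibble::as_tibble(s), s$coordinate), as.list))
  )
  jsonlite::write_json(peak_doc, file.path(out_dir, "peak_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.lid_study <- function(x, ...) {
  cat(sprintf("<lid_study> %d patients, %d profiles, arms: %s\n",
              dplyr::n_distinct(x$profiles$patient_id),
              nrow(dplyr::distinct(x$profiles, .data$patient_id,
                                   .data$timepoint, .data$eye_role)),
              paste(names(x$change_tables), collapse = ", ")))
  if (length(x$excluded)) {
    cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Simulate a cohort study end to end
#'
#' Generates synthetic surgical cohorts ([synth_cohort()]) for the
#' requested arms, runs the full analysis ([run_study()]) on them, and
#' tabulates the measured group means against the generator's analytic
#' ground truth.
#'
#' @param config A [study_config()]; `config$seed` is the master seed.
#' @param n_per_arm Patients per arm.
#' @param arms Character vector of arms to simulate (`"ELA"`,
#'   `"MMCR"`).
#' @param noise A [noise_model()] (its seed is overridden by per-arm
#'   seeds derived from `config$seed`).
#' @param ... Passed on to [synth_cohort()].
#' @return A list of class `lid_simulation`: `study` (a `lid_study`),
#'   `cohorts`, `manifest` (ground-truth manifest rows), and
#'   `truth_comparison` (tibble of measured vs. true group-mean heights
#'   per arm, role and position).
#' @export
run_simulation <- function(config = study_config(), n_per_arm = 16,
                           arms = c("ELA", "MMCR"),
                           noise = noise_model(tilt_deg = 8), ...) {
  stopifnot(inherits(config, "study_config"))
  arm_seeds <- with_seed(config$seed,
                         sample.int(.Machine$integer.max - 10L, length(arms)))
  cohorts <- purrr::map2(arms, arm_seeds, function(a, s) {
    synth_cohort(n_patients = n_per_arm, arm = a,
                 noise = noise_model(noise$landmark_sd_px,
                                     noise$margin_sd_mm, noise$tilt_deg,
                                     noise$scale_px_per_mm, seed = s), ...)
  })
  names(cohorts) <- arms

  photos <- unlist(lapply(cohorts, cohort_photos), recursive = FALSE)
  arms_map <- unlist(lapply(cohorts, function(co)
    setNames(rep(co$arm, length(co$patients)),
             vapply(co$patients, `[[`, "", "patient_id"))))
  names(arms_map) <- sub("^(ELA|MMCR)\\.", "", names(arms_map))
  manifest <- tibble::tibble(photo = photos,
                             arm = unname(arms_map[vapply(photos, `[[`, "",
                                                          "patient_id")]))
  study <- run_study(manifest, config)

  truth <- purrr::map_dfr(cohorts, function(co) {
    purrr::map_dfr(co$patients, function(p) {
      purrr::map_dfr(c("pre", "post"), function(tp) {
        ph <- p[[if (tp == "pre") "pre" else "post"]]
        purrr::map_dfr(c("right", "left"), function(side) {
          tr <- ph$truth[[side]]
          dplyr::mutate(tr$profile, patient_id = p$patient_id, arm = co$arm,
                        timepoint = ph$photo$timepoint,
                        eye_role = tr$role, .before = 1)
        })
      })
    })
  })
  truth_cmp <- truth |>
    dplyr::rename(true_mm = "height_mm") |>
    dplyr::left_join(
      dplyr::select(study$profiles,
                    dplyr::all_of(c("patient_id", "timepoint", "eye_role",
                                    "position", "height_mm"))),
      by = c("patient_id", "timepoint", "eye_role", "position")
    ) |>
    dplyr::summarise(
      true_mean = mean(.data$true_mm, na.rm = TRUE),
      measured_mean = mean(.data$height_mm, na.rm = TRUE),
      n = sum(!is.na(.data$height_mm)),
      .by = c("arm", "timepoint", "eye_role", "position")
    ) |>
    dplyr::mutate(bias = .data$measured_mean - .data$true_mean)

  out <- structure(list(study = study, cohorts = cohorts,
                        manifest = purrr::map_dfr(cohorts, cohort_manifest),
                        truth_comparison = truth_cmp),
                   class = "lid_simulation")
  if (!is.null(config$out_dir)) {
    readr::write_csv(truth_cmp,
                     file.path(config$out_dir, "truth_comparison.csv"))
    readr::write_csv(out$manifest,
                     file.path(config$out_dir, "cohort_manifest.csv"))
  }
  out
}
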