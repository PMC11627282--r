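#' Per-position mean of a set of contour profiles
#'
#' Arithmetic mean of the multiple-MRD1 heights across profiles,
#' position by position, using only the profiles where a position is
#' present (available-case means).  A position missing in every profile
#' gets an `NA` mean with `n = 0`.
#'
#' @param profiles Either a list of profile tibbles (from
#'   [contour_profile()]) or one long data frame containing columns
#'   `position` and `height_mm`.
#' @return A tibble with columns `position`, `x_mm`, `n`, `mean_mm`.
#' @export
group_mean_profile <- function(profiles) {
  if (is.data.frame(profiles)) {
    df <- profiles
  } else if (is.list(profiles) && length(profiles) > 0) {
    df <- dplyr::bind_rows(profiles)
  } else {
    stop("`profiles` must be a non-empty list of profiles or a data frame",
         call. = FALSE)
  }
  if (nrow(df) == 0) stop("`profiles` is empty", call. = FALSE)
  df |>
    dplyr::mutate(position = factor(as.character(.data$position),
                                    levels = MRD_LABELS)) |>
    dplyr::summarise(
      n = sum(!is.na(.data$height_mm)),
      mean_mm = if (sum(!is.na(.data$height_mm)) > 0)
        mean(.data$height_mm, na.rm = TRUE) else NA_real_,
      .by = "position"
    ) |>
    dplyr::arrange(.data$position) |>
    dplyr::mutate(x_mm = MRD_X[as.integer(.data$position)], .after = "position")
}

#' Paired Student t-test with pairwise deletion
#'
#' Two-sided paired t-test of `mean(a - b) = 0` after dropping pairs in
#' which either value is missing.  Two degenerate cases are resolved
#' explicitly: identical vectors give `t = 0, p = 1`, and non-zero
#' differences with zero variance are flagged (`zero_variance = TRUE`)
#' with the p-value reported at the smallest positive double.
#'
#' @param a,b Numeric vectors of equal length (mm); `NA` allowed.
#' @return A one-row tibble: `estimate` (mean difference a - b),
#'   `statistic` (t), `df`, `p_value`, `n` (pairs used), `zero_variance`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) {
    stop("`a` and `b` must have the same length", call. = FALSE)
  }
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 2) stop("fewer than 2 complete pairs", call. = FALSE)
  d <- a - b
  if (sd(d) == 0) {
    if (all(d == 0)) {
      return(tibble::tibble(estimate = 0, statistic = 0, df = n - 1,
                            p_value = 1, n = n, zero_variance = FALSE))
    }
    return(tibble::tibble(estimate = mean(d),
                          statistic = sign(mean(d)) * Inf, df = n - 1,
                          p_value = .Machine$double.xmin, n = n,
                          zero_variance = TRUE))
  }
  tt <- t.test(a, b, paired = TRUE)
  tibble::tibble(estimate = unname(tt$estimate),
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value, n = n, zero_variance = FALSE)
}

# paired or independent (Welch) comparison; returns the paired_t shape
compare_groups <- function(a, b, type = c("paired", "independent")) {
  type <- match.arg(type)
  if (type == "paired") return(paired_t(a, b))
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("fewer than 2 observations per group", call. = FALSE)
  }
  tt <- t.test(a, b)
  tibble::tibble(estimate = mean(a) - mean(b),
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value,
                 n = min(length(a), length(b)), zero_variance = FALSE)
}

#' Pool group means with group-size weights
#'
#' n-weighted mean of per-group means, e.g. to pool two surgical arms
#' into a whole-cohort ("total") summary.
#'
#' @param group_means Numeric vector of group means (mm).
#' @param group_ns Positive integer vector of group sizes, same length.
#' @return Pooled mean in mm.
#' @export
pooled_mean <- function(group_means, group_ns) {
  if (length(group_means) == 0 || length(group_means) != length(group_ns)) {
    stop("`group_means` and `group_ns` must be non-empty and of equal length",
         call. = FALSE)
  }
  if (any(group_ns <= 0)) stop("`group_ns` must be positive", call. = FALSE)
  weighted.mean(group_means, group_ns)
}

#' Arrange measurements into per-patient pre/post/fellow triplets
#'
#' Reshapes long per-photo profile measurements into one row per patient
#' and grid position with columns `pre` (ptotic eye, preoperative photo),
#' `post` (ptotic eye, 6-month photo) and `fellow` (non-ptotic eye, taken
#' from the photo chosen by `fellow_from`).
#'
#' @param profiles Long tibble with columns `patient_id`, `timepoint`,
#'   `eye_role`, `position`, `x_mm`, `height_mm` (see [measure_cohort()]).
#' @param fellow_from Photograph from which the fellow eye is read:
#'   `"postop"` (default; symmetry is judged on the postoperative photo)
#'   or `"preop"`.
#' @return Tibble with columns `patient_id`, `position`, `x_mm`, `pre`,
#'   `post`, `fellow` (plus `arm` if present in the input).
#' @export
triplet_profiles <- function(profiles, fellow_from = c("postop", "preop")) {
  fellow_from <- match.arg(fellow_from)
  fellow_tp <- if (fellow_from == "postop") "postop6m" else "preop"
  keys <- intersect(c("patient_id", "arm"), names(profiles))
  long <- profiles |>
    dplyr::mutate(role3 = dplyr::case_when(
      .data$eye_role == "ptotic" & .data$timepoint == "preop" ~ "pre",
      .data$eye_role == "ptotic" & .data$timepoint == "postop6m" ~ "post",
      .data$eye_role == "fellow" & .data$timepoint == fellow_tp ~ "fellow",
      TRUE ~ NA_character_
    )) |>
    dplyr::filter(!is.na(.data$role3))
  long |>
    tidyr::pivot_wider(id_cols = dplyr::all_of(c(keys, "position", "x_mm")),
                       names_from = "role3", values_from = "height_mm") |>
    dplyr::arrange(.data$patient_id, .data$position)
}

#' @rdname triplet_profiles
#' @param peaks Long peak tibble with columns `patient_id`, `timepoint`,
#'   `eye_role`, `x_mm`, `y_mm`.
#' @export
triplet_peaks <- function(peaks, fellow_from = c("postop", "preop")) {
  fellow_from <- match.arg(fellow_from)
  fellow_tp <- if (fellow_from == "postop") "postop6m" else "preop"
  keys <- intersect(c("patient_id", "arm"), names(peaks))
  peaks |>
    dplyr::mutate(role3 = dplyr::case_when(
      .data$eye_role == "ptotic" & .data$timepoint == "preop" ~ "pre",
      .data$eye_role == "ptotic" & .data$timepoint == "postop6m" ~ "post",
      .data$eye_role == "fellow" & .data$timepoint == fellow_tp ~ "fellow",
      TRUE ~ NA_character_
    )) |>
    dplyr::filter(!is.na(.data$role3)) |>
    tidyr::pivot_wider(id_cols = dplyr::all_of(keys),
                       names_from = "role3",
                       values_from = c("x_mm", "y_mm")) |>
    dplyr::arrange(.data$patient_id)
}

safe_test <- function(a, b, type) {
  tryCatch(compare_groups(a, b, type),
           error = function(e) tibble::tibble(
             estimate = NA_real_, statistic = NA_real_, df = NA_real_,
             p_value = NA_real_, n = sum(is.finite(a) & is.finite(b)),
             zero_variance = FALSE))
}

#' Per-position cohort comparison table
#'
#' For each of the ten grid positions: available-case group means of the
#' preoperative, postoperative, and fellow eyelid heights; a paired
#' t-test of postoperative vs. preoperative heights (`p_change`, did
#' surgery elevate this position?); and a test of postoperative vs.
#' fellow heights (`p_symmetry`, is the operated lid still different from
#' the non-ptotic fellow?).  Pairs with a missing value are dropped
#' per position (pairwise deletion).
#'
#' @param triplets Tibble from [triplet_profiles()].
#' @param alpha Significance level for the `sig_*` flags (default 0.05).
#' @param correction `"none"` (default, one test per position as
#'   conventionally presented) or `"holm"` (step-down adjustment across
#'   the ten positions, applied separately to the change and symmetry
#'   families).
#' @param symmetry Treat post vs. fellow as `"paired"` (within-patient,
#'   default) or `"independent"` samples.
#' @return A tibble of class `contour_change_table`, one row per
#'   position: means, `n_*` counts, t statistics, p-values and
#'   significance flags.  Attributes `alpha`, `correction`, `symmetry`,
#'   `n_patients`.
#' @export
contour_change_table <- function(triplets, alpha = 0.05,
                                 correction = c("none", "holm"),
                                 symmetry = c("paired", "independent")) {
  correction <- match.arg(correction)
  symmetry <- match.arg(symmetry)
  if (!is.data.frame(triplets) || nrow(triplets) == 0) {
    stop("`triplets` is empty", call. = FALSE)
  }
  if (!all(c("position", "pre", "post", "fellow") %in% names(triplets))) {
    stop("`triplets` must have columns position, pre, post, fellow (see triplet_profiles())",
         call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)

  tab <- triplets |>
    dplyr::mutate(position = factor(as.character(.data$position),
                                    levels = MRD_LABELS)) |>
    dplyr::reframe(
      x_mm = MRD_X[as.integer(.data$position[1])],
      n_pre = sum(is.finite(.data$pre)),
      n_post = sum(is.finite(.data$post)),
      n_fellow = sum(is.finite(.data$fellow)),
      mean_pre = if (any(is.finite(.data$pre)))
        mean(.data$pre, na.rm = TRUE) else NA_real_,
      mean_post = if (any(is.finite(.data$post)))
        mean(.data$post, na.rm = TRUE) else NA_real_,
      mean_fellow = if (any(is.finite(.data$fellow)))
        mean(.data$fellow, na.rm = TRUE) else NA_real_,
      {
        chg <- safe_test(.data$post, .data$pre, "paired")
        sym <- safe_test(.data$post, .data$fellow, symmetry)
        tibble::tibble(
          n_change = chg$n, t_change = chg$statistic, p_change = chg$p_value,
          n_symmetry = sym$n, t_symmetry = sym$statistic,
          p_symmetry = sym$p_value
        )
      },
      .by = "position"
    ) |>
    dplyr::arrange(.data$position)

  if (correction == "holm") {
    tab$p_change <- p.adjust(tab$p_change, method = "holm")
    tab$p_symmetry <- p.adjust(tab$p_symmetry, method = "holm")
  }
  tab$sig_change <- !is.na(tab$p_change) & tab$p_change < alpha
  tab$sig_symmetry <- !is.na(tab$p_symmetry) & tab$p_symmetry < alpha

  structure(
    tab,
    alpha = alpha, correction = correction, symmetry = symmetry,
    n_patients = if ("patient_id" %in% names(triplets))
      dplyr::n_distinct(triplets$patient_id) else NA_integer_,
    class = c("contour_change_table", class(tab))
  )
}

#' Peak-point shift summary
#'
#' Group means of the marginal-peak x and y coordinates for the
#' preoperative, postoperative, and fellow eyelids, with the change
#' (post vs. pre, paired) and symmetry (post vs. fellow) t-tests for each
#' coordinate.
#'
#' @param peak_triplets Tibble from [triplet_peaks()].
#' @inheritParams contour_change_table
#' @return A tibble of class `peak_shift_summary`, one row per coordinate
#'   (`"x"`, `"y"`).
#' @export
peak_shift_summary <- function(peak_triplets, alpha = 0.05,
                               symmetry = c("paired", "independent")) {
  symmetry <- match.arg(symmetry)
  if (!is.data.frame(peak_triplets) || nrow(peak_triplets) < 2) {
    stop("at least 2 patient triplets are required", call. = FALSE)
  }
  one <- function(coord) {
    pre <- peak_triplets[[paste0(coord, "_mm_pre")]]
    post <- peak_triplets[[paste0(coord, "_mm_post")]]
    fel <- peak_triplets[[paste0(coord, "_mm_fellow")]]
    chg <- safe_test(post, pre, "paired")
    sym <- safe_test(post, fel, symmetry)
    tibble::tibble(
      coordinate = coord,
      mean_pre = mean(pre, na.rm = TRUE),
      mean_post = mean(post, na.rm = TRUE),
      mean_fellow = mean(fel, na.rm = TRUE),
      n_change = chg$n, t_change = chg$statistic, p_change = chg$p_value,
      n_symmetry = sym$n, t_symmetry = sym$statistic,
      p_symmetry = sym$p_value,
      sig_change = !is.na(chg$p_value) & chg$p_value < alpha,
      sig_symmetry = !is.na(sym$p_value) & sym$p_value < alpha
    )
  }
  out <- dplyr::bind_rows(one("x"), one("y"))
  structure(out, alpha = alpha, symmetry = symmetry,
            class = c("peak_shift_summary", class(out)))
}

#' @export
tidy.contour_change_table <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::select(dplyr::all_of(c("position", "x_mm", "t_change", "p_change",
                                  "sig_change", "t_symmetry", "p_symmetry",
                                  "sig_symmetry"))) |>
    tidyr::pivot_longer(
      -dplyr::all_of(c("position", "x_mm")),
      names_to = c(".value", "contrast"),
      names_pattern = "^(t|p|sig)_(change|symmetry)$"
    ) |>
    dplyr::rename(statistic = "t", p.value = "p", significant = "sig")
}

#' @export
glance.contour_change_table <- function(x, ...) {
  tibble::tibble(
    n_patients = attr(x, "n_patients"),
    alpha = attr(x, "alpha"),
    correction = attr(x, "correction"),
    symmetry = attr(x, "symmetry"),
    n_sig_change = sum(x$sig_change),
    n_sig_symmetry = sum(x$sig_symmetry)
  )
}
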