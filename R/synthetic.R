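#' Parametric ground-truth eyelid contour
#'
#' A piecewise-parabolic model of the upper-eyelid margin in the
#' pupil-centred millimetre frame: height `peak_y - curv * (x - peak_x)^2`
#' with independent nasal and temporal curvatures, defined between the
#' nasal and temporal ends of the traceable margin.  Two curvatures are
#' the simplest way to reproduce the nasal/temporal droop asymmetry seen
#' in real lids; no claim about true lid biomechanics is intended.
#'
#' @param peak_x,peak_y Peak (vertex) position in mm; `peak_x < 0` means a
#'   nasally peaked lid.
#' @param curv_nasal,curv_temporal Downward curvature (1/mm, > 0) nasal
#'   and temporal of the peak.
#' @param canthus_nasal_x,canthus_temporal_x Support of the margin in mm
#'   (nasal end < 0 < temporal end); the lateral canthus sits at the
#'   temporal end.
#' @return An object of class `contour_params`.
#' @export
contour_params <- function(peak_x = -1.18, peak_y = 1.59,
                           curv_nasal = 0.033, curv_temporal = 0.022,
                           canthus_nasal_x = -12, canthus_temporal_x = 14) {
  vals <- c(peak_x, peak_y, curv_nasal, curv_temporal,
            canthus_nasal_x, canthus_temporal_x)
  if (!all(is.finite(vals))) stop("contour parameters must be finite", call. = FALSE)
  if (curv_nasal <= 0 || curv_temporal <= 0) {
    stop("curvatures must be positive", call. = FALSE)
  }
  if (!(canthus_nasal_x < 0 && canthus_temporal_x > 0)) {
    stop("support must straddle the pupil centre (canthus_nasal_x < 0 < canthus_temporal_x)",
         call. = FALSE)
  }
  if (peak_x <= canthus_nasal_x || peak_x >= canthus_temporal_x) {
    stop("peak_x must lie strictly inside the margin support", call. = FALSE)
  }
  structure(
    list(peak_x = peak_x, peak_y = peak_y, curv_nasal = curv_nasal,
         curv_temporal = curv_temporal, canthus_nasal_x = canthus_nasal_x,
         canthus_temporal_x = canthus_temporal_x),
    class = "contour_params"
  )
}

#' Analytic height function of a parametric contour
#'
#' @param params A [contour_params()].
#' @return A vectorised function `f(x)` returning heights in mm (`NA`
#'   outside the support), of class `eyelid_contour`, carrying `support`
#'   and `peak` attributes used as exact ground truth by the synthetic
#'   pipeline.
#' @export
contour_fun <- function(params) {
  stopifnot(inherits(params, "contour_params"))
  lo <- params$canthus_nasal_x
  hi <- params$canthus_temporal_x
  px <- params$peak_x; py <- params$peak_y
  cn <- params$curv_nasal; ct <- params$curv_temporal
  f <- function(x) {
    y <- ifelse(x < px, py - cn * (x - px)^2, py - ct * (x - px)^2)
    y[x < lo | x > hi] <- NA_real_
    y
  }
  structure(f, support = c(lo, hi), peak = c(x = px, y = py),
            class = c("eyelid_contour", "function"))
}

as_contour_fun <- function(contour) {
  if (inherits(contour, "eyelid_contour")) return(contour)
  if (inherits(contour, "contour_params")) return(contour_fun(contour))
  stop("`contour` must be contour_params or an eyelid_contour function",
       call. = FALSE)
}

#' Sample a contour into a dense polyline
#'
#' Samples the analytic contour uniformly in x over its support (the peak
#' x is always inserted as a sample point so that the polyline's maximum
#' coincides exactly with the analytic peak).
#'
#' @param params A [contour_params()] or an `eyelid_contour` function.
#' @param n_points Number of uniform samples (>= 10).
#' @return A list with `margin` (tibble `x`, `y` in mm) and `fn` (the
#'   analytic height function, for oracle use).
#' @export
make_contour <- function(params, n_points = 201) {
  if (!is.numeric(n_points) || n_points < 10) {
    stop("`n_points` must be >= 10", call. = FALSE)
  }
  fn <- as_contour_fun(params)
  s <- attr(fn, "support")
  xs <- sort(unique(c(seq(s[1], s[2], length.out = n_points),
                      attr(fn, "peak")[["x"]])))
  list(margin = tibble::tibble(x = xs, y = fn(xs)), fn = fn)
}

#' Surgical elevation model
#'
#' How a ptosis repair elevates the lid margin along its length.
#' `"uniform"` raises every point by `effect_mm` (the dome-tent picture:
#' widespread support along a continuous suture line, as in a
#' Muller's-muscle conjunctival resection).  `"center_weighted"` raises
#' the lid by `effect_mm` at `center_x`, tapering as a Gaussian with
#' standard-deviation width `taper_width_mm` (the bell-tent picture: a
#' central suspension suture, as in an external levator advancement,
#' whose effect fades toward the canthi).
#'
#' @param kind `"uniform"` or `"center_weighted"`.
#' @param effect_mm Elevation at the centre, mm (>= 0).
#' @param taper_width_mm Gaussian taper width, mm (> 0;
#'   `center_weighted` only).
#' @param center_x Centre of the elevation, mm.
#' @return An object of class `surgery_model`.
#' @export
surgery_model <- function(kind = c("uniform", "center_weighted"),
                          effect_mm = 1, taper_width_mm = 5, center_x = 0) {
  kind <- match.arg(kind)
  if (!is.finite(effect_mm) || effect_mm < 0) {
    stop("`effect_mm` must be >= 0", call. = FALSE)
  }
  if (!is.finite(taper_width_mm) || taper_width_mm <= 0) {
    stop("`taper_width_mm` must be > 0", call. = FALSE)
  }
  structure(list(kind = kind, effect_mm = effect_mm,
                 taper_width_mm = taper_width_mm, center_x = center_x),
            class = "surgery_model")
}

#' Elevation profile of a surgery model
#'
#' @param model A [surgery_model()].
#' @return Vectorised function of x (mm) giving the elevation in mm.
#' @export
elevation_fun <- function(model) {
  stopifnot(inherits(model, "surgery_model"))
  if (model$kind == "uniform") {
    function(x) rep(model$effect_mm, length(x))
  } else {
    function(x) {
      model$effect_mm *
        exp(-(x - model$center_x)^2 / (2 * model$taper_width_mm^2))
    }
  }
}

#' Apply a surgical elevation to a contour
#'
#' Pointwise sum of the base contour and the model's elevation profile.
#' The returned function carries the elevated contour's true peak: exact
#' for uniform elevation, located numerically (dense scan plus golden
#' section refinement) for centre-weighted elevation.
#'
#' @param contour A [contour_params()] or `eyelid_contour` function.
#' @param model A [surgery_model()].
#' @return An `eyelid_contour` function.
#' @export
apply_surgery <- function(contour, model) {
  stopifnot(inherits(model, "surgery_model"))
  base <- as_contour_fun(contour)
  elev <- elevation_fun(model)
  g <- function(x) base(x) + elev(x)
  s <- attr(base, "support")
  if (model$kind == "uniform") {
    pk <- attr(base, "peak")
    peak <- c(x = unname(pk[["x"]]), y = unname(pk[["y"]]) + model$effect_mm)
  } else {
    xs <- seq(s[1], s[2], by = 1e-3)
    i <- which.max(g(xs))
    lo <- xs[max(1L, i - 2L)]; hi <- xs[min(length(xs), i + 2L)]
    opt <- optimize(g, c(lo, hi), maximum = TRUE, tol = 1e-10)
    peak <- c(x = opt$maximum, y = opt$objective)
  }
  structure(g, support = s, peak = peak,
            class = c("eyelid_contour", "function"))
}

#' Acquisition noise model for synthetic photographs
#'
#' Describes the imperfections of a simulated photograph/annotation:
#' Gaussian pixel noise on the point landmarks, a smooth stochastic
#' tracing error on the hand-drawn margin with pointwise standard
#' deviation `margin_sd_mm` (a sum of random low-frequency cosines, so
#' neighbouring margin points err together as a human tracing does),
#' a head tilt, and the pixel scale of the camera geometry.
#'
#' @param landmark_sd_px SD of landmark placement error, px (>= 0).
#' @param margin_sd_mm Pointwise SD of the margin tracing error, mm (>= 0).
#' @param tilt_deg Head tilt applied to the photograph, degrees.
#' @param scale_px_per_mm True pixel scale (> 0).
#' @param seed Integer seed; a given seed reproduces the photograph
#'   byte-for-byte.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(landmark_sd_px = 1, margin_sd_mm = 0.5,
                        tilt_deg = 0, scale_px_per_mm = 10, seed = 1L) {
  if (landmark_sd_px < 0 || margin_sd_mm < 0) {
    stop("noise standard deviations must be >= 0", call. = FALSE)
  }
  if (!is.finite(scale_px_per_mm) || scale_px_per_mm <= 0) {
    stop("`scale_px_per_mm` must be > 0", call. = FALSE)
  }
  structure(list(landmark_sd_px = landmark_sd_px, margin_sd_mm = margin_sd_mm,
                 tilt_deg = tilt_deg, scale_px_per_mm = scale_px_per_mm,
                 seed = as.integer(seed)),
            class = "noise_model")
}

# smooth stationary random function with pointwise SD exactly `sd`:
# sd * sqrt(2/K) * sum_k cos(w_k x + phi_k), w_k ~ U(0.25, 1.5) rad/mm
margin_noise_fun <- function(sd, n_waves = 8) {
  if (sd == 0) return(function(x) numeric(length(x)))
  w <- runif(n_waves, 0.25, 1.5)
  phi <- runif(n_waves, 0, 2 * pi)
  amp <- sd * sqrt(2 / n_waves)
  function(x) amp * colSums(cos(outer(w, x) + phi))
}

jitter_point <- function(p, sd) p + rnorm(2, 0, sd)

#' Simulate one annotated photograph with known ground truth
#'
#' Constructs the pixel-space landmark annotation a human would produce
#' for a frontal photograph of the given true contours: pupil centres,
#' limbus points separated by the sex-specific white-to-white distance,
#' lateral canthi at the temporal end of each margin, and dense margin
#' polylines; then applies a global head-tilt rotation, smooth margin
#' tracing error, and Gaussian landmark noise.  The exact analytic
#' multiple-MRD1 profile and peak point of each eye are returned
#' alongside, for oracle use.
#'
#' @param contour_ptotic,contour_fellow True contours
#'   ([contour_params()] or `eyelid_contour` functions) of the ptotic and
#'   fellow eye.
#' @param noise A [noise_model()]; its `seed` makes the photograph fully
#'   reproducible.
#' @param sex,ptotic_side,timepoint,patient_id Passed to
#'   [photo_annotation()].
#' @param n_margin Number of uniform margin samples per eye; the ten
#'   grid positions and the true peak x are always included as extra
#'   vertices, so the polyline is exact where the pipeline measures it.
#' @param ipd_mm Inter-pupillary distance of the simulated face, mm.
#' @param pupil_diameter_mm True pupil diameter, mm.
#' @return A list of class `synth_photo`: `photo` (a
#'   [photo_annotation()]), `truth` (per side: `role`, analytic `profile`
#'   tibble and `peak` tibble), and `contours` (the per-side analytic
#'   functions).
#' @export
synth_photo <- function(contour_ptotic, contour_fellow,
                        noise = noise_model(), sex = "male",
                        ptotic_side = "right", timepoint = "preop",
                        patient_id = "SYN001", n_margin = 401,
                        ipd_mm = 62, pupil_diameter_mm = 4) {
  stopifnot(inherits(noise, "noise_model"))
  sex <- match.arg(sex, c("male", "female"))
  ptotic_side <- match.arg(ptotic_side, c("right", "left"))
  fn_ptotic <- as_contour_fun(contour_ptotic)
  fn_fellow <- as_contour_fun(contour_fellow)

  s <- noise$scale_px_per_mm
  wtw <- wtw_mm(sex)
  cy <- 450
  centers <- list(right = c(800 - ipd_mm / 2 * s, cy),
                  left = c(800 + ipd_mm / 2 * s, cy))
  # patient's right eye appears on the viewer's left; temporal = -x there
  tsigns <- c(right = -1, left = 1)

  with_seed(noise$seed, {
    eyes <- list(); truth <- list(); contours <- list()
    for (side in c("right", "left")) {
      fn <- if (side == ptotic_side) fn_ptotic else fn_fellow
      role <- if (side == ptotic_side) "ptotic" else "fellow"
      sup <- attr(fn, "support")
      pk <- attr(fn, "peak")
      ts <- tsigns[[side]]
      pc <- centers[[side]]

      # uniform samples plus the grid positions and the true peak as
      # vertices (so sampling never biases the measured profile or peak);
      # uniform samples crowding an inserted vertex are dropped
      anchors <- c(MRD_X[MRD_X >= sup[1] & MRD_X <= sup[2]], pk[["x"]])
      h <- (sup[2] - sup[1]) / (n_margin - 1)
      xs_u <- seq(sup[1], sup[2], length.out = n_margin)
      keep <- vapply(xs_u, function(x) all(abs(x - anchors) > max(h / 2, 0.01)),
                     logical(1))
      xs <- sort(unique(c(xs_u[keep], anchors)))
      y_true <- fn(xs)
      y_obs <- y_true + margin_noise_fun(noise$margin_sd_mm)(xs)

      margin_px <- tibble::tibble(x = pc[1] + ts * xs * s,
                                  y = pc[2] - y_obs * s)
      landmarks <- list(
        pupil_center = pc,
        limbus_nasal = c(pc[1] - ts * wtw / 2 * s, pc[2]),
        limbus_temporal = c(pc[1] + ts * wtw / 2 * s, pc[2]),
        lateral_canthus = c(pc[1] + ts * sup[2] * s, pc[2])
      )

      # global head tilt about the midpoint between the two pupils
      mid <- c(800, cy)
      landmarks <- lapply(landmarks, rotate_about, theta_deg = noise$tilt_deg,
                          center = mid)
      th <- noise$tilt_deg * pi / 180
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      mrot <- sweep(cbind(margin_px$x, margin_px$y), 2, mid) %*% t(R)
      mrot <- sweep(mrot, 2, mid, `+`)
      # landmark placement error (margin error is already modelled in mm)
      landmarks <- lapply(landmarks, jitter_point, sd = noise$landmark_sd_px)

      eyes[[side]] <- eye_annotation(
        side = side,
        pupil_center = landmarks$pupil_center,
        limbus_nasal = landmarks$limbus_nasal,
        limbus_temporal = landmarks$limbus_temporal,
        lateral_canthus = landmarks$lateral_canthus,
        margin = tibble::tibble(x = mrot[, 1], y = mrot[, 2]),
        pupil_diameter = pupil_diameter_mm * s
      )
      g <- mrd_grid()
      g$height_mm <- fn(g$x_mm)
      truth[[side]] <- list(
        role = role,
        profile = g,
        peak = tibble::tibble(x_mm = unname(pk[["x"]]),
                              y_mm = unname(pk[["y"]]))
      )
      contours[[side]] <- fn
    }
    photo <- photo_annotation(
      patient_id = patient_id, timepoint = timepoint, sex = sex,
      ptotic_side = ptotic_side, eyes = eyes,
      metadata = list(synthetic = TRUE, seed = noise$seed,
                      tilt_deg = noise$tilt_deg,
                      scale_px_per_mm = noise$scale_px_per_mm)
    )
    structure(list(photo = photo, truth = truth, contours = contours),
              class = "synth_photo")
  })
}

arm_defaults <- function(arm) {
  # base (ptotic) and fellow contours approximating published group-mean
  # profiles of the two arms; surgery per the bell-tent / dome-tent picture
  switch(arm,
    ELA = list(
      base = contour_params(peak_x = -1.18, peak_y = 1.59,
                            curv_nasal = 0.033, curv_temporal = 0.022),
      fellow = contour_params(peak_x = -0.32, peak_y = 3.01,
                              curv_nasal = 0.041, curv_temporal = 0.030),
      surgery = surgery_model("center_weighted", effect_mm = 1,
                              taper_width_mm = 5, center_x = 0)
    ),
    MMCR = list(
      base = contour_params(peak_x = 0.03, peak_y = 1.2,
                            curv_nasal = 0.030, curv_temporal = 0.025),
      fellow = contour_params(peak_x = 0.09, peak_y = 2.62,
                              curv_nasal = 0.036, curv_temporal = 0.028),
      surgery = surgery_model("uniform", effect_mm = 1.1)
    ),
    stop("unknown arm: ", arm, call. = FALSE)
  )
}

perturb_params <- function(p, sd_peak_x, sd_peak_y, sd_log_curv) {
  lo <- p$canthus_nasal_x; hi <- p$canthus_temporal_x
  px <- p$peak_x + rnorm(1, 0, sd_peak_x)
  px <- min(max(px, lo + 2), hi - 2)
  contour_params(
    peak_x = px,
    peak_y = p$peak_y + rnorm(1, 0, sd_peak_y),
    curv_nasal = p$curv_nasal * exp(rnorm(1, 0, sd_log_curv)),
    curv_temporal = p$curv_temporal * exp(rnorm(1, 0, sd_log_curv)),
    canthus_nasal_x = lo, canthus_temporal_x = hi
  )
}

#' Simulate a unilateral-ptosis surgical cohort
#'
#' Generates `n_patients` patients of one surgical arm.  Each patient
#' gets individually perturbed true contours (peak position, height, and
#' curvatures jittered around the arm's base parameters), a preoperative
#' photograph of the ptotic and fellow eye, and a postoperative
#' photograph in which the ptotic contour has been elevated by the arm's
#' surgery model.  Per-patient sub-seeds are drawn deterministically from
#' the master seed (`noise$seed`), so any single patient is reproducible
#' in isolation from the manifest.
#'
#' @param n_patients Number of patients (>= 2).
#' @param arm `"ELA"` (centre-weighted elevation) or `"MMCR"` (uniform
#'   elevation); selects default contours and surgery via the arm's
#'   published group profile.
#' @param base_params,fellow_params Optional [contour_params()]
#'   overriding the arm defaults for the ptotic and fellow eye.
#' @param surgery Optional [surgery_model()] overriding the arm default.
#' @param noise A [noise_model()]; `noise$seed` is the cohort master
#'   seed and `noise$tilt_deg` is the maximum head tilt (each photo draws
#'   a tilt uniformly from ±`tilt_deg`).
#' @param sd_peak_x,sd_peak_y Between-patient SD of the true peak
#'   coordinates, mm.
#' @param sd_log_curv Between-patient SD of log-curvature.
#' @param prop_male Probability a patient is male.
#' @param n_margin Margin samples per eye per photo.
#' @return A list of class `synth_cohort` with `patients` (each a list
#'   with ids, true parameters, and `pre`/`post` [synth_photo()]
#'   results), and the generating `arm`, `surgery`, `noise`.
#' @export
synth_cohort <- function(n_patients = 16, arm = c("ELA", "MMCR"),
                         base_params = NULL, surgery = NULL,
                         fellow_params = NULL, noise = noise_model(),
                         sd_peak_x = 0.8, sd_peak_y = 1.0,
                         sd_log_curv = 0.15, prop_male = 0.65,
                         n_margin = 401) {
  arm <- match.arg(arm)
  if (n_patients < 2) stop("`n_patients` must be >= 2", call. = FALSE)
  defs <- arm_defaults(arm)
  if (is.null(base_params)) base_params <- defs$base
  if (is.null(fellow_params)) fellow_params <- defs$fellow
  if (is.null(surgery)) surgery <- defs$surgery

  draws <- with_seed(noise$seed, list(
    sub_seeds = sample.int(.Machine$integer.max - 10L, n_patients),
    sexes = sample(c("male", "female"), n_patients, replace = TRUE,
                   prob = c(prop_male, 1 - prop_male)),
    sides = sample(c("right", "left"), n_patients, replace = TRUE)
  ))

  patients <- lapply(seq_len(n_patients), function(i) {
    id <- sprintf("%s%03d", arm, i)
    pp <- with_seed(draws$sub_seeds[i], {
      list(
        pre = perturb_params(base_params, sd_peak_x, sd_peak_y, sd_log_curv),
        fellow = perturb_params(fellow_params, sd_peak_x, sd_peak_y,
                                sd_log_curv),
        tilts = runif(2, -abs(noise$tilt_deg), abs(noise$tilt_deg))
      )
    })
    noise_pre <- noise_model(noise$landmark_sd_px, noise$margin_sd_mm,
                             tilt_deg = pp$tilts[1],
                             scale_px_per_mm = noise$scale_px_per_mm,
                             seed = draws$sub_seeds[i] + 1L)
    noise_post <- noise_model(noise$landmark_sd_px, noise$margin_sd_mm,
                              tilt_deg = pp$tilts[2],
                              scale_px_per_mm = noise$scale_px_per_mm,
                              seed = draws$sub_seeds[i] + 2L)
    post_fn <- apply_surgery(pp$pre, surgery)
    list(
      patient_id = id, arm = arm, sex = draws$sexes[i],
      ptotic_side = draws$sides[i], sub_seed = draws$sub_seeds[i],
      params = pp,
      pre = synth_photo(pp$pre, pp$fellow, noise_pre, draws$sexes[i],
                        draws$sides[i], "preop", id, n_margin = n_margin),
      post = synth_photo(post_fn, pp$fellow, noise_post, draws$sexes[i],
                         draws$sides[i], "postop6m", id,
                         n_margin = n_margin)
    )
  })
  structure(list(patients = patients, arm = arm, surgery = surgery,
                 noise = noise),
            class = "synth_cohort")
}

#' Manifest of a synthetic cohort
#'
#' One row per simulated patient: identifiers, sub-seed, and the
#' ground-truth contour parameters, for reproducing any patient in
#' isolation.
#'
#' @param cohort A [synth_cohort()].
#' @return A tibble.
#' @export
cohort_manifest <- function(cohort) {
  stopifnot(inherits(cohort, "synth_cohort"))
  purrr::map_dfr(cohort$patients, function(p) {
    tibble::tibble(
      patient_id = p$patient_id, arm = p$arm, sex = p$sex,
      ptotic_side = p$ptotic_side, sub_seed = p$sub_seed,
      true_pre_peak_x = p$params$pre$peak_x,
      true_pre_peak_y = p$params$pre$peak_y,
      true_fellow_peak_x = p$params$fellow$peak_x,
      true_fellow_peak_y = p$params$fellow$peak_y
    )
  })
}

#' Photographs of a synthetic cohort
#'
#' @param cohort A [synth_cohort()].
#' @return A list of [photo_annotation()] objects (two per patient).
#' @export
cohort_photos <- function(cohort) {
  stopifnot(inherits(cohort, "synth_cohort"))
  unlist(lapply(cohort$patients, function(p) list(p$pre$photo, p$post$photo)),
         recursive = FALSE)
}
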