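# Shared fixtures, built in code.

# a hand-sized two-eye annotation: pupils 400 px apart, limbus landmarks
# exactly wtw(sex)/0.1 px apart so the true scale is 0.1 mm/px, canthi
# level, margins gentle arches 30 px above the pupils
toy_photo <- function(patient_id = "T001", timepoint = "preop",
                      sex = "male", ptotic_side = "right",
                      pupil_y = 300) {
  half_wtw_px <- wtw_mm(sex) / 0.1 / 2
  mk <- function(side, cx) {
    ts <- if (side == "right") -1 else 1   # temporal sign in viewer px
    xs <- cx + ts * seq(-100, 130, by = 10)
    eye_annotation(
      side = side,
      pupil_center = c(cx, pupil_y),
      limbus_nasal = c(cx - ts * half_wtw_px, pupil_y),
      limbus_temporal = c(cx + ts * half_wtw_px, pupil_y),
      lateral_canthus = c(cx + ts * 130, pupil_y),
      margin = tibble::tibble(
        x = xs,
        y = pupil_y - 30 + 0.002 * (xs - cx)^2
      ),
      pupil_diameter = 40
    )
  }
  photo_annotation(patient_id, timepoint, sex, ptotic_side,
                   eyes = list(right = mk("right", 300),
                               left = mk("left", 700)))
}

# noise-free acquisition: measurement chain should be exact
quiet_noise <- function(tilt_deg = 0, scale = 10, seed = 1L) {
  noise_model(landmark_sd_px = 0, margin_sd_mm = 0, tilt_deg = tilt_deg,
              scale_px_per_mm = scale, seed = seed)
}

# piecewise-linear contour through one row of the example group means
example_margin <- function(which_group) {
  m <- example_group_means()
  m <- m[m$group == which_group, ]
  data.frame(x = m$x_mm, y = m$height_mm)
}

# random jagged polyline for peak-detection oracles
random_polyline <- function(n = NULL) {
  if (is.null(n)) n <- sample(5:40, 1)
  x <- sort(runif(n, -10, 12))
  # ensure distinct x so the polyline is a function
  x <- x + seq_len(n) * 1e-6
  data.frame(x = x, y = runif(n, -2, 4))
}

# brute-force peak: argmax over a dense resampling of the polyline
# (the polyline's own x are included so the sampling is exact at vertices,
# where a piecewise-linear maximum must lie)
brute_peak <- function(margin, step = 0.001) {
  xs <- sort(unique(c(seq(min(margin$x), max(margin$x), by = step),
                      margin$x)))
  ys <- approx(margin$x, margin$y, xout = xs)$y
  i <- which.max(ys)
  c(x = xs[i], y = ys[i])
}
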