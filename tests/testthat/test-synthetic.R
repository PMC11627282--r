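test_that("parametric contours are parabolic around their peak", {
  prm <- contour_params(peak_x = 0, peak_y = 3,
                        curv_nasal = 0.03, curv_temporal = 0.03)
  mc <- make_contour(prm, 5001)
  fn <- mc$fn
  expect_equal(fn(0), 3)
  expect_equal(fn(2), fn(-2))            # symmetric curvatures
  expect_equal(fn(4), 3 - 0.03 * 16)

  prm2 <- contour_params(peak_x = -1.18, peak_y = 1.59)
  mc2 <- make_contour(prm2, 501)
  expect_equal(mc2$margin$x[which.max(mc2$margin$y)], -1.18)
  expect_equal(max(mc2$margin$y), 1.59)

  # polyline agrees with the analytic function at random positions
  set.seed(1)
  xr <- runif(100, prm$canthus_nasal_x, prm$canthus_temporal_x)
  expect_lt(max(abs(height_at(mc$margin, xr) - fn(xr))), 1e-6)

  expect_error(contour_params(curv_nasal = -1), "positive")
  expect_error(contour_params(peak_x = 20), "inside")
  expect_error(make_contour(prm, 5), ">= 10")
})

test_that("surgery models elevate as advertised", {
  prm <- contour_params(peak_x = -1, peak_y = 1.5)
  base <- contour_fun(prm)
  xs <- seq(-11, 13, by = 0.5)

  up <- apply_surgery(prm, surgery_model("uniform", effect_mm = 1))
  expect_equal(up(xs), base(xs) + 1)
  expect_equal(unname(attr(up, "peak")), c(-1, 2.5))

  cw_model <- surgery_model("center_weighted", effect_mm = 1,
                            taper_width_mm = 5, center_x = 0)
  cw <- apply_surgery(prm, cw_model)
  elev <- elevation_fun(cw_model)
  expect_equal(elev(0), 1)
  expect_equal(elev(10), exp(-100 / 50))
  expect_equal(cw(xs), base(xs) + elev(xs))
  # elevation strictly decreases with distance from the centre
  d <- elev(seq(0, 12, by = 0.1))
  expect_true(all(diff(d) < 0))
  # elevated peak sits between the old peak and the elevation centre
  pk <- attr(cw, "peak")
  expect_true(pk[["x"]] > -1 && pk[["x"]] < 0)
  expect_gt(pk[["y"]], 1.5)

  expect_error(surgery_model("uniform", effect_mm = -1), ">= 0")
})

test_that("synthetic photographs are reproducible and exact when noise-free", {
  prm <- contour_params()
  fel <- contour_params(peak_x = -0.32, peak_y = 3.01)

  a <- synth_photo(prm, fel, noise_model(seed = 8))
  b <- synth_photo(prm, fel, noise_model(seed = 8))
  expect_identical(a$photo, b$photo)
  c <- synth_photo(prm, fel, noise_model(seed = 9))
  expect_false(identical(a$photo, c$photo))

  sp <- synth_photo(prm, fel, quiet_noise(), n_margin = 3001)
  meas <- measure_photo(sp$photo)
  for (s in c("right", "left")) {
    tr <- sp$truth[[s]]
    got <- meas$profiles[meas$profiles$side == s, ]
    expect_lt(max(abs(got$height_mm - tr$profile$height_mm)), 1e-6)
    pk <- meas$peaks[meas$peaks$side == s, ]
    expect_lt(abs(pk$x_mm - tr$peak$x_mm), 1e-6)
    expect_lt(abs(pk$y_mm - tr$peak$y_mm), 1e-6)
  }
  # ptotic eye is nasally peaked: negative measured peak x
  side <- sp$photo$ptotic_side
  expect_lt(meas$peaks$x_mm[meas$peaks$side == side &
                              meas$peaks$timepoint == "preop"][1], 0)
})

test_that("measurements are invariant to head tilt and pixel scale", {
  prm <- contour_params(peak_x = -1.5, peak_y = 2.2)
  fel <- contour_params(peak_x = 0.3, peak_y = 2.9)
  ref <- measure_photo(synth_photo(prm, fel, quiet_noise(),
                                   n_margin = 3001)$photo)
  for (tilt in c(-15, -7, 7, 15)) {
    for (scale in c(3, 30)) {
      m <- measure_photo(synth_photo(prm, fel,
                                     quiet_noise(tilt_deg = tilt,
                                                 scale = scale),
                                     n_margin = 3001)$photo)
      expect_lt(max(abs(m$profiles$height_mm - ref$profiles$height_mm)),
                1e-6)
      expect_lt(max(abs(m$peaks$y_mm - ref$peaks$y_mm)), 1e-6)
      expect_lt(max(abs(m$peaks$x_mm - ref$peaks$x_mm)), 1e-6)
      expect_equal(m$log$tilt_deg, tilt, tolerance = 1e-9)
    }
  }
})

test_that("synthetic cohorts are structurally valid and reproducible", {
  co <- synth_cohort(4, "MMCR", noise = noise_model(tilt_deg = 8, seed = 55),
                     n_margin = 101)
  expect_length(co$patients, 4)
  photos <- cohort_photos(co)
  expect_length(photos, 8)
  # every annotation round-trips through the schema (validators pass)
  f <- withr::local_tempfile(fileext = ".json")
  for (ph in photos) {
    write_photo_annotation(ph, f)
    expect_s3_class(read_photo_annotation(f), "photo_annotation")
  }
  man <- cohort_manifest(co)
  expect_equal(nrow(man), 4)
  expect_true(all(man$sub_seed > 0))

  co2 <- synth_cohort(4, "MMCR", noise = noise_model(tilt_deg = 8, seed = 55),
                      n_margin = 101)
  expect_identical(cohort_photos(co2)[[3]], photos[[3]])
})

test_that("a null surgery produces no systematic change", {
  co <- synth_cohort(16, "MMCR",
                     surgery = surgery_model("uniform", effect_mm = 0),
                     noise = noise_model(margin_sd_mm = 0.5, tilt_deg = 8,
                                         seed = 77),
                     n_margin = 201)
  trip <- triplet_profiles(measure_cohort(co)$profiles)
  # per-patient MRD1 differences are independent across patients
  d <- with(trip[trip$position == "MRD1", ], post - pre)
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d)), 4 * se)
})
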