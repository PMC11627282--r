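make_profile <- function(heights) {
  g <- mrd_grid()
  g$height_mm <- heights
  g
}

test_that("group means are available-case, position-wise", {
  p1 <- make_profile(rep(2, 10))
  p2 <- make_profile(rep(4, 10))
  gm <- group_mean_profile(list(p1, p2))
  expect_equal(gm$mean_mm[gm$position == "MRD1"], 3)
  expect_equal(gm$n, rep(2L, 10))

  # identity for a single profile
  gm1 <- group_mean_profile(list(p1))
  expect_equal(gm1$mean_mm, p1$height_mm)

  # a position missing in one profile is averaged over the rest;
  # missing everywhere stays missing
  p3 <- make_profile(c(rep(1, 9), NA))
  p4 <- make_profile(c(rep(3, 9), NA))
  gm2 <- group_mean_profile(list(p3, p4))
  expect_equal(gm2$mean_mm[10], NA_real_)
  expect_equal(gm2$n[10], 0L)
  expect_equal(gm2$mean_mm[1], 2)
})

test_that("group means of noisy profiles recover generator means", {
  fn <- contour_fun(contour_params(peak_x = -0.5, peak_y = 2.5))
  truth <- fn(mrd_grid()$x_mm)
  set.seed(99)
  profs <- lapply(1:16, function(i) make_profile(truth + rnorm(10, 0, 0.5)))
  gm <- group_mean_profile(profs)
  se <- 0.5 / sqrt(16)
  expect_true(all(abs(gm$mean_mm - truth) < 4 * se))
})

test_that("paired t-test matches the closed form and its degenerate cases", {
  # differences (1, 2, 3): t = mean / (sd / sqrt(n)) = 2 / (1 / sqrt(3))
  b <- c(5, 5, 5)
  a <- b + c(1, 2, 3)
  res <- paired_t(a, b)
  t_closed <- 2 / (1 / sqrt(3))
  expect_equal(res$statistic, t_closed, tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, 2 * stats::pt(-t_closed, df = 2),
               tolerance = 1e-12)
  expect_equal(res$estimate, 2)

  # identical vectors: t = 0, p = 1
  same <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$zero_variance)

  # constant non-zero differences: flagged, p at the machine floor
  zv <- paired_t(c(2, 3, 4), c(1, 2, 3))
  expect_true(zv$zero_variance)
  expect_lte(zv$p_value, .Machine$double.xmin)

  # pairwise deletion and the n >= 2 precondition
  del <- paired_t(c(1, NA, 3, 4), c(0, 1, NA, 1))
  expect_equal(del$n, 2)
  expect_error(paired_t(c(1, NA), c(1, 2)), "fewer than 2")
  expect_error(paired_t(1:3, 1:2), "same length")
})

test_that("change table: no change means p = 1 everywhere, never significant", {
  g <- mrd_grid()
  set.seed(5)
  trip <- purrr::map_dfr(1:6, function(i) {
    h <- 2 - 0.03 * g$x_mm^2 + rnorm(1, 0, 0.5)
    tibble::tibble(patient_id = paste0("P", i), position = g$position,
                   x_mm = g$x_mm, pre = h, post = h, fellow = h + 0.4)
  })
  tab <- contour_change_table(trip)
  expect_s3_class(tab, "contour_change_table")
  expect_equal(tab$p_change, rep(1, 10))
  expect_false(any(tab$sig_change))
  expect_equal(tab$mean_post, tab$mean_pre)
  expect_equal(tab$n_change, rep(6L, 10))

  # pairwise deletion: n never exceeds the cohort, missing pairs drop out
  trip2 <- trip
  trip2$post[trip2$patient_id == "P1" & trip2$position == "T10"] <- NA
  tab2 <- contour_change_table(trip2)
  expect_equal(tab2$n_change[tab2$position == "T10"], 5L)
  expect_true(all(tab2$n_change <= 6))

  expect_error(contour_change_table(trip[0, ]), "empty")
})

test_that("holm correction and independent symmetry options work", {
  g <- mrd_grid()
  set.seed(17)
  trip <- purrr::map_dfr(1:8, function(i) {
    h <- 1.5 - 0.02 * g$x_mm^2 + rnorm(10, 0, 0.3)
    tibble::tibble(patient_id = paste0("P", i), position = g$position,
                   x_mm = g$x_mm, pre = h, post = h + 0.6 + rnorm(10, 0, 0.3),
                   fellow = h + 0.6 + rnorm(10, 0, 0.3))
  })
  plain <- contour_change_table(trip)
  holm <- contour_change_table(trip, correction = "holm")
  expect_true(all(holm$p_change >= plain$p_change))
  indep <- contour_change_table(trip, symmetry = "independent")
  expect_false(identical(indep$p_symmetry, plain$p_symmetry))

  td <- tidy(plain)
  expect_setequal(unique(td$contrast), c("change", "symmetry"))
  expect_equal(nrow(td), 20)
  gl <- glance(plain)
  expect_equal(gl$n_patients, 8)
  expect_equal(gl$alpha, 0.05)
})

test_that("peak shift summary recovers a known shift and sign convention", {
  set.seed(23)
  n <- 16
  pre_x <- rnorm(n, -1.2, 0.8)
  shift <- 0.9 + rnorm(n, 0, 0.3)
  trip <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:n),
    x_mm_pre = pre_x, x_mm_post = pre_x + shift,
    x_mm_fellow = rnorm(n, -0.3, 0.5),
    y_mm_pre = rnorm(n, 1.6, 0.6), y_mm_post = rnorm(n, 2.6, 0.6),
    y_mm_fellow = rnorm(n, 3.0, 0.6)
  )
  ps <- peak_shift_summary(trip)
  xrow <- ps[ps$coordinate == "x", ]
  est_shift <- xrow$mean_post - xrow$mean_pre
  se <- sd(shift) / sqrt(n)
  expect_lt(abs(est_shift - 0.9), 4 * se)
  # nasally peaked cohort: negative mean x
  expect_lt(xrow$mean_pre, 0)
  expect_true(xrow$sig_change)

  # identical pre/post peaks: change p = 1
  trip0 <- trip
  trip0$x_mm_post <- trip0$x_mm_pre
  trip0$y_mm_post <- trip0$y_mm_pre
  ps0 <- peak_shift_summary(trip0)
  expect_equal(ps0$p_change, c(1, 1))

  expect_error(peak_shift_summary(trip[1, ]), "at least 2")
})

test_that("pooled means reproduce whole-cohort summaries", {
  expect_equal(pooled_mean(c(1.46, 1.12), c(16, 16)), 1.29)
  expect_equal(pooled_mean(c(2.88, 2.58), c(16, 16)), 2.73)
  expect_equal(pooled_mean(3.7, 12), 3.7)
  # weighting matters for unequal n
  expect_equal(pooled_mean(c(1, 4), c(3, 1)), 1.75)
  expect_error(pooled_mean(numeric(0), numeric(0)), "non-empty")
  expect_error(pooled_mean(c(1, 2), c(4, 0)), "positive")
})

test_that("triplet assembly pairs the right photos and fellow source", {
  co <- synth_cohort(3, "MMCR", noise = quiet_noise(seed = 31), n_margin = 101)
  meas <- measure_cohort(co)
  trip <- triplet_profiles(meas$profiles)
  expect_equal(nrow(trip), 30)
  expect_true(all(c("pre", "post", "fellow") %in% names(trip)))
  # noise-free uniform surgery: post - pre equals the effect everywhere
  expect_equal(trip$post - trip$pre,
               rep(co$surgery$effect_mm, 30), tolerance = 1e-6)
  # fellow from the preop photo instead
  trip_pre <- triplet_profiles(meas$profiles, fellow_from = "preop")
  expect_equal(trip_pre$fellow, trip$fellow, tolerance = 1e-6)
})
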