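test_that("constructors validate their invariants", {
  ph <- toy_photo()
  expect_s3_class(ph, "photo_annotation")
  expect_named(ph$eyes, c("right", "left"))

  eye <- ph$eyes$right
  # negative pupil diameter
  expect_error(
    eye_annotation("right", eye$pupil_center, eye$limbus_nasal,
                   eye$limbus_temporal, eye$lateral_canthus, eye$margin,
                   pupil_diameter = -3),
    "pupil_diameter"
  )
  # coincident limbus points
  expect_error(
    eye_annotation("right", eye$pupil_center, c(1, 1), c(1, 1),
                   eye$lateral_canthus, eye$margin),
    "distinct"
  )
  # non-finite coordinate
  expect_error(
    eye_annotation("right", c(NA_real_, 1), eye$limbus_nasal,
                   eye$limbus_temporal, eye$lateral_canthus, eye$margin),
    "finite"
  )
  # margin too short
  expect_error(
    eye_annotation("right", eye$pupil_center, eye$limbus_nasal,
                   eye$limbus_temporal, eye$lateral_canthus,
                   data.frame(x = 1, y = 1)),
    "at least 2"
  )
  # one eye absent
  expect_error(
    photo_annotation("P1", "preop", "male", "right",
                     eyes = list(right = eye)),
    "right.*left|left.*right"
  )
  # eye under the wrong name
  expect_error(
    photo_annotation("P1", "preop", "male", "right",
                     eyes = list(right = eye, left = eye)),
    "side"
  )
})

test_that("JSON writer/reader round-trips annotations bit-exactly", {
  ph <- toy_photo()
  f <- withr::local_tempfile(fileext = ".json")
  write_photo_annotation(ph, f)
  back <- read_photo_annotation(f)
  expect_identical(back$eyes$right$margin$x, ph$eyes$right$margin$x)
  expect_identical(back$eyes$left$margin$y, ph$eyes$left$margin$y)
  expect_identical(back$eyes$right$pupil_center, ph$eyes$right$pupil_center)
  expect_identical(back$patient_id, ph$patient_id)
  expect_identical(back$timepoint, ph$timepoint)

  # awkward decimals survive exactly
  ph2 <- toy_photo()
  ph2$eyes$right$margin$y <- ph2$eyes$right$margin$y + 0.1 + 0.2
  f2 <- withr::local_tempfile(fileext = ".json")
  write_photo_annotation(ph2, f2)
  expect_identical(read_photo_annotation(f2)$eyes$right$margin$y,
                   ph2$eyes$right$margin$y)
})

test_that("synthetic generator output survives write-then-read unchanged", {
  sp <- synth_photo(contour_params(),
                    contour_params(peak_x = -0.32, peak_y = 3.01),
                    noise_model(seed = 42), patient_id = "RT001")
  f <- withr::local_tempfile(fileext = ".json")
  write_photo_annotation(sp$photo, f)
  back <- read_photo_annotation(f)
  for (s in c("right", "left")) {
    expect_identical(back$eyes[[s]]$margin, sp$photo$eyes[[s]]$margin)
    expect_identical(back$eyes[[s]]$pupil_center,
                     sp$photo$eyes[[s]]$pupil_center)
    expect_identical(back$eyes[[s]]$limbus_nasal,
                     sp$photo$eyes[[s]]$limbus_nasal)
    expect_identical(back$eyes[[s]]$lateral_canthus,
                     sp$photo$eyes[[s]]$lateral_canthus)
  }
  expect_equal(back$metadata$seed, 42)
})

test_that("reader reports missing fields and invalid values by name", {
  f <- withr::local_tempfile(fileext = ".json")
  write_photo_annotation(toy_photo(), f)
  doc <- jsonlite::read_json(f)

  d1 <- doc; d1$sex <- NULL
  f1 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(d1, f1, auto_unbox = TRUE)
  expect_error(read_photo_annotation(f1), "sex")

  d2 <- doc; d2$eyes$left <- NULL
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(d2, f2, auto_unbox = TRUE)
  expect_error(read_photo_annotation(f2), "left")

  d3 <- doc; d3$eyes$right$pupil_diameter <- -3
  f3 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(d3, f3, auto_unbox = TRUE)
  expect_error(read_photo_annotation(f3), "pupil_diameter")

  expect_error(read_photo_annotation(withr::local_tempfile()), "no such file")
})

test_that("profile table writes N8..T10 in order, blanks missing cells, round-trips", {
  g <- mrd_grid()
  prof <- tibble::tibble(
    patient_id = "P1", timepoint = "preop", eye_role = "ptotic",
    position = g$position, x_mm = g$x_mm,
    height_mm = c(0.61, 1.64, 2.31, 2.82, 2.88, 2.78, 2.51, 1.90, 1.06, -0.17)
  )
  f <- withr::local_tempfile(fileext = ".csv")
  wide <- write_profile_table(prof, f)
  expect_identical(names(wide),
                   c("patient_id", "timepoint", "eye_role",
                     "N8", "N6", "N4", "N2", "MRD1",
                     "T2", "T4", "T6", "T8", "T10"))
  header <- readLines(f, n = 1)
  expect_match(header, "N8,N6,N4,N2,MRD1,T2,T4,T6,T8,T10$")

  back <- read_profile_table(f)
  expect_equal(back$height_mm, prof$height_mm, tolerance = 1e-9)
  expect_identical(as.character(back$position), as.character(prof$position))

  # a missing T10 becomes an empty trailing cell
  prof2 <- prof
  prof2$height_mm[10] <- NA
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_profile_table(prof2, f2)
  expect_match(readLines(f2)[2], ",$")
  expect_true(is.na(read_profile_table(f2)$height_mm[10]))

  # duplicate (patient, timepoint, role) rows are rejected
  expect_error(write_profile_table(dplyr::bind_rows(prof, prof), f),
               "duplicate")
  expect_error(write_profile_table(prof[0, ], f), "empty")
})
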