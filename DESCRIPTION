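Package: lidcontour
Title: Digital Eyelid Contour Analysis with Multiple Margin Reflex
    Distances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying upper-eyelid contour from
    landmark-annotated periocular photographs.  Annotations are
    tilt-corrected using the inter-canthal line, calibrated to
    millimetres with sex-specific white-to-white corneal diameters, and
    expressed in a pupil-centred, temporal-positive frame.  The eyelid
    margin is then summarised as margin reflex distances sampled every
    2 mm from 8 mm nasal to 10 mm temporal of the pupil centre
    ("multiple MRD1s") together with the marginal peak point, and
    cohorts of unilateral ptosis patients are compared pre- versus
    post-operatively and against the non-ptotic fellow eyelid with
    per-position paired t-tests.  A synthetic-cohort generator provides
    ground-truth contours, simulated surgical elevation profiles,
    landmark noise, head tilt and rendered test images so the whole
    pipeline can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
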