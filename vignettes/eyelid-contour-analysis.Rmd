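---
title: "Quantifying upper-eyelid contour: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying upper-eyelid contour: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lidcontour)
library(dplyr)
```

## The measurement problem

The margin reflex distance (MRD1) — the vertical distance from the pupil
centre to the upper-eyelid margin — is the standard single number used to
describe eyelid height after ptosis repair. But the lid margin is an arch,
and two lids with identical MRD1 can have very different shapes: a repair
can raise the centre of the lid while leaving the regions toward the canthi
behind. `lidcontour` implements a contour-level analysis of
landmark-annotated frontal photographs:

1. **Tilt correction.** The line through the two lateral canthi estimates
   head tilt; all landmarks are rigidly rotated about the inter-canthal
   midpoint until that line is horizontal.
2. **Metric calibration.** Pixels are converted to millimetres using the
   horizontal corneal (white-to-white) diameter as an in-image ruler, with
   the population constants 11.77 mm for men and 11.64 mm for women.
3. **Pupil-centred frame.** Each eye's margin polyline is re-expressed with
   the pupil centre at the origin, y pointing up, and x oriented so the
   eye's own lateral canthus has positive x ("temporal-positive"). Nasal
   positions are therefore negative for either eye, and left/right eyes —
   or mirrored image exports — become directly comparable.
4. **Multiple MRD1s.** The margin height is sampled at ten fixed
   positions, every 2 mm from 8 mm nasal (`N8`) to 10 mm temporal (`T10`)
   of the pupil centre. The height at `x = 0` is the classical MRD1.
5. **Marginal peak point.** The highest point of the margin — the idealised
   contact point of a horizontal line raised until it becomes tangent to
   the lid — reported as a signed (x, y) pair; negative x means the peak
   sits nasal of the mid-pupillary line.
6. **Cohort statistics.** For unilateral-ptosis cohorts, per-position
   paired t-tests compare the operated lid before vs. after surgery
   ("change") and after surgery vs. the non-ptotic fellow lid
   ("symmetry").

## Geometric conventions and their edge cases

**Raster input, y-up output.** Annotations arrive in image coordinates
(y grows downward), because that is what annotation tools produce. The
y-axis is flipped exactly once, inside `to_pupil_frame()`; everything
downstream is y-up, so a negative `T10` height simply means the margin is
below the pupil centre there.

**Tilt angle.** `tilt_angle()` returns the signed angle of the
inter-canthal line in (−90°, 90°], independent of which canthus is listed
first. The rotation centre is the inter-canthal midpoint; since every eye
is subsequently re-centred on its own pupil, the choice of rotation centre
is mathematically immaterial — the midpoint simply keeps both eyes in
frame.

**Temporal orientation.** The temporal direction is defined by the sign of
(lateral canthus x − pupil x) *after* tilt correction, not by the eye-side
label. This makes the pipeline robust to mirrored exports and is what the
mirror-symmetry tests exercise.

**Margins as functions.** Hand-traced margins can contain duplicate or
retrograde x. After mapping to the pupil frame the points are sorted by x
and exact duplicates collapsed to their mean y; the margin must then have
at least two distinct x values. Within the sampled range the upper-lid
margin is treated as a function of x.

**Interpolation.** Heights between margin vertices are linearly
interpolated (`interp = "linear"`, the default used by every reference
analysis); a monotone Hermite cubic is available for users who prefer a
smooth curve. Positions outside the traced margin yield `NA` rather than
an extrapolated value — small palpebral fissures genuinely may not reach
`T10`, and available-case means with per-position n are reported instead.

**Peak on a polyline.** A piecewise-linear margin attains its maximum at a
vertex, so `peak_point()` scans vertices. If several vertices tie within
1e−6 mm (a plateau), the midpoint of the widest contiguous contact
interval is reported; ties between equally wide plateaus resolve to the
more nasal one. The brute-force oracle in the test suite (argmax over a
0.001 mm resampling that includes the vertices) checks this logic on
1,000 random polylines.

## Statistical choices

* **Paired tests.** The design is within-patient (the same lid before and
  after surgery; the fellow lid of the same face), so Student's paired
  t-test is used, two-sided, at α = 0.05. `paired_t()` resolves the two
  degenerate cases explicitly: identical vectors give t = 0, p = 1;
  constant non-zero differences are flagged (`zero_variance`) and the
  p-value reported at the smallest positive double.
* **Pairwise deletion.** Each position's test uses only the patients with
  both values present; reported n never exceeds the cohort size.
* **No multiplicity correction by default.** Per-position p-values are
  conventionally presented uncorrected in this literature;
  `correction = "holm"` applies a step-down adjustment across the ten
  positions (change and symmetry families adjusted separately) for users
  who want it.
* **Symmetry comparison.** Post-vs-fellow is paired by default;
  `symmetry = "independent"` switches to a Welch two-sample test.
* **Fellow-eye source.** Both photographs of a patient contain the fellow
  eye. The default takes the fellow reference from the *postoperative*
  photograph, since the symmetry question is about the postoperative
  state; `fellow_from = "preop"` is available.
* **Pooling.** Whole-cohort summaries pool per-arm means weighted by arm
  size (`pooled_mean()`); SDs in outputs are sample SDs (n − 1).

## The synthetic-data generator

No patient images are distributed, so the package ships a generator that
emulates the whole acquisition chain with known ground truth.

**Contour family.** A lid margin is modelled as two parabolic arcs sharing
a vertex (`contour_params()`): height
`peak_y − curv · (x − peak_x)²` with independent nasal and temporal
curvatures, on a support running from 12 mm nasal to 14 mm temporal of the
pupil. This is the simplest family that reproduces the nasal/temporal
droop asymmetry of real group-mean profiles (e.g. a fellow lid falling to
−0.17 mm at `T10` but only to 0.61 mm at `N8`); it is a measurement test
bed, not a biomechanical claim. The default arm parameters are least-
squares-style fits of the vertex and end heights to published group-mean
contours: for the centre-suture arm, a ptotic lid peaking at
(−1.18, 1.59) mm and a fellow lid at (−0.32, 3.01) mm; for the
continuous-suture arm, (0.03, 1.2) and (0.09, 2.62) mm.

**Surgery models.** `surgery_model("uniform", effect_mm)` raises every
point equally — the "dome tent" picture of a repair supported along a
continuous suture line. `surgery_model("center_weighted", effect_mm,
taper_width_mm, center_x)` raises the lid by `effect_mm` at the centre
with a Gaussian taper — the "bell tent" picture of a single central
suspension suture whose effect fades toward the canthi. Defaults follow
the respective arms' central MRD1 gains (1.0 mm centre-weighted with a
5 mm taper; 1.1 mm uniform).

**Noise model.** Three realistic imperfections, all behind one seed
(`noise_model()`): Gaussian pixel error on point landmarks (default
1 px); a *smooth* stochastic tracing error on the margin — a sum of eight
random low-frequency cosines with pointwise SD exactly `margin_sd_mm`
(default 0.5 mm), because a human tracing errs coherently over
millimetres, not independently per pixel; and a head tilt (each simulated
photo draws a tilt uniformly within ±`tilt_deg`). Between-patient
anatomical variation is separate: per-patient jitter of the true peak
position (SD 0.8 mm in x, 1.0 mm in y) and log-curvature (SD 0.15),
chosen to give cohort SDs of the order seen in published demographic
tables (≈1–1.5 mm for MRD1).

**Exactness by construction.** The sampled margin includes the ten grid
positions and the true peak x as vertices (uniform samples that crowd an
inserted vertex to within half a sample spacing, or 0.01 mm, are
dropped, so near-duplicate vertices never blur the peak's plateau test).
With noise switched off the measured profile and peak therefore equal
the analytic ground truth to floating-point accuracy, and the exactness
tests check the *transform chain* — rotation, calibration, frame change —
rather than sampling density. Between vertices, linear interpolation of
a parabola carries the usual curvature·h²/8 bias; at the default 401
samples this is ≈2e−5 mm, far below the noise scales of any realistic
use. The same photographs are re-measured under tilts up to ±15° and
scales from 3 to 30 px/mm to verify that normalisation is exact, not
approximate.

**Seeding.** A cohort's master seed draws per-patient sub-seeds
(`sample.int` under the master seed), recorded in the cohort manifest, so
any single patient can be regenerated in isolation; each photograph's
annotation is byte-reproducible from its own seed.

**What passing tests do and do not show.** The generator covers landmark
noise, tracing error, head tilt, pixel scale, sex-specific calibration and
missing temporal coverage. It does not simulate lens distortion,
perspective, eyelash occlusion, notched or multi-peaked margins, or
segmentation error in locating the pupil from an actual image — real
photographs were annotated manually, and this package deliberately starts
from landmarks, not pixels. Results on synthetic cohorts validate the
*measurement and statistics chain*, not the annotation step.

## Known statistical behaviour of the simulated arms

With the default study conditions (16 patients per arm, margin noise SD
0.5 mm per photo), the uniform 1.1 mm arm shows significant elevation at
all ten positions in essentially every simulated cohort. The
centre-weighted arm reliably shows the qualitative contrast — strong
central significance with weaker edges — but the *strict* pattern
"significant centrally and non-significant at every one of N8, T8, T10"
is only observed in roughly a third of simulated cohorts. This is a power
fact, not a bug: the centre-weighted elevation at x = ±8 mm is
1.0·exp(−64/50) ≈ 0.28 mm, while a paired difference of two photographs
carries noise SD ≈ √2·0.5 ≈ 0.71 mm, giving the edge positions ≈30% power
at n = 16 — so each edge position comes out (correctly) non-significant
only ~70% of the time, and all three jointly far less often. The
corresponding acceptance check is therefore expected to fail under these
conditions, and the package does not tune the generator to mask that.

## Problem sizes used by the test suite

Simulation-based tests use cohorts of 16 patients per arm with 201-point
margins (pattern checks over 20 seeds), 3001-point margins for exactness
checks, 1,000 random polylines for the peak oracle, and 10,000 replicates
for the t-test size check — sizes chosen so the whole suite exercises
every property at comfortable statistical resolution while remaining
quick on a laptop.

## A worked example

```{r example, eval = FALSE}
sim <- run_simulation(study_config(seed = 1), n_per_arm = 16)
autoplot(sim$study$change_tables$ELA)
glance(sim$study$change_tables$MMCR)
sim$study$peak_summaries$ELA
```

## Limitations

Two-dimensional analysis of a three-dimensional structure; manual (or
simulated) landmarks rather than automatic segmentation; linear
interpolation between traced points; no lens/perspective correction
(acquisition at ~1 m in the frontal plane is assumed affine-negligible);
and the piecewise-parabolic synthetic family cannot represent notches or
double peaks.
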