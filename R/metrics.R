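# Accept a normalized_eye or a bare data frame of margin points (columns
# x, y in mm); return a margin tibble sorted by x with duplicate x
# collapsed to mean y.
margin_of <- function(eye) {
  if (inherits(eye, "normalized_eye")) return(eye$margin)
  if (is.data.frame(eye) && all(c("x", "y") %in% names(eye))) {
    m <- as_margin(eye)
    ord <- order(m$x)
    return(tibble::tibble(x = m$x[ord], y = m$y[ord]) |>
             dplyr::summarise(y = mean(.data$y), .by = "x"))
  }
  stop("`eye` must be a normalized_eye or a data frame with columns x and y (mm)",
       call. = FALSE)
}

#' Eyelid-margin height at given horizontal positions
#'
#' Height of the upper-eyelid margin above the pupil centre at horizontal
#' position(s) `x`, by interpolation of the normalised margin polyline.
#' Positions outside the traced margin's support yield `NA` (missing, not
#' an error): no extrapolation is performed.
#'
#' @param eye A `normalized_eye` or a data frame of margin points
#'   (columns `x`, `y`, in mm, pupil-centred).
#' @param x Numeric vector of positions in mm (temporal positive).
#' @param interp `"linear"` (the default, used by all reference
#'   analyses) or `"monotone"` (monotone Hermite cubic).
#' @return Numeric vector of heights in mm, `NA` outside the margin.
#' @export
height_at <- function(eye, x, interp = c("linear", "monotone")) {
  interp <- match.arg(interp)
  m <- margin_of(eye)
  if (interp == "linear") {
    approx(m$x, m$y, xout = x, method = "linear", rule = 1)$y
  } else {
    f <- splinefun(m$x, m$y, method = "monoH.FC")
    out <- f(x)
    out[x < min(m$x) | x > max(m$x)] <- NA_real_
    out
  }
}

#' Multiple-MRD1 contour profile
#'
#' Samples the normalised eyelid margin at the ten fixed grid positions
#' ([mrd_grid()]): 2 mm intervals from 8 mm nasal to 10 mm temporal of
#' the pupil centre.  The height at `x = 0` is the MRD1.  Positions
#' outside the traced margin are `NA`.
#'
#' @inheritParams height_at
#' @return A tibble with columns `position` (factor `N8` ... `T10`),
#'   `x_mm`, and `height_mm`.
#' @export
contour_profile <- function(eye, interp = c("linear", "monotone")) {
  g <- mrd_grid()
  g$height_mm <- height_at(eye, g$x_mm, interp = interp)
  g
}

#' Margin reflex distance (MRD1)
#'
#' The contour height at `x = 0`: from a profile tibble (the `MRD1` row)
#' or directly from a normalised eye.
#'
#' @param x A profile tibble from [contour_profile()], a
#'   `normalized_eye`, or a margin data frame.
#' @return MRD1 in mm, or `NA` if missing.
#' @export
mrd1 <- function(x) {
  if (is.data.frame(x) && all(c("x_mm", "height_mm") %in% names(x))) {
    h <- x$height_mm[x$x_mm == 0]
    if (length(h) != 1) stop("profile has no unique x = 0 entry", call. = FALSE)
    return(h)
  }
  height_at(x, 0)
}

#' Marginal peak point of the eyelid contour
#'
#' The highest point of the upper-eyelid margin, idealised from the
#' manual procedure of raising a horizontal line until it is tangent to
#' the margin.  On a piecewise-linear margin the maximum is attained at a
#' vertex; if it is attained along a plateau wider than `tol`, the
#' midpoint of the widest contact interval is reported (first one on
#' ties).  x is signed temporal-positive, so a negative peak x means the
#' peak sits nasal to the mid-pupillary line.
#'
#' @inheritParams height_at
#' @param tol Height tolerance (mm) for plateau membership.
#' @return A one-row tibble with `x_mm` and `y_mm`.
#' @export
peak_point <- function(eye, tol = 1e-6) {
  m <- margin_of(eye)
  ymax <- max(m$y)
  at_max <- m$y >= ymax - tol
  r <- rle(at_max)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  spans <- m$x[ends[runs]] - m$x[starts[runs]]
  best <- runs[which.max(spans)]
  xs <- m$x[starts[best]:ends[best]]
  tibble::tibble(x_mm = (min(xs) + max(xs)) / 2, y_mm = ymax)
}
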