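# set every pixel of `img` (h x w x 3 array) whose centre lies within
# `radius` of (x0, y0) to `col`; `aspect` squashes y for ellipses
fill_disc <- function(img, x0, y0, radius, col, aspect = 1) {
  h <- dim(img)[1]; w <- dim(img)[2]
  rows <- max(1L, floor(y0 - radius / aspect)):min(h, ceiling(y0 + radius / aspect))
  cols <- max(1L, floor(x0 - radius)):min(w, ceiling(x0 + radius))
  if (length(rows) == 0 || length(cols) == 0) return(img)
  dx2 <- outer(rep(1, length(rows)), (cols - x0)^2)
  dy2 <- outer(((rows - y0) * aspect)^2, rep(1, length(cols)))
  inside <- dx2 + dy2 <= radius^2
  for (k in 1:3) {
    plane <- img[rows, cols, k]
    plane[inside] <- col[k]
    img[rows, cols, k] <- plane
  }
  img
}

draw_polyline <- function(img, xs, ys, col, width = 1) {
  h <- dim(img)[1]; w <- dim(img)[2]
  # dense resample so consecutive pixels connect
  pts <- lapply(seq_len(length(xs) - 1), function(i) {
    n <- max(2L, ceiling(max(abs(xs[i + 1] - xs[i]),
                             abs(ys[i + 1] - ys[i]))) * 2L)
    list(x = seq(xs[i], xs[i + 1], length.out = n),
         y = seq(ys[i], ys[i + 1], length.out = n))
  })
  px <- round(unlist(lapply(pts, `[[`, "x")))
  py <- round(unlist(lapply(pts, `[[`, "y")))
  for (dx in -width:width) {
    for (dy in -width:width) {
      cc <- px + dx; rr <- py + dy
      ok <- cc >= 1 & cc <= w & rr >= 1 & rr <= h
      idx <- cbind(rr[ok], cc[ok])
      for (k in 1:3) {
        plane <- img[, , k]
        plane[idx] <- col[k]
        img[, , k] <- plane
      }
    }
  }
  img
}

#' Render a synthetic annotation as a PNG image
#'
#' Draws a schematic periocular image from a landmark annotation: a
#' scleral ellipse, an iris disc spanning the white-to-white distance, a
#' black pupil disc, and the upper-eyelid margin polyline in red.  The
#' rendering is deterministic: the same annotation always produces the
#' same bytes.  Intended for producing image fixtures for `image_path`
#' round-trips, not for photorealism.
#'
#' @param photo A [photo_annotation()].
#' @param canvas Canvas size `c(width, height)` in pixels; all landmarks
#'   must fit inside it.
#' @param path Optional file to write with [png::writePNG()].
#' @return The image as an `height x width x 3` array in `[0, 1]`,
#'   invisibly.
#' @export
render_png <- function(photo, canvas = c(1600, 900), path = NULL) {
  stopifnot(inherits(photo, "photo_annotation"))
  if (length(canvas) != 2 || any(!is.finite(canvas)) || any(canvas < 1)) {
    stop("`canvas` must be two positive pixel dimensions", call. = FALSE)
  }
  w <- as.integer(canvas[1]); h <- as.integer(canvas[2])
  all_pts <- do.call(rbind, lapply(photo$eyes, function(e) {
    rbind(e$pupil_center, e$limbus_nasal, e$limbus_temporal,
          e$lateral_canthus, cbind(e$margin$x, e$margin$y))
  }))
  if (any(all_pts[, 1] < 1) || any(all_pts[, 1] > w) ||
      any(all_pts[, 2] < 1) || any(all_pts[, 2] > h)) {
    stop("landmarks fall outside the canvas", call. = FALSE)
  }
  img <- array(1, dim = c(h, w, 3))
  for (side in c("right", "left")) {
    e <- photo$eyes[[side]]
    r_iris <- sqrt(sum((e$limbus_temporal - e$limbus_nasal)^2)) / 2
    r_pupil <- if (!is.null(e$pupil_diameter)) e$pupil_diameter / 2
               else 0.4 * r_iris
    img <- fill_disc(img, e$pupil_center[1], e$pupil_center[2],
                     1.8 * r_iris, c(0.93, 0.93, 0.95), aspect = 1.6)
    img <- fill_disc(img, e$pupil_center[1], e$pupil_center[2],
                     r_iris, c(0.45, 0.55, 0.60))
    img <- fill_disc(img, e$pupil_center[1], e$pupil_center[2],
                     r_pupil, c(0, 0, 0))
    img <- draw_polyline(img, e$margin$x, e$margin$y, c(0.8, 0.1, 0.1),
                         width = 1)
  }
  if (!is.null(path)) png::writePNG(img, path)
  invisible(img)
}
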