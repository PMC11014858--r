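#' Reconstruct beam geometry and pixel calibration from tracked landmarks
#'
#' The beam top is the straight line through the two tracked beam-top
#' landmarks; because they are static objects, each landmark is aggregated
#' as the per-coordinate median over its non-missing frames, which is robust
#' to tracking jitter. Pixel calibration comes from the start/stop markings
#' painted on the beam a known distance apart: `px_per_cm =
#' |start_x - stop_x| / marking_span_cm`, and the beam height in pixels is
#' `beam_height_cm * px_per_cm`.
#'
#' @param table A (preferably conditioned) [tracking_table()].
#' @param beam_height_cm Physical beam height in cm (default 2).
#' @param marking_span_cm Physical distance between the start and stop
#'   markings in cm (default 39).
#' @param labels Named character vector giving the label names of the four
#'   landmarks: `beam_left`, `beam_right`, `start_mark`, `stop_mark`.
#' @return An object of class `beam_geometry` with elements `left_top`,
#'   `right_top`, `slope`, `intercept` (beam top line `y = slope*x +
#'   intercept` in image coordinates), `px_per_cm`, `beam_height_px`,
#'   `start_x`, `stop_x`, `beam_height_cm`, `marking_span_cm`.
#' @export
#' @examples
#' tt <- tracking_table(list(
#'   beam_left  = data.frame(x = 100,  y = 500, likelihood = 1),
#'   beam_right = data.frame(x = 1800, y = 500, likelihood = 1),
#'   start_mark = data.frame(x = 200,  y = 500, likelihood = 1),
#'   stop_mark  = data.frame(x = 980,  y = 500, likelihood = 1)))
#' fit_beam_geometry(tt)
fit_beam_geometry <- function(table, beam_height_cm = 2, marking_span_cm = 39,
                              labels = c(beam_left = "beam_left",
                                         beam_right = "beam_right",
                                         start_mark = "start_mark",
                                         stop_mark = "stop_mark")) {
  stopifnot(inherits(table, "tracking_table"),
            beam_height_cm > 0, marking_span_cm > 0)
  need <- c("beam_left", "beam_right", "start_mark", "stop_mark")
  stopifnot(all(need %in% names(labels)))
  landmark <- function(canon) {
    lab <- labels[[canon]]
    d <- table$data[[lab]]
    if (is.null(d))
      stop("landmark label '", lab, "' not present in the tracking table")
    ok <- !d$missing
    if (!any(ok))
      stop("landmark label '", lab, "' is fully missing; cannot fit geometry")
    c(x = median(d$x[ok]), y = median(d$y[ok]))
  }
  lt <- landmark("beam_left")
  rt <- landmark("beam_right")
  if (lt[["x"]] >= rt[["x"]]) {
    tmp <- lt; lt <- rt; rt <- tmp
  }
  if (abs(rt[["x"]] - lt[["x"]]) < .Machine$double.eps^0.5)
    stop("degenerate beam geometry: beam-top landmarks are coincident in x")
  slope <- (rt[["y"]] - lt[["y"]]) / (rt[["x"]] - lt[["x"]])
  intercept <- lt[["y"]] - slope * lt[["x"]]
  start_x <- landmark("start_mark")[["x"]]
  stop_x <- landmark("stop_mark")[["x"]]
  if (abs(start_x - stop_x) < .Machine$double.eps^0.5)
    stop("degenerate geometry: start and stop markings coincide")
  px_per_cm <- abs(start_x - stop_x) / marking_span_cm
  structure(list(left_top = lt, right_top = rt,
                 slope = slope, intercept = intercept,
                 px_per_cm = px_per_cm,
                 beam_height_px = beam_height_cm * px_per_cm,
                 start_x = start_x, stop_x = stop_x,
                 beam_height_cm = beam_height_cm,
                 marking_span_cm = marking_span_cm),
            class = "beam_geometry")
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat(sprintf(
    "<beam_geometry> top line y = %.4g*x + %.4g\n  %.3g px/cm, beam height %.3g px (%.3g cm)\n  markings at x = %.5g / %.5g (%.3g cm apart)\n",
    x$slope, x$intercept, x$px_per_cm, x$beam_height_px, x$beam_height_cm,
    x$start_x, x$stop_x, x$marking_span_cm))
  invisible(x)
}

#' Beam-top y coordinate at given x positions
#' @param geom A [fit_beam_geometry()] result.
#' @param x Numeric vector of image x coordinates (pixels).
#' @return Numeric vector of beam-top y coordinates (pixels).
#' @export
beam_y_at <- function(geom, x) {
  stopifnot(inherits(geom, "beam_geometry"))
  geom$slope * x + geom$intercept
}

#' Beam-relative vertical position in percent of beam height
#'
#' Converts image coordinates to the beam-relative convention: 0% is the
#' beam top, 100% is one beam height above the top, negative values are
#' below the beam (image y grows downward, so a larger y means a lower,
#' more negative position).
#'
#' @param geom A [fit_beam_geometry()] result.
#' @param x,y Numeric vectors of image coordinates (pixels). `NA` in either
#'   propagates to `NA` in the result.
#' @return Numeric vector of positions in percent of beam height.
#' @export
#' @examples
#' g <- structure(list(slope = 0, intercept = 500, beam_height_px = 40),
#'                class = "beam_geometry")
#' relative_position(g, 100, c(500, 520, 480))  # 0, -50, +50
relative_position <- function(geom, x, y) {
  stopifnot(inherits(geom, "beam_geometry"))
  (beam_y_at(geom, x) - y) / geom$beam_height_px * 100
}

#' Per-frame beam-relative positions of one label
#'
#' @param table A [tracking_table()].
#' @param geom A [fit_beam_geometry()] result.
#' @param label Label name.
#' @return Numeric vector (one value per frame, `NA` where the point is
#'   missing) of positions in percent of beam height.
#' @export
label_positions <- function(table, geom, label) {
  d <- table$data[[label]]
  if (is.null(d)) stop("label '", label, "' not present")
  out <- relative_position(geom, d$x, d$y)
  out[d$missing] <- NA_real_
  out
}

#' Tail-base angle between the rays to the nose and to the tail tip
#'
#' Rudimentary posture measure: the angle at the tail base formed by the
#' vector to the nose and the vector to the tail tip. When the tail tip is
#' occluded (missing), the tail center substitutes as a fallback. The angle
#' is reported in `[0, 360)` degrees: values in `(0, 180)` mean the tail tip
#' sits above the tail base (higher tail carriage), values in `(180, 360)`
#' mean the tip hangs below the base. At exactly equal height the unsigned
#' angle is reported (the "above" branch), so 0 and 180 degrees behave as
#' the colinear boundary cases.
#'
#' All four arguments are data frames (or lists) with numeric `x`, `y` and
#' logical `missing`, vectorized over frames.
#'
#' @param nose,base,tip,center Per-frame points: nose, tail base, tail tip
#'   and tail center.
#' @return A data frame with `theta` (degrees, `NA` where not computable,
#'   e.g. nose or base missing, both tip and center missing, or a
#'   zero-length tail vector) and `used_fallback` (logical).
#' @export
tail_base_angle <- function(nose, base, tip, center) {
  as_pt <- function(p) {
    p <- as.data.frame(p)
    if (is.null(p$missing)) p$missing <- FALSE
    p
  }
  nose <- as_pt(nose); base <- as_pt(base)
  tip <- as_pt(tip); center <- as_pt(center)
  n <- max(nrow(nose), nrow(base), nrow(tip), nrow(center))
  used_fallback <- tip$missing & !center$missing
  ref_x <- ifelse(used_fallback, center$x, tip$x)
  ref_y <- ifelse(used_fallback, center$y, tip$y)
  ref_missing <- tip$missing & center$missing
  ux <- nose$x - base$x; uy <- nose$y - base$y
  vx <- ref_x - base$x;  vy <- ref_y - base$y
  nu <- sqrt(ux^2 + uy^2); nv <- sqrt(vx^2 + vy^2)
  cosa <- pmin(1, pmax(-1, (ux * vx + uy * vy) / (nu * nv)))
  alpha <- acos(cosa) * 180 / pi
  below <- ref_y > base$y  # image y grows downward
  theta <- ifelse(below, 360 - alpha, alpha)
  theta[theta >= 360] <- 0
  bad <- nose$missing | base$missing | ref_missing | nu == 0 | nv == 0
  theta[bad] <- NA_real_
  used_fallback[bad] <- NA
  data.frame(theta = theta, used_fallback = used_fallback)
}

#' Body area spanned by nose, back, tail base and belly
#'
#' Computes the area of the irregular quadrilateral through the four torso
#' landmarks, ordered along the anatomical perimeter nose, back, tail base,
#' belly (dorsal points first, then back along the ventral side) so the
#' polygon does not self-intersect. The shoelace area in square pixels is
#' converted to cm^2 with the pixel calibration.
#'
#' @param nose,back,tail_base,belly Per-frame points (data frames with `x`,
#'   `y`, `missing`), vectorized over frames.
#' @param px_per_cm Pixel calibration (> 0).
#' @return Numeric vector of areas in cm^2; `NA` where any vertex is missing.
#' @export
#' @examples
#' pt <- function(x, y) data.frame(x = x, y = y, missing = FALSE)
#' body_area(pt(0, 0), pt(1, 0), pt(1, 1), pt(0, 1), px_per_cm = 1)  # 1
body_area <- function(nose, back, tail_base, belly, px_per_cm) {
  stopifnot(px_per_cm > 0)
  as_pt <- function(p) {
    p <- as.data.frame(p)
    if (is.null(p$missing)) p$missing <- FALSE
    p
  }
  pts <- lapply(list(nose, back, tail_base, belly), as_pt)
  xs <- lapply(pts, `[[`, "x")
  ys <- lapply(pts, `[[`, "y")
  s <- 0
  for (k in 1:4) {
    k2 <- if (k == 4) 1 else k + 1
    s <- s + xs[[k]] * ys[[k2]] - xs[[k2]] * ys[[k]]
  }
  area <- abs(s) / 2 / px_per_cm^2
  bad <- Reduce(`|`, lapply(pts, `[[`, "missing"))
  area[bad] <- NA_real_
  area
}
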