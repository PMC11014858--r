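test_that("beam geometry recovers line, calibration and markings", {
  g <- make_geom()
  expect_equal(g$slope, 0)
  expect_equal(g$intercept, 500)
  # 780 px over 39 cm -> 20 px/cm; 2 cm beam -> 40 px
  expect_equal(g$px_per_cm, 20)
  expect_equal(g$beam_height_px, 40)

  # tilted beam through (0, 500) and (1000, 520)
  g2 <- make_geom(beam_left_x = 0, beam_right_x = 1000, slope = 0.02)
  expect_equal(g2$slope, 0.02)
  expect_equal(g2$intercept, 500)
  expect_equal(beam_y_at(g2, 500), 510)
})

test_that("geometry errors name the offending landmark", {
  frames <- landmark_frames()
  frames$start_mark$likelihood <- 0
  tt <- condition_tracks(tracking_table(frames))
  expect_error(fit_beam_geometry(tt), "start_mark")

  frames <- landmark_frames(beam_right_x = 100)  # coincides with beam_left
  expect_error(fit_beam_geometry(tracking_table(frames)), "degenerate")
})

test_that("relative position uses the beam-height percent convention", {
  g <- make_geom()  # horizontal beam at y = 500, height 40 px
  expect_equal(relative_position(g, 300, 500), 0)
  expect_equal(relative_position(g, 300, 520), -50)
  expect_equal(relative_position(g, 300, 480), 50)
})

test_that("relative position is invariant under scene translation and rescaling", {
  set.seed(7)
  for (i in 1:50) {
    bl <- runif(1, 0, 200); br <- runif(1, 1000, 1900)
    sl <- runif(1, -0.05, 0.05)
    sx <- runif(1, 250, 400); ox <- runif(1, 900, 1100)
    frames <- landmark_frames(beam_left_x = bl, beam_right_x = br,
                              slope = sl, start_x = sx, stop_x = ox,
                              beam_y = runif(1, 400, 600))
    g <- fit_beam_geometry(tracking_table(frames))
    x <- runif(1, 0, 1900); y <- runif(1, 0, 1000)
    v0 <- relative_position(g, x, y)

    dx <- runif(1, -50, 50); dy <- runif(1, -50, 50)
    shifted <- lapply(frames, function(d) {
      d$x <- d$x + dx; d$y <- d$y + dy; d
    })
    gs <- fit_beam_geometry(tracking_table(shifted))
    expect_equal(relative_position(gs, x + dx, y + dy), v0)

    s <- runif(1, 0.5, 2)
    scaled <- lapply(frames, function(d) {
      d$x <- d$x * s; d$y <- d$y * s; d
    })
    gz <- fit_beam_geometry(tracking_table(scaled))
    expect_equal(relative_position(gz, x * s, y * s), v0)
  }
})

test_that("tail-base angle matches hand-derived configurations", {
  base <- pt(500, 300); nose <- pt(600, 300)
  # colinear with the nose ray, equal height
  expect_equal(tail_base_angle(nose, base, pt(700, 300), pt(0, 0))$theta, 0)
  # directly opposite the nose, equal height
  expect_equal(tail_base_angle(nose, base, pt(400, 300), pt(0, 0))$theta, 180)
  # dot-product oracle: u = (100, 0), v = (-50, -50) -> 135, tip above
  expect_equal(tail_base_angle(nose, base, pt(450, 250), pt(0, 0))$theta, 135)
  # reflected below the base -> 360 - 135
  expect_equal(tail_base_angle(nose, base, pt(450, 350), pt(0, 0))$theta, 225)
  # straight up / straight down (image y grows downward)
  expect_equal(tail_base_angle(nose, base, pt(500, 200), pt(0, 0))$theta, 90)
  expect_equal(tail_base_angle(nose, base, pt(500, 400), pt(0, 0))$theta, 270)
})

test_that("tail-center fallback triggers only when the tip is missing", {
  base <- pt(500, 300); nose <- pt(600, 300)
  res <- tail_base_angle(nose, base, pt(NA, NA, missing = TRUE),
                         pt(500, 200))
  expect_equal(res$theta, 90)
  expect_true(res$used_fallback)
  res2 <- tail_base_angle(nose, base, pt(500, 400), pt(500, 200))
  expect_equal(res2$theta, 270)
  expect_false(res2$used_fallback)
  # both references missing, or degenerate zero-length tail vector
  expect_true(is.na(tail_base_angle(nose, base,
                                    pt(NA, NA, missing = TRUE),
                                    pt(NA, NA, missing = TRUE))$theta))
  expect_true(is.na(tail_base_angle(nose, base, pt(500, 300),
                                    pt(0, 0))$theta))
})

test_that("mirrored tail configurations sum to 360 degrees", {
  set.seed(11)
  for (i in 1:200) {
    base <- pt(runif(1, 100, 900), runif(1, 100, 900))
    nose <- pt(base$x + runif(1, -200, 200), base$y + runif(1, -200, 200))
    tip <- pt(base$x + runif(1, -200, 200), base$y + runif(1, -200, 200))
    if (tip$y == base$y) next
    a <- tail_base_angle(nose, base, tip, pt(0, 0))$theta
    mirror <- function(p) pt(p$x, 2 * base$y - p$y)
    b <- tail_base_angle(mirror(nose), base, mirror(tip), pt(0, 0))$theta
    expect_equal(a + b, 360)
  }
})

test_that("body area handles the closed forms and is rigid-motion invariant", {
  expect_equal(body_area(pt(0, 0), pt(1, 0), pt(1, 1), pt(0, 1), 1), 1)
  expect_equal(body_area(pt(0, 0), pt(1, 1), pt(2, 2), pt(3, 3), 1), 0)
  expect_equal(body_area(pt(0, 0), pt(20, 0), pt(20, 20), pt(0, 20), 10), 4)

  set.seed(3)
  for (i in 1:50) {
    ps <- replicate(4, pt(runif(1, 0, 100), runif(1, 0, 100)),
                    simplify = FALSE)
    a0 <- body_area(ps[[1]], ps[[2]], ps[[3]], ps[[4]], 5)
    th <- runif(1, 0, 2 * pi); dx <- runif(1, -50, 50); dy <- runif(1, -50, 50)
    rot <- lapply(ps, function(p)
      pt(cos(th) * p$x - sin(th) * p$y + dx,
         sin(th) * p$x + cos(th) * p$y + dy))
    expect_equal(body_area(rot[[1]], rot[[2]], rot[[3]], rot[[4]], 5), a0)
    # cyclic rotation of the vertex order preserves the polygon
    expect_equal(body_area(ps[[2]], ps[[3]], ps[[4]], ps[[1]], 5), a0)
  }
})
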