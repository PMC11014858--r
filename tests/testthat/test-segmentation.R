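# table in which belly/back/tail_base move by a controlled amount per frame
still_table <- function(steps_belly, steps_back, steps_tail) {
  n <- length(steps_belly) + 1
  mk <- function(steps) data.frame(x = cumsum(c(100, steps)),
                                   y = rep(500, n), likelihood = 1)
  tracking_table(list(belly = mk(steps_belly), back = mk(steps_back),
                      tail_base = mk(steps_tail)))
}

test_that("stationarity requires all three reference labels to be still", {
  tt <- still_table(c(1.0, 2.0, 1.0), c(1.0, 0, 1.6), c(1.0, 0, 0))
  m <- stationary_mask(tt)
  expect_false(m[1])          # no previous frame
  expect_true(m[2])           # all moved 1.0 <= 1.5
  expect_false(m[3])          # belly moved 2.0
  expect_false(m[4])          # back moved 1.6
})

test_that("a missing reference point makes the frame non-stationary", {
  tt <- still_table(c(0, 0), c(0, 0), c(0, 0))
  tt$data$tail_base$missing[2] <- TRUE
  m <- stationary_mask(tt)
  expect_false(m[2])
  expect_false(m[3])  # previous frame missing for tail_base
})

test_that("stationary mask is invariant under scene translation", {
  set.seed(5)
  for (i in 1:20) {
    tt <- random_table(i, labels = c("belly", "back", "tail_base"))
    m0 <- stationary_mask(tt)
    dx <- runif(1, -100, 100); dy <- runif(1, -100, 100)
    shifted <- tt
    shifted$data <- lapply(tt$data, function(d) {
      d$x <- d$x + dx; d$y <- d$y + dy; d
    })
    expect_identical(stationary_mask(shifted), m0)
  }
})

ramp_table <- function(xs, still_after = NULL) {
  n <- length(xs)
  mk <- function() data.frame(x = xs, y = 480, likelihood = 1)
  tracking_table(c(list(label = mk(), back = mk(), belly = mk(),
                        tail_base = mk()),
                   landmark_frames(n = n)))
}

test_that("trial span keeps only frames between the markings", {
  xs <- seq(100, 900, length.out = 41)
  tt <- ramp_table(xs)
  g <- fit_beam_geometry(tt)   # markings at 200 / 980
  seg <- segment_trial(tt, g, "label")
  expect_identical(seg$frames_in_span, which(xs >= 200 & xs <= 980))
  expect_equal(seg$direction, 1L)

  rev_tt <- ramp_table(rev(xs))
  seg_rev <- segment_trial(rev_tt, fit_beam_geometry(rev_tt), "label")
  expect_equal(seg_rev$direction, -1L)
})

test_that("stationary and out-of-span frames are excluded", {
  # animal parked inside the span: every frame after the first is stationary
  tt <- ramp_table(rep(500, 20))
  seg <- segment_trial(tt, fit_beam_geometry(tt), "label")
  expect_equal(seg$n_valid, 1L)  # the first frame has no previous frame
  expect_equal(sum(seg$stationary), 19L)

  # animal never enters the span: empty trial with a warning
  tt2 <- ramp_table(rep(100, 20))
  expect_warning(seg2 <- segment_trial(tt2, fit_beam_geometry(tt2), "label"),
                 "empty")
  expect_equal(seg2$n_valid, 0L)
})

test_that("shrinking the marking span never lengthens the trial", {
  set.seed(9)
  xs <- cumsum(runif(80, 0, 20))
  for (i in 1:10) {
    s1 <- sort(runif(2, min(xs), max(xs)))
    shrink <- c(s1[1] + 0.2 * diff(s1), s1[2] - 0.2 * diff(s1))
    n_of <- function(span) {
      tt <- ramp_table(xs)
      tt$data$start_mark$x[] <- span[1]
      tt$data$stop_mark$x[] <- span[2]
      seg <- suppressWarnings(segment_trial(tt, fit_beam_geometry(tt), "label"))
      seg$n_valid
    }
    expect_lte(n_of(shrink), n_of(s1))
  }
})

test_that("trial metrics count valid frames and time below the beam", {
  xs <- seq(210, 970, length.out = 100)
  tt <- ramp_table(xs)
  g <- fit_beam_geometry(tt)
  seg <- segment_trial(tt, g, "label")
  pos <- label_positions(tt, g, "label")   # y=480 on a 500 beam -> +50%
  m <- trial_metrics(seg, pos, fps = 50)
  expect_equal(m$trial_length_frames, 100)
  expect_equal(m$trial_length_s, 2.0)
  expect_equal(m$below_beam_fraction, 0)

  # push 40 of the frames below the beam
  tt$data$label$y[11:50] <- 530
  pos2 <- label_positions(tt, g, "label")
  m2 <- trial_metrics(seg, pos2, fps = 50)
  expect_equal(m2$below_beam_frames, 40)
  expect_equal(m2$below_beam_fraction, 0.4)

  empty <- trial_metrics(suppressWarnings(
    segment_trial(ramp_table(rep(0, 5)), g, "label")), rep(NA_real_, 5), 50)
  expect_true(empty$empty)
})
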