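hind <- slip_thresholds(20, 50)
fore <- slip_thresholds(10, 30)

test_that("depth classification follows the per-limb threshold partition", {
  expect_equal(classify_depth(c(0, 19.99, 20, 30, 50), hind),
               c("none", "none", "minor", "minor", "minor"))
  expect_equal(classify_depth(c(50.01, 60), hind), c("major", "major"))
  expect_equal(classify_depth(c(9.99, 10, 15, 30, 30.01), fore),
               c("none", "minor", "minor", "minor", "major"))
  expect_error(classify_depth(-1, hind), "non-negative")
})

test_that("single dips, separated dips and rebounds produce the right events", {
  ep <- event_params()
  # nothing below threshold
  expect_equal(nrow(detect_slip_events(1:20, rep(0, 20), hind, ep)), 0)

  # one smooth dip to depth 60 over 5 frames -> one major event
  d <- c(0, 0, 30, 50, 60, 50, 30, 0, 0)
  ev <- detect_slip_events(seq_along(d), d, hind, ep)
  expect_equal(ev$klass, "major")
  expect_equal(ev$extremum_depth, 60)
  expect_equal(ev$extremum_frame, 5)
  expect_equal(c(ev$start_frame, ev$end_frame), c(3, 7))

  # two dips to depth 30 separated by 10 frames at depth 0 -> two minors
  d2 <- c(rep(0, 3), 30, 30, 30, rep(0, 10), 30, 30, 30, rep(0, 3))
  ev2 <- detect_slip_events(seq_along(d2), d2, hind, ep)
  expect_equal(ev2$klass, c("minor", "minor"))

  # one run dipping to 55, rebounding to 20, dipping to 58 -> split into two
  d3 <- c(0, 25, 40, 55, 40, 28, 20, 28, 40, 58, 40, 25, 0)
  ev3 <- detect_slip_events(seq_along(d3), d3, hind, ep)
  expect_equal(ev3$klass, c("major", "major"))
  expect_equal(ev3$extremum_depth, c(55, 58))

  # same shape but shallow rebound (< 10 points) stays one event
  d4 <- c(0, 25, 40, 55, 50, 48, 50, 56, 40, 25, 0)
  ev4 <- detect_slip_events(seq_along(d4), d4, hind, ep)
  expect_equal(ev4$klass, "major")
})

test_that("runs respect duration, separation and missing-gap rules", {
  ep <- event_params()  # min_duration 2, min_separation 3
  # a single below-threshold frame never opens an event
  d <- c(0, 0, 60, 0, 0)
  expect_equal(nrow(detect_slip_events(seq_along(d), d, hind, ep)), 0)

  # interruptions shorter than min_separation do not split a run
  d2 <- c(30, 30, 0, 0, 30, 30)
  expect_equal(nrow(detect_slip_events(seq_along(d2), d2, hind, ep)), 1)
  d3 <- c(30, 30, 0, 0, 0, 30, 30)
  expect_equal(nrow(detect_slip_events(seq_along(d3), d3, hind, ep)), 2)

  # an absent-frame gap longer than max_gap terminates the run
  f <- c(1:4, 20:23)
  d4 <- rep(30, 8)
  expect_equal(nrow(detect_slip_events(f, d4, hind, ep,
                                       max_gap_frames = 10)), 2)
  f2 <- c(1:4, 10:13)
  expect_equal(nrow(detect_slip_events(f2, d4, hind, ep,
                                       max_gap_frames = 10)), 1)
})

test_that("event detection matches the brute-force reference on random traces", {
  ep <- event_params()
  for (s in 1:300) {
    tr <- simulate_depth_trace(s)
    a <- detect_slip_events(tr$frames, tr$depth, hind, ep)
    b <- slip_events_bruteforce(tr$frames, tr$depth, hind, ep)
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b)
  }
})

test_that("detection is deterministic and conserves counts", {
  tr <- simulate_depth_trace(99)
  a <- detect_slip_events(tr$frames, tr$depth, hind)
  b <- detect_slip_events(tr$frames, tr$depth, hind)
  expect_identical(a, b)
  cnt <- count_slips(a)
  expect_equal(cnt$n_minor + cnt$n_major, nrow(a))
})

test_that("deepening a trace never demotes a major event", {
  ep <- event_params()
  for (s in 1:100) {
    tr <- simulate_depth_trace(s)
    ev <- detect_slip_events(tr$frames, tr$depth, hind, ep)
    maj <- ev[ev$klass == "major", , drop = FALSE]
    if (!nrow(maj)) next
    deeper <- detect_slip_events(tr$frames, tr$depth + runif(1, 1, 15),
                                 hind, ep)
    for (k in seq_len(nrow(maj))) {
      hit <- deeper[deeper$start_frame <= maj$extremum_frame[k] &
                      deeper$end_frame >= maj$extremum_frame[k], ,
                    drop = FALSE]
      expect_equal(nrow(hit), 1)
      expect_equal(hit$klass, "major")
    }
  }
})

test_that("slip counts and agreement rates follow their definitions", {
  ev <- data.frame(klass = c("minor", "major", "major"))
  expect_equal(count_slips(ev), list(n_minor = 1L, n_major = 2L))
  expect_equal(count_slips(ev[sample(3), , drop = FALSE]),
               list(n_minor = 1L, n_major = 2L))
  expect_equal(count_slips(empty <- data.frame(klass = character(0))),
               list(n_minor = 0L, n_major = 0L))

  expect_equal(agreement_rate(c(2, 3), c(2, 3)), 1)
  expect_equal(agreement_rate(c(5, 3), c(6, 5)), 0.5)
  expect_equal(agreement_rate(2, 2, tolerance = 0), 1)
  expect_error(agreement_rate(1:3, 1:2), "equal length")
})
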