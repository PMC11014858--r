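test_that("DLC CSV write/read round-trips values exactly", {
  tt <- tracking_table(list(
    nose = data.frame(x = c(1.25, 2.5, 3.75), y = c(10, 11.5, 13),
                      likelihood = c(1, 0.9, 0.85)),
    back = data.frame(x = c(5, 6, 7), y = c(20, 21, 22),
                      likelihood = c(0.99, 1, 0.5))))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dlc_csv(tt, path)
  back <- read_dlc_csv(path)
  expect_identical(labels(back), c("nose", "back"))
  for (lab in labels(back)) {
    expect_equal(back$data[[lab]]$x, tt$data[[lab]]$x)
    expect_equal(back$data[[lab]]$y, tt$data[[lab]]$y)
    expect_equal(back$data[[lab]]$likelihood, tt$data[[lab]]$likelihood)
    # no conditioning at read time: everything present
    expect_false(any(back$data[[lab]]$missing))
  }
})

test_that("malformed headers and bad cells are rejected with clear errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  # second (bodyparts) header row absent
  writeLines(c("scorer,s,s,s",
               "coords,x,y,likelihood",
               "0,1,2,0.9"), path)
  expect_error(read_dlc_csv(path), "bodyparts")

  writeLines(c("scorer,s,s,s",
               "bodyparts,nose,nose,nose",
               "coords,x,y,likelihood",
               "0,1,oops,0.9"), path)
  expect_error(read_dlc_csv(path), "non-numeric.*nose")

  writeLines(c("scorer,s,s,s,s,s,s",
               "bodyparts,nose,nose,nose,nose,nose,nose",
               "coords,x,y,likelihood,x,y,likelihood",
               "0,1,2,0.9,1,2,0.9"), path)
  expect_error(read_dlc_csv(path), "duplicate")
})

test_that("likelihood gate and velocity gate mark points missing", {
  tt <- tracking_table(list(
    nose = data.frame(x = c(0, 0, 0, 0, 0), y = c(0, 0, 100, 0, 0),
                      likelihood = c(1, 1, 1, 1, 0.1))))
  out <- condition_tracks(tt, conditioning_params(p_cutoff = 0.2,
                                                  max_jump_px = 30))
  d <- out$data$nose
  # frame 5: sub-cutoff likelihood stays missing (trailing gap, no neighbor)
  expect_true(d$missing[5])
  # frame 3: 100-px single-frame excursion removed, then interpolated across
  expect_false(d$missing[3])
  expect_equal(d$y, c(0, 0, 0, 0, 0))
  expect_equal(d$missing, c(FALSE, FALSE, FALSE, FALSE, TRUE))
})

test_that("short gaps are linearly interpolated with min-neighbor likelihood", {
  tt <- tracking_table(list(
    nose = data.frame(x = c(5, 5, 5, 5), y = c(10, 99, 99, 16),
                      likelihood = c(0.9, 0.1, 0.15, 0.7))))
  out <- condition_tracks(tt, conditioning_params())
  d <- out$data$nose
  expect_equal(d$y, c(10, 12, 14, 16))
  expect_equal(d$x, rep(5, 4))
  expect_equal(d$likelihood[2:3], c(0.7, 0.7))
  expect_false(any(d$missing))
})

test_that("gaps longer than max_gap_frames stay missing", {
  n <- 20
  lik <- rep(1, n); lik[5:18] <- 0.05
  tt <- tracking_table(list(
    nose = data.frame(x = seq_len(n), y = rep(0, n), likelihood = lik)))
  out <- condition_tracks(tt, conditioning_params(max_gap_frames = 10))
  expect_true(all(out$data$nose$missing[5:18]))
})

test_that("clean tracks pass through conditioning unchanged", {
  set.seed(42)
  tt <- tracking_table(list(
    nose = data.frame(x = cumsum(runif(30, 0, 5)),
                      y = 500 + cumsum(rnorm(30)), likelihood = 1)))
  out <- condition_tracks(tt, conditioning_params())
  expect_equal(out$data$nose, tt$data$nose)
})

test_that("conditioning is idempotent on random tables", {
  params <- conditioning_params()
  for (seed in 1:25) {
    once <- condition_tracks(random_table(seed), params)
    twice <- condition_tracks(once, params)
    expect_equal(twice, once)
  }
})

test_that("conditioning never alters points that pass both gates", {
  params <- conditioning_params()
  for (seed in 1:10) {
    tt <- random_table(seed)
    out <- condition_tracks(tt, params)
    for (lab in labels(tt)) {
      keep <- !out$data[[lab]]$missing &
        out$data[[lab]]$likelihood == tt$data[[lab]]$likelihood
      # points with unchanged likelihood were not interpolated; their
      # coordinates must be untouched
      expect_equal(out$data[[lab]]$x[keep], tt$data[[lab]]$x[keep])
      expect_equal(out$data[[lab]]$y[keep], tt$data[[lab]]$y[keep])
    }
  }
})
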