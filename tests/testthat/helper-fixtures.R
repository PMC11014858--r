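# Fixture builders shared across the suite; everything is generated in code.

# Minimal table with the four beam landmarks needed for geometry fitting.
landmark_frames <- function(n = 3, beam_y = 500, start_x = 200, stop_x = 980,
                            beam_left_x = 100, beam_right_x = 1800,
                            slope = 0) {
  line_y <- function(x) beam_y + slope * (x - beam_left_x)
  const <- function(x, y) data.frame(x = rep(x, n), y = rep(y, n),
                                     likelihood = 1)
  list(beam_left = const(beam_left_x, line_y(beam_left_x)),
       beam_right = const(beam_right_x, line_y(beam_right_x)),
       start_mark = const(start_x, line_y(start_x)),
       stop_mark = const(stop_x, line_y(stop_x)))
}

make_geom <- function(...) {
  fit_beam_geometry(tracking_table(landmark_frames(...)))
}

# A random tracking table with plausible structure: random-walk coordinates,
# some likelihood dropouts, some large jumps.
random_table <- function(seed, n = 60, labels = c("nose", "back", "belly")) {
  set.seed(seed)
  data <- lapply(seq_along(labels), function(i) {
    x <- cumsum(rnorm(n, 3, 4)) + 100 * i
    y <- 500 + cumsum(rnorm(n, 0, 3))
    jump <- sample(n, size = max(1, rpois(1, 2)))
    y[jump] <- y[jump] + sample(c(-1, 1), length(jump), TRUE) * runif(length(jump), 60, 200)
    lik <- runif(n, 0.05, 1)
    data.frame(x = x, y = y, likelihood = lik)
  })
  names(data) <- labels
  tracking_table(data)
}

pt <- function(x, y, missing = FALSE) data.frame(x = x, y = y,
                                                 missing = missing)
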