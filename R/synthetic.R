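## Longitudinal (along-beam) offsets of each label from the body center, in
## pixels, before multiplication by travel direction.
.label_dx <- c(nose = 70, left_eye = 55, left_forepaw = 40,
               right_forepaw = 35, left_hindpaw = -30, right_hindpaw = -35,
               back = 0, belly = 5, tail_base = -60, tail_center = -95,
               tail_tip = -130)

## Gait-phase offsets (radians) so limbs and body bob are out of phase.
.label_phase <- c(nose = 0.3, left_eye = 0.3, left_forepaw = 0,
                  right_forepaw = pi, left_hindpaw = pi, right_hindpaw = 0,
                  back = 0, belly = pi / 2, tail_base = 1, tail_center = 2,
                  tail_tip = 3)

#' Configuration of one synthetic beam-crossing trial
#'
#' Describes a simulated 50 fps, 1920x1080 recording of a mouse crossing
#' the marked 39 cm span of a 2 cm-high beam. Body labels follow the beam
#' line at configurable height offsets (percent of beam height) with a
#' smooth gait bob; paw labels oscillate with the stride and dip below the
#' beam exactly as prescribed by `slip_spec`; pauses freeze the animal;
#' dropouts push the likelihood below the conditioning cutoff; Gaussian
#' pixel noise is added throughout. All randomness is governed by `seed`.
#'
#' @param seed Integer RNG seed; the same configuration always generates
#'   the same trial.
#' @param fps Frame rate (default 50).
#' @param frame_size Image size in pixels, `c(width, height)`.
#' @param beam_y Beam-top y at the left beam landmark (pixels).
#' @param beam_tilt Slope of the beam top line (pixels y per pixel x).
#' @param px_per_cm Pixel calibration (default 20 px/cm).
#' @param beam_height_cm,marking_span_cm Physical beam dimensions (2 cm
#'   height, 39 cm marking span).
#' @param beam_x x positions of the left and right beam-top landmarks.
#' @param crossing_speed Walking speed in cm/s (default 8).
#' @param stride_hz Stride (paw oscillation) frequency in Hz (default 4).
#' @param direction +1 = left-to-right, -1 = right-to-left.
#' @param body_offsets Named percent-of-beam-height offsets of the body
#'   labels above the beam top. Defaults follow healthy-control posture:
#'   nose 27, belly 20, back 155, tail base 92, tail center 60, tail tip
#'   30, eye 140.
#' @param bob_amp_pct Amplitude of the vertical gait bob of body labels
#'   (percent of beam height, default 3).
#' @param lift_amp_pct Peak stride lift of the paws above the beam
#'   (percent, default 12; safely below the shallowest slip threshold).
#' @param slip_spec Data frame `limb`, `start_s`, `duration_s`,
#'   `depth_pct`, optional `shape` ("cosine" default, or "square"): paw
#'   excursions below the beam with their peak depth.
#' @param pause_spec Data frame `start_s`, `duration_s`: stationary bouts
#'   during which the whole animal freezes in place.
#' @param noise_sd_px SD of Gaussian pixel noise added to animal labels.
#' @param dropout Data frame `label`, `start_s`, `duration_s`: windows in
#'   which that label's likelihood falls below 0.2.
#' @param lead_px Extra travel (pixels) before the start and after the stop
#'   marking so every label fully traverses the span.
#' @return An object of class `synthetic_trial_config`.
#' @seealso [generate_trial()]
#' @export
synthetic_trial_config <- function(seed = 1L, fps = 50,
                                   frame_size = c(1920L, 1080L),
                                   beam_y = 520, beam_tilt = 0,
                                   px_per_cm = 20, beam_height_cm = 2,
                                   marking_span_cm = 39,
                                   beam_x = c(60, 1860),
                                   crossing_speed = 8, stride_hz = 4,
                                   direction = 1L,
                                   body_offsets = c(nose = 27, left_eye = 140,
                                                    back = 155, belly = 20,
                                                    tail_base = 92,
                                                    tail_center = 60,
                                                    tail_tip = 30),
                                   bob_amp_pct = 3, lift_amp_pct = 12,
                                   slip_spec = NULL, pause_spec = NULL,
                                   noise_sd_px = 1,
                                   dropout = NULL, lead_px = 180) {
  stopifnot(fps > 0, px_per_cm > 0, crossing_speed > 0, stride_hz > 0,
            direction %in% c(-1L, 1L), noise_sd_px >= 0, lead_px > 0)
  empty_slips <- data.frame(limb = character(0), start_s = numeric(0),
                            duration_s = numeric(0), depth_pct = numeric(0),
                            shape = character(0))
  if (is.null(slip_spec)) slip_spec <- empty_slips
  slip_spec <- as.data.frame(slip_spec)
  if (nrow(slip_spec)) {
    if (is.null(slip_spec$shape)) slip_spec$shape <- "cosine"
    stopifnot(all(slip_spec$depth_pct > 0), all(slip_spec$duration_s > 0),
              all(slip_spec$start_s >= 0),
              all(slip_spec$shape %in% c("cosine", "square")))
    for (limb in unique(slip_spec$limb)) {
      s <- slip_spec[slip_spec$limb == limb, , drop = FALSE]
      s <- s[order(s$start_s), , drop = FALSE]
      if (nrow(s) > 1 &&
          any(s$start_s[-1] < (s$start_s + s$duration_s)[-nrow(s)]))
        stop("overlapping slip windows on limb '", limb, "'")
    }
  }
  if (is.null(pause_spec))
    pause_spec <- data.frame(start_s = numeric(0), duration_s = numeric(0))
  pause_spec <- as.data.frame(pause_spec)
  if (nrow(pause_spec))
    stopifnot(all(pause_spec$duration_s > 0), all(pause_spec$start_s >= 0))
  if (is.null(dropout))
    dropout <- data.frame(label = character(0), start_s = numeric(0),
                          duration_s = numeric(0))
  structure(list(seed = as.integer(seed), fps = fps,
                 frame_size = as.integer(frame_size),
                 beam_y = beam_y, beam_tilt = beam_tilt,
                 px_per_cm = px_per_cm, beam_height_cm = beam_height_cm,
                 marking_span_cm = marking_span_cm, beam_x = beam_x,
                 crossing_speed = crossing_speed, stride_hz = stride_hz,
                 direction = as.integer(direction),
                 body_offsets = body_offsets,
                 bob_amp_pct = bob_amp_pct, lift_amp_pct = lift_amp_pct,
                 slip_spec = slip_spec, pause_spec = pause_spec,
                 noise_sd_px = noise_sd_px, dropout = as.data.frame(dropout),
                 lead_px = lead_px),
            class = "synthetic_trial_config")
}

#' Trial-time interval during which a label is inside the marking span
#'
#' Computed from the configuration's kinematics (ignoring pauses, which
#' shift but never shrink the interval). Useful for placing slip windows
#' inside the analyzed span.
#'
#' @param cfg A [synthetic_trial_config()].
#' @param label Label name (default left hindpaw).
#' @return Numeric `c(t_in, t_out)` in seconds.
#' @export
span_time_window <- function(cfg, label = "left_hindpaw") {
  geom <- synthetic_marking_positions(cfg)
  speed_px <- cfg$crossing_speed * cfg$px_per_cm
  dx <- .label_dx[[label]] * cfg$direction
  if (cfg$direction == 1) {
    x0 <- geom$start_x - cfg$lead_px
    sort(c((geom$start_x - x0 - dx), (geom$stop_x - x0 - dx)) / speed_px)
  } else {
    x0 <- geom$stop_x + cfg$lead_px
    sort(c((x0 - geom$stop_x + dx), (x0 - geom$start_x + dx)) / speed_px)
  }
}

synthetic_marking_positions <- function(cfg) {
  span_px <- cfg$marking_span_cm * cfg$px_per_cm
  start_x <- (cfg$frame_size[1] - span_px) / 2
  list(start_x = start_x, stop_x = start_x + span_px)
}

#' Generate one synthetic beam-crossing trial with ground truth
#'
#' Deterministic given the configuration's seed. Returns both the tracking
#' table (same dialect as [read_dlc_csv()] output) and the construction
#' ground truth: the slip events that were injected (classified with the
#' standard per-limb thresholds), the stationary frames, the per-label
#' height offsets and the travel direction.
#'
#' During pause bouts the entire animal is held at its bout-entry
#' coordinates (measurement noise included up to the bout entry, then
#' frozen), so the stationarity rule is satisfied exactly from the second
#' bout frame on; the ground-truth stationary set therefore excludes each
#' bout's first frame.
#'
#' @param cfg A [synthetic_trial_config()].
#' @return List with `table` (a [tracking_table()]) and `truth` (list with
#'   `slips`, `stationary_frames`, `offsets`, `direction`, `n_frames`).
#' @export
#' @examples
#' tr <- generate_trial(synthetic_trial_config(seed = 7))
#' tr$table
generate_trial <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_trial_config"))
  set.seed(cfg$seed)
  fps <- cfg$fps
  h_px <- cfg$beam_height_cm * cfg$px_per_cm
  speed_px <- cfg$crossing_speed * cfg$px_per_cm
  geom <- synthetic_marking_positions(cfg)
  intercept <- cfg$beam_y - cfg$beam_tilt * cfg$beam_x[1]
  beam_line <- function(x) cfg$beam_tilt * x + intercept

  travel <- geom$stop_x - geom$start_x + 2 * cfg$lead_px
  moving_s <- travel / speed_px
  total_s <- moving_s + sum(cfg$pause_spec$duration_s)
  n <- ceiling(total_s * fps) + 1
  t_frame <- (seq_len(n) - 1) / fps

  if (nrow(cfg$slip_spec) &&
      any(cfg$slip_spec$start_s + cfg$slip_spec$duration_s > total_s))
    stop("slip window extends beyond the trial duration")

  in_pause <- rep(FALSE, n)
  for (k in seq_len(nrow(cfg$pause_spec)))
    in_pause <- in_pause |
      (t_frame >= cfg$pause_spec$start_s[k] &
         t_frame < cfg$pause_spec$start_s[k] + cfg$pause_spec$duration_s[k])
  step <- rep(speed_px / fps, n)
  step[1] <- 0
  step[in_pause] <- 0
  x0 <- if (cfg$direction == 1) geom$start_x - cfg$lead_px
        else geom$stop_x + cfg$lead_px
  center_x <- x0 + cfg$direction * cumsum(step)
  gait_t <- cumsum(step > 0) / fps  # gait phase advances only while moving

  labs <- names(.label_dx)
  data <- list()
  for (lab in labs) {
    x <- center_x + .label_dx[[lab]] * cfg$direction
    omega <- 2 * pi * cfg$stride_hz * gait_t + .label_phase[[lab]]
    if (lab %in% names(cfg$body_offsets)) {
      rel <- cfg$body_offsets[[lab]] + cfg$bob_amp_pct * sin(omega)
    } else {
      rel <- cfg$lift_amp_pct * pmax(0, sin(omega))
      rows <- which(cfg$slip_spec$limb == lab)
      for (k in rows) {
        s0 <- cfg$slip_spec$start_s[k]
        dur <- cfg$slip_spec$duration_s[k]
        u <- (t_frame - s0) / dur
        inwin <- u >= 0 & u <= 1
        dip <- if (cfg$slip_spec$shape[k] == "square")
          cfg$slip_spec$depth_pct[k] * inwin
        else
          cfg$slip_spec$depth_pct[k] * (1 - cos(2 * pi * u)) / 2 * inwin
        rel <- ifelse(inwin, -dip, rel)
      }
    }
    y <- beam_line(x) - rel / 100 * h_px
    if (cfg$noise_sd_px > 0) {
      x <- x + rnorm(n, 0, cfg$noise_sd_px)
      y <- y + rnorm(n, 0, cfg$noise_sd_px)
    }
    lik <- runif(n, 0.95, 1)
    rows <- which(cfg$dropout$label == lab)
    for (k in rows) {
      win <- t_frame >= cfg$dropout$start_s[k] &
        t_frame < cfg$dropout$start_s[k] + cfg$dropout$duration_s[k]
      lik[win] <- runif(sum(win), 0.01, 0.15)
    }
    data[[lab]] <- data.frame(x = x, y = y, likelihood = lik)
  }

  ## freeze the whole animal at the entry coordinates of each pause bout
  if (any(in_pause)) {
    r <- rle(in_pause)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      idx <- starts[k]:ends[k]
      for (lab in labs) {
        data[[lab]]$x[idx] <- data[[lab]]$x[idx[1]]
        data[[lab]]$y[idx] <- data[[lab]]$y[idx[1]]
      }
    }
  }

  ## static beam landmarks and trial markings, with sub-noise jitter
  jit_sd <- cfg$noise_sd_px / 3
  static_label <- function(x, y) {
    data.frame(x = x + rnorm(n, 0, jit_sd), y = y + rnorm(n, 0, jit_sd),
               likelihood = runif(n, 0.95, 1))
  }
  data$beam_left <- static_label(cfg$beam_x[1], beam_line(cfg$beam_x[1]))
  data$beam_right <- static_label(cfg$beam_x[2], beam_line(cfg$beam_x[2]))
  data$start_mark <- static_label(geom$start_x, beam_line(geom$start_x))
  data$stop_mark <- static_label(geom$stop_x, beam_line(geom$stop_x))

  table <- tracking_table(data, fps = fps, frame_size = cfg$frame_size,
                          scorer = "beamwalkr-synthetic")

  ## ground truth
  truth_slips <- cfg$slip_spec
  if (nrow(truth_slips)) {
    klass <- character(nrow(truth_slips))
    for (k in seq_len(nrow(truth_slips))) {
      thr <- if (grepl("hind", truth_slips$limb[k])) slip_thresholds(20, 50)
             else slip_thresholds(10, 30)
      klass[k] <- classify_depth(truth_slips$depth_pct[k], thr)
    }
    truth_slips$klass <- klass
    truth_slips$start_frame <- floor(truth_slips$start_s * fps) + 1
    truth_slips$end_frame <-
      ceiling((truth_slips$start_s + truth_slips$duration_s) * fps) + 1
  } else {
    truth_slips$klass <- character(0)
    truth_slips$start_frame <- integer(0)
    truth_slips$end_frame <- integer(0)
  }
  stat_frames <- integer(0)
  if (any(in_pause)) {
    r <- rle(in_pause)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in which(r$values))
      if (r$lengths[k] > 1) stat_frames <- c(stat_frames,
                                             (starts[k] + 1):ends[k])
  }
  truth <- list(slips = truth_slips, stationary_frames = stat_frames,
                offsets = cfg$body_offsets, direction = cfg$direction,
                n_frames = n)
  list(table = table, truth = truth)
}

## Place k non-overlapping event windows of the given durations inside
## [t0, t1] with at least `gap` seconds between them; drops windows from the
## end when they cannot fit. Returns start times.
place_windows <- function(k, durations, t0, t1, gap = 0.3) {
  while (k > 0 && sum(durations[seq_len(k)]) + gap * (k - 1) > (t1 - t0))
    k <- k - 1
  if (k == 0) return(numeric(0))
  durations <- durations[seq_len(k)]
  slack <- (t1 - t0) - sum(durations) - gap * (k - 1)
  cuts <- sort(runif(k))
  parts <- diff(c(0, cuts)) / max(cuts, .Machine$double.eps) * slack
  starts <- numeric(k)
  pos <- t0
  for (i in seq_len(k)) {
    pos <- pos + parts[i]
    starts[i] <- pos
    pos <- pos + durations[i] + gap
  }
  starts
}

#' Simulate a random below-beam depth trace
#'
#' Generates an adversarial paw-depth series for validating the event
#' detector against the brute-force reference: a reflected Gaussian random
#' walk (so the trace wanders across the slip thresholds), injected
#' square-pulse dips of random depth and width, and random absent-frame
#' gaps (as left by stationarity/occlusion exclusion), including some gaps
#' long enough to split events.
#'
#' @param seed Integer seed.
#' @param n Number of retained samples (default 200).
#' @return List with `frames` (strictly increasing integers) and `depth`
#'   (non-negative percent values).
#' @export
simulate_depth_trace <- function(seed, n = 200) {
  set.seed(seed)
  walk <- abs(cumsum(rnorm(n, 0, 8)))
  walk <- walk * 0.9^(seq_len(n) / n * 5)  # drift back toward the beam
  depth <- pmax(0, walk - 10)
  n_dips <- sample(0:3, 1)
  for (k in seq_len(n_dips)) {
    w <- sample(3:12, 1)
    s <- sample(seq_len(n - w), 1)
    depth[s:(s + w - 1)] <- runif(1, 25, 85)
  }
  gaps <- sample(c(rep(1, 40), 2, 3, 6, 15), n - 1, replace = TRUE)
  frames <- cumsum(c(1, gaps))
  list(frames = frames, depth = depth)
}

#' Default group parameters for synthetic cohorts
#'
#' Two phenotypes bracketing the study conditions: a healthy control group
#' (rare major slips, body carried well above the beam) and an ataxic group
#' (frequent major slips, belly and tail carried low). Offsets are percent
#' of beam height; slip rates are expected events per trial (Poisson).
#'
#' @param phenotype `"control"` or `"ataxic"`.
#' @return List with `offsets_mean`, `offsets_sd` (between-mouse SD),
#'   `minor_rate`, `major_rate`, `minor_depth`, `major_depth` (depth ranges
#'   in percent).
#' @export
cohort_group_params <- function(phenotype = c("control", "ataxic")) {
  phenotype <- match.arg(phenotype)
  base <- list(offsets_sd = 5,
               minor_depth = c(25, 45), major_depth = c(55, 75))
  if (phenotype == "control") {
    c(base, list(offsets_mean = c(nose = 27, left_eye = 140, back = 155,
                                  belly = 20, tail_base = 92,
                                  tail_center = 60, tail_tip = 30),
                 minor_rate = 2, major_rate = 1, crossing_speed = 10))
  } else {
    ## ataxic mice carry the body low and cross slowly, leaving room for
    ## their much higher slip rate within one trial
    c(base, list(offsets_mean = c(nose = 14, left_eye = 120, back = 131,
                                  belly = -2, tail_base = 12,
                                  tail_center = 0, tail_tip = -15),
                 minor_rate = 3, major_rate = 8, crossing_speed = 5))
  }
}

#' Generate a synthetic cohort of beam-crossing trials
#'
#' Hierarchical simulation: per mouse, latent body-height offsets are drawn
#' around the group means (Gaussian, between-mouse SD from the group
#' parameters); per trial, left-hindpaw slip counts are Poisson with the
#' group rates, slip depths uniform in the group depth ranges, and slip
#' windows placed inside the hindpaw's in-span time. Every trial is
#' rendered by [generate_trial()] and is deterministic given `seed`.
#'
#' @param groups Named list of group parameter lists (see
#'   [cohort_group_params()]). Default: `control` and `ataxic`.
#' @param n_mice Mice per group (default 8).
#' @param n_trials Trials per mouse (default 3).
#' @param seed Integer master seed.
#' @param noise_sd_px Pixel noise SD for all trials (default 2).
#' @param age_group Age label stamped on the manifest (default "18m").
#' @param write_dir Optional directory; when given, each trial is written
#'   as a DLC-format CSV plus a per-trial ground-truth JSON, and a
#'   `manifest.csv` (columns `file`, `mouse_id`, `group`, `age_group`,
#'   `trial_id`) is written alongside.
#' @return List with `trials` (list of `table`/`truth`/ids per trial) and
#'   `manifest` (data frame; includes `file` when written).
#' @export
generate_cohort <- function(groups = list(control = cohort_group_params("control"),
                                          ataxic = cohort_group_params("ataxic")),
                            n_mice = 8, n_trials = 3, seed = 1,
                            noise_sd_px = 2, age_group = "18m",
                            write_dir = NULL) {
  stopifnot(n_mice >= 1, n_trials >= 1, length(groups) >= 1,
            !is.null(names(groups)))
  set.seed(seed)
  trials <- list()
  manifest <- list()
  for (g in names(groups)) {
    gp <- groups[[g]]
    for (m in seq_len(n_mice)) {
      mouse_id <- sprintf("%s_m%02d", g, m)
      offs <- gp$offsets_mean +
        rnorm(length(gp$offsets_mean), 0, gp$offsets_sd)
      names(offs) <- names(gp$offsets_mean)
      for (tr in seq_len(n_trials)) {
        n_min <- rpois(1, gp$minor_rate)
        n_maj <- rpois(1, gp$major_rate)
        depths <- c(runif(n_min, gp$minor_depth[1], gp$minor_depth[2]),
                    runif(n_maj, gp$major_depth[1], gp$major_depth[2]))
        depths <- depths[sample.int(length(depths))]
        durations <- runif(length(depths), 0.3, 0.5)
        trial_seed <- sample.int(2^30, 1)
        speed <- gp$crossing_speed %||% 8
        cfg0 <- synthetic_trial_config(seed = trial_seed,
                                       body_offsets = offs,
                                       crossing_speed = speed,
                                       noise_sd_px = noise_sd_px)
        win <- span_time_window(cfg0, "left_hindpaw")
        starts <- place_windows(length(depths), durations,
                                win[1] + 0.25, win[2] - 0.25)
        k <- length(starts)
        slip_spec <- if (k)
          data.frame(limb = "left_hindpaw", start_s = starts,
                     duration_s = durations[seq_len(k)],
                     depth_pct = depths[seq_len(k)], shape = "cosine")
        else NULL
        cfg <- synthetic_trial_config(seed = trial_seed,
                                      body_offsets = offs,
                                      crossing_speed = speed,
                                      noise_sd_px = noise_sd_px,
                                      slip_spec = slip_spec)
        out <- generate_trial(cfg)
        rec <- list(table = out$table, truth = out$truth,
                    mouse_id = mouse_id, group = g,
                    age_group = age_group, trial_id = tr)
        trials[[length(trials) + 1]] <- rec
        manifest[[length(manifest) + 1]] <- data.frame(
          mouse_id = mouse_id, group = g, age_group = age_group,
          trial_id = tr, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, manifest)
  if (!is.null(write_dir)) {
    dir.create(write_dir, showWarnings = FALSE, recursive = TRUE)
    files <- character(nrow(manifest))
    for (i in seq_along(trials)) {
      fn <- sprintf("%s_trial%02d.csv", manifest$mouse_id[i],
                    manifest$trial_id[i])
      write_dlc_csv(trials[[i]]$table, file.path(write_dir, fn))
      jsonlite::write_json(
        trials[[i]]$truth,
        file.path(write_dir, sub("\\.csv$", "_truth.json", fn)),
        auto_unbox = TRUE, digits = NA)
      files[i] <- fn
    }
    manifest$file <- files
    write.csv(manifest, file.path(write_dir, "manifest.csv"),
              row.names = FALSE)
  }
  list(trials = trials, manifest = manifest, seed = seed)
}

#' Simulate per-trial mouse summaries without rendering trajectories
#'
#' Summary-level counterpart of [generate_cohort()] for statistical
#' power/type-I studies: per mouse a latent measure value is drawn around
#' its group mean (Gaussian between-mouse variation), and each trial
#' measures that latent value with Gaussian trial-to-trial noise. The
#' result feeds directly into [mouse_means()] and [compare_groups()].
#'
#' @param group_means Named numeric vector: group label to mean measure
#'   value.
#' @param n_mice Mice per group (default 8).
#' @param n_trials Trials per mouse (default 3).
#' @param between_sd Between-mouse SD of the latent value (default 5).
#' @param trial_sd Within-mouse, between-trial SD (default 2).
#' @param measure Name of the measure column (default `"pos_belly"`).
#' @param age_group Age label (default "18m").
#' @param seed Integer seed.
#' @return Per-trial data frame with `mouse_id`, `group`, `age_group`,
#'   `trial_id` and the measure column.
#' @export
simulate_mouse_summaries <- function(group_means, n_mice = 8, n_trials = 3,
                                     between_sd = 5, trial_sd = 2,
                                     measure = "pos_belly",
                                     age_group = "18m", seed = 1) {
  stopifnot(!is.null(names(group_means)), n_mice >= 1, n_trials >= 1)
  set.seed(seed)
  rows <- list()
  for (g in names(group_means)) {
    latent <- rnorm(n_mice, group_means[[g]], between_sd)
    for (m in seq_len(n_mice)) {
      vals <- rnorm(n_trials, latent[m], trial_sd)
      rows[[length(rows) + 1]] <- data.frame(
        mouse_id = sprintf("%s_m%02d", g, m), group = g,
        age_group = age_group, trial_id = seq_len(n_trials),
        value = vals, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  names(out)[names(out) == "value"] <- measure
  out
}
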