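#' Conditioning parameters for tracked coordinates
#'
#' Controls how raw tracking tables are cleaned before analysis: points below
#' the likelihood cutoff are discarded, implausibly fast jumps are discarded,
#' and short gaps are closed by linear interpolation so that event detection
#' stays contiguous.
#'
#' @param p_cutoff Likelihood threshold in `[0, 1]`; points with likelihood
#'   strictly below it are marked missing. Default 0.2.
#' @param max_jump_px Maximum plausible speed of a tracked point, in pixels
#'   per frame. A point whose Euclidean displacement from the previous
#'   non-missing point of the same label exceeds `max_jump_px` times the
#'   number of frames elapsed is marked missing. Default 30 (px/frame at
#'   50 fps).
#' @param max_gap_frames Missing runs of at most this many frames, flanked by
#'   valid points on both sides, are filled by per-coordinate linear
#'   interpolation. Longer runs stay missing. Default 10.
#'
#' @return An object of class `conditioning_params`.
#' @seealso [condition_tracks()]
#' @export
#' @examples
#' conditioning_params(p_cutoff = 0.3)
conditioning_params <- function(p_cutoff = 0.2, max_jump_px = 30,
                                max_gap_frames = 10) {
  stopifnot(is.numeric(p_cutoff), length(p_cutoff) == 1,
            p_cutoff >= 0, p_cutoff <= 1,
            is.numeric(max_jump_px), max_jump_px > 0,
            is.numeric(max_gap_frames), max_gap_frames >= 0)
  structure(list(p_cutoff = p_cutoff, max_jump_px = max_jump_px,
                 max_gap_frames = as.integer(max_gap_frames)),
            class = "conditioning_params")
}

#' Slip depth thresholds for one limb
#'
#' Depths are expressed in percent of beam height below the beam top. A paw
#' excursion whose extremum depth lies in `[minor_lo, major_lo]` is a minor
#' slip; an extremum strictly deeper than `major_lo` is a major slip.
#' Hindpaw defaults are 20/50, forepaw defaults 10/30.
#'
#' @param minor_lo Lower bound (percent depth) for a minor slip.
#' @param major_lo Depth (percent) above which a slip is major; the boundary
#'   itself still counts as minor.
#' @return An object of class `slip_thresholds`.
#' @export
#' @examples
#' slip_thresholds(20, 50)  # hindpaw
#' slip_thresholds(10, 30)  # forepaw
slip_thresholds <- function(minor_lo = 20, major_lo = 50) {
  stopifnot(is.numeric(minor_lo), is.numeric(major_lo),
            minor_lo > 0, major_lo > minor_lo)
  structure(list(minor_lo = minor_lo, major_lo = major_lo),
            class = "slip_thresholds")
}

#' Event-detection parameters for slip counting
#'
#' Tuning knobs for turning a below-beam depth trace into discrete slip
#' events. A run of below-threshold frames opens an event only after
#' `min_duration_frames` consecutive frames; runs separated by at least
#' `min_separation_frames` above-threshold frames are distinct events; within
#' one run, two depth extrema ("valleys" of the paw trajectory) at least
#' `valley_window` frames apart are counted as separate slips when the paw
#' rebounds at least `split_prominence_pct` percentage points between them.
#'
#' @param min_duration_frames Consecutive below-threshold frames required to
#'   open an event. Default 2.
#' @param valley_window Window width (frames) for local-extremum detection;
#'   valleys closer together than this are merged, keeping the deeper one.
#'   Default 5.
#' @param min_separation_frames Above-threshold frames required to terminate
#'   a run. Default 3.
#' @param split_prominence_pct Rebound (percentage points of beam height)
#'   between adjacent valleys that splits one run into two events. Default 10.
#' @return An object of class `event_params`.
#' @seealso [detect_slip_events()]
#' @export
event_params <- function(min_duration_frames = 2, valley_window = 5,
                         min_separation_frames = 3,
                         split_prominence_pct = 10) {
  stopifnot(min_duration_frames >= 1, valley_window >= 1,
            min_separation_frames >= 1, split_prominence_pct > 0)
  structure(list(min_duration_frames = as.integer(min_duration_frames),
                 valley_window = as.integer(valley_window),
                 min_separation_frames = as.integer(min_separation_frames),
                 split_prominence_pct = split_prominence_pct),
            class = "event_params")
}

#' Full analysis configuration
#'
#' Bundles every tunable parameter of the trial pipeline: conditioning,
#' beam geometry calibration, stationarity exclusion, slip thresholds per
#' limb and event detection. Label names can be remapped for files that use
#' different bodypart names.
#'
#' @param conditioning A [conditioning_params()] object.
#' @param beam_height_cm Physical beam height in cm (default 2).
#' @param marking_span_cm Distance between the start and stop markings in cm
#'   (default 39); the only physical distance used for pixel calibration.
#' @param stationary_threshold_px Maximum per-frame displacement (pixels) of
#'   each of the stationary reference labels for a frame to count as
#'   stationary. Default 1.5.
#' @param stationary_labels Labels that must all be still for a frame to be
#'   stationary. Default belly, back, tail_base.
#' @param thresholds Named list of [slip_thresholds()] per analyzed paw.
#' @param events An [event_params()] object.
#' @param fps Frame rate of the recordings (frames/second, default 50).
#' @param labels Named character vector mapping canonical label names used by
#'   the pipeline to the bodypart names in the tracking files.
#' @param position_labels Labels whose beam-relative position is summarized
#'   per trial.
#' @param density_labels Labels whose frame-level positions are pooled for
#'   group density estimates.
#'
#' @return An object of class `bas_config` (a validated list).
#' @export
#' @examples
#' cfg <- bas_config(fps = 50)
#' cfg$thresholds$left_hindpaw$minor_lo
bas_config <- function(conditioning = conditioning_params(),
                       beam_height_cm = 2,
                       marking_span_cm = 39,
                       stationary_threshold_px = 1.5,
                       stationary_labels = c("belly", "back", "tail_base"),
                       thresholds = list(
                         left_hindpaw = slip_thresholds(20, 50),
                         left_forepaw = slip_thresholds(10, 30)),
                       events = event_params(),
                       fps = 50,
                       labels = NULL,
                       position_labels = c("nose", "belly", "back",
                                           "tail_base", "tail_center",
                                           "tail_tip", "left_hindpaw",
                                           "left_forepaw"),
                       density_labels = c("left_hindpaw", "nose", "belly",
                                          "tail_base")) {
  stopifnot(inherits(conditioning, "conditioning_params"),
            beam_height_cm > 0, marking_span_cm > 0,
            stationary_threshold_px > 0,
            inherits(events, "event_params"), fps > 0)
  if (!all(vapply(thresholds, inherits, logical(1), "slip_thresholds")))
    stop("`thresholds` must be a named list of slip_thresholds objects")
  default_labels <- c(nose = "nose", left_eye = "left_eye",
                      left_forepaw = "left_forepaw",
                      right_forepaw = "right_forepaw",
                      left_hindpaw = "left_hindpaw",
                      right_hindpaw = "right_hindpaw",
                      belly = "belly", back = "back",
                      tail_base = "tail_base", tail_center = "tail_center",
                      tail_tip = "tail_tip",
                      beam_left = "beam_left", beam_right = "beam_right",
                      start_mark = "start_mark", stop_mark = "stop_mark")
  if (!is.null(labels)) {
    unknown <- setdiff(names(labels), names(default_labels))
    if (length(unknown))
      stop("unknown canonical label name(s): ", paste(unknown, collapse = ", "))
    default_labels[names(labels)] <- labels
  }
  structure(list(conditioning = conditioning,
                 beam_height_cm = beam_height_cm,
                 marking_span_cm = marking_span_cm,
                 stationary_threshold_px = stationary_threshold_px,
                 stationary_labels = stationary_labels,
                 thresholds = thresholds,
                 events = events,
                 fps = fps,
                 labels = default_labels,
                 position_labels = position_labels,
                 density_labels = density_labels),
            class = "bas_config")
}
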