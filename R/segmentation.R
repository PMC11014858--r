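#' Stationary-frame mask
#'
#' A frame is stationary when the animal is standing still: each of the
#' reference labels (belly, back, tail base by default) moved no more than
#' `threshold_px` pixels (Euclidean) since the previous frame, with both
#' frames non-missing for that label. Missing reference points make a frame
#' non-stationary (conservative: the frame stays in the analysis). The first
#' frame is never stationary (no previous frame). Stationary frames are
#' excluded from all averaged measures and from event detection.
#'
#' @param table A [tracking_table()].
#' @param threshold_px Maximum per-frame displacement in pixels (default 1.5).
#' @param labels Reference labels that must all be still.
#' @return Logical vector, one entry per frame (`TRUE` = stationary).
#' @export
stationary_mask <- function(table, threshold_px = 1.5,
                            labels = c("belly", "back", "tail_base")) {
  stopifnot(inherits(table, "tracking_table"), threshold_px > 0)
  missing_labs <- setdiff(labels, names(table$data))
  if (length(missing_labs))
    stop("stationary reference label(s) not in table: ",
         paste(missing_labs, collapse = ", "))
  n <- table$n_frames
  still <- rep(TRUE, n)
  still[1] <- FALSE
  for (lab in labels) {
    d <- table$data[[lab]]
    disp <- c(Inf, sqrt(diff(d$x)^2 + diff(d$y)^2))
    ok <- !d$missing & !c(TRUE, d$missing[-n])  # both frames tracked
    still <- still & ok & (disp <= threshold_px)
  }
  still
}

#' Restrict one label to the trial span between the start/stop markings
#'
#' The trial window is gated per analyzed label: only frames in which that
#' label's own x coordinate lies between the start and stop marking
#' positions are considered. Stationary frames are flagged for exclusion
#' from averaged measures and event detection. Travel direction is the sign
#' of the median per-frame x displacement of the back label within the span
#' (+1 = toward larger x).
#'
#' @param table A [tracking_table()].
#' @param geom A [fit_beam_geometry()] result.
#' @param label Label to gate on.
#' @param stationary Optional precomputed [stationary_mask()]; computed from
#'   `table` with defaults when `NULL`.
#' @param direction_label Label used to infer travel direction (default
#'   `"back"`).
#' @return An object of class `trial_segment`: list with `label`,
#'   `frames_in_span` (integer frame indices, 1-based), `in_span` and
#'   `stationary` logical masks over all frames, `valid` mask (in-span,
#'   non-stationary, non-missing), `n_valid`, and `direction` (+1, -1, or
#'   `NA` when undeterminable).
#' @export
segment_trial <- function(table, geom, label, stationary = NULL,
                          direction_label = "back") {
  stopifnot(inherits(table, "tracking_table"),
            inherits(geom, "beam_geometry"))
  d <- table$data[[label]]
  if (is.null(d)) stop("label '", label, "' not present")
  if (is.null(stationary)) stationary <- stationary_mask(table)
  lo <- min(geom$start_x, geom$stop_x)
  hi <- max(geom$start_x, geom$stop_x)
  in_span <- !d$missing & d$x >= lo & d$x <= hi
  valid <- in_span & !stationary
  n_valid <- sum(valid)
  direction <- NA_integer_
  db <- table$data[[direction_label]]
  if (!is.null(db)) {
    idx <- which(in_span & !db$missing)
    if (length(idx) >= 2) {
      dx <- diff(db$x[idx]) / diff(idx)
      med <- median(dx)
      if (is.finite(med) && med != 0) direction <- as.integer(sign(med))
    }
  }
  if (n_valid == 0)
    warning("empty trial for label '", label,
            "': no in-span, non-stationary frames")
  structure(list(label = label,
                 frames_in_span = which(in_span),
                 in_span = in_span,
                 stationary = stationary,
                 valid = valid,
                 n_valid = n_valid,
                 direction = direction),
            class = "trial_segment")
}

#' Trial timing metrics for one label
#'
#' Trial length is the number of valid frames of the analyzed label within
#' the marking span (stationary frames excluded from both numerator and
#' denominator), converted to seconds with the frame rate. The time below
#' the beam is the share of those frames in which the label's beam-relative
#' position is negative.
#'
#' @param segment A [segment_trial()] result.
#' @param positions Per-frame beam-relative positions of the same label
#'   (from [label_positions()]), aligned with the full frame index.
#' @param fps Frame rate (frames/second).
#' @return A list with `trial_length_frames`, `trial_length_s`,
#'   `below_beam_frames`, `below_beam_fraction` and `empty` (TRUE when the
#'   segment has no valid frames; the other fields are then 0/`NA`).
#' @export
trial_metrics <- function(segment, positions, fps) {
  stopifnot(inherits(segment, "trial_segment"), fps > 0)
  use <- segment$valid & !is.na(positions)
  n <- sum(use)
  if (n == 0)
    return(list(trial_length_frames = 0L, trial_length_s = 0,
                below_beam_frames = 0L, below_beam_fraction = NA_real_,
                empty = TRUE))
  below <- sum(positions[use] < 0)
  list(trial_length_frames = n,
       trial_length_s = n / fps,
       below_beam_frames = below,
       below_beam_fraction = below / n,
       empty = FALSE)
}
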