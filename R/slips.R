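#' Classify a below-beam excursion depth as none, minor or major
#'
#' Depth is the positive distance below the beam top in percent of beam
#' height (0 for points on or above the beam). For the hindpaw (thresholds
#' 20/50), extrema between 20 and 50 percent are minor slips and anything
#' deeper than 50 percent is major; the forepaw uses 10/30. The boundary at
#' `major_lo` is classified minor (inclusive upper bound) so the partition
#' is exhaustive and disjoint.
#'
#' @param depth Numeric vector of excursion depths in percent (>= 0).
#' @param thr A [slip_thresholds()] object.
#' @return Character vector with values `"none"`, `"minor"`, `"major"`.
#' @export
#' @examples
#' classify_depth(c(10, 30, 50, 60), slip_thresholds(20, 50))
classify_depth <- function(depth, thr = slip_thresholds()) {
  stopifnot(inherits(thr, "slip_thresholds"))
  if (any(depth < 0, na.rm = TRUE))
    stop("depth must be non-negative (percent below the beam)")
  out <- ifelse(depth > thr$major_lo, "major",
                ifelse(depth >= thr$minor_lo, "minor", "none"))
  out
}

empty_events <- function() {
  data.frame(klass = character(0), start_frame = integer(0),
             end_frame = integer(0), extremum_depth = numeric(0),
             extremum_frame = integer(0))
}

## Valleys of the paw trajectory = local maxima of the depth trace within a
## +/- floor(valley_window/2)-frame window; ties resolved to the earliest
## frame of a plateau; valleys closer than valley_window frames are merged,
## keeping the deeper one (the later of an equal pair is dropped).
find_valleys <- function(f, d, below, valley_window) {
  half <- valley_window %/% 2
  n <- length(f)
  is_valley <- logical(n)
  for (i in seq_len(n)) {
    if (!below[i]) next
    js <- which(abs(f - f[i]) <= half & seq_len(n) != i)
    is_valley[i] <- all(d[i] >= d[js]) && all(d[i] > d[js[f[js] < f[i]]])
  }
  v <- which(is_valley)
  repeat {
    if (length(v) < 2) break
    gaps <- diff(f[v])
    k <- which(gaps < valley_window)
    if (!length(k)) break
    k <- k[1]
    drop <- if (d[v[k]] < d[v[k + 1]]) k else k + 1
    v <- v[-drop]
  }
  v
}

#' Detect and classify slip events in a below-beam depth trace
#'
#' Takes the per-frame excursion depth of one paw on a trial segment
#' (stationary and missing frames already excluded, so the frame index may
#' have holes) and returns discrete slip events. The procedure:
#'
#' 1. Below-threshold runs: maximal stretches of entries with depth at or
#'    beyond the minor threshold. A run tolerates interruptions of fewer
#'    than `min_separation_frames` above-threshold entries, but is always
#'    terminated by an absent-frame gap longer than `max_gap_frames` (frames
#'    lost to occlusion or stationarity cannot bridge events). A run only
#'    yields events if it contains at least `min_duration_frames`
#'    frame-consecutive below-threshold entries.
#' 2. Valleys: local depth maxima within a `valley_window`-frame window;
#'    valleys closer than `valley_window` frames are merged (deeper wins).
#' 3. Splitting: adjacent valleys between which the paw rebounds by at
#'    least `split_prominence_pct` percentage points (lower valley depth
#'    minus the intervening minimum) delimit separate events; the split is
#'    placed at the first intervening minimum.
#'
#' Each event is classified by its extremum depth via [classify_depth()];
#' a major event is not additionally counted as minor. Events are disjoint
#' in frames.
#'
#' @param frames Strictly increasing integer frame indices of the retained
#'   samples.
#' @param depth Non-negative depths (percent of beam height below the beam
#'   top) at those frames.
#' @param thr A [slip_thresholds()] object.
#' @param params An [event_params()] object.
#' @param max_gap_frames Largest absent-frame gap an event may span
#'   (default 10, matching the conditioning gap limit).
#' @return A data frame with one row per event: `klass` ("minor"/"major"),
#'   `start_frame`, `end_frame`, `extremum_depth`, `extremum_frame`.
#' @seealso [slip_events_bruteforce()] for a straightforward loop-based
#'   re-derivation of the same definition, used for validation.
#' @export
#' @examples
#' f <- 1:12
#' d <- c(0, 0, 25, 40, 60, 58, 30, 0, 0, 0, 0, 0)
#' detect_slip_events(f, d, slip_thresholds(20, 50))
detect_slip_events <- function(frames, depth, thr = slip_thresholds(),
                               params = event_params(),
                               max_gap_frames = 10) {
  stopifnot(inherits(thr, "slip_thresholds"),
            inherits(params, "event_params"),
            length(frames) == length(depth))
  if (!length(frames)) return(empty_events())
  if (any(diff(frames) <= 0)) stop("frames must be strictly increasing")
  if (any(depth < 0)) stop("depths must be non-negative")
  f <- as.integer(frames); d <- as.numeric(depth)
  n <- length(f)
  below <- d >= thr$minor_lo
  if (!any(below)) return(empty_events())
  hard_break <- c(FALSE, diff(f) - 1 > max_gap_frames)  # before entry i

  ## blocks of consecutive below entries not crossing a hard break
  grp <- cumsum(c(TRUE, diff(below) != 0 | hard_break[-1]))
  blocks <- list()
  for (g in unique(grp[below])) {
    idx <- which(grp == g & below)
    if (length(idx)) blocks[[length(blocks) + 1]] <- range(idx)
  }
  if (!length(blocks)) return(empty_events())

  ## merge adjacent blocks across short, gap-free separations
  runs <- list(blocks[[1]])
  if (length(blocks) > 1) {
    for (b in blocks[-1]) {
      prev <- runs[[length(runs)]]
      between <- if (b[1] - 1 >= prev[2] + 1) (prev[2] + 1):(b[1] - 1)
                 else integer(0)
      n_above <- sum(!below[between])
      crosses_gap <- any(hard_break[(prev[2] + 1):b[1]])
      if (n_above < params$min_separation_frames && !crosses_gap)
        runs[[length(runs)]] <- c(prev[1], b[2])
      else
        runs[[length(runs) + 1]] <- b
    }
  }

  events <- list()
  for (r in runs) {
    idx <- r[1]:r[2]
    ## qualification: >= min_duration frame-consecutive below entries
    bi <- idx[below[idx]]
    new_stretch <- c(TRUE, !(diff(f[bi]) == 1 & diff(bi) == 1))
    longest <- max(tabulate(cumsum(new_stretch)))
    if (longest < params$min_duration_frames) next
    v <- find_valleys(f[idx], d[idx], below[idx], params$valley_window)
    splits <- integer(0)
    if (length(v) >= 2) {
      for (k in seq_len(length(v) - 1)) {
        mid <- seq(v[k] + 1, v[k + 1] - 1)
        if (!length(mid)) next
        m <- min(d[idx][mid])
        if (min(d[idx][v[k]], d[idx][v[k + 1]]) - m >=
              params$split_prominence_pct)
          splits <- c(splits, mid[which.min(d[idx][mid])])
      }
    }
    bounds <- c(0, splits, length(idx))
    for (k in seq_len(length(bounds) - 1)) {
      part <- idx[(bounds[k] + 1):bounds[k + 1]]
      pb <- part[below[part]]
      if (!length(pb)) next
      ext <- part[which.max(d[part])]
      events[[length(events) + 1]] <- data.frame(
        klass = classify_depth(d[ext], thr),
        start_frame = f[pb[1]],
        end_frame = f[pb[length(pb)]],
        extremum_depth = d[ext],
        extremum_frame = f[ext])
    }
  }
  if (!length(events)) return(empty_events())
  do.call(rbind, events)
}

#' Brute-force reference slip detection
#'
#' A deliberately naive, loop-based re-derivation of the slip-event
#' definition of [detect_slip_events()], written directly from the rules
#' (walk the trace entry by entry, assemble runs, scan every window for
#' valleys, test every adjacent valley pair for a rebound). It shares no
#' code with the production path and exists purely as an independent check:
#' the two implementations must agree on any input.
#'
#' @inheritParams detect_slip_events
#' @return Same shape as [detect_slip_events()].
#' @export
slip_events_bruteforce <- function(frames, depth, thr = slip_thresholds(),
                                   params = event_params(),
                                   max_gap_frames = 10) {
  f <- as.integer(frames); d <- as.numeric(depth)
  n <- length(f)
  out <- empty_events()
  if (n == 0) return(out)
  below <- d >= thr$minor_lo

  ## walk the series, growing one run at a time
  runs <- list()
  i <- 1
  while (i <= n) {
    if (!below[i]) { i <- i + 1; next }
    start <- i
    end <- i
    j <- i + 1
    pending_above <- 0
    while (j <= n) {
      if (f[j] - f[j - 1] - 1 > max_gap_frames) break
      if (below[j]) {
        end <- j
        pending_above <- 0
      } else {
        pending_above <- pending_above + 1
        if (pending_above >= params$min_separation_frames) break
      }
      j <- j + 1
    }
    runs[[length(runs) + 1]] <- c(start, end)
    i <- end + 1
    while (i <= n && !below[i]) i <- i + 1
  }

  half <- params$valley_window %/% 2
  for (r in runs) {
    span <- r[1]:r[2]
    ## qualification: a stretch of min_duration below entries at adjacent frames
    best <- 0; cur <- 0
    for (k in span) {
      if (below[k] && (cur == 0 || (f[k] - f[k - 1] == 1 && below[k - 1])))
        cur <- cur + 1
      else cur <- if (below[k]) 1 else 0
      best <- max(best, cur)
    }
    if (best < params$min_duration_frames) next

    ## valleys: window maxima, earliest frame of a plateau
    valleys <- c()
    for (k in span) {
      if (!below[k]) next
      ok <- TRUE
      for (j in span) {
        if (j == k || abs(f[j] - f[k]) > half) next
        if (d[j] > d[k] || (d[j] == d[k] && f[j] < f[k])) { ok <- FALSE; break }
      }
      if (ok) valleys <- c(valleys, k)
    }
    ## merge valleys closer than valley_window frames (deeper wins)
    repeat {
      merged <- FALSE
      if (length(valleys) >= 2) {
        for (k in seq_len(length(valleys) - 1)) {
          if (f[valleys[k + 1]] - f[valleys[k]] < params$valley_window) {
            keep <- if (d[valleys[k]] >= d[valleys[k + 1]]) k else k + 1
            valleys <- valleys[-(if (keep == k) k + 1 else k)]
            merged <- TRUE
            break
          }
        }
      }
      if (!merged) break
    }

    ## rebounds between adjacent valleys
    cuts <- c()
    if (length(valleys) >= 2) {
      for (k in seq_len(length(valleys) - 1)) {
        lo <- valleys[k] + 1; hi <- valleys[k + 1] - 1
        if (lo > hi) next
        m_idx <- lo
        for (j in lo:hi) if (d[j] < d[m_idx]) m_idx <- j
        if (min(d[valleys[k]], d[valleys[k + 1]]) - d[m_idx] >=
              params$split_prominence_pct)
          cuts <- c(cuts, m_idx)
      }
    }

    pieces <- list()
    lo <- r[1]
    for (cut in cuts) { pieces[[length(pieces) + 1]] <- lo:cut; lo <- cut + 1 }
    pieces[[length(pieces) + 1]] <- lo:r[2]
    for (p in pieces) {
      pb <- p[below[p]]
      if (!length(pb)) next
      ext <- p[1]
      for (j in p) if (d[j] > d[ext]) ext <- j
      out <- rbind(out, data.frame(
        klass = classify_depth(d[ext], thr),
        start_frame = f[min(pb)], end_frame = f[max(pb)],
        extremum_depth = d[ext], extremum_frame = f[ext]))
    }
  }
  out
}

#' Tally slip events of one trial
#'
#' @param events Event table from [detect_slip_events()].
#' @return List with `n_minor` and `n_major` counts.
#' @export
count_slips <- function(events) {
  list(n_minor = sum(events$klass == "minor"),
       n_major = sum(events$klass == "major"))
}

#' Agreement rate between automated and manual slip counts
#'
#' Fraction of trials on which the automated count is within `tolerance`
#' of the manual count. The published validation convention is a tolerance
#' of one slip per trial; an overall rate pools minor and major counts.
#'
#' @param auto,manual Equal-length numeric vectors of per-trial counts.
#' @param tolerance Maximum absolute difference that still counts as
#'   agreement (default 1).
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' agreement_rate(c(5, 3), c(6, 5))  # 0.5
agreement_rate <- function(auto, manual, tolerance = 1) {
  if (length(auto) != length(manual))
    stop("auto and manual count vectors must have equal length")
  if (!length(auto)) stop("empty count vectors")
  mean(abs(auto - manual) <= tolerance)
}
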