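## Rename file bodypart labels to the canonical names used by the pipeline.
canonicalize_labels <- function(table, config) {
  map <- config$labels  # canonical -> file label
  out <- table
  data <- list()
  for (canon in names(map)) {
    if (!is.null(table$data[[map[[canon]]]]))
      data[[canon]] <- table$data[[map[[canon]]]]
  }
  if (!length(data))
    stop("none of the configured labels are present in the tracking table")
  out$data <- data
  out
}

#' Analyze one beam-crossing trial
#'
#' Runs the full per-trial pipeline: conditioning, beam-geometry fit,
#' stationarity exclusion, per-label trial segmentation, beam-relative
#' positions, slip detection on the left hindpaw and forepaw, tail-base
#' angle, body area and trial timing metrics.
#'
#' @param table A [tracking_table()] (raw; conditioning is applied here
#'   unless `condition = FALSE`).
#' @param config A [bas_config()].
#' @param geometry Optional precomputed [fit_beam_geometry()] result;
#'   fitted from the conditioned table when `NULL`.
#' @param condition Apply [condition_tracks()] first (default `TRUE`).
#' @return An object of class `beamwalk_trial`: list with `measures`
#'   (named numeric vector: slip counts, mean positions, tail angle, body
#'   area, trial length, below-beam fraction), `events` (per-paw event
#'   tables), `metrics` (per-label timing metrics), `n_valid` (per-label
#'   valid frame counts), `direction`, `qc` (per-label missing fractions),
#'   `frame_values` (per-label valid-frame positions, for pooled density
#'   estimates), `geometry` and `empty`.
#' @export
analyze_trial <- function(table, config = bas_config(), geometry = NULL,
                          condition = TRUE) {
  stopifnot(inherits(table, "tracking_table"), inherits(config, "bas_config"))
  tab <- canonicalize_labels(table, config)
  if (condition) tab <- condition_tracks(tab, config$conditioning)
  if (is.null(geometry))
    geometry <- fit_beam_geometry(tab, config$beam_height_cm,
                                  config$marking_span_cm)
  still <- stationary_mask(tab, config$stationary_threshold_px,
                           config$stationary_labels)
  qc <- vapply(tab$data, function(d) mean(d$missing), numeric(1))

  measures <- c()
  metrics <- list()
  n_valid <- c()
  frame_values <- list()
  events <- list()
  direction <- NA_integer_

  for (lab in intersect(config$position_labels, names(tab$data))) {
    seg <- suppressWarnings(segment_trial(tab, geometry, lab,
                                          stationary = still))
    pos <- label_positions(tab, geometry, lab)
    use <- seg$valid & !is.na(pos)
    measures[paste0("pos_", lab)] <-
      if (any(use)) mean(pos[use]) else NA_real_
    metrics[[lab]] <- trial_metrics(seg, pos, config$fps)
    n_valid[lab] <- sum(use)
    if (lab %in% config$density_labels)
      frame_values[[lab]] <- pos[use]
    if (lab == "back" || is.na(direction))
      direction <- seg$direction

    if (lab %in% names(config$thresholds)) {
      thr <- config$thresholds[[lab]]
      idx <- which(use)
      depth <- pmax(0, -pos[idx])
      ev <- detect_slip_events(idx, depth, thr, config$events,
                               config$conditioning$max_gap_frames)
      events[[lab]] <- ev
      cnt <- count_slips(ev)
      short <- if (grepl("hind", lab)) "hind" else "fore"
      measures[paste0("minor_", short)] <- cnt$n_minor
      measures[paste0("major_", short)] <- cnt$n_major
      measures[paste0("below_frac_", short)] <-
        metrics[[lab]]$below_beam_fraction
    }
  }

  ## trial length reported for the left hindpaw (the primary analyzed label)
  if (!is.null(metrics$left_hindpaw)) {
    measures["trial_length_s"] <- metrics$left_hindpaw$trial_length_s
  }

  ## tail-base angle with tail-center fallback
  if (all(c("nose", "tail_base") %in% names(tab$data)) &&
      any(c("tail_tip", "tail_center") %in% names(tab$data))) {
    blank <- data.frame(x = rep(NA_real_, tab$n_frames), y = NA_real_,
                        missing = TRUE)
    ang <- tail_base_angle(tab$data$nose, tab$data$tail_base,
                           if (is.null(tab$data$tail_tip)) blank
                           else tab$data$tail_tip,
                           if (is.null(tab$data$tail_center)) blank
                           else tab$data$tail_center)
    seg_tb <- suppressWarnings(segment_trial(tab, geometry, "tail_base",
                                             stationary = still))
    use <- seg_tb$valid & !is.na(ang$theta)
    measures["tail_angle"] <-
      if (any(use)) mean(ang$theta[use]) else NA_real_
    measures["tail_angle_fallback_frac"] <-
      if (any(use)) mean(ang$used_fallback[use]) else NA_real_
    frame_values[["tail_angle"]] <- ang$theta[use]
  }

  ## body area gated on the back label's trial span
  if (all(c("nose", "back", "tail_base", "belly") %in% names(tab$data))) {
    area <- body_area(tab$data$nose, tab$data$back, tab$data$tail_base,
                      tab$data$belly, geometry$px_per_cm)
    seg_bk <- suppressWarnings(segment_trial(tab, geometry, "back",
                                             stationary = still))
    use <- seg_bk$valid & !is.na(area)
    measures["body_area_cm2"] <-
      if (any(use)) mean(area[use]) else NA_real_
  }

  empty <- is.null(metrics$left_hindpaw) || metrics$left_hindpaw$empty
  structure(list(measures = measures, events = events, metrics = metrics,
                 n_valid = n_valid, direction = direction, qc = qc,
                 frame_values = frame_values, geometry = geometry,
                 empty = empty),
            class = "beamwalk_trial")
}

#' @export
print.beamwalk_trial <- function(x, ...) {
  cat("<beamwalk_trial>\n")
  tl <- if ("trial_length_s" %in% names(x$measures))
    x$measures[["trial_length_s"]] else NA_real_
  cat(sprintf("  direction: %s, trial length %.2f s%s\n",
              if (is.na(x$direction)) "?" else
                if (x$direction > 0) "left-to-right" else "right-to-left",
              tl, if (x$empty) " [EMPTY]" else ""))
  for (lab in names(x$events)) {
    ev <- x$events[[lab]]
    cat(sprintf("  %s: %d minor, %d major slip(s)\n", lab,
                sum(ev$klass == "minor"), sum(ev$klass == "major")))
  }
  keep <- grep("^pos_|^tail_angle$|^body_area", names(x$measures),
               value = TRUE)
  for (m in keep)
    cat(sprintf("  %s: %.2f\n", m, x$measures[[m]]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Analyze a cohort of trials
#'
#' Applies [analyze_trial()] to every trial, assembles the per-trial
#' measure table, aggregates per-mouse means, runs all pairwise group
#' comparisons (Mann-Whitney U + Holm, per measure and age group), and
#' pools valid frames per group for density estimates.
#'
#' @param trials Either the result of [generate_cohort()] or a list of
#'   per-trial lists with elements `table`, `mouse_id`, `group`,
#'   `age_group`, `trial_id`.
#' @param config A [bas_config()].
#' @param measures Measure columns compared across groups; default the
#'   slip counts and mean positions present in the results.
#' @param density_measures Frame-level measures pooled for group densities
#'   (default the configured density labels plus the tail angle).
#' @return Object of class `beamwalk_cohort`: list with `trial_results`,
#'   `summaries`, `comparisons`, `densities` (nested list age > measure >
#'   group of [density_estimate()] objects), `qc` and `config`.
#' @export
analyze_cohort <- function(trials, config = bas_config(), measures = NULL,
                           density_measures = NULL) {
  if (!is.null(trials$trials)) trials <- trials$trials
  stopifnot(length(trials) >= 1)
  rows <- list()
  pooled <- list()
  results <- list()
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    res <- analyze_trial(tr$table, config)
    results[[i]] <- res
    row <- data.frame(mouse_id = tr$mouse_id, group = tr$group,
                      age_group = tr$age_group %||% "all",
                      trial_id = tr$trial_id, stringsAsFactors = FALSE)
    for (m in names(res$measures)) row[[m]] <- res$measures[[m]]
    row$n_valid_hind <- res$n_valid[["left_hindpaw"]] %||% 0L
    row$direction <- res$direction
    row$empty <- res$empty
    rows[[i]] <- row
    for (fv in names(res$frame_values)) {
      key <- paste(row$age_group, fv, tr$group, sep = "\r")
      pooled[[key]] <- c(pooled[[key]], res$frame_values[[fv]])
    }
  }
  all_cols <- unique(unlist(lapply(rows, names)))
  trial_results <- do.call(rbind, lapply(rows, function(r) {
    add <- setdiff(all_cols, names(r))
    for (col in add) r[[col]] <- NA
    r[all_cols]
  }))
  summaries <- mouse_means(trial_results)
  if (is.null(measures))
    measures <- intersect(c("minor_hind", "major_hind", "minor_fore",
                            "major_fore", "pos_nose", "pos_belly",
                            "pos_back", "pos_tail_base", "pos_tail_center",
                            "pos_tail_tip", "pos_left_hindpaw",
                            "pos_left_forepaw", "tail_angle",
                            "body_area_cm2"),
                          names(summaries))
  comparisons <- compare_groups(summaries, measures)
  densities <- list()
  for (key in names(pooled)) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    vals <- pooled[[key]]
    if (length(vals) >= 2)
      densities[[parts[1]]][[parts[2]]][[parts[3]]] <- density_estimate(vals)
  }
  qc <- do.call(rbind, lapply(seq_along(results), function(i) {
    data.frame(mouse_id = trials[[i]]$mouse_id,
               trial_id = trials[[i]]$trial_id,
               n_valid_hind = results[[i]]$n_valid[["left_hindpaw"]] %||% 0L,
               direction = results[[i]]$direction,
               frac_missing_max = max(results[[i]]$qc),
               empty = results[[i]]$empty, stringsAsFactors = FALSE)
  }))
  structure(list(trial_results = trial_results, summaries = summaries,
                 comparisons = comparisons, densities = densities, qc = qc,
                 config = config),
            class = "beamwalk_cohort")
}

#' @export
print.beamwalk_cohort <- function(x, ...) {
  cat(sprintf("<beamwalk_cohort> %d trials, %d mice, %d group(s)\n",
              nrow(x$trial_results), nrow(x$summaries),
              length(unique(x$summaries$group))))
  sig <- x$comparisons[x$comparisons$p_adj < 0.05, , drop = FALSE]
  cat(sprintf("  %d comparison(s), %d significant at adjusted p < 0.05\n",
              nrow(x$comparisons), nrow(sig)))
  invisible(x)
}

#' @export
summary.beamwalk_cohort <- function(object, ...) {
  print(object)
  cat("\nPer-group mean of per-mouse means:\n")
  num <- names(object$summaries)[vapply(object$summaries, is.numeric,
                                        logical(1))]
  num <- setdiff(num, c("trial_id", "n_trials"))
  agg <- aggregate(object$summaries[num],
                   by = list(group = object$summaries$group), mean,
                   na.rm = TRUE)
  print(agg, digits = 3)
  if (nrow(object$comparisons)) {
    cat("\nGroup comparisons (Mann-Whitney U, Holm-adjusted):\n")
    print(object$comparisons, digits = 3)
  }
  invisible(object)
}

#' @export
plot.beamwalk_cohort <- function(x, measure = "major_hind",
                                 age = NULL, ...) {
  s <- x$summaries
  if (!is.null(age)) s <- s[s$age_group == age, , drop = FALSE]
  boxplot(s[[measure]] ~ s$group, xlab = "group", ylab = measure, ...)
  stripchart(s[[measure]] ~ s$group, vertical = TRUE, add = TRUE,
             pch = 19, method = "jitter",
             col = adjustcolor("steelblue", 0.7))
  invisible(x)
}

#' Write cohort result tables to a directory
#'
#' Writes `trial_results.csv`, `mouse_summaries.csv`,
#' `group_comparisons.csv`, `densities.csv` (long format: age_group,
#' measure, group, grid, density), `qc_log.csv` and a resolved
#' configuration snapshot `config.yaml`. Output is deterministic: running
#' twice on the same inputs produces byte-identical files.
#'
#' @param cohort An [analyze_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written file paths.
#' @export
write_cohort_outputs <- function(cohort, dir) {
  stopifnot(inherits(cohort, "beamwalk_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  wr <- function(df, name) {
    p <- file.path(dir, name)
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(cohort$trial_results, "trial_results.csv")
  wr(cohort$summaries, "mouse_summaries.csv")
  wr(cohort$comparisons, "group_comparisons.csv")
  dens <- list()
  for (age in names(cohort$densities))
    for (meas in names(cohort$densities[[age]]))
      for (g in names(cohort$densities[[age]][[meas]])) {
        d <- cohort$densities[[age]][[meas]][[g]]
        dens[[length(dens) + 1]] <- data.frame(
          age_group = age, measure = meas, group = g,
          grid = d$grid, density = d$density)
      }
  wr(if (length(dens)) do.call(rbind, dens) else
       data.frame(age_group = character(0), measure = character(0),
                  group = character(0), grid = numeric(0),
                  density = numeric(0)),
     "densities.csv")
  wr(cohort$qc, "qc_log.csv")
  cfgpath <- file.path(dir, "config.yaml")
  yaml::write_yaml(config_to_list(cohort$config), cfgpath)
  paths <- c(paths, cfgpath)
  invisible(paths)
}

config_to_list <- function(config) {
  list(conditioning = unclass(config$conditioning),
       beam_height_cm = config$beam_height_cm,
       marking_span_cm = config$marking_span_cm,
       stationary_threshold_px = config$stationary_threshold_px,
       stationary_labels = config$stationary_labels,
       thresholds = lapply(config$thresholds, unclass),
       events = unclass(config$events),
       fps = config$fps,
       labels = as.list(config$labels))
}

config_from_list <- function(lst) {
  args <- list()
  if (!is.null(lst$conditioning))
    args$conditioning <- do.call(conditioning_params, lst$conditioning)
  if (!is.null(lst$thresholds))
    args$thresholds <- lapply(lst$thresholds,
                              function(t) do.call(slip_thresholds, t))
  if (!is.null(lst$events)) args$events <- do.call(event_params, lst$events)
  for (f in c("beam_height_cm", "marking_span_cm",
              "stationary_threshold_px", "stationary_labels", "fps"))
    if (!is.null(lst[[f]])) args[[f]] <- lst[[f]]
  if (!is.null(lst$labels)) args$labels <- unlist(lst$labels)
  do.call(bas_config, args)
}

#' Run the full pipeline over a manifest of tracking files
#'
#' Manifest-driven batch analysis: reads every tracking CSV listed in the
#' manifest, analyzes it, and writes all result tables plus a per-trial QC
#' log and a resolved configuration snapshot. Unreadable or failing trials
#' are skipped with a logged reason; the run fails only when no trial is
#' usable.
#'
#' @param manifest Either a data frame or a CSV path with columns `file`,
#'   `mouse_id`, `group`, `age_group`, `trial_id`.
#' @param data_dir Directory the manifest's `file` column is relative to
#'   (default the manifest's own directory, or `"."` for a data frame).
#' @param output_dir Directory for the result tables; skipped when `NULL`.
#' @param config A [bas_config()], or a YAML file path with the
#'   corresponding parameter blocks.
#' @return The [analyze_cohort()] result, invisibly. The QC log gains a
#'   `skipped` note for every unreadable trial.
#' @export
run_pipeline <- function(manifest, data_dir = NULL, output_dir = NULL,
                         config = bas_config()) {
  if (is.character(config)) config <- config_from_list(yaml::read_yaml(config))
  if (is.character(manifest)) {
    if (is.null(data_dir)) data_dir <- dirname(manifest)
    manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  }
  if (is.null(data_dir)) data_dir <- "."
  need <- c("file", "mouse_id", "group", "trial_id")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (is.null(manifest$age_group)) manifest$age_group <- "all"
  trials <- list()
  skipped <- list()
  for (i in seq_len(nrow(manifest))) {
    path <- file.path(data_dir, manifest$file[i])
    tab <- tryCatch(read_dlc_csv(path, fps = config$fps),
                    error = function(e) e)
    if (inherits(tab, "error")) {
      skipped[[length(skipped) + 1]] <- data.frame(
        file = manifest$file[i], reason = conditionMessage(tab))
      message("skipping ", manifest$file[i], ": ", conditionMessage(tab))
      next
    }
    trials[[length(trials) + 1]] <- list(
      table = tab, mouse_id = manifest$mouse_id[i],
      group = manifest$group[i], age_group = manifest$age_group[i],
      trial_id = manifest$trial_id[i])
  }
  if (!length(trials))
    stop("no usable trials: every manifest entry failed to load")
  cohort <- analyze_cohort(trials, config)
  if (length(skipped))
    cohort$skipped <- do.call(rbind, skipped)
  if (!is.null(output_dir)) write_cohort_outputs(cohort, output_dir)
  invisible(cohort)
}

#' Score automated slip counts against manual annotation
#'
#' Joins a manual annotation table (per-trial minor/major counts from a
#' trained rater, or synthetic ground truth standing in for one) to the
#' automated results and reports per-class and overall agreement at the
#' standard +/-1-slip tolerance, the per-trial differences, and a
#' Mann-Whitney comparison of automated versus manual per-mouse mean
#' counts (a systematic-bias check; non-significance is the desired
#' outcome).
#'
#' @param cohort An [analyze_cohort()] result.
#' @param annotations Data frame (or CSV path) with columns `mouse_id`,
#'   `trial_id`, `n_minor`, `n_major`.
#' @param tolerance Count tolerance for agreement (default 1).
#' @return List with `agreement` (named rates: minor, major, overall),
#'   `differences` (per-trial table), `bias_test` (per-class Mann-Whitney
#'   results) and `unmatched` (annotation rows without a matching trial).
#' @export
validate_against_manual <- function(cohort, annotations, tolerance = 1) {
  stopifnot(inherits(cohort, "beamwalk_cohort"))
  if (is.character(annotations))
    annotations <- read.csv(annotations, stringsAsFactors = FALSE)
  need <- c("mouse_id", "trial_id", "n_minor", "n_major")
  if (!is.data.frame(annotations) || !nrow(annotations) ||
      !all(need %in% names(annotations)))
    stop("annotations must be a non-empty table with columns: ",
         paste(need, collapse = ", "))
  res <- cohort$trial_results
  key_auto <- paste(res$mouse_id, res$trial_id)
  key_man <- paste(annotations$mouse_id, annotations$trial_id)
  hit <- match(key_man, key_auto)
  unmatched <- annotations[is.na(hit), , drop = FALSE]
  annotations <- annotations[!is.na(hit), , drop = FALSE]
  hit <- hit[!is.na(hit)]
  if (!length(hit)) stop("no annotation rows match the analyzed trials")
  diffs <- data.frame(mouse_id = annotations$mouse_id,
                      trial_id = annotations$trial_id,
                      auto_minor = res$minor_hind[hit],
                      manual_minor = annotations$n_minor,
                      auto_major = res$major_hind[hit],
                      manual_major = annotations$n_major)
  diffs$d_minor <- diffs$auto_minor - diffs$manual_minor
  diffs$d_major <- diffs$auto_major - diffs$manual_major
  agree <- c(minor = agreement_rate(diffs$auto_minor, diffs$manual_minor,
                                    tolerance),
             major = agreement_rate(diffs$auto_major, diffs$manual_major,
                                    tolerance),
             overall = agreement_rate(c(diffs$auto_minor, diffs$auto_major),
                                      c(diffs$manual_minor,
                                        diffs$manual_major), tolerance))
  per_mouse <- function(v) tapply(v, diffs$mouse_id, mean)
  bias_test <- list(
    minor = mann_whitney_u(per_mouse(diffs$auto_minor),
                           per_mouse(diffs$manual_minor)),
    major = mann_whitney_u(per_mouse(diffs$auto_major),
                           per_mouse(diffs$manual_major)))
  list(agreement = agree, differences = diffs, bias_test = bias_test,
       unmatched = unmatched)
}
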