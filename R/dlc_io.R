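#' Construct a tracking table
#'
#' In-memory container for one trial video's pose-tracking output: for every
#' frame and label an x/y position (image coordinates, origin top-left, y
#' increasing downward), a likelihood in `[0, 1]` and a missing flag.
#' Downstream computations never use the coordinates of missing points.
#'
#' @param data Named list (one entry per label) of data frames with numeric
#'   columns `x`, `y`, `likelihood` and logical `missing`, all with one row
#'   per frame. A `missing` column is added (all `FALSE`) when absent.
#' @param fps Frame rate in frames/second (default 50).
#' @param frame_size Integer vector `c(width, height)` in pixels (default
#'   1920 x 1080).
#' @param scorer Scorer string carried through to written CSVs.
#' @return An object of class `tracking_table`.
#' @export
#' @examples
#' tt <- tracking_table(list(
#'   nose = data.frame(x = 1:3, y = c(5, 6, 7), likelihood = 1)))
#' tt
tracking_table <- function(data, fps = 50, frame_size = c(1920L, 1080L),
                           scorer = "beamwalkr") {
  if (!is.list(data) || is.null(names(data)) || any(names(data) == ""))
    stop("`data` must be a named list of per-label data frames")
  if (anyDuplicated(names(data)))
    stop("duplicate label name(s): ",
         paste(unique(names(data)[duplicated(names(data))]), collapse = ", "))
  n <- unique(vapply(data, nrow, integer(1)))
  if (length(n) != 1)
    stop("all labels must have the same number of frames")
  data <- lapply(data, function(d) {
    d <- as.data.frame(d)
    for (col in c("x", "y", "likelihood"))
      if (is.null(d[[col]]) || !is.numeric(d[[col]]))
        stop("each label needs numeric columns x, y, likelihood")
    if (any(d$likelihood < 0 | d$likelihood > 1, na.rm = TRUE))
      stop("likelihood values must lie in [0, 1]")
    if (is.null(d$missing)) d$missing <- FALSE
    d$missing <- d$missing | !is.finite(d$x) | !is.finite(d$y)
    d[c("x", "y", "likelihood", "missing")]
  })
  structure(list(data = data, n_frames = n, fps = fps,
                 frame_size = as.integer(frame_size), scorer = scorer),
            class = "tracking_table")
}

#' @export
print.tracking_table <- function(x, ...) {
  cat(sprintf("<tracking_table> %d frames @ %g fps, %d labels\n",
              x$n_frames, x$fps, length(x$data)))
  miss <- vapply(x$data, function(d) mean(d$missing), numeric(1))
  cat("  labels:", paste(names(x$data), collapse = ", "), "\n")
  if (any(miss > 0))
    cat(sprintf("  missing: %s\n",
                paste(sprintf("%s %.0f%%", names(miss)[miss > 0],
                              100 * miss[miss > 0]), collapse = ", ")))
  invisible(x)
}

#' @export
labels.tracking_table <- function(object, ...) names(object$data)

#' Number of frames of a tracking table
#' @param table A [tracking_table()].
#' @return Integer frame count.
#' @export
n_frames <- function(table) {
  stopifnot(inherits(table, "tracking_table"))
  table$n_frames
}

#' Read a DeepLabCut-format tracking CSV
#'
#' Parses the DLC CSV dialect: three header rows (`scorer`, `bodyparts`,
#' `coords`), a leading frame-index column, and per bodypart the three
#' columns `x`, `y`, `likelihood`. Values are read as-is; no conditioning is
#' applied (see [condition_tracks()]).
#'
#' @param path Path to the CSV file.
#' @param fps Frame rate to record on the table (frames/second, default 50).
#' @param frame_size Pixel size `c(width, height)` recorded on the table.
#' @return A [tracking_table()] with every label found in the file.
#' @export
read_dlc_csv <- function(path, fps = 50, frame_size = c(1920L, 1080L)) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, header = FALSE, colClasses = "character",
                  check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(raw) < 3)
    stop("malformed DLC header in ", basename(path),
         ": expected 3 header rows (scorer / bodyparts / coords)")
  h <- tolower(trimws(as.character(raw[1:3, 1])))
  expected <- c("scorer", "bodyparts", "coords")
  bad <- which(h != expected)
  if (length(bad))
    stop("malformed DLC header in ", basename(path), ": missing '",
         expected[bad[1]], "' header row (found '", h[bad[1]], "')")
  if (ncol(raw) < 4 || (ncol(raw) - 1) %% 3 != 0)
    stop("malformed DLC file: expected x/y/likelihood column triplets")
  scorer <- as.character(raw[1, 2])
  bodyparts <- as.character(unlist(raw[2, -1]))
  coords <- tolower(as.character(unlist(raw[3, -1])))
  body <- raw[-(1:3), , drop = FALSE]
  lab_of_triplet <- bodyparts[seq(1, length(bodyparts), by = 3)]
  if (anyDuplicated(lab_of_triplet))
    stop("duplicate bodypart label(s): ",
         paste(unique(lab_of_triplet[duplicated(lab_of_triplet)]),
               collapse = ", "))
  data <- list()
  for (k in seq_along(lab_of_triplet)) {
    cols <- 1 + (k - 1) * 3 + 1:3
    if (!identical(coords[(k - 1) * 3 + 1:3], c("x", "y", "likelihood")))
      stop("malformed coords header row for bodypart '", lab_of_triplet[k],
           "': expected x, y, likelihood")
    vals <- lapply(cols, function(j) {
      v <- suppressWarnings(as.numeric(body[[j]]))
      bad <- which(is.na(v) & !(trimws(body[[j]]) %in%
                                  c("", "NA", "NaN", "nan")))
      if (length(bad))
        stop("non-numeric cell at frame ", bad[1] - 1, " for label '",
             lab_of_triplet[k], "'")
      v
    })
    data[[lab_of_triplet[k]]] <-
      data.frame(x = vals[[1]], y = vals[[2]], likelihood = vals[[3]])
  }
  tracking_table(data, fps = fps, frame_size = frame_size, scorer = scorer)
}

#' Write a tracking table as a DeepLabCut-format CSV
#'
#' Emits the same three-header-row dialect that [read_dlc_csv()] reads, so
#' a write/read round trip reproduces the table. Missing points are written
#' with their stored coordinates (reading does not condition).
#'
#' @param table A [tracking_table()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_dlc_csv <- function(table, path) {
  stopifnot(inherits(table, "tracking_table"))
  labs <- names(table$data)
  header1 <- c("scorer", rep(table$scorer, 3 * length(labs)))
  header2 <- c("bodyparts", rep(labs, each = 3))
  header3 <- c("coords", rep(c("x", "y", "likelihood"), length(labs)))
  mat <- do.call(cbind, lapply(table$data, function(d)
    cbind(d$x, d$y, d$likelihood)))
  body <- cbind(seq_len(table$n_frames) - 1, mat)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(paste(header1, collapse = ","),
               paste(header2, collapse = ","),
               paste(header3, collapse = ",")), con)
  write.table(body, con, sep = ",", col.names = FALSE, row.names = FALSE,
              qmethod = "double")
  invisible(path)
}

## Conditioning of one label: likelihood gate, velocity gate, gap closing.
condition_label <- function(d, params) {
  n <- nrow(d)
  miss <- d$missing | d$likelihood < params$p_cutoff
  ## velocity gate relative to the previous surviving point
  last <- NA_integer_
  for (i in seq_len(n)) {
    if (miss[i]) next
    if (!is.na(last)) {
      disp <- sqrt((d$x[i] - d$x[last])^2 + (d$y[i] - d$y[last])^2)
      if (disp > params$max_jump_px * (i - last)) {
        miss[i] <- TRUE
        next
      }
    }
    last <- i
  }
  ## close short gaps by linear interpolation
  if (any(miss) && params$max_gap_frames > 0) {
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in seq_along(r$lengths)) {
      if (!r$values[k] || r$lengths[k] > params$max_gap_frames) next
      a <- starts[k] - 1; b <- ends[k] + 1
      if (a < 1 || b > n || miss[a] || miss[b]) next
      idx <- starts[k]:ends[k]
      w <- (idx - a) / (b - a)
      d$x[idx] <- d$x[a] + w * (d$x[b] - d$x[a])
      d$y[idx] <- d$y[a] + w * (d$y[b] - d$y[a])
      d$likelihood[idx] <- min(d$likelihood[a], d$likelihood[b])
      miss[idx] <- FALSE
    }
  }
  d$missing <- miss
  d
}

#' Condition tracked coordinates by likelihood and jump filtering
#'
#' Cleans every label of a tracking table independently, in three ordered
#' steps: (1) points with likelihood below `p_cutoff` are marked missing;
#' (2) points whose Euclidean displacement from the previous non-missing
#' point exceeds `max_jump_px` pixels per elapsed frame are marked missing
#' (a velocity gate against tracking jumps); (3) missing runs of at most
#' `max_gap_frames` frames with valid neighbors on both sides are replaced
#' by per-coordinate linear interpolation. Interpolated points are not
#' missing and carry the smaller of the two flanking likelihoods, so
#' downstream occlusion fallbacks (e.g. tail-tip to tail-center) still
#' trigger where tracking was weak.
#'
#' Conditioning is idempotent and never alters a point that passed both
#' filters and does not lie inside an interpolated gap. A fully missing
#' label is allowed.
#'
#' @param table A [tracking_table()].
#' @param params A [conditioning_params()] object.
#' @return A conditioned [tracking_table()].
#' @export
#' @examples
#' tt <- tracking_table(list(
#'   nose = data.frame(x = c(1, 2, 3), y = c(10, 13, 16),
#'                     likelihood = c(1, 0.1, 1))))
#' condition_tracks(tt, conditioning_params())$data$nose
condition_tracks <- function(table, params = conditioning_params()) {
  stopifnot(inherits(table, "tracking_table"),
            inherits(params, "conditioning_params"))
  table$data <- lapply(table$data, condition_label, params = params)
  table
}
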