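## Cache of exact rank-sum distributions, keyed by "n1,n2" (tie-free case
## depends only on the group sizes).
.rank_sum_cache <- new.env(parent = emptyenv())

## Number of size-n1 subsets of ranks 1..n1+n2 attaining each rank sum,
## by dynamic programming over ranks.
rank_sum_counts <- function(n1, n2) {
  key <- paste(n1, n2, sep = ",")
  if (!is.null(.rank_sum_cache[[key]])) return(.rank_sum_cache[[key]])
  n <- n1 + n2
  smax <- sum((n - n1 + 1):n)
  ## f[k+1, s+1] = number of k-subsets of ranks seen so far with sum s
  f <- matrix(0, nrow = n1 + 1, ncol = smax + 1)
  f[1, 1] <- 1
  for (r in seq_len(n)) {
    for (k in rev(seq_len(min(r, n1)))) {
      idx <- (r + 1):(smax + 1)
      f[k + 1, idx] <- f[k + 1, idx] + f[k, idx - r]
    }
  }
  counts <- f[n1 + 1, ]
  .rank_sum_cache[[key]] <- counts
  counts
}

#' Two-tailed Mann-Whitney U test
#'
#' Rank-based comparison of two independent samples. The statistic counts
#' pairs `(i, j)` with `a[i] < b[j]` plus half of the tied pairs, and the
#' reported `U` is the smaller of that count and its complement
#' `nA*nB - U`. The two-sided p-value is exact (full enumeration of rank
#' assignments via a rank-sum recursion) when `nA + nB <= 16` and the
#' pooled data are tie-free; otherwise the normal approximation with tie
#' and continuity correction is used.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @return A list with `U`, `p` (two-sided), `method` ("exact" or
#'   "normal"), `n1`, `n2`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
mann_whitney_u <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b))
    stop("both groups must contain at least one value")
  if (anyNA(a) || anyNA(b)) stop("missing values are not allowed")
  n1 <- length(a); n2 <- length(b); m <- n1 * n2
  u_less <- sum(outer(a, b, "<")) + 0.5 * sum(outer(a, b, "=="))
  u_stat <- min(u_less, m - u_less)
  ties <- anyDuplicated(c(a, b)) > 0
  if (n1 + n2 <= 16 && !ties) {
    counts <- rank_sum_counts(n1, n2)
    ## rank sum s of group a corresponds to W = s - n1(n1+1)/2 pairs a > b;
    ## by symmetry the distribution of pair counts is the same either way.
    w <- seq_along(counts) - 1 - n1 * (n1 + 1) / 2
    total <- sum(counts)
    p <- (sum(counts[w <= u_stat]) + sum(counts[w >= m - u_stat])) / total
    method <- "exact"
  } else {
    pooled <- c(a, b)
    t_sizes <- table(pooled)
    mu <- m / 2
    sigma2 <- (m / 12) *
      ((n1 + n2 + 1) - sum(t_sizes^3 - t_sizes) /
         ((n1 + n2) * (n1 + n2 - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- max(0, abs(u_less - mu) - 0.5) / sqrt(sigma2)
      p <- 2 * pnorm(-z)
    }
    method <- "normal"
  }
  list(U = u_stat, p = min(1, p), method = method, n1 = n1, n2 = n2)
}

#' Bonferroni-Holm step-down adjustment
#'
#' Sorts the raw p-values ascending, multiplies the k-th smallest by
#' `m - k + 1`, enforces monotonicity by a running maximum, caps at 1, and
#' returns the adjusted values in the original order.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))  # 0.03 0.06 0.06
holm_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Gaussian kernel density estimate on a fixed grid
#'
#' Silverman's rule-of-thumb bandwidth, evaluated on an equally spaced grid
#' spanning the data range plus three bandwidths on each side, and
#' renormalized so the trapezoid integral over the grid is exactly 1 (the
#' Gaussian tails beyond the grid carry a fraction of a percent of mass).
#' Used for the group-level probability distributions of body positions
#' and tail angles.
#'
#' @param values Numeric vector (at least 2 finite values).
#' @param grid_points Number of grid points (default 512).
#' @param bw Optional bandwidth override; default [stats::bw.nrd0()].
#' @return Object of class `density_curve`: list with `grid`, `density`,
#'   `bw`, `n`.
#' @export
density_estimate <- function(values, grid_points = 512, bw = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 2)
    stop("density estimation needs at least 2 finite values")
  if (is.null(bw)) bw <- bw.nrd0(values)
  lo <- min(values) - 3 * bw
  hi <- max(values) + 3 * bw
  dd <- density(values, bw = bw, from = lo, to = hi, n = grid_points)
  step <- diff(dd$x)
  integral <- sum((dd$y[-1] + dd$y[-length(dd$y)]) / 2 * step)
  structure(list(grid = dd$x, density = dd$y / integral, bw = bw,
                 n = length(values)),
            class = "density_curve")
}

#' @export
print.density_curve <- function(x, ...) {
  cat(sprintf(
    "<density_curve> n = %d, bw = %.4g, grid [%.4g, %.4g] (%d points)\n",
    x$n, x$bw, min(x$grid), max(x$grid), length(x$grid)))
  invisible(x)
}

#' @export
plot.density_curve <- function(x, ..., xlab = "value", ylab = "density") {
  graphics::plot(x$grid, x$density, type = "l", xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Per-mouse means over trials
#'
#' Aggregates a per-trial measure table to one row per mouse (per age
#' group), taking the arithmetic mean of every measure over that mouse's
#' non-empty trials. Trials flagged empty (no valid frames) are dropped
#' first; mice left with zero trials are excluded with a message.
#'
#' @param trials Data frame with one row per trial, identifier columns and
#'   numeric measure columns. An optional logical `empty` column flags
#'   trials to drop.
#' @param measures Character vector of measure columns to average; default
#'   all numeric non-identifier columns.
#' @param id_cols Identifier columns defining one mouse (default
#'   `mouse_id`, `group`, `age_group`, intersected with what is present).
#' @return Data frame with the identifier columns, per-measure means and
#'   `n_trials`.
#' @export
mouse_means <- function(trials, measures = NULL,
                        id_cols = c("mouse_id", "group", "age_group")) {
  stopifnot(is.data.frame(trials))
  id_cols <- intersect(id_cols, names(trials))
  if (!("mouse_id" %in% id_cols)) stop("trials must have a mouse_id column")
  if (!is.null(trials$empty)) trials <- trials[!trials$empty, , drop = FALSE]
  if (is.null(measures))
    measures <- setdiff(names(trials)[vapply(trials, is.numeric, logical(1))],
                        c(id_cols, "trial_id", "empty", "direction",
                          "n_valid_hind"))
  if (!nrow(trials)) stop("no non-empty trials to aggregate")
  key <- interaction(trials[id_cols], drop = TRUE)
  out <- unique(trials[id_cols])
  out <- out[match(levels(key), interaction(out[id_cols], drop = TRUE)), ,
             drop = FALSE]
  for (m in measures)
    out[[m]] <- as.numeric(tapply(trials[[m]], key,
                                  function(v) mean(v, na.rm = TRUE)))
  out$n_trials <- as.integer(tapply(trials$mouse_id, key, length))
  rownames(out) <- NULL
  out
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Pairwise group comparisons with Holm correction
#'
#' For every measure and age group, runs a two-tailed Mann-Whitney U test
#' ([mann_whitney_u()]) on the per-mouse means of every pair of groups.
#' The Holm correction family is the set of pairwise comparisons for one
#' measure at one age (e.g. three pairs for three groups), matching a
#' per-panel correction. Groups with fewer than two mice are skipped with
#' a warning.
#'
#' @param summaries Per-mouse summary table from [mouse_means()].
#' @param measures Character vector of measure columns to compare.
#' @param group_col,age_col Column names for group and age labels; a
#'   missing age column treats all mice as one age group.
#' @return Data frame with one row per comparison: `age_group`, `measure`,
#'   `group_a`, `group_b`, `n_a`, `n_b`, `median_a`, `median_b`, `U`,
#'   `p_raw`, `p_adj`, `stars`.
#' @export
compare_groups <- function(summaries, measures, group_col = "group",
                           age_col = "age_group") {
  stopifnot(is.data.frame(summaries), all(measures %in% names(summaries)),
            group_col %in% names(summaries))
  if (!(age_col %in% names(summaries))) {
    summaries[[age_col]] <- "all"
  }
  rows <- list()
  for (age in unique(summaries[[age_col]])) {
    sub <- summaries[summaries[[age_col]] == age, , drop = FALSE]
    groups <- unique(sub[[group_col]])
    sizes <- table(sub[[group_col]])
    small <- names(sizes)[sizes < 2]
    if (length(small)) {
      warning("group(s) with < 2 mice skipped: ",
              paste(small, collapse = ", "))
      groups <- setdiff(groups, small)
    }
    if (length(groups) < 2) next
    pairs <- combn(as.character(groups), 2)
    for (meas in measures) {
      fam <- list()
      for (k in seq_len(ncol(pairs))) {
        ga <- pairs[1, k]; gb <- pairs[2, k]
        va <- sub[[meas]][sub[[group_col]] == ga]
        vb <- sub[[meas]][sub[[group_col]] == gb]
        va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
        if (length(va) < 2 || length(vb) < 2) next
        tst <- mann_whitney_u(va, vb)
        fam[[length(fam) + 1]] <- data.frame(
          age_group = age, measure = meas, group_a = ga, group_b = gb,
          n_a = length(va), n_b = length(vb),
          median_a = median(va), median_b = median(vb),
          U = tst$U, p_raw = tst$p, stringsAsFactors = FALSE)
      }
      if (!length(fam)) next
      fam <- do.call(rbind, fam)
      fam$p_adj <- holm_adjust(fam$p_raw)
      fam$stars <- significance_stars(fam$p_adj)
      rows[[length(rows) + 1]] <- fam
    }
  }
  if (!length(rows))
    return(data.frame(age_group = character(0), measure = character(0),
                      group_a = character(0), group_b = character(0),
                      n_a = integer(0), n_b = integer(0),
                      median_a = numeric(0), median_b = numeric(0),
                      U = numeric(0), p_raw = numeric(0),
                      p_adj = numeric(0), stars = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
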