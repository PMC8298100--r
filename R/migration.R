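# 2D cell-migration track statistics.
#
# Tracks are tidy data frames of timestamped positions, one row per frame per
# cell: columns `cell_id`, optionally `experiment_id` and `condition`, and
# `t` (min), `x`, `y` (um). Single-track operations accept the rows of one
# cell; cohort operations split on `cell_id`. Lag-based statistics (MSD,
# direction autocorrelation) use overlapping (time-averaged) windows and
# skip pairs that span gaps in the sampling.

check_track <- function(track) {
  if (!is.data.frame(track) || !all(c("t", "x", "y") %in% names(track))) {
    stop("a track is a data frame with columns t, x, y", call. = FALSE)
  }
  if (nrow(track) < 2L) stop("a track needs >= 2 points", call. = FALSE)
  if (anyNA(track[c("t", "x", "y")])) stop("track contains NA", call. = FALSE)
  dt <- diff(track$t)
  if (any(dt == 0)) stop("duplicate timestamps in track", call. = FALSE)
  if (any(dt < 0)) stop("track timestamps must be strictly increasing", call. = FALSE)
  track
}

split_tracks <- function(tracks) {
  if (!"cell_id" %in% names(tracks)) return(list(track = tracks))
  split(tracks, tracks$cell_id)
}

step_lengths <- function(track) {
  sqrt(diff(track$x)^2 + diff(track$y)^2)
}

#' Instantaneous speed series of a track
#'
#' Per-step Euclidean displacement divided by the step duration.
#'
#' @param track One cell's track (data frame with `t`, `x`, `y`).
#' @return Data frame with `t` (end of step) and `speed` (um/min).
#' @export
instantaneous_speed <- function(track) {
  track <- check_track(track)
  data.frame(t = track$t[-1L], speed = step_lengths(track) / diff(track$t))
}

#' Cumulative path distance of a track
#'
#' Running sum of step lengths; starts at 0.
#'
#' @param track One cell's track.
#' @return Data frame with `t` and `distance` (um).
#' @export
cumulative_distance <- function(track) {
  track <- check_track(track)
  data.frame(t = track$t, distance = c(0, cumsum(step_lengths(track))))
}

#' Average speed of a track
#'
#' Total path length divided by total elapsed time.
#'
#' @param track One cell's track.
#' @return Scalar speed, um/min.
#' @export
average_speed <- function(track) {
  track <- check_track(track)
  elapsed <- track$t[nrow(track)] - track$t[1L]
  sum(step_lengths(track)) / elapsed
}

#' Directionality ratio series of a track
#'
#' At each time point, the straight-line distance from the start divided by
#' the cumulative path length; 1 for perfectly straight movement. Entries
#' before the first nonzero path are `NA`.
#'
#' @param track One cell's track.
#' @return Data frame with `t` and `ratio` in `[0, 1]` (or `NA`).
#' @export
directionality_ratio <- function(track) {
  track <- check_track(track)
  cd <- c(0, cumsum(step_lengths(track)))
  net <- sqrt((track$x - track$x[1L])^2 + (track$y - track$y[1L])^2)
  ratio <- ifelse(cd > 0, net / cd, NA_real_)
  data.frame(t = track$t, ratio = ratio)
}

# steps of a track restricted to the regular sampling interval; returns a
# data frame of step vectors with a `regular` flag for gap handling
track_steps <- function(track, tol = 1e-6) {
  dt <- diff(track$t)
  dt0 <- median(dt)
  data.frame(dx = diff(track$x), dy = diff(track$y), dt = dt,
             regular = abs(dt - dt0) <= tol * max(dt0, 1))
}

#' Time-averaged mean squared displacement
#'
#' Per track, the MSD at lag `k` steps is the mean over all overlapping pairs
#' of positions `k` frames apart (pairs spanning irregular sampling gaps are
#' excluded). The cohort curve is the mean and SEM across cells at each lag
#' time. Lags run up to `max_lag_fraction` of each track's length.
#'
#' @param tracks Tidy track table (one or many cells).
#' @param max_lag_fraction Largest lag as a fraction of track length.
#' @return Data frame with `lag` (min), `msd` (um^2), `sem`, `n_cells`.
#' @export
msd <- function(tracks, max_lag_fraction = 0.5) {
  per_track <- lapply(split_tracks(tracks), function(tr) {
    tr <- check_track(tr)
    n <- nrow(tr)
    dt0 <- median(diff(tr$t))
    kmax <- max(1L, floor(max_lag_fraction * (n - 1L)))
    ks <- seq_len(kmax)
    vals <- vapply(ks, function(k) {
      i <- seq_len(n - k)
      ok <- abs((tr$t[i + k] - tr$t[i]) - k * dt0) <= 1e-6 * max(dt0, 1)
      if (!any(ok)) return(NA_real_)
      mean((tr$x[i + k][ok] - tr$x[i][ok])^2 + (tr$y[i + k][ok] - tr$y[i][ok])^2)
    }, 0)
    data.frame(lag = ks * dt0, msd = vals)
  })
  pool_lag_curves(per_track, "msd")
}

#' Direction autocorrelation
#'
#' For lag `k`, the mean cosine of the angle between step unit vectors `i`
#' and `i + k`, over all overlapping pairs of regular, nonzero-length steps;
#' lag 0 is 1 by definition. Cohort mean and SEM across cells.
#'
#' @inheritParams msd
#' @return Data frame with `lag` (min), `dacf` in `[-1, 1]`, `sem`, `n_cells`.
#' @export
direction_autocorrelation <- function(tracks, max_lag_fraction = 0.5) {
  per_track <- lapply(split_tracks(tracks), function(tr) {
    tr <- check_track(tr)
    st <- track_steps(tr)
    len <- sqrt(st$dx^2 + st$dy^2)
    use <- st$regular & len > 0
    ux <- st$dx / len; uy <- st$dy / len
    n <- nrow(st)
    dt0 <- median(st$dt)
    kmax <- max(1L, floor(max_lag_fraction * n))
    ks <- 0:kmax
    vals <- vapply(ks, function(k) {
      if (k == 0L) return(1)
      i <- seq_len(n - k)
      ok <- use[i] & use[i + k]
      if (!any(ok)) return(NA_real_)
      mean(ux[i][ok] * ux[i + k][ok] + uy[i][ok] * uy[i + k][ok])
    }, 0)
    data.frame(lag = ks * dt0, dacf = vals)
  })
  pool_lag_curves(per_track, "dacf")
}

# cohort mean +- SEM of per-track lag curves
pool_lag_curves <- function(per_track, value) {
  all <- do.call(rbind, per_track)
  all <- all[is.finite(all[[value]]), , drop = FALSE]
  lags <- sort(unique(all$lag))
  out <- lapply(lags, function(l) {
    v <- all[[value]][all$lag == l]
    data.frame(lag = l, mean = mean(v),
               sem = if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_,
               n_cells = length(v))
  })
  out <- do.call(rbind, out)
  names(out)[names(out) == "mean"] <- value
  out
}

#' Turning angles of tracks
#'
#' Signed angle between consecutive step vectors, in `(-pi, pi]`;
#' zero-length steps are skipped. Positive angles are counterclockwise.
#'
#' @param tracks Tidy track table.
#' @return Numeric vector of angles in radians.
#' @export
turning_angles <- function(tracks) {
  out <- lapply(split_tracks(tracks), function(tr) {
    tr <- check_track(tr)
    if (nrow(tr) < 3L) return(numeric(0))
    st <- track_steps(tr)
    len <- sqrt(st$dx^2 + st$dy^2)
    keep <- len > 0
    dx <- st$dx[keep]; dy <- st$dy[keep]
    if (length(dx) < 2L) return(numeric(0))
    i <- seq_len(length(dx) - 1L)
    ang <- atan2(dx[i] * dy[i + 1L] - dy[i] * dx[i + 1L],
                 dx[i] * dx[i + 1L] + dy[i] * dy[i + 1L])
    # map -pi to +pi so angles lie in (-pi, pi]
    ang[ang == -pi] <- pi
    ang
  })
  unlist(out, use.names = FALSE)
}

#' Fastest time to traverse a path segment
#'
#' Minimum elapsed time over all windows of consecutive points whose
#' cumulative path length reaches `segment_length` (25 um by default).
#' Windows are whole-step windows without sub-step interpolation, so the
#' result is biased upward by at most one frame. Returns `NA` if the total
#' path is shorter than the segment.
#'
#' @param track One cell's track.
#' @param segment_length Segment length in um.
#' @return Minimum traversal time in minutes, or `NA`.
#' @export
fastest_segment_time <- function(track, segment_length = 25) {
  track <- check_track(track)
  check_number(segment_length, "segment_length", 0, strict = TRUE)
  cd <- c(0, cumsum(step_lengths(track)))
  n <- length(cd)
  if (cd[n] < segment_length) return(NA_real_)
  best <- Inf
  j <- 1L
  for (i in seq_len(n)) {
    if (j < i) j <- i
    while (j <= n && cd[j] - cd[i] < segment_length) j <- j + 1L
    if (j > n) break
    best <- min(best, track$t[j] - track$t[i])
  }
  best
}

#' Per-cell track statistics table
#'
#' One row per cell: average speed, total path length, final directionality
#' ratio, and fastest 25-um segment time, with the cell's labels carried
#' along.
#'
#' @param tracks Tidy track table.
#' @param segment_length Segment length for [fastest_segment_time()].
#' @return Data frame, one row per cell.
#' @export
track_stats <- function(tracks, segment_length = 25) {
  out <- lapply(split_tracks(tracks), function(tr) {
    tr <- check_track(tr)
    dr <- directionality_ratio(tr)$ratio
    data.frame(
      cell_id = if ("cell_id" %in% names(tr)) tr$cell_id[1L] else NA,
      experiment_id = if ("experiment_id" %in% names(tr)) tr$experiment_id[1L] else NA,
      condition = if ("condition" %in% names(tr)) tr$condition[1L] else NA,
      average_speed = average_speed(tr),
      path_length = sum(step_lengths(tr)),
      directionality = dr[length(dr)],
      fastest_segment_time = fastest_segment_time(tr, segment_length))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Superplot summary: experiment-level means and test
#'
#' Summarizes a per-cell statistic to per-experiment means (the replicate-
#' aware "superplot" summary) and tests between conditions using experiments
#' as the sampling unit: a two-sided Student's t-test for two conditions, or
#' Dunnett's test against `control` for more.
#'
#' @param data Per-cell table (e.g. from [track_stats()]).
#' @param value Name of the per-cell statistic column.
#' @param condition,experiment Names of the grouping columns.
#' @param control Control condition label (required for > 2 conditions).
#' @return A list with `experiment_means` (condition, experiment, mean, n
#'   cells) and `test` (`method`, `p`, plus estimates).
#' @export
superplot_summary <- function(data, value, condition = "condition",
                              experiment = "experiment_id", control = NULL) {
  for (col in c(value, condition, experiment)) {
    if (!col %in% names(data)) stop("column not found: ", col, call. = FALSE)
  }
  v <- data[[value]]
  keep <- is.finite(v)
  em <- aggregate(list(mean = v[keep]),
                  by = list(condition = data[[condition]][keep],
                            experiment = data[[experiment]][keep]), FUN = mean)
  ncells <- aggregate(list(n_cells = v[keep]),
                      by = list(condition = data[[condition]][keep],
                                experiment = data[[experiment]][keep]), FUN = length)
  em <- merge(em, ncells)
  conds <- unique(as.character(em$condition))
  if (length(conds) < 2L) stop("need >= 2 conditions", call. = FALSE)
  groups <- split(em$mean, as.character(em$condition))
  if (length(conds) == 2L) {
    if (any(lengths(groups) < 2L)) {
      stop("Student's t-test on experiment means needs >= 2 experiments per ",
           "condition (df = 0 otherwise)", call. = FALSE)
    }
    g1 <- groups[[conds[1L]]]; g2 <- groups[[conds[2L]]]
    diff_means <- mean(g1) - mean(g2)
    p <- if (var(g1) == 0 && var(g2) == 0) {
      # zero spread: identical means are maximally compatible with the null
      if (diff_means == 0) 1 else 0
    } else {
      t.test(g1, g2, var.equal = TRUE)$p.value
    }
    test <- list(method = "Student's t on experiment means",
                 p = p, difference = diff_means, n_exp = lengths(groups))
  } else {
    if (is.null(control)) {
      stop("more than two conditions: supply `control` for Dunnett's test",
           call. = FALSE)
    }
    dn <- dunnett_vs_control(groups, control)
    test <- list(method = "Dunnett on experiment means vs control", dunnett = dn,
                 p = setNames(dn$p_adj, dn$group))
  }
  list(experiment_means = em, test = test)
}

# --- track I/O --------------------------------------------------------------

#' Read tracks from delimited text
#'
#' Two dialects: the Fiji Manual Tracking export (columns "Track n", "Slice
#' n", "X", "Y" in pixels and frames; separator auto-detected) and the native
#' tidy format written by [write_tracks()] (`cell_id`, `experiment_id`,
#' `condition`, `t`, `x`, `y`). `"auto"` sniffs the header.
#'
#' @param path File path.
#' @param format `"auto"`, `"fiji"`, or `"tidy"`.
#' @param pixel_size um per pixel (Fiji dialect; positions are scaled).
#' @param frame_interval Minutes per frame (Fiji dialect).
#' @param condition,experiment_id Labels attached to Fiji-dialect tracks.
#' @return Tidy track data frame.
#' @export
read_tracks <- function(path, format = c("auto", "fiji", "tidy"),
                        pixel_size = 1, frame_interval = 1,
                        condition = NA, experiment_id = NA) {
  format <- match.arg(format)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else if (grepl(";", header)) ";" else ","
  if (format == "auto") {
    format <- if (grepl("track", header, ignore.case = TRUE) &&
                  grepl("slice", header, ignore.case = TRUE)) "fiji" else "tidy"
  }
  d <- read.delim(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
  if (format == "fiji") {
    find_col <- function(pattern) {
      hit <- grep(pattern, names(d), ignore.case = TRUE)
      if (!length(hit)) stop("Fiji track file lacks a column matching ", pattern,
                             call. = FALSE)
      hit[1L]
    }
    track_col <- find_col("track")
    slice_col <- find_col("slice")
    x_col <- find_col("^x$|^x ")
    y_col <- find_col("^y$|^y ")
    out <- data.frame(
      cell_id = paste0("track", d[[track_col]]),
      experiment_id = experiment_id,
      condition = condition,
      t = (d[[slice_col]] - 1) * frame_interval,
      x = d[[x_col]] * pixel_size,
      y = d[[y_col]] * pixel_size)
    out <- out[order(out$cell_id, out$t), , drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    req <- c("cell_id", "t", "x", "y")
    if (!all(req %in% names(d))) {
      stop("tidy track file needs columns: ", paste(req, collapse = ", "),
           call. = FALSE)
    }
    d
  }
}

#' Write tracks as tidy delimited text
#' @param tracks Tidy track table.
#' @param path Output path (CSV).
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  write.csv(tracks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
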