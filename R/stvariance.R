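# Spatiotemporal variance scoring.
#
# The score distinguishes proteins riding on fast-moving sub-resolution
# vesicles (high per-pixel temporal variance) from diffuse cytoplasmic
# localization (low variance). Protocol: normalize each frame to its own mean
# intensity, compute the per-pixel variance over time inside small cytoplasmic
# ROIs, and report the mean variance per pixel pooled over the ROIs as one
# scalar per cell. ROI conventions: 20 x 20 px excerpts (five per cell) for
# Rab-type movies, one 50 x 50 px ROI for FKBP-construct movies.

#' Define a rectangular region of interest
#'
#' Pixel coordinates are 0-based and half-open: `x`, `y` index the top-left
#' pixel; the ROI covers columns `x .. x + width - 1` and rows
#' `y .. y + height - 1`.
#'
#' @param x,y Top-left pixel (0-based; x = column, y = row).
#' @param width,height Extent in pixels.
#' @return A named integer vector of class `roi`.
#' @export
roi <- function(x, y, width, height = width) {
  for (v in list(x = x, y = y)) check_number(v, "x/y", 0, integer = TRUE)
  check_number(width, "width", 1, integer = TRUE)
  check_number(height, "height", 1, integer = TRUE)
  structure(c(x = as.integer(x), y = as.integer(y),
              width = as.integer(width), height = as.integer(height)),
            class = "roi")
}

as_roi_list <- function(rois) {
  if (inherits(rois, "roi")) return(list(rois))
  if (is.matrix(rois)) rois <- lapply(seq_len(nrow(rois)), function(i) rois[i, ])
  if (!is.list(rois) || !length(rois)) {
    stop("`rois` must be a non-empty list of roi() objects", call. = FALSE)
  }
  lapply(rois, function(r) {
    if (inherits(r, "roi")) r else roi(r[[1L]], r[[2L]], r[[3L]], r[[4L]])
  })
}

check_roi_inside <- function(r, dim_hw) {
  if (r[["x"]] + r[["width"]] > dim_hw[2L] || r[["y"]] + r[["height"]] > dim_hw[1L]) {
    stop(sprintf("ROI (x=%d, y=%d, %dx%d) exceeds the %dx%d frame",
                 r[["x"]], r[["y"]], r[["width"]], r[["height"]],
                 dim_hw[2L], dim_hw[1L]), call. = FALSE)
  }
  invisible(r)
}

roi_rows <- function(r) (r[["y"]] + 1L):(r[["y"]] + r[["height"]])
roi_cols <- function(r) (r[["x"]] + 1L):(r[["x"]] + r[["width"]])

#' Normalize each frame to its mean intensity
#'
#' Divides every frame by that frame's mean over the whole frame, removing
#' global brightness changes (illumination drift, photobleaching of the
#' pool). Each output frame has mean exactly 1.
#'
#' @param stack A [frame_stack()].
#' @return A [frame_stack()] of normalized frames.
#' @export
normalize_frames <- function(stack) {
  a <- as_stack_array(stack)
  means <- apply(a, 3L, mean)
  if (any(means <= 0)) {
    stop("cannot normalize: frame(s) ", paste(which(means <= 0), collapse = ", "),
         " have non-positive mean", call. = FALSE)
  }
  for (t in seq_len(dim(a)[3L])) a[, , t] <- a[, , t] / means[t]
  frame_stack(a, frame_interval = attr(stack, "frame_interval"),
              pixel_size = attr(stack, "pixel_size"))
}

#' Per-pixel temporal variance inside an ROI
#'
#' For each pixel of the ROI, the sample variance (divisor T - 1) of its
#' normalized intensity across all frames. The stack is expected to be
#' normalized already (see [normalize_frames()]).
#'
#' @param stack A [frame_stack()] with at least two frames.
#' @param roi An [roi()].
#' @return A height x width matrix of variances.
#' @export
temporal_variance_map <- function(stack, roi) {
  a <- as_stack_array(stack)
  if (dim(a)[3L] < 2L) stop("temporal variance needs >= 2 frames", call. = FALSE)
  r <- as_roi_list(roi)[[1L]]
  check_roi_inside(r, dim(a))
  sub <- a[roi_rows(r), roi_cols(r), , drop = FALSE]
  apply(sub, c(1L, 2L), var)
}

#' Spatiotemporal variance score of a movie
#'
#' Normalizes the stack (optional), computes a temporal variance map per ROI,
#' and returns the mean of all pixel variances pooled across ROIs — the
#' per-cell "spatiotemporal variance". For equal-sized ROIs this equals the
#' mean of the per-ROI map means.
#'
#' @param stack A [frame_stack()].
#' @param rois A list of [roi()]s (or an n x 4 matrix of x, y, w, h rows).
#' @param normalize Normalize frames first (default `TRUE`). Set to `FALSE`
#'   if the stack is already normalized.
#' @return A single non-negative scalar.
#' @examples
#' mov <- simulate_vesicle_movie(n_puncta = 10, frames = 10,
#'                               field_size = c(64, 64), seed = 1)
#' spatiotemporal_variance(mov, list(roi(10, 10, 20), roi(30, 30, 20)))
#' @export
spatiotemporal_variance <- function(stack, rois, normalize = TRUE) {
  rois <- as_roi_list(rois)
  if (check_flag(normalize, "normalize")) stack <- normalize_frames(stack)
  maps <- lapply(rois, function(r) temporal_variance_map(stack, r))
  sum(vapply(maps, sum, 0)) / sum(vapply(maps, length, 0L))
}

#' Automatically place cytoplasmic ROIs
#'
#' Emulates manual placement of excerpts "in the cytoplasm away from bright
#' structures": candidate ROIs are laid on a grid (stride = `size`, hence
#' non-overlapping), and a candidate qualifies when the mean of its time-mean
#' intensity lies within the given percentile band of the first frame and no
#' pixel of its time-mean exceeds the bright-structure fence (the band
#' ceiling plus 1.5 band widths, a Tukey-style outlier fence: a hard ceiling
#' at the band's own upper percentile would reject plain noise, whose block
#' maximum always exceeds the 75th percentile). `n` winners are drawn
#' deterministically from the qualifiers under `seed`. Manually supplied
#' ROIs are always honored in preference to automatic placement.
#'
#' @param stack A [frame_stack()].
#' @param n Number of ROIs.
#' @param size ROI side length in px (20 for Rab movies, 50 for FKBP).
#' @param brightness_band Percentile pair, default `c(25, 75)`.
#' @param seed Integer seed for the deterministic draw.
#' @return A list of `n` non-overlapping [roi()]s.
#' @export
auto_select_rois <- function(stack, n = 5, size = 20,
                             brightness_band = c(25, 75), seed = NULL) {
  a <- as_stack_array(stack)
  check_number(n, "n", 1, integer = TRUE)
  check_number(size, "size", 1, integer = TRUE)
  if (length(brightness_band) != 2L || any(brightness_band < 0) ||
      any(brightness_band > 100) || diff(brightness_band) <= 0) {
    stop("`brightness_band` must be an increasing percentile pair in [0, 100]",
         call. = FALSE)
  }
  h <- dim(a)[1L]; w <- dim(a)[2L]
  if (size > h || size > w) stop("ROI `size` exceeds the field", call. = FALSE)
  band <- quantile(a[, , 1L], brightness_band / 100, names = FALSE)
  fence <- band[2L] + 1.5 * (band[2L] - band[1L])
  tmean <- if (dim(a)[3L] == 1L) a[, , 1L] else apply(a, c(1L, 2L), mean)
  ys <- seq(0L, h - size, by = size)
  xs <- seq(0L, w - size, by = size)
  cand <- expand.grid(y = ys, x = xs)
  ok <- vapply(seq_len(nrow(cand)), function(i) {
    block <- tmean[(cand$y[i] + 1L):(cand$y[i] + size),
                   (cand$x[i] + 1L):(cand$x[i] + size)]
    m <- mean(block)
    m >= band[1L] && m <= band[2L] && max(block) <= fence
  }, TRUE)
  if (sum(ok) < n) {
    stop(sprintf("only %d of %d candidate positions qualify (need %d); widen the band or reduce `n`",
                 sum(ok), nrow(cand), n), call. = FALSE)
  }
  idx <- which(ok)
  pick <- with_seed(seed, sample(idx, n))
  lapply(pick, function(i) roi(cand$x[i], cand$y[i], size))
}
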