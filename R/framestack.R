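# Frame stacks: the container for time-lapse movies.

#' Create a frame stack
#'
#' A frame stack is an H x W x T array of non-negative intensities with the
#' acquisition metadata the downstream analyses need: the frame interval in
#' seconds and the pixel size in micrometres per pixel.
#'
#' @param data Numeric H x W x T array (or a matrix, taken as a single frame).
#' @param frame_interval Seconds between frames (may be `NULL` if unknown).
#' @param pixel_size Micrometres per pixel (may be `NULL` if unknown).
#' @return An object of class `frame_stack`.
#' @examples
#' fs <- frame_stack(array(1, dim = c(4, 4, 3)), frame_interval = 0.3,
#'                   pixel_size = 0.1)
#' n_frames(fs)
#' @export
frame_stack <- function(data, frame_interval = NULL, pixel_size = NULL) {
  a <- as_stack_array(data)
  if (!all(is.finite(a))) stop("frame stack intensities must be finite", call. = FALSE)
  if (!is.null(frame_interval)) check_number(frame_interval, "frame_interval", 0, strict = TRUE)
  if (!is.null(pixel_size)) check_number(pixel_size, "pixel_size", 0, strict = TRUE)
  structure(a, frame_interval = frame_interval, pixel_size = pixel_size,
            class = "frame_stack")
}

# Coerce matrix / array / frame_stack to a plain H x W x T array.
as_stack_array <- function(x) {
  if (inherits(x, "frame_stack")) x <- unclass(x)
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L || !is.numeric(x)) {
    stop("`data` must be a numeric matrix or H x W x T array", call. = FALSE)
  }
  storage.mode(x) <- "double"
  attributes(x) <- list(dim = dim(x))
  x
}

#' Number of frames in a stack
#' @param x A `frame_stack`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "frame_stack"))
  dim(x)[3L]
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<frame_stack> %d x %d px, %d frame%s\n", d[1L], d[2L], d[3L],
              if (d[3L] == 1L) "" else "s"))
  fi <- attr(x, "frame_interval"); ps <- attr(x, "pixel_size")
  if (!is.null(fi)) cat(sprintf("  frame interval: %g s\n", fi))
  if (!is.null(ps)) cat(sprintf("  pixel size: %g um/px\n", ps))
  invisible(x)
}

#' @export
`[.frame_stack` <- function(x, ...) {
  out <- unclass(x)[...]
  out
}
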