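# Minimal baseline TIFF codec.
#
# The package reads and writes plain grayscale multi-frame TIFF stacks:
# uncompressed, single sample per pixel, strip-organized. The writer always
# emits 32-bit IEEE float, little-endian, one strip per frame; the reader
# additionally accepts 8/16-bit unsigned data, multiple strips and either
# byte order. This covers the microscopy export formats the analyses consume
# without pulling in an image I/O dependency.

TIFF_TYPE_SIZES <- c(1L, 1L, 2L, 4L, 8L)  # BYTE, ASCII, SHORT, LONG, RATIONAL

#' Write a grayscale multi-frame TIFF
#'
#' Frames are written as uncompressed 32-bit IEEE floats, one TIFF directory
#' per frame. Frame interval and pixel size (when known) are stored as a
#' key-value `ImageDescription` so that [read_tiff()] round-trips a
#' [frame_stack()] losslessly apart from float32 precision.
#'
#' @param x A numeric matrix (H x W), an H x W x T array, or a `frame_stack`.
#' @param path Output file path.
#' @param frame_interval,pixel_size Optional metadata in seconds and um/px;
#'   taken from `x` when it is a `frame_stack`.
#' @return `path`, invisibly.
#' @seealso [read_tiff()]
#' @export
write_tiff <- function(x, path, frame_interval = NULL, pixel_size = NULL) {
  if (inherits(x, "frame_stack")) {
    frame_interval <- frame_interval %||% attr(x, "frame_interval")
    pixel_size <- pixel_size %||% attr(x, "pixel_size")
  }
  a <- as_stack_array(x)
  h <- dim(a)[1L]; w <- dim(a)[2L]; nt <- dim(a)[3L]
  desc <- character(0)
  if (!is.null(frame_interval)) desc <- c(desc, sprintf("frame_interval=%.10g", frame_interval))
  if (!is.null(pixel_size)) desc <- c(desc, sprintf("pixel_size=%.10g", pixel_size))
  has_desc <- length(desc) > 0L
  desc_raw <- raw(0)
  if (has_desc) {
    desc_raw <- c(charToRaw(paste0(paste(desc, collapse = ";"), ";")), as.raw(0L))
    if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0L))
  }

  frame_bytes <- h * w * 4L
  data_offset <- 8L + (seq_len(nt) - 1L) * frame_bytes
  ifd_sizes <- ifelse(seq_len(nt) == 1L & has_desc, 10L * 12L + 6L, 9L * 12L + 6L)
  ifd_offset <- 8L + nt * frame_bytes + c(0L, cumsum(ifd_sizes))[seq_len(nt)]
  desc_offset <- 8L + nt * frame_bytes + sum(ifd_sizes)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2L, endian = "little")
  writeBin(ifd_offset[1L], con, size = 4L, endian = "little")
  for (t in seq_len(nt)) {
    writeBin(as.double(t(a[, , t])), con, size = 4L, endian = "little")
  }
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2L, endian = "little")
    writeBin(as.integer(type), con, size = 2L, endian = "little")
    writeBin(as.integer(count), con, size = 4L, endian = "little")
    if (type == 3L && count == 1L) {
      writeBin(as.integer(value), con, size = 2L, endian = "little")
      writeBin(0L, con, size = 2L, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4L, endian = "little")
    }
  }
  for (t in seq_len(nt)) {
    first <- t == 1L && has_desc
    writeBin(if (first) 10L else 9L, con, size = 2L, endian = "little")
    entry(256L, 3L, 1L, w)                    # ImageWidth
    entry(257L, 3L, 1L, h)                    # ImageLength
    entry(258L, 3L, 1L, 32L)                  # BitsPerSample
    entry(259L, 3L, 1L, 1L)                   # Compression: none
    entry(262L, 3L, 1L, 1L)                   # Photometric: BlackIsZero
    if (first) entry(270L, 2L, length(desc_raw), desc_offset)
    entry(273L, 4L, 1L, data_offset[t])       # StripOffsets
    entry(278L, 3L, 1L, h)                    # RowsPerStrip
    entry(279L, 4L, 1L, frame_bytes)          # StripByteCounts
    entry(339L, 3L, 1L, 3L)                   # SampleFormat: IEEE float
    writeBin(if (t < nt) ifd_offset[t + 1L] else 0L, con, size = 4L, endian = "little")
  }
  if (has_desc) writeBin(desc_raw, con)
  invisible(path)
}

#' Read a grayscale multi-frame TIFF
#'
#' Supports uncompressed, single-channel, strip-organized TIFFs with 8- or
#' 16-bit unsigned or 32-bit float samples, in either byte order. Metadata
#' written by [write_tiff()] (frame interval, pixel size) is recovered from
#' the `ImageDescription` tag.
#'
#' @param path TIFF file path.
#' @param frame_interval,pixel_size Override metadata absent from the file.
#' @return A [frame_stack()].
#' @export
read_tiff <- function(path, frame_interval = NULL, pixel_size = NULL) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file: ", path, call. = FALSE)
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file (bad byte-order mark): ", path, call. = FALSE))
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer", size = 2L,
                               signed = FALSE, endian = endian)
  u32 <- function(off) readBin(raw[(off + 1):(off + 4)], "integer", size = 4L,
                               endian = endian)
  if (u16(2L) != 42L) stop("not a TIFF file (bad magic): ", path, call. = FALSE)

  read_values <- function(type, count, off_entry) {
    size <- TIFF_TYPE_SIZES[type]
    total <- size * count
    off <- if (total <= 4L) off_entry + 8L else u32(off_entry + 8L)
    bytes <- raw[(off + 1):(off + total)]
    switch(as.character(type),
      "1" = as.integer(bytes),
      "2" = rawToChar(bytes[bytes != as.raw(0L)]),
      "3" = readBin(bytes, "integer", n = count, size = 2L, signed = FALSE, endian = endian),
      "4" = readBin(bytes, "integer", n = count, size = 4L, endian = endian),
      stop("unsupported TIFF field type: ", type, call. = FALSE))
  }

  frames <- list()
  desc <- NULL
  ifd <- u32(4L)
  while (ifd != 0L) {
    n <- u16(ifd)
    tags <- list()
    for (i in seq_len(n)) {
      off_entry <- ifd + 2L + (i - 1L) * 12L
      tag <- u16(off_entry)
      type <- u16(off_entry + 2L)
      count <- u32(off_entry + 4L)
      if (tag %in% c(256L, 257L, 258L, 259L, 262L, 270L, 273L, 277L, 278L, 279L, 339L)) {
        tags[[as.character(tag)]] <- read_values(type, count, off_entry)
      }
    }
    w <- tags[["256"]]; h <- tags[["257"]]
    if (is.null(w) || is.null(h)) stop("TIFF directory missing image dimensions", call. = FALSE)
    if ((tags[["259"]] %||% 1L) != 1L) stop("compressed TIFF not supported", call. = FALSE)
    if ((tags[["277"]] %||% 1L) != 1L) stop("multi-channel TIFF not supported", call. = FALSE)
    bits <- tags[["258"]] %||% 1L
    fmt <- tags[["339"]] %||% 1L
    if (!is.null(tags[["270"]]) && is.null(desc)) desc <- tags[["270"]]
    offs <- tags[["273"]]; cnts <- tags[["279"]]
    if (is.null(offs) || is.null(cnts)) stop("TIFF directory missing strip layout", call. = FALSE)
    bytes <- raw[unlist(lapply(seq_along(offs), function(i) (offs[i] + 1):(offs[i] + cnts[i])))]
    vals <- if (fmt == 3L && bits == 32L) {
      readBin(bytes, "double", n = h * w, size = 4L, endian = endian)
    } else if (fmt %in% c(1L, 4L) && bits == 16L) {
      readBin(bytes, "integer", n = h * w, size = 2L, signed = FALSE, endian = endian)
    } else if (fmt %in% c(1L, 4L) && bits == 8L) {
      as.integer(bytes)
    } else {
      stop(sprintf("unsupported TIFF sample layout (%d-bit, format %d)", bits, fmt),
           call. = FALSE)
    }
    frames[[length(frames) + 1L]] <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
    ifd <- u32(ifd + 2L + n * 12L)
  }
  if (!length(frames)) stop("TIFF contains no images", call. = FALSE)

  get_meta <- function(key) {
    if (is.null(desc)) return(NULL)
    m <- regmatches(desc, regexec(paste0(key, "=([-0-9.eE+]+)"), desc))[[1L]]
    if (length(m) == 2L) as.numeric(m[2L]) else NULL
  }
  frame_interval <- frame_interval %||% get_meta("frame_interval")
  pixel_size <- pixel_size %||% get_meta("pixel_size")
  a <- array(unlist(frames), dim = c(nrow(frames[[1L]]), ncol(frames[[1L]]), length(frames)))
  frame_stack(a, frame_interval = frame_interval, pixel_size = pixel_size)
}
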