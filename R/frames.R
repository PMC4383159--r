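#' Validate and coerce a matrix to an 8-bit grayscale frame
#'
#' A frame is a plain numeric matrix of integer intensities in `[0, 255]`,
#' indexed `[y + 1, x + 1]` for pixel `(x, y)` (x = column, y = row,
#' 0-based).  3-channel arrays are converted to grayscale by luminance
#' (0.299 R + 0.587 G + 0.114 B); an alpha channel is dropped.
#'
#' @param x numeric matrix (intensities 0-255) or h x w x c array.
#' @return a validated frame matrix.
#' @export
as_frame <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) {
    nc <- dim(x)[3L]
    if (nc >= 3L) {
      x <- 0.299 * x[, , 1L] + 0.587 * x[, , 2L] + 0.114 * x[, , 3L]
    } else {
      x <- x[, , 1L]
    }
  }
  if (!is.matrix(x) || !is.numeric(x))
    stop("a frame must be a numeric matrix", call. = FALSE)
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("a frame must have positive height and width", call. = FALSE)
  x <- round(x)
  if (anyNA(x) || any(x < 0) || any(x > 255))
    stop("frame intensities must be integers in [0, 255]", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

#' Construct a frame sequence
#'
#' @param frames list of frames (see [as_frame()]); all must share the same
#'   dimensions.
#' @param frame_rate_hz optional positive acquisition frame rate (metadata
#'   only).
#' @return an object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, frame_rate_hz = NULL) {
  if (!is.list(frames) || length(frames) < 1L)
    stop("`frames` must be a non-empty list", call. = FALSE)
  frames <- lapply(frames, as_frame)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames in a sequence must have identical dimensions",
         call. = FALSE)
  if (!is.null(frame_rate_hz) &&
      (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0))
    stop("`frame_rate_hz` must be a positive number", call. = FALSE)
  structure(list(frames = frames, frame_rate_hz = frame_rate_hz),
            class = "frame_sequence")
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("frame_sequence: %d frame(s), %d x %d (h x w)%s\n",
              length(x$frames), d[1], d[2],
              if (is.null(x$frame_rate_hz)) ""
              else sprintf(", %g Hz", x$frame_rate_hz)))
  invisible(x)
}

read_image_file <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  img <- switch(ext,
    png = list(png::readPNG(path)),
    tif = ,
    tiff = {
      pages <- tiff::readTIFF(path, all = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      pages
    },
    stop(sprintf("unreadable image format: '%s' (expected PNG or TIFF)",
                 path), call. = FALSE)
  )
  # readers return values in [0, 1]
  lapply(img, function(a) as_frame(a * 255))
}

#' Load an image sequence from disk
#'
#' Accepts a directory of lexicographically ordered PNG/TIFF frames, a
#' multi-page TIFF, or a single image file.  All images are converted to
#' 8-bit grayscale.
#'
#' @param path file or directory path.
#' @param frame_rate_hz optional frame-rate metadata.
#' @return a [frame_sequence()].
#' @export
load_sequence <- function(path, frame_rate_hz = NULL) {
  if (!file.exists(path))
    stop(sprintf("path does not exist: '%s'", path), call. = FALSE)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    files <- sort(files)
    if (length(files) == 0L)
      stop(sprintf("no PNG/TIFF frames found in directory '%s'", path),
           call. = FALSE)
    frames <- unlist(lapply(files, read_image_file), recursive = FALSE)
  } else {
    frames <- read_image_file(path)
  }
  frame_sequence(frames, frame_rate_hz = frame_rate_hz)
}

#' Write a frame sequence as numbered PNG files
#'
#' @param sequence a [frame_sequence()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
write_frames <- function(sequence, dir, prefix = "frame") {
  stopifnot(inherits(sequence, "frame_sequence"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(sequence$frames))
  for (k in seq_along(sequence$frames)) {
    paths[k] <- file.path(dir, sprintf("%s_%03d.png", prefix, k - 1L))
    png::writePNG(sequence$frames[[k]] / 255, paths[k])
  }
  invisible(paths)
}

#' Extract an n x n block centered at a pixel
#'
#' Coordinates outside the frame are replicate-padded (edge clamp), so the
#' output always has shape `n` x `n` regardless of the center position.
#'
#' @param frame a frame matrix.
#' @param center_x,center_y 0-based center pixel (x = column, y = row).
#' @param n odd block side length.
#' @return an `n` x `n` intensity matrix.
#' @export
extract_block <- function(frame, center_x, center_y, n) {
  frame <- as_frame(frame)
  if (length(n) != 1L || n < 1L || n %% 2L != 1L)
    stop("block size `n` must be an odd positive integer", call. = FALSE)
  hw <- (n - 1L) / 2L
  xs <- pmin(pmax((center_x - hw):(center_x + hw), 0L), ncol(frame) - 1L)
  ys <- pmin(pmax((center_y - hw):(center_y + hw), 0L), nrow(frame) - 1L)
  frame[ys + 1L, xs + 1L, drop = FALSE]
}
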