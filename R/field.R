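#' Define a rectangular region of interest
#'
#' @param x,y 0-based origin (x = column, y = row) of the top-left pixel.
#' @param width,height positive extents in pixels.
#' @return an object of class `roi`.
#' @export
roi <- function(x, y, width, height) {
  if (x < 0 || y < 0) stop("ROI origin must be non-negative", call. = FALSE)
  if (width < 1 || height < 1)
    stop("ROI extents must be positive", call. = FALSE)
  structure(list(x = as.integer(x), y = as.integer(y),
                 width = as.integer(width), height = as.integer(height)),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("roi: origin (%d, %d), %d x %d (w x h)\n",
              x$x, x$y, x$width, x$height))
  invisible(x)
}

roi_in_frame <- function(roi, frame) {
  roi$x + roi$width <= ncol(frame) && roi$y + roi$height <= nrow(frame)
}

#' Construct a dense motion field over an ROI
#'
#' `ux` and `uy` are `height` x `width` matrices of per-pixel displacement
#' components aligned to the ROI: entry `[iy + 1, ix + 1]` is the vector at
#' ROI pixel `(ix, iy)` (0-based, ROI-relative).  Under the backward
#' matching convention the current-frame pixel `p` corresponds to reference
#' pixel `p + u`.
#'
#' @param ux,uy numeric matrices of displacement components (pixels).
#' @param roi the [roi()] the field covers; defaults to origin (0, 0) with
#'   the matrices' extents.
#' @param iteration non-negative iteration counter metadata.
#' @return an object of class `motion_field`.
#' @export
motion_field <- function(ux, uy, roi = NULL, iteration = 0L) {
  if (!is.matrix(ux) || !is.matrix(uy) || !all(dim(ux) == dim(uy)))
    stop("`ux` and `uy` must be matrices of identical dimensions",
         call. = FALSE)
  if (is.null(roi)) {
    roi <- roi(0L, 0L, ncol(ux), nrow(ux))
  }
  if (nrow(ux) != roi$height || ncol(ux) != roi$width)
    stop("field matrices must be roi$height x roi$width", call. = FALSE)
  if (iteration < 0) stop("`iteration` must be non-negative", call. = FALSE)
  structure(list(roi = roi, ux = ux, uy = uy,
                 iteration = as.integer(iteration)),
            class = "motion_field")
}

#' @export
print.motion_field <- function(x, ...) {
  cat(sprintf(
    "motion_field: %d x %d vectors at roi origin (%d, %d), iteration %d\n",
    x$roi$width, x$roi$height, x$roi$x, x$roi$y, x$iteration))
  invisible(x)
}

#' Round a motion field to integer displacements
#'
#' Components are rounded half-away-from-zero (the block-evaluation
#' convention).
#'
#' @param field a [motion_field()].
#' @return a `motion_field` with integer-valued components.
#' @export
round_field <- function(field) {
  stopifnot(inherits(field, "motion_field"))
  motion_field(round_away(field$ux), round_away(field$uy), field$roi,
               field$iteration)
}

#' Write a motion field as CSV
#'
#' Plain-text format: a `#`-prefixed header comment recording the ROI and
#' iteration, then a CSV table with columns `x, y, ux, uy` where `x, y` are
#' 0-based ROI-relative pixel coordinates (row-major, `y` slowest).
#'
#' @param field a [motion_field()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "motion_field"))
  r <- field$roi
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# roi %d %d %d %d iteration %d",
                     r$x, r$y, r$width, r$height, field$iteration), con)
  grid <- expand.grid(x = 0:(r$width - 1L), y = 0:(r$height - 1L))
  df <- data.frame(x = grid$x, y = grid$y,
                   ux = as.vector(t(field$ux)), uy = as.vector(t(field$uy)))
  writeLines("x,y,ux,uy", con)
  writeLines(paste(df$x, df$y,
                   format(df$ux, digits = 17, trim = TRUE, scientific = FALSE),
                   format(df$uy, digits = 17, trim = TRUE, scientific = FALSE),
                   sep = ","), con)
  invisible(path)
}

#' Read a motion field written by [write_field()]
#'
#' @param path CSV file path.
#' @return a [motion_field()]; `read_field(write_field(f)) == f` for all
#'   valid fields.
#' @export
read_field <- function(path) {
  if (!file.exists(path))
    stop(sprintf("path does not exist: '%s'", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  org <- c(0L, 0L)
  iteration <- 0L
  if (startsWith(first, "#")) {
    toks <- strsplit(trimws(sub("^#", "", first)), "\\s+")[[1]]
    if (length(toks) >= 5L && toks[1] == "roi") {
      org <- as.integer(toks[2:3])
      it_idx <- match("iteration", toks)
      if (!is.na(it_idx) && length(toks) > it_idx)
        iteration <- as.integer(toks[it_idx + 1L])
    }
  }
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#"),
    error = function(e) stop(sprintf("malformed field file '%s': %s",
                                     path, conditionMessage(e)),
                             call. = FALSE))
  if (!identical(names(df), c("x", "y", "ux", "uy")))
    stop("field file must have columns x, y, ux, uy", call. = FALSE)
  if (anyNA(df) || !all(vapply(df, is.numeric, logical(1))))
    stop("field file contains missing or non-numeric values", call. = FALSE)
  if (anyDuplicated(df[, c("x", "y")]))
    stop("field file contains duplicate pixel coordinates", call. = FALSE)
  w <- max(df$x) + 1L
  h <- max(df$y) + 1L
  if (nrow(df) != w * h || any(df$x < 0) || any(df$y < 0))
    stop("field file does not cover a full rectangular grid", call. = FALSE)
  ux <- matrix(NA_real_, h, w)
  uy <- matrix(NA_real_, h, w)
  idx <- cbind(df$y + 1L, df$x + 1L)
  ux[idx] <- df$ux
  uy[idx] <- df$uy
  motion_field(ux, uy, roi(org[1], org[2], w, h), iteration)
}
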