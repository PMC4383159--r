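# Speckle phantoms: filtered white-noise scatterer grids, magnitude
# envelope, 8-bit quantization, known dense motion plus optional
# frame-to-frame decorrelation noise.  The stand-in for in-vivo B-mode data
# that ground-truth evaluation requires; labelled synthetic throughout.

#' Translation motion specification
#'
#' @param dx,dy per-frame-step displacement in pixels (integer values give
#'   exact ground truth).
#' @return a `motion_spec`.
#' @export
motion_translation <- function(dx, dy) {
  structure(list(type = "translation", dx = dx, dy = dy),
            class = "motion_spec")
}

#' Affine motion specification
#'
#' The per-step displacement at pixel `(x, y)` is
#' `A %*% c(x, y, 1)` where `A` is a 2 x 3 matrix (rows: x- and
#' y-displacement).  Ground truth is continuous; the rounded field is
#' approximate.
#'
#' @param A 2 x 3 numeric matrix.
#' @return a `motion_spec`.
#' @export
motion_affine <- function(A) {
  if (!is.matrix(A) || !all(dim(A) == c(2, 3)))
    stop("`A` must be a 2 x 3 matrix", call. = FALSE)
  structure(list(type = "affine", A = A), class = "motion_spec")
}

#' Smooth sinusoidal shear motion specification
#'
#' Per-step displacement `ux = amplitude * sin(2 * pi * y / period)`,
#' `uy = 0`: a smooth horizontal shear varying down the image.
#'
#' @param amplitude peak displacement in pixels.
#' @param period spatial period in pixels.
#' @return a `motion_spec`.
#' @export
motion_sinusoidal <- function(amplitude, period) {
  if (period <= 0) stop("`period` must be positive", call. = FALSE)
  structure(list(type = "sinusoidal", amplitude = amplitude,
                 period = period), class = "motion_spec")
}

# per-step displacement grids (h x w matrices ux, uy) at full-frame pixels
motion_step_field <- function(motion, width, height) {
  gx <- matrix(rep(0:(width - 1L), each = height), height)
  gy <- matrix(rep(0:(height - 1L), times = width), height)
  switch(motion$type,
    translation = list(ux = matrix(motion$dx, height, width),
                       uy = matrix(motion$dy, height, width)),
    affine = list(
      ux = motion$A[1, 1] * gx + motion$A[1, 2] * gy + motion$A[1, 3],
      uy = motion$A[2, 1] * gx + motion$A[2, 2] * gy + motion$A[2, 3]),
    sinusoidal = list(
      ux = motion$amplitude * sin(2 * pi * gy / motion$period),
      uy = matrix(0, height, width)),
    stop("unknown motion type", call. = FALSE))
}

#' Phantom generator configuration
#'
#' @param width,height frame extents in pixels.
#' @param motion a `motion_spec` ([motion_translation()],
#'   [motion_affine()] or [motion_sinusoidal()]).
#' @param psf_sigma speckle correlation length in pixels (standard
#'   deviation of the Gaussian point-spread surrogate); default 2, a
#'   B-mode-like speckle cell of a few pixels.
#' @param decorrelation_noise_sigma standard deviation (intensity units) of
#'   independent zero-mean noise added to every frame, emulating temporal
#'   speckle decorrelation; 0 disables it.
#' @param frames number of frames (>= 2).
#' @param seed integer seed.
#' @param max_displacement the search half-width W the phantom targets;
#'   every per-step ground-truth displacement magnitude must stay within
#'   it (checked at generation).
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(width, height, motion = motion_translation(2, 1),
                           psf_sigma = 2, decorrelation_noise_sigma = 0,
                           frames = 2L, seed = 1L, max_displacement = 7L) {
  if (width < 1 || height < 1)
    stop("phantom extents must be positive", call. = FALSE)
  if (!inherits(motion, "motion_spec"))
    stop("`motion` must be a motion_spec", call. = FALSE)
  if (psf_sigma <= 0) stop("`psf_sigma` must be positive", call. = FALSE)
  if (decorrelation_noise_sigma < 0)
    stop("`decorrelation_noise_sigma` must be non-negative", call. = FALSE)
  if (frames < 2) stop("a phantom needs at least 2 frames", call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 motion = motion, psf_sigma = psf_sigma,
                 decorrelation_noise_sigma = decorrelation_noise_sigma,
                 frames = as.integer(frames), seed = as.integer(seed),
                 max_displacement = as.integer(max_displacement)),
            class = "phantom_config")
}

# circular FFT convolution with a normalized Gaussian kernel; callers pad
# the grid so wrap-around never reaches the region of interest
gaussian_smooth <- function(mat, sigma) {
  h <- nrow(mat)
  w <- ncol(mat)
  dy <- pmin(0:(h - 1), h - (0:(h - 1)))
  dx <- pmin(0:(w - 1), w - (0:(w - 1)))
  kern <- outer(exp(-dy^2 / (2 * sigma^2)), exp(-dx^2 / (2 * sigma^2)))
  kern <- kern / sum(kern)
  Re(stats::fft(stats::fft(mat) * stats::fft(kern), inverse = TRUE)) /
    (h * w)
}

speckle_envelope <- function(scatterers, psf_sigma) {
  abs(gaussian_smooth(scatterers, psf_sigma))
}

#' Render a speckle frame from a scatterer grid
#'
#' Convolves real-valued white-noise scatterer amplitudes with an isotropic
#' Gaussian kernel, takes the magnitude envelope, rescales to `[0, 255]`
#' and quantizes to 8 bits.  Deterministic given the scatterer grid.
#'
#' @param scatterers real-valued matrix of scatterer amplitudes.
#' @param psf_sigma Gaussian point-spread standard deviation in pixels.
#' @return a frame matrix.
#' @export
render_speckle <- function(scatterers, psf_sigma) {
  if (!is.matrix(scatterers) || !is.numeric(scatterers))
    stop("`scatterers` must be a numeric matrix", call. = FALSE)
  if (psf_sigma <= 0) stop("`psf_sigma` must be positive", call. = FALSE)
  env <- speckle_envelope(scatterers, psf_sigma)
  mx <- max(env)
  if (mx == 0) return(as_frame(matrix(0, nrow(env), ncol(env))))
  as_frame(round(env / mx * 255))
}

# bilinear sample of matrix `big` at continuous 0-based (x, y), edge-clamped
bilinear_sample <- function(big, x, y) {
  x <- pmin(pmax(x, 0), ncol(big) - 1)
  y <- pmin(pmax(y, 0), nrow(big) - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, ncol(big) - 1); y1 <- pmin(y0 + 1, nrow(big) - 1)
  fx <- x - x0; fy <- y - y0
  v00 <- big[cbind(y0 + 1, x0 + 1)]
  v01 <- big[cbind(y0 + 1, x1 + 1)]
  v10 <- big[cbind(y1 + 1, x0 + 1)]
  v11 <- big[cbind(y1 + 1, x1 + 1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

quantize_frame <- function(x) {
  as_frame(pmin(pmax(round(x), 0), 255))
}

#' Generate a synthetic speckle sequence with known motion
#'
#' Frame `k` is rendered from the scatterer field warped by the cumulative
#' ground-truth motion (speckle moves with the tissue), then independent
#' zero-mean Gaussian noise of scale `decorrelation_noise_sigma` is added
#' and the frame re-quantized.  Truth fields use the backward convention:
#' the vector at a pixel of frame `k` points to its source in frame
#' `k - 1`, directly comparable to estimator output.  For integer
#' translations the warp is an exact shift of a single rendered grid, so
#' interior blocks match their displaced counterparts exactly.
#'
#' @param config a [phantom_config()].
#' @return a `phantom`: list with `sequence` (a [frame_sequence()]) and
#'   `truth` (list of one [motion_field()] per consecutive frame pair,
#'   covering the full frame), plus the `config` echo.
#' @export
generate_sequence <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  w <- config$width
  h <- config$height
  step <- motion_step_field(config$motion, w, h)
  if (max(abs(step$ux), abs(step$uy)) > config$max_displacement)
    stop("ground-truth displacement exceeds `max_displacement`",
         call. = FALSE)
  nstep <- config$frames - 1L
  maxcum <- nstep * max(abs(step$ux), abs(step$uy))
  pad <- ceiling(maxcum) + ceiling(4 * config$psf_sigma) + 1L
  set.seed(config$seed)
  S <- matrix(rnorm((h + 2L * pad) * (w + 2L * pad)), h + 2L * pad)

  integer_translation <- config$motion$type == "translation" &&
    config$motion$dx == round(config$motion$dx) &&
    config$motion$dy == round(config$motion$dy)

  frames <- vector("list", config$frames)
  if (integer_translation) {
    env <- speckle_envelope(S, config$psf_sigma)
    big <- quantize_frame(env / max(env) * 255)
    for (k in 0:nstep) {
      oy <- pad + k * as.integer(config$motion$dy)
      ox <- pad + k * as.integer(config$motion$dx)
      frames[[k + 1L]] <- big[oy + seq_len(h), ox + seq_len(w)]
    }
  } else {
    # warp the scatterer grid by bilinear sampling, then render per frame;
    # margin q keeps the blur free of edge effects near the crop
    q <- ceiling(3 * config$psf_sigma)
    gx <- matrix(rep((-q):(w + q - 1L), each = h + 2L * q), h + 2L * q)
    gy <- matrix(rep((-q):(h + q - 1L), times = w + 2L * q), h + 2L * q)
    cx <- pmin(pmax(gx, 0), w - 1L)
    cy <- pmin(pmax(gy, 0), h - 1L)
    ux1 <- matrix(step$ux[cbind(as.vector(cy) + 1L, as.vector(cx) + 1L)],
                  h + 2L * q)
    uy1 <- matrix(step$uy[cbind(as.vector(cy) + 1L, as.vector(cx) + 1L)],
                  h + 2L * q)
    scale <- NULL
    for (k in 0:nstep) {
      Sk <- matrix(bilinear_sample(S, as.vector(gx + k * ux1) + pad,
                                   as.vector(gy + k * uy1) + pad),
                   h + 2L * q)
      Ek <- speckle_envelope(Sk, config$psf_sigma)
      Ek <- Ek[q + seq_len(h), q + seq_len(w)]
      if (is.null(scale)) scale <- 255 / max(Ek)
      frames[[k + 1L]] <- quantize_frame(Ek * scale)
    }
  }

  if (config$decorrelation_noise_sigma > 0) {
    for (k in seq_along(frames)) {
      frames[[k]] <- quantize_frame(
        frames[[k]] + rnorm(h * w, 0, config$decorrelation_noise_sigma))
    }
  }

  truth <- lapply(seq_len(nstep), function(k) {
    motion_field(step$ux, step$uy, roi(0L, 0L, w, h), iteration = 0L)
  })
  structure(list(sequence = frame_sequence(frames),
                 truth = truth, config = config),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf(
    "phantom: %d frame(s) %d x %d, motion '%s', psf_sigma=%g, noise_sigma=%g, seed=%d\n",
    x$config$frames, x$config$height, x$config$width, x$config$motion$type,
    x$config$psf_sigma, x$config$decorrelation_noise_sigma, x$config$seed))
  invisible(x)
}
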