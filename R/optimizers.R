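#' Euclidean distance between two motion vectors
#'
#' @param a,b numeric length-2 displacements `c(ux, uy)`.
#' @return non-negative distance in pixels.
#' @export
firefly_distance <- function(a, b) {
  if (length(a) != 2L || length(b) != 2L)
    stop("motion vectors must have length 2", call. = FALSE)
  sqrt(sum((a - b)^2))
}

#' Firefly attractiveness at distance r
#'
#' Exponential decay `beta0 * exp(-gamma * r)` clamped to at most 1.
#' `beta0` is the sum of the two fireflies' brightness values and can
#' exceed 1; the clamp keeps the subsequent position update a convex
#' combination.
#'
#' @param beta0 positive base attractiveness.
#' @param gamma positive light absorption coefficient.
#' @param r non-negative distance.
#' @return attractiveness in `(0, 1]`.
#' @export
attractiveness <- function(beta0, gamma, r) {
  if (beta0 <= 0) stop("`beta0` must be positive", call. = FALSE)
  if (gamma <= 0) stop("`gamma` must be positive", call. = FALSE)
  if (r < 0) stop("`r` must be non-negative", call. = FALSE)
  min(1, beta0 * exp(-gamma * r))
}

#' Move a firefly toward a brighter one
#'
#' Convex combination `(1 - beta) * xi + beta * xj` plus a per-component
#' random walk, clamped to `[-W, W]`.
#'
#' @param xi,xj positions (length-2) of the moving and target fireflies.
#' @param beta attractiveness in `[0, 1]` (already clamped).
#' @param walk length-2 walk drawn uniformly from `(-0.5, 0.5)` per
#'   component.
#' @param W search half-width for clamping.
#' @return the new position.
#' @export
move_firefly <- function(xi, xj, beta, walk, W) {
  if (beta < 0 || beta > 1) stop("`beta` must lie in [0, 1]", call. = FALSE)
  pmin(pmax((1 - beta) * xi + beta * xj + walk, -W), W)
}

#' Random walk of the brightest firefly
#'
#' @param x current position (length-2).
#' @param walk length-2 walk drawn uniformly from `(-0.5, 0.5)` per
#'   component.
#' @param W search half-width for clamping.
#' @return the walked position, clamped to `[-W, W]`.
#' @export
random_walk <- function(x, walk, W) {
  pmin(pmax(x + walk, -W), W)
}

prepare_neighbors <- function(neighbor_mvs) {
  if (is.null(neighbor_mvs) || length(neighbor_mvs) == 0L)
    return(matrix(numeric(0), 0, 2))
  if (is.list(neighbor_mvs)) neighbor_mvs <- do.call(rbind, neighbor_mvs)
  if (is.vector(neighbor_mvs)) neighbor_mvs <- matrix(neighbor_mvs, ncol = 2)
  if (ncol(neighbor_mvs) != 2L || nrow(neighbor_mvs) > 8L)
    stop("`neighbor_mvs` must hold at most 8 length-2 vectors",
         call. = FALSE)
  neighbor_mvs
}

#' Firefly-swarm displacement search at one pixel
#'
#' Runs a full `config$iterations`-sweep swarm of `config$swarm_size`
#' fireflies at block center `(center_x, center_y)` against a fixed set of
#' previous-iteration neighbor vectors.  Randomness comes from R's global
#' stream; call `set.seed()` beforehand for reproducibility.
#'
#' @param current,reference frame matrices.
#' @param center_x,center_y 0-based block center.
#' @param neighbor_mvs previous-iteration neighbor vectors (see
#'   [smoothness()]).
#' @param config a [search_config()].
#' @param init optional `m` x 2 matrix of initial firefly displacements
#'   (otherwise drawn uniformly on `[-W, W]^2`).
#' @return list with `mv` (integer length-2 best displacement `u_BestCu`),
#'   `brightness` (its fitness) and `evaluations` (fitness evaluations
#'   spent).
#' @export
ifa_estimate_pixel <- function(current, reference, center_x, center_y,
                               neighbor_mvs, config, init = NULL) {
  stopifnot(inherits(config, "search_config"))
  nb <- prepare_neighbors(neighbor_mvs)
  res <- cpp_ifa_pixel(as_frame(current), as_frame(reference),
                       as.integer(center_x), as.integer(center_y),
                       nb[, 1], nb[, 2], config$block_size,
                       config$search_width, config$lambda, config$gamma,
                       config$swarm_size, config$iterations, init)
  list(mv = c(res$ux, res$uy), brightness = res$fitness,
       evaluations = res$evaluations)
}

#' Exhaustive displacement search at one pixel
#'
#' Evaluates the fitness of all `(2W+1)^2` integer displacements and
#' returns the maximizer (ties: first in row-major `(uy, ux)` scan order
#' from `(-W, -W)`).  Deterministic.
#'
#' @inheritParams ifa_estimate_pixel
#' @return list with `mv`, `brightness`, `evaluations` (always
#'   `(2W+1)^2`).
#' @export
ifsa_estimate_pixel <- function(current, reference, center_x, center_y,
                                neighbor_mvs, config) {
  stopifnot(inherits(config, "search_config"))
  nb <- prepare_neighbors(neighbor_mvs)
  res <- cpp_ifsa_pixel(as_frame(current), as_frame(reference),
                        as.integer(center_x), as.integer(center_y),
                        nb[, 1], nb[, 2], config$block_size,
                        config$search_width, config$lambda)
  list(mv = c(res$ux, res$uy), brightness = res$fitness,
       evaluations = res$evaluations)
}

#' Estimate a dense motion field over an ROI
#'
#' Runs the iterative estimator between `sequence` frames
#' `frame_index - 1` (reference) and `frame_index` (current).  The field is
#' initialized with uniform random integer vectors, then updated for
#' `config$iterations` synchronous Jacobi sweeps: every pixel's smoothness
#' term reads the previous sweep's field, so update order is immaterial.
#' With `method = "ifa"` each pixel carries a persistent firefly swarm that
#' performs one update step per sweep; with `method = "ifsa"` each pixel is
#' re-solved by exhaustive scan each sweep.
#'
#' @param sequence a [frame_sequence()] (or a plain list of 2+ frames).
#' @param frame_index 1-based index of the current frame (>= 2).
#' @param roi a [roi()] lying fully inside the frames.
#' @param config a [search_config()]; `config$seed` seeds the run.
#' @param method `"ifa"` (firefly swarm) or `"ifsa"` (exhaustive).
#' @param record_psnr if `TRUE`, record the motion-compensated ROI PSNR
#'   after every sweep (the convergence-curve surface).
#' @return an `estimation_result`: list with `field` ([motion_field()] of
#'   integer vectors), `fitness_evaluations`, `iterations_run`,
#'   `per_iteration_psnr` (dB, or `NULL`), `fitness` (per-pixel best
#'   fitness matrix) and `method`.
#' @export
estimate_field <- function(sequence, frame_index, roi, config,
                           method = c("ifa", "ifsa"),
                           record_psnr = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(config, "search_config"), inherits(roi, "roi"))
  if (!inherits(sequence, "frame_sequence"))
    sequence <- frame_sequence(sequence)
  if (length(sequence$frames) < 2L)
    stop("estimation needs a sequence of at least 2 frames", call. = FALSE)
  if (frame_index < 2L || frame_index > length(sequence$frames))
    stop("`frame_index` must address a frame with a predecessor",
         call. = FALSE)
  current <- sequence$frames[[frame_index]]
  reference <- sequence$frames[[frame_index - 1L]]
  if (!roi_in_frame(roi, current))
    stop("ROI does not lie fully inside the frame", call. = FALSE)
  set.seed(config$seed)
  res <- cpp_estimate_field(current, reference, roi$x, roi$y, roi$width,
                            roi$height, config$block_size,
                            config$search_width, config$lambda,
                            config$gamma, config$swarm_size,
                            config$iterations,
                            if (method == "ifsa") 0L else 1L,
                            isTRUE(record_psnr), config$persist_swarms)
  structure(list(
    field = motion_field(res$ux, res$uy, roi, config$iterations),
    fitness_evaluations = res$evaluations,
    iterations_run = config$iterations,
    per_iteration_psnr = if (record_psnr) res$psnr_trace else NULL,
    fitness = res$fitness,
    method = method
  ), class = "estimation_result")
}

#' @export
print.estimation_result <- function(x, ...) {
  cat(sprintf(
    "estimation_result (%s): %d x %d field, %d iterations, %.0f fitness evaluations\n",
    x$method, x$field$roi$width, x$field$roi$height, x$iterations_run,
    x$fitness_evaluations))
  invisible(x)
}
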