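#' Estimator configuration
#'
#' Bundles every parameter of the block-matching estimators.  Defaults are
#' the operating point used for the in-vivo tendon benchmark: 7 x 7 blocks,
#' a 15 x 15 search window (`search_width` W = 7, i.e. 225 candidate
#' displacements), smoothness weight `lambda` = 1, light absorption
#' `gamma` = 1, 5 fireflies and 200 global iterations.
#'
#' @param block_size odd block side length n (pixels).
#' @param search_width search half-width W: displacements range over
#'   `[-W, W]` per component.
#' @param lambda non-negative smoothness weight on the neighbor-consistency
#'   penalty.
#' @param gamma positive light absorption coefficient of the firefly
#'   attractiveness decay `beta0 * exp(-gamma * r)`.
#' @param swarm_size number of fireflies m per pixel; must not exceed the
#'   number of integer candidates `(2W+1)^2`.
#' @param iterations number of global Jacobi sweeps l.
#' @param seed integer seed for all randomness of a run.
#' @param persist_swarms if `FALSE` (default) each pixel's firefly
#'   positions are redrawn uniformly at the start of every sweep, giving
#'   the swarm a random-restart character while the per-pixel elite record
#'   (`u_BestCu`) and the smoothness recursion carry information across
#'   sweeps; if `TRUE` positions persist across sweeps.  Persistent swarms
#'   collapse onto their early best and stop exploring, which measurably
#'   degrades recovery of known motion on speckle phantoms (see the
#'   methods vignette), so re-initialization is the default.
#' @return an object of class `search_config`.
#' @export
search_config <- function(block_size = 7L, search_width = 7L, lambda = 1.0,
                          gamma = 1.0, swarm_size = 5L, iterations = 200L,
                          seed = 1L, persist_swarms = FALSE) {
  if (block_size < 1 || block_size %% 2 != 1)
    stop("`block_size` must be an odd positive integer", call. = FALSE)
  if (search_width < 1)
    stop("`search_width` must be a positive integer", call. = FALSE)
  if (lambda < 0) stop("`lambda` must be non-negative", call. = FALSE)
  if (gamma <= 0) stop("`gamma` must be positive", call. = FALSE)
  if (swarm_size < 1) stop("`swarm_size` must be positive", call. = FALSE)
  if (swarm_size > (2 * search_width + 1)^2)
    stop("`swarm_size` must not exceed (2W+1)^2 candidate displacements",
         call. = FALSE)
  if (iterations < 1) stop("`iterations` must be positive", call. = FALSE)
  structure(list(block_size = as.integer(block_size),
                 search_width = as.integer(search_width),
                 lambda = as.numeric(lambda), gamma = as.numeric(gamma),
                 swarm_size = as.integer(swarm_size),
                 iterations = as.integer(iterations),
                 seed = as.integer(seed),
                 persist_swarms = isTRUE(persist_swarms)),
            class = "search_config")
}

#' @export
print.search_config <- function(x, ...) {
  cat(sprintf(paste0(
    "search_config: n=%d, W=%d, lambda=%g, gamma=%g, m=%d, l=%d, seed=%d,",
    " persist_swarms=%s\n"),
    x$block_size, x$search_width, x$lambda, x$gamma, x$swarm_size,
    x$iterations, x$seed, x$persist_swarms))
  invisible(x)
}
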