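#' Block mean square error at a candidate displacement
#'
#' MSE over the `n` x `n` block centered at `(center_x, center_y)` between
#' the current frame and the reference frame displaced by `mv`:
#' `mean((f_k(p) - f_{k-1}(p + u))^2)`.  Continuous `mv` components are
#' rounded half-away-from-zero before evaluation; blocks near frame borders
#' use replicate padding.
#'
#' @param current,reference frame matrices of identical size.
#' @param center_x,center_y 0-based block center.
#' @param mv numeric length-2 displacement `c(ux, uy)` in pixels.
#' @param n odd block side length.
#' @return non-negative MSE in squared intensity units.
#' @export
block_mse <- function(current, reference, center_x, center_y, mv, n) {
  current <- as_frame(current)
  reference <- as_frame(reference)
  if (!all(dim(current) == dim(reference)))
    stop("`current` and `reference` must have identical dimensions",
         call. = FALSE)
  if (length(n) != 1L || n < 1L || n %% 2L != 1L)
    stop("block size `n` must be an odd positive integer", call. = FALSE)
  if (length(mv) != 2L || anyNA(mv))
    stop("`mv` must be a length-2 numeric displacement", call. = FALSE)
  cpp_block_mse(current, reference, as.integer(center_x),
                as.integer(center_y), mv[1], mv[2], as.integer(n))
}

#' Smoothness constraint against previous-iteration neighbor vectors
#'
#' Mean over the available 8-connected neighbor vectors of the squared
#' vector difference `(ux - ux_i)^2 + (uy - uy_i)^2`.  Fewer than 8
#' neighbors are allowed at ROI borders (the divisor is the neighbor
#' count); an empty neighbor set yields 0.
#'
#' @param mv numeric length-2 displacement `c(ux, uy)`.
#' @param neighbor_mvs neighbor displacements: a k x 2 matrix, a list of
#'   length-2 vectors (k <= 8), or `NULL`/empty.
#' @return non-negative smoothness penalty in squared pixels.
#' @export
smoothness <- function(mv, neighbor_mvs) {
  if (length(mv) != 2L || anyNA(mv))
    stop("`mv` must be a length-2 numeric displacement", call. = FALSE)
  if (is.null(neighbor_mvs) || length(neighbor_mvs) == 0L) return(0)
  if (is.list(neighbor_mvs))
    neighbor_mvs <- do.call(rbind, neighbor_mvs)
  if (is.vector(neighbor_mvs)) neighbor_mvs <- matrix(neighbor_mvs, ncol = 2)
  if (ncol(neighbor_mvs) != 2L || nrow(neighbor_mvs) > 8L)
    stop("`neighbor_mvs` must hold at most 8 length-2 vectors",
         call. = FALSE)
  mean((mv[1] - neighbor_mvs[, 1])^2 + (mv[2] - neighbor_mvs[, 2])^2)
}

#' Smoothness-regularized matching fitness
#'
#' `1 / (1 + mse + lambda * sc)`: a similarity score in `(0, 1]` that is 1
#' exactly when the block matches perfectly and the smoothness penalty
#' vanishes, and strictly decreasing in both terms.
#'
#' @param mse non-negative block MSE.
#' @param sc non-negative smoothness penalty.
#' @param lambda non-negative smoothness weight.
#' @return fitness in `(0, 1]`.
#' @export
fitness <- function(mse, sc, lambda) {
  if (anyNA(c(mse, sc, lambda)) || mse < 0 || sc < 0 || lambda < 0)
    stop("`mse`, `sc` and `lambda` must be finite and non-negative",
         call. = FALSE)
  1 / (1 + mse + lambda * sc)
}

#' Fitness of an integer displacement at a pixel
#'
#' Convenience wrapper combining [block_mse()], [smoothness()] and
#' [fitness()]; returns the full breakdown.
#'
#' @inheritParams block_mse
#' @param neighbor_mvs previous-iteration neighbor vectors (see
#'   [smoothness()]).
#' @param lambda smoothness weight.
#' @return list with components `mse`, `sc`, `fitness`.
#' @export
fitness_breakdown <- function(current, reference, center_x, center_y, mv,
                              neighbor_mvs, n, lambda) {
  mv <- round_away(mv)
  mse <- block_mse(current, reference, center_x, center_y, mv, n)
  sc <- smoothness(mv, neighbor_mvs)
  list(mse = mse, sc = sc, fitness = fitness(mse, sc, lambda))
}
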