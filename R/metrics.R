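#' Motion-compensate a reference frame over an ROI
#'
#' Predicts the current frame from the reference: ROI pixel `(x, y)` is
#' read from `reference(x + ux, y + uy)` with the field's vectors rounded
#' to integers and replicate padding for displaced reads outside the frame
#' (the backward matching convention).
#'
#' @param reference the reference frame matrix.
#' @param field a [motion_field()]; its ROI addresses frame coordinates.
#' @return an `roi$height` x `roi$width` predicted intensity matrix.
#' @export
compensate <- function(reference, field) {
  reference <- as_frame(reference)
  stopifnot(inherits(field, "motion_field"))
  r <- field$roi
  if (!roi_in_frame(r, reference))
    stop("field ROI does not lie inside the reference frame", call. = FALSE)
  gx <- matrix(rep(r$x + 0:(r$width - 1L), each = r$height), r$height)
  gy <- matrix(rep(r$y + 0:(r$height - 1L), times = r$width), r$height)
  sx <- pmin(pmax(gx + round_away(field$ux), 0), ncol(reference) - 1L)
  sy <- pmin(pmax(gy + round_away(field$uy), 0), nrow(reference) - 1L)
  matrix(reference[cbind(as.vector(sy) + 1L, as.vector(sx) + 1L)],
         r$height, r$width)
}

#' Mean square compensation error over an ROI
#'
#' MSE between the current frame's ROI and its motion-compensated
#' prediction from the reference frame.
#'
#' @param current the current frame matrix.
#' @param reference the reference frame matrix.
#' @param field a [motion_field()].
#' @return non-negative MSE.
#' @export
compensation_mse <- function(current, reference, field) {
  current <- as_frame(current)
  r <- field$roi
  crop <- current[r$y + seq_len(r$height), r$x + seq_len(r$width),
                  drop = FALSE]
  mean((crop - compensate(reference, field))^2)
}

#' Peak signal-to-noise ratio for 8-bit imagery
#'
#' `10 * log10(255^2 / mse)`; an MSE of exactly 0 (perfect compensation)
#' is reported as `+Inf`.
#'
#' @param mse non-negative mean square error.
#' @return PSNR in dB.
#' @export
psnr <- function(mse) {
  if (anyNA(mse) || any(mse < 0))
    stop("`mse` must be non-negative", call. = FALSE)
  ifelse(mse > 0, 10 * log10(255^2 / mse), Inf)
}

#' PSNR degradation ratio (percent)
#'
#' `(psnr_ref - psnr_test) / psnr_ref * 100`: the relative quality loss of
#' a test method against a reference baseline.  Negative when the test
#' method wins.  When both PSNRs are infinite (both compensations perfect)
#' the degradation is 0 by convention.
#'
#' @param psnr_ref baseline PSNR (dB), must be positive.
#' @param psnr_test test-method PSNR (dB).
#' @return degradation in percent.
#' @export
d_psnr <- function(psnr_ref, psnr_test) {
  if (anyNA(psnr_ref) || any(psnr_ref <= 0))
    stop("`psnr_ref` must be positive", call. = FALSE)
  ifelse(is.infinite(psnr_ref) & is.infinite(psnr_test),
         0, (psnr_ref - psnr_test) / psnr_ref * 100)
}

#' Computation-saving ratio (percent)
#'
#' `(cost_ref - cost_test) / cost_ref * 100`.  Applicable to wall-clock
#' times or (preferred, hardware-independent) fitness-evaluation counts.
#'
#' @param cost_ref baseline cost, must be positive.
#' @param cost_test test-method cost.
#' @return saving in percent (100 when the test cost is 0).
#' @export
csr <- function(cost_ref, cost_test) {
  if (anyNA(cost_ref) || any(cost_ref <= 0))
    stop("`cost_ref` must be positive", call. = FALSE)
  (cost_ref - cost_test) / cost_ref * 100
}

#' Endpoint error of an estimated field against ground truth
#'
#' @param field,truth [motion_field()]s over matching ROIs.
#' @return list with `mean_error` (mean Euclidean error in pixels) and
#'   `exact_fraction` (fraction of pixels whose rounded vectors agree
#'   exactly).
#' @export
endpoint_error <- function(field, truth) {
  stopifnot(inherits(field, "motion_field"), inherits(truth, "motion_field"))
  if (!all(dim(field$ux) == dim(truth$ux)))
    stop("`field` and `truth` must cover matching ROIs", call. = FALSE)
  dx <- field$ux - truth$ux
  dy <- field$uy - truth$uy
  list(mean_error = mean(sqrt(dx^2 + dy^2)),
       exact_fraction = mean(round_away(field$ux) == round_away(truth$ux) &
                             round_away(field$uy) == round_away(truth$uy)))
}

#' Compare the two estimators over a set of ROIs
#'
#' Runs both the firefly (IFA) and exhaustive (IFSA) estimators on the same
#' frame pair and ROIs and tabulates per-ROI compensated MSE/PSNR, the PSNR
#' degradation ratio of IFA against IFSA, fitness-evaluation counts and the
#' evaluation-count computation-saving ratio.  A final `average` row
#' summarizes the columns.
#'
#' @param sequence a [frame_sequence()].
#' @param frame_index 1-based current-frame index (>= 2).
#' @param rois list of [roi()]s.
#' @param config a [search_config()] for IFA (`config$iterations` sweeps).
#' @param ifsa_iterations sweeps for the IFSA baseline (it converges in far
#'   fewer sweeps than the swarm).
#' @return a `data.frame` with one row per ROI plus an average row.
#' @export
compare_methods <- function(sequence, frame_index, rois, config,
                            ifsa_iterations = 20L) {
  stopifnot(inherits(config, "search_config"))
  if (inherits(rois, "roi")) rois <- list(rois)
  cfg_ifsa <- config
  cfg_ifsa$iterations <- as.integer(ifsa_iterations)
  rows <- lapply(seq_along(rois), function(i) {
    r_ifsa <- estimate_field(sequence, frame_index, rois[[i]], cfg_ifsa,
                             method = "ifsa")
    r_ifa <- estimate_field(sequence, frame_index, rois[[i]], config,
                            method = "ifa")
    cur <- sequence$frames[[frame_index]]
    ref <- sequence$frames[[frame_index - 1L]]
    mse_ifsa <- compensation_mse(cur, ref, r_ifsa$field)
    mse_ifa <- compensation_mse(cur, ref, r_ifa$field)
    p_ifsa <- psnr(mse_ifsa)
    p_ifa <- psnr(mse_ifa)
    data.frame(
      roi = sprintf("ROI %d", i),
      mse_ifsa = mse_ifsa, psnr_ifsa = p_ifsa,
      mse_ifa = mse_ifa, psnr_ifa = p_ifa,
      d_psnr_percent = d_psnr(p_ifsa, p_ifa),
      evals_ifsa = r_ifsa$fitness_evaluations,
      evals_ifa = r_ifa$fitness_evaluations,
      csr_percent = csr(r_ifsa$fitness_evaluations,
                        r_ifa$fitness_evaluations))
  })
  tab <- do.call(rbind, rows)
  avg <- data.frame(roi = "average", t(colMeans(tab[, -1, drop = FALSE])))
  names(avg) <- names(tab)
  rbind(tab, avg)
}
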