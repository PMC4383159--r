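#' Reference in-vivo tendon-tracking benchmark values
#'
#' Per-ROI measurements reported for an in-vivo extensor-tendon B-mode
#' sequence (39 fps, ten 25 x 25-pixel ROIs, 7 x 7 blocks, 15 x 15 search
#' window) tracked with both estimators: compensated MSE and PSNR, wall
#' clock time, the PSNR degradation ratio of the firefly estimator against
#' the exhaustive baseline, and the computation-saving ratio.  The
#' exhaustive baseline ran 20 iterations; the firefly estimator 200 or 300
#' (the `iterations` column).  These printed values are the inputs for the
#' worked-example reproduction of every metric formula — the source images
#' are not available, so the numbers themselves cannot be recomputed from
#' pixels.
#'
#' @param iterations optionally restrict to the 200- or 300-iteration runs.
#' @return a `data.frame` with columns `iterations`, `roi`, `mse_ifsa`,
#'   `psnr_ifsa`, `time_ifsa`, `mse_ifa`, `psnr_ifa`, `time_ifa`,
#'   `d_psnr_percent`, `csr_percent`.
#' @export
tendon_benchmark <- function(iterations = NULL) {
  path <- system.file("extdata", "tendon_benchmark.csv",
                      package = "specklemotion", mustWork = TRUE)
  tab <- utils::read.csv(path)
  if (!is.null(iterations)) tab <- tab[tab$iterations %in% iterations, ]
  tab
}
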