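test_that("speckle rendering is deterministic and handles degenerate input", {
  set.seed(60)
  s <- matrix(rnorm(64 * 64), 64, 64)
  f1 <- render_speckle(s, 2)
  f2 <- render_speckle(s, 2)
  expect_identical(f1, f2)
  expect_true(all(f1 >= 0 & f1 <= 255))
  # all-zero scatterers give a constant frame
  expect_true(all(render_speckle(matrix(0, 32, 32), 2) == 0))
})

test_that("speckle correlation length grows with the PSF width", {
  # autocorrelation area of the envelope (independent FFT measurement)
  autocorr_area <- function(f) {
    x <- f - mean(f)
    ac <- Re(stats::fft(abs(stats::fft(x))^2, inverse = TRUE))
    ac <- ac / ac[1, 1]
    sum(ac > 0.5) / length(ac)
  }
  set.seed(61)
  s <- matrix(rnorm(128 * 128), 128, 128)
  expect_gt(autocorr_area(render_speckle(s, 3.0)),
            autocorr_area(render_speckle(s, 0.5)))
})

test_that("integer translation phantoms shift exactly with valid truth", {
  ph <- generate_sequence(phantom_config(48, 48, motion_translation(2, 1),
                                         seed = 62))
  f0 <- ph$sequence$frames[[1]]
  f1 <- ph$sequence$frames[[2]]
  # cur(x, y) == ref(x + 2, y + 1) wherever both sides are in frame
  expect_equal(f1[1:47, 1:46], f0[1 + 1:47, 2 + 1:46])
  # cross-correlation peak sits at the true shift
  cc <- Re(stats::fft(stats::fft(f1 - mean(f1)) *
                      Conj(stats::fft(f0 - mean(f0))), inverse = TRUE))
  peak <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  # circular correlation places a shift (dx, dy) at index (N - dy, N - dx) + 1
  expect_equal(unname(peak), c(48 - 1 + 1, 48 - 2 + 1))
  # truth is the constant (2, 1) field over the full frame
  expect_true(all(ph$truth[[1]]$ux == 2))
  expect_true(all(ph$truth[[1]]$uy == 1))
  # block MSE at the truth is exactly 0 for interior blocks
  for (c in list(c(20, 20), c(10, 30), c(35, 12))) {
    expect_equal(block_mse(f1, f0, c[1], c[2], c(2, 1), 7), 0)
  }
})

test_that("zero motion with zero noise yields identical frames", {
  ph <- generate_sequence(phantom_config(32, 32, motion_translation(0, 0),
                                         frames = 3, seed = 63))
  expect_identical(ph$sequence$frames[[1]], ph$sequence$frames[[2]])
  expect_identical(ph$sequence$frames[[2]], ph$sequence$frames[[3]])
})

test_that("phantom generation is bit-reproducible for a fixed seed", {
  cfg <- phantom_config(32, 32, motion_sinusoidal(2, 16),
                        decorrelation_noise_sigma = 5, seed = 64)
  a <- generate_sequence(cfg)
  b <- generate_sequence(cfg)
  expect_identical(a$sequence$frames, b$sequence$frames)
  expect_identical(a$truth, b$truth)
})

test_that("displacements beyond the search window are rejected", {
  expect_error(generate_sequence(
    phantom_config(32, 32, motion_translation(9, 0), max_displacement = 7)),
    "exceeds")
  expect_error(generate_sequence(
    phantom_config(32, 32, motion_sinusoidal(8, 16), max_displacement = 7)),
    "exceeds")
})

test_that("decorrelation noise degrades the best attainable match", {
  best_mse <- function(sigma, seed) {
    ph <- generate_sequence(phantom_config(
      40, 40, motion_translation(2, 1), decorrelation_noise_sigma = sigma,
      seed = seed))
    cfg <- search_config(search_width = 3, lambda = 0, iterations = 1,
                         seed = seed)
    res <- estimate_field(ph$sequence, 2, roi(12, 12, 8, 8), cfg,
                          method = "ifsa")
    mean(1 / res$fitness - 1)  # per-pixel best-match MSE from fitness
  }
  m <- sapply(c(0, 6, 15), function(s)
    mean(sapply(1:6, function(seed) best_mse(s, seed))))
  expect_lt(m[1], m[2])
  expect_lt(m[2], m[3])
})

test_that("non-integer motion produces continuous truth flagged per pixel", {
  ph <- generate_sequence(phantom_config(32, 32, motion_affine(
    matrix(c(0.02, 0, 0.5, 0, 0.02, -0.5), 2, 3, byrow = TRUE)),
    seed = 65))
  expect_false(all(ph$truth[[1]]$ux == round(ph$truth[[1]]$ux)))
  expect_identical(dim(ph$truth[[1]]$ux), c(32L, 32L))
  # displacement magnitudes stay within the declared window
  expect_lte(max(abs(ph$truth[[1]]$ux), abs(ph$truth[[1]]$uy)), 7)
})
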