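# Programmatic fixtures and independent oracles shared across the suite.

# non-repeating textured frame: random 8-bit intensities
textured_frame <- function(h, w, seed = 1) {
  set.seed(seed)
  matrix(sample(0:255, h * w, replace = TRUE) + 0, h, w)
}

# frame pair where cur(x, y) == ref(x + dx, y + dy) exactly (interior and
# borders alike, both cropped from one larger texture)
shifted_pair <- function(h, w, dx, dy, seed = 1, margin = 10) {
  big <- textured_frame(h + 2 * margin, w + 2 * margin, seed)
  ref <- big[margin + seq_len(h), margin + seq_len(w)]
  cur <- big[margin + dy + seq_len(h), margin + dx + seq_len(w)]
  list(cur = cur, ref = ref)
}

# independent block MSE oracle: direct clamped indexing, no package code
oracle_block_mse <- function(cur, ref, cx, cy, ux, uy, n) {
  hw <- (n - 1) / 2
  x1 <- pmin(pmax((cx - hw):(cx + hw), 0), ncol(cur) - 1)
  y1 <- pmin(pmax((cy - hw):(cy + hw), 0), nrow(cur) - 1)
  x2 <- pmin(pmax((cx + ux - hw):(cx + ux + hw), 0), ncol(ref) - 1)
  y2 <- pmin(pmax((cy + uy - hw):(cy + uy + hw), 0), nrow(ref) - 1)
  mean((cur[y1 + 1, x1 + 1] - ref[y2 + 1, x2 + 1])^2)
}

# brute-force argmin-MSE field oracle (lambda = 0 reference); ties broken
# by the first minimizer in row-major (uy, ux) order from (-W, -W)
oracle_min_mse_field <- function(cur, ref, r, n, W) {
  ux <- matrix(NA_real_, r$height, r$width)
  uy <- matrix(NA_real_, r$height, r$width)
  for (iy in seq_len(r$height)) {
    for (ix in seq_len(r$width)) {
      best <- Inf
      bu <- c(NA, NA)
      for (vy in -W:W) {
        for (vx in -W:W) {
          m <- oracle_block_mse(cur, ref, r$x + ix - 1, r$y + iy - 1,
                                vx, vy, n)
          if (m < best) {
            best <- m
            bu <- c(vx, vy)
          }
        }
      }
      ux[iy, ix] <- bu[1]
      uy[iy, ix] <- bu[2]
    }
  }
  list(ux = ux, uy = uy)
}

# crop a full-frame truth field to an ROI
crop_truth <- function(truth, r) {
  motion_field(truth$ux[r$y + seq_len(r$height), r$x + seq_len(r$width),
                        drop = FALSE],
               truth$uy[r$y + seq_len(r$height), r$x + seq_len(r$width),
                        drop = FALSE], r)
}

exact_fraction_interior <- function(field, truth_cropped) {
  i <- 2:(nrow(field$ux) - 1)
  j <- 2:(ncol(field$ux) - 1)
  mean(field$ux[i, j] == truth_cropped$ux[i, j] &
       field$uy[i, j] == truth_cropped$uy[i, j])
}
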