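test_that("firefly primitives follow their closed forms", {
  expect_equal(firefly_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(firefly_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(firefly_distance(c(-1, 2), c(2, -2)), 5)

  expect_equal(attractiveness(1, 2, 0), 1)
  expect_equal(attractiveness(1, 1, log(4)), 0.25)
  expect_equal(attractiveness(2, 1, 0), 1)  # clamped
  expect_error(attractiveness(0, 1, 1), "beta0")

  expect_equal(move_firefly(c(2, 3), c(-4, 1), 0, c(0, 0), 7), c(2, 3))
  expect_equal(move_firefly(c(2, 3), c(-4, 1), 1, c(0, 0), 7), c(-4, 1))
  expect_equal(move_firefly(c(-2, 4), c(4, 0), 0.5, c(0, 0), 7), c(1, 2))
  expect_equal(move_firefly(c(6, 6), c(7, 7), 1, c(0.4, 0.4), 7), c(7, 7))

  expect_equal(random_walk(c(1, 1), c(0, 0), 7), c(1, 1))
  expect_equal(random_walk(c(7, 7), c(0.4, 0.4), 7), c(7, 7))
  expect_equal(random_walk(c(0, 0), c(0.3, -0.2), 7), c(0.3, -0.2))
})

test_that("exhaustive pixel search equals the brute-force oracle", {
  p <- shifted_pair(32, 32, 3, -2, seed = 20)
  cfg <- search_config(search_width = 4, lambda = 0)
  res <- ifsa_estimate_pixel(p$cur, p$ref, 16, 16, NULL, cfg)
  expect_equal(res$mv, c(3, -2))
  expect_equal(res$brightness, 1)
  expect_equal(res$evaluations, (2 * 4 + 1)^2)
  # with smoothness: compare the full fitness against R-composed values
  set.seed(21)
  nb <- matrix(runif(16, -4, 4), 8, 2)
  cfg1 <- search_config(search_width = 4, lambda = 1.5)
  res1 <- ifsa_estimate_pixel(p$cur, p$ref, 10, 20, nb, cfg1)
  cand <- expand.grid(ux = -4:4, uy = -4:4)  # row-major (uy, ux) order
  fits <- mapply(function(ux, uy) {
    fitness(block_mse(p$cur, p$ref, 10, 20, c(ux, uy), 7),
            smoothness(c(ux, uy), nb), 1.5)
  }, cand$ux, cand$uy)
  k <- which.max(fits)
  expect_equal(res1$mv, c(cand$ux[k], cand$uy[k]))
  expect_equal(res1$brightness, fits[k])
})

test_that("swarm search finds the zero vector on identical frames", {
  f <- textured_frame(32, 32, seed = 22)
  cfg <- search_config(lambda = 0, iterations = 200)
  set.seed(1)
  res <- ifa_estimate_pixel(f, f, 16, 16, NULL, cfg)
  expect_equal(res$mv, c(0, 0))
  expect_equal(res$brightness, 1)
})

test_that("exhaustive initial swarm coverage finds the optimum in one sweep", {
  # W = 1, m = 9 fireflies placed on all 9 integer displacements: after one
  # sweep the elite record must equal the brute-force argmin MSE
  p <- shifted_pair(24, 24, 1, -1, seed = 23)
  cfg <- search_config(search_width = 1, swarm_size = 9, lambda = 0,
                       iterations = 1)
  init <- as.matrix(expand.grid(ux = -1:1, uy = -1:1))
  set.seed(2)
  res <- ifa_estimate_pixel(p$cur, p$ref, 12, 12, NULL, cfg, init = init)
  mses <- apply(init, 1, function(u)
    block_mse(p$cur, p$ref, 12, 12, u, 7))
  expect_equal(res$mv, unname(init[which.min(mses), ]))
})

test_that("field estimation with lambda = 0 and one sweep matches the oracle", {
  set.seed(30)
  cur <- textured_frame(32, 32, seed = 31)
  ref <- textured_frame(32, 32, seed = 32)
  r <- roi(12, 12, 6, 6)
  cfg <- search_config(search_width = 3, lambda = 0, iterations = 1)
  res <- estimate_field(frame_sequence(list(ref, cur)), 2, r, cfg,
                        method = "ifsa")
  orc <- oracle_min_mse_field(cur, ref, r, 7, 3)
  expect_equal(res$field$ux, orc$ux)
  expect_equal(res$field$uy, orc$uy)
  expect_equal(res$fitness_evaluations, 36 * 49)
})

test_that("estimated fields respect the clamp invariant", {
  ph <- generate_sequence(phantom_config(40, 40, motion_translation(1, 0),
                                         seed = 33))
  r <- roi(12, 12, 10, 10)
  cfg <- search_config(search_width = 3, iterations = 15, seed = 5)
  for (m in c("ifa", "ifsa")) {
    res <- estimate_field(ph$sequence, 2, r, cfg, method = m)
    expect_true(all(abs(res$field$ux) <= 3))
    expect_true(all(abs(res$field$uy) <= 3))
    expect_true(all(res$field$ux == round(res$field$ux)))
  }
})

test_that("a dominant smoothness weight drives the field to spatial constancy", {
  set.seed(34)
  cur <- textured_frame(40, 40, seed = 35)
  ref <- textured_frame(40, 40, seed = 36)
  r <- roi(14, 14, 10, 10)
  cfg <- search_config(search_width = 3, lambda = 1e6, iterations = 30,
                       seed = 6)
  res <- estimate_field(frame_sequence(list(ref, cur)), 2, r, cfg,
                        method = "ifsa")
  expect_lte(length(unique(as.vector(res$field$ux))), 2)
  expect_lte(length(unique(as.vector(res$field$uy))), 2)
  expect_lte(max(res$field$ux) - min(res$field$ux), 1)
})

test_that("both estimators recover a noiseless uniform translation", {
  ph <- generate_sequence(phantom_config(48, 48, motion_translation(2, 1),
                                         seed = 37))
  r <- roi(14, 14, 15, 15)
  tru <- crop_truth(ph$truth[[1]], r)
  cfg_fsa <- search_config(iterations = 10, seed = 7)
  res_fsa <- estimate_field(ph$sequence, 2, r, cfg_fsa, method = "ifsa")
  expect_equal(res_fsa$field$ux, tru$ux)
  expect_equal(res_fsa$field$uy, tru$uy)
  cfg_ifa <- search_config(iterations = 200, seed = 7)
  res_ifa <- estimate_field(ph$sequence, 2, r, cfg_ifa, method = "ifa")
  expect_gte(endpoint_error(res_ifa$field, tru)$exact_fraction, 0.95)
})

test_that("swarm re-initialization outperforms persistent swarms on
           speckle with a narrow correlation basin", {
  ph <- generate_sequence(phantom_config(48, 48, motion_translation(2, 1),
                                         seed = 44))
  r <- roi(14, 14, 15, 15)
  tru <- crop_truth(ph$truth[[1]], r)
  rec <- sapply(c(FALSE, TRUE), function(persist) {
    cfg <- search_config(iterations = 200, seed = 9,
                         persist_swarms = persist)
    res <- estimate_field(ph$sequence, 2, r, cfg, method = "ifa")
    endpoint_error(res$field, tru)$exact_fraction
  })
  expect_gte(rec[1], 0.95)   # re-initialized (default)
  expect_lt(rec[2], rec[1])  # persistent swarms collapse early
})

test_that("runs are deterministic given the seed", {
  ph <- generate_sequence(phantom_config(40, 40, motion_translation(1, 1),
                                         seed = 40))
  r <- roi(12, 12, 8, 8)
  cfg <- search_config(search_width = 3, iterations = 25, seed = 11)
  for (m in c("ifa", "ifsa")) {
    a <- estimate_field(ph$sequence, 2, r, cfg, method = m)
    b <- estimate_field(ph$sequence, 2, r, cfg, method = m)
    expect_identical(a$field, b$field)
    expect_identical(a$fitness_evaluations, b$fitness_evaluations)
  }
})

test_that("the elite record per pixel is non-decreasing across sweeps", {
  # same seed: the first 10 sweeps of a 20-sweep run consume the same
  # random stream, so the 20-sweep elite fitness must dominate pointwise
  ph <- generate_sequence(phantom_config(40, 40, motion_translation(2, 0),
                                         seed = 41))
  r <- roi(12, 12, 8, 8)
  cfg10 <- search_config(iterations = 10, seed = 12)
  cfg20 <- search_config(iterations = 20, seed = 12)
  f10 <- estimate_field(ph$sequence, 2, r, cfg10, method = "ifa")
  f20 <- estimate_field(ph$sequence, 2, r, cfg20, method = "ifa")
  expect_true(all(f20$fitness >= f10$fitness))
})

test_that("swarm evaluation counts stay below the exhaustive budget", {
  ph <- generate_sequence(phantom_config(40, 40, motion_translation(1, 0),
                                         seed = 42))
  r <- roi(12, 12, 8, 8)
  res_ifa <- estimate_field(ph$sequence, 2, r,
                            search_config(iterations = 200, seed = 13),
                            method = "ifa")
  res_fsa <- estimate_field(ph$sequence, 2, r,
                            search_config(iterations = 20, seed = 13),
                            method = "ifsa")
  expect_lt(res_ifa$fitness_evaluations, res_fsa$fitness_evaluations)
  expect_equal(res_fsa$fitness_evaluations, 64 * 225 * 20)
  # per pixel per sweep the swarm spends at most 2m evaluations
  expect_lte(res_ifa$fitness_evaluations, 64 * 200 * 2 * 5)
})

test_that("frame and ROI preconditions are enforced", {
  ph <- generate_sequence(phantom_config(32, 32, motion_translation(1, 0),
                                         seed = 43))
  cfg <- search_config(iterations = 1)
  expect_error(estimate_field(ph$sequence, 1, roi(4, 4, 4, 4), cfg),
               "predecessor")
  expect_error(estimate_field(ph$sequence, 2, roi(28, 28, 10, 10), cfg),
               "inside")
})
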