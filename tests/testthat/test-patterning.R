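test_that("estimate_affine recovers generating transforms", {
  # identity from identity pairs
  cam <- cbind(c(0, 100, 0), c(0, 0, 100))
  m <- estimate_affine(cam, cam)
  expect_equal(m$coefficients, cbind(diag(2), c(0, 0)), tolerance = 1e-12)
  expect_lt(attr(m, "rms_residual"), 1e-12)

  # scale 0.5 + translation (30, 40) on 5 random points
  set.seed(3)
  cam <- matrix(runif(10, 0, 1000), 5, 2)
  dmd <- 0.5 * cam + matrix(rep(c(30, 40), each = 5), 5, 2)
  m <- estimate_affine(cam, dmd)
  expect_equal(m$coefficients, cbind(0.5 * diag(2), c(30, 40)),
               tolerance = 1e-9)

  # collinear points and too few points
  line <- cbind(1:3, 2 * (1:3))
  expect_error(estimate_affine(line, line), "collinear")
  expect_error(estimate_affine(cam[1:2, ], dmd[1:2, ]), ">= 3")
})

test_that("random affine transforms are recovered from exact pairs", {
  set.seed(21)
  for (i in 1:100) {
    repeat {
      A <- matrix(runif(4, -2, 2), 2, 2)
      if (abs(det(A)) >= 0.1 && abs(det(A)) <= 10) break
    }
    b <- runif(2, -50, 50)
    cam <- matrix(runif(12, 0, 500), 6, 2)
    dmd <- t(A %*% t(cam) + b)
    m <- estimate_affine(cam, dmd)
    expect_lt(max(abs(m$coefficients - cbind(A, b))), 1e-9)
  }
})

test_that("apply_affine and invert_affine compose to the identity", {
  m <- affine_map(rbind(c(1.2, 0.1, 30), c(-0.2, 0.9, -10)))
  pts <- matrix(runif(20, 0, 100), 10, 2)
  back <- apply_affine(invert_affine(m), apply_affine(m, pts))
  expect_equal(back, pts, tolerance = 1e-10)
  expect_error(affine_map(rbind(c(1, 2, 0), c(2, 4, 0))), "degenerate")
})

test_that("mask_to_dmd equals the brute-force pullback", {
  set.seed(14)
  shapes <- list(identity = affine_map(cbind(diag(2), c(0, 0))),
                 general = affine_map(rbind(c(0.8, 0.15, 5),
                                            c(-0.1, 1.1, 3))))
  for (m in shapes) {
    mask <- matrix(runif(64 * 64) > 0.7, 64, 64)
    got <- suppressWarnings(mask_to_dmd(mask, m, dmd_shape = c(64L, 64L)))
    want <- naive_mask_to_dmd(mask, m, c(64L, 64L))
    expect_identical(unname(got[, ]), want)
  }

  # identity map, equal shapes: output equals input
  mask <- matrix(FALSE, 32, 32); mask[10:20, 5:15] <- TRUE
  id <- affine_map(cbind(diag(2), c(0, 0)))
  out <- mask_to_dmd(mask, id, dmd_shape = c(32L, 32L))
  expect_identical(unname(out[, ]), mask)
  expect_equal(attr(out, "clipped_fraction"), 0)

  # mask entirely outside the DMD footprint: all false, 100% clipped
  far <- affine_map(cbind(diag(2), c(5000, 5000)))
  expect_warning(out <- mask_to_dmd(mask, far, dmd_shape = c(32L, 32L)),
                 "clipped")
  expect_false(any(out))
  expect_equal(attr(out, "clipped_fraction"), 1)

  # pure translation preserves the pixel count up to the perimeter
  tr <- affine_map(cbind(diag(2), c(3.3, -2.7)))
  out <- suppressWarnings(mask_to_dmd(mask, tr, dmd_shape = c(32L, 32L)))
  perim <- 2 * (11 + 11)
  expect_lt(abs(sum(out) - sum(mask)), perim)
})

test_that("tile grids partition the extent", {
  # the reference 12 x 8 grid over 1.2 x 1.0 mm: 96 tiles of 0.0125 mm^2
  g <- tile_grid(extent = c(1.2, 1.0), n_cols = 12, n_rows = 8)
  expect_equal(tile_area(g), 0.0125)
  ps <- 0.0027
  rs <- make_tile_grid(g, ps, frame_shape = c(512L, 512L))
  expect_length(rs$masks, 96L)
  # disjoint and exact cover of the in-extent pixels
  total <- Reduce(`+`, lapply(rs$masks, `*`, 1L))
  expect_true(all(total <= 1L))
  inside_px <- sum(total)
  expect_equal(inside_px, round(1.2 / ps) * round(1.0 / ps), tolerance = 0.01)
  expect_equal(sum(vapply(rs$masks, sum, numeric(1))), inside_px)
  # pixel-count areas agree with the geometric tile area
  expect_equal(unname(rs$areas), rep(tile_area(g), 96), tolerance = 0.05)

  # 1 x 1 grid: a single tile covering the full extent
  g1 <- tile_grid(extent = c(0.5, 0.5), n_cols = 1, n_rows = 1)
  rs1 <- make_tile_grid(g1, ps, frame_shape = c(256L, 256L))
  expect_length(rs1$masks, 1L)
  expect_equal(tile_area(g1), 0.25)

  # partition holds for assorted shapes
  for (shape in list(c(3, 5), c(7, 2), c(1, 9))) {
    g2 <- tile_grid(origin = c(10, 20), extent = c(0.31, 0.17),
                    n_cols = shape[1], n_rows = shape[2])
    rs2 <- make_tile_grid(g2, ps, frame_shape = c(256L, 256L))
    tot <- Reduce(`+`, lapply(rs2$masks, `*`, 1L))
    expect_true(all(tot <= 1L))
    expect_equal(sum(vapply(rs2$masks, sum, numeric(1))), sum(tot))
  }
  expect_error(tile_grid(extent = c(-1, 1), n_cols = 2, n_rows = 2),
               "positive")
})

test_that("duty cycle and acquisition plans match the instrument numbers", {
  # 20-us pulses at 3 kHz: 6% duty cycle
  expect_equal(duty_cycle(20e-6, 3000), 0.06)
  expect_equal(duty_cycle(0, 3000), 0)
  expect_error(duty_cycle(500e-6, 3000), "infeasible")

  # 96 tiles at 10 Hz: 9.6 s
  plan <- acquisition_plan(pattern_schedule(n_patterns = 96L))
  expect_equal(plan$total_time, 9.6)
  expect_equal(plan$per_pattern_decay_time, 200 / 3000)
  expect_true(plan$feasible)  # 66.7 ms <= 100 ms

  # the faster published alternative: 50 Hz with 40 decays
  plan50 <- acquisition_plan(pattern_schedule(pattern_rate = 50,
                                              decays_per_pattern = 40L,
                                              n_patterns = 96L))
  expect_equal(plan50$per_pattern_decay_time, 40 / 3000)
  expect_true(plan50$feasible)  # 13.3 ms <= 20 ms

  # increasing decays_per_pattern never makes an infeasible plan feasible
  feas <- vapply(seq(50L, 500L, by = 50L), function(d)
    acquisition_plan(pattern_schedule(pattern_rate = 10, d,
                                      n_patterns = 1L))$feasible, logical(1))
  expect_true(all(diff(as.integer(feas)) <= 0))
})

test_that("pixel scale comes from the field of view", {
  # 3.5 x 2.8 mm on 1280 x 1024 pixels
  expect_equal(pixel_scale_from_fov(c(3.5, 2.8), c(1280, 1024)),
               mean(c(3.5 / 1280, 2.8 / 1024)), tolerance = 1e-12)
  expect_equal(pixel_scale_from_fov(c(3.5, 2.8), c(1280, 1024)), 0.002734,
               tolerance = 1e-3)
  expect_equal(pixel_scale_from_fov(c(1, 1), c(1000, 1000)), 0.001)
  expect_error(pixel_scale_from_fov(c(2, 1), c(1000, 1000)), "anisotropic")
})
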