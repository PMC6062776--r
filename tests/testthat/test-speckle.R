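test_that("compute_contrast matches the definition and flags borders", {
  # constant frame: zero variance everywhere
  ci <- compute_contrast(matrix(100, 20, 20), window = 7)
  expect_true(all(ci$K[ci$valid_mask] == 0))
  # border band of width (window-1)/2 is invalid
  expect_false(any(ci$valid_mask[1:3, ]))
  expect_false(any(ci$valid_mask[, 18:20]))
  expect_true(all(is.na(ci$K[!ci$valid_mask])))

  # single 7x7 patch with values 1..49: center K from direct evaluation
  patch <- matrix(1:49, 7, 7)
  ci <- compute_contrast(patch, window = 7, bias_correct = FALSE)
  mu <- mean(1:49)
  expect_equal(ci$K[4, 4], sqrt(mean((1:49 - mu)^2)) / mu, tolerance = 1e-12)
  expect_equal(sum(ci$valid_mask), 1L)

  # zero window mean: flagged invalid, no error
  f <- matrix(10, 9, 9); f[1:7, 1:7] <- 0
  ci <- compute_contrast(f, window = 7)
  expect_false(ci$valid_mask[4, 4])
  expect_true(ci$valid_mask[6, 6])

  expect_error(compute_contrast(matrix(1, 10, 10), window = 6), "odd")
  expect_error(compute_contrast(matrix(1, 5, 5), window = 7), "smaller")
})

test_that("fast box-filter contrast equals the naive two-pass oracle", {
  set.seed(101)
  for (i in 1:5) {
    f <- matrix(rgamma(64 * 64, shape = 2, scale = 100), 64, 64)
    fast <- compute_contrast(f, window = 7, bias_correct = FALSE)
    ref <- naive_contrast(f, 7)
    idx <- fast$valid_mask
    expect_lt(max(abs(fast$K[idx] - ref[idx]) / ref[idx]), 1e-12)
  }
  # also for the smallest window
  f <- matrix(runif(30 * 40, 1, 2), 30, 40)
  fast <- compute_contrast(f, window = 3, bias_correct = FALSE)
  ref <- naive_contrast(f, 3)
  expect_lt(max(abs(fast$K - ref) / ref, na.rm = TRUE), 1e-12)
})

test_that("average_contrast is a pixelwise mean with invalid propagation", {
  f1 <- matrix(runif(144, 90, 110), 12, 12)
  ci1 <- compute_contrast(f1)
  # mean of identical images is the image
  avg <- average_contrast(list(ci1, ci1, ci1))
  expect_equal(avg$K, ci1$K)
  expect_equal(avg$n_averaged, 3L)

  ci2 <- compute_contrast(matrix(runif(144, 90, 110), 12, 12))
  avg <- average_contrast(list(ci1, ci2))
  expect_equal(avg$K[6, 6], (ci1$K[6, 6] + ci2$K[6, 6]) / 2)

  # a pixel invalid in one input is invalid in the mean
  ci2$valid_mask[6, 6] <- FALSE; ci2$K[6, 6] <- NA_real_
  avg <- average_contrast(list(ci1, ci2))
  expect_false(avg$valid_mask[6, 6])
  expect_true(is.na(avg$K[6, 6]))

  expect_error(average_contrast(list()), "non-empty")
  ci3 <- compute_contrast(matrix(runif(100, 90, 110), 10, 10))
  expect_error(average_contrast(list(ci1, ci3)), "shapes")
  ci4 <- compute_contrast(f1, window = 5)
  expect_error(average_contrast(list(ci1, ci4)), "window")
})

test_that("contrast_from_tau evaluates the exposure model", {
  p <- speckle_params(beta = 1, exposure_T = 5e-3)
  # x = 1: K = sqrt((exp(-2) + 1) / 2)
  expect_equal(contrast_from_tau(5e-3, p), sqrt((exp(-2) + 1) / 2),
               tolerance = 1e-12)
  expect_equal(contrast_from_tau(5e-3, p), 0.753437, tolerance = 1e-6)
  # tau >> T: K -> 1
  expect_equal(contrast_from_tau(5e3, p), 1, tolerance = 1e-6)
  # beta = 0.25, x -> 0: K -> 0.5
  expect_equal(contrast_from_tau(5e3, speckle_params(0.25, 5e-3)), 0.5,
               tolerance = 1e-6)
  expect_error(contrast_from_tau(-1, p), "positive")
  expect_error(contrast_from_tau(0, p), "positive")
})

test_that("series and direct branches of the model agree", {
  T_ <- 5e-3
  p <- speckle_params(exposure_T = T_)
  # series region: agree with a cancellation-safe direct evaluation
  x <- 10^seq(-6, -3, length.out = 61)
  direct <- expm1_speckle_K(T_ / x, T_)
  expect_lt(max(abs(contrast_from_tau(T_ / x, p) - direct) / direct), 1e-10)
  # moderate x: agree with the plain textbook form
  x2 <- 10^seq(-2, 1, length.out = 31)
  plain <- plain_speckle_K(T_ / x2, T_)
  expect_lt(max(abs(contrast_from_tau(T_ / x2, p) - plain) / plain), 1e-12)
  # continuity at the switch itself
  eps <- 1e-9
  expect_equal(contrast_from_tau(T_ / (1e-3 - eps), p),
               contrast_from_tau(T_ / (1e-3 + eps), p), tolerance = 1e-9)
})

test_that("contrast model is monotone and inverts to 1e-9", {
  p <- speckle_params(exposure_T = 5e-3)
  taus <- 10^seq(-6, -1, length.out = 50)
  K <- contrast_from_tau(taus, p)
  expect_true(all(diff(K) > 0))              # strictly increasing in tau_c
  back <- invert_contrast(K, p)
  expect_lt(max(abs(back - taus) / taus), 1e-9)
  expect_true(all(diff(back) > 0))           # increasing in K

  # x = 1 roundtrip at the frozen value
  expect_equal(invert_contrast(0.753437, p), 5e-3, tolerance = 1e-5)
  # K at/above sqrt(beta): no finite tau
  expect_true(is.na(invert_contrast(1.0, p)))
  expect_true(is.na(invert_contrast(1.2, p)))
  expect_true(is.na(invert_contrast(0, p)))
  expect_error(invert_contrast(1.0, p, strict = TRUE), "out of model")
})

test_that("flow_map inverts per pixel and isolates bad pixels", {
  p <- speckle_params(exposure_T = 5e-3)
  K <- matrix(0.753437, 10, 10)
  ci <- compute_contrast(matrix(100, 10, 10))  # geometry donor
  ci$K <- K; ci$valid_mask[] <- TRUE; ci$exposure_T <- 5e-3
  fm <- flow_map(ci, p)
  expect_equal(unname(fm$tau_c[5, 5]), 5e-3, tolerance = 1e-5)
  expect_equal(fm$icr, 1 / fm$tau_c)

  ci$K[3, 3] <- 1.2                            # out of model
  fm <- flow_map(ci, p)
  expect_false(fm$valid_mask[3, 3])
  expect_true(all(is.finite(fm$tau_c[fm$valid_mask])))
  expect_equal(sum(!fm$valid_mask), 1L)

  ci$valid_mask[] <- FALSE
  expect_error(flow_map(ci, p), "no valid pixels")
})

test_that("relative_flow is the ratio of ROI-median correlation times", {
  p <- speckle_params(exposure_T = 5e-3)
  set.seed(7)
  tau <- matrix(exp(rnorm(400, log(5e-3), 0.2)), 20, 20)
  mk_fm <- function(tau) {
    ci <- compute_contrast(matrix(100, 20, 20))
    ci$K <- matrix(contrast_from_tau(as.vector(tau), p), 20)
    ci$valid_mask[] <- TRUE; ci$exposure_T <- 5e-3
    flow_map(ci, p)
  }
  base <- mk_fm(tau)
  rois <- roi_set(list(a = matrix(rep(c(TRUE, FALSE), each = 200), 20),
                       b = matrix(rep(c(FALSE, TRUE), each = 200), 20)),
                  pixel_scale = 0.0027)
  # identity: exactly 1 everywhere
  rf <- relative_flow(base, base, rois)
  expect_equal(rf$rcbf, c(1, 1))
  # uniform doubling of tau_c: rCBF = 0.5 in every region
  rf <- relative_flow(mk_fm(2 * tau), base, rois)
  expect_equal(rf$rcbf, c(0.5, 0.5), tolerance = 1e-9)
  # region without valid pixels: missing with a warning, others intact
  cur <- mk_fm(tau)
  cur$valid_mask[, 11:20] <- FALSE
  expect_warning(rf <- relative_flow(cur, base, rois), "no valid pixels")
  expect_true(is.na(rf$rcbf[2]))
  expect_false(is.na(rf$rcbf[1]))
})

test_that("simulated uniform stacks recover tau_c within 3%", {
  p <- speckle_params(exposure_T = 5e-3)
  sc <- speckle_scenario(matrix(5e-3, 128, 128), n_frames = 45, seed = 11)
  st <- synth_speckle_stack(sc)
  ci <- average_contrast(compute_contrast(st$stack))
  expect_equal(mean(ci$K[ci$valid_mask]), 0.753437, tolerance = 0.01)
  fm <- flow_map(ci, p)
  expect_equal(median(fm$tau_c[fm$valid_mask]), 5e-3, tolerance = 0.03)
})
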