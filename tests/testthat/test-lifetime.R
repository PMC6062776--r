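test_that("average_decays is a pointwise mean with accumulated count", {
  t <- seq(0, 1e-4, by = 1e-8)
  tr <- decay_trace(t, exp(-t / 2e-5), n_averaged = 100L)
  avg <- average_decays(list(tr, tr))
  expect_equal(avg$signal, tr$signal)
  expect_equal(avg$n_averaged, 200L)

  neg <- decay_trace(t, -tr$signal, n_averaged = 100L)
  expect_equal(average_decays(list(tr, neg))$signal, rep(0, length(t)))

  other <- decay_trace(t + 1e-6, tr$signal, n_averaged = 1L)
  expect_error(average_decays(list(tr, other)), "time base")
})

test_that("averaging n noisy traces shrinks noise like 1/sqrt(n)", {
  t <- seq(0, 1e-4, by = 1e-8)
  set.seed(42)
  mk <- function() decay_trace(t, rnorm(length(t), sd = 1))
  avg <- average_decays(replicate(100, mk(), simplify = FALSE))
  ratio <- 1 / sd(avg$signal)    # single-trace sd is 1
  expect_equal(ratio, 10, tolerance = 0.15)
})

test_that("instrument offset trims, re-zeroes and preserves the lifetime", {
  cal <- paper_cal()
  tr <- synth_decay(50, cal, A = 0.1, B = 2, sample_rate = 100e6,
                    duration = 300e-6, noise_sd = 0, seed = 1)
  off <- apply_instrument_offset(tr, 2e-6)
  # 2 us at 100 MHz: exactly 200 samples removed, time re-zeroed
  expect_equal(length(off$t), length(tr$t) - 200L)
  expect_equal(off$t[1], 0)
  expect_true(off$offset_applied)
  expect_error(apply_instrument_offset(off), "already applied")
  expect_error(apply_instrument_offset(tr, 1), "shorter than")

  # zero offset: identity on the samples
  id <- apply_instrument_offset(tr, 0)
  expect_equal(id$signal, tr$signal)

  # exponential shift: same tau, amplitude scaled by exp(-offset/tau)
  tau_true <- tau_from_pO2(50, cal)
  ft <- fit_decay(off)
  expect_equal(ft$tau, tau_true, tolerance = 1e-6)
  expect_equal(ft$B, 2 * exp(-2e-6 / tau_true), tolerance = 1e-6)
  expect_equal(ft$A, 0.1, tolerance = 1e-6)
})

test_that("fit_decay recovers noiseless parameters and gates failures", {
  t <- seq(0, 300e-6, by = 1e-8)
  tr <- decay_trace(t, 0.02 + 1.0 * exp(-t / 20e-6), offset_applied = TRUE)
  ft <- fit_decay(tr)
  expect_true(ft$converged)
  expect_equal(ft$A, 0.02, tolerance = 1e-6)
  expect_equal(ft$B, 1.0, tolerance = 1e-6)
  expect_equal(ft$tau, 20e-6, tolerance = 1e-6)
  expect_lt(ft$rss, 1e-12)

  # anoxic decay generated through the calibration: tau = 47 us
  anx <- apply_instrument_offset(
    suppressWarnings(synth_decay(0, paper_cal(), noise_sd = 0)))
  expect_equal(fit_decay(anx)$tau, 47e-6, tolerance = 1e-6)

  # flat trace plus noise: no decaying component
  set.seed(5)
  flat <- decay_trace(t, rnorm(length(t), mean = 1, sd = 0.05),
                      offset_applied = TRUE)
  expect_false(fit_decay(flat)$converged)

  expect_error(fit_decay(decay_trace(t, rep(1, length(t)),
                                     offset_applied = TRUE)), "constant")
  raw <- decay_trace(t, exp(-t / 2e-5))
  expect_error(fit_decay(raw), "offset")
})

test_that("fit is equivariant under signal scaling", {
  t <- seq(0, 300e-6, by = 2e-8)
  set.seed(9)
  y <- 0.05 + 0.8 * exp(-t / 30e-6) + rnorm(length(t), sd = 1e-3)
  f1 <- fit_decay(decay_trace(t, y, offset_applied = TRUE))
  f2 <- fit_decay(decay_trace(t, 100 * y, offset_applied = TRUE))
  expect_equal(f2$tau, f1$tau, tolerance = 1e-9)
  expect_equal(f2$A / f1$A, 100, tolerance = 1e-9)
  expect_equal(f2$B / f1$B, 100, tolerance = 1e-9)
})

test_that("Stern-Volmer conversion matches the calibration constants", {
  cal <- paper_cal()
  # unquenched: tau0 = 47 us at zero oxygen
  expect_equal(tau_from_pO2(0, cal), 47e-6)
  expect_equal(suppressWarnings(pO2_from_tau(47e-6, cal))$pO2, 0)
  # frozen direct evaluations of the branch
  expect_equal(suppressWarnings(pO2_from_tau(16e-6, cal))$pO2,
               (1 / 16e-6 - 1 / 47e-6) / 291.014, tolerance = 1e-12)
  expect_equal(suppressWarnings(pO2_from_tau(16e-6, cal))$pO2, 141.6544,
               tolerance = 1e-6)
  expect_equal(tau_from_pO2(100, cal), 1 / (1 / 47e-6 + 291.014 * 100),
               tolerance = 1e-12)
  expect_equal(tau_from_pO2(100, cal), 19.84994e-6, tolerance = 1e-6)
  # clamp above tau0
  res <- suppressWarnings(pO2_from_tau(60e-6, cal))
  expect_equal(res$pO2, 0)
  expect_true(res$clamped)
  # warning outside the asserted regime
  expect_warning(pO2_from_tau(20e-6, cal), "Stern-Volmer regime")
  expect_silent(pO2_from_tau(10e-6, cal))
  expect_error(pO2_from_tau(-1e-6, cal), "positive")
  expect_error(tau_from_pO2(-5, cal), "non-negative")
})

test_that("tau <-> pO2 roundtrip is an algebraic identity", {
  cal <- paper_cal()
  for (p in c(0, 20, 80, 160)) {
    expect_equal(suppressWarnings(pO2_from_tau(tau_from_pO2(p, cal), cal))$pO2,
                 p, tolerance = 1e-12)
  }
  # monotonicity
  ps <- seq(0, 200, by = 5)
  taus <- tau_from_pO2(ps, cal)
  expect_true(all(diff(taus) < 0))
  expect_true(all(diff(suppressWarnings(
    pO2_from_tau(seq(5e-6, 40e-6, by = 1e-6), cal))$pO2) < 0))
})

test_that("a calibration table overrides the analytic branch", {
  cal <- paper_cal()
  taus <- seq(10e-6, 45e-6, by = 1e-6)
  tab <- cbind(taus, suppressWarnings(pO2_from_tau(taus, cal))$pO2)
  cal_tab <- stern_volmer_calibration(table = tab)
  # interpolation reproduces the generating curve between the knots
  probe <- c(12.5e-6, 20.3e-6, 33.7e-6)
  got <- pO2_from_tau(probe, cal_tab)$pO2
  want <- suppressWarnings(pO2_from_tau(probe, cal))$pO2
  expect_equal(got, want, tolerance = 1e-3)
  expect_error(stern_volmer_calibration(table = tab[c(2, 1), ]),
               "increasing")
})

test_that("roi_pO2_timecourse processes traces and isolates failures", {
  cal <- paper_cal()
  sched <- pattern_schedule(pattern_rate = 10, n_patterns = 5L)
  ids <- c("A1", "A2", "V1", "P1", "P2")
  truth <- c(80, 78, 50, 60, 62)
  entries <- lapply(seq_along(ids), function(i)
    list(roi_id = ids[i],
         trace = synth_decay(truth[i], cal, A = 0.02, B = 1,
                             sample_rate = 1e7, noise_sd = 0.2,
                             n_averaged = 200L, seed = 100 + i)))
  tc <- roi_pO2_timecourse(entries, cal, schedule = sched)
  expect_equal(nrow(tc), 5L)
  expect_true(all(tc$converged))
  expect_equal(tc$pO2_mmhg, truth, tolerance = 0.05)
  # schedule midpoints: (i - 1/2) / pattern_rate
  expect_equal(tc$time_s, (seq_along(ids) - 0.5) / 10)

  # one saturated (constant) trace: that sample missing, others intact
  t <- seq(0, 3e-4, by = 1e-7)
  entries[[3]]$trace <- decay_trace(t, rep(2, length(t)))
  tc <- roi_pO2_timecourse(entries, cal, schedule = sched)
  expect_true(is.na(tc$pO2_mmhg[3]))
  expect_false(tc$converged[3])
  expect_true(all(tc$converged[-3]))

  expect_error(roi_pO2_timecourse(list()), "non-empty")
})
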