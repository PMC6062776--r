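# Independent oracles kept deliberately naive: they must not share code
# with the fast paths they check.

# Two-pass per-window speckle contrast (population SD / mean), border NA.
naive_contrast <- function(frame, window = 7L) {
  h <- (window - 1L) %/% 2L
  K <- matrix(NA_real_, nrow(frame), ncol(frame))
  for (r in (h + 1L):(nrow(frame) - h)) {
    for (cc in (h + 1L):(ncol(frame) - h)) {
      w <- frame[(r - h):(r + h), (cc - h):(cc + h)]
      mu <- mean(w)
      if (mu > 0) K[r, cc] <- sqrt(mean((w - mu)^2)) / mu
    }
  }
  K
}

# Brute-force per-pixel pullback rasterization of a camera mask onto the
# DMD grid (the definition, pixel by pixel).
naive_mask_to_dmd <- function(mask, map, dmd_shape) {
  inv <- solve(rbind(map$coefficients, c(0, 0, 1)))
  out <- matrix(FALSE, dmd_shape[1], dmd_shape[2])
  for (r in seq_len(dmd_shape[1])) {
    for (cc in seq_len(dmd_shape[2])) {
      p <- inv %*% c(cc - 1, r - 1, 1)
      x <- round(p[1]); y <- round(p[2])
      if (x >= 0 && x < ncol(mask) && y >= 0 && y < nrow(mask))
        out[r, cc] <- mask[y + 1, x + 1]
    }
  }
  out
}

# Direct evaluations of the exposure model, independent of the package's
# branched implementation: the plain textbook form (accurate for x not
# too small) and a cancellation-safe form via expm1 (accurate to ~1e-10
# down to x = 1e-6).
plain_speckle_K <- function(tau_c, T_, beta = 1) {
  x <- T_ / tau_c
  sqrt(beta * (exp(-2 * x) - 1 + 2 * x) / (2 * x^2))
}
expm1_speckle_K <- function(tau_c, T_, beta = 1) {
  x <- T_ / tau_c
  sqrt(beta * (expm1(-2 * x) + 2 * x) / (2 * x^2))
}

paper_cal <- function() stern_volmer_calibration(kq = 291.014, tau0 = 47e-6)
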