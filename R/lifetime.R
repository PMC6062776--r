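#' Phosphorescence decay trace
#'
#' A sampled phosphorescence decay `I(t)`, typically the on-board average
#' of many per-pulse decays (the instrument accumulates 200 decays per
#' projected pattern at a 10-Hz pattern rate).
#'
#' @param t sample times in seconds, strictly increasing, uniformly spaced.
#' @param signal signal values (arbitrary units), same length as `t`.
#' @param n_averaged number of single-pulse decays averaged into this
#'   trace.
#' @param sample_rate digitizer rate in Hz; must match the spacing of `t`
#'   within 1e-6 relative.  Defaults to `1 / median(diff(t))`.
#' @param offset_applied has the instrument-response offset already been
#'   applied (see [apply_instrument_offset()])?
#' @return An object of class `decay_trace`.
#' @export
decay_trace <- function(t, signal, n_averaged = 1L, sample_rate = NULL,
                        offset_applied = FALSE) {
  if (!is.numeric(t) || !is.numeric(signal) || length(t) != length(signal))
    stop_param("'t' and 'signal' must be numeric vectors of equal length")
  if (length(t) < 2L || any(diff(t) <= 0))
    stop_param("'t' must be strictly increasing with >= 2 samples")
  dt <- stats::median(diff(t))
  if (is.null(sample_rate)) sample_rate <- 1 / dt
  if (abs(1 / sample_rate - dt) > 1e-6 * dt)
    stop_param("'sample_rate' inconsistent with the spacing of 't'")
  if (n_averaged < 1L) stop_param("'n_averaged' must be a positive integer")
  structure(list(t = as.numeric(t), signal = as.numeric(signal),
                 n_averaged = as.integer(n_averaged),
                 sample_rate = sample_rate,
                 offset_applied = isTRUE(offset_applied)),
            class = "decay_trace")
}

#' @export
print.decay_trace <- function(x, ...) {
  cat(sprintf("<decay_trace> %d samples @ %g MHz, %d decays averaged, offset %s\n",
              length(x$t), x$sample_rate / 1e6, x$n_averaged,
              if (x$offset_applied) "applied" else "not applied"))
  invisible(x)
}

#' Average decay traces
#'
#' Pointwise mean of traces sharing a common time base; `n_averaged`
#' accumulates, so averaging two 100-decay traces yields a 200-decay
#' trace.  Additive white noise shrinks as `1/sqrt(n)`.
#'
#' @param traces list of [decay_trace()] objects on identical time bases.
#' @return A single averaged `decay_trace`.
#' @export
average_decays <- function(traces) {
  if (!is.list(traces) || length(traces) == 0L)
    stop_param("'traces' must be a non-empty list of decay traces")
  ref <- traces[[1L]]
  for (tr in traces) {
    if (!inherits(tr, "decay_trace")) stop_param("inputs must be decay traces")
    if (length(tr$t) != length(ref$t) ||
        max(abs(tr$t - ref$t)) > 1e-9 * max(abs(ref$t), 1e-12))
      stop_param("decay traces do not share a time base")
    if (tr$offset_applied != ref$offset_applied)
      stop_param("cannot mix offset-applied and raw traces")
  }
  sig <- Reduce(`+`, lapply(traces, `[[`, "signal")) / length(traces)
  decay_trace(ref$t, sig,
              n_averaged = sum(vapply(traces, `[[`, integer(1), "n_averaged")),
              sample_rate = ref$sample_rate,
              offset_applied = ref$offset_applied)
}

#' Apply the instrument-response temporal offset
#'
#' The first microseconds after gate-off are contaminated by the
#' instrument response, so samples earlier than `offset` (default 2 us)
#' are discarded and the time axis re-zeroed at the first retained sample.
#' For a pure exponential this leaves the lifetime unchanged and scales
#' the amplitude by `exp(-offset / tau)`.
#'
#' @param trace a [decay_trace()], not yet offset-corrected.
#' @param offset offset duration in seconds (default `2e-6`); must be
#'   shorter than the trace.  `0` is the identity (the flag is still set).
#' @return The trimmed, re-zeroed `decay_trace` with `offset_applied = TRUE`.
#' @export
apply_instrument_offset <- function(trace, offset = 2e-6) {
  if (!inherits(trace, "decay_trace")) stop_param("'trace' must be a decay_trace")
  if (trace$offset_applied)
    stop_param("instrument offset already applied to this trace")
  if (!is.numeric(offset) || length(offset) != 1L || offset < 0)
    stop_param("'offset' must be a non-negative scalar (seconds)")
  dur <- trace$t[length(trace$t)] - trace$t[1L]
  if (offset >= dur) stop_param("'offset' must be shorter than the trace")
  keep <- trace$t >= trace$t[1L] + offset - 1e-12 / trace$sample_rate
  t2 <- trace$t[keep]
  decay_trace(t2 - t2[1L], trace$signal[keep],
              n_averaged = trace$n_averaged,
              sample_rate = trace$sample_rate,
              offset_applied = TRUE)
}

#' Fit a mono-exponential phosphorescence decay
#'
#' Nonlinear least-squares fit of `I(t) = A + B * exp(-t / tau)` to an
#' offset-corrected trace.  Starting values: `A0` is the mean of the last
#' 10 percent of samples; `tau0` and `B0` come from a log-linear fit of
#' `signal - A0` over the first half of the window.  The lifetime is
#' bounded to `[0.5 us, 1 ms]`.  The fit is reported as converged only
#' when the optimizer converged, `B > 0` and the relative standard error
#' of `tau` is below 20 percent; otherwise the diagnostics are returned
#' with `converged = FALSE` (no exception).
#'
#' @param trace an offset-corrected [decay_trace()] with >= 50 samples.
#' @return An object of class `lifetime_fit`: `A`, `B`, `tau` (s), `rss`,
#'   `rel_se_tau`, `converged`, and `reason` when not converged.
#' @examples
#' cal <- stern_volmer_calibration()
#' tr <- synth_decay(pO2 = 0, cal, A = 0, B = 1, sample_rate = 1e7,
#'                   duration = 3e-4, noise_sd = 0, seed = 1)
#' fit_decay(apply_instrument_offset(tr))$tau * 1e6  # 47 us
#' @export
fit_decay <- function(trace) {
  if (!inherits(trace, "decay_trace")) stop_param("'trace' must be a decay_trace")
  if (!trace$offset_applied)
    stop_param("apply the instrument offset before fitting")
  if (length(trace$t) < 50L) stop_param("need >= 50 samples to fit")
  y <- trace$signal; tt <- trace$t
  if (max(y) - min(y) <= 0)
    stop_param("constant signal: no decaying component to fit")

  n <- length(y)
  A0 <- mean(y[max(1L, floor(0.9 * n)):n])
  half <- seq_len(max(10L, n %/% 2L))
  d <- y[half] - A0
  pos <- d > 0
  if (sum(pos) >= 10L) {
    cf <- stats::lm.fit(cbind(1, tt[half][pos]), log(d[pos]))$coefficients
    tau0 <- if (is.finite(cf[2L]) && cf[2L] < 0) -1 / cf[2L] else 20e-6
    B0 <- exp(cf[1L])
  } else {
    tau0 <- 20e-6
    B0 <- max(y) - A0
  }
  tau0 <- min(max(tau0, 5e-7), 1e-3)
  if (!is.finite(B0) || B0 <= 0) B0 <- max(max(y) - A0, 1e-12)

  failed <- function(reason) structure(
    list(A = NA_real_, B = NA_real_, tau = NA_real_, rss = NA_real_,
         rel_se_tau = NA_real_, converged = FALSE, reason = reason),
    class = "lifetime_fit")

  fit <- tryCatch(
    suppressWarnings(stats::nls(
      y ~ A + B * exp(-tt / tau),
      start = list(A = A0, B = B0, tau = tau0),
      algorithm = "port",
      lower = c(A = -Inf, B = 0, tau = 5e-7),
      upper = c(A = Inf, B = Inf, tau = 1e-3),
      control = stats::nls.control(maxiter = 200, warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) return(failed("optimizer error"))

  cf <- stats::coef(fit)
  rss <- sum(stats::resid(fit)^2)
  se_tau <- tryCatch(summary(fit)$coefficients["tau", "Std. Error"],
                     error = function(e) NA_real_)
  rel_se <- if (is.finite(se_tau)) se_tau / cf[["tau"]] else Inf
  conv <- fit$convInfo$isConv && cf[["B"]] > 0 && rel_se < 0.20
  structure(list(A = cf[["A"]], B = cf[["B"]], tau = cf[["tau"]],
                 rss = rss, rel_se_tau = rel_se, converged = conv,
                 reason = if (conv) NA_character_ else "quality gate"),
            class = "lifetime_fit")
}

#' @export
print.lifetime_fit <- function(x, ...) {
  if (isTRUE(x$converged))
    cat(sprintf("<lifetime_fit> tau = %.4g us (A = %.4g, B = %.4g, rel SE %.2g%%)\n",
                1e6 * x$tau, x$A, x$B, 100 * x$rel_se_tau))
  else cat(sprintf("<lifetime_fit> not converged (%s)\n", x$reason))
  invisible(x)
}

#' Per-region oxygen tension timecourse
#'
#' Processes a sequence of region-tagged decay traces through the full
#' oximetry chain: instrument offset, mono-exponential fit, Stern-Volmer
#' conversion.  Traces that fail the fit quality gate yield missing pO2
#' values (the rest of the series is unaffected).  When a
#' [pattern_schedule()] is given, samples are timestamped at the midpoint
#' of their projection slot, `(i - 1/2) / pattern_rate` for the i-th trace.
#'
#' @param decays list of entries, each a list with `roi_id` (character)
#'   and `trace` (a [decay_trace()]); raw traces are offset-corrected
#'   internally, already-corrected traces are used as-is.  An optional
#'   `time_s` per entry overrides the schedule timestamp.
#' @param cal a [stern_volmer_calibration()].
#' @param schedule optional [pattern_schedule()] providing the timebase.
#' @param offset instrument offset in seconds for raw traces (default 2 us).
#' @return Data frame with columns `roi_id`, `time_s`, `A`, `B`, `tau_s`,
#'   `pO2_mmhg`, `clamped`, `converged`.
#' @export
roi_pO2_timecourse <- function(decays, cal = stern_volmer_calibration(),
                               schedule = NULL, offset = 2e-6) {
  if (!is.list(decays) || length(decays) == 0L)
    stop_param("'decays' must be a non-empty list")
  rows <- vector("list", length(decays))
  for (i in seq_along(decays)) {
    e <- decays[[i]]
    if (is.null(e$roi_id) || !inherits(e$trace, "decay_trace"))
      stop_param("each entry needs 'roi_id' and a 'trace' decay_trace")
    tr <- e$trace
    if (!tr$offset_applied) tr <- apply_instrument_offset(tr, offset)
    ft <- tryCatch(fit_decay(tr), error = function(err) NULL)
    time_s <- if (!is.null(e$time_s)) e$time_s
      else if (!is.null(schedule)) (i - 0.5) / schedule$pattern_rate
      else NA_real_
    if (is.null(ft) || !isTRUE(ft$converged)) {
      rows[[i]] <- data.frame(roi_id = e$roi_id, time_s = time_s,
                              A = NA_real_, B = NA_real_, tau_s = NA_real_,
                              pO2_mmhg = NA_real_, clamped = FALSE,
                              converged = FALSE)
      next
    }
    p <- suppressWarnings(pO2_from_tau(ft$tau, cal))
    rows[[i]] <- data.frame(roi_id = e$roi_id, time_s = time_s,
                            A = ft$A, B = ft$B, tau_s = ft$tau,
                            pO2_mmhg = p$pO2, clamped = p$clamped,
                            converged = TRUE)
  }
  do.call(rbind, rows)
}
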