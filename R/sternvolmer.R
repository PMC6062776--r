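#' Stern-Volmer oxygen calibration
#'
#' Calibration linking phosphorescence lifetime to absolute oxygen tension
#' via Stern-Volmer kinetics, `1/tau = 1/tau0 + kq * pO2`, where `tau0` is
#' the unquenched lifetime in an oxygen-free environment and `kq` the
#' quenching constant.  The defaults are the physiological-condition
#' constants for the Oxyphor PtG4 probe (37 C, pH 7.2): `kq = 291.014`
#' mmHg^-1 s^-1 and `tau0 = 47` us.  Pure Stern-Volmer kinetics are
#' asserted for lifetimes below `sv_regime_tau` (16 us); above it the
#' relation is still applied by default, with a warning, unless a measured
#' `(tau, pO2)` lookup table is supplied, in which case monotone cubic
#' interpolation of the table is used instead.
#'
#' @param kq quenching constant, mmHg^-1 s^-1 (> 0).
#' @param tau0 unquenched lifetime, seconds (> `sv_regime_tau`).
#' @param sv_regime_tau lifetime threshold (s) below which Stern-Volmer
#'   kinetics are asserted valid.
#' @param table optional 2-column matrix/data.frame `(tau_s, pO2_mmhg)`
#'   with strictly increasing `tau_s` and strictly decreasing `pO2_mmhg`.
#' @return An object of class `stern_volmer_calibration`.
#' @examples
#' cal <- stern_volmer_calibration()
#' tau_from_pO2(0, cal) * 1e6  # 47 us
#' @export
stern_volmer_calibration <- function(kq = 291.014, tau0 = 47e-6,
                                     sv_regime_tau = 16e-6, table = NULL) {
  if (!is.numeric(kq) || length(kq) != 1L || kq <= 0)
    stop_param("'kq' must be a positive scalar (mmHg^-1 s^-1)")
  if (!is.numeric(tau0) || length(tau0) != 1L || tau0 <= 0)
    stop_param("'tau0' must be a positive scalar (seconds)")
  if (!is.numeric(sv_regime_tau) || length(sv_regime_tau) != 1L ||
      sv_regime_tau <= 0 || tau0 <= sv_regime_tau)
    stop_param("'sv_regime_tau' must be positive and below 'tau0'")
  if (!is.null(table)) {
    table <- as.matrix(table)
    if (ncol(table) != 2L || nrow(table) < 2L)
      stop_param("'table' must have >= 2 rows of (tau_s, pO2_mmhg)")
    if (any(diff(table[, 1L]) <= 0) || any(diff(table[, 2L]) >= 0))
      stop_param("'table' must have strictly increasing tau and decreasing pO2")
    colnames(table) <- c("tau_s", "pO2_mmhg")
  }
  structure(list(kq = kq, tau0 = tau0, sv_regime_tau = sv_regime_tau,
                 table = table),
            class = "stern_volmer_calibration")
}

#' @export
print.stern_volmer_calibration <- function(x, ...) {
  cat(sprintf("<stern_volmer_calibration> kq = %g mmHg^-1 s^-1, tau0 = %g us%s\n",
              x$kq, 1e6 * x$tau0,
              if (is.null(x$table)) "" else sprintf(", %d-row table", nrow(x$table))))
  invisible(x)
}

#' Oxygen tension from phosphorescence lifetime
#'
#' Converts a measured lifetime to absolute pO2.  Without a lookup table,
#' the Stern-Volmer branch `pO2 = (1/tau - 1/tau0) / kq` is applied over
#' the full lifetime range; a warning is raised for lifetimes at or above
#' the calibration's asserted Stern-Volmer regime (`tau >= sv_regime_tau`).
#' Lifetimes exceeding the unquenched lifetime `tau0` (possible under
#' noise) yield pO2 clamped to 0 and flagged rather than a negative value,
#' so timecourses stay contiguous.
#'
#' @param tau lifetime(s) in seconds (> 0); vectorized.
#' @param cal a [stern_volmer_calibration()].
#' @return A data frame with columns `pO2` (mmHg, >= 0) and `clamped`.
#' @export
pO2_from_tau <- function(tau, cal = stern_volmer_calibration()) {
  if (!is.numeric(tau) || any(!is.finite(tau)) || any(tau <= 0))
    stop_param("'tau' must be positive and finite (seconds)")
  if (is.null(cal$table)) {
    if (any(tau >= cal$sv_regime_tau))
      warning(sprintf(
        "lifetime >= %g us: outside the asserted Stern-Volmer regime; %s",
        1e6 * cal$sv_regime_tau,
        "supply a measured (tau, pO2) table for calibrated conversion"),
        call. = FALSE)
    p <- (1 / tau - 1 / cal$tau0) / cal$kq
  } else {
    f <- stats::splinefun(cal$table[, 1L], cal$table[, 2L], method = "hyman")
    p <- f(pmin(pmax(tau, min(cal$table[, 1L])), max(cal$table[, 1L])))
  }
  clamped <- p < 0
  p[clamped] <- 0
  data.frame(pO2 = p, clamped = clamped)
}

#' Phosphorescence lifetime from oxygen tension
#'
#' Exact inverse of the Stern-Volmer branch:
#' `tau = 1 / (1/tau0 + kq * pO2)`.  Round-tripping with
#' [pO2_from_tau()] is an algebraic identity.
#'
#' @param pO2 oxygen tension(s) in mmHg (>= 0); vectorized.
#' @param cal a [stern_volmer_calibration()].
#' @return Lifetime(s) in seconds.
#' @export
tau_from_pO2 <- function(pO2, cal = stern_volmer_calibration()) {
  if (!is.numeric(pO2) || any(!is.finite(pO2)) || any(pO2 < 0))
    stop_param("'pO2' must be non-negative and finite (mmHg)")
  1 / (1 / cal$tau0 + cal$kq * pO2)
}
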