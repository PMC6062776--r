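#' Synthetic speckle acquisition scenario
#'
#' Ground-truth description of a speckle acquisition to simulate: a
#' per-pixel correlation-time map, the exposure duration, the number of
#' frames, and the mean detected intensity.  The generator draws each
#' pixel of each frame independently from a gamma distribution whose
#' shape is `1 / K*^2`, where `K*` is the model contrast for that pixel's
#' `tau_c` — so the local contrast of the generated frames converges to
#' `K*`.  Spatial speckle correlation is deliberately not simulated.
#'
#' @param tau_c_map matrix of true correlation times, seconds (> 0).
#' @param exposure_T exposure duration, s (default 5 ms).
#' @param n_frames frames to generate (default 45, one contrast-averaging
#'   block at 60 fps).
#' @param mean_intensity mean detected intensity, counts (default 500, a
#'   mid-range level for a 16-bit sensor at moderate gain).
#' @param seed integer RNG seed.
#' @return An object of class `speckle_scenario`.
#' @export
speckle_scenario <- function(tau_c_map, exposure_T = 5e-3, n_frames = 45L,
                             mean_intensity = 500, seed = 1L) {
  if (!is.matrix(tau_c_map) || any(!is.finite(tau_c_map)) ||
      any(tau_c_map <= 0))
    stop_param("'tau_c_map' must be a matrix of positive correlation times")
  if (exposure_T <= 0 || n_frames < 1L || mean_intensity <= 0)
    stop_param("'exposure_T', 'n_frames' and 'mean_intensity' must be positive")
  structure(list(tau_c_map = tau_c_map, exposure_T = exposure_T,
                 n_frames = as.integer(n_frames),
                 mean_intensity = mean_intensity, seed = as.integer(seed)),
            class = "speckle_scenario")
}

#' Generate a synthetic speckle stack
#'
#' Simulates time-integrated speckle frames for a [speckle_scenario()]
#' under the gamma-statistics model (see there) and returns both the
#' stack and the ground truth, so estimator recovery can be tested
#' end-to-end.  Deterministic for a fixed seed.
#'
#' @param scenario a [speckle_scenario()].
#' @return List with `stack` (a [speckle_stack()]), `truth_tau_c` (the
#'   scenario map) and `truth_K` (the model contrast map).
#' @examples
#' sc <- speckle_scenario(matrix(5e-3, 32, 32), n_frames = 5, seed = 7)
#' s <- synth_speckle_stack(sc)
#' dim(s$stack$frames)
#' @export
synth_speckle_stack <- function(scenario) {
  if (!inherits(scenario, "speckle_scenario"))
    stop_param("'scenario' must be a speckle_scenario")
  pars <- speckle_params(beta = 1, exposure_T = scenario$exposure_T)
  Kstar <- matrix(contrast_from_tau(as.vector(scenario$tau_c_map), pars),
                  nrow(scenario$tau_c_map))
  shape <- 1 / (Kstar * Kstar)
  npx <- length(shape)
  frames <- with_seed(scenario$seed, {
    a <- array(0, c(dim(Kstar), scenario$n_frames))
    for (f in seq_len(scenario$n_frames))
      a[, , f] <- stats::rgamma(npx, shape = shape,
                                scale = scenario$mean_intensity / shape)
    a
  })
  list(stack = speckle_stack(frames, scenario$exposure_T),
       truth_tau_c = scenario$tau_c_map, truth_K = Kstar)
}

#' Generate a synthetic phosphorescence decay
#'
#' Simulates one averaged decay trace at a prescribed oxygen tension: the
#' lifetime comes from the Stern-Volmer calibration
#' (`tau = tau_from_pO2(pO2)`), the noiseless signal is
#' `A + B exp(-t/tau)`, and additive white Gaussian noise of standard
#' deviation `noise_sd / sqrt(n_averaged)` models on-board decay
#' averaging.  The trace is raw (`offset_applied = FALSE`): feed it
#' through [apply_instrument_offset()] before fitting, as for real data.
#'
#' @param pO2 oxygen tension, mmHg (>= 0).
#' @param cal a [stern_volmer_calibration()].
#' @param A baseline offset (arbitrary units).
#' @param B decay amplitude (> 0).
#' @param sample_rate digitizer rate, Hz (default 100 MHz).
#' @param duration trace duration, s (default 300 us, the usable window of
#'   a 3-kHz pulse train); a warning is raised if shorter than `10 * tau`.
#' @param n_averaged decays averaged (default 200).
#' @param noise_sd single-decay noise standard deviation (default 0).
#' @param seed integer RNG seed.
#' @return A [decay_trace()].
#' @export
synth_decay <- function(pO2, cal = stern_volmer_calibration(), A = 0, B = 1,
                        sample_rate = 100e6, duration = 300e-6,
                        n_averaged = 200L, noise_sd = 0, seed = 1L) {
  if (B <= 0) stop_param("'B' must be positive")
  if (noise_sd < 0) stop_param("'noise_sd' must be non-negative")
  tau <- tau_from_pO2(pO2, cal)
  if (duration < 10 * tau)
    warning("trace duration < 10 * tau: decay tail under-sampled",
            call. = FALSE)
  t <- seq(0, duration - 1 / sample_rate, by = 1 / sample_rate)
  sig <- A + B * exp(-t / tau)
  if (noise_sd > 0)
    sig <- sig + with_seed(seed, stats::rnorm(length(t),
                                              sd = noise_sd / sqrt(n_averaged)))
  decay_trace(t, sig, n_averaged = n_averaged, sample_rate = sample_rate,
              offset_applied = FALSE)
}

#' Scripted occlusion timeline
#'
#' Declarative description of a targeted-occlusion imaging session:
#' named regions with baseline relative flow 1 and a baseline pO2 each,
#' a list of events (multiplicative flow factor and pO2 setpoint applied
#' to one region from a given time onward), and an optional spreading
#' depolarization — a transient dip that sweeps across regions with
#' per-region lags.  The default region template mirrors a typical
#' session layout: two arterioles (A1, A2), one vein (V1) and two
#' parenchyma regions (P1, P2), with the occlusion targeting A1.
#'
#' @param rois a [roi_set()]; mask shapes define the simulated frame.
#' @param baseline_pO2 named vector of baseline pO2 (mmHg) per region.
#' @param events data frame with columns `time_s`, `roi`, `flow_factor`,
#'   `pO2_mmhg` (rows in non-decreasing time order; factors > 0).
#' @param depolarization optional list with `onset_s`, `lag_s` (named,
#'   per region), `dip_fraction` (named, multiplies flow and pO2) and
#'   `duration_s`.
#' @return An object of class `stroke_timeline`.
#' @export
stroke_timeline <- function(rois, baseline_pO2, events,
                            depolarization = NULL) {
  if (!inherits(rois, "roi_set")) stop_param("'rois' must be a roi_set")
  ids <- names(rois$masks)
  if (!all(ids %in% names(baseline_pO2)))
    stop_param("'baseline_pO2' must name every region")
  req <- c("time_s", "roi", "flow_factor", "pO2_mmhg")
  if (!is.data.frame(events) || !all(req %in% names(events)))
    stop_param("'events' needs columns time_s, roi, flow_factor, pO2_mmhg")
  if (nrow(events) > 0) {
    if (is.unsorted(events$time_s)) stop_param("event times must be non-decreasing")
    if (any(events$flow_factor <= 0)) stop_param("flow factors must be positive")
    if (!all(events$roi %in% ids)) stop_param("event rois must exist in 'rois'")
  }
  structure(list(rois = rois, baseline_pO2 = baseline_pO2[ids],
                 events = events, depolarization = depolarization),
            class = "stroke_timeline")
}

#' @rdname stroke_timeline
#' @param frame_shape simulated frame dimensions `c(rows, cols)`.
#' @param pixel_scale mm per pixel for the default region set.
#' @export
default_stroke_timeline <- function(frame_shape = c(384L, 384L),
                                    pixel_scale = 0.0027) {
  nr <- frame_shape[1L]; nc <- frame_shape[2L]
  block <- function(r0, c0, h = nr %/% 4L, w = nc %/% 4L) {
    m <- matrix(FALSE, nr, nc); m[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- TRUE; m
  }
  q <- nr %/% 4L
  masks <- list(A1 = block(2L, 2L), A2 = block(2L, nc - q - 1L),
                V1 = block(nr %/% 2L, nc %/% 2L - q %/% 2L),
                P1 = block(nr - q - 1L, 2L), P2 = block(nr - q - 1L, nc - q - 1L))
  rois <- roi_set(masks, pixel_scale)
  # Arterioles sit near arterial oxygen tension, veins and parenchyma lower.
  baseline <- c(A1 = 80, A2 = 78, V1 = 50, P1 = 60, P2 = 62)
  events <- data.frame(time_s = 120, roi = "A1", flow_factor = 0.5,
                       pO2_mmhg = 20, stringsAsFactors = FALSE)
  stroke_timeline(rois, baseline, events)
}

# Internal: binary dilation by a (2r+1)-square structuring element.
dilate_mask <- function(mask, r) {
  if (r < 1L) return(mask)
  out <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  for (dy in -r:r) for (dx in -r:r) {
    if (dy == 0L && dx == 0L) next
    sr <- max(1L, 1L + dy):min(nr, nr + dy)
    sc <- max(1L, 1L + dx):min(nc, nc + dx)
    out[sr, sc] <- out[sr, sc] | mask[sr - dy, sc - dx]
  }
  out
}

# Internal: region state (flow factor, pO2) at a time point.
timeline_state <- function(timeline, time_s) {
  ids <- names(timeline$rois$masks)
  f <- stats::setNames(rep(1, length(ids)), ids)
  p <- timeline$baseline_pO2
  ev <- timeline$events
  if (nrow(ev) > 0) for (i in seq_len(nrow(ev))) if (ev$time_s[i] <= time_s) {
    f[ev$roi[i]] <- f[ev$roi[i]] * ev$flow_factor[i]
    p[ev$roi[i]] <- ev$pO2_mmhg[i]
  }
  dp <- timeline$depolarization
  if (!is.null(dp)) for (id in ids) {
    t0 <- dp$onset_s + dp$lag_s[[id]]
    if (time_s >= t0 && time_s < t0 + dp$duration_s) {
      f[id] <- f[id] * dp$dip_fraction[[id]]
      p[id] <- p[id] * dp$dip_fraction[[id]]
    }
  }
  list(flow_factor = f, pO2 = p)
}

#' Simulate a full occlusion imaging session
#'
#' Generates, at each requested time point, one speckle frame stack and
#' one averaged phosphorescence decay per region, following a scripted
#' [stroke_timeline()].  Correlation times scale inversely with the flow
#' factor (`rCBF = tau_c_initial / tau_c` by definition, so a flow factor
#' of 0.5 doubles `tau_c` in the affected region), and region pO2
#' setpoints drive decay generation through the calibration.  Ground
#' truth is returned for recovery testing.
#'
#' @param timeline a [stroke_timeline()].
#' @param scenario a [speckle_scenario()] providing the baseline
#'   `tau_c` map (same shape as the region masks), exposure, frames per
#'   block and intensity.
#' @param cal a [stern_volmer_calibration()].
#' @param schedule a [pattern_schedule()]; must be feasible.
#' @param times numeric vector of sample times, s (default `c(0, 240)`:
#'   one baseline and one post-event block for the default timeline).
#' @param decay_noise_sd single-decay noise level for the region decays.
#' @param dilate_px radius (pixels) by which the perturbed territory
#'   extends beyond each measurement region (default 3, one half of the
#'   7-pixel contrast window).  An occlusion affects the vessel and its
#'   surroundings, not just the drawn region; without this margin,
#'   contrast windows centered near the region edge would straddle the
#'   perturbation boundary and mix flow statistics.
#' @param seed integer RNG seed.
#' @return List with `times`, `stacks` (list of [speckle_stack()]),
#'   `decays` (per time point, named list of [decay_trace()]), and
#'   `truth` (data frame `time_s, roi, rcbf_true, pO2_true`).
#' @export
synth_stroke_session <- function(timeline, scenario,
                                 cal = stern_volmer_calibration(),
                                 schedule = pattern_schedule(n_patterns = 5L),
                                 times = c(0, 240), decay_noise_sd = 0.05,
                                 dilate_px = 3L, seed = 1L) {
  if (!inherits(timeline, "stroke_timeline"))
    stop_param("'timeline' must be a stroke_timeline")
  if (!inherits(scenario, "speckle_scenario"))
    stop_param("'scenario' must be a speckle_scenario")
  if (!acquisition_plan(schedule)$feasible)
    stop_param("infeasible pattern schedule")
  ids <- names(timeline$rois$masks)
  if (!identical(dim(timeline$rois$masks[[1L]]), dim(scenario$tau_c_map)))
    stop_param("region masks and scenario tau_c map differ in shape")

  territory <- lapply(timeline$rois$masks, dilate_mask, r = dilate_px)
  stacks <- vector("list", length(times))
  decays <- vector("list", length(times))
  truth <- NULL
  for (k in seq_along(times)) {
    st <- timeline_state(timeline, times[k])
    tau_map <- scenario$tau_c_map
    for (id in ids)
      tau_map[territory[[id]]] <-
        tau_map[territory[[id]]] / st$flow_factor[[id]]
    sc_k <- speckle_scenario(tau_map, scenario$exposure_T, scenario$n_frames,
                             scenario$mean_intensity,
                             seed = scenario$seed + 1000L * k)
    stacks[[k]] <- synth_speckle_stack(sc_k)$stack
    decays[[k]] <- stats::setNames(lapply(seq_along(ids), function(j)
      synth_decay(st$pO2[[ids[j]]], cal, A = 0.02, B = 1,
                  n_averaged = schedule$decays_per_pattern,
                  noise_sd = decay_noise_sd,
                  seed = seed + 1000L * k + j)), ids)
    truth <- rbind(truth, data.frame(
      time_s = times[k], roi = ids,
      rcbf_true = as.numeric(st$flow_factor[ids]),
      pO2_true = as.numeric(st$pO2[ids]),
      stringsAsFactors = FALSE))
  }
  list(times = times, stacks = stacks, decays = decays, truth = truth)
}
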