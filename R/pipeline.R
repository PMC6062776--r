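#' Write a simulated session to disk in the pipeline layout
#'
#' Serializes the output of [synth_stroke_session()] into a directory that
#' [run_pipeline()] can consume: frame stacks as multi-page TIFF with
#' sidecars, region masks as PGM, per-region decays as CSV, calibration
#' and schedule as JSON, ground truth as CSV, and a `config.json` tying
#' everything together.
#'
#' @param session result of [synth_stroke_session()].
#' @param timeline the [stroke_timeline()] that produced it (for masks).
#' @param dir output directory (created if needed).
#' @param cal a [stern_volmer_calibration()].
#' @param schedule a [pattern_schedule()].
#' @param window,beta,average_n,offset_s processing defaults recorded in
#'   the config (7-pixel window, beta 1, 45-image averaging, 2-us offset).
#' @param pixel_scale camera scale, mm/pixel.
#' @return Path of the written `config.json`.
#' @export
write_session <- function(session, timeline, dir,
                          cal = stern_volmer_calibration(),
                          schedule = pattern_schedule(n_patterns = 5L),
                          window = 7L, beta = 1, average_n = 45L,
                          offset_s = 2e-6, pixel_scale = 0.0027) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "stacks"), showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  dir.create(file.path(dir, "decays"), showWarnings = FALSE)

  stacks <- list()
  for (k in seq_along(session$stacks)) {
    p <- file.path("stacks", sprintf("block_%03d.tif", k))
    write_stack(session$stacks[[k]], file.path(dir, p))
    stacks[[k]] <- list(path = p, time_s = session$times[k])
  }
  masks <- list()
  for (id in names(timeline$rois$masks)) {
    p <- file.path("masks", paste0(id, ".pgm"))
    write_mask(timeline$rois$masks[[id]], file.path(dir, p))
    masks[[id]] <- p
  }
  decays <- list()
  for (k in seq_along(session$decays)) for (id in names(session$decays[[k]])) {
    p <- file.path("decays", sprintf("%s_block_%03d.csv", id, k))
    write_decay(session$decays[[k]][[id]], file.path(dir, p))
    decays[[length(decays) + 1L]] <-
      list(roi_id = id, time_s = session$times[k], path = p)
  }
  write_calibration(cal, file.path(dir, "calibration.json"))
  write_schedule(schedule, file.path(dir, "schedule.json"))
  write_timecourse(session$truth, file.path(dir, "truth.csv"))

  st1 <- session$stacks[[1L]]
  config <- list(exposure_s = st1$exposure_T, frame_rate_hz = st1$frame_rate,
                 window = window, beta = beta, average_n = average_n,
                 offset_s = offset_s, pixel_scale_mm_per_px = pixel_scale,
                 calibration = "calibration.json",
                 schedule = "schedule.json",
                 stacks = stacks, masks = masks, decays = decays,
                 out_dir = "results")
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA)
  cfg_path
}

#' Run the full dual-modality analysis pipeline
#'
#' Executes both analysis chains on a session directory: raw speckle
#' stacks to contrast (sliding-window, averaged), contrast to correlation
#' time, and correlation time to baseline-relative blood flow per region;
#' and raw decays through instrument offset, mono-exponential fit and
#' Stern-Volmer conversion to per-region pO2.  The first stack is the
#' baseline.  Outputs (flow and pO2 timecourse CSVs, per-block contrast
#' and correlation-time maps, and a JSON run manifest recording package
#' version, parameters and per-stage counts) are written under the
#' config's `out_dir`.  Re-running the same config reproduces the CSVs
#' byte-for-byte.
#'
#' @param config path to a session `config.json` (see [write_session()])
#'   or an equivalent list; relative paths resolve against the config
#'   directory.
#' @return Invisibly, a list with `rcbf` and `po2` data frames and the
#'   paths of the written outputs.
#' @export
run_pipeline <- function(config) {
  base <- "."
  if (is.character(config)) {
    base <- dirname(config)
    config <- jsonlite::read_json(config)
  }
  rel <- function(p) if (startsWith(p, "/")) p else file.path(base, p)
  fail <- function(stage, msg) stop_param(sprintf("[%s] %s", stage, msg))

  cal <- tryCatch(read_calibration(rel(config$calibration)),
                  error = function(e) fail("calibration", conditionMessage(e)))
  masks <- lapply(config$masks, function(p) read_mask(rel(p)))
  rois <- roi_set(masks, config$pixel_scale_mm_per_px %||% 1)
  pars <- speckle_params(beta = config$beta %||% 1,
                         exposure_T = config$exposure_s)
  out_dir <- rel(config$out_dir %||% "results")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # speckle chain: contrast -> averaged contrast -> tau_c -> rCBF
  baseline <- NULL
  rcbf <- NULL
  n_invalid <- integer(0)
  for (k in seq_along(config$stacks)) {
    entry <- config$stacks[[k]]
    stack <- tryCatch(read_stack(rel(entry$path),
                                 exposure_T = config$exposure_s,
                                 frame_rate = config$frame_rate_hz),
                      error = function(e) fail("speckle", conditionMessage(e)))
    cis <- compute_contrast(stack, window = config$window %||% 7L)
    n_avg <- min(config$average_n %||% 45L, length(cis))
    ci <- average_contrast(cis, n_avg)
    fm <- flow_map(ci, pars)
    write_map(ci$K, file.path(out_dir, sprintf("contrast_%03d.tif", k)))
    write_map(fm$tau_c, file.path(out_dir, sprintf("tau_c_%03d.tif", k)))
    n_invalid <- c(n_invalid, sum(!fm$valid_mask))
    if (is.null(baseline)) baseline <- fm
    rf <- relative_flow(fm, baseline, rois)
    rcbf <- rbind(rcbf, data.frame(time_s = entry$time_s %||% NA_real_,
                                   roi_id = rf$roi_id, rcbf = rf$rcbf,
                                   n_valid_pixels = rf$n_valid_pixels))
  }

  # oximetry chain: offset -> fit -> pO2
  po2 <- NULL
  if (length(config$decays) > 0L) {
    entries <- lapply(config$decays, function(d)
      list(roi_id = d$roi_id, time_s = d$time_s,
           trace = read_decay(rel(d$path))))
    po2 <- suppressWarnings(
      roi_pO2_timecourse(entries, cal, offset = config$offset_s %||% 2e-6))
  }

  rcbf_path <- file.path(out_dir, "rcbf.csv")
  write_timecourse(rcbf, rcbf_path)
  po2_path <- NULL
  if (!is.null(po2)) {
    po2_path <- file.path(out_dir, "po2.csv")
    write_timecourse(po2, po2_path)
  }
  manifest <- list(
    package = "corticox",
    version = as.character(utils::packageVersion("corticox")),
    parameters = list(exposure_s = config$exposure_s,
                      window = config$window %||% 7L,
                      beta = config$beta %||% 1,
                      average_n = config$average_n %||% 45L,
                      offset_s = config$offset_s %||% 2e-6),
    n_stacks = length(config$stacks),
    n_decays = length(config$decays),
    invalid_pixels_per_block = as.list(n_invalid),
    failed_fits = if (is.null(po2)) 0L else sum(!po2$converged))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(rcbf = rcbf, po2 = po2, rcbf_path = rcbf_path,
                 po2_path = po2_path,
                 manifest_path = file.path(out_dir, "manifest.json")))
}
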