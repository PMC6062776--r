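# Readers/writers for the on-disk session formats.  Frame stacks and
# derived maps travel as grayscale TIFF with a JSON sidecar for
# acquisition metadata; region masks as plain-text PGM (portable graymap,
# nonzero = inside); decays and timecourses as CSV; calibration, affine
# maps, schedules and run manifests as JSON.

sidecar_path <- function(path) paste0(path, ".json")

#' Read / write a speckle frame stack
#'
#' Stacks are stored as multi-page 16-bit grayscale TIFF plus a JSON
#' sidecar (`<path>.json`) holding `exposure_s` and `frame_rate_hz`.
#' Metadata given as arguments overrides the sidecar; a stack without any
#' exposure source is a hard error (the contrast model is meaningless
#' without `T`).
#'
#' @param path TIFF file path.
#' @param exposure_T,frame_rate optional metadata overriding the sidecar.
#' @return `read_stack()`: a [speckle_stack()].
#' @export
read_stack <- function(path, exposure_T = NULL, frame_rate = NULL) {
  frames <- read_tiff(path)
  meta <- if (file.exists(sidecar_path(path)))
    jsonlite::read_json(sidecar_path(path)) else list()
  if (is.null(exposure_T)) exposure_T <- meta$exposure_s
  if (is.null(frame_rate)) frame_rate <- meta$frame_rate_hz
  if (is.null(exposure_T))
    stop_param("no exposure metadata: supply 'exposure_T' or a sidecar JSON")
  if (is.null(frame_rate)) frame_rate <- 60
  speckle_stack(frames, as.numeric(exposure_T), as.numeric(frame_rate))
}

#' @rdname read_stack
#' @param stack a [speckle_stack()] to write.
#' @export
write_stack <- function(stack, path) {
  if (!inherits(stack, "speckle_stack")) stop_param("'stack' must be a speckle_stack")
  write_tiff(stack$frames, path, "uint16")
  jsonlite::write_json(list(exposure_s = stack$exposure_T,
                            frame_rate_hz = stack$frame_rate),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write a derived map (contrast or correlation time)
#'
#' Derived per-pixel maps are stored as 32-bit float TIFF; `NaN` encodes
#' invalid pixels (16-bit storage would quantize contrast).
#'
#' @param m numeric matrix (`NA`/`NaN` = invalid pixel).
#' @param path file path.
#' @export
write_map <- function(m, path) {
  write_tiff(m, path, "float32")
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  a <- read_tiff(path)
  if (dim(a)[3] != 1L) stop_param("expected a single-page map TIFF")
  a[, , 1L]
}

#' Read / write a binary region mask
#'
#' Masks are plain-text PGM (P2): any nonzero pixel is inside the region.
#' Camera coordinates (row = y, col = x).
#'
#' @param mask logical matrix.
#' @param path file path.
#' @export
write_mask <- function(mask, path) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop_param("'mask' must be a logical matrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(mask), nrow(mask)), "1"), con)
  write(t(mask) * 1L, con, ncolumns = ncol(mask))
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (lines[1L] != "P2") stop_param("mask must be a plain-text PGM (P2)")
  toks <- as.numeric(unlist(strsplit(paste(lines[-1L], collapse = " "), "\\s+")))
  toks <- toks[!is.na(toks)]
  w <- toks[1L]; h <- toks[2L]
  px <- toks[-(1:3)]
  if (length(px) != w * h) stop_param("PGM pixel count disagrees with header")
  matrix(px != 0, nrow = h, ncol = w, byrow = TRUE)
}

# Full-precision CSV: numbers serialized with %.17g so write -> read is a
# lossless roundtrip for doubles.
write_csv_full <- function(df, path) {
  fmt_col <- function(x) {
    if (is.numeric(x) && !is.integer(x)) {
      out <- sprintf("%.17g", x)
      out[is.na(x)] <- "NA"
      out
    } else as.character(x)
  }
  mat <- vapply(df, fmt_col, character(nrow(df)))
  if (nrow(df) == 1L) mat <- matrix(mat, nrow = 1L)
  lines <- c(paste(names(df), collapse = ","),
             if (nrow(df) > 0L) apply(mat, 1L, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write ROI timecourses
#'
#' CSV with columns `time_s, roi_id, rcbf, n_valid_pixels` (flow) or the
#' pO2 fit columns of [roi_pO2_timecourse()]; numeric columns round-trip
#' losslessly (17 significant digits).
#'
#' @param rows data frame of timecourse rows.
#' @param path CSV path.
#' @export
write_timecourse <- function(rows, path) {
  if (!is.data.frame(rows)) stop_param("'rows' must be a data frame")
  write_csv_full(rows, path)
}

#' @rdname write_timecourse
#' @export
read_timecourse <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time_s" %in% names(df))
    stop_param("malformed timecourse header: no time_s column")
  df
}

#' Read / write a decay trace as CSV
#'
#' CSV with header `time_s, signal` plus a JSON sidecar
#' `{n_averaged, sample_rate_hz, offset_applied}`.
#'
#' @param trace a [decay_trace()].
#' @param path CSV path.
#' @export
write_decay <- function(trace, path) {
  if (!inherits(trace, "decay_trace")) stop_param("'trace' must be a decay_trace")
  write_csv_full(data.frame(time_s = trace$t, signal = trace$signal), path)
  jsonlite::write_json(list(n_averaged = trace$n_averaged,
                            sample_rate_hz = trace$sample_rate,
                            offset_applied = trace$offset_applied),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_decay
#' @export
read_decay <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "signal") %in% names(df)))
    stop_param("malformed decay CSV: need columns time_s, signal")
  meta <- if (file.exists(sidecar_path(path)))
    jsonlite::read_json(sidecar_path(path)) else list()
  decay_trace(df$time_s, df$signal,
              n_averaged = meta$n_averaged %||% 1L,
              sample_rate = meta$sample_rate_hz %||% NULL,
              offset_applied = isTRUE(meta$offset_applied))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a Stern-Volmer calibration as JSON
#'
#' JSON schema: `{kq_per_mmhg_s, tau0_s, sv_regime_tau_s, table}` where
#' `table` is an optional array of `[tau_s, pO2_mmhg]` pairs.
#'
#' @param cal a [stern_volmer_calibration()].
#' @param path JSON path.
#' @export
write_calibration <- function(cal, path) {
  obj <- list(kq_per_mmhg_s = cal$kq, tau0_s = cal$tau0,
              sv_regime_tau_s = cal$sv_regime_tau)
  if (!is.null(cal$table)) obj$table <- unname(apply(cal$table, 1L, as.list))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path)
  table <- NULL
  if (!is.null(obj$table))
    table <- do.call(rbind, lapply(obj$table, function(r)
      c(as.numeric(r[[1L]]), as.numeric(r[[2L]]))))
  stern_volmer_calibration(kq = obj$kq_per_mmhg_s, tau0 = obj$tau0_s,
                           sv_regime_tau = obj$sv_regime_tau_s %||% 16e-6,
                           table = table)
}

#' Read / write an affine map as JSON
#'
#' @param map an [affine_map()].
#' @param path JSON path.
#' @export
write_affine <- function(map, path) {
  jsonlite::write_json(list(coefficients = unname(apply(map$coefficients, 1L,
                                                        as.list))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_affine
#' @export
read_affine <- function(path) {
  obj <- jsonlite::read_json(path)
  M <- do.call(rbind, lapply(obj$coefficients, function(r) as.numeric(unlist(r))))
  affine_map(M)
}

#' Read / write a pattern schedule as JSON
#'
#' @param schedule a [pattern_schedule()].
#' @param path JSON path.
#' @export
write_schedule <- function(schedule, path) {
  jsonlite::write_json(unclass(schedule), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  o <- jsonlite::read_json(path)
  pattern_schedule(o$pattern_rate, o$decays_per_pattern, o$pulse_width,
                   o$rep_rate, o$n_patterns)
}

#' Read control-point pairs from CSV
#'
#' CSV with header `x_cam, y_cam, x_dmd, y_dmd`.
#'
#' @param path CSV path.
#' @return List with `camera` and `dmd` n x 2 matrices.
#' @export
read_control_points <- function(path) {
  df <- utils::read.csv(path)
  req <- c("x_cam", "y_cam", "x_dmd", "y_dmd")
  if (!all(req %in% names(df)))
    stop_param("control points need columns x_cam, y_cam, x_dmd, y_dmd")
  list(camera = cbind(df$x_cam, df$y_cam), dmd = cbind(df$x_dmd, df$y_dmd))
}
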