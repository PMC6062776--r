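#' 2-D affine map between camera and DMD pixel coordinates
#'
#' Wraps a 2 x 3 coefficient matrix mapping camera points `(x, y)` (in
#' pixels, 0-based, x = column, y = row, at pixel centers) to DMD points:
#' `(x', y')' = M[, 1:2] %*% (x, y)' + M[, 3]`.  The optical magnification
#' between the DMD and the cortex is absorbed entirely into this map.
#'
#' @param coefficients numeric 2 x 3 matrix; the 2 x 2 linear part must be
#'   invertible.
#' @return An object of class `affine_map`.
#' @export
affine_map <- function(coefficients) {
  coefficients <- as.matrix(coefficients)
  if (!identical(dim(coefficients), c(2L, 3L)))
    stop_param("'coefficients' must be a 2 x 3 matrix")
  if (abs(det(coefficients[, 1:2])) < 1e-12)
    stop_param("degenerate affine map: linear part is singular")
  structure(list(coefficients = coefficients), class = "affine_map")
}

#' @export
print.affine_map <- function(x, ...) {
  cat("<affine_map> camera -> DMD\n")
  print(x$coefficients)
  invisible(x)
}

#' Estimate an affine map from control-point pairs
#'
#' Least-squares affine transform from >= 3 corresponding point pairs;
#' exact (machine-precision residual) for 3 noncollinear pairs.  The RMS
#' residual over the pairs is attached as attribute `"rms_residual"`.
#'
#' @param camera,dmd n x 2 matrices of corresponding `(x, y)` points.
#' @return An [affine_map()].
#' @examples
#' cam <- cbind(c(0, 100, 0), c(0, 0, 100))
#' estimate_affine(cam, cam)  # identity
#' @export
estimate_affine <- function(camera, dmd) {
  camera <- as.matrix(camera); dmd <- as.matrix(dmd)
  if (ncol(camera) != 2L || ncol(dmd) != 2L || nrow(camera) != nrow(dmd))
    stop_param("'camera' and 'dmd' must be matching n x 2 point matrices")
  if (nrow(camera) < 3L) stop_param("need >= 3 control-point pairs")
  X <- cbind(camera, 1)
  q <- qr(X)
  if (q$rank < 3L) stop_param("camera points are collinear: affine underdetermined")
  beta <- qr.coef(q, dmd)           # 3 x 2: (a, b, c) per output axis
  M <- t(beta)[, c(1L, 2L, 3L), drop = FALSE]
  resid <- X %*% beta - dmd
  map <- affine_map(M)
  attr(map, "rms_residual") <- sqrt(mean(resid^2))
  map
}

#' Apply or invert an affine map
#'
#' @param map an [affine_map()].
#' @param points n x 2 matrix of `(x, y)` points.
#' @return `apply_affine()`: the transformed n x 2 matrix;
#'   `invert_affine()`: the inverse `affine_map`.
#' @export
apply_affine <- function(map, points) {
  points <- rbind(as.matrix(points)) # keeps 1 x 2 vectors as a row
  t(map$coefficients[, 1:2] %*% t(points) + map$coefficients[, 3])
}

#' @rdname apply_affine
#' @export
invert_affine <- function(map) {
  A <- map$coefficients[, 1:2]
  Ai <- solve(A)
  affine_map(cbind(Ai, -Ai %*% map$coefficients[, 3]))
}

#' Transform a camera-space binary mask into DMD coordinates
#'
#' Rasterizes a region mask onto the DMD mirror array: each DMD pixel is
#' switched on iff its center, pulled back through the inverse affine map,
#' lands (nearest-neighbor) on a true camera pixel.  Binary masks stay
#' binary; no interpolation threshold is involved.  Mask content whose
#' forward image falls outside the DMD footprint is clipped with a
#' warning (regions near the field edge are legitimate), and the clipped
#' fraction is attached as attribute `"clipped_fraction"`.
#'
#' @param mask logical matrix in camera coordinates (row = y, col = x).
#' @param map camera-to-DMD [affine_map()].
#' @param dmd_shape DMD array dimensions `c(rows, cols)`; default the
#'   DLP3000's 608 x 684 mirrors.
#' @return Logical `dmd_shape` matrix.
#' @export
mask_to_dmd <- function(mask, map, dmd_shape = c(608L, 684L)) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop_param("'mask' must be a logical matrix")
  if (!inherits(map, "affine_map")) stop_param("'map' must be an affine_map")
  inv <- invert_affine(map)
  nr <- dmd_shape[1L]; nc <- dmd_shape[2L]
  # DMD pixel centers, 0-based (x = col, y = row)
  xs <- rep(0:(nc - 1L), each = nr)
  ys <- rep(0:(nr - 1L), times = nc)
  cam <- apply_affine(inv, cbind(xs, ys))
  cx <- round(cam[, 1L]); cy <- round(cam[, 2L])
  inside <- cx >= 0 & cx <= ncol(mask) - 1L & cy >= 0 & cy <= nrow(mask) - 1L
  val <- logical(length(xs))
  val[inside] <- mask[cbind(cy[inside] + 1L, cx[inside] + 1L)]
  out <- matrix(val, nrow = nr, ncol = nc)

  # clipped fraction: true camera pixels whose forward image leaves the DMD
  idx <- which(mask, arr.ind = TRUE)
  clipped <- 0
  if (nrow(idx) > 0L) {
    fwd <- apply_affine(map, cbind(idx[, 2L] - 1L, idx[, 1L] - 1L))
    off <- fwd[, 1L] < -0.5 | fwd[, 1L] > nc - 0.5 |
           fwd[, 2L] < -0.5 | fwd[, 2L] > nr - 0.5
    clipped <- mean(off)
    if (clipped > 0)
      warning(sprintf("%.1f%% of mask pixels map outside the DMD and were clipped",
                      100 * clipped), call. = FALSE)
  }
  attr(out, "clipped_fraction") <- clipped
  out
}

#' Set of named regions of interest
#'
#' Named binary masks in camera pixel coordinates with the physical pixel
#' scale; per-region areas are the true-pixel counts times the squared
#' pixel scale.
#'
#' @param masks named list of logical matrices (unique names, equal dims).
#' @param pixel_scale physical scale, mm per camera pixel.
#' @return An object of class `roi_set` with elements `masks`,
#'   `pixel_scale` and `areas` (mm^2).
#' @export
roi_set <- function(masks, pixel_scale) {
  if (!is.list(masks) || length(masks) == 0L || is.null(names(masks)) ||
      anyDuplicated(names(masks)) || any(!nzchar(names(masks))))
    stop_param("'masks' must be a non-empty uniquely named list")
  d <- dim(masks[[1L]])
  for (m in masks)
    if (!is.matrix(m) || !is.logical(m) || !identical(dim(m), d))
      stop_param("all masks must be logical matrices of equal shape")
  if (!is.numeric(pixel_scale) || pixel_scale <= 0)
    stop_param("'pixel_scale' must be positive (mm/pixel)")
  areas <- vapply(masks, function(m) sum(m) * pixel_scale^2, numeric(1))
  structure(list(masks = masks, pixel_scale = pixel_scale, areas = areas),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d region(s), %g mm/px\n", length(x$masks),
              x$pixel_scale))
  for (nm in names(x$masks))
    cat(sprintf("  %-10s %6d px  %.4f mm^2\n", nm, sum(x$masks[[nm]]),
                x$areas[[nm]]))
  invisible(x)
}

#' Rectangular tile grid specification
#'
#' A grid of `n_cols x n_rows` rectangular tiles partitioning a physical
#' extent (half-open intervals: every point of the extent belongs to
#' exactly one tile).  Sequentially projecting such a grid yields a
#' coarse pO2 map across the field of view; the instrument's reference
#' configuration is 12 x 8 tiles over 1.2 mm x 1.0 mm, i.e. 96 tiles of
#' 0.0125 mm^2 each.
#'
#' @param origin `(x, y)` camera pixel coordinates of the grid's top-left
#'   corner (0-based).
#' @param extent `(width, height)` of the grid in mm.
#' @param n_cols,n_rows positive tile counts.
#' @return An object of class `tile_grid`.
#' @export
tile_grid <- function(origin = c(0, 0), extent, n_cols, n_rows) {
  if (length(origin) != 2L || length(extent) != 2L || any(extent <= 0))
    stop_param("'origin' and 'extent' must be positive length-2 vectors")
  n_cols <- as.integer(n_cols); n_rows <- as.integer(n_rows)
  if (n_cols < 1L || n_rows < 1L) stop_param("tile counts must be positive")
  structure(list(origin = as.numeric(origin), extent = as.numeric(extent),
                 n_cols = n_cols, n_rows = n_rows),
            class = "tile_grid")
}

#' Per-tile projected area of a grid
#'
#' @param grid a [tile_grid()].
#' @return Geometric area of one tile, mm^2
#'   (`width * height / (n_cols * n_rows)`).
#' @export
tile_area <- function(grid) {
  grid$extent[1L] * grid$extent[2L] / (grid$n_cols * grid$n_rows)
}

#' Rasterize a tile grid into a region set
#'
#' Builds the `n_cols * n_rows` rectangular masks of a [tile_grid()] on
#' the camera pixel array.  Pixel centers are assigned to tiles by
#' half-open intervals, so tiles are disjoint and their union is exactly
#' the set of pixels inside the extent.
#'
#' @param grid a [tile_grid()].
#' @param pixel_scale camera scale, mm per pixel.
#' @param frame_shape camera array dimensions `c(rows, cols)`; default the
#'   instrument's 1024 x 1280 sensor.
#' @return A [roi_set()] with tiles named `tile_r<row>_c<col>`.
#' @export
make_tile_grid <- function(grid, pixel_scale, frame_shape = c(1024L, 1280L)) {
  if (!inherits(grid, "tile_grid")) stop_param("'grid' must be a tile_grid")
  if (!is.numeric(pixel_scale) || pixel_scale <= 0)
    stop_param("'pixel_scale' must be positive (mm/pixel)")
  nr <- frame_shape[1L]; nc <- frame_shape[2L]
  w_px <- grid$extent[1L] / pixel_scale
  h_px <- grid$extent[2L] / pixel_scale
  x <- matrix(rep(0:(nc - 1L), each = nr), nr, nc) - grid$origin[1L]
  y <- matrix(rep(0:(nr - 1L), times = nc), nr, nc) - grid$origin[2L]
  col_idx <- floor(x / (w_px / grid$n_cols))
  row_idx <- floor(y / (h_px / grid$n_rows))
  inside <- x >= 0 & x < w_px & y >= 0 & y < h_px
  masks <- list()
  for (r in seq_len(grid$n_rows)) for (cc in seq_len(grid$n_cols)) {
    nm <- sprintf("tile_r%02d_c%02d", r, cc)
    masks[[nm]] <- inside & row_idx == r - 1L & col_idx == cc - 1L
  }
  roi_set(masks, pixel_scale)
}

#' Pulse-train duty cycle
#'
#' Fraction of time the excitation laser is on:
#' `duty = pulse_width * rep_rate`.  The reference gating (20-us pulses at
#' ~3 kHz) has a 6 percent duty cycle.
#'
#' @param pulse_width pulse duration, seconds (>= 0).
#' @param rep_rate pulse repetition rate, Hz (> 0).
#' @return Duty-cycle fraction in `[0, 1)`.
#' @export
duty_cycle <- function(pulse_width, rep_rate) {
  if (!is.numeric(pulse_width) || pulse_width < 0 ||
      !is.numeric(rep_rate) || rep_rate <= 0)
    stop_param("'pulse_width' must be >= 0 and 'rep_rate' > 0")
  d <- pulse_width * rep_rate
  if (d >= 1) stop_param("infeasible pulse train: duty cycle >= 1")
  d
}

#' Acquisition schedule for sequential pattern projection
#'
#' Timing budget of a structured-illumination acquisition: patterns are
#' projected sequentially at `pattern_rate`, and during each projection
#' `decays_per_pattern` phosphorescence decays are collected at the pulse
#' repetition rate.  The reference configuration projects at 10 Hz with
#' 200 decays per pattern from a 3-kHz, 20-us pulse train.
#'
#' @param pattern_rate pattern display rate, Hz.
#' @param decays_per_pattern decays averaged per projected pattern.
#' @param pulse_width excitation pulse duration, seconds.
#' @param rep_rate pulse repetition rate, Hz.
#' @param n_patterns number of patterns in the sequence.
#' @return An object of class `pattern_schedule`.
#' @export
pattern_schedule <- function(pattern_rate = 10, decays_per_pattern = 200L,
                             pulse_width = 20e-6, rep_rate = 3000,
                             n_patterns = 1L) {
  vals <- c(pattern_rate, decays_per_pattern, pulse_width, rep_rate, n_patterns)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_param("all schedule fields must be positive")
  duty_cycle(pulse_width, rep_rate)  # validates duty < 1
  structure(list(pattern_rate = pattern_rate,
                 decays_per_pattern = as.integer(decays_per_pattern),
                 pulse_width = pulse_width, rep_rate = rep_rate,
                 n_patterns = as.integer(n_patterns)),
            class = "pattern_schedule")
}

#' Acquisition plan and feasibility check
#'
#' Computes the total acquisition time and the time needed to collect the
#' requested decays within each projection slot.  The schedule is feasible
#' iff the decays fit in the slot:
#' `decays_per_pattern / rep_rate <= 1 / pattern_rate`.
#'
#' @param schedule a [pattern_schedule()].
#' @return List with `total_time` (s), `per_pattern_decay_time` (s),
#'   `duty_cycle` and `feasible`.
#' @examples
#' acquisition_plan(pattern_schedule(n_patterns = 96))$total_time  # 9.6 s
#' @export
acquisition_plan <- function(schedule) {
  if (!inherits(schedule, "pattern_schedule"))
    stop_param("'schedule' must be a pattern_schedule")
  per <- schedule$decays_per_pattern / schedule$rep_rate
  list(total_time = schedule$n_patterns / schedule$pattern_rate,
       per_pattern_decay_time = per,
       duty_cycle = duty_cycle(schedule$pulse_width, schedule$rep_rate),
       feasible = per <= 1 / schedule$pattern_rate)
}

#' Pixel scale from field of view and sensor size
#'
#' Physical camera scale in mm per pixel from the optical field of view
#' and the sensor resolution, e.g. a 3.5 mm x 2.8 mm field on a
#' 1280 x 1024 sensor gives ~0.00273 mm/pixel.  The two axes must agree
#' within 2 percent (square pixels assumed); their mean is returned.
#'
#' @param fov `(width, height)` field of view, mm.
#' @param sensor `(cols, rows)` sensor resolution, pixels.
#' @return Scale in mm/pixel.
#' @export
pixel_scale_from_fov <- function(fov = c(3.5, 2.8), sensor = c(1280L, 1024L)) {
  if (length(fov) != 2L || length(sensor) != 2L || any(fov <= 0) ||
      any(sensor <= 0))
    stop_param("'fov' and 'sensor' must be positive length-2 vectors")
  sx <- fov[1L] / sensor[1L]
  sy <- fov[2L] / sensor[2L]
  if (abs(sx - sy) > 0.02 * max(sx, sy))
    stop_param("anisotropic pixels: per-axis scales differ by > 2%")
  mean(c(sx, sy))
}
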