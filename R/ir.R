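# Infrared-thermography analysis: extraction of edge-area temperature
# profiles from frames or simulated fields, the simulation-measurement
# "fitting degree", and spatial heat-spread descriptors.

#' Thermal frame
#'
#' One infrared camera frame: a 2-D temperature grid with a pixel pitch.
#'
#' @param values Numeric matrix of temperatures (degC), rows x columns.
#' @param pitch_mm Pixel pitch (mm/pixel), > 0.
#' @param time_s Timestamp (s).
#' @param frame_rate_hz Acquisition rate (Hz).
#' @return An object of class `thermal_frame`.
#' @export
thermal_frame <- function(values, pitch_mm, time_s = 0, frame_rate_hz = 30) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("frame values must be finite")
  if (pitch_mm <= 0) stop("pixel pitch must be > 0")
  structure(list(values = values, pitch_mm = pitch_mm, time_s = time_s,
                 frame_rate_hz = frame_rate_hz),
            class = "thermal_frame")
}

#' Thermal profile
#'
#' Temperature versus distance from the electrode edge at a fixed time.
#'
#' @param distance_mm Non-decreasing distances (mm) from the electrode
#'   edge (0 at the edge, increasing outward).
#' @param temperature Temperatures (degC), same length.
#' @param time_s Timestamp (s).
#' @return An object of class `thermal_profile`.
#' @export
thermal_profile <- function(distance_mm, temperature, time_s = NA_real_) {
  if (length(distance_mm) != length(temperature))
    stop("distance and temperature must have equal length")
  if (length(distance_mm) < 3L)
    stop("a profile needs at least 3 points")
  if (is.unsorted(distance_mm))
    stop("distances must be non-decreasing")
  structure(list(distance_mm = as.numeric(distance_mm),
                 temperature = as.numeric(temperature), time_s = time_s),
            class = "thermal_profile")
}

#' @export
print.thermal_profile <- function(x, ...) {
  cat(sprintf("<thermal_profile: %d points, %.2f..%.2f mm, %.1f..%.1f degC>\n",
              length(x$distance_mm), min(x$distance_mm), max(x$distance_mm),
              min(x$temperature), max(x$temperature)))
  invisible(x)
}

#' Read / write two-column profile CSV
#'
#' Columns `distance_mm`, `temperature_C` with a header.
#'
#' @param path CSV path.
#' @return A [thermal_profile()] object.
#' @export
read_profile_csv <- function(path) {
  d <- utils::read.csv(path)
  thermal_profile(d[[1]], d[[2]])
}

#' @rdname read_profile_csv
#' @param profile A [thermal_profile()] to write.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(data.frame(distance_mm = profile$distance_mm,
                              temperature_C = profile$temperature),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a thermal frame from a matrix CSV
#'
#' The CSV holds one temperature value per pixel (rows x columns, header
#' optional as written by [write.csv()]).
#'
#' @param path CSV path.
#' @param pitch_mm Pixel pitch (mm/pixel).
#' @param time_s,frame_rate_hz Passed to [thermal_frame()].
#' @return A [thermal_frame()] object.
#' @export
read_frame_csv <- function(path, pitch_mm, time_s = 0, frame_rate_hz = 30) {
  thermal_frame(as.matrix(utils::read.csv(path)), pitch_mm,
                time_s = time_s, frame_rate_hz = frame_rate_hz)
}

#' Extract an edge-area temperature profile
#'
#' Samples temperature along the heat-spread (x) axis at a fixed time,
#' reporting distance in mm outward from the electrode edge.
#'
#' For a `weld_sim`, the top tissue surface is sampled along the centre y
#' row at the stored checkpoint nearest to `time` (an error if no
#' checkpoint is within `dt` of it); for a list of [thermal_frame()]s the
#' frame nearest in time is sampled along pixel row `line` starting at
#' pixel column `origin_px` (the electrode edge).
#'
#' @param x A `weld_sim` result or a list of `thermal_frame`s.
#' @param time Requested time (s).
#' @param ... Method arguments.
#' @return A [thermal_profile()] object.
#' @export
extract_profile <- function(x, time, ...) UseMethod("extract_profile")

#' @rdname extract_profile
#' @export
extract_profile.weld_sim <- function(x, time, ...) {
  if (length(x$checkpoints) == 0L)
    stop("simulation stored no checkpoints")
  dtime <- abs(x$checkpoint_times - time)
  if (min(dtime) > x$config$dt + 1e-9)
    stop("time ", time, " s outside the recorded checkpoints")
  arr <- x$checkpoints[[which.min(dtime)]]
  geom <- x$geometry
  k <- .k_tissue_top(geom)
  j <- max(1L, geom$ny %/% 2L)
  Tline <- arr[, j, k]
  sel <- which(geom$xc >= geom$edge_x - 1e-12)
  thermal_profile((geom$xc[sel] - geom$edge_x) * 1e3, Tline[sel],
                  time_s = x$checkpoint_times[which.min(dtime)])
}

#' @rdname extract_profile
#' @param line Pixel row index (1-based) to sample along.
#' @param origin_px Pixel column (1-based) of the electrode edge.
#' @export
extract_profile.list <- function(x, time, line, origin_px = 1L, ...) {
  stopifnot(length(x) >= 1L, inherits(x[[1]], "thermal_frame"))
  tms <- vapply(x, function(f) f$time_s, numeric(1))
  if (time < min(tms) - 1e-9 || time > max(tms) + 1e-9)
    stop("time ", time, " s outside the frame record")
  fr <- x[[which.min(abs(tms - time))]]
  if (line < 1L || line > nrow(fr$values))
    stop("line outside the frame")
  vals <- fr$values[line, origin_px:ncol(fr$values)]
  thermal_profile((seq_along(vals) - 1) * fr$pitch_mm, vals,
                  time_s = fr$time_s)
}

#' Fitting degree between simulated and measured profiles
#'
#' Quantifies the agreement of a simulated edge-area profile with an
#' infrared measurement as the coefficient of determination in percent,
#' `100 (1 - SS_res / SS_tot)`, after restricting to the window
#' `x >= window_start` (the band nearer the electrode is excluded because
#' the electrode heat sink displaces the measured maximum there) and
#' interpolating the simulation onto the measurement grid (the measurement
#' is ground truth).  An alternative normalised-RMSE metric
#' `100 (1 - RMSE / range)` is available via `method`.
#'
#' @param sim,meas [thermal_profile()] objects with overlapping x-ranges.
#' @param window_start Comparison window start (mm), default 1.
#' @param method `"r2"` (default) or `"nrmse"`.
#' @return A `fit_report` list: `fitting_degree` (%), `window` (mm),
#'   `rmse` (degC), `n` points.
#' @export
fitting_degree <- function(sim, meas, window_start = 1,
                           method = c("r2", "nrmse")) {
  stopifnot(inherits(sim, "thermal_profile"),
            inherits(meas, "thermal_profile"))
  method <- match.arg(method)
  lo <- max(window_start, min(sim$distance_mm), min(meas$distance_mm))
  hi <- min(max(sim$distance_mm), max(meas$distance_mm))
  if (hi <= lo) stop("profiles do not overlap on the comparison window")
  sel <- meas$distance_mm >= lo & meas$distance_mm <= hi
  xg <- meas$distance_mm[sel]
  if (length(xg) < 3L) stop("fewer than 3 measurement points in the window")
  ym <- meas$temperature[sel]
  ys <- stats::approx(sim$distance_mm, sim$temperature, xout = xg)$y
  ss_tot <- sum((ym - mean(ym))^2)
  if (ss_tot == 0)
    stop("measured profile is constant on the window; fitting degree undefined")
  ss_res <- sum((ym - ys)^2)
  fd <- if (method == "r2") 100 * (1 - ss_res / ss_tot)
  else 100 * (1 - sqrt(mean((ym - ys)^2)) / diff(range(ym)))
  structure(list(fitting_degree = fd, window = c(lo, hi),
                 rmse = sqrt(mean((ym - ys)^2)), n = length(xg),
                 method = method),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("<fit_report: %.2f%% (%s) on %.2f..%.2f mm, RMSE %.3f degC, n = %d>\n",
              x$fitting_degree, x$method, x$window[1], x$window[2], x$rmse,
              x$n))
  invisible(x)
}

#' Thermal diffusion width of a profile
#'
#' Width (mm) of the contiguous band, starting at the electrode edge, in
#' which the temperature exceeds ambient by more than `eps`.  The outer
#' crossing is located by linear interpolation; 0 if the first point is
#' already at ambient.
#'
#' @param profile A [thermal_profile()] object.
#' @param eps Threshold above ambient (degC), > 0; default 0.5.
#' @param ambient Ambient temperature (degC), default 25.
#' @return Width in mm.
#' @export
diffusion_width <- function(profile, eps = 0.5, ambient = 25) {
  stopifnot(inherits(profile, "thermal_profile"))
  if (eps <= 0) stop("eps must be > 0")
  x <- profile$distance_mm
  y <- profile$temperature
  thr <- ambient + eps
  if (y[1] <= thr) return(0)
  below <- which(y <= thr)
  if (length(below) == 0L) return(max(x) - x[1])
  i <- below[1]
  x0 <- x[i - 1]; x1 <- x[i]; y0 <- y[i - 1]; y1 <- y[i]
  xc <- if (y1 == y0) x1 else x0 + (thr - y0) / (y1 - y0) * (x1 - x0)
  xc - x[1]
}

#' Isotherm deviation rate
#'
#' The through-thickness displacement of an isotherm expressed as a
#' percentage of the thermal-diffusion width: `100 * deviation / width`.
#' Scaling both inputs by the same factor leaves the rate unchanged.
#'
#' @param isotherm_deviation Deviation (mm), >= 0.
#' @param diffusion_width Width (mm), > 0.
#' @return Percentage.
#' @examples
#' deviation_rate(0.24, 4.32)  # 5.56
#' @export
deviation_rate <- function(isotherm_deviation, diffusion_width) {
  if (diffusion_width <= 0) stop("diffusion width must be > 0")
  100 * isotherm_deviation / diffusion_width
}

# locate the outermost +x position where a line profile crosses T_iso
.iso_x <- function(xc, Tline, T_iso) {
  above <- which(Tline >= T_iso)
  if (length(above) == 0L) return(NA_real_)
  i <- max(above)
  if (i == length(Tline)) return(xc[i])
  x0 <- xc[i]; x1 <- xc[i + 1]; y0 <- Tline[i]; y1 <- Tline[i + 1]
  if (y1 == y0) return(x1)
  x0 + (T_iso - y0) / (y1 - y0) * (x1 - x0)
}

#' Through-thickness isotherm deviation
#'
#' Locates the outermost x-position of the `T_iso` isotherm on the top and
#' bottom tissue surfaces (centre y row, both +x and -x halves for a
#' simulated field) and returns the maximum displacement between them, in
#' mm.  A z-uniform field gives 0.
#'
#' @param x A `weld_sim` result, or a 3-D temperature array.
#' @param time Checkpoint time (s) when `x` is a `weld_sim`.
#' @param T_iso Isotherm temperature (degC).
#' @param geom A [build_geometry()] object (required for an array input).
#' @return Maximum |dx| (mm).
#' @export
isotherm_z_deviation <- function(x, T_iso, time = NULL, geom = NULL) {
  if (inherits(x, "weld_sim")) {
    if (is.null(time)) stop("time is required for a weld_sim input")
    dtime <- abs(x$checkpoint_times - time)
    if (length(dtime) == 0L || min(dtime) > x$config$dt + 1e-9)
      stop("time ", time, " s outside the recorded checkpoints")
    arr <- x$checkpoints[[which.min(dtime)]]
    geom <- x$geometry
  } else {
    arr <- x
    if (is.null(geom)) stop("geom is required for an array input")
  }
  j <- max(1L, geom$ny %/% 2L)
  ktop <- .k_tissue_top(geom)
  kbot <- .k_tissue_bottom(geom)
  xc <- geom$xc * 1e3
  devs <- c()
  for (side in c(1, -1)) {
    ord <- if (side > 0) order(xc) else order(-xc)
    xs <- side * xc[ord]
    top <- .iso_x(xs, arr[ord, j, ktop], T_iso)
    bot <- .iso_x(xs, arr[ord, j, kbot], T_iso)
    if (is.na(top) || is.na(bot)) next
    devs <- c(devs, abs(top - bot))
  }
  if (length(devs) == 0L)
    stop("isotherm at ", T_iso, " degC absent from the field")
  max(devs)
}
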