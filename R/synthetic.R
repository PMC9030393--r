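# Synthetic-data generators: IR frame sequences, Raman spectra and T-peel
# strength samples with the statistical structure the analysis stages
# assume.  All generators are pure functions of (config, seed).

#' Configuration for synthetic IR sequences
#'
#' Emulates a 30 Hz infrared recording of the exposed tissue surface.
#' The field source is either a `weld_sim` result (its top tissue surface
#' is resampled onto the pixel grid) or an analytic function
#' `f(x_mm, y_mm, t_s)` returning degC.  Frames default to a down-scaled
#' 96 x 128 grid for speed; the full 384 x 512 sensor is available by
#' setting `frame_size`.  Sensor noise is additive i.i.d. Gaussian (the
#' camera's rated accuracy of +-0.1 degC motivates sd defaults of
#' 0.05-0.2).  Optional blob artefacts emulate residual adipose tissue
#' disturbing the surface temperature.
#'
#' @param field A `weld_sim` or `function(x_mm, y_mm, t_s)`.
#' @param frame_rate_hz Frames per second, > 0. Default 30.
#' @param frame_size `c(rows, cols)` pixels. Default `c(96, 128)`.
#' @param pitch_mm Pixel pitch (mm/pixel). Default 0.15.
#' @param noise_sd Gaussian noise sd (degC), >= 0. Default 0.1.
#' @param duration_s Recording length (s). Default 1.
#' @param t_start_s Time of the first frame (s). Default 0.
#' @param artifacts Optional data frame (`x_mm`, `y_mm`, `radius_mm`,
#'   `amplitude_C`) of Gaussian blob artefacts.
#' @param seed RNG seed.
#' @return An `ir_synthetic_config` list.
#' @export
ir_synthetic_config <- function(field, frame_rate_hz = 30,
                                frame_size = c(96, 128), pitch_mm = 0.15,
                                noise_sd = 0.1, duration_s = 1,
                                t_start_s = 0, artifacts = NULL,
                                seed = 1) {
  if (frame_rate_hz <= 0) stop("frame rate must be > 0")
  if (noise_sd < 0) stop("noise sd must be >= 0")
  structure(list(field = field, frame_rate_hz = frame_rate_hz,
                 frame_size = frame_size, pitch_mm = pitch_mm,
                 noise_sd = noise_sd, duration_s = duration_s,
                 t_start_s = t_start_s, artifacts = artifacts, seed = seed),
            class = "ir_synthetic_config")
}

# evaluate the configured field on the pixel grid (centres) at time t
.ir_eval_field <- function(config, t) {
  rows <- config$frame_size[1]
  cols <- config$frame_size[2]
  # pixel centres, camera centred over the slab centre
  xs <- (seq_len(cols) - (cols + 1) / 2) * config$pitch_mm
  ys <- (seq_len(rows) - (rows + 1) / 2) * config$pitch_mm
  f <- config$field
  if (inherits(f, "weld_sim")) {
    geom <- f$geometry
    dtime <- abs(f$checkpoint_times - t)
    if (length(dtime) == 0L || min(dtime) > f$config$dt + 1e-9)
      stop("time ", t, " s outside the simulation checkpoints")
    arr <- f$checkpoints[[which.min(dtime)]]
    sl <- arr[, , .k_tissue_top(geom)]
    xc <- geom$xc * 1e3
    yc <- geom$yc * 1e3
    ix <- findInterval(xs, xc, all.inside = TRUE)
    iy <- findInterval(ys, yc, all.inside = TRUE)
    # bilinear interpolation, clamped at the slab border
    interp1 <- function(grid, pos, i) {
      lo <- pmin(pmax(i, 1L), length(grid) - 1L)
      w <- (pos - grid[lo]) / (grid[lo + 1L] - grid[lo])
      pmin(pmax(w, 0), 1)
    }
    wx <- interp1(xc, xs, ix)
    wy <- interp1(yc, ys, iy)
    out <- matrix(NA_real_, rows, cols)
    for (r in seq_len(rows)) {
      a <- sl[cbind(ix, rep(iy[r], cols))]
      b <- sl[cbind(ix + 1L, rep(iy[r], cols))]
      cc <- sl[cbind(ix, rep(iy[r] + 1L, cols))]
      d <- sl[cbind(ix + 1L, rep(iy[r] + 1L, cols))]
      out[r, ] <- (1 - wy[r]) * ((1 - wx) * a + wx * b) +
        wy[r] * ((1 - wx) * cc + wx * d)
    }
    out
  } else if (is.function(f)) {
    outer(ys, xs, function(Y, X) {
      v <- f(X, Y, t)
      if (length(v) == length(X)) v
      else vapply(seq_along(X), function(i) f(X[i], Y[i], t), numeric(1))
    })
  } else {
    stop("field must be a weld_sim or a function(x_mm, y_mm, t_s)")
  }
}

#' Generate a synthetic IR frame sequence
#'
#' @param config An [ir_synthetic_config()] object.
#' @return List of [thermal_frame()] objects; deterministic for a fixed
#'   seed.
#' @export
gen_ir_sequence <- function(config) {
  stopifnot(inherits(config, "ir_synthetic_config"))
  set.seed(config$seed)
  nframes <- max(1L, as.integer(round(config$duration_s *
                                        config$frame_rate_hz)))
  rows <- config$frame_size[1]
  cols <- config$frame_size[2]
  xs <- (seq_len(cols) - (cols + 1) / 2) * config$pitch_mm
  ys <- (seq_len(rows) - (rows + 1) / 2) * config$pitch_mm
  art <- config$artifacts
  lapply(seq_len(nframes), function(s) {
    t <- config$t_start_s + (s - 1) / config$frame_rate_hz
    vals <- .ir_eval_field(config, t)
    if (!is.null(art))
      for (a in seq_len(nrow(art))) {
        d2 <- outer((ys - art$y_mm[a])^2, (xs - art$x_mm[a])^2, `+`)
        vals <- vals + art$amplitude_C[a] *
          exp(-d2 / (2 * art$radius_mm[a]^2))
      }
    if (config$noise_sd > 0)
      vals <- vals + matrix(stats::rnorm(rows * cols, 0, config$noise_sd),
                            rows, cols)
    thermal_frame(vals, config$pitch_mm, time_s = t,
                  frame_rate_hz = config$frame_rate_hz)
  })
}

#' Configuration for synthetic Raman spectra
#'
#' A sum of pseudo-Voigt peaks on a polynomial baseline with Gaussian
#' noise, on a 1 1/cm grid over the fingerprint window.  The default peak
#' pair emulates the amide-III region of vessel collagen (centres near
#' 1247 and 1325 1/cm, FWHM 30-130 1/cm as observed across weld states).
#'
#' @param peaks Data frame (`center`, `height`, `fwhm`, `eta`).
#' @param baseline Polynomial coefficients (ascending powers of the
#'   0-1-rescaled wavenumber).
#' @param wavenumber Grid (1/cm). Default `seq(800, 2000, 1)`.
#' @param noise_sd Gaussian noise sd (a.u.). Default 0.
#' @param seed RNG seed.
#' @return A `raman_synthetic_config` list.
#' @export
raman_synthetic_config <- function(
    peaks = data.frame(center = c(1247, 1325), height = c(3227, 1409),
                       fwhm = c(37, 51), eta = c(0.5, 0.5)),
    baseline = c(0, 0), wavenumber = seq(800, 2000, 1),
    noise_sd = 0, seed = 1) {
  stopifnot(all(c("center", "height", "fwhm", "eta") %in% names(peaks)))
  if (any(peaks$fwhm <= 0)) stop("FWHM must be > 0")
  if (any(peaks$center < min(wavenumber) | peaks$center > max(wavenumber)))
    stop("peaks must lie inside the wavenumber grid")
  if (noise_sd < 0) stop("noise sd must be >= 0")
  structure(list(peaks = peaks, baseline = baseline,
                 wavenumber = wavenumber, noise_sd = noise_sd, seed = seed),
            class = "raman_synthetic_config")
}

#' Generate a synthetic Raman spectrum
#'
#' @param config A [raman_synthetic_config()] object.
#' @return List with `spectrum` (a [raman_spectrum()]), `truth` (the peak
#'   table) and `baseline` (evaluated baseline).  Deterministic for a
#'   fixed seed.
#' @export
gen_raman_spectrum <- function(config) {
  stopifnot(inherits(config, "raman_synthetic_config"))
  set.seed(config$seed)
  nu <- config$wavenumber
  y <- numeric(length(nu))
  for (p in seq_len(nrow(config$peaks)))
    y <- y + pseudo_voigt(nu, config$peaks$center[p],
                          config$peaks$height[p], config$peaks$fwhm[p],
                          config$peaks$eta[p])
  u <- (nu - min(nu)) / diff(range(nu))
  bl <- numeric(length(nu))
  for (d in seq_along(config$baseline))
    bl <- bl + config$baseline[d] * u^(d - 1)
  y <- y + bl
  if (config$noise_sd > 0)
    y <- y + stats::rnorm(length(nu), 0, config$noise_sd)
  list(spectrum = raman_spectrum(nu, y), truth = config$peaks,
       baseline = bl)
}

#' Configuration for synthetic strength samples
#'
#' Per-group F-unit draws from a normal distribution truncated at zero
#' (forces cannot be negative; the truncation bias is negligible at the
#' reference mean/sd scales).  Defaults follow the reference bench data:
#' group means 0.10/0.15/0.24/0.32/0.70 N/mm for 10-30 s, 10 samples per
#' group, and a high failure probability only in the 30 s group where
#' welds burn out.
#'
#' @param groups Welding times (s).
#' @param means,sds Per-group F-unit mean and sd (N/mm).
#' @param n Samples per group. Default 10.
#' @param failure_prob Per-group probability a sample is `damaged`.
#' @param width_mean,width_sd Weld width distribution (mm).
#' @param seed RNG seed.
#' @return A `strength_synthetic_config` list.
#' @export
strength_synthetic_config <- function(
    groups = c(10, 15, 20, 25, 30),
    means = c(0.10, 0.15, 0.24, 0.32, 0.70),
    sds = c(0.025, 0.03, 0.025, 0.022, 0.10),
    n = 10, failure_prob = c(0.2, 0, 0, 0, 0.6),
    width_mean = 5, width_sd = 0.5, seed = 1) {
  stopifnot(length(means) == length(groups),
            length(sds) == length(groups))
  if (any(sds < 0)) stop("sds must be >= 0")
  if (n < 1) stop("n must be >= 1")
  failure_prob <- rep_len(failure_prob, length(groups))
  structure(list(groups = groups, means = means, sds = sds, n = n,
                 failure_prob = failure_prob, width_mean = width_mean,
                 width_sd = width_sd, seed = seed),
            class = "strength_synthetic_config")
}

#' Generate synthetic strength samples
#'
#' @param config A [strength_synthetic_config()] object.
#' @return Data frame with columns `sample_id`, `weld_time_s`,
#'   `peak_force_N`, `weld_width_mm`, `status`.  Deterministic for a
#'   fixed seed.
#' @export
gen_strength_samples <- function(config) {
  stopifnot(inherits(config, "strength_synthetic_config"))
  set.seed(config$seed)
  rows <- list()
  for (gi in seq_along(config$groups)) {
    for (s in seq_len(config$n)) {
      # truncated-at-zero normal by rejection
      repeat {
        fu <- stats::rnorm(1, config$means[gi], config$sds[gi])
        if (fu >= 0) break
      }
      width <- max(0.5, stats::rnorm(1, config$width_mean, config$width_sd))
      failed <- stats::runif(1) < config$failure_prob[gi]
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("t%02d_s%02d", config$groups[gi], s),
        weld_time_s = config$groups[gi],
        peak_force_N = fu * width, weld_width_mm = width,
        status = if (failed) "damaged" else "ok",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
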