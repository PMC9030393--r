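# Welding-phase classification: collagen denaturation begins near 40 degC
# and thermal damage near 60 degC, dividing a weld into phase I (baseline
# heating), II (denaturation / re-crosslinking) and III (thermal damage).

#' Phase thresholds
#'
#' @param onset Collagen-denaturation onset (degC), default 40.
#' @param damage Thermal-damage onset (degC), default 60; must exceed
#'   `onset`.
#' @return An object of class `phase_thresholds`.
#' @export
phase_thresholds <- function(onset = 40, damage = 60) {
  if (!(onset < damage)) stop("onset must be below damage threshold")
  structure(list(onset = onset, damage = damage),
            class = "phase_thresholds")
}

#' Classify a temperature into a welding phase
#'
#' Half-open upward convention: a temperature exactly at a threshold
#' belongs to the higher phase, so phase I is `T < onset`, phase II is
#' `onset <= T < damage`, phase III is `T >= damage`.
#'
#' @param T Temperature(s), degC, finite. Vectorised.
#' @param thresholds A [phase_thresholds()] object.
#' @return Ordered factor with levels `I < II < III`.
#' @export
classify_phase <- function(T, thresholds = phase_thresholds()) {
  if (any(!is.finite(T))) stop("temperature must be finite")
  phase <- ifelse(T >= thresholds$damage, "III",
                  ifelse(T >= thresholds$onset, "II", "I"))
  factor(phase, levels = c("I", "II", "III"), ordered = TRUE)
}

#' Phase-boundary crossing times
#'
#' First crossing times of the two thresholds in a central-temperature
#' history, by linear interpolation between recorded steps.  The history
#' is expected to be monotone non-decreasing (heating); if it is not, a
#' warning is raised and the first crossings are still returned.
#'
#' @param time,temperature History vectors (s, degC).
#' @param thresholds A [phase_thresholds()] object.
#' @return List with `onset_time` and `damage_time` (s; `NA` when never
#'   crossed), each rounded to 0.1 s in the printed summary but returned
#'   at full precision.
#' @export
phase_boundaries <- function(time, temperature,
                             thresholds = phase_thresholds()) {
  stopifnot(length(time) == length(temperature))
  if (any(diff(temperature) < -1e-9))
    warning("temperature history is not monotone non-decreasing")
  structure(list(onset_time = crossing_time(time, temperature,
                                            thresholds$onset),
                 damage_time = crossing_time(time, temperature,
                                             thresholds$damage),
                 thresholds = thresholds),
            class = "phase_boundaries")
}

#' @export
print.phase_boundaries <- function(x, ...) {
  fmt <- function(t) if (is.na(t)) "never" else sprintf("%.1f s", t)
  cat(sprintf("<phase_boundaries: %g degC at %s, %g degC at %s>\n",
              x$thresholds$onset, fmt(x$onset_time),
              x$thresholds$damage, fmt(x$damage_time)))
  invisible(x)
}

#' Temperature range
#'
#' @param low,high Bounds (degC), `low <= high`.
#' @param provenance Label: `"strength"`, `"raman"`, `"phase"` or other.
#' @return An object of class `temperature_range`.
#' @export
temperature_range <- function(low, high, provenance = NA_character_) {
  if (low > high) stop("low must be <= high")
  structure(list(low = low, high = high, provenance = provenance),
            class = "temperature_range")
}

#' Intersect temperature ranges
#'
#' `[max of lows, min of highs]`; the result carries `empty = TRUE` when
#' the ranges do not overlap.  Commutative and associative; intersecting
#' with a superset is the identity.
#'
#' @param ranges List of [temperature_range()] objects (>= 1).
#' @return A `temperature_range` (provenance `"intersection"`) with an
#'   additional `empty` flag.
#' @export
intersect_ranges <- function(ranges) {
  if (length(ranges) < 1L) stop("at least one range required")
  stopifnot(all(vapply(ranges, inherits, logical(1), "temperature_range")))
  lo <- max(vapply(ranges, function(r) r$low, numeric(1)))
  hi <- min(vapply(ranges, function(r) r$high, numeric(1)))
  out <- structure(list(low = min(lo, hi), high = hi,
                        provenance = "intersection"),
                   class = "temperature_range")
  out$empty <- lo > hi
  if (!out$empty) out$low <- lo
  out
}

#' @export
print.temperature_range <- function(x, ...) {
  if (isTRUE(x$empty)) cat("<temperature_range: empty>\n")
  else cat(sprintf("<temperature_range: %g..%g degC (%s)>\n", x$low,
                   x$high, x$provenance))
  invisible(x)
}
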