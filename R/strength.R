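# T-peel strength analysis: F-unit normalisation (peel force per unit weld
# width), exclusion of failed samples, per-group statistics, and
# inter-group change rates.

#' Strength sample
#'
#' One T-peel test record.  The force may be a scalar peak or a full
#' force-displacement trace, in which case its maximum is taken.
#'
#' @param force Peak force (N) or a numeric force trace.
#' @param width Weld width (mm), > 0 for testable samples.
#' @param weld_time_s Welding-time group (s).
#' @param status One of `"ok"`, `"no_weld"`, `"damaged"`.
#' @param sample_id Optional label.
#' @return A one-row data frame (columns `sample_id`, `weld_time_s`,
#'   `peak_force_N`, `weld_width_mm`, `status`).
#' @export
strength_sample <- function(force, width, weld_time_s,
                            status = c("ok", "no_weld", "damaged"),
                            sample_id = NA_character_) {
  status <- match.arg(status)
  peak <- max(force)
  if (peak < 0) stop("peak force must be >= 0")
  if (status == "ok" && width <= 0)
    stop("weld width must be > 0 for testable samples")
  data.frame(sample_id = sample_id, weld_time_s = weld_time_s,
             peak_force_N = peak, weld_width_mm = width, status = status,
             stringsAsFactors = FALSE)
}

#' F-unit: peel strength per unit weld width
#'
#' Normalising by the weld width makes welds of different footprint sizes
#' comparable.
#'
#' @param force Peak force (N).
#' @param width Weld width (mm), > 0.
#' @return Strength in N/mm.
#' @export
f_unit <- function(force, width) {
  if (any(width <= 0)) stop("weld width must be > 0")
  force / width
}

#' Drop samples without a testable weld
#'
#' Samples whose weld never formed (`no_weld`) or failed by thermal damage
#' (`damaged`) carry no strength reading and are excluded; the number
#' dropped per group is attached as attribute `dropped`.
#'
#' @param samples Data frame with columns as in [strength_sample()].
#' @return Filtered data frame.
#' @export
filter_samples <- function(samples) {
  stopifnot(is.data.frame(samples))
  if (nrow(samples) == 0L) {
    attr(samples, "dropped") <- data.frame(weld_time_s = numeric(),
                                           dropped = integer())
    return(samples)
  }
  keep <- samples$status == "ok"
  dropped <- stats::aggregate(list(dropped = !keep),
                              by = list(weld_time_s = samples$weld_time_s),
                              FUN = sum)
  out <- samples[keep, , drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}

#' Per-group strength statistics
#'
#' Maximum, minimum and mean F-unit per welding-time group, computed from
#' unrounded per-sample values.  Groups left empty after filtering are
#' omitted with a warning.
#'
#' @param samples Data frame of ok samples (see [filter_samples()]).
#' @return Data frame `weld_time_s`, `n`, `max`, `min`, `mean` (N/mm).
#' @export
group_stats <- function(samples) {
  stopifnot(is.data.frame(samples))
  bad <- samples$status != "ok"
  if (any(bad)) {
    warning(sum(bad), " non-ok sample(s) ignored; use filter_samples()")
    samples <- samples[!bad, , drop = FALSE]
  }
  if (nrow(samples) == 0L) {
    warning("no testable samples; empty result")
    return(data.frame(weld_time_s = numeric(), n = integer(),
                      max = numeric(), min = numeric(), mean = numeric()))
  }
  fu <- f_unit(samples$peak_force_N, samples$weld_width_mm)
  agg <- stats::aggregate(
    list(stats = fu), by = list(weld_time_s = samples$weld_time_s),
    FUN = function(v) c(n = length(v), max = max(v), min = min(v),
                        mean = mean(v)))
  data.frame(weld_time_s = agg$weld_time_s,
             n = as.integer(agg$stats[, "n"]), max = agg$stats[, "max"],
             min = agg$stats[, "min"], mean = agg$stats[, "mean"])
}

#' Inter-group change rate
#'
#' Percentage change of the mean F-unit between consecutive welding-time
#' groups: `100 (curr / prev - 1)`.
#'
#' @param prev_mean Previous group mean (N/mm), > 0.
#' @param curr_mean Current group mean (N/mm).
#' @return Percentage change.
#' @examples
#' change_rate(0.244, 0.321)  # 31.56...
#' @export
change_rate <- function(prev_mean, curr_mean) {
  if (any(prev_mean <= 0)) stop("previous mean must be > 0")
  100 * (curr_mean / prev_mean - 1)
}

#' Full strength-table analysis
#'
#' Filters, aggregates and chains change rates, mirroring the standard
#' report layout (max/min/mean per group plus the rate against the
#' previous group).
#'
#' @param samples Data frame with columns `sample_id`, `weld_time_s`,
#'   `peak_force_N`, `weld_width_mm`, `status`.
#' @return Data frame `weld_time_s`, `n`, `max`, `min`, `mean`,
#'   `change_rate_pct` (NA for the first group).
#' @export
analyze_strength <- function(samples) {
  ok <- filter_samples(samples)
  gs <- group_stats(ok)
  gs <- gs[order(gs$weld_time_s), , drop = FALSE]
  gs$change_rate_pct <- c(NA_real_,
                          if (nrow(gs) > 1)
                            change_rate(gs$mean[-nrow(gs)], gs$mean[-1]))
  gs
}

#' Bundled reference strength summary
#'
#' Group-level T-peel strength summaries (max/min/mean F-unit, N/mm) for
#' welding times 10-30 s from high-frequency vessel-welding bench tests;
#' the defaults of the synthetic strength generator derive from it.
#'
#' @return Data frame `weld_time_s`, `max`, `min`, `mean`.
#' @export
reference_strength_groups <- function() {
  utils::read.csv(system.file("extdata", "vessel_weld_strength_groups.csv",
                              package = "weldtherm"))
}
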