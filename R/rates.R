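#' Radiotracer turnover rates
#'
#' Converts 14C tracer incubations to process rates with the single
#' time-point first-order turnover form:
#' `rate = (product_activity / added_activity) * pool / duration`
#' in nmol cm^-3 day^-1 (pool in uM is identically nmol cm^-3 under the
#' 1 cm^3 = 1 mL slurry volume convention). For acetate oxidation measured
#' as 14CO2, `co2_double = TRUE` multiplies the rate by 2 to account for the
#' two CO2 molecules produced per acetate.
#'
#' @param tracers Data frame of incubations with columns `added_activity`,
#'   `product_activity`, `pool`, `duration` (as from [observe_tracers()]).
#' @param co2_double Apply the x2 acetate-to-CO2 standardization.
#' @return The input with a `rate` column (nmol cm^-3 day^-1).
#' @examples
#' inc <- data.frame(added_activity = 100, product_activity = 1,
#'                   pool = 20000, duration = 1)
#' tracer_rate(inc)$rate            # 200
#' tracer_rate(inc, co2_double = TRUE)$rate  # 400
#' @export
tracer_rate <- function(tracers, co2_double = FALSE) {
  stopifnot(all(c("added_activity", "product_activity", "pool",
                  "duration") %in% names(tracers)))
  if (any(tracers$added_activity <= 0))
    stop("tracer_rate: added_activity must be > 0")
  if (any(tracers$product_activity < 0) ||
      any(tracers$product_activity > tracers$added_activity))
    stop("tracer_rate: product activity must lie in [0, added_activity]")
  if (any(tracers$duration <= 0))
    stop("tracer_rate: duration must be > 0")
  if (any(tracers$pool < 0))
    stop("tracer_rate: pool must be >= 0")
  frac <- tracers$product_activity / tracers$added_activity
  tracers$rate <- frac * tracers$pool / tracers$duration *
    (if (co2_double) 2 else 1)
  tracers
}

#' Aggregate tracer rates by the three-time-point convention
#'
#' Within each group (process x temperature x incubation start), replicate
#' rates are averaged within each of the (up to three) incubation time
#' points, and the group rate is the unweighted mean of the time-point
#' means; the reported dispersion is the standard deviation of the
#' time-point means. Time points are weighted equally regardless of how
#' many replicates each carries. Groups with a single usable time point get
#' sd 0 and `flag = "single_timepoint"`.
#'
#' @param rates Data frame with columns `rate`, `timepoint_index` and the
#'   grouping columns in `by`.
#' @param by Grouping columns.
#' @return Data frame: grouping columns, `rate`, `sd`, `n_timepoints`,
#'   `n_incubations`, `flag`.
#' @export
aggregate_rates <- function(rates,
                            by = c("process", "temperature", "start_day")) {
  if (nrow(rates) == 0) stop("aggregate_rates: empty input")
  by <- intersect(by, names(rates))
  key <- interaction(rates[by], drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(split(rates, key), function(g) {
    tp_means <- tapply(g$rate, g$timepoint_index, mean)
    res <- g[1, by, drop = FALSE]
    res$rate <- mean(tp_means)
    res$sd <- if (length(tp_means) > 1) stats::sd(tp_means) else 0
    res$n_timepoints <- length(tp_means)
    res$n_incubations <- nrow(g)
    res$flag <- if (length(tp_means) > 1) "ok" else "single_timepoint"
    res
  }))
  rownames(out) <- NULL
  out
}

#' Sulphate removal rates from concentration differences
#'
#' Sulphate reduction is quantified chemically: for each temperature, the
#' rate over each pair of consecutive sampling points is
#' `(c1 - c2) / (t2 - t1)` (uM day^-1 = nmol cm^-3 day^-1), assigned to the
#' interval midpoint. Replicates are averaged per sampling point first.
#' Apparent negative removal (concentration increase, i.e. noise) is
#' reported as 0 with the raw signed value retained in `rate_raw`.
#'
#' @param series Long concentration data frame (as from
#'   [observe_concentrations()]) containing `species == "sulphate"` rows.
#' @param species Name of the sulphate species column value.
#' @return Data frame: `process` ("sulphate_removal"), `temperature`,
#'   `time` (interval midpoint, days), `rate`, `rate_raw`, `rate_sd`
#'   (standard error of the interval rate propagated from replicate
#'   spread), `n`.
#' @export
sulphate_removal_rates <- function(series, species = "sulphate") {
  so4 <- series[series$species == species, ]
  if (nrow(so4) == 0) stop("sulphate_removal_rates: no sulphate rows")
  if (anyDuplicated(so4[c("temperature", "time", "replicate")]))
    stop("sulphate_removal_rates: duplicate (temperature, time, replicate) rows")
  out <- do.call(rbind, lapply(split(so4, so4$temperature), function(g) {
    m <- tapply(g$value, g$time, mean)
    se2 <- tapply(g$value, g$time,
                  function(v) if (length(v) > 1)
                    stats::var(v) / length(v) else 0)
    tt <- as.numeric(names(m))
    o <- order(tt); tt <- tt[o]; m <- m[o]; se2 <- se2[o]
    if (length(tt) < 2)
      stop("sulphate_removal_rates: need >= 2 time points at T = ",
           g$temperature[1], " C")
    raw <- -diff(m) / diff(tt)
    # propagated standard error of each interval rate from replicate spread
    sd_rate <- sqrt(se2[-1] + se2[-length(se2)]) / diff(tt)
    data.frame(process = "sulphate_removal",
               temperature = g$temperature[1],
               time = (tt[-1] + tt[-length(tt)]) / 2,
               rate = pmax(raw, 0), rate_raw = raw, rate_sd = sd_rate,
               n = length(unique(g$replicate)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-temperature maximum rates
#'
#' For each (process, temperature), keeps the maximum rate over time,
#' carrying its time stamp; ties keep the earliest time. These maxima are
#' the inputs of the Arrhenius analysis.
#'
#' @param rates Data frame with `process`, `temperature`, `time`, `rate`.
#' @param time_col Name of the time column (e.g. `"start_day"` for
#'   aggregated tracer rates).
#' @return One row per (process, temperature): `process`, `temperature`,
#'   `time`, `rate`.
#' @export
max_rate_profile <- function(rates, time_col = "time") {
  stopifnot(all(c("process", "temperature", time_col, "rate") %in%
                  names(rates)))
  key <- interaction(rates$process, rates$temperature, drop = TRUE)
  out <- do.call(rbind, lapply(split(rates, key), function(g) {
    g <- g[order(g[[time_col]]), ]
    i <- which.max(g$rate)   # which.max takes the first (earliest) tie
    data.frame(process = g$process[1], temperature = g$temperature[1],
               time = g[[time_col]][i], rate = g$rate[i],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
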