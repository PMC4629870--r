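#' Lower bound on the hydrogenotrophic fraction of sulphate reduction
#'
#' Total acetate oxidation (tracer-measured in CO2 units) caps how much
#' sulphate reduction can run on acetate: with two CO2 per acetate and 1:1
#' acetate:sulphate stoichiometry, at most `min(srr, acox_co2 / 2)` of the
#' sulphate removal rate can be acetoclastic. The remainder is a lower
#' bound on the fraction driven by H2 (or other non-acetate donors):
#' `fraction_h2_min = (srr - min(srr, acox_co2/2)) / srr`, 0 when srr = 0
#' (flagged degenerate).
#'
#' @param srr Sulphate removal rate(s), nmol cm^-3 day^-1.
#' @param acox_co2 Total acetate oxidation rate(s) in CO2 units,
#'   nmol cm^-3 day^-1.
#' @return Data frame: `srr`, `acox_acetate_units`, `fraction_h2_min`,
#'   `flag`.
#' @examples
#' h2_fraction_bound(100, 58)$fraction_h2_min   # 0.71
#' @export
h2_fraction_bound <- function(srr, acox_co2) {
  if (any(srr < 0) || any(acox_co2 < 0))
    stop("h2_fraction_bound: rates must be >= 0")
  acox_acetate <- acox_co2 / 2
  frac <- ifelse(srr > 0, (srr - pmin(srr, acox_acetate)) / srr, 0)
  data.frame(srr = srr, acox_acetate_units = acox_acetate,
             fraction_h2_min = frac,
             flag = ifelse(srr > 0, "ok", "degenerate"),
             stringsAsFactors = FALSE)
}

#' Substrate partition of sulphate reduction across temperature
#'
#' Pairs sulphate removal with total acetate oxidation per temperature and
#' applies [h2_fraction_bound()], reporting the lowest temperature at which
#' at least half of sulphate reduction must be hydrogenotrophic. Pairing
#' `"max"` uses each profile's per-temperature maximum over time
#' (the convention of maximum-activity comparisons); `"timewise"` evaluates
#' the bound at the time of the sulphate-removal maximum using the
#' time-matched acetate oxidation rate.
#'
#' Concentration-difference rates carry substantial uncertainty when the
#' pool is large and the signal small (a few percent noise on a >20 mM
#' sulphate pool swamps slow removal). When `srr_rates` carries a `rate_sd`
#' column (as from [sulphate_removal_rates()]), temperatures whose paired
#' rate falls below `min_signal` standard errors are flagged
#' `below_quantification` and excluded from the threshold scan.
#'
#' @param srr_rates Data frame `temperature`, `time`, `rate` (optionally
#'   `rate_sd`) for sulphate removal.
#' @param acox_rates Same layout for acetate oxidation in CO2 units.
#' @param pairing `"max"` or `"timewise"`.
#' @param min_signal Signal-to-noise multiple a rate must exceed to count
#'   as quantifiable (used only when `rate_sd` is present).
#' @param sustain The reported threshold is the lowest quantifiable
#'   temperature at which the fraction reaches 0.5 and stays there for this
#'   many consecutive quantifiable grid temperatures (truncated at the top
#'   of the grid); guards the critical-temperature call against isolated
#'   noise spikes.
#' @return List of class `partition_profile`: `table` (per-temperature
#'   bound), `threshold_temp` (lowest quantifiable T with a sustained
#'   fraction >= 0.5, `NA` if never reached), `flag`.
#' @export
partition_profile <- function(srr_rates, acox_rates,
                              pairing = c("max", "timewise"),
                              min_signal = 2, sustain = 3) {
  pairing <- match.arg(pairing)
  temps <- sort(unique(srr_rates$temperature))
  miss <- setdiff(temps, unique(acox_rates$temperature))
  if (length(miss))
    stop("partition_profile: acetate oxidation missing at temperature(s): ",
         paste(miss, collapse = ", "))
  has_sd <- "rate_sd" %in% names(srr_rates)
  rows <- lapply(temps, function(T_) {
    s <- srr_rates[srr_rates$temperature == T_, ]
    a <- acox_rates[acox_rates$temperature == T_, ]
    i_max <- which.max(s$rate)
    srr <- s$rate[i_max]
    if (pairing == "max") {
      acox <- max(a$rate)
    } else {
      j <- which.min(abs(a$time - s$time[i_max]))
      acox <- a$rate[j]
    }
    r <- cbind(temperature = T_, h2_fraction_bound(srr, acox))
    if (has_sd && srr < min_signal * s$rate_sd[i_max])
      r$flag <- "below_quantification"
    r
  })
  tab <- do.call(rbind, rows)
  q <- tab[tab$flag == "ok", ]
  above <- q$fraction_h2_min >= 0.5
  hit <- NA_real_
  for (i in which(above)) {
    run <- seq(i, min(i + sustain - 1, nrow(q)))
    if (all(above[run])) { hit <- q$temperature[i]; break }
  }
  structure(list(table = tab,
                 threshold_temp = hit,
                 flag = if (is.na(hit)) "never_reached" else "ok",
                 pairing = pairing),
            class = "partition_profile")
}

#' @export
print.partition_profile <- function(x, ...) {
  cat(sprintf("Sulphate-reduction partition (%s pairing), %d temperatures\n",
              x$pairing, nrow(x$table)))
  if (is.na(x$threshold_temp))
    cat("  >= 50% hydrogenotrophic bound never reached\n")
  else
    cat(sprintf("  >= 50%% hydrogenotrophic from %g C\n", x$threshold_temp))
  invisible(x)
}

# simple least squares of y on x returning the residual sum of squares
linfit_sse <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- if (sxx > 0) sum((x - mx) * (y - my)) / sxx else 0
  intercept <- my - slope * mx
  list(slope = slope, intercept = intercept,
       sse = sum((y - intercept - slope * x)^2))
}

#' Detect a critical temperature as a two-segment breakpoint
#'
#' Exhaustive two-segment least squares: for each candidate break with at
#' least three points strictly below and three at/above, both segments are
#' fit by OLS and the candidate minimizing the total SSE is returned (ties
#' resolved to the lowest temperature). `improvement` compares against a
#' single straight-line fit; values near 0 mean the data carry no
#' detectable break.
#'
#' @param x Temperatures (or any ordinate), degrees C.
#' @param y Response (e.g. ln rate, net mineralization).
#' @param grid Candidate break positions.
#' @return List of class `breakpoint_result`: `break_temp`, `sse_total`,
#'   `left_fit`/`right_fit` (slope + intercept), `sse_single`,
#'   `improvement`.
#' @export
detect_breakpoint <- function(x, y, grid) {
  stopifnot(length(x) == length(y))
  best <- NULL
  for (b in sort(grid)) {
    li <- x < b
    if (sum(li) < 3 || sum(!li) < 3) next
    fl <- linfit_sse(x[li], y[li])
    fr <- linfit_sse(x[!li], y[!li])
    sse <- fl$sse + fr$sse
    if (is.null(best) || sse < best$sse_total - 1e-12)
      best <- list(break_temp = b, sse_total = sse,
                   left_fit = fl, right_fit = fr)
  }
  if (is.null(best))
    stop("detect_breakpoint: no candidate with >= 3 points on each side")
  f1 <- linfit_sse(x, y)
  best$sse_single <- f1$sse
  best$improvement <- if (f1$sse > 0) 1 - best$sse_total / f1$sse else 0
  structure(best, class = "breakpoint_result")
}

#' @export
print.breakpoint_result <- function(x, ...) {
  cat(sprintf(
    "Breakpoint at %g C (SSE %.4g vs single-fit %.4g, improvement %.1f%%)\n",
    x$break_temp, x$sse_total, x$sse_single, 100 * x$improvement))
  invisible(x)
}
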