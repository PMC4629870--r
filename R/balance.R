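#' Default CO2 standardizing factor table
#'
#' Signed mol CO2 generated (+) or consumed (-) per mol of each process's
#' reported rate unit, reconstructed from reaction stoichiometry:
#' hydrogenotrophic methanogenesis -1 (one CO2 fixed per CH4),
#' hydrogenotrophic acetogenesis -2 (two CO2 per acetate), acetoclastic
#' methanogenesis +1 (one CO2 per acetate split), methylotrophic
#' methanogenesis +0.25 (4 CH3NH2 -> 3 CH4 + CO2), acetate oxidation to CO2
#' +1 (tracer rates already expressed in CO2 units), acetoclastic sulphate
#' reduction +2 and acetoclastic metal reduction +2 (full acetate
#' oxidation; the factor 2 for metal reduction is the standard
#' convention), hydrogenotrophic sulphate reduction 0 (no carbon). Fully
#' overridable; every process fed to the balance must have an entry.
#'
#' @return Named numeric vector, process -> factor.
#' @export
default_co2_factors <- function() {
  c(hydrogenotrophic_methanogenesis = -1,
    hydrogenotrophic_acetogenesis = -2,
    acetoclastic_methanogenesis = 1,
    methylotrophic_methanogenesis = 0.25,
    acetate_oxidation_co2 = 1,
    acetoclastic_sulphate_reduction = 2,
    hydrogenotrophic_sulphate_reduction = 0,
    acetoclastic_metal_reduction = 2,
    sulphate_removal = 0)
}

#' CO2 contribution of one set of rate estimates
#'
#' `contribution = factor * rate`, in nmol CO2 cm^-3 day^-1. Missing
#' factors are an error (never silently defaulted).
#'
#' @param rates Data frame with `process` and `rate` columns.
#' @param factors Named factor table, as [default_co2_factors()].
#' @return The input with a `co2_rate` column.
#' @export
co2_contribution <- function(rates, factors = default_co2_factors()) {
  miss <- setdiff(unique(rates$process), names(factors))
  if (length(miss))
    stop("co2_contribution: no CO2 factor for process(es): ",
         paste(miss, collapse = ", "))
  rates$co2_rate <- unname(factors[rates$process]) * rates$rate
  rates
}

#' Net carbon mineralization balance
#'
#' Applies the standardizing factors to every per-process rate, sums the
#' signed contributions per (temperature, time) cell into a net CO2 rate,
#' and summarizes mean net rates below versus at/above a split temperature
#' (default 43 C, the critical temperature) together with their ratio.
#'
#' @param rates Data frame with `process`, `temperature`, `time`, `rate`.
#' @param factors Named CO2 factor table.
#' @param split_temp Split temperature, degrees C.
#' @return List of class `mineralization_balance`: `cells` (per-cell net
#'   rate and per-process contribution columns), `summary` (mean net rate
#'   below / at-or-above the split and `ratio` below/above), `split_temp`.
#' @export
net_balance <- function(rates, factors = default_co2_factors(),
                        split_temp = 43) {
  if (nrow(rates) == 0)
    return(structure(list(cells = rates, summary = NULL,
                          split_temp = split_temp),
                     class = "mineralization_balance"))
  contrib <- co2_contribution(rates, factors)
  wide <- stats::reshape(
    contrib[c("process", "temperature", "time", "co2_rate")],
    idvar = c("temperature", "time"), timevar = "process",
    direction = "wide")
  pcols <- setdiff(names(wide), c("temperature", "time"))
  names(wide)[match(pcols, names(wide))] <- sub("^co2_rate\\.", "", pcols)
  pcols <- setdiff(names(wide), c("temperature", "time"))
  wide$net <- rowSums(wide[pcols], na.rm = TRUE)
  wide <- wide[order(wide$temperature, wide$time), ]
  rownames(wide) <- NULL
  below <- wide$temperature < split_temp
  mean_below <- mean(wide$net[below])
  mean_above <- mean(wide$net[!below])
  structure(list(
    cells = wide,
    summary = data.frame(mean_net_below = mean_below,
                         mean_net_above = mean_above,
                         ratio = mean_below / mean_above),
    split_temp = split_temp),
    class = "mineralization_balance")
}

#' @export
print.mineralization_balance <- function(x, ...) {
  cat(sprintf("Mineralization balance over %d (T, t) cells, split at %g C\n",
              nrow(x$cells), x$split_temp))
  if (!is.null(x$summary))
    cat(sprintf(
      "  mean net CO2 rate below %g C: %.1f, at/above: %.1f nmol cm-3 d-1 (ratio %.1f)\n",
      x$split_temp, x$summary$mean_net_below, x$summary$mean_net_above,
      x$summary$ratio))
  invisible(x)
}

#' Group shares of gross CO2 production
#'
#' Percentage of total positive (gross) CO2 production attributable to each
#' process group; CO2-consuming terms are excluded from both numerator and
#' denominator. Every CO2-producing process must be assigned a group.
#'
#' @param rates Data frame with `process` and `rate`.
#' @param factors Named CO2 factor table.
#' @param groups Named character vector, process -> group label.
#' @return Data frame `group`, `co2_production`, `share_percent`; attribute
#'   `flag` is `"undefined"` when there is no production at all.
#' @export
share_of_mineralization <- function(rates, factors = default_co2_factors(),
                                    groups = stats::setNames(
                                      unique(rates$process),
                                      unique(rates$process))) {
  contrib <- co2_contribution(rates, factors)
  pos <- contrib[contrib$co2_rate > 0, ]
  producing <- unique(pos$process)
  miss <- setdiff(producing, names(groups))
  if (length(miss))
    stop("share_of_mineralization: no group for producing process(es): ",
         paste(miss, collapse = ", "))
  total <- sum(pos$co2_rate)
  if (total <= 0) {
    out <- data.frame(group = character(), co2_production = numeric(),
                      share_percent = numeric())
    attr(out, "flag") <- "undefined"
    return(out)
  }
  by_group <- tapply(pos$co2_rate, groups[pos$process], sum)
  out <- data.frame(group = names(by_group),
                    co2_production = as.numeric(by_group),
                    share_percent = 100 * as.numeric(by_group) / total,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "flag") <- "ok"
  out
}
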