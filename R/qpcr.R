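#' Convert 16S rRNA gene copies to cell numbers
#'
#' Divides copy counts by the domain-average 16S rRNA gene copy number per
#' cell (defaults 4.19 for Bacteria and 1.71 for Archaea, rrnDB averages;
#' configurable because database averages drift across versions).
#'
#' @param copies Data frame with `domain` and `copies_per_ml` columns, or a
#'   numeric vector with `domain` given separately.
#' @param domain Domain labels when `copies` is numeric.
#' @param divisors Named vector, domain -> copies per cell (> 0).
#' @return Input data frame with `cells_per_ml` and `divisor_used` columns
#'   (or a numeric vector of cells for vector input).
#' @examples
#' copies_to_cells(4.19e6, "Bacteria")   # 1e6 cells
#' @export
copies_to_cells <- function(copies, domain = NULL,
                            divisors = c(Bacteria = 4.19, Archaea = 1.71)) {
  if (any(divisors <= 0)) stop("copies_to_cells: divisors must be > 0")
  if (is.data.frame(copies)) {
    dom <- copies$domain
    unknown <- setdiff(unique(dom), names(divisors))
    if (length(unknown))
      stop("copies_to_cells: no divisor for domain(s): ",
           paste(unknown, collapse = ", "))
    copies$divisor_used <- unname(divisors[dom])
    copies$cells_per_ml <- copies$copies_per_ml / copies$divisor_used
    return(copies)
  }
  unknown <- setdiff(unique(domain), names(divisors))
  if (length(unknown))
    stop("copies_to_cells: no divisor for domain(s): ",
         paste(unknown, collapse = ", "))
  unname(copies / divisors[domain])
}

#' Summarize cell estimates across replicates
#'
#' Converts replicate copy counts to cells, then reports mean and sample
#' standard deviation per (domain, temperature, time); the divisor is
#' treated as exact, so sd(cells) = sd(copies)/divisor. Cells with a single
#' replicate get sd 0 and a flag. The archaeal share of the total
#' population is computed from the mean cell numbers at each
#' (temperature, time).
#'
#' @param records Data frame: `domain`, `temperature`, `time`, `replicate`,
#'   `copies_per_ml`.
#' @param divisors Named vector, domain -> copies per cell.
#' @return List: `cells` (per domain/T/t mean, sd, n, flag) and `shares`
#'   (per T/t archaeal percentage of total cells).
#' @export
summarize_cells <- function(records,
                            divisors = c(Bacteria = 4.19, Archaea = 1.71)) {
  rec <- copies_to_cells(records, divisors = divisors)
  key <- interaction(rec$domain, rec$temperature, rec$time, drop = TRUE)
  cells <- do.call(rbind, lapply(split(rec, key), function(g) {
    data.frame(domain = g$domain[1], temperature = g$temperature[1],
               time = g$time[1],
               cells_per_ml = mean(g$cells_per_ml),
               sd = if (nrow(g) > 1) stats::sd(g$cells_per_ml) else 0,
               n = nrow(g),
               divisor_used = g$divisor_used[1],
               flag = if (nrow(g) > 1) "ok" else "single_replicate",
               stringsAsFactors = FALSE)
  }))
  rownames(cells) <- NULL
  cells <- cells[order(cells$temperature, cells$time, cells$domain), ]
  wide_key <- interaction(cells$temperature, cells$time, drop = TRUE)
  shares <- do.call(rbind, lapply(split(cells, wide_key), function(g) {
    arch <- sum(g$cells_per_ml[g$domain == "Archaea"])
    bact <- sum(g$cells_per_ml[g$domain == "Bacteria"])
    data.frame(temperature = g$temperature[1], time = g$time[1],
               archaeal_share_percent =
                 if (arch + bact > 0) 100 * arch / (arch + bact) else NA_real_)
  }))
  rownames(shares) <- NULL
  list(cells = cells, shares = shares[order(shares$temperature,
                                            shares$time), ])
}
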