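R_GAS <- 8.314  # J K^-1 mol^-1

#' Arrhenius fit of a temperature-rate profile
#'
#' Ordinary least squares of `ln(rate)` on `1/T` (K) per the Arrhenius
#' relation `ln k = ln A - Ea/(R T)`: the activation energy is
#' `-slope * R`, reported in kJ mol^-1. Non-positive rates cannot be
#' log-transformed and are excluded before fitting; the exclusion count is
#' reported. At least three usable points are required.
#'
#' @param profile Data frame with `temperature` (degrees C) and `rate`
#'   columns (per-temperature maximum rates, nmol cm^-3 day^-1).
#' @param temp_range Optional `c(lo, hi)` in degrees C restricting the fit
#'   (e.g. the rising limb).
#' @return Object of class `arrhenius_fit`: `ea` (kJ mol^-1), `ln_a`,
#'   `r_squared`, `temp_range`, `n_points`, `n_excluded`, `fit` (the lm).
#' @examples
#' k <- 1e6 * exp(-50000 / (8.314 * (273.15 + c(10, 20, 30, 40))))
#' fit_arrhenius(data.frame(temperature = c(10, 20, 30, 40), rate = k))
#' @export
fit_arrhenius <- function(profile, temp_range = NULL) {
  stopifnot(all(c("temperature", "rate") %in% names(profile)))
  if (!is.null(temp_range))
    profile <- profile[profile$temperature >= temp_range[1] &
                         profile$temperature <= temp_range[2], ]
  usable <- is.finite(profile$rate) & profile$rate > 0
  n_excl <- sum(!usable)
  profile <- profile[usable, ]
  if (nrow(profile) < 3)
    stop("fit_arrhenius: need >= 3 positive rates, have ", nrow(profile))
  inv_t <- 1 / (profile$temperature + 273.15)
  fit <- stats::lm(log(profile$rate) ~ inv_t)
  sst <- sum((log(profile$rate) - mean(log(profile$rate)))^2)
  sse <- sum(stats::resid(fit)^2)
  structure(list(
    ea = -unname(stats::coef(fit)[2]) * R_GAS / 1000,
    ln_a = unname(stats::coef(fit)[1]),
    r_squared = if (sst > 0) 1 - sse / sst else 1,
    temp_range = range(profile$temperature),
    n_points = nrow(profile), n_excluded = n_excl, fit = fit),
    class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf(
    "Arrhenius fit: Ea = %.1f kJ mol-1, ln A = %.2f, R2 = %.3f (%d points, %g-%g C)\n",
    x$ea, x$ln_a, x$r_squared, x$n_points, x$temp_range[1], x$temp_range[2]))
  invisible(x)
}

#' Two-regime (breakpoint) Arrhenius fit
#'
#' Processes that switch substrate with temperature show two activation
#' energies. For every candidate break temperature with at least three
#' positive rates strictly on each side, both sides are fit independently
#' and the candidate minimizing the total squared residual in ln-space is
#' returned (ties resolved to the lowest break temperature). When no
#' candidate is feasible a single-regime fit is returned with
#' `fallback = TRUE`.
#'
#' @inheritParams fit_arrhenius
#' @param candidate_breaks Candidate break temperatures, degrees C.
#' @return List of class `two_regime_fit`: `break_temp`, `left`/`right`
#'   ([fit_arrhenius()] objects; left = below the break), `sse_total`,
#'   `sse_single` (single-regime SSE over the same usable points),
#'   `improvement` (`1 - sse_total/sse_single`), `fallback`.
#' @export
two_regime_fit <- function(profile, candidate_breaks) {
  usable <- profile[is.finite(profile$rate) & profile$rate > 0, ]
  sse_of <- function(f) sum(stats::resid(f$fit)^2)
  best <- NULL
  for (b in sort(candidate_breaks)) {
    lo <- usable[usable$temperature < b, ]
    hi <- usable[usable$temperature >= b, ]
    if (nrow(lo) < 3 || nrow(hi) < 3) next
    fl <- fit_arrhenius(lo)
    fr <- fit_arrhenius(hi)
    sse <- sse_of(fl) + sse_of(fr)
    if (is.null(best) || sse < best$sse_total - 1e-12)
      best <- list(break_temp = b, left = fl, right = fr, sse_total = sse)
  }
  single <- fit_arrhenius(usable)
  sse1 <- sse_of(single)
  if (is.null(best))
    return(structure(list(break_temp = NA_real_, left = single,
                          right = NULL, sse_total = sse1,
                          sse_single = sse1, improvement = 0,
                          fallback = TRUE),
                     class = "two_regime_fit"))
  best$sse_single <- sse1
  best$improvement <- if (sse1 > 0) 1 - best$sse_total / sse1 else 0
  best$fallback <- FALSE
  structure(best, class = "two_regime_fit")
}

#' @export
print.two_regime_fit <- function(x, ...) {
  if (x$fallback) {
    cat("Two-regime fit: no feasible break, single-regime fallback\n")
  } else {
    cat(sprintf(
      "Two-regime fit: break at %g C; Ea below = %.1f, above = %.1f kJ mol-1 (improvement %.1f%%)\n",
      x$break_temp, x$left$ea, x$right$ea, 100 * x$improvement))
  }
  invisible(x)
}

#' Q10 from activation energy (and back)
#'
#' `Q10 = exp((Ea/R) * dT / (T1 T2))`: the factor by which a rate grows for
#' a 10 C increase, evaluated by convention over 10-20 C
#' (T1 = 283.15 K, T2 = 293.15 K). `ea_from_q10` is the algebraic inverse.
#'
#' @param ea Activation energy, kJ mol^-1.
#' @param t1,t2 Interval bounds, K, with `t2 > t1`.
#' @return `q10_from_ea`: list of class `q10_result` with `q10`, `ea`,
#'   `t1`, `t2`, `delta_t`. `ea_from_q10`: kJ mol^-1.
#' @examples
#' q10_from_ea(8.9)$q10    # ~1.1
#' ea_from_q10(2.5)        # ~63 kJ mol^-1
#' @export
q10_from_ea <- function(ea, t1 = 283.15, t2 = 293.15) {
  if (!is.finite(ea)) stop("q10_from_ea: ea must be finite")
  if (t2 <= t1) stop("q10_from_ea: t2 must exceed t1")
  structure(list(q10 = exp((ea * 1000 / R_GAS) * (t2 - t1) / (t1 * t2)),
                 ea = ea, t1 = t1, t2 = t2, delta_t = t2 - t1),
            class = "q10_result")
}

#' @rdname q10_from_ea
#' @param q10 Temperature coefficient (> 0).
#' @export
ea_from_q10 <- function(q10, t1 = 283.15, t2 = 293.15) {
  if (q10 <= 0) stop("ea_from_q10: q10 must be > 0")
  if (t2 <= t1) stop("ea_from_q10: t2 must exceed t1")
  R_GAS * log(q10) * (t1 * t2) / (t2 - t1) / 1000
}

#' @export
print.q10_result <- function(x, ...) {
  cat(sprintf("Q10 = %.1f (Ea = %.1f kJ mol-1, %g-%g K)\n",
              x$q10, x$ea, x$t1, x$t2))
  invisible(x)
}
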