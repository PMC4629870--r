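#' Asymmetric Gaussian temperature window
#'
#' Anaerobic processes in thermal-gradient slurries are active inside
#' bounded temperature "windows of opportunity". Each window is modelled as
#' an asymmetric Gaussian: a peak at `t_opt` with independent left and right
#' standard deviations, scaled by a weight in (0, 1]. A process may carry
#' several windows (e.g. psychrophilic and thermophilic populations of the
#' same metabolism).
#'
#' @param t_opt Optimum temperature, degrees C.
#' @param sigma_left Spread below the optimum, degrees C (> 0).
#' @param sigma_right Spread above the optimum, degrees C (> 0).
#' @param weight Peak height relative to the process maximum rate, in (0, 1].
#' @return An object of class `thermal_window`.
#' @examples
#' w <- thermal_window(t_opt = 29, sigma_left = 12, sigma_right = 6)
#' window_response(29, list(w))   # 1 at the optimum
#' @export
thermal_window <- function(t_opt, sigma_left, sigma_right, weight = 1) {
  stopifnot(is.numeric(t_opt), length(t_opt) == 1L)
  if (!(sigma_left > 0 && sigma_right > 0))
    stop("thermal_window: sigma_left and sigma_right must be > 0")
  if (!(weight > 0 && weight <= 1))
    stop("thermal_window: weight must be in (0, 1]")
  structure(list(t_opt = t_opt, sigma_left = sigma_left,
                 sigma_right = sigma_right, weight = weight),
            class = "thermal_window")
}

#' Temperature response of a process
#'
#' Evaluates the dimensionless activity multiplier in \[0, 1\] at temperature
#' `temp_c`: the maximum over the process's windows of
#' `weight * exp(-(T - t_opt)^2 / (2 sigma^2))`, using `sigma_left` below the
#' optimum and `sigma_right` above it. Combining by max (not sum) keeps the
#' multiplier bounded by the largest window weight and produces the
#' inter-window activity gaps seen between mesophilic and thermophilic
#' zones. Beyond six sigma from the optimum the response is exactly zero:
#' a population contributes nothing that far outside its window, and the
#' cutoff keeps far-field rates identically zero rather than
#' astronomically small.
#'
#' @param temp_c Temperature(s), degrees C. Vectorised.
#' @param windows Non-empty list of [thermal_window()] objects.
#' @return Numeric vector of multipliers in \[0, 1\], one per temperature.
#' @export
window_response <- function(temp_c, windows) {
  if (length(windows) == 0L)
    stop("window_response: process has no temperature windows configured")
  resp <- numeric(length(temp_c))
  for (w in windows) {
    sigma <- ifelse(temp_c < w$t_opt, w$sigma_left, w$sigma_right)
    z <- abs(temp_c - w$t_opt) / sigma
    resp <- pmax(resp, ifelse(z > 6, 0, w$weight * exp(-z^2 / 2)))
  }
  resp
}
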