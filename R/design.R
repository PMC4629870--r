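#' Thermal-gradient experiment design
#'
#' Describes one slurry incubation series: the temperature grid, sampling
#' days, replication, amendment scenario, initial pool sizes, measurement
#' noise and detection limits.
#'
#' The unamended scenario starts from the residual H2 left by anaerobic
#' handling (~45 uM gas-equivalent); the amended scenario adds 2 mM acetate,
#' 2 mM methylamine and an H2:CO2 headspace (~36 mM H2 gas-equivalent).
#'
#' @param temperatures Degrees C, each within \[0, 80\].
#' @param time_points Sampling days, strictly increasing, max <= 100.
#' @param replicates Number of replicate vials per (T, t) cell (>= 1).
#' @param scenario `"unamended"` or `"amended"`.
#' @param initial_state Named vector of initial pools (uM); defaults depend
#'   on `scenario`.
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   measurement noise.
#' @param detection_limits Named vector of lower detection limits (uM);
#'   values below are reported at the limit and flagged.
#' @param seed Integer seed for the observation layer.
#' @return Object of class `experiment_design`.
#' @export
experiment_design <- function(temperatures = 0:80,
                              time_points = c(15, 40, 70, 100),
                              replicates = 3,
                              scenario = c("unamended", "amended"),
                              initial_state = NULL,
                              noise_cv = 0.05,
                              detection_limits = default_detection_limits(),
                              seed = 1L) {
  scenario <- match.arg(scenario)
  if (any(temperatures < 0 | temperatures > 80))
    stop("experiment_design: temperatures must lie within [0, 80] C")
  if (any(diff(time_points) <= 0) || max(time_points) > 100)
    stop("experiment_design: time_points must be strictly increasing, max <= 100")
  if (replicates < 1) stop("experiment_design: replicates must be >= 1")
  if (is.null(initial_state)) initial_state <- initial_pools(scenario)
  miss <- setdiff(species_table()$name, names(initial_state))
  if (length(miss))
    stop("experiment_design: initial_state missing species: ",
         paste(miss, collapse = ", "))
  if (any(initial_state < 0))
    stop("experiment_design: initial pools must be >= 0")
  structure(list(temperatures = temperatures, time_points = time_points,
                 replicates = as.integer(replicates), scenario = scenario,
                 initial_state = initial_state[species_table()$name],
                 noise_cv = noise_cv, detection_limits = detection_limits,
                 seed = as.integer(seed)),
            class = "experiment_design")
}

#' @rdname experiment_design
#' @param scenario Amendment scenario.
#' @export
initial_pools <- function(scenario = c("unamended", "amended")) {
  scenario <- match.arg(scenario)
  # metal_ox is the solid-phase metal-oxide electron-accepting capacity
  # expressed as uM of single-electron-pair equivalents
  base <- c(sulphate = 22000, h2 = 45, ch4 = 5, acetate = 10,
            methylamine = 100, nh4 = 500, dic = 20000, metal_ox = 600000)
  if (scenario == "amended") {
    base[["acetate"]] <- 2000
    base[["methylamine"]] <- 2000
    base[["h2"]] <- 36000
  }
  base
}

#' @rdname experiment_design
#' @export
default_detection_limits <- function() {
  c(sulphate = 50, h2 = 1, ch4 = 1, acetate = 1, methylamine = 120,
    nh4 = 10, dic = 100, metal_ox = 100)
}
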