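# small designs and catalogues shared across tests; everything is built in
# code so no stored fixtures are needed

tiny_design <- function(temps = c(25, 55), times = c(10, 20), cv = 0,
                        seed = 1L, ...) {
  experiment_design(temperatures = temps, time_points = times,
                    noise_cv = cv, seed = seed, ...)
}

# one-process catalogue: hydrogenotrophic sulphate reduction, wide window
single_h2sr <- function(r_max = 100, k_h2 = 1e-6) {
  list(h2sr = process_spec(
    "h2sr", c(h2 = -4, sulphate = -1), rate_species = "sulphate",
    r_max = r_max, windows = list(thermal_window(40, 50, 50)),
    half_saturation = c(h2 = k_h2)))
}

# random but valid process over the standard species set (for property
# tests); substrates drawn from the pools, Monod constants moderate
random_process <- function(name) {
  subs <- sample(c("h2", "acetate", "sulphate", "methylamine", "dic"), 2)
  st <- stats::setNames(c(-stats::runif(1, 1, 4), -1, 1),
                        c(subs, "ch4"))
  process_spec(name, st, rate_species = subs[2],
               r_max = stats::runif(1, 0, 300),
               windows = list(thermal_window(stats::runif(1, 5, 70),
                                             stats::runif(1, 2, 15),
                                             stats::runif(1, 2, 15))),
               half_saturation = stats::setNames(stats::runif(2, 5, 100),
                                                 subs),
               onset_day = sample(c(0, 0, 30), 1))
}

# default-condition simulation cached per test run (expensive-ish)
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- experiment_design(temperatures = 0:80,
                             time_points = c(15, 40, 70, 100))
      cache <<- simulate_slurry(d)
    }
    cache
  }
})

# independent brute-force two-segment least squares (oracle for
# detect_breakpoint / two_regime_fit); deliberately naive
brute_breakpoint <- function(x, y, grid) {
  fit1 <- function(xx, yy) {
    f <- stats::lm(yy ~ xx)
    sum(stats::resid(f)^2)
  }
  best_b <- NA
  best_sse <- Inf
  for (b in sort(grid)) {
    if (sum(x < b) < 3 || sum(x >= b) < 3) next
    sse <- fit1(x[x < b], y[x < b]) + fit1(x[x >= b], y[x >= b])
    if (sse < best_sse - 1e-12) { best_sse <- sse; best_b <- b }
  }
  list(break_temp = best_b, sse = best_sse)
}
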