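#' Advance slurry pools by one explicit-Euler step
#'
#' Computes, for each process, the instantaneous rate
#' `r = r_max * window_response(T) * prod(c / (c + K)) * onset-gate`
#' (in `rate_species` units), converts it to a reaction advance through the
#' stoichiometry, and applies a limiting-substrate clamp: if the summed
#' proposed consumption of any pool over the step exceeds what is present,
#' all processes drawing on that pool are scaled down proportionally so no
#' pool goes negative and stoichiometric ratios stay exact at depletion.
#' Organic-matter activation sources then add acetate / H2 / methylamine
#' and the carbon they carry is returned for the carbon ledger.
#'
#' @param state Named numeric vector of pools (uM), all >= 0.
#' @param specs List of [process_spec()] objects.
#' @param temp_c Temperature, degrees C.
#' @param dt Step length, days (> 0).
#' @param t_now Elapsed time (days) at the start of the step; gates
#'   processes whose `onset_day` has not been reached.
#' @param source_pars Source-term parameters ([default_source_pars()]), or
#'   `NULL` to disable sources.
#' @return List with `state` (updated pools), `rates` (named realized rates,
#'   nmol cm^-3 day^-1 in each process's rate-species units) and
#'   `carbon_added` (nmol C cm^-3 added by sources during the step).
#' @export
step_state <- function(state, specs, temp_c, dt, t_now = Inf,
                       source_pars = NULL) {
  if (dt <= 0) stop("step_state: dt must be > 0")
  S <- matrix(state, nrow = 1, dimnames = list(NULL, names(state)))
  out <- step_matrix(S, specs, temp_c, dt, t_now, source_pars)
  list(state = out$state[1, ], rates = out$rates[1, ],
       carbon_added = out$carbon_added[1])
}

# Vectorised step over a temperature grid: S is n_temp x n_species.
step_matrix <- function(S, specs, temps, dt, t_now, source_pars) {
  if (any(S < 0))
    stop("step_state: negative pool on entry: ",
         paste(colnames(S)[colSums(S < 0) > 0], collapse = ", "))
  nT <- nrow(S)
  nP <- length(specs)
  rates <- matrix(0, nT, nP,
                  dimnames = list(NULL, vapply(specs, `[[`, "", "name")))
  if (nP > 0) {
    adv <- matrix(0, nT, nP)        # reaction advances, mol advance / day
    for (j in seq_len(nP)) {
      sp <- specs[[j]]
      if (sp$r_max == 0 || t_now < sp$onset_day) next
      r <- sp$r_max * window_response(temps, sp$windows)
      for (s in names(sp$half_saturation)) {
        c_s <- S[, s]
        r <- r * c_s / (c_s + sp$half_saturation[[s]])
      }
      rates[, j] <- r
      adv[, j] <- r / abs(sp$stoichiometry[[sp$rate_species]])
    }
    # limiting-substrate clamp: per-pool scale, processes take the min
    # over their substrates
    cons <- matrix(0, nT, ncol(S), dimnames = list(NULL, colnames(S)))
    for (j in seq_len(nP)) {
      st <- specs[[j]]$stoichiometry
      for (s in names(st)[st < 0])
        cons[, s] <- cons[, s] + adv[, j] * dt * (-st[[s]])
    }
    pool_scale <- matrix(1, nT, ncol(S), dimnames = list(NULL, colnames(S)))
    over <- cons > S & cons > 0
    pool_scale[over] <- S[over] / cons[over]
    f <- matrix(1, nT, nP)
    for (j in seq_len(nP)) {
      st <- specs[[j]]$stoichiometry
      for (s in names(st)[st < 0]) f[, j] <- pmin(f[, j], pool_scale[, s])
    }
    adv <- adv * f
    rates <- rates * f
    for (j in seq_len(nP)) {
      st <- specs[[j]]$stoichiometry
      for (s in names(st)) S[, s] <- S[, s] + adv[, j] * dt * st[[s]]
    }
  }
  carbon_added <- numeric(nT)
  if (!is.null(source_pars)) {
    src <- source_rates(temps, source_pars) * dt
    cc <- ifelse(colnames(src) %in% names(carbon_content),
                 carbon_content[colnames(src)], 0)
    for (s in colnames(src)) S[, s] <- S[, s] + src[, s]
    carbon_added <- as.numeric(src %*% cc)
  }
  S[S < 0 & S > -1e-9] <- 0          # float dust from exact depletion
  if (any(!is.finite(S)) || any(S < 0)) {
    bad <- which(!is.finite(S) | S < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("step_state: invalid pool value at T=%g C, species '%s'",
                 temps[bad[1]], colnames(S)[bad[2]]))
  }
  list(state = S, rates = rates, carbon_added = carbon_added)
}

#' Simulate a thermal-gradient slurry incubation
#'
#' Forward-integrates the coupled substrate pools at every temperature of
#' the design with explicit Euler steps of length `dt`, recording the full
#' trajectory, the realized instantaneous process rates and the cumulative
#' carbon added by organic-matter activation sources. The dynamics contain
#' no randomness; noise enters only in the `observe_*` functions.
#'
#' @param design An [experiment_design()].
#' @param specs Process catalogue; defaults to [default_process_catalogue()].
#' @param dt Integration step, days.
#' @param source_pars Organic-matter activation source parameters, or `NULL`
#'   to disable the sources.
#' @return Object of class `slurry_simulation` with elements `times`
#'   (recorded days), `temps`, `traj` (array temp x species x time, uM),
#'   `rates` (array temp x process x time, nmol cm^-3 day^-1 in rate-species
#'   units), `carbon_ledger` (matrix temp x time, cumulative nmol C cm^-3),
#'   `design`, `specs`, `dt`, `source_pars`.
#' @examples
#' d <- experiment_design(temperatures = c(25, 55), time_points = c(10, 20))
#' sim <- simulate_slurry(d, dt = 0.5)
#' state_at(sim, 55, 20)
#' @export
simulate_slurry <- function(design, specs = default_process_catalogue(),
                            dt = 0.1, source_pars = default_source_pars()) {
  stopifnot(inherits(design, "experiment_design"))
  temps <- design$temperatures
  t_end <- max(design$time_points)
  n_steps <- ceiling(t_end / dt - 1e-9)
  times <- c(seq_len(n_steps) - 1, n_steps) * dt
  nT <- length(temps)
  spn <- species_table()$name
  prn <- vapply(specs, `[[`, "", "name")
  S <- matrix(rep(design$initial_state, each = nT), nrow = nT,
              dimnames = list(NULL, spn))
  traj <- array(NA_real_, c(nT, length(spn), n_steps + 1),
                dimnames = list(NULL, spn, NULL))
  rates <- array(0, c(nT, length(prn), n_steps + 1),
                 dimnames = list(NULL, prn, NULL))
  ledger <- matrix(0, nT, n_steps + 1)
  traj[, , 1] <- S
  for (k in seq_len(n_steps)) {
    st <- step_matrix(S, specs, temps, dt, t_now = times[k], source_pars)
    S <- st$state
    traj[, , k + 1] <- S
    rates[, , k] <- st$rates
    ledger[, k + 1] <- ledger[, k] + st$carbon_added
  }
  # instantaneous rates at the final state (zero-length step equivalent)
  fin <- step_matrix(S, specs, temps, dt, t_now = times[n_steps + 1],
                     source_pars = NULL)
  rates[, , n_steps + 1] <- fin$rates
  structure(list(times = times, temps = temps, traj = traj, rates = rates,
                 carbon_ledger = ledger, design = design, specs = specs,
                 dt = dt, source_pars = source_pars),
            class = "slurry_simulation")
}

#' @export
print.slurry_simulation <- function(x, ...) {
  cat(sprintf(
    "slurry_simulation: %d temperatures (%g-%g C), %g days (dt = %g d), %d processes\n",
    length(x$temps), min(x$temps), max(x$temps), max(x$times), x$dt,
    dim(x$rates)[2]))
  invisible(x)
}

time_index <- function(sim, time) {
  k <- which.min(abs(sim$times - time))
  if (abs(sim$times[k] - time) > sim$dt / 2 + 1e-9)
    stop("time ", time, " outside the simulated range")
  k
}

temp_index <- function(sim, temp) {
  i <- which.min(abs(sim$temps - temp))
  if (abs(sim$temps[i] - temp) > 1e-6)
    stop("temperature ", temp, " C was not simulated")
  i
}

#' Query a simulation
#'
#' `state_at` returns the pool vector (uM) at the recorded step nearest to
#' `time`; `rate_at` the realized instantaneous rate of one process;
#' `true_rates_df` a long data frame of rates at the design's sampling
#' days; `trajectories_df` the long concentration table.
#'
#' @param sim A `slurry_simulation`.
#' @param temp Temperature (must be on the simulated grid).
#' @param time Day.
#' @export
state_at <- function(sim, temp, time) {
  sim$traj[temp_index(sim, temp), , time_index(sim, time)]
}

#' @rdname state_at
#' @param process Process name.
#' @export
rate_at <- function(sim, process, temp, time) {
  sim$rates[temp_index(sim, temp), process, time_index(sim, time)]
}

#' @rdname state_at
#' @param times Days at which to report (default: design time points).
#' @export
true_rates_df <- function(sim, times = sim$design$time_points) {
  prn <- dimnames(sim$rates)[[2]]
  out <- expand.grid(process = prn, temperature = sim$temps, time = times,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$rate <- mapply(function(p, T_, t_) rate_at(sim, p, T_, t_),
                     out$process, out$temperature, out$time)
  out
}

#' @rdname state_at
#' @export
trajectories_df <- function(sim, times = sim$design$time_points) {
  spn <- dimnames(sim$traj)[[2]]
  out <- expand.grid(species = spn, temperature = sim$temps, time = times,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$value <- mapply(function(s, T_, t_)
    sim$traj[temp_index(sim, T_), s, time_index(sim, t_)],
    out$species, out$temperature, out$time)
  out
}
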