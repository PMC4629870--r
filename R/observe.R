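# run expr with a local RNG stream; leaves the caller's RNG untouched
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# multiplicative lognormal noise with unit mean and coefficient of
# variation cv (cv = 0 returns x unchanged)
lognorm_noise <- function(x, cv) {
  if (cv == 0) return(x)
  sdlog <- sqrt(log(1 + cv^2))
  x * exp(stats::rnorm(length(x), mean = -sdlog^2 / 2, sd = sdlog))
}

#' Observe concentrations with measurement noise and detection limits
#'
#' Samples the simulated trajectories at the design's time points and
#' replicates, applying multiplicative lognormal noise with coefficient of
#' variation `design$noise_cv` (concentrations cannot go negative).
#' Observations below a species' detection limit are reported at the limit
#' and flagged, mirroring "<limit" reporting conventions.
#'
#' @param sim A [simulate_slurry()] result.
#' @param design The [experiment_design()]; its `seed` drives the noise.
#' @return Long data frame: `temperature`, `time`, `species`, `replicate`,
#'   `value` (uM), `below_detection` (logical).
#' @export
observe_concentrations <- function(sim, design = sim$design) {
  spn <- dimnames(sim$traj)[[2]]
  grid <- expand.grid(replicate = seq_len(design$replicates),
                      species = spn,
                      time = design$time_points,
                      temperature = design$temperatures,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  truth <- mapply(function(s, T_, t_)
    sim$traj[temp_index(sim, T_), s, time_index(sim, t_)],
    grid$species, grid$temperature, grid$time)
  obs <- with_local_seed(design$seed,
                         lognorm_noise(truth, design$noise_cv))
  lim <- design$detection_limits[grid$species]
  lim[is.na(lim)] <- 0
  below <- obs < lim
  obs[below] <- lim[below]
  data.frame(temperature = grid$temperature, time = grid$time,
             species = grid$species, replicate = grid$replicate,
             value = as.numeric(obs), below_detection = as.logical(below),
             stringsAsFactors = FALSE)
}

#' Synthesize radiotracer incubations
#'
#' For each process and temperature, emits triplicate incubations started at
#' each design time point for three increasing durations. The product
#' activity fraction is `(true instantaneous rate at start x duration) /
#' substrate pool at start` (linear turnover, clamped at 1 and flagged when
#' saturated), with lognormal noise at `design$noise_cv`. A zero substrate
#' pool yields a zero fraction and a warning flag.
#'
#' Where substrate turnover is fast (pool/rate shorter than the scheduled
#' incubation), the scheduled duration would consume the whole labelled
#' pool and the linear turnover form saturates. Mirroring the practice of
#' shortening incubations for active samples (pilot "indicator" vials set
#' the sampling times), each duration is capped at `turnover_caps[i]` times
#' the local turnover time, keeping the label conversion in the linear
#' range; the actual duration used is recorded per incubation.
#'
#' @param sim A [simulate_slurry()] result.
#' @param design The [experiment_design()].
#' @param schedule Three strictly increasing incubation durations, days.
#' @param processes Names of processes to measure (default: all simulated).
#' @param turnover_caps Maximum label turnover fraction targeted by each of
#'   the three incubation time points.
#' @return Data frame with one row per incubation: `process`, `temperature`,
#'   `start_day`, `duration`, `timepoint_index`, `replicate`,
#'   `added_activity`, `product_activity`, `pool` (uM = nmol cm^-3),
#'   `flag` (`"ok"`, `"zero_pool"` or `"saturated"`).
#' @export
observe_tracers <- function(sim, design = sim$design,
                            schedule = c(1, 2, 3),
                            processes = dimnames(sim$rates)[[2]],
                            turnover_caps = c(0.1, 0.2, 0.3)) {
  if (length(schedule) != 3 || any(diff(schedule) <= 0))
    stop("observe_tracers: schedule must be three strictly increasing durations")
  added <- 1e5   # dispensed label activity (arbitrary activity units)
  grid <- expand.grid(replicate = seq_len(design$replicates),
                      timepoint_index = seq_along(schedule),
                      start_day = design$time_points,
                      temperature = design$temperatures,
                      process = processes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$duration <- schedule[grid$timepoint_index]
  rs <- vapply(sim$specs, `[[`, "", "rate_species")[grid$process]
  grid$pool <- mapply(function(s, T_, t_)
    sim$traj[temp_index(sim, T_), s, time_index(sim, t_)],
    rs, grid$temperature, grid$start_day)
  rate <- mapply(function(p, T_, t_) rate_at(sim, p, T_, t_),
                 grid$process, grid$temperature, grid$start_day)
  fast <- rate > 0 & grid$pool > 0
  cap <- turnover_caps[grid$timepoint_index] * grid$pool / pmax(rate, 1e-300)
  grid$duration[fast] <- pmin(grid$duration, cap)[fast]
  frac <- ifelse(grid$pool > 0, rate * grid$duration / grid$pool, 0)
  grid$flag <- ifelse(grid$pool <= 0, "zero_pool",
                      ifelse(frac > 1, "saturated", "ok"))
  if (any(grid$flag == "zero_pool"))
    warning("observe_tracers: zero substrate pool in ",
            sum(grid$flag == "zero_pool"), " incubation(s)")
  frac <- pmin(frac, 1)
  frac <- with_local_seed(design$seed + 1L,
                          pmin(lognorm_noise(frac, design$noise_cv), 1))
  grid$added_activity <- added
  grid$product_activity <- frac * added
  grid[c("process", "temperature", "start_day", "duration",
         "timepoint_index", "replicate", "added_activity",
         "product_activity", "pool", "flag")]
}

#' Population model and qPCR observation
#'
#' Cell densities respond to cumulative catabolic turnover (growth yield per
#' nmol of rate-species turned over) and decline at temperatures above a
#' survival threshold. `true_cell_numbers` evaluates the model exactly;
#' `observe_qpcr` converts cells to 16S rRNA gene copies with the
#' domain-specific copies-per-cell factors and adds triplicate lognormal
#' noise.
#'
#' @param sim A [simulate_slurry()] result.
#' @param pars Model parameters; see [default_qpcr_model()].
#' @return `true_cell_numbers`: data frame `domain`, `temperature`, `time`,
#'   `cells_per_ml`. `observe_qpcr`: the same grid with `replicate` and
#'   `copies_per_ml`.
#' @export
true_cell_numbers <- function(sim, pars = default_qpcr_model()) {
  prn <- dimnames(sim$rates)[[2]]
  grid <- expand.grid(time = sim$design$time_points,
                      temperature = sim$design$temperatures,
                      domain = c("Bacteria", "Archaea"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  dt <- sim$dt
  cum_turn <- function(T_, t_, procs) {
    procs <- intersect(procs, prn)
    if (!length(procs)) return(0)
    i <- temp_index(sim, T_); k <- time_index(sim, t_)
    sum(sim$rates[i, procs, seq_len(max(k - 1, 1)), drop = FALSE]) * dt
  }
  grid$cells_per_ml <- mapply(function(dom, T_, t_) {
    base <- if (dom == "Bacteria") pars$base_bacteria else pars$base_archaea
    yield <- if (dom == "Bacteria") pars$yield_bacteria else pars$yield_archaea
    procs <- if (dom == "Bacteria") pars$bacterial_processes else
      pars$archaeal_processes
    surv <- exp(-pmax(0, T_ - pars$survival_temp) / pars$survival_scale)
    (base + yield * cum_turn(T_, t_, procs)) * surv
  }, grid$domain, grid$temperature, grid$time)
  grid[c("domain", "temperature", "time", "cells_per_ml")]
}

#' @rdname true_cell_numbers
#' @param design The [experiment_design()] (noise CV and seed).
#' @param copies_per_cell Named vector of 16S copies per cell by domain.
#' @export
observe_qpcr <- function(sim, design = sim$design,
                         pars = default_qpcr_model(),
                         copies_per_cell = c(Bacteria = 4.19,
                                             Archaea = 1.71)) {
  truth <- true_cell_numbers(sim, pars)
  out <- truth[rep(seq_len(nrow(truth)), each = design$replicates), ]
  out$replicate <- rep(seq_len(design$replicates), nrow(truth))
  copies <- out$cells_per_ml * copies_per_cell[out$domain]
  out$copies_per_ml <- with_local_seed(design$seed + 2L,
                                       lognorm_noise(copies,
                                                     design$noise_cv))
  rownames(out) <- NULL
  out[c("domain", "temperature", "time", "replicate", "copies_per_ml")]
}

#' @rdname true_cell_numbers
#' @export
default_qpcr_model <- function() {
  list(base_bacteria = 2e8, base_archaea = 2e7,
       yield_bacteria = 5e3, yield_archaea = 2e3,
       bacterial_processes = c("acetoclastic_metal_reduction",
                               "acetoclastic_sulphate_reduction",
                               "hydrogenotrophic_sulphate_reduction",
                               "hydrogenotrophic_acetogenesis"),
       archaeal_processes = c("methylotrophic_methanogenesis",
                              "acetoclastic_methanogenesis",
                              "hydrogenotrophic_methanogenesis"),
       survival_temp = 15, survival_scale = 30)
}
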