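#' Chemical species tracked by the slurry simulator
#'
#' Pools are expressed in micromolar referenced to slurry volume; gases
#' (H2, CH4) are carried as micromolar gas-equivalents so that 1 uM is
#' identically 1 nmol cm^-3 of slurry. Under this convention concentration
#' differences over time are directly rates in nmol cm^-3 day^-1.
#'
#' @return Data frame with columns `name`, `phase`, `unit`.
#' @export
species_table <- function() {
  data.frame(
    name  = c("sulphate", "h2", "ch4", "acetate", "methylamine",
              "nh4", "dic", "metal_ox"),
    phase = c("dissolved", "gas", "gas", "dissolved", "dissolved",
              "dissolved", "dissolved", "dissolved"),
    unit  = "uM",
    stringsAsFactors = FALSE
  )
}

#' Define an anaerobic process
#'
#' A process couples a stoichiometry over the tracked species to a maximum
#' rate, one or more temperature windows, Monod half-saturation constants
#' for its substrates, an onset lag, a nominal activation energy on the
#' rising limb, and a CO2 standardizing factor used by the mineralization
#' balance.
#'
#' @param name Identifier.
#' @param stoichiometry Named numeric vector, mol of species per mol of
#'   reaction advance; substrates negative, products positive.
#' @param rate_species Species in whose units the process rate is reported;
#'   its stoichiometric coefficient must be non-zero.
#' @param r_max Maximum rate, nmol cm^-3 day^-1 in `rate_species` units.
#' @param windows List of [thermal_window()] objects (non-empty).
#' @param half_saturation Named numeric vector of Monod constants (uM) for
#'   substrates; every named species must appear with negative stoichiometry.
#' @param onset_day Lag (days) before the process switches on.
#' @param ea Nominal activation energy on the rising limb, kJ mol^-1
#'   (ground-truth bookkeeping; the window shape governs dynamics).
#' @param co2_factor Signed mol CO2 per mol of `rate_species` turned over.
#' @return Object of class `process_spec`.
#' @export
process_spec <- function(name, stoichiometry, rate_species, r_max, windows,
                         half_saturation = numeric(), onset_day = 0,
                         ea = NA_real_, co2_factor = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  if (r_max < 0) stop("process_spec: r_max must be >= 0")
  if (length(windows) == 0L) stop("process_spec: windows must be non-empty")
  if (!rate_species %in% names(stoichiometry) ||
      stoichiometry[[rate_species]] == 0)
    stop("process_spec: rate_species must have non-zero stoichiometry")
  for (s in names(half_saturation)) {
    if (!s %in% names(stoichiometry) || stoichiometry[[s]] >= 0)
      stop("process_spec: half_saturation species '", s,
           "' must be a substrate (negative stoichiometry)")
    if (half_saturation[[s]] <= 0)
      stop("process_spec: half-saturation constants must be > 0")
  }
  structure(list(name = name, stoichiometry = stoichiometry,
                 rate_species = rate_species, r_max = r_max,
                 windows = windows, half_saturation = half_saturation,
                 onset_day = onset_day, ea = ea, co2_factor = co2_factor),
            class = "process_spec")
}

#' Default anaerobic process catalogue
#'
#' Eight processes calibrated to the activity zones observed in tidal-flat
#' slurry thermal gradients: acetoclastic metal-oxide reduction (up to
#' ~34 C), acetoclastic sulphate reduction (up to ~43 C), hydrogenotrophic
#' sulphate reduction (~43-73 C), methylotrophic methanogenesis from
#' methylamine (~12-43 C), acetoclastic methanogenesis (two windows,
#' ~30-43 C and ~50-65 C, the hot window developing late), hydrogenotrophic
#' methanogenesis (cold window below ~20 C and hot window ~45-80 C) and
#' hydrogenotrophic acetogenesis (~43-80 C). Anaerobic oxidation of methane
#' and ammonium oxidation are available but off by default
#' (`include_optional = TRUE` adds them); a thermal gradient study infers
#' them only indirectly.
#'
#' Rates are reported in the units of each process's `rate_species`:
#' sulphate for the sulphate reducers, acetate for acetotrophs and
#' acetogenesis, methylamine for methylotrophic methanogenesis, CH4 for
#' hydrogenotrophic methanogenesis.
#'
#' @param include_optional Add AOM and anaerobic ammonium oxidation.
#' @return Named list of [process_spec()] objects.
#' @export
default_process_catalogue <- function(include_optional = FALSE) {
  cat_ <- list(
    acetoclastic_metal_reduction = process_spec(
      "acetoclastic_metal_reduction",
      c(acetate = -1, metal_ox = -8, dic = 2),
      rate_species = "acetate", r_max = 1500,
      windows = list(thermal_window(25, 10, 5)),
      half_saturation = c(acetate = 15, metal_ox = 5000),
      ea = 60, co2_factor = 2),
    acetoclastic_sulphate_reduction = process_spec(
      "acetoclastic_sulphate_reduction",
      c(acetate = -1, sulphate = -1, dic = 2),
      rate_species = "sulphate", r_max = 250,
      windows = list(thermal_window(29, 12, 8)),
      half_saturation = c(acetate = 15, sulphate = 200),
      ea = 56.8, co2_factor = 2),
    hydrogenotrophic_sulphate_reduction = process_spec(
      "hydrogenotrophic_sulphate_reduction",
      c(h2 = -4, sulphate = -1),
      rate_species = "sulphate", r_max = 700,
      windows = list(thermal_window(65, 13, 3)),
      half_saturation = c(h2 = 5, sulphate = 200),
      ea = 8.9, co2_factor = 0),
    methylotrophic_methanogenesis = process_spec(
      "methylotrophic_methanogenesis",
      c(methylamine = -1, ch4 = 0.75, dic = 0.25, nh4 = 1),
      rate_species = "methylamine", r_max = 60,
      windows = list(thermal_window(30, 8, 4.5)),
      half_saturation = c(methylamine = 25),
      ea = 70, co2_factor = 0.25),
    acetoclastic_methanogenesis = process_spec(
      "acetoclastic_methanogenesis",
      c(acetate = -1, ch4 = 1, dic = 1),
      rate_species = "acetate", r_max = 15,
      windows = list(thermal_window(36, 4, 3, weight = 0.6),
                     thermal_window(55, 4, 4)),
      half_saturation = c(acetate = 400),
      onset_day = 60, ea = 45, co2_factor = 1),
    hydrogenotrophic_methanogenesis = process_spec(
      "hydrogenotrophic_methanogenesis",
      c(h2 = -4, dic = -1, ch4 = 1),
      rate_species = "ch4", r_max = 100,
      windows = list(thermal_window(10, 6, 5, weight = 0.3),
                     thermal_window(60, 12, 9, weight = 1)),
      half_saturation = c(h2 = 15, dic = 500),
      onset_day = 50, ea = 35, co2_factor = -1),
    hydrogenotrophic_acetogenesis = process_spec(
      "hydrogenotrophic_acetogenesis",
      c(h2 = -4, dic = -2, acetate = 1),
      rate_species = "acetate", r_max = 200,
      windows = list(thermal_window(62, 11, 9)),
      half_saturation = c(h2 = 20, dic = 500),
      ea = 75, co2_factor = -2)
  )
  if (include_optional) {
    cat_$anaerobic_methane_oxidation <- process_spec(
      "anaerobic_methane_oxidation",
      c(ch4 = -1, sulphate = -1, dic = 1),
      rate_species = "ch4", r_max = 5,
      windows = list(thermal_window(50, 10, 10)),
      half_saturation = c(ch4 = 100, sulphate = 500),
      ea = 40, co2_factor = 1)
    cat_$anaerobic_ammonium_oxidation <- process_spec(
      "anaerobic_ammonium_oxidation",
      c(nh4 = -1),
      rate_species = "nh4", r_max = 20,
      windows = list(thermal_window(25, 6, 6)),
      half_saturation = c(nh4 = 200),
      ea = 50, co2_factor = 0)
  }
  cat_
}

#' Organic-matter activation source terms
#'
#' Two routes release fermentation products into the pools. Mesophilic
#' hydrolysis/fermentation supplies acetate inside its own asymmetric
#' temperature window (the fermenter community fades above ~40 C); thermal
#' activation of buried organic matter releases H2 and additional acetate
#' along a sigmoid rising above ~40 C. Sources add carbon to the system and
#' are recorded in the simulator's carbon ledger.
#'
#' @param temp_c Temperature(s), degrees C.
#' @param pars Named list: `acetate_base` (uM/d at all T),
#'   `acetate_ferm_max` (uM/d at the fermentation window peak) with
#'   `ferm_opt`, `ferm_sigma_left`, `ferm_sigma_right` (C); `acetate_max`
#'   and `h2_max` (uM/d at the thermal plateau) with sigmoid `midpoint` and
#'   `scale` (C); `methylamine_max` (uM/d, default 0).
#' @return Matrix `length(temp_c)` x 3 with columns acetate, h2, methylamine
#'   (uM day^-1).
#' @export
source_rates <- function(temp_c, pars = default_source_pars()) {
  sig <- 1 / (1 + exp(-(temp_c - pars$midpoint) / pars$scale))
  ferm <- window_response(temp_c,
                          list(thermal_window(pars$ferm_opt,
                                              pars$ferm_sigma_left,
                                              pars$ferm_sigma_right)))
  cbind(acetate     = pars$acetate_base + pars$acetate_ferm_max * ferm +
          pars$acetate_max * sig,
        h2          = pars$h2_max * sig,
        methylamine = pars$methylamine_max * sig)
}

#' @rdname source_rates
#' @export
default_source_pars <- function() {
  list(acetate_base = 30, acetate_ferm_max = 400,
       ferm_opt = 28, ferm_sigma_left = 12, ferm_sigma_right = 7,
       acetate_max = 25, h2_max = 1100,
       midpoint = 45, scale = 3, methylamine_max = 0)
}

# carbon atoms per molecule of each carbon-carrying tracked pool
carbon_content <- c(acetate = 2, methylamine = 1, ch4 = 1, dic = 1)
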