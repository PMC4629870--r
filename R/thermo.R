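T0_K <- 298.15

ext_file <- function(name) {
  system.file("extdata", name, package = "thermoslurry", mustWork = TRUE)
}

read_ext_csv <- function(name) {
  utils::read.csv(ext_file(name), comment.char = "#",
                  stringsAsFactors = FALSE)
}

#' Bundled catabolic reaction table
#'
#' Six reactions spanning the hydrogenotrophic (methanogenesis,
#' acetogenesis, sulphate reduction), acetoclastic (methanogenesis,
#' sulphate reduction) and methylotrophic (methanogenesis from methylamine)
#' metabolisms. Standard Gibbs energies use the pH-7 convention (H+ activity
#' referenced to 1e-7 mol/L) at 298.15 K; enthalpies are treated as
#' temperature-independent. The constants are bundled defaults compiled
#' from standard anaerobe-energetics literature and live in an editable CSV
#' (`system.file("extdata", "reactions.csv", ...)`).
#'
#' @param path Optional path to an alternative reaction CSV.
#' @param stoich_path Optional path to an alternative stoichiometry CSV.
#' @return Named list of `reaction_spec` objects with fields `name`,
#'   `stoichiometry` (named numeric), `dg0`, `dh0` (kJ mol^-1).
#' @export
reaction_table <- function(path = NULL, stoich_path = NULL) {
  meta <- if (is.null(path)) read_ext_csv("reactions.csv") else
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  st <- if (is.null(stoich_path)) read_ext_csv("reaction_stoichiometry.csv")
  else utils::read.csv(stoich_path, comment.char = "#",
                       stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(meta)), function(i) {
    rx <- meta$reaction[i]
    s <- st[st$reaction == rx, ]
    if (nrow(s) == 0) stop("reaction_table: no stoichiometry for ", rx)
    structure(list(name = rx,
                   stoichiometry = stats::setNames(s$coefficient, s$species),
                   dg0 = meta$dg0[i], dh0 = meta$dh0[i]),
              class = "reaction_spec")
  })
  stats::setNames(out, meta$reaction)
}

#' Element balance of a reaction
#'
#' Checks that the signed stoichiometry conserves C, H, O, S and N against
#' the bundled element table.
#'
#' @param rx A `reaction_spec` from [reaction_table()].
#' @param tol Absolute tolerance on each element sum.
#' @return Named vector of element imbalances (invisibly); errors if any
#'   exceeds `tol`.
#' @export
check_element_balance <- function(rx, tol = 1e-9) {
  el <- read_ext_csv("thermo_elements.csv")
  rownames(el) <- el$species
  miss <- setdiff(names(rx$stoichiometry), el$species)
  if (length(miss))
    stop("check_element_balance: species missing from element table: ",
         paste(miss, collapse = ", "))
  m <- as.matrix(el[names(rx$stoichiometry), c("C", "H", "O", "S", "N")])
  bal <- drop(rx$stoichiometry %*% m)
  if (any(abs(bal) > tol))
    stop("check_element_balance: reaction '", rx$name, "' unbalanced: ",
         paste(sprintf("%s=%+g", names(bal)[abs(bal) > tol],
                       bal[abs(bal) > tol]), collapse = ", "))
  invisible(bal)
}

#' Standard Gibbs energy at temperature
#'
#' Integrated Gibbs-Helmholtz with constant reaction enthalpy:
#' `dG0(T) = dG0(T0) * (T/T0) + dH0 * (1 - T/T0)`, T0 = 298.15 K.
#'
#' @param rx A `reaction_spec`.
#' @param temp_k Temperature in K, within \[250, 400\].
#' @return kJ per mol reaction.
#' @export
dg0_at_temperature <- function(rx, temp_k) {
  if (any(temp_k < 250 | temp_k > 400))
    stop("dg0_at_temperature: temperature outside [250, 400] K")
  rx$dg0 * (temp_k / T0_K) + rx$dh0 * (1 - temp_k / T0_K)
}

#' Temperature-dependent Henry constants
#'
#' Converts dissolved gas concentrations (uM) to equivalent partial
#' pressures (bar) with van't Hoff-corrected Henry solubility constants
#' from the bundled table.
#'
#' @param species `"h2"`, `"ch4"` or `"co2"`.
#' @param conc_um Dissolved concentration, uM.
#' @param temp_k Temperature, K.
#' @return Partial pressure, bar.
#' @export
dissolved_to_bar <- function(species, conc_um, temp_k) {
  h <- read_ext_csv("henry_constants.csv")
  i <- match(species, h$species)
  if (any(is.na(i))) stop("dissolved_to_bar: no Henry constant for ",
                          paste(species[is.na(i)], collapse = ", "))
  kh <- h$k298[i] * exp(h$vant_hoff_c[i] * (1 / temp_k - 1 / T0_K))
  (conc_um * 1e-6) / kh
}

#' In-situ Gibbs free energy of reaction
#'
#' `dG'r = dG0'(T) + R T ln Q`, with `Q` the product of activities raised to
#' the signed stoichiometric coefficients. Dissolved species enter as
#' mol L^-1, gases as bar, water as 1, and H+ as `10^-(pH - 7)` (the
#' bundled dG0 values use the pH-7 reference). A zero activity for a
#' consumed species returns `-Inf` with `flag = "zero_substrate"` (formally
#' infinitely favourable; non-physical, left to the caller).
#'
#' @param rx A `reaction_spec`.
#' @param activities Named vector of activities on the scales above;
#'   `h2o` and `h_plus` may be omitted (defaults 1 and pH from `ph`).
#' @param temp_k Temperature, K.
#' @param ph pH used for the H+ activity when not supplied explicitly.
#' @return List of class `gibbs_result`: `reaction`, `temperature`,
#'   `dg_prime` (kJ mol^-1), `ln_q`, `flag`.
#' @export
delta_g_prime <- function(rx, activities, temp_k, ph = 7) {
  a <- activities
  if (!"h2o" %in% names(a)) a <- c(a, h2o = 1)
  if (!"h_plus" %in% names(a)) a <- c(a, h_plus = 10^-(ph - 7))
  miss <- setdiff(names(rx$stoichiometry), names(a))
  if (length(miss))
    stop("delta_g_prime: missing activities for: ",
         paste(miss, collapse = ", "))
  coef <- rx$stoichiometry
  av <- a[names(coef)]
  if (any(av < 0)) stop("delta_g_prime: negative activity")
  flag <- "ok"
  if (any(av == 0 & coef < 0)) {
    flag <- "zero_substrate"
    ln_q <- -Inf
  } else if (any(av == 0 & coef > 0)) {
    ln_q <- -Inf           # zero product also drives Q to 0
  } else {
    ln_q <- sum(coef * log(av))
  }
  dg <- dg0_at_temperature(rx, temp_k) + R_GAS / 1000 * temp_k * ln_q
  structure(list(reaction = rx$name, temperature = temp_k,
                 dg_prime = dg, ln_q = ln_q, flag = flag),
            class = "gibbs_result")
}

# map a simulator pool vector (uM) at temperature temp_k to thermodynamic
# activities: gases via Henry's law, DIC treated as dissolved CO2, solutes
# as mol/L
pools_to_activities <- function(pools, temp_k) {
  a <- c(
    h2 = if ("h2" %in% names(pools))
      dissolved_to_bar("h2", pools[["h2"]], temp_k) else NA_real_,
    ch4 = if ("ch4" %in% names(pools))
      dissolved_to_bar("ch4", pools[["ch4"]], temp_k) else NA_real_,
    co2 = if ("dic" %in% names(pools))
      dissolved_to_bar("co2", pools[["dic"]], temp_k) else NA_real_,
    acetate = pools[["acetate"]] * 1e-6,
    sulphate = pools[["sulphate"]] * 1e-6,
    methylamine = if ("methylamine" %in% names(pools))
      pools[["methylamine"]] * 1e-6 else NA_real_,
    nh4 = if ("nh4" %in% names(pools)) pools[["nh4"]] * 1e-6 else NA_real_,
    hs = 1e-3    # sulphide is not a tracked pool; reduced medium default
  )
  a[!is.na(a)]
}

#' Thermodynamic favourability across a concentration table
#'
#' Computes dG'r per (temperature, time) from replicate-averaged
#' concentrations and flags the reaction "open" when dG'r falls below a
#' bioenergetic threshold (default -10 kJ per mol reaction, roughly a third
#' of an ATP under physiological conditions).
#'
#' @param rx A `reaction_spec`.
#' @param series Long concentration data frame (`temperature`, `time`,
#'   `species`, `value` in uM).
#' @param ph Assumed pH.
#' @param threshold Openness threshold, kJ per mol reaction.
#' @return Data frame: `reaction`, `temperature` (C), `time`, `dg_prime`,
#'   `ln_q`, `open`, `flag`; rows whose state lacks a needed species are
#'   skipped and counted in attribute `n_skipped`.
#' @export
favourability_profile <- function(rx, series, ph = 7.5, threshold = -10) {
  key <- interaction(series$temperature, series$time, drop = TRUE)
  rows <- list()
  n_skip <- 0L
  for (g in split(series, key)) {
    pools <- tapply(g$value, g$species, mean)
    temp_k <- g$temperature[1] + 273.15
    act <- pools_to_activities(pools, temp_k)
    need <- setdiff(names(rx$stoichiometry), c("h2o", "h_plus"))
    if (!all(need %in% names(act))) { n_skip <- n_skip + 1L; next }
    gr <- delta_g_prime(rx, act, temp_k, ph = ph)
    rows[[length(rows) + 1L]] <- data.frame(
      reaction = rx$name, temperature = g$temperature[1], time = g$time[1],
      dg_prime = gr$dg_prime, ln_q = gr$ln_q,
      open = is.finite(gr$dg_prime) && gr$dg_prime < threshold,
      flag = gr$flag, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$temperature, out$time), ]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skip
  out
}
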