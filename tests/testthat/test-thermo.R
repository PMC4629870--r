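test_that("every bundled reaction is element-balanced", {
  for (rx in reaction_table())
    expect_silent(check_element_balance(rx))
})

test_that("Gibbs-Helmholtz correction behaves at its fixed points", {
  rx <- reaction_table()[["hydrogenotrophic_methanogenesis"]]
  expect_equal(dg0_at_temperature(rx, 298.15), rx$dg0)
  # dH0 == dG0 makes dG0 temperature-independent
  rx2 <- rx; rx2$dh0 <- rx2$dg0
  for (T_ in c(273.15, 298.15, 333.15, 363.15))
    expect_equal(dg0_at_temperature(rx2, T_), rx2$dg0, tolerance = 1e-12)
  # hand-evaluated correction at 60 C for dG0 = -131, dH0 = -253
  expect_equal(dg0_at_temperature(rx, 333.15), -116.6783, tolerance = 1e-3)
  expect_error(dg0_at_temperature(rx, 200), "\\[250, 400\\]")
})

test_that("dG'r reduces to dG0 at unit activities and follows the log law", {
  rx <- reaction_table()[["acetoclastic_methanogenesis"]]
  a1 <- c(acetate = 1, ch4 = 1, co2 = 1)
  g <- delta_g_prime(rx, a1, 298.15, ph = 7)
  expect_equal(g$dg_prime, rx$dg0, tolerance = 1e-12)
  # doubling a product's activity adds RT ln2 times its coefficient
  a2 <- a1; a2[["ch4"]] <- 2
  g2 <- delta_g_prime(rx, a2, 298.15, ph = 7)
  expect_equal(g2$dg_prime - g$dg_prime, 0.008314 * 298.15 * log(2),
               tolerance = 1e-9)
})

test_that("hydrogenotrophic methanogenesis energy matches a hand computation", {
  rx <- reaction_table()[["hydrogenotrophic_methanogenesis"]]
  # H2 at the ~45 uM-equivalent configured as 1e-4 bar; 10 C
  act <- c(h2 = 1e-4, ch4 = 1e-3, co2 = 10^-1.5)
  g <- delta_g_prime(rx, act, 283.15)
  # independent arithmetic: dG0(283.15) + RT[ln pCH4 - 4 ln pH2 - ln pCO2]
  dg0_t <- -131 * (283.15 / 298.15) + (-253) * (1 - 283.15 / 298.15)
  lnq <- log(1e-3) - 4 * log(1e-4) - log(10^-1.5)
  expect_equal(g$dg_prime, dg0_t + 0.008314 * 283.15 * lnq,
               tolerance = 1e-9)
  expect_equal(g$dg_prime, -58.54, tolerance = 0.1)
})

test_that("zero substrate activity yields the flagged -Inf sentinel", {
  rx <- reaction_table()[["hydrogenotrophic_methanogenesis"]]
  g <- delta_g_prime(rx, c(h2 = 0, ch4 = 1e-3, co2 = 0.01), 298.15)
  expect_identical(g$dg_prime, -Inf)
  expect_identical(g$flag, "zero_substrate")
})

test_that("dG'r is additive over summed reactions at identical state", {
  rxs <- reaction_table()
  r1 <- rxs[["hydrogenotrophic_methanogenesis"]]
  r2 <- rxs[["acetoclastic_methanogenesis"]]
  both <- names(table(c(names(r1$stoichiometry), names(r2$stoichiometry))))
  sum_rx <- structure(list(
    name = "sum",
    stoichiometry = vapply(both, function(s)
      sum(r1$stoichiometry[s], r2$stoichiometry[s], na.rm = TRUE), 0),
    dg0 = r1$dg0 + r2$dg0, dh0 = r1$dh0 + r2$dh0),
    class = "reaction_spec")
  act <- c(h2 = 1e-4, ch4 = 2e-3, co2 = 0.05, acetate = 5e-4)
  T_ <- 310
  g_sum <- delta_g_prime(sum_rx, act, T_, ph = 7.5)$dg_prime
  g_parts <- delta_g_prime(r1, act, T_, ph = 7.5)$dg_prime +
    delta_g_prime(r2, act, T_, ph = 7.5)$dg_prime
  expect_equal(g_sum, g_parts, tolerance = 1e-9)
})

test_that("favourability profile reduces to the dg0 curve at Q = 1", {
  rx <- reaction_table()[["acetoclastic_methanogenesis"]]
  # construct concentrations whose activities are exactly 1
  temps <- c(10, 30, 50)
  # concentration (uM) whose equivalent partial pressure is exactly 1 bar
  c_unit <- function(sp, T_) 1 / dissolved_to_bar(sp, 1, T_ + 273.15)
  rows <- do.call(rbind, lapply(temps, function(T_) {
    data.frame(temperature = T_, time = 10,
               species = c("acetate", "ch4", "dic", "sulphate",
                           "methylamine", "nh4", "h2"),
               replicate = 1,
               value = c(1e6, c_unit("ch4", T_), c_unit("co2", T_), 1e6,
                         1e6, 1e6, c_unit("h2", T_)))
  }))
  prof <- favourability_profile(rx, rows, ph = 7)
  expect_equal(prof$dg_prime,
               dg0_at_temperature(rx, temps + 273.15), tolerance = 1e-6)
})

test_that("simulated 55 C state opens acetoclastic methanogenesis", {
  sim <- default_sim()
  d <- sim$design
  conc <- observe_concentrations(sim, d)
  sub <- conc[conc$temperature == 55 & conc$time == 100, ]
  rx <- reaction_table()[["acetoclastic_methanogenesis"]]
  prof <- favourability_profile(rx, sub, ph = 7.5)
  expect_true(prof$open)   # acetate > 1 mM, products dilute
})

test_that("vanishing H2 closes the hydrogenotrophic window", {
  rx <- reaction_table()[["hydrogenotrophic_methanogenesis"]]
  g <- delta_g_prime(rx, c(h2 = 1e-9, ch4 = 1e-3, co2 = 0.01), 288.15)
  expect_gt(g$dg_prime, -10)   # below threshold: flagged closed upstream
})
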