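test_that("CO2 contributions multiply rate by the signed factor", {
  r <- data.frame(process = c("acetoclastic_metal_reduction",
                              "hydrogenotrophic_methanogenesis",
                              "acetoclastic_methanogenesis"),
                  rate = c(100, 50, 0))
  out <- co2_contribution(r)
  expect_equal(out$co2_rate, c(200, -50, 0))
  expect_error(co2_contribution(data.frame(process = "mystery", rate = 1)),
               "mystery")
})

test_that("net balance is the exact signed sum of contributions", {
  r <- expand.grid(process = c("acetoclastic_methanogenesis",
                               "hydrogenotrophic_methanogenesis"),
                   temperature = c(20, 50), time = c(10, 50),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  r$rate <- c(10, 10, 3, 7, 8, 8, 4, 4)
  bal <- net_balance(r)
  pc <- setdiff(names(bal$cells), c("temperature", "time", "net"))
  expect_equal(bal$cells$net, rowSums(bal$cells[pc]))
  # exact cancellation leaves net 0 with non-zero per-process columns
  cancel <- bal$cells[abs(bal$cells$net) < 1e-12, ]
  expect_true(nrow(cancel) > 0)
  expect_true(all(abs(cancel[pc]) > 0))
})

test_that("uniform single-process table gives ratio 1", {
  r <- expand.grid(process = "acetoclastic_methanogenesis",
                   temperature = seq(10, 70, 10), time = 10,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  r$rate <- 5
  bal <- net_balance(r, split_temp = 43)
  expect_true(all(bal$cells$net == 5))
  expect_equal(bal$summary$ratio, 1)
})

test_that("below/above split reproduces a hand-built 8.7-fold contrast", {
  # constructed so the below-split mean is 870 and the above-split 100
  r <- data.frame(process = "acetate_oxidation_co2",
                  temperature = c(20, 30, 40, 50, 60, 70),
                  time = 10,
                  rate = c(800, 870, 940, 90, 100, 110))
  bal <- net_balance(r, split_temp = 43)
  expect_equal(bal$summary$mean_net_below, 870)
  expect_equal(bal$summary$mean_net_above, 100)
  expect_equal(bal$summary$ratio, 8.7)
})

test_that("production shares split gross CO2 production only", {
  r <- data.frame(process = c("acetoclastic_sulphate_reduction",
                              "acetoclastic_metal_reduction",
                              "acetoclastic_methanogenesis",
                              "hydrogenotrophic_acetogenesis"),
                  rate = c(132.5, 366, 3, 50))
  # positive contributions: 265, 732, 3; acetogenesis consumes (excluded)
  groups <- c(acetoclastic_sulphate_reduction = "sulphate reduction",
              acetoclastic_metal_reduction = "metal reduction",
              acetoclastic_methanogenesis = "other")
  sh <- share_of_mineralization(r, groups = groups)
  expect_equal(sh$share_percent[sh$group == "sulphate reduction"], 26.5)
  expect_equal(sh$share_percent[sh$group == "metal reduction"], 73.2)
  expect_equal(sum(sh$share_percent), 100)
  # a single producing group takes 100%
  one <- share_of_mineralization(
    data.frame(process = "acetoclastic_methanogenesis", rate = 7))
  expect_equal(one$share_percent, 100)
})

test_that("consumption-only tables flag the share as undefined", {
  r <- data.frame(process = "hydrogenotrophic_acetogenesis", rate = 10)
  sh <- share_of_mineralization(r)
  expect_equal(attr(sh, "flag"), "undefined")
  expect_equal(nrow(sh), 0)
})

test_that("balance reproduces simulated DIC production where closed", {
  # on noise-free simulated data the summed CO2 contributions of the
  # catalogue track d(DIC)/dt minus the abiotic source terms
  d <- tiny_design(temps = c(25, 60), times = c(30, 60), cv = 0)
  sim <- simulate_slurry(d, dt = 0.1)
  for (T_ in d$temperatures) for (t_ in d$time_points) {
    rates <- data.frame(
      process = dimnames(sim$rates)[[2]],
      temperature = T_, time = t_,
      rate = sapply(dimnames(sim$rates)[[2]],
                    function(p) rate_at(sim, p, T_, t_)))
    bal <- net_balance(rates)
    i <- which.min(abs(sim$times - t_))
    ii <- if (i < length(sim$times)) c(i, i + 1) else c(i - 1, i)
    dic_flux <- (sim$traj[match(T_, sim$temps), "dic", ii[2]] -
                   sim$traj[match(T_, sim$temps), "dic", ii[1]]) / sim$dt
    # 5% per cell, with a small absolute floor for near-zero fluxes
    expect_lt(abs(bal$cells$net - dic_flux), 0.05 * abs(dic_flux) + 0.1)
  }
})
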