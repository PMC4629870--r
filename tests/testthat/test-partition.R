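test_that("hydrogenotrophic fraction bound arithmetic", {
  b <- h2_fraction_bound(100, 58)
  expect_equal(b$acox_acetate_units, 29)
  expect_equal(b$fraction_h2_min, 0.71)
  # abundant acetate oxidation drives the bound to zero
  expect_equal(h2_fraction_bound(100, 400)$fraction_h2_min, 0)
  # degenerate srr = 0
  z <- h2_fraction_bound(0, 10)
  expect_equal(z$fraction_h2_min, 0)
  expect_equal(z$flag, "degenerate")
  expect_error(h2_fraction_bound(-1, 5), ">= 0")
})

test_that("bound is anti-monotone in acetate oxidation and 1 when acox = 0", {
  srr <- 80
  acox <- seq(0, 300, by = 10)
  fr <- h2_fraction_bound(rep(srr, length(acox)), acox)$fraction_h2_min
  expect_true(all(diff(fr) <= 1e-12))
  expect_equal(fr[1], 1)
  expect_true(all(fr >= 0 & fr <= 1))
})

test_that("constructed monotone profile reports the 43 C grid point", {
  temps <- seq(35, 55, by = 1)
  # fraction rises through 0.5 between 42 and 44
  srr <- 100 + 5 * (temps - 35)
  frac_true <- stats::plogis((temps - 43) / 1.5)
  acox <- 2 * srr * (1 - frac_true)
  srr_df <- data.frame(temperature = temps, time = 50, rate = srr)
  acox_df <- data.frame(temperature = temps, time = 50, rate = acox)
  pp <- partition_profile(srr_df, acox_df)
  expect_equal(pp$threshold_temp, 43)
})

test_that("threshold undefined when acetate supply always suffices", {
  temps <- 30:50
  srr_df <- data.frame(temperature = temps, time = 50, rate = 100)
  acox_df <- data.frame(temperature = temps, time = 50, rate = 450)
  pp <- partition_profile(srr_df, acox_df)
  expect_true(is.na(pp$threshold_temp))
  expect_equal(pp$flag, "never_reached")
})

test_that("disjoint temperature grids are reported", {
  srr_df <- data.frame(temperature = c(40, 45, 50), time = 1, rate = 1)
  acox_df <- data.frame(temperature = c(40, 45), time = 1, rate = 1)
  expect_error(partition_profile(srr_df, acox_df), "50")
})

test_that("perfect piecewise-linear data recover the kink exactly", {
  x <- seq(20, 60, by = 2)
  y <- ifelse(x < 43, 2 * x, 86 + 0.2 * (x - 43))
  b <- detect_breakpoint(x, y, grid = 30:60)
  expect_equal(b$break_temp, 43)
  expect_lt(b$sse_total, 1e-18)
  expect_gt(b$improvement, 0.99)
})

test_that("breakpoint detection survives 5% noise in >= 95% of seeds", {
  # response peaking at the critical temperature, as a net-mineralization
  # or rate profile does
  x <- seq(20, 60, by = 2)
  y0 <- ifelse(x < 43, 2 * x, 86 - 2 * (x - 43))
  sigma <- 0.05 * diff(range(y0))
  set.seed(404)
  hits <- replicate(200, {
    b <- detect_breakpoint(x, y0 + rnorm(length(x), 0, sigma), 30:60)
    abs(b$break_temp - 43) <= 2
  })
  expect_gte(mean(hits), 0.95)
})

test_that("a straight line yields no decisive improvement", {
  x <- seq(10, 70, by = 3)
  # exact line: the two-segment fit cannot improve on zero residual
  b0 <- detect_breakpoint(x, 1 + 0.5 * x, grid = 25:55)
  expect_equal(b0$improvement, 0)
  expect_lt(b0$sse_total, 1e-18)
  # under noise the freely chosen split soaks up some variance, but far
  # less than a genuine kink does (compare: > 0.99 for exact kinks)
  set.seed(505)
  imp <- replicate(100, {
    y <- 1 + 0.5 * x + rnorm(length(x), 0, 1)
    detect_breakpoint(x, y, grid = 25:55)$improvement
  })
  expect_lt(stats::median(imp), 0.5)
  expect_error(detect_breakpoint(1:4, 1:4, grid = 100), "3 points")
})

test_that("breakpoint search matches the brute-force oracle exactly", {
  set.seed(606)
  for (rep in 1:5) {
    x <- sort(stats::runif(25, 0, 80))
    y <- sin(x / 10) + stats::rnorm(25, 0, 0.2)
    grid <- seq(10, 70, length.out = 100)
    b <- detect_breakpoint(x, y, grid)
    or <- brute_breakpoint(x, y, grid)
    expect_equal(b$break_temp, or$break_temp)
    expect_equal(b$sse_total, or$sse, tolerance = 1e-10)
  }
})

test_that("fraction bound from simulator output never exceeds the true share", {
  d <- experiment_design(temperatures = 0:80,
                         time_points = c(15, 40, 70, 100), noise_cv = 0)
  sim <- simulate_slurry(d)
  conc <- observe_concentrations(sim, d)
  trc <- tracer_rate(observe_tracers(sim, d))
  agg <- aggregate_rates(trc)
  srr <- sulphate_removal_rates(conc)
  acox <- thermoslurry:::derive_acox_co2(agg)
  pp <- partition_profile(srr, acox)
  # true cumulative hydrogenotrophic share per temperature
  h2c <- apply(sim$rates[, "hydrogenotrophic_sulphate_reduction", ], 1, sum)
  acc <- apply(sim$rates[, "acetoclastic_sulphate_reduction", ], 1, sum)
  share <- ifelse(h2c + acc > 0, h2c / (h2c + acc), 0)
  tab <- pp$table[pp$table$flag == "ok", ]
  viol <- tab$fraction_h2_min - share[match(tab$temperature, sim$temps)]
  expect_lt(max(viol), 0.05)
  # and the noise-free threshold sits at the catalogue's substrate switch
  expect_lte(abs(pp$threshold_temp - 43), 3)
})
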