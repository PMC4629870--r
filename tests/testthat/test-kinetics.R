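test_that("noiseless Arrhenius data invert exactly", {
  temps <- c(10, 20, 30, 40)
  ea_true <- 50   # kJ mol-1
  k <- 1e6 * exp(-ea_true * 1000 / (8.314 * (temps + 273.15)))
  f <- fit_arrhenius(data.frame(temperature = temps, rate = k))
  expect_equal(f$ea, ea_true, tolerance = 1e-9)
  expect_equal(f$ln_a, log(1e6), tolerance = 1e-9)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
})

test_that("fits refuse fewer than three positive points and count exclusions", {
  expect_error(fit_arrhenius(data.frame(temperature = c(10, 20),
                                        rate = c(1, 2))), "3 positive")
  df <- data.frame(temperature = c(10, 20, 30, 40, 50),
                   rate = c(0, 1, 2, 4, 0))
  f <- fit_arrhenius(df)
  expect_equal(f$n_points, 3)
  expect_equal(f$n_excluded, 2)
})

test_that("activation energy is invariant to rate rescaling", {
  temps <- seq(5, 45, by = 5)
  k <- 3e4 * exp(-30 * 1000 / (8.314 * (temps + 273.15)))
  f1 <- fit_arrhenius(data.frame(temperature = temps, rate = k))
  f2 <- fit_arrhenius(data.frame(temperature = temps, rate = 17.3 * k))
  expect_equal(f1$ea, f2$ea, tolerance = 1e-9)
  expect_equal(f2$ln_a - f1$ln_a, log(17.3), tolerance = 1e-9)
})

test_that("Q10 over the 10-20 C convention matches frozen evaluations", {
  expect_equal(q10_from_ea(0)$q10, 1)
  # Ea of 8.9 kJ/mol: the low-energy hydrogenotrophic regime
  expect_equal(round(q10_from_ea(8.9)$q10, 1), 1.1)
  expect_equal(q10_from_ea(8.9)$q10, 1.137651, tolerance = 1e-6)
  # Ea of 56.8 kJ/mol: the acetate-fuelled regime
  expect_equal(q10_from_ea(56.8)$q10, 2.277460, tolerance = 1e-6)
  expect_equal(round(q10_from_ea(56.8)$q10, 2), 2.28)
  expect_error(q10_from_ea(10, t1 = 300, t2 = 290), "exceed")
})

test_that("Q10 <-> Ea round trip is an algebraic identity", {
  expect_equal(ea_from_q10(1), 0)
  for (x in c(1, 5, 25, 56.8, 120, 200))
    expect_equal(ea_from_q10(q10_from_ea(x)$q10), x, tolerance = 1e-10)
  expect_equal(ea_from_q10(2.5), 63.233872, tolerance = 1e-6)
  expect_error(ea_from_q10(0), "> 0")
})

test_that("Q10 is strictly increasing in activation energy", {
  eas <- seq(0, 150, by = 5)
  q <- vapply(eas, function(e) q10_from_ea(e)$q10, 0)
  expect_true(all(diff(q) > 0))
})

test_that("noisy Arrhenius recovery finds the true Ea within 10% (median)", {
  temps <- seq(5, 45, by = 5)   # 9 temperatures
  ea_true <- 56.8
  k_true <- 5e8 * exp(-ea_true * 1000 / (8.314 * (temps + 273.15)))
  set.seed(101)
  est <- replicate(200, {
    k <- k_true * exp(rnorm(length(k_true), 0, sqrt(log(1 + 0.05^2))))
    fit_arrhenius(data.frame(temperature = temps, rate = k))$ea
  })
  expect_lt(abs(stats::median(est) - ea_true) / ea_true, 0.10)
})

test_that("two-regime fit recovers a synthetic substrate switch", {
  temps <- seq(10, 70, by = 4)
  ea <- ifelse(temps < 43, 56.8, 8.9)
  ln_a <- ifelse(temps < 43, 20, 4)
  k <- exp(ln_a - ea * 1000 / (8.314 * (temps + 273.15)))
  tr <- two_regime_fit(data.frame(temperature = temps, rate = k), 30:60)
  expect_false(tr$fallback)
  expect_lte(abs(tr$break_temp - 43), 2)
  expect_equal(tr$left$ea, 56.8, tolerance = 0.1)
  expect_equal(tr$right$ea, 8.9, tolerance = 0.1)
})

test_that("two-regime search matches the brute-force oracle", {
  set.seed(202)
  temps <- seq(5, 75, by = 5)
  for (rep in 1:5) {
    y <- 2 + 0.1 * temps + stats::rnorm(length(temps), 0, 0.5) +
      ifelse(temps >= 40, 0.05 * (temps - 40), 0)
    k <- exp(y)
    grid <- seq(20, 60, by = 1)
    tr <- two_regime_fit(data.frame(temperature = temps, rate = k), grid)
    # independent exhaustive search with closed-form OLS in ln(k) ~ 1/T
    ols_sse <- function(tt, yy) {
      x <- 1 / (tt + 273.15)
      X <- cbind(1, x)
      b <- solve(crossprod(X), crossprod(X, yy))
      sum((yy - X %*% b)^2)
    }
    best_b <- NA; best_sse <- Inf
    for (b in grid) {
      lo <- temps < b
      if (sum(lo) < 3 || sum(!lo) < 3) next
      sse <- ols_sse(temps[lo], log(k)[lo]) + ols_sse(temps[!lo],
                                                      log(k)[!lo])
      if (sse < best_sse - 1e-12) { best_sse <- sse; best_b <- b }
    }
    expect_equal(tr$break_temp, best_b)
    expect_equal(tr$sse_total, best_sse, tolerance = 1e-8)
  }
})

test_that("single-regime data yield little improvement and feasible fallback", {
  temps <- seq(5, 75, by = 5)
  k <- 1e7 * exp(-40 * 1000 / (8.314 * (temps + 273.15)))
  set.seed(303)
  imp <- replicate(50, {
    kk <- k * exp(rnorm(length(k), 0, 0.03))
    two_regime_fit(data.frame(temperature = temps, rate = kk),
                   30:60)$improvement
  })
  expect_lt(stats::median(imp), 0.35)   # no decisive break under the null
  # infeasible grid falls back to the single fit with a flag
  tr <- two_regime_fit(data.frame(temperature = temps[1:4], rate = k[1:4]),
                       candidate_breaks = 90)
  expect_true(tr$fallback)
})
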