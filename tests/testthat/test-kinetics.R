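test_that("a noiseless exponential on the standard grid is fitted exactly", {
  fit <- fit_first_order_rate(exact_decay(0.05))
  expect_equal(fit$k, 0.05, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_true(fit$significant_degradation)
})

test_that("a constant series gives k = 0 and no significant degradation", {
  fit <- fit_first_order_rate(decay_series(90, c(0, 5, 10, 20), rep(2, 4)))
  expect_equal(fit$k, 0)
  expect_false(fit$significant_degradation)
})

test_that("nonpositive values abort the log transform naming the time point", {
  s <- decay_series(150, c(0, 5, 10, 20), c(1, 0.5, 0, 0.1))
  expect_error(fit_first_order_rate(s), "t = 10")
})

test_that("series validation enforces the type invariants", {
  expect_error(decay_series(120, c(0, 5), c(1, 0.5)), "at least 3")
  expect_error(decay_series(120, c(1, 5, 10), c(1, 0.5, 0.2)),
               "must be 0")
  expect_error(decay_series(120, c(0, 5, 5), c(1, 0.5, 0.2)),
               "strictly increasing")
  expect_error(decay_series(120, c(0, 5, 10), c(0, 0.5, 0.2)),
               "strictly positive")
})

test_that("the OLS rate matches the brute-force SSE grid search on noisy instances", {
  set.seed(2024)
  for (i in 1:8) {
    k_true <- runif(1, 0.01, 0.3)
    times <- c(0, 2, 5, 7, 10, 20, 30, 40)
    vals <- exp(-k_true * times) * exp(rnorm(length(times), 0, 0.02))
    vals <- vals / vals[1] * 1  # keep C0 positive scale
    s <- decay_series(140, times, vals)
    k_hat <- fit_first_order_rate(s)$k
    k_oracle <- grid_search_rate(times, vals, k_max = 0.5)
    expect_lt(abs(k_hat - k_oracle), 1e-4)
  }
})

test_that("D and t1/2 follow ln(10)/k and ln(2)/k, matching published rows", {
  expect_equal(decimal_reduction_time(log(10)), 1)
  expect_equal(half_life(log(2)), 1)
  # published rate constants: 120 and 180 degC anthocyanin, 180 degC DPPH
  expect_equal(decimal_reduction_time(0.0228), 101.01, tolerance = 0.01)
  expect_equal(half_life(0.0228), 30.40, tolerance = 0.01)
  expect_equal(decimal_reduction_time(0.2268), 10.15, tolerance = 0.01)
  expect_equal(half_life(0.0485), 14.29, tolerance = 0.01)
  expect_error(decimal_reduction_time(0), "no degradation")
  expect_error(half_life(-0.1), "no degradation")
})

test_that("z-value fit recovers an exact log-linear D profile and published columns", {
  temps <- seq(100, 160, 10)
  d_exact <- 10^(3 - temps / 50)  # z = 50 by construction
  z <- fit_z_value(temps, d_exact)
  expect_equal(z$z_value, 50, tolerance = 1e-9)
  expect_equal(z$r_squared, 1)

  t1 <- published_anthocyanin()
  z1 <- fit_z_value(t1$temperature_c, t1$d_value_min)
  expect_equal(z1$z_value, 61.72, tolerance = 0.02)

  t2 <- published_antioxidant()
  z2 <- fit_z_value(t2$temperature_c, t2$d_value_min)
  expect_equal(z2$z_value, 75.75, tolerance = 0.02)
})

test_that("z-value fit warns on non-physical (increasing D) input", {
  expect_warning(z <- fit_z_value(c(100, 110, 120), c(10, 20, 40)),
                 "non-physical")
  expect_true(z$non_physical)
  expect_true(is.na(z$z_value))
  expect_error(fit_z_value(c(100, 110), c(10, 5)), "insufficient data")
})

test_that("Arrhenius fit recovers exact inputs and published k columns", {
  temps <- c(100, 120, 140, 160, 180)
  k_exact <- 1e6 * exp(-50e3 / (8.314 * (temps + 273.15)))
  arr <- fit_arrhenius(temps, k_exact)
  expect_equal(arr$ea, 50, tolerance = 1e-9)
  expect_equal(arr$r_squared, 1)
  expect_equal(arr$ln_pre_exponential, log(1e6), tolerance = 1e-9)

  t1 <- published_anthocyanin()
  expect_equal(fit_arrhenius(t1$temperature_c, t1$k_per_min)$ea, 55.75,
               tolerance = 0.02)
  t2 <- published_antioxidant()
  expect_equal(fit_arrhenius(t2$temperature_c, t2$k_per_min)$ea, 41.12,
               tolerance = 0.03)
})

test_that("duplicate temperatures collapse to geometric-mean k before fitting", {
  temps <- c(120, 120, 140, 160)
  ks <- c(0.01, 0.04, 0.05, 0.1)
  expect_message(arr <- fit_arrhenius(temps, ks), "geometric-mean")
  ref <- fit_arrhenius(c(120, 140, 160), c(sqrt(0.01 * 0.04), 0.05, 0.1))
  expect_equal(arr$ea, ref$ea)
  expect_error(suppressMessages(fit_arrhenius(c(120, 120, 140),
                                              c(0.01, 0.02, 0.05))),
               "insufficient data")
})

test_that("predicted retention is 100 exp(-kt), about 70% at 180 degC for 7 min", {
  expect_equal(predicted_retention(0.1, 0), 100)
  expect_equal(predicted_retention(0, 500), 100)
  expect_equal(predicted_retention(0.0485, 7), 71.2, tolerance = 1e-3)
  expect_error(predicted_retention(0.1, -1), "parameter error")
})

test_that("summary splits thermostable from degrading temperatures and recovers Ea", {
  cfg <- generator_config(ea_true = 55, noise_cv = 0, replicates = 1,
                          stable_below = 120,
                          ln_a_true = log(0.03) +
                            55e3 / (GAS_CONSTANT * 393.15))
  sim <- simulate_decay(cfg)
  smry <- summarize_kinetics(sim$series)
  expect_equal(smry$thermostable, c(80, 90, 100, 110))
  expect_equal(smry$rows$temperature_c, seq(120, 180, 10))
  expect_equal(smry$arrhenius$ea, 55, tolerance = 1e-6)
  expect_false(smry$z$non_physical)
})

test_that("degenerate summaries carry rows but no Ea/z", {
  flat <- lapply(c(80, 90, 100), function(tt)
    decay_series(tt, c(0, 10, 20, 30), rep(1, 4)))
  smry <- summarize_kinetics(flat)
  expect_equal(nrow(smry$rows), 0)
  expect_null(smry$arrhenius)

  one <- summarize_kinetics(list(exact_decay(0.05, temperature = 150)))
  expect_equal(nrow(one$rows), 1)
  expect_null(one$arrhenius)
})

test_that("summary rows satisfy the exact D*k and t1/2*k identities", {
  cfg <- generator_config(noise_cv = 0.03, seed = 7)
  smry <- summarize_kinetics(simulate_decay(cfg)$series)
  expect_true(nrow(smry$rows) >= 3)
  expect_equal(smry$rows$d_value_min * smry$rows$k_per_min,
               rep(log(10), nrow(smry$rows)))
  expect_equal(smry$rows$half_life_min * smry$rows$k_per_min,
               rep(log(2), nrow(smry$rows)))
  expect_equal(smry$rows$half_life_min / smry$rows$d_value_min,
               rep(log10(2), nrow(smry$rows)))
})

test_that("k increases monotonically with temperature at zero noise", {
  cfg <- generator_config(noise_cv = 0, replicates = 1, stable_below = NULL,
                          temperatures = seq(120, 180, 10))
  smry <- summarize_kinetics(simulate_decay(cfg)$series)
  expect_true(all(diff(smry$rows$k_per_min) > 0))
})

test_that("z approximately equals ln(10)*R*Tmid^2/Ea on the published values", {
  # consistency of the two thermal-sensitivity parameterisations at the
  # midpoint temperature of the degrading range (documented approximation)
  t1 <- published_anthocyanin()
  arr <- fit_arrhenius(t1$temperature_c, t1$k_per_min)
  zfit <- fit_z_value(t1$temperature_c, t1$d_value_min)
  z_approx <- log(10) * GAS_CONSTANT * 423^2 / (arr$ea * 1000)
  expect_equal(zfit$z_value, z_approx, tolerance = 0.05)
})

test_that("replicates at the same temperature and time are averaged before fitting", {
  t <- c(0, 5, 10, 20)
  s1 <- decay_series(130, t, exp(-0.04 * t) * 1.1, replicate_id = "a")
  s2 <- decay_series(130, t, exp(-0.04 * t) * 0.9, replicate_id = "b")
  smry <- summarize_kinetics(list(s1, s2, exact_decay(0.05, 140),
                                  exact_decay(0.06, 150)))
  mean_series <- decay_series(130, t, (exp(-0.04 * t) * 1.1 +
                                         exp(-0.04 * t) * 0.9) / 2)
  expect_equal(smry$rows$k_per_min[smry$rows$temperature_c == 130],
               fit_first_order_rate(mean_series)$k)
})

test_that("model-order comparison prefers first order on exponential decay", {
  cmp <- compare_reaction_orders(exact_decay(0.1))
  expect_equal(cmp$r_squared_first_order, 1)
  expect_lt(cmp$r_squared_zero_order, 1)
  expect_equal(cmp$preferred, "first")

  t <- c(0, 5, 10, 20, 30)
  lin <- decay_series(100, t, 10 - 0.2 * t)
  expect_equal(compare_reaction_orders(lin)$preferred, "zero")
})
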