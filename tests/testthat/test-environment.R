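test_that("skewed diel curve hits its anchors and is monotone on each arc", {
  expect_equal(skewed_diel_curve(seq(0, 23), 20, 20), rep(20, 24))
  expect_equal(skewed_diel_curve(15, 10, 30, t_min = 5, t_max = 15), 30)
  expect_equal(skewed_diel_curve(5, 10, 30, t_min = 5, t_max = 15), 10)
  for (sk in c(0.5, 1, 2)) {
    g <- seq(5, 15, 0.1)
    v <- skewed_diel_curve(g, 10, 30, t_min = 5, t_max = 15, skew = sk)
    expect_true(all(diff(v) > 0))
    g2 <- seq(15.1, 28.9, 0.1)   # falling arc, wrapped past midnight
    v2 <- skewed_diel_curve(g2 %% 24, 10, 30, t_min = 5, t_max = 15,
                            skew = sk)
    expect_true(all(diff(v2) < 0))
  }
  expect_error(skewed_diel_curve(1, 30, 10), "v_min")
  expect_error(skewed_diel_curve(1, 10, 30, t_min = 5, t_max = 5), "differ")
})

test_that("light curve peaks at noon, clamps below compensation, spans daylength", {
  expect_equal(light_curve(12, i_max = 250), 250)
  expect_equal(light_curve(0, i_max = 250), 0)
  ## window edges sit exactly at the compensation clamp
  eps <- 1e-4
  expect_equal(light_curve(6 + eps, 250, daylength = 12), 30,
               tolerance = 1e-3)
  expect_equal(light_curve(6 - eps, 250, daylength = 12), 0)
  expect_equal(light_curve(18 - eps, 250, daylength = 12), 30,
               tolerance = 1e-3)
  ## the sigma solving I(edge) = compensation reproduces the curve
  sigma <- 6 / sqrt(2 * log(250 / 30))
  expect_equal(light_curve(9, 250), 250 * exp(-9 / (2 * sigma^2)))
  expect_error(light_curve(12, i_max = 20), "compensation")
  expect_error(light_curve(12, 250, daylength = 25), "daylength")
})

test_that("stomatal water cost matches an independently coded closed form", {
  for (T in c(10, 20, 30, 40, 48)) for (rh in c(0, 0.4, 0.8, 1)) {
    expect_equal(water_per_co2(T, rh), oracle_water_per_co2(T, rh),
                 tolerance = 1e-12)
  }
  ## hand-checked magnitude at the reference daytime conditions
  expect_equal(water_per_co2(30, 0.4), 335.169, tolerance = 1e-4)
  expect_equal(water_per_co2(25, 1), 0)
  expect_gt(water_per_co2(40, 0.1), water_per_co2(30, 0.4))
  ## strictly increasing in T, strictly decreasing in RH
  Ts <- seq(5, 45, 5)
  expect_true(all(diff(water_per_co2(Ts, 0.5)) > 0))
  rhs <- seq(0, 1, 0.1)
  expect_true(all(diff(water_per_co2(25, rhs)) < 0))
  ## cost scales as 1/(1 - ci_ratio)
  r1 <- water_per_co2(30, 0.4, gas_exchange_params(ci_ratio = 0.7))
  r2 <- water_per_co2(30, 0.4, gas_exchange_params(ci_ratio = 0.85))
  expect_equal(r2 / r1, 0.3 / 0.15, tolerance = 1e-12)
  expect_error(water_per_co2(30, 1.2), "rh")
  expect_error(gas_exchange_params(ci_ratio = 1.2), "ci_ratio")
})

test_that("total water loss integrates linearly over the diel cycle", {
  env <- diel_environment()
  expect_equal(total_water_loss(rep(0, 24), env), 0)
  u1 <- runif(24, 0, 5); u2 <- runif(24, 0, 5)
  expect_equal(total_water_loss(2 * u1 + 3 * u2, env),
               2 * total_water_loss(u1, env) + 3 * total_water_loss(u2, env),
               tolerance = 1e-12)
  ## closed form at constant conditions
  flat <- diel_environment(t_min = 30, t_max = 30, rh_min = 0.4,
                           rh_max = 0.4)
  expect_equal(total_water_loss(rep(1, 24), flat),
               86400e-6 * oracle_water_per_co2(30, 0.4), tolerance = 1e-10)
  ## uptake at the coolest, most humid hour costs no more than the same
  ## uptake at the hottest, driest hour
  r <- water_per_co2(env$T, env$RH)
  cool <- hot <- rep(0, 24)
  cool[which.min(r)] <- 1; hot[which.max(r)] <- 1
  expect_lte(total_water_loss(cool, env), total_water_loss(hot, env))
  expect_error(total_water_loss(rep(-1, 24), env), "nonnegative")
  expect_error(total_water_loss(rep(1, 12), env), "one entry per")
})

test_that("the reference profile has afternoon temperature peak and anti-phased humidity", {
  env <- diel_environment(t_max = 30, rh_min = 0.4)
  expect_equal(sum(env$is_day), 12)
  expect_equal(env$hour[which.max(env$T)], 14.5)   # step containing 15:00
  expect_equal(which.min(env$RH), which.max(env$T))
  expect_equal(max(env$T), 30, tolerance = 0.05)
  expect_equal(min(env$RH), 0.4, tolerance = 0.005)
  expect_true(all(env$RH >= 0 & env$RH <= 1))
  expect_true(all(env$I >= 0))
  expect_equal(nrow(diel_environment(n_steps = 6)), 6)
  expect_error(diel_environment(n_steps = 7), "divide")
  expect_error(diel_environment(rh_min = 0.9, rh_max = 0.4), "humidity")
})
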