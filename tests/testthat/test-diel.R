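test_that("diel expansion has the expected variables, bounds and couplings", {
  net <- toy_net(); env <- ref_env(); cs <- ref_cs()
  model <- expand_diel(net, env, cs)
  N <- 24; R <- nrow(net$reactions); Ns <- nrow(net$storables)
  expect_equal(nrow(model$vars), N * R + N * Ns)
  expect_equal(sum(model$vars$kind == "linker"), N * Ns)
  ## all linker fluxes nonnegative
  expect_true(all(model$vars$lb[model$vars$kind == "linker"] == 0))
  bounds <- model_bounds(model)
  ## light uptake capped by the light curve at every step
  light <- bounds[bounds$reaction_id == "EX_PHOTON", ]
  expect_equal(light$ub[order(light$step)], pmin(env$I, model$flux_cap))
  ## Rubisco silent at night, carboxylase:oxygenase 3:1 rows by day
  for (id in c("RBC_CARB", "RBC_OXY")) {
    b <- bounds[bounds$reaction_id == id, ]
    expect_true(all(b$ub[!env$is_day[b$step]] == 0))
  }
  expect_equal(sum(model$row_kind == "rubisco_ratio"), sum(env$is_day))
  ## CO2 uptake capped at 15 umol m-2 s-1
  up <- bounds[bounds$reaction_id == "CO2_UPTAKE", ]
  expect_true(all(up$ub <= 15 + 1e-12))
  ## maintenance fixed per step with 3:1 day:night and 3:1 ATP:NADPH
  ma <- bounds[bounds$reaction_id == "ATP_MAINT", ]
  mn <- bounds[bounds$reaction_id == "NADPH_MAINT", ]
  expect_true(all(ma$lb == ma$ub))
  m_day <- ma$ub[env$is_day[ma$step]][1]
  m_night <- ma$ub[!env$is_day[ma$step]][1]
  expect_equal(m_day / m_night, 3)
  expect_equal(ma$ub / mn$ub, rep(3, N))
  expect_equal(m_day, cs$maintenance_k * mean(env$I[env$is_day]))
  ## phloem and nitrate day/night couplings present
  expect_equal(sum(model$row_kind == "phloem_couple"), N - 1)
  expect_equal(sum(model$row_kind == "nitrate_couple"), N - 1)
})

test_that("a linker flux of 1 umol m-2 s-1 over a 1-h step stores 3.6 mmol m-2", {
  model <- diel_variant("cam")
  x <- numeric(nrow(model$vars))
  lnk <- which(model$vars$kind == "linker" &
                 model$vars$id == "MAL_v" & model$vars$step == 5)
  x[lnk] <- 1
  sol <- diel_solution(model, x)
  prof <- linker_profiles(sol)
  expect_equal(prof$amount_mmol[prof$storable == "MAL_v" & prof$step == 5],
               3.6)
  expect_true(all(prof$amount_mmol[prof$storable != "MAL_v" |
                                     prof$step != 5] == 0))
})

test_that("vacuolar capacity rows constrain solutes but never starch", {
  net <- toy_net(); env <- ref_env(); cs <- ref_cs()
  base <- expand_diel(net, env, cs)
  expect_equal(sum(apply_vacuole_capacity(base, Inf)$row_kind ==
                     "vacuole_cap"), 0)
  m0 <- couple_water_loss(apply_vacuole_capacity(base, 0))
  sol <- maximize_phloem(m0)
  vac <- sol$model$net$storables$compartment == "vacuole"
  expect_lt(max(sol$linkers[vac, ]), 1e-6)
  expect_gt(max(sol$linkers["STARCH_p", ]), 0.01)
  ## capacity must be a single nonnegative number
  expect_error(apply_vacuole_capacity(base, -1), "nonnegative")
  ## CAM anatomy multiplies the C3 capacity 3.1-fold
  expect_equal(cs$cam_capacity_factor, 3.1)
  ## stored amounts respect the capacity in a solved model
  s80 <- sol80("cam")
  stor <- s80$model$net$storables
  amounts <- colSums(s80$linkers[stor$compartment == "vacuole", ]) * 3.6e-3
  expect_true(all(amounts <= cs$vacuole_capacity_c3 * 3.1 + 1e-6))
})

test_that("blocking all carry-over makes obligatory night maintenance infeasible", {
  model <- diel_variant("c3")
  model$vars$ub[model$vars$kind == "linker"] <- 0
  expect_error(maximize_phloem(model), "infeasible")
})

test_that("solved models satisfy per-step steady state and cyclic conservation", {
  for (mode in c("c3", "cam", "unlimited")) {
    sol <- sol80(mode)
    expect_lt(balance_residual(sol), 1e-9)
    ## over the closed cycle, what enters each store leaves it again
    turnover <- rowSums(sol$linkers)   # finite by construction
    expect_true(all(is.finite(turnover)))
    ## nonnegative carry-over (within the polish bound tolerance)
    expect_gte(min(sol$linkers), -3e-6)
  }
})

test_that("water coupling mirrors the gas-exchange model exactly", {
  model <- diel_variant("cam")
  env <- ref_env()
  expect_equal(model$water_coefs, water_per_co2(env$T, env$RH))
  expect_equal(which.max(model$water_coefs), which.max(env$T))
  ## recomputed water of a solution is linear in uptake
  sol <- sol80("cam")
  up <- sol$fluxes["CO2_UPTAKE", ]
  expect_equal(sol$water_total, total_water_loss(pmax(up, 0), env))
  expect_equal(total_water_loss(2 * pmax(up, 0), env), 2 * sol$water_total)
})

test_that("halving the time resolution changes daily phloem output by under 5%", {
  net <- toy_net(); cs <- ref_cs()
  p24 <- ref_pstar()
  env12 <- diel_environment(n_steps = 12)
  m12 <- couple_water_loss(apply_vacuole_capacity(
    expand_diel(net, env12, cs), cs$vacuole_capacity_c3))
  p12 <- maximize_phloem(m12, minimize_flux_after = FALSE)$phloem_output
  expect_lt(abs(p12 - p24) / p24, 0.05)
})
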