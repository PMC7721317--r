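test_that("ICDH reversibility scenarios enforce their bounds and ordering", {
  s_rev <- sol80("cam")
  s_ir <- sol80("cam", toy_net_irrev())
  ## reversible variant fixes CO2 through carboxylating mitochondrial ICDH
  ## during at least one dark step
  night <- !ref_env()$is_day
  expect_lt(min(s_rev$fluxes["ICDH_M", night]), -0.05)
  ## irreversible variant never runs it backwards
  expect_gte(min(s_ir$fluxes["ICDH_M", ]), -1e-6)
  ## losing the carboxylating route costs water
  expect_lte(s_rev$water_total, s_ir$water_total * (1 + 1e-4))
})

test_that("run_scenario applies the named variant configuration", {
  env6 <- diel_environment(n_steps = 6)
  cfg <- scenario_config(icdh_mode = "irreversible", vacuole_mode = "CAM",
                         productivity_fraction = 80, env = env6)
  sol <- fixture("scen_irrev6", function() run_scenario(cfg, toy_net()))
  expect_s3_class(sol, "diel_solution")
  expect_gte(min(sol$fluxes["ICDH_M", ]), -1e-6)
  expect_equal(sol$phloem_output, 0.8 * attr(sol, "max_phloem"),
               tolerance = 1e-3)
  expect_error(scenario_config(icdh_mode = "reversible",
                               cit_night_only = TRUE),
               "irreversible")
})

test_that("the Cit_night variant blocks daytime vacuolar (iso)citrate import", {
  env6 <- diel_environment(n_steps = 6)
  cfg <- scenario_config(icdh_mode = "irreversible", cit_night_only = TRUE,
                         vacuole_mode = "CAM", productivity_fraction = 80,
                         env = env6)
  sol <- fixture("scen_citnight6", function() run_scenario(cfg, toy_net()))
  day <- env6$is_day
  for (vt in c("VT_CIT", "VT_ICIT"))
    expect_lte(max(sol$fluxes[vt, day]), 1e-6)   # import is forward flux
  ## a constraint superset can only need more water
  cfg_ir <- scenario_config(icdh_mode = "irreversible",
                            vacuole_mode = "CAM",
                            productivity_fraction = 80, env = env6)
  sol_ir <- fixture("scen_ir_ref6", function()
    run_scenario(cfg_ir, toy_net(),
                 max_phloem = attr(sol, "max_phloem")))
  expect_gte(sol$water_total, sol_ir$water_total * (1 - 1e-4))
})

test_that("environment grid records carry consistent water-saving metrics", {
  rec <- fixture("grid_small", function()
    environment_grid(toy_net(), t_max_grid = c(25, 35),
                     rh_min_grid = c(0.4, 0.8), fraction = 80,
                     n_steps = 12))
  expect_equal(nrow(rec), 4)
  ok <- rec$status == "optimal"
  expect_true(all(ok))
  expect_equal(rec$saving_abs, rec$water_c3_100 - rec$water_rev)
  expect_equal(rec$saving_rel_pct, 100 * rec$saving_abs / rec$water_c3_100)
  expect_equal(rec$icdh_rel_pct, 100 * (rec$water_irrev - rec$water_rev) /
                 rec$water_c3_100)
  ## relaxation orderings on every cell
  expect_true(all(rec$icdh_abs >= -1e-3))
  expect_true(all(rec$saving_abs >= -1e-3))
  expect_true(all(rec$saving_rel_pct <= 100 + 1e-6))
  ## hotter, drier cells lose more absolute water in the C3 reference
  byrh <- rec[order(rec$t_max, rec$rh_min), ]
  expect_gt(rec$water_c3_100[rec$t_max == 35 & rec$rh_min == 0.4],
            rec$water_c3_100[rec$t_max == 25 & rec$rh_min == 0.8])
})

test_that("water loss rises monotonically with the internal CO2 ratio", {
  tab <- fixture("ci_tab", function()
    ci_sensitivity(toy_net(), ci_ratios = c(0.6, 0.7, 0.8), fraction = 80,
                   env = diel_environment(n_steps = 12)))
  expect_true(all(tab$status == "optimal"))
  expect_true(all(diff(tab$water_total) > 0))
  expect_error(ci_sensitivity(toy_net(), ci_ratios = c(0.5, 1.2)),
               "strictly between")
})
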