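test_that("CO2 budget balances and identifies the expected fixers", {
  sol <- sol80("cam")
  bud <- co2_budget(sol)
  expect_s3_class(bud, "flux_budget")
  ## production balances consumption at every step
  expect_lt(bud$balance, 1e-6)
  ## an infinite threshold empties the table
  expect_equal(nrow(co2_budget(sol, threshold = Inf)$contributions), 0)
  ## Rubisco dominates daytime consumption; PEPC and carboxylating
  ## mitochondrial ICDH fix CO2 at night
  day <- ref_env()$is_day
  cons_day <- rowSums(pmin(bud$contributions[, day, drop = FALSE], 0))
  expect_equal(names(which.min(cons_day)), "RBC_CARB")
  night_contrib <- bud$contributions[, !day, drop = FALSE]
  expect_true("PEPC" %in% rownames(night_contrib))
  ## PEPC consumes bicarbonate (negative contribution) during the night
  expect_lt(min(night_contrib["PEPC", ]), -0.5)
  expect_lt(min(night_contrib["ICDH_M", ]), -0.1)
})

test_that("ATP budget turnover is production, and costs rank the variants", {
  s_rev <- sol80("cam")
  s_ir <- sol80("cam", toy_net_irrev())
  b_rev <- atp_budget(s_rev)
  b_ir <- atp_budget(s_ir)
  expect_lt(b_rev$balance, 1e-6)
  ## blocking the carboxylating ICDH route forces costlier flux detours
  expect_gte(b_ir$turnover, b_rev$turnover * 0.99)
  expect_gte(s_ir$flux_sum_l1, s_rev$flux_sum_l1 * 0.99)
  ## a zero-flux solution has zero turnover
  model <- s_rev$model
  zero <- diel_solution(model, numeric(nrow(model$vars)))
  expect_equal(atp_budget(zero)$turnover, 0)
  expect_equal(co2_budget(zero)$turnover, 0)
})

test_that("linker profiles flag the storables the water-saving mode relies on", {
  sol <- sol80("cam")
  prof <- linker_profiles(sol)
  flagged <- attr(prof, "flagged")
  ## nocturnally fixed carbon is parked as (iso)citrate; Pro and Asn carry
  ## the amino-acid legs of the cycle
  expect_true(any(c("CIT_v", "ICIT_v") %in% flagged))
  expect_true("PRO_v" %in% flagged)
  expect_true("STARCH_p" %in% flagged)
  ## Asn stores the nocturnal amino-nitrogen leg; its pool is smaller on
  ## the reduced network, so it clears a correspondingly lower threshold
  expect_true("ASN_v" %in% attr(linker_profiles(sol, 0.1), "flagged"))
  ## a zero-linker solution yields an all-zero table
  zero <- diel_solution(sol$model, numeric(nrow(sol$model$vars)))
  expect_true(all(linker_profiles(zero)$amount_mmol == 0))
})

test_that("phase detection follows the uptake/light pattern rules", {
  model <- diel_variant("cam")
  env <- ref_env()
  mk_sol <- function(uptake) {
    x <- numeric(nrow(model$vars))
    x[rxn_cols_test(model, "CO2_UPTAKE")] <- uptake
    diel_solution(model, x)
  }
  ## pure C3: uptake across the whole photoperiod, none at night
  ph <- detect_phases(mk_sol(ifelse(env$is_day, 5, 0)))
  expect_false("III" %in% ph)
  expect_false("I" %in% ph)
  expect_setequal(unique(ph[env$is_day]), c("II", "IV"))
  ## uptake only at night: phases I and III only
  ph2 <- detect_phases(mk_sol(ifelse(env$is_day, 0, 5)))
  expect_setequal(unique(ph2), c("I", "III"))
  ## labels partition the day: every step gets exactly one label
  expect_length(ph2, 24)
})

test_that("serialized solutions reproduce the water total on re-reading", {
  sol <- sol80("cam")
  stem <- file.path(tempdir(), "camrun")
  paths <- write_solution(sol, stem)
  expect_true(all(file.exists(paths)))
  w <- water_from_files(stem)
  expect_equal(w, sol$water_total, tolerance = 1e-9)
  summ <- jsonlite::read_json(paste0(stem, "_summary.json"))
  expect_equal(summ$phloem_output, sol$phloem_output, tolerance = 1e-12)
  expect_equal(summ$water_total, sol$water_total, tolerance = 1e-12)
})
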