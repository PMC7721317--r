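test_that("the synthetic core network is well-formed and fully tagged", {
  net <- toy_net()
  expect_s3_class(net, "metabolic_network")
  expect_gte(nrow(net$reactions), 60)
  expect_lte(nrow(net$reactions), 120)
  expect_setequal(unique(net$metabolites$compartment),
                  c("cytosol", "plastid", "mitochondrion", "peroxisome",
                    "vacuole", "extracellular"))
  roles <- check_required_tags(net)
  expect_length(roles, 8)
  ## the vacuolar storables include the three carboxylic acids
  expect_true(all(c("MAL_v", "CIT_v", "ICIT_v") %in%
                    net$storables$metabolite))
  expect_true("STARCH_p" %in% net$storables$metabolite)
  ## every tag except vacuolar transport resolves uniquely
  for (tg in c("PEPC", "ICDH_M", "ICDH_C", "RUBISCO_CARB", "RUBISCO_OXY",
               "GDC", "PHLOEM_EXPORT", "NITRATE_UPTAKE", "CO2_UPTAKE"))
    expect_length(find_tag(net, tg), 1)
  expect_gt(length(find_tag(net, "VACUOLAR_TRANSPORT", several = TRUE)), 5)
  expect_error(find_tag(net, "NO_SUCH_ROLE"), "configuration error")
})

test_that("a strictly positive conservation weighting exists (no mass leaks)", {
  cc <- stoichiometric_consistency(toy_net())
  expect_true(cc$consistent)
  expect_true(all(cc$w >= 1 - 1e-9))
})

test_that("mass balance admits nonzero flux and required routes are feasible", {
  net <- toy_net()
  S <- stoich_matrix(net)
  lb <- net$reactions$lb; ub <- net$reactions$ub
  ub[net$reactions$id == "EX_PHOTON"] <- 250
  ub[net$reactions$id == "CO2_UPTAKE"] <- 15
  solve_fba <- function(lb, ub, obj = NULL) {
    if (is.null(obj)) obj <- numeric(ncol(S))
    solve_program(obj, S, numeric(nrow(S)), sense = rep("=", nrow(S)),
                  lb = lb, ub = ub, maximize = TRUE)
  }
  ## phloem export achievable: S v = 0 has nonzero feasible v
  obj <- as.numeric(net$reactions$id == "PHLOEM")
  r <- solve_fba(lb, ub, obj)
  expect_equal(r$status, "optimal")
  expect_gt(r$objval, 1)
  ## the nocturnal fixation cycle (PEPC -> OAA -> Asp/2OG -> carboxylating
  ## mitochondrial ICDH -> (iso)citrate; Pro cycle feeding 2OG) can carry flux
  lb2 <- lb; ub2 <- ub
  lb2[net$reactions$id == "PEPC"] <- 0.1
  ub2[net$reactions$id == "ICDH_M"] <- -0.1   # reverse = carboxylating
  lb2[net$reactions$id == "PRODH"] <- 0.1
  lb2[net$reactions$id == "P5CS"] <- 0.1
  ## Asn synthesis kept below what phloem export can drain in a snapshot
  lb2[net$reactions$id == "ASN_SYN"] <- 0.02
  expect_equal(solve_fba(lb2, ub2)$status, "optimal")
  ## ... and the daytime decarboxylation leg ((iso)citrate -> 2OG + CO2 via
  ## cytosolic ICDH, 2OG -> Pro) separately: the two legs run at different
  ## times of day and are joined by the vacuole in the diel model
  lb3 <- lb; ub3 <- ub
  lb3[net$reactions$id == "ICDH_C"] <- 0.1
  lb3[net$reactions$id == "P5CS"] <- 0.1
  lb3[net$reactions$id == "P5CR"] <- 0.1
  expect_equal(solve_fba(lb3, ub3)$status, "optimal")
  ## no light, no export
  ub3 <- ub; ub3[net$reactions$id == "EX_PHOTON"] <- 0
  expect_lt(solve_fba(lb, ub3, obj)$objval, 1e-6)
})

test_that("network options control ICDH reversibility and flag contradictions", {
  net <- toy_net()
  expect_lt(net$reactions$lb[net$reactions$id == "ICDH_M"], 0)
  net_ir <- toy_net_irrev()
  expect_equal(net_ir$reactions$lb[net_ir$reactions$id == "ICDH_M"], 0)
  expect_error(build_toy_core(icdh_reversible = FALSE, mitochondria = FALSE),
               "configuration error")
  nomito <- build_toy_core(mitochondria = FALSE)
  expect_false(any(grepl("_m$", nomito$metabolites$id)))
  expect_error(build_toy_core(phloem_sucrose_fraction = 1.2))
})

test_that("container constructors validate their invariants", {
  mets <- data.frame(id = c("A_c", "B_c"), name = c("A", "B"),
                     compartment = "cytosol")
  rx <- data.frame(id = "R1", name = "R1", lb = 0, ub = 10)
  st <- data.frame(reaction = "R1", metabolite = c("A_c", "B_c"),
                   coef = c(-1, 1))
  net <- metabolic_network(mets, rx, st)
  expect_equal(dim(stoich_matrix(net)), c(2, 1))
  expect_error(metabolic_network(mets[c(1, 1), ], rx, st), "duplicate")
  expect_error(metabolic_network(mets, rx,
                                 data.frame(reaction = "R1",
                                            metabolite = "Z_c", coef = 1)),
               "unknown metabolites")
  rx_bad <- rx; rx_bad$lb <- 20
  expect_error(metabolic_network(mets, rx_bad, st), "lb > ub")
  mets_bad <- mets; mets_bad$compartment <- "nucleus"
  expect_error(metabolic_network(mets_bad, rx, st), "compartment")
  ## is_co2_species implies carries_carbon
  mets2 <- mets; mets2$is_co2_species <- c(TRUE, FALSE)
  mets2$carries_carbon <- FALSE
  expect_error(metabolic_network(mets2, rx, st), "carries_carbon")
})
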