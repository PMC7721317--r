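## Named model variants (ICDH reversibility, vacuolar anatomy), environment
## grid scans and water-saving metrics.

#' Scenario configuration
#'
#' Describes one named model variant: the reversibility mode of
#' mitochondrial ICDH, whether daytime vacuolar (iso)citrate import is
#' blocked (the `Cit_night` variant, only meaningful on top of irreversible
#' ICDH), the vacuolar anatomy (C3, CAM = 3.1 x C3, or unlimited), and the
#' required productivity as a fraction of the maximum phloem output.
#'
#' @param icdh_mode `"reversible"` (mitochondrial ICDH may carboxylate
#'   2-oxoglutarate) or `"irreversible"` (conventional forward direction
#'   only).
#' @param cit_night_only block vacuolar (iso)citrate import during daylight
#'   steps; requires `icdh_mode = "irreversible"` to reproduce the named
#'   variant.
#' @param vacuole_mode `"C3"`, `"CAM"` or `"unlimited"`.
#' @param productivity_fraction percent of the maximum phloem output that
#'   must be sustained (default 80).
#' @param env an [diel_environment()] profile.
#' @param gas a [gas_exchange_params()].
#' @param constraints a [diel_constraints()] set.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(icdh_mode = c("reversible", "irreversible"),
                            cit_night_only = FALSE,
                            vacuole_mode = c("CAM", "C3", "unlimited"),
                            productivity_fraction = 80,
                            env = diel_environment(),
                            gas = gas_exchange_params(),
                            constraints = diel_constraints()) {
  icdh_mode <- match.arg(icdh_mode)
  vacuole_mode <- match.arg(vacuole_mode)
  if (cit_night_only && icdh_mode != "irreversible")
    stop("cit_night_only reproduces the ICDH_irrev,Cit_night variant and ",
         "requires icdh_mode = 'irreversible'")
  stopifnot(productivity_fraction > 0, productivity_fraction <= 100)
  structure(list(icdh_mode = icdh_mode, cit_night_only = cit_night_only,
                 vacuole_mode = vacuole_mode,
                 productivity_fraction = productivity_fraction,
                 env = env, gas = gas, constraints = constraints),
            class = "scenario_config")
}

scenario_capacity <- function(cs, vacuole_mode) {
  switch(vacuole_mode,
         C3 = cs$vacuole_capacity_c3,
         CAM = cs$vacuole_capacity_c3 * cs$cam_capacity_factor,
         unlimited = Inf)
}

## Build the diel model for a scenario, applying ICDH and citrate bounds.
scenario_model <- function(cfg, net) {
  icdh_id <- find_tag(net, "ICDH_M")
  if (cfg$icdh_mode == "irreversible")
    net$reactions$lb[net$reactions$id == icdh_id] <-
      pmax(net$reactions$lb[net$reactions$id == icdh_id], 0)
  model <- expand_diel(net, cfg$env, cfg$constraints)
  model <- apply_vacuole_capacity(model,
                                  scenario_capacity(cfg$constraints,
                                                    cfg$vacuole_mode))
  model <- couple_water_loss(model, cfg$gas)
  if (cfg$cit_night_only) {
    ## forward transporter flux is vacuolar import; forbid it by day
    vt <- intersect(find_tag(net, "VACUOLAR_TRANSPORT", several = TRUE),
                    net$stoichiometry$reaction[net$stoichiometry$metabolite
                                               %in% c("CIT_v", "ICIT_v")])
    if (!length(vt))
      stop("configuration error: no vacuolar (iso)citrate transporter found")
    day <- cfg$env$is_day
    hit <- model$vars$kind == "rxn" & model$vars$id %in% vt &
      day[model$vars$step]
    model$vars$ub[hit] <- pmin(model$vars$ub[hit], 0)
  }
  model
}

#' Run a named scenario
#'
#' Builds the diel model for the scenario and solves the lexicographic
#' stack: the maximum phloem output is computed first, then water loss is
#' minimized at `productivity_fraction` percent of it, then the quadratic
#' flux sum is minimized at the pinned objectives.
#'
#' @param cfg a [scenario_config()].
#' @param net a [metabolic_network()]; default [build_toy_core()].
#' @param max_phloem optionally, a precomputed maximum phloem output in
#'   mol m-2 day-1 (avoids re-solving the reference when scanning).
#' @return a [diel_solution()]; the model is in `$model` and the maximum
#'   output used for the floor in `attr(, "max_phloem")`.
#' @export
run_scenario <- function(cfg, net = build_toy_core(), max_phloem = NULL) {
  model <- scenario_model(cfg, net)
  if (is.null(max_phloem))
    max_phloem <- maximize_phloem(model, minimize_flux_after = FALSE)$phloem_output
  sol <- minimize_water(model, cfg$productivity_fraction / 100 * max_phloem)
  attr(sol, "max_phloem") <- max_phloem
  sol
}

#' Environment grid scan of CAM water saving
#'
#' For every cell of a (T_max, RH_min) grid crossed with light-intensity /
#' photoperiod combinations, solves three models under the same
#' environment: the C3-anatomy reference at 100% productivity, and the
#' CAM-anatomy variants with reversible and irreversible mitochondrial
#' ICDH at `fraction` percent productivity. Reports, per cell, the water
#' saving of the reversible-ICDH CAM leaf with respect to the C3 reference
#' and the absolute and relative water-saving contribution of ICDH (the
#' difference between the irreversible and reversible variants). Nighttime
#' extremes co-vary with the daytime ones: `T_min = T_max - 10`,
#' `RH_max = min(1, RH_min + 0.4)`.
#'
#' @param net a [metabolic_network()].
#' @param t_max_grid,rh_min_grid numeric grids of daily extremes.
#' @param light_grid data.frame with columns `i_max`, `daylength`; default
#'   the single reference regime (250 umol m-2 s-1, 12 h).
#' @param fraction productivity fraction (percent) for the CAM variants.
#' @param constraints a [diel_constraints()] set.
#' @param gas a [gas_exchange_params()].
#' @param n_steps time resolution of each cell's model.
#' @return data.frame with one row per grid cell: the environment
#'   parameters, `water_c3_100`, `water_rev`, `water_irrev`, `saving_abs`,
#'   `saving_rel_pct`, `icdh_abs`, `icdh_rel_pct`, `status`.
#' @export
environment_grid <- function(net, t_max_grid = c(20, 30, 40),
                             rh_min_grid = c(0.4, 0.7),
                             light_grid = data.frame(i_max = 250,
                                                     daylength = 12),
                             fraction = 80,
                             constraints = diel_constraints(),
                             gas = gas_exchange_params(),
                             n_steps = 24) {
  stopifnot(length(t_max_grid) > 0, length(rh_min_grid) > 0)
  net_ir <- net
  icdh_id <- find_tag(net, "ICDH_M")
  net_ir$reactions$lb[net_ir$reactions$id == icdh_id] <-
    pmax(net_ir$reactions$lb[net_ir$reactions$id == icdh_id], 0)
  cells <- expand.grid(t_max = t_max_grid, rh_min = rh_min_grid,
                       light = seq_len(nrow(light_grid)))
  rows <- lapply(seq_len(nrow(cells)), function(k) {
    tmax <- cells$t_max[k]; rhmin <- cells$rh_min[k]
    lg <- light_grid[cells$light[k], ]
    out <- data.frame(t_max = tmax, rh_min = rhmin, i_max = lg$i_max,
                      daylength = lg$daylength, water_c3_100 = NA_real_,
                      water_rev = NA_real_, water_irrev = NA_real_,
                      saving_abs = NA_real_, saving_rel_pct = NA_real_,
                      icdh_abs = NA_real_, icdh_rel_pct = NA_real_,
                      status = "optimal")
    res <- tryCatch({
      env <- diel_environment(n_steps = n_steps, t_min = tmax - 10,
                              t_max = tmax, rh_min = rhmin,
                              rh_max = min(1, rhmin + 0.4),
                              i_max = lg$i_max, daylength = lg$daylength)
      c3 <- couple_water_loss(apply_vacuole_capacity(
        expand_diel(net, env, constraints),
        scenario_capacity(constraints, "C3")), gas)
      pstar <- maximize_phloem(c3, minimize_flux_after = FALSE)$phloem_output
      w_c3 <- minimize_water(c3, pstar,
                             minimize_flux_after = FALSE)$water_total
      cam_capacity <- scenario_capacity(constraints, "CAM")
      solve_variant <- function(nn) {
        m <- couple_water_loss(apply_vacuole_capacity(
          expand_diel(nn, env, constraints), cam_capacity), gas)
        minimize_water(m, fraction / 100 * pstar,
                       minimize_flux_after = FALSE)$water_total
      }
      w_rev <- solve_variant(net)
      w_irrev <- solve_variant(net_ir)
      list(w_c3 = w_c3, w_rev = w_rev, w_irrev = w_irrev)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$status <- conditionMessage(res)
      return(out)
    }
    out$water_c3_100 <- res$w_c3
    out$water_rev <- res$w_rev
    out$water_irrev <- res$w_irrev
    out$saving_abs <- res$w_c3 - res$w_rev
    out$saving_rel_pct <- 100 * out$saving_abs / res$w_c3
    out$icdh_abs <- res$w_irrev - res$w_rev
    out$icdh_rel_pct <- 100 * out$icdh_abs / res$w_c3
    out
  })
  do.call(rbind, rows)
}

#' Sensitivity of water loss to the internal CO2 concentration
#'
#' Re-solves the water-minimal solution at a fixed productivity fraction
#' for a list of internal:atmospheric CO2 ratios. A larger ratio leaves a
#' smaller CO2 gradient across the stomata, so every mole of CO2 costs
#' more water (the cost scales as `1 / (1 - ci_ratio)`), and the minimal
#' total water loss increases monotonically.
#'
#' @param net a [metabolic_network()].
#' @param ci_ratios internal:atmospheric CO2 ratios, each strictly in
#'   (0, 1).
#' @param fraction productivity fraction (percent).
#' @param env an [diel_environment()].
#' @param constraints a [diel_constraints()].
#' @param vacuole_mode vacuolar anatomy of the solved variant.
#' @return data.frame with columns `ci_ratio`, `water_total`,
#'   `phloem_output`, `status`.
#' @export
ci_sensitivity <- function(net, ci_ratios = c(0.5, 0.7, 0.9), fraction = 80,
                           env = diel_environment(),
                           constraints = diel_constraints(),
                           vacuole_mode = "CAM") {
  if (any(ci_ratios <= 0 | ci_ratios >= 1))
    stop("ci_ratios must lie strictly between 0 and 1")
  capacity <- scenario_capacity(constraints, vacuole_mode)
  base <- apply_vacuole_capacity(expand_diel(net, env, constraints), capacity)
  rows <- lapply(ci_ratios, function(ci) {
    res <- tryCatch({
      m <- couple_water_loss(base, gas_exchange_params(ci_ratio = ci))
      pstar <- maximize_phloem(m, minimize_flux_after = FALSE)$phloem_output
      minimize_water(m, fraction / 100 * pstar, minimize_flux_after = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error"))
      data.frame(ci_ratio = ci, water_total = NA, phloem_output = NA,
                 status = conditionMessage(res))
    else data.frame(ci_ratio = ci, water_total = res$water_total,
                    phloem_output = res$phloem_output, status = res$status)
  })
  do.call(rbind, rows)
}
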