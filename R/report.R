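## Diagnostic summaries of diel solutions: CO2 and ATP budgets, storage
## (linker) profiles, CAM phase detection, and file input/output.

## per-step signed contribution of every reaction to a set of species
species_contributions <- function(sol, species_ids) {
  net <- sol$model$net
  st <- net$stoichiometry[net$stoichiometry$metabolite %in% species_ids, ]
  if (!nrow(st)) return(NULL)
  coef <- tapply(st$coef, st$reaction, sum)
  rids <- names(coef)
  contrib <- sol$fluxes[rids, , drop = FALSE] * as.numeric(coef)
  contrib
}

#' CO2 budget of a diel solution
#'
#' Signed per-step contribution of every reaction that produces or consumes
#' a CO2 or bicarbonate species (positive = releases CO2, negative = fixes
#' it), restricted to reactions whose contribution exceeds `threshold` at
#' one or more steps. Because every CO2 species is balanced at every step,
#' the contributions of all reactions (including uptake and efflux) sum to
#' zero at each step.
#'
#' @param sol a [diel_solution()].
#' @param threshold significance threshold in umol m-2 s-1.
#' @return object of class `flux_budget`: list with `species = "CO2"`,
#'   `contributions` (matrix reactions x steps, filtered), `daily` (named
#'   cumulative daily totals in mol m-2 over the filtered reactions) and
#'   `turnover` (total production summed over reactions and steps, in
#'   umol m-2 s-1).
#' @export
co2_budget <- function(sol, threshold = 0.5) {
  ids <- sol$model$net$metabolites$id[sol$model$net$metabolites$is_co2_species]
  budget_for(sol, ids, "CO2", threshold)
}

#' ATP budget of a diel solution
#'
#' As [co2_budget()], for ATP species in every compartment. The reported
#' `turnover` is the total ATP production summed over all reactions and
#' time points, in umol m-2 s-1; production equals consumption because ATP
#' is balanced at every step.
#'
#' @param sol a [diel_solution()].
#' @param threshold significance threshold in umol m-2 s-1.
#' @return a `flux_budget`.
#' @export
atp_budget <- function(sol, threshold = 0.5) {
  mets <- sol$model$net$metabolites
  ids <- mets$id[mets$name == "ATP" | grepl("^ATP_", mets$id)]
  budget_for(sol, ids, "ATP", threshold)
}

budget_for <- function(sol, species_ids, species, threshold) {
  contrib <- species_contributions(sol, species_ids)
  if (is.null(contrib))
    stop("no reactions touch any ", species, " species")
  keep <- apply(abs(contrib), 1, max) > threshold
  daily <- rowSums(contrib) * flux_to_daily(sol$model)
  structure(list(species = species,
                 contributions = contrib[keep, , drop = FALSE],
                 daily = daily[keep],
                 turnover = sum(pmax(contrib, 0)),
                 balance = max(abs(colSums(contrib))),
                 threshold = threshold),
            class = "flux_budget")
}

#' @export
print.flux_budget <- function(x, ...) {
  cat("<flux_budget> ", x$species, ": ", nrow(x$contributions),
      " reactions above ", x$threshold, " umol m-2 s-1\n", sep = "")
  cat("  total turnover:", round(x$turnover, 1), "umol m-2 s-1;",
      "per-step balance residual:", format(x$balance, digits = 3), "\n")
  ord <- order(-abs(x$daily))
  for (i in utils::head(ord, 10))
    cat(sprintf("  %-14s daily %+8.4f mol m-2\n",
                names(x$daily)[i], x$daily[i]))
  invisible(x)
}

#' Stored amounts per storable per step
#'
#' Converts linker fluxes to stored amounts: a linker flux of 1 umol m-2
#' s-1 sustained over a 1-h interval carries 3.6 mmol m-2 into the next
#' interval. Storables whose peak stored amount exceeds `threshold_flux`
#' (in flux units, the same significance convention as the budgets) are
#' flagged.
#'
#' @param sol a [diel_solution()].
#' @param threshold_flux significance threshold in umol m-2 s-1.
#' @return data.frame with columns `storable`, `step`, `amount_mmol`
#'   (carried from `step` into the next), and attribute `flagged` (names
#'   of significant storables).
#' @export
linker_profiles <- function(sol, threshold_flux = 0.5) {
  L <- sol$linkers
  amount <- L * sol$model$step_hours * 3.6   # umol/s over step -> mmol m-2
  flagged <- rownames(L)[apply(L, 1, max) > threshold_flux]
  out <- data.frame(storable = rep(rownames(L), ncol(L)),
                    step = rep(seq_len(ncol(L)), each = nrow(L)),
                    amount_mmol = as.numeric(amount))
  attr(out, "flagged") <- flagged
  out
}

#' Classify the diel CO2-uptake pattern into CAM phases
#'
#' Phase I: net CO2 uptake during the dark period (nocturnal fixation).
#' Phase II: daylight uptake contiguous with dawn. Phase III: daylight
#' steps with closed stomata (no uptake). Phase IV: daylight uptake
#' contiguous with dusk. Isolated daylight uptake islands are assigned II
#' before solar noon and IV after. A pure C3 day has II and IV spanning
#' the whole photoperiod and no III.
#'
#' @param sol a [diel_solution()].
#' @param tol uptake below this flux (umol m-2 s-1) counts as closed
#'   stomata.
#' @return character vector, one label (`"I"`, `"II"`, `"III"`, `"IV"`,
#'   or `"dark"` for night steps without uptake) per step.
#' @export
detect_phases <- function(sol, tol = 1e-3) {
  env <- sol$model$env
  up <- sol$fluxes[sol$model$tags["CO2_UPTAKE"], ]
  N <- length(up)
  open <- up > tol
  day <- env$is_day
  phase <- rep("dark", N)
  phase[!day & open] <- "I"
  phase[day & !open] <- "III"
  if (any(day)) {
    dsteps <- which(day)
    dawn <- dsteps[1]; dusk <- dsteps[length(dsteps)]
    noon <- mean(env$hour[dsteps])
    for (t in dsteps[open[dsteps]]) {
      from_dawn <- all(open[dawn:t])
      to_dusk <- all(open[t:dusk])
      phase[t] <- if (from_dawn && !to_dusk) "II"
      else if (to_dusk && !from_dawn) "IV"
      else if (from_dawn && to_dusk) {
        if (env$hour[t] <= noon) "II" else "IV"
      } else if (env$hour[t] <= noon) "II" else "IV"
    }
  }
  phase
}

#' Write a diel solution to plain-text files
#'
#' Writes the flux table (`<stem>_fluxes.tsv`: reaction_id, step, flux),
#' the linker table (`<stem>_linkers.tsv`), the environment profile
#' (`<stem>_profile.csv`) and a summary JSON (`<stem>_summary.json`) with
#' the daily totals and solver status.
#'
#' @param sol a [diel_solution()].
#' @param stem file path stem.
#' @return invisibly, the paths written.
#' @export
write_solution <- function(sol, stem) {
  fl <- data.frame(reaction_id = rep(rownames(sol$fluxes), ncol(sol$fluxes)),
                   step = rep(seq_len(ncol(sol$fluxes)),
                              each = nrow(sol$fluxes)),
                   flux = as.numeric(sol$fluxes))
  lk <- data.frame(storable = rep(rownames(sol$linkers), ncol(sol$linkers)),
                   step = rep(seq_len(ncol(sol$linkers)),
                              each = nrow(sol$linkers)),
                   flux = as.numeric(sol$linkers))
  env <- as.data.frame(sol$model$env)
  paths <- paste0(stem, c("_fluxes.tsv", "_linkers.tsv", "_profile.csv",
                          "_summary.json"))
  utils::write.table(fl, paths[1], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(lk, paths[2], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.csv(env, paths[3], row.names = FALSE)
  summary <- list(status = sol$status, phloem_output = sol$phloem_output,
                  co2_total = sol$co2_total, water_total = sol$water_total,
                  flux_sum_l1 = sol$flux_sum_l1,
                  step_hours = sol$model$step_hours,
                  gas = sol$model$gas[c("c_atm", "ci_ratio", "diff_ratio",
                                        "pressure")])
  jsonlite::write_json(summary, paths[4], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}

#' Recompute the daily water loss from serialized outputs
#'
#' Independent check of serialization fidelity: reads the flux TSV and
#' profile CSV written by [write_solution()] and recomputes the total
#' transpirational water loss from scratch.
#'
#' @param stem the file stem passed to [write_solution()].
#' @param gas a [gas_exchange_params()] (must match the solved model).
#' @return water loss in mol m-2 day-1.
#' @export
water_from_files <- function(stem, gas = gas_exchange_params()) {
  fl <- utils::read.delim(paste0(stem, "_fluxes.tsv"))
  prof <- utils::read.csv(paste0(stem, "_profile.csv"))
  up <- fl[fl$reaction_id == fl$reaction_id[grep("CO2_UPTAKE",
                                                 fl$reaction_id)[1]], ]
  up <- up[order(up$step), "flux"]
  r <- water_per_co2(prof$T, prof$RH, gas)
  step_seconds <- 24 / nrow(prof) * 3600
  sum(r * pmax(up, 0) * step_seconds) * 1e-6
}
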