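## Diel assembly: concatenate N copies of a network into a closed 24-h
## cycle with storage linker reactions and per-step constraints.

#' Diel constraint set
#'
#' Collects every per-step constraint applied when a network is expanded
#' over the diel cycle.
#'
#' @param phloem_day_night_ratio per-hour phloem export rate, day over
#'   night (3:1).
#' @param nitrate_day_night_ratio per-hour nitrate uptake rate, day over
#'   night (3:2).
#' @param maintenance_day_night_ratio maintenance cost, day over night (3:1).
#' @param maintenance_atp_nadph_ratio ATP over NADPH maintenance cost (3:1).
#' @param rubisco_carb_oxy_ratio Rubisco carboxylation over oxygenation,
#'   held fixed at every daylight step (3:1).
#' @param co2_uptake_max upper bound on CO2 uptake at any step, in
#'   umol m-2 s-1.
#' @param vacuole_capacity_c3 total vacuolar storage capacity of a C3 leaf
#'   in mol m-2 (total solutes carried between consecutive steps; starch in
#'   the plastid is not counted).
#' @param cam_capacity_factor CAM leaf anatomy multiplies the C3 capacity
#'   by this factor (3.1).
#' @param maintenance_k daytime ATP maintenance cost per unit mean daytime
#'   light intensity (umol ATP per umol photons).
#' @param light_compensation light-compensation point in umol m-2 s-1.
#' @param flux_cap absolute cap applied to all per-step reaction bounds, in
#'   umol m-2 s-1; `NULL` derives it from the light curve
#'   (`max(200, 1.5 * max(I))`). Keeps the solve well-scaled without
#'   constraining any physically reachable flux.
#' @param storable_weights optional named vector of per-metabolite weights
#'   for the vacuolar capacity count (mol capacity consumed per mol
#'   stored); default 1 for every storable.
#' @param count_nitrate should vacuolar nitrate count against the storage
#'   capacity? Default `TRUE`.
#' @return object of class `diel_constraints`.
#' @export
diel_constraints <- function(phloem_day_night_ratio = 3,
                             nitrate_day_night_ratio = 1.5,
                             maintenance_day_night_ratio = 3,
                             maintenance_atp_nadph_ratio = 3,
                             rubisco_carb_oxy_ratio = 3,
                             co2_uptake_max = 15,
                             vacuole_capacity_c3 = 0.03,
                             cam_capacity_factor = 3.1,
                             maintenance_k = 0.02,
                             light_compensation = 30,
                             flux_cap = NULL,
                             storable_weights = NULL,
                             count_nitrate = TRUE) {
  ratios <- c(phloem_day_night_ratio, nitrate_day_night_ratio,
              maintenance_day_night_ratio, maintenance_atp_nadph_ratio,
              rubisco_carb_oxy_ratio)
  if (any(ratios <= 0)) stop("all day:night and ATP:NADPH ratios must be positive")
  if (vacuole_capacity_c3 < 0) stop("vacuole capacity must be >= 0 (or Inf)")
  structure(list(phloem_day_night_ratio = phloem_day_night_ratio,
                 nitrate_day_night_ratio = nitrate_day_night_ratio,
                 maintenance_day_night_ratio = maintenance_day_night_ratio,
                 maintenance_atp_nadph_ratio = maintenance_atp_nadph_ratio,
                 rubisco_carb_oxy_ratio = rubisco_carb_oxy_ratio,
                 co2_uptake_max = co2_uptake_max,
                 vacuole_capacity_c3 = vacuole_capacity_c3,
                 cam_capacity_factor = cam_capacity_factor,
                 maintenance_k = maintenance_k,
                 light_compensation = light_compensation,
                 flux_cap = flux_cap,
                 storable_weights = storable_weights,
                 count_nitrate = count_nitrate),
            class = "diel_constraints")
}

#' Expand a network into a cyclic diel model
#'
#' Concatenates `nrow(env)` copies of the network, one per time interval,
#' joined by nonnegative linker reactions that carry each storable
#' metabolite from one interval to the next; the last interval feeds the
#' first, closing the cycle. Applies the per-step constraints: light uptake
#' bounded by the light curve; Rubisco active only in daylight, with
#' carboxylation:oxygenation fixed at 3:1; phloem export per hour equal
#' within day and within night and in a 3:1 day:night ratio; nitrate uptake
#' likewise at 3:2; ATP and NADPH maintenance fixed per step (daytime value
#' proportional to mean daytime light, day:night 3:1, ATP:NADPH 3:1); CO2
#' uptake capped at every step.
#'
#' @param net a [metabolic_network()] whose required role tags resolve.
#' @param env an [diel_environment()] profile.
#' @param cs a [diel_constraints()] set.
#' @return object of class `diel_model`.
#' @export
expand_diel <- function(net, env, cs = diel_constraints()) {
  tags <- check_required_tags(net)
  N <- nrow(env)
  step_hours <- attr(env, "step_hours")
  R <- nrow(net$reactions)
  stor <- net$storables
  Ns <- nrow(stor)
  day <- which(env$is_day); night <- which(!env$is_day)

  ## ---- variables: N*R step reactions then N*Ns linkers ----
  rid <- net$reactions$id
  vars <- data.frame(
    kind = c(rep("rxn", N * R), rep("linker", N * Ns)),
    id = c(rep(rid, N), rep(stor$metabolite, N)),
    step = c(rep(seq_len(N), each = R), rep(seq_len(N), each = Ns)))
  vidx_rxn <- function(id, t) (t - 1) * R + match(id, rid)
  vidx_lnk <- function(s, t) N * R + (t - 1) * Ns + s

  ## per-step bounds
  lbm <- matrix(rep(net$reactions$lb, N), nrow = R)
  ubm <- matrix(rep(net$reactions$ub, N), nrow = R)
  cap <- cs$flux_cap %||% max(200, 1.5 * max(env$I))
  lbm <- pmax(lbm, -cap); ubm <- pmin(ubm, cap)
  i_light <- match(tags["LIGHT_UPTAKE"], rid)
  ubm[i_light, ] <- pmin(ubm[i_light, ], env$I)
  i_carb <- match(tags["RUBISCO_CARB"], rid)
  i_oxy <- match(tags["RUBISCO_OXY"], rid)
  lbm[c(i_carb, i_oxy), night] <- 0
  ubm[c(i_carb, i_oxy), night] <- 0
  i_up <- match(tags["CO2_UPTAKE"], rid)
  ubm[i_up, ] <- pmin(ubm[i_up, ], cs$co2_uptake_max)
  ## maintenance: fixed per step
  m_day <- if (length(day)) cs$maintenance_k * mean(env$I[day]) else 0
  m_night <- m_day / cs$maintenance_day_night_ratio
  m_atp <- ifelse(env$is_day, m_day, m_night)
  i_matp <- match(tags["ATP_MAINT"], rid)
  i_mnad <- match(tags["NADPH_MAINT"], rid)
  lbm[i_matp, ] <- ubm[i_matp, ] <- m_atp
  lbm[i_mnad, ] <- ubm[i_mnad, ] <- m_atp / cs$maintenance_atp_nadph_ratio
  vars$lb <- c(as.numeric(lbm), rep(0, N * Ns))
  vars$ub <- c(as.numeric(ubm), rep(cap, N * Ns))

  ## ---- balance rows: every metabolite, every step ----
  S <- stoich_matrix(net)
  tri0 <- Matrix::summary(methods::as(S, "TsparseMatrix"))
  M <- nrow(S)
  row_of <- function(mi, t) (t - 1) * M + mi    # balance row index
  bi <- rep(tri0$i, N) + M * rep(seq_len(N) - 1, each = nrow(tri0))
  bj <- rep(tri0$j, N) + R * rep(seq_len(N) - 1, each = nrow(tri0))
  bx <- rep(tri0$x, N)
  ## linker terms: storable s consumed at step t, produced at step t+1
  smi <- match(stor$metabolite, net$metabolites$id)
  ts <- rep(seq_len(N), each = Ns)
  ss <- rep(seq_len(Ns), N)
  lcols <- vidx_lnk(ss, ts)
  tnext <- ts %% N + 1
  bi <- c(bi, row_of(smi[ss], ts), row_of(smi[ss], tnext))
  bj <- c(bj, lcols, lcols)
  bx <- c(bx, rep(-1, N * Ns), rep(1, N * Ns))
  n_balance <- M * N
  rhs <- numeric(n_balance)
  sense <- rep("=", n_balance)
  row_kind <- rep("balance", n_balance)

  add_rows <- function(env_, entries, rhs_, sense_, kind_) {
    ## entries: list of data.frame(row_offset, col, x)
    n_new <- length(rhs_)
    base <- length(env_$rhs)
    env_$bi <- c(env_$bi, base + entries$row)
    env_$bj <- c(env_$bj, entries$col)
    env_$bx <- c(env_$bx, entries$x)
    env_$rhs <- c(env_$rhs, rhs_)
    env_$sense <- c(env_$sense, sense_)
    env_$row_kind <- c(env_$row_kind, rep(kind_, n_new))
    env_
  }
  acc <- list(bi = bi, bj = bj, bx = bx, rhs = rhs, sense = sense,
              row_kind = row_kind)

  ## rubisco carboxylase = ratio * oxygenase, every daylight step
  if (length(day)) {
    ent <- data.frame(row = rep(seq_along(day), 2),
                      col = c(vidx_rxn(tags["RUBISCO_CARB"], day),
                              vidx_rxn(tags["RUBISCO_OXY"], day)),
                      x = c(rep(1, length(day)),
                            rep(-cs$rubisco_carb_oxy_ratio, length(day))))
    acc <- add_rows(acc, ent, numeric(length(day)), rep("=", length(day)),
                    "rubisco_ratio")
  }

  ## day/night equality couplings for phloem export and nitrate uptake
  couple <- function(acc, rx, ratio, kind) {
    ent_row <- 0L; rows <- list()
    add <- function(c1, c2, x2) {
      ent_row <<- ent_row + 1L
      data.frame(row = c(ent_row, ent_row), col = c(c1, c2), x = c(1, x2))
    }
    if (length(day) > 1)
      for (t in day[-1]) rows <- c(rows, list(add(vidx_rxn(rx, t), vidx_rxn(rx, day[1]), -1)))
    if (length(night) > 1)
      for (t in night[-1]) rows <- c(rows, list(add(vidx_rxn(rx, t), vidx_rxn(rx, night[1]), -1)))
    if (length(day) && length(night))
      rows <- c(rows, list(add(vidx_rxn(rx, day[1]), vidx_rxn(rx, night[1]), -ratio)))
    if (!length(rows)) return(acc)
    ent <- do.call(rbind, rows)
    add_rows(acc, ent, numeric(ent_row), rep("=", ent_row), kind)
  }
  acc <- couple(acc, tags["PHLOEM_EXPORT"], cs$phloem_day_night_ratio,
                "phloem_couple")
  acc <- couple(acc, tags["NITRATE_UPTAKE"], cs$nitrate_day_night_ratio,
                "nitrate_couple")

  structure(list(net = net, env = env, cs = cs, tags = tags,
                 n_steps = N, step_hours = step_hours,
                 vars = vars, tri = list(i = acc$bi, j = acc$bj, x = acc$bx),
                 rhs = acc$rhs, sense = acc$sense, row_kind = acc$row_kind,
                 flux_cap = cap, gas = NULL,
                 vacuole_capacity = Inf),
            class = "diel_model")
}

#' @export
print.diel_model <- function(x, ...) {
  cat("<diel_model> ", x$n_steps, " steps x ", nrow(x$net$reactions),
      " reactions + ", sum(x$vars$kind == "linker"), " linkers; ",
      length(x$rhs), " constraint rows\n", sep = "")
  cat("  vacuole capacity:", x$vacuole_capacity, "mol m-2;",
      "water loss", if (is.null(x$gas)) "not" else "", "coupled\n")
  invisible(x)
}

## column indices of per-step copies of one reaction
rxn_cols <- function(model, id) {
  which(model$vars$kind == "rxn" & model$vars$id == id)
}

#' Apply a vacuolar storage capacity
#'
#' Adds, for every step, the constraint that the total amount of vacuolar
#' solutes carried into the step (linker flux times interval length, in
#' mol m-2) does not exceed `capacity`. Starch, stored in the plastid,
#' accumulates freely and is not counted. `capacity = Inf` removes the
#' constraint (the unlimited-vacuole variant); `capacity = 0` forbids all
#' vacuolar carry-over while leaving starch linkers untouched.
#'
#' @param model a [expand_diel()] model.
#' @param capacity vacuolar storage capacity in mol m-2, or `Inf`.
#' @return the model with capacity rows added.
#' @export
apply_vacuole_capacity <- function(model, capacity) {
  if (length(capacity) != 1 || is.na(capacity) || capacity < 0)
    stop("capacity must be a single nonnegative number (or Inf)")
  model$vacuole_capacity <- capacity
  if (!is.finite(capacity)) return(model)
  stor <- model$net$storables
  vac <- which(stor$compartment == "vacuole")
  if (!model$cs$count_nitrate)
    vac <- setdiff(vac, which(stor$metabolite ==
      model$net$metabolites$id[match("NO3_v", model$net$metabolites$id)]))
  wts <- rep(1, nrow(stor))
  if (!is.null(model$cs$storable_weights)) {
    hit <- match(names(model$cs$storable_weights), stor$metabolite)
    wts[hit[!is.na(hit)]] <- model$cs$storable_weights[!is.na(hit)]
  }
  N <- model$n_steps; Ns <- nrow(stor)
  amount_per_flux <- model$step_hours * 3600 * 1e-6  # umol/s over a step -> mol
  base <- length(model$rhs)
  ## row t: sum over vacuolar storables of linker flux out of step t-1
  prev <- function(t) (t - 2) %% N + 1
  for (t in seq_len(N)) {
    cols <- nrow(model$net$reactions) * N + (prev(t) - 1) * Ns + vac
    model$tri$i <- c(model$tri$i, rep(base + t, length(vac)))
    model$tri$j <- c(model$tri$j, cols)
    model$tri$x <- c(model$tri$x, wts[vac] * amount_per_flux)
  }
  model$rhs <- c(model$rhs, rep(capacity, N))
  model$sense <- c(model$sense, rep("<=", N))
  model$row_kind <- c(model$row_kind, rep("vacuole_cap", N))
  model
}

#' Couple transpirational water loss to CO2 uptake
#'
#' Adds one auxiliary variable per step, constrained equal to
#' `water_per_co2(T_t, RH_t) * co2_uptake_t`, and a total-water variable
#' equal to their time-weighted sum in mol m-2 day-1; both are then usable
#' as objective terms.
#'
#' @param model a [expand_diel()] model.
#' @param gas a [gas_exchange_params()].
#' @return the model with water variables and defining rows added.
#' @export
couple_water_loss <- function(model, gas = gas_exchange_params()) {
  N <- model$n_steps
  r <- water_per_co2(model$env$T, model$env$RH, gas)
  up <- rxn_cols(model, model$tags["CO2_UPTAKE"])
  stopifnot(length(up) == N)
  n0 <- nrow(model$vars)
  wmax <- max(r) * max(model$vars$ub[up]) * 1.01
  model$vars <- rbind(model$vars,
    data.frame(kind = "water", id = "water", step = seq_len(N),
               lb = 0, ub = wmax),
    data.frame(kind = "water_total", id = "water_total", step = NA,
               lb = 0, ub = wmax * 86400e-6 * 1.01))
  wcols <- n0 + seq_len(N); Wcol <- n0 + N + 1
  base <- length(model$rhs)
  ## w_t - r_t * uptake_t = 0
  model$tri$i <- c(model$tri$i, base + seq_len(N), base + seq_len(N))
  model$tri$j <- c(model$tri$j, wcols, up)
  model$tri$x <- c(model$tri$x, rep(1, N), -r)
  ## W - sum_t w_t * dt = 0   (dt in s, result in mol m-2 day-1)
  dt <- model$step_hours * 3600 * 1e-6
  model$tri$i <- c(model$tri$i, base + N + 1, rep(base + N + 1, N))
  model$tri$j <- c(model$tri$j, Wcol, wcols)
  model$tri$x <- c(model$tri$x, 1, rep(-dt, N))
  model$rhs <- c(model$rhs, numeric(N + 1))
  model$sense <- c(model$sense, rep("=", N + 1))
  model$row_kind <- c(model$row_kind, rep("water_def", N), "water_total_def")
  model$gas <- gas
  model$water_coefs <- r
  model
}

## Assemble the sparse constraint system of a diel model.
model_program <- function(model) {
  A <- Matrix::sparseMatrix(i = model$tri$i, j = model$tri$j, x = model$tri$x,
                            dims = c(length(model$rhs), nrow(model$vars)))
  list(A = A, rhs = model$rhs, sense = model$sense,
       lb = model$vars$lb, ub = model$vars$ub)
}

#' Dump per-step reaction bounds as a data frame
#'
#' Audit view of the expanded model: one row per (reaction, step) with the
#' applied bounds.
#' @param model a [expand_diel()] model.
#' @return data.frame with columns `reaction_id`, `step`, `lb`, `ub`.
#' @export
model_bounds <- function(model) {
  v <- model$vars[model$vars$kind == "rxn", ]
  data.frame(reaction_id = v$id, step = v$step, lb = v$lb, ub = v$ub)
}
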