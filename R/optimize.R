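## Lexicographic optimization of diel models:
##   1. maximize daily phloem output (LP)
##   2. minimize daily water loss at fixed output (LP)
##   3. minimize the quadratic flux sum at the pinned objectives (QP)

## daily-integral coefficients (umol m-2 s-1 sustained over a step -> mol m-2)
flux_to_daily <- function(model) model$step_hours * 3600 * 1e-6

solve_model <- function(model, obj, qdiag = NULL, maximize = FALSE,
                        extra = NULL, qdiag_slack = 0, control = list()) {
  pg <- model_program(model)
  A <- pg$A; rhs <- pg$rhs; sense <- pg$sense
  if (!is.null(extra)) {
    A <- rbind(A, extra$A)
    rhs <- c(rhs, extra$rhs)
    sense <- c(sense, extra$sense)
  }
  soft <- if (is.null(extra)) integer(0) else
    nrow(pg$A) + seq_along(extra$rhs)
  r <- solve_program(obj, A, rhs, sense, pg$lb, pg$ub, qdiag = qdiag,
                     maximize = maximize, qdiag_slack = qdiag_slack,
                     soft_rows = soft, control = control)
  ## degenerate vertices occasionally derail the interior-point trajectory;
  ## a jittered restart takes a different path to the same optimum
  for (jit in 1:2) {
    if (r$status != "numerical") break
    r <- solve_program(obj, A, rhs, sense, pg$lb, pg$ub, qdiag = qdiag,
                       maximize = maximize, qdiag_slack = qdiag_slack,
                       soft_rows = soft,
                       control = modifyList(list(max_iter = 300, jitter = jit),
                                            control))
  }
  r
}

phloem_obj <- function(model) {
  obj <- numeric(nrow(model$vars))
  obj[rxn_cols(model, model$tags["PHLOEM_EXPORT"])] <- flux_to_daily(model)
  obj
}

water_obj <- function(model) {
  if (is.null(model$gas))
    stop("water loss is not coupled; call couple_water_loss() first")
  obj <- numeric(nrow(model$vars))
  obj[model$vars$kind == "water_total"] <- 1
  obj
}

## single-row linear constraint on the daily phloem output
phloem_row <- function(model, sense, value) {
  cols <- rxn_cols(model, model$tags["PHLOEM_EXPORT"])
  list(A = Matrix::sparseMatrix(i = rep(1, length(cols)), j = cols,
                                x = rep(flux_to_daily(model), length(cols)),
                                dims = c(1, nrow(model$vars))),
       rhs = value, sense = sense)
}

water_row <- function(model, sense, value) {
  col <- which(model$vars$kind == "water_total")
  list(A = Matrix::sparseMatrix(i = 1, j = col, x = 1,
                                dims = c(1, nrow(model$vars))),
       rhs = value, sense = sense)
}

cat_rows <- function(a, b) {
  if (is.null(a)) return(b)
  list(A = rbind(a$A, b$A), rhs = c(a$rhs, b$rhs), sense = c(a$sense, b$sense))
}

diag_infeasible <- function(model, what) {
  pg <- model_program(model)
  ineq <- pg$sense != "="
  ## convert inequalities to equalities with slacks for the probe
  A <- pg$A; lb <- pg$lb; ub <- pg$ub
  if (any(ineq)) {
    sgn <- ifelse(pg$sense[ineq] == "<=", 1, -1)
    A <- cbind(A, Matrix::sparseMatrix(i = which(ineq), j = seq_len(sum(ineq)),
                                       x = sgn, dims = c(nrow(A), sum(ineq))))
    lb <- c(lb, numeric(sum(ineq)))
    ub <- c(ub, rep(Inf, sum(ineq)))
  }
  pr <- elastic_probe(A, pg$rhs, lb, ub)
  viol <- pr$row_violation > 1e-6 * (1 + max(abs(pg$rhs)))
  classes <- unique(model$row_kind[which(viol)])
  stop(what, ": model infeasible; binding constraint classes: ",
       if (length(classes)) paste(classes, collapse = ", ") else "unresolved")
}

#' Construct a diel solution object from a solved flux vector
#'
#' @param model the solved [expand_diel()] model (water-coupled or not).
#' @param x full variable vector from the solver.
#' @param status solver status string.
#' @return object of class `diel_solution` with per-step flux and linker
#'   matrices and derived daily totals.
#' @export
diel_solution <- function(model, x, status = "optimal") {
  N <- model$n_steps
  vr <- model$vars$kind == "rxn"
  vl <- model$vars$kind == "linker"
  R <- nrow(model$net$reactions)
  fluxes <- matrix(x[vr], nrow = R, ncol = N,
                   dimnames = list(model$net$reactions$id, NULL))
  Ns <- nrow(model$net$storables)
  linkers <- matrix(x[vl], nrow = Ns, ncol = N,
                    dimnames = list(model$net$storables$metabolite, NULL))
  daily <- flux_to_daily(model)
  up <- fluxes[model$tags["CO2_UPTAKE"], ]
  water <- if (!is.null(model$gas))
    total_water_loss(pmax(up, 0), model$env, model$gas) else NA_real_
  structure(list(
    model = model, status = status,
    fluxes = fluxes, linkers = linkers,
    phloem_output = sum(fluxes[model$tags["PHLOEM_EXPORT"], ]) * daily,
    co2_total = sum(up) * daily,
    water_total = water,
    flux_sum_l1 = sum(abs(fluxes)) + sum(abs(linkers)),
    flux_sum_l2 = sum(fluxes^2) + sum(linkers^2)),
    class = "diel_solution")
}

#' @export
print.diel_solution <- function(x, ...) {
  cat("<diel_solution> status:", x$status, "\n")
  cat(sprintf("  phloem output: %.4f mol m-2 d-1\n", x$phloem_output))
  cat(sprintf("  CO2 uptake:    %.4f mol m-2 d-1\n", x$co2_total))
  if (!is.na(x$water_total))
    cat(sprintf("  water loss:    %.1f mol m-2 d-1\n", x$water_total))
  cat(sprintf("  flux sum (L1): %.1f umol m-2 s-1\n", x$flux_sum_l1))
  invisible(x)
}

#' Maximize daily phloem output
#'
#' Primary objective of the reference (C3) run: maximize the daily integral
#' of the phloem-export reaction, then (by default) minimize the quadratic
#' flux sum without degrading the optimum.
#'
#' @param model a diel model (water coupling optional).
#' @param minimize_flux_after run the flux-sum QP at the pinned optimum.
#' @param pin_tol relative pin tolerance for the flux-sum stage.
#' @return a [diel_solution()].
#' @export
maximize_phloem <- function(model, minimize_flux_after = TRUE,
                            pin_tol = 1e-4) {
  ## a whisper of curvature makes the LP strictly convex; the objective
  ## bias (<= 1e-10 * sum(x^2) / 2) is far below the pin tolerance
  obj <- phloem_obj(model)
  r1 <- solve_model(model, obj, maximize = TRUE,
                    qdiag = rep(1e-10, nrow(model$vars)), qdiag_slack = 1e-10)
  if (r1$status != "optimal") {
    if (r1$status == "infeasible") diag_infeasible(model, "maximize_phloem")
    stop("maximize_phloem: solver status ", r1$status)
  }
  pstar <- sum(obj * r1$x)
  if (!minimize_flux_after) return(diel_solution(model, r1$x, r1$status))
  sol <- minimize_flux(model, phloem_floor = pstar, pin_tol = pin_tol)
  stopifnot(abs(sol$phloem_output - pstar) <= 20 * pin_tol * (1 + abs(pstar)))
  sol
}

#' Minimize daily water loss at a required phloem output
#'
#' Fixes the minimum required phloem output and minimizes total
#' transpirational water loss, then (by default) minimizes the quadratic
#' flux sum with both objectives pinned.
#'
#' @param model a water-coupled diel model.
#' @param phloem_floor required daily phloem output in mol m-2 day-1.
#' @param minimize_flux_after run the flux-sum QP afterwards.
#' @param pin_tol relative pin tolerance for the flux-sum stage.
#' @return a [diel_solution()].
#' @export
minimize_water <- function(model, phloem_floor, minimize_flux_after = TRUE,
                           pin_tol = 1e-4) {
  ex <- phloem_row(model, ">=", phloem_floor)
  obj <- water_obj(model)
  r1 <- solve_model(model, obj, extra = ex,
                    qdiag = rep(1e-8, nrow(model$vars)), qdiag_slack = 1e-8)
  if (r1$status != "optimal") {
    if (r1$status == "infeasible")
      stop("minimize_water: infeasible at phloem floor ", phloem_floor,
           " (floor above maximum output?)")
    stop("minimize_water: solver status ", r1$status)
  }
  wstar <- sum(obj * r1$x)
  if (!minimize_flux_after) return(diel_solution(model, r1$x, r1$status))
  sol <- minimize_flux(model, phloem_floor = phloem_floor,
                       water_ceiling = wstar, pin_tol = pin_tol)
  stopifnot(sol$water_total <= wstar + 110 * pin_tol * (1 + wstar))
  sol
}

#' Minimize the quadratic flux sum at pinned objectives
#'
#' Selects, among the alternative optima of the preceding linear stages,
#' the flux distribution with the smallest sum of squared fluxes (step
#' reactions and linkers) - the solution with the least variation in fluxes
#' between time points. The linear objectives already attained are pinned:
#' phloem output from below, water loss from above.
#'
#' @param model a diel model.
#' @param phloem_floor pinned daily phloem output (lower bound), or `NULL`.
#' @param water_ceiling pinned daily water loss (upper bound), or `NULL`.
#' @param pin_tol relative tolerance with which the water objective is
#'   pinned (the preceding stage's optimum may be exceeded by at most this
#'   relative amount).
#' @return a [diel_solution()].
#' @export
minimize_flux <- function(model, phloem_floor = NULL, water_ceiling = NULL,
                          pin_tol = 1e-4) {
  ## unit weight on fluxes and linkers; a whisper of curvature on the
  ## auxiliary water variables and row slacks keeps the QP strictly convex
  ## in every direction without biasing the selection
  qd <- ifelse(model$vars$kind %in% c("rxn", "linker"), 1, 1e-8)
  ## the preceding LP optima carry their own tolerance, so the pins start
  ## tight and widen geometrically until the pinned QP is solvable
  slacks <- pin_tol * c(0.1, 1, 5, 25, 100)
  r <- NULL
  for (sl in slacks) {
    ex <- NULL
    if (!is.null(phloem_floor))
      ex <- cat_rows(ex, phloem_row(model, ">=", phloem_floor * (1 - sl / 10)))
    if (!is.null(water_ceiling))
      ex <- cat_rows(ex, water_row(model, "<=", water_ceiling * (1 + sl)))
    r <- solve_model(model, numeric(nrow(model$vars)), qdiag = qd, extra = ex,
                     qdiag_slack = 1e-8)
    if (r$status == "optimal") break
    if (is.null(water_ceiling) && is.null(phloem_floor)) break
  }
  if (r$status != "optimal")
    stop("minimize_flux: solver status ", r$status)
  diel_solution(model, r$x)
}

#' Pareto scan of phloem output against water loss
#'
#' Starts from the maximum phloem output (Pareto step 1) and reduces the
#' required output in `step_pct` steps down to `floor_pct`, minimizing
#' water loss (then the flux sum) at each required output.
#'
#' @param model a water-coupled diel model.
#' @param step_pct step size in percent of the maximum output.
#' @param floor_pct lowest fraction scanned, in percent.
#' @param minimize_flux_after run the flux-sum QP at each point (slower,
#'   but gives reproducible flux patterns).
#' @return data.frame of class `pareto_scan`: `fraction` (percent),
#'   `phloem_output`, `water_total`, `flux_sum_l1`, `status`, with the
#'   solutions in `attr(, "solutions")`.
#' @export
pareto_scan <- function(model, step_pct = 5, floor_pct = 20,
                        minimize_flux_after = TRUE) {
  ref <- maximize_phloem(model, minimize_flux_after = FALSE)
  pstar <- ref$phloem_output
  fractions <- seq(100, floor_pct, by = -step_pct)
  sols <- vector("list", length(fractions))
  rows <- lapply(seq_along(fractions), function(k) {
    f <- fractions[k]
    res <- tryCatch(
      minimize_water(model, phloem_floor = f / 100 * pstar,
                     minimize_flux_after = minimize_flux_after),
      error = function(e) e)
    if (inherits(res, "error"))
      ## break exact degeneracy of the floor before giving up on the point
      res <- tryCatch(
        minimize_water(model, phloem_floor = f / 100 * pstar * (1 - 1e-7),
                       minimize_flux_after = minimize_flux_after),
        error = function(e) e)
    if (inherits(res, "error"))
      return(data.frame(fraction = f, phloem_output = NA, water_total = NA,
                        flux_sum_l1 = NA, status = conditionMessage(res)))
    sols[[k]] <<- res
    data.frame(fraction = f, phloem_output = res$phloem_output,
               water_total = res$water_total,
               flux_sum_l1 = res$flux_sum_l1, status = res$status)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("pareto_scan", "data.frame"),
            max_phloem = pstar, solutions = sols)
}
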