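## Independent oracles, kept deliberately separate from the package's own
## numerical paths.

## Brute-force vertex enumeration for  min/max c'x  s.t. Ax = b, lb<=x<=ub.
## Vertices of the polytope have (n - rank(A)) variables at bounds; all
## bound-assignment subsets are enumerated and the remaining square system
## solved exactly. Only viable for ~a dozen variables.
vertex_enum_lp <- function(obj, A, b, lb, ub, maximize = FALSE, tol = 1e-9) {
  A <- as.matrix(A)
  n <- ncol(A)
  m <- qr(A)$rank
  stopifnot(n <= 14)
  best <- NULL
  free_sets <- utils::combn(n, m, simplify = FALSE)
  for (fs in free_sets) {
    Af <- A[, fs, drop = FALSE]
    if (qr(Af)$rank < m) next
    fixed <- setdiff(seq_len(n), fs)
    if (length(fixed)) {
      choices <- expand.grid(rep(list(c("l", "u")), length(fixed)),
                             stringsAsFactors = FALSE)
    } else choices <- data.frame(row.names = 1)
    for (ci in seq_len(nrow(choices))) {
      x <- numeric(n)
      if (length(fixed)) {
        sel <- unlist(choices[ci, ])
        x[fixed] <- ifelse(sel == "l", lb[fixed], ub[fixed])
        if (any(!is.finite(x[fixed]))) next
      }
      rhs <- b - if (length(fixed))
        A[, fixed, drop = FALSE] %*% x[fixed] else 0
      xf <- tryCatch(qr.solve(Af, rhs), error = function(e) NULL)
      if (is.null(xf)) next
      x[fs] <- xf
      if (any(x < lb - tol) || any(x > ub + tol)) next
      if (max(abs(A %*% x - b)) > tol * (1 + max(abs(b)))) next
      val <- sum(obj * x)
      if (is.null(best) || (maximize && val > best$val + 1e-12) ||
          (!maximize && val < best$val - 1e-12))
        best <- list(val = val, x = x)
    }
  }
  best
}

## Independently coded stomatal water cost (same physics, separate code).
oracle_water_per_co2 <- function(temp_c, rh, c_atm = 400, ci_ratio = 0.7,
                                 diff_ratio = 1.6, pressure = 101.325) {
  esat <- 0.61121 * exp((18.678 - temp_c / 234.5) *
                          (temp_c / (257.14 + temp_c)))
  vpd_frac <- esat * (1 - rh) / pressure
  grad <- (c_atm / 1e6) * (1 - ci_ratio)
  diff_ratio * vpd_frac / grad
}

## A 3-reaction, 2-step toy used for tiny diel LP oracle checks: uptake of
## an external substrate into a storable pool and a demand reaction.
tiny_chain_net <- function(ub_uptake = 3) {
  mets <- data.frame(
    id = c("S_e", "M_c", "M_v"),
    name = c("S", "M", "M"),
    compartment = c("extracellular", "cytosol", "vacuole"),
    carries_carbon = TRUE, is_co2_species = FALSE)
  rx <- data.frame(id = c("EX_S", "UPT", "VT_M", "DEMAND"),
                   name = c("EX_S", "UPT", "VT_M", "DEMAND"),
                   lb = c(0, 0, -10, 0), ub = c(10, ub_uptake, 10, 10))
  rx$tags <- list(character(0), character(0), "VACUOLAR_TRANSPORT",
                  character(0))
  rx$boundary <- c(TRUE, FALSE, FALSE, TRUE)
  st <- data.frame(
    reaction = c("EX_S", "UPT", "UPT", "VT_M", "VT_M", "DEMAND"),
    metabolite = c("S_e", "S_e", "M_c", "M_c", "M_v", "M_c"),
    coef = c(1, -1, 1, -1, 1, -1))
  metabolic_network(mets, rx, st,
                    storables = data.frame(metabolite = "M_v",
                                           compartment = "vacuole"))
}

## A 3-step cyclic toy with alternative optima: constant demand of 1 per
## step, uptake capped at 3 per step, storage carrying surplus forward.
## Any uptake pattern summing to 3 is optimal; the quadratic flux-sum stage
## must select the uniform one.
three_step_program <- function(uptake_pattern = NULL) {
  net <- tiny_chain_net(ub_uptake = 3)
  S <- stoich_matrix(net)
  N <- 3; R <- nrow(net$reactions)
  A <- Matrix::bdiag(S, S, S)
  mv <- match("M_v", rownames(S))
  L <- matrix(0, nrow(S) * N, N)
  for (t in 1:N) {
    L[(t - 1) * nrow(S) + mv, t] <- -1
    L[(t %% N) * nrow(S) + mv, t] <- 1
  }
  A <- cbind(A, L)
  lb <- c(rep(net$reactions$lb, N), numeric(N))
  ub <- c(rep(net$reactions$ub, N), rep(10, N))
  idem <- match("DEMAND", net$reactions$id) + R * (0:(N - 1))
  lb[idem] <- ub[idem] <- 1
  iup <- match("UPT", net$reactions$id) + R * (0:(N - 1))
  if (!is.null(uptake_pattern)) lb[iup] <- ub[iup] <- uptake_pattern
  list(A = A, lb = lb, ub = ub, iup = iup, n = ncol(A))
}

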