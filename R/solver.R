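#' @importFrom Matrix sparseMatrix Diagonal crossprod t Cholesky solve drop0
NULL

#' Solve a linear or diagonal-quadratic program
#'
#' Minimizes \eqn{c'x + \frac{1}{2} x' \mathrm{diag}(q) x} subject to linear
#' constraints with row senses (`=`, `<=`, `>=`) and box bounds, using a
#' primal-dual interior-point method on sparse normal equations. With
#' `q = 0` this is a plain LP. Diel flux-balance models produced by
#' [expand_diel()] are solved through this routine.
#'
#' Inequality rows are converted to equalities with slack variables before
#' the interior-point iteration. Near-optimal iterates are polished by
#' projecting onto the active-set equality system so that constraint
#' residuals reach close to machine precision.
#'
#' @param obj numeric objective vector (length n).
#' @param A constraint matrix (dense or `Matrix` sparse, m x n).
#' @param rhs right-hand side (length m).
#' @param sense character vector of row senses, one of `"="`, `"<="`, `">="`.
#' @param lb,ub numeric bounds; `lb` must be finite, `ub` may be `Inf`.
#' @param qdiag optional nonnegative diagonal of the quadratic term.
#' @param qdiag_slack quadratic weight given to the slack variables of
#'   inequality rows; a tiny positive value makes a QP strictly convex in
#'   every variable, which sharpens convergence on degenerate instances.
#' @param maximize if `TRUE`, maximize `obj` (only meaningful for LPs).
#' @param soft_rows indices of rows excluded from the final feasibility
#'   polish (e.g. objective pins that carry their own tolerance); they are
#'   still enforced by the interior-point iteration itself.
#' @param control list of solver controls (`tol_p`, `tol_d`, `tol_gap`,
#'   `max_iter`, `polish`).
#' @return list with elements `x`, `objval`, `status` (one of `"optimal"`,
#'   `"infeasible"`, `"max_iter"`, `"numerical"`), `iterations`, and
#'   `residual` (max absolute equality-constraint violation).
#' @export
solve_program <- function(obj, A, rhs, sense = rep("=", length(rhs)),
                          lb, ub, qdiag = NULL, maximize = FALSE,
                          qdiag_slack = 0, soft_rows = integer(0),
                          control = list()) {
  A <- methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  n <- ncol(A)
  m <- nrow(A)
  stopifnot(length(obj) == n, length(rhs) == m, length(sense) == m,
            length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb))) stop("solve_program: lower bounds must be finite")
  if (any(lb > ub + 1e-12)) stop("solve_program: lb > ub")
  if (is.null(qdiag)) qdiag <- numeric(n) else stopifnot(all(qdiag >= 0))
  cvec <- if (maximize) -obj else obj

  ## slacks for inequality rows
  ineq <- which(sense != "=")
  n_sl <- length(ineq)
  if (n_sl) {
    sgn <- ifelse(sense[ineq] == "<=", 1, -1)
    S <- Matrix::sparseMatrix(i = ineq, j = seq_len(n_sl), x = sgn,
                              dims = c(m, n_sl))
    A_full <- cbind(A, S)
    cvec <- c(cvec, numeric(n_sl))
    qdiag <- c(qdiag, rep(qdiag_slack, n_sl))
    lb <- c(lb, numeric(n_sl))
    ub <- c(ub, rep(Inf, n_sl))
  } else A_full <- A

  ## row equilibration: scale every row to unit max coefficient
  rmax <- vapply(seq_len(m), function(i) 0, numeric(1))
  trA <- methods::as(A_full, "TsparseMatrix")
  rmax <- rep(0, m)
  tmp <- tapply(abs(trA@x), trA@i + 1L, max)
  rmax[as.integer(names(tmp))] <- tmp
  rs <- 1 / pmax(rmax, 1e-12)
  A_sc <- Matrix::Diagonal(m, rs) %*% A_full
  soft <- rep(FALSE, m); soft[soft_rows] <- TRUE
  res <- ipm_core(cvec, qdiag, A_sc, rs * rhs, lb, ub, control, soft = soft)
  x <- res$x[seq_len(n)]
  objval <- sum(obj * x) + 0.5 * sum(qdiag[seq_len(n)] * x^2)
  resid <- if (m) max(abs(as.numeric(A_full %*% res$x) - rhs)) else 0
  list(x = x, objval = objval, status = res$status,
       iterations = res$iterations, residual = resid)
}

## Mehrotra predictor-corrector IPM for
##   min c'x + 1/2 x' diag(q) x  s.t.  A x = b,  lb <= x <= ub
## lb finite, ub possibly Inf.
ipm_core <- function(cvec, qvec, A, b, lb, ub, control = list(),
                     soft = rep(FALSE, nrow(A))) {
  ctl <- modifyList(list(tol_p = 1e-8, tol_d = 1e-6, tol_gap = 1e-9,
                         max_iter = 150, polish = TRUE, verbose = FALSE),
                    control)
  n <- length(cvec)

  ## eliminate fixed variables
  fixed <- which(ub - lb <= 1e-12)
  x_full <- numeric(n)
  if (length(fixed)) {
    x_full[fixed] <- lb[fixed]
    b <- b - as.numeric(A[, fixed, drop = FALSE] %*% lb[fixed])
    keep <- setdiff(seq_len(n), fixed)
    if (!length(keep)) {
      resid <- max(abs(b))
      return(list(x = x_full, status = if (resid < 1e-7) "optimal" else "infeasible",
                  iterations = 0L, residual = resid))
    }
    A <- A[, keep, drop = FALSE]
    cvec <- cvec[keep]; qvec <- qvec[keep]; lb <- lb[keep]; ub <- ub[keep]
  } else keep <- seq_len(n)
  nk <- length(keep)

  ## drop all-zero rows
  rn <- Matrix::rowSums(abs(A))
  zr <- which(rn == 0)
  if (length(zr)) {
    if (any(abs(b[zr]) > 1e-9))
      return(list(x = x_full, status = "infeasible", iterations = 0L,
                  residual = max(abs(b[zr]))))
    kr <- which(rn > 0)
    A <- A[kr, , drop = FALSE]; b <- b[kr]; soft <- soft[kr]
  }
  m <- nrow(A)
  hard <- which(!soft)

  ## shift to y = x - lb in [0, r]
  r <- ub - lb
  bnd <- is.finite(r)
  b_y <- b - as.numeric(A %*% lb)
  c_y <- cvec + qvec * lb
  At <- Matrix::t(A)

  ## starting point: least-squares primal/dual estimates, pushed interior
  y <- ifelse(bnd, pmax(pmin(r * 0.5, 1000), pmin(r * 0.25, 1e-2)), 1)
  lam <- numeric(m)
  z <- rep(max(1, mean(abs(c_y))), nk)
  ls0 <- tryCatch({
    M0 <- Matrix::tcrossprod(A)
    M0 <- Matrix::forceSymmetric(M0 + Matrix::Diagonal(m, 1e-10 * (1 + Matrix::diag(M0))))
    ch0 <- Matrix::Cholesky(M0, LDL = FALSE, perm = TRUE)
    y_ls <- as.numeric(At %*% Matrix::solve(ch0, b_y))
    lam_ls <- as.numeric(Matrix::solve(ch0, as.numeric(A %*% c_y)))
    list(y = y_ls, lam = lam_ls)
  }, error = function(e) NULL)
  if (!is.null(ls0)) {
    jit <- 1 + (ctl$jitter %||% 0) * 0.07
    ls0$y <- ls0$y * jit
    dp <- max(1e-2, -1.5 * min(ls0$y), 1e-3 * max(abs(ls0$y)))
    y <- ls0$y + dp
    y[bnd] <- pmin(pmax(ls0$y[bnd] + dp, 0.02 * pmin(r[bnd], 1e4)),
                   0.98 * pmin(r[bnd], 1e6))
    y <- pmax(y, 1e-8)
    lam <- ls0$lam
    rd0 <- c_y + qvec * y - as.numeric(At %*% lam)
    zf <- max(1e-1, 0.5 * mean(abs(rd0)))
    z <- pmax(rd0, zf)
    s_all <- pmax(-rd0, zf)
  } else s_all <- rep(max(1, mean(abs(c_y))), nk)
  w <- pmax(r[bnd] - y[bnd], 1e-8)
  s <- s_all[bnd]

  ## primal scale from the unshifted rhs: bound shifts can inflate b_y by
  ## orders of magnitude, which would make a "relative" tolerance loose in
  ## the units the constraints are actually stated in
  bsc <- 1 + max(abs(b)); csc <- 1 + max(abs(c_y))
  status <- "max_iter"; it <- 0L
  best <- list(merit = Inf)
  stall <- 0L
  Chol <- NULL
  Eidx <- which(bnd)

  dual_res <- function(y, lam, z, s) {
    rd <- c_y + qvec * y - as.numeric(At %*% lam) - z
    rd[Eidx] <- rd[Eidx] + s
    rd
  }

  for (it in seq_len(ctl$max_iter)) {
    rp <- b_y - as.numeric(A %*% y)
    rb <- r[Eidx] - y[Eidx] - w
    rd <- dual_res(y, lam, z, s)
    mu <- (sum(y * z) + sum(w * s)) / (nk + length(w))
    if (anyNA(rp) || anyNA(rd) || !is.finite(mu)) { status <- "numerical"; break }
    rel_p <- max(abs(rp)) / bsc
    rel_d <- max(abs(rd)) / csc
    ## normalize the gap by the objective in original (unshifted) units -
    ## the shifted objective c_y'y can be inflated by the bound translation
    gap <- mu / (1 + abs(sum(cvec * (lb + y)) + 0.5 * sum(qvec * (lb + y)^2)))
    merit <- max(rel_p, rel_d, gap)
    if (isTRUE(ctl$verbose))
      cat(sprintf("it %3d rp %.2e rd %.2e gap %.2e mu %.2e\n",
                  it, rel_p, rel_d, gap, mu))
    if (merit < best$merit) {
      best <- list(merit = merit, rel_p = rel_p, rel_d = rel_d, gap = gap,
                   y = y, w = w, lam = lam, z = z, s = s)
      stall <- 0L
    } else stall <- stall + 1L
    if (rel_p < ctl$tol_p && rel_d < ctl$tol_d && gap < ctl$tol_gap) {
      status <- "optimal"; break
    }
    ## converged in the gap with primal residual at its numerical floor:
    ## accept and let the polish step restore exact feasibility
    if (gap < 1e-10 && rel_p < 1e-5 && rel_d < 1e-4) { status <- "optimal"; break }
    ## past the useful region: mu has collapsed and feasibility is degrading
    if (gap < 1e-9 && rel_p > 10 * best$rel_p) break
    if (stall > 25L) break

    d <- qvec + z / y
    d[Eidx] <- d[Eidx] + s / w
    Dinv <- 1 / pmax(d, 1e-9)
    M <- A %*% (Dinv * At)
    M <- Matrix::forceSymmetric(M + Matrix::Diagonal(m, 1e-11 * (1 + Matrix::diag(M))))
    ok <- TRUE
    Chol <- tryCatch({
      if (is.null(Chol)) Matrix::Cholesky(M, LDL = FALSE, perm = TRUE)
      else Matrix::update(Chol, M)
    }, error = function(e) { ok <<- FALSE; NULL })
    if (!ok) {
      M <- M + Matrix::Diagonal(m, 1e-6 * (1 + Matrix::diag(M)))
      Chol <- tryCatch(Matrix::Cholesky(M, LDL = FALSE, perm = TRUE),
                       error = function(e) NULL)
      if (is.null(Chol)) { status <- "numerical"; break }
    }

    solve_newton <- function(rc1, rc2) {
      rhs_y <- -rd + rc1 / y
      tmp <- numeric(nk)
      tmp[Eidx] <- -rc2 / w + (s / w) * rb
      rhs_y <- rhs_y + tmp
      rhs_lam <- rp - as.numeric(A %*% (Dinv * rhs_y))
      dlam <- as.numeric(Matrix::solve(Chol, rhs_lam))
      ## one pass of iterative refinement on the normal equations
      rres <- rhs_lam - as.numeric(M %*% dlam)
      dlam <- dlam + as.numeric(Matrix::solve(Chol, rres))
      dy <- Dinv * (rhs_y + as.numeric(At %*% dlam))
      dz <- (rc1 - z * dy) / y
      dw <- rb - dy[Eidx]
      ds <- (rc2 - s * dw) / w
      list(dy = dy, dlam = dlam, dz = dz, dw = dw, ds = ds)
    }
    step_len <- function(v, dv) {
      neg <- !is.na(dv) & dv < 0
      if (!any(neg)) return(1)
      min(1, min(-v[neg] / dv[neg]))
    }

    ## predictor
    aff <- solve_newton(-y * z, -w * s)
    ap <- min(step_len(y, aff$dy), step_len(w, aff$dw))
    ad <- min(step_len(z, aff$dz), step_len(s, aff$ds))
    mu_aff <- (sum((y + ap * aff$dy) * (z + ad * aff$dz)) +
               sum((w + ap * aff$dw) * (s + ad * aff$ds))) / (nk + length(w))
    sigma <- max(min((mu_aff / mu)^3, 1), 1e-8)

    ## corrector
    cor <- solve_newton(sigma * mu - y * z - aff$dy * aff$dz,
                        sigma * mu - w * s - aff$dw * aff$ds)
    if (anyNA(cor$dy) || anyNA(cor$dz)) { status <- "numerical"; break }
    ap <- 0.9995 * min(step_len(y, cor$dy), step_len(w, cor$dw))
    ad <- 0.9995 * min(step_len(z, cor$dz), step_len(s, cor$ds))
    if (any(qvec > 0)) ap <- ad <- min(ap, ad)
    y <- pmax(y + ap * cor$dy, 1e-300)
    w <- pmax(w + ap * cor$dw, 1e-300)
    lam <- lam + ad * cor$dlam
    z <- pmax(z + ad * cor$dz, 1e-300)
    s <- pmax(s + ad * cor$ds, 1e-300)
  }

  ## fall back to the best iterate seen if the last ones degraded
  if (status != "optimal" && is.finite(best$merit)) {
    y <- best$y
    if (best$rel_p < 1e-5 && best$rel_d < 1e-3 && best$gap < 1e-5) {
      status <- "optimal"
    } else if (best$rel_p < 1e-3 && best$rel_d < 1e-3 && best$gap < 1e-6) {
      ## gap-converged but the primal residual hit its numerical floor:
      ## accept if refinement restores feasibility (the correction distance
      ## is of the order of the floor)
      xp <- polish_point(lb + y, A, b, lb, ub, hard = hard)
      if (max(abs(as.numeric(A[hard, , drop = FALSE] %*% xp) - b[hard])) <
            1e-8 * bsc) {
        x_full[keep] <- xp
        return(list(x = x_full, status = "optimal", iterations = it,
                    residual = max(abs(as.numeric(A %*% xp) - b))))
      }
      status <- "numerical"
    } else if (best$rel_p > 1e-5) {
      status <- if (elastic_infeasible(A, b, lb, ub)) "infeasible" else "numerical"
    } else status <- "numerical"
  }
  x <- lb + y
  if (status == "optimal" && isTRUE(ctl$polish))
    x <- polish_point(x, A, b, lb, ub, hard = hard)
  x_full[keep] <- x
  resid <- if (m) max(abs(as.numeric(A %*% x) - b)) else 0
  list(x = x_full, status = status, iterations = it, residual = resid)
}

## Project a near-feasible point exactly onto the equality system, holding
## variables at active bounds fixed; variables pushed past a bound by the
## projection are clamped and the projection repeated on the remaining free
## set. Brings |Ax - b| down to ~1e-12 for a well-centered iterate.
polish_point <- function(x, A, b, lb, ub, act_tol = 1e-7, rounds = 4,
                         hard = seq_along(b)) {
  ## soft rows (objective pins with their own tolerance) are excluded from
  ## the projection: repairing them to machine precision would route large
  ## corrections through bound-hugging variables
  A <- A[hard, , drop = FALSE]; b <- b[hard]
  res0 <- if (length(b)) max(abs(b - as.numeric(A %*% x))) else 0
  if (res0 < 1e-13) return(x)
  x0 <- x
  ubf <- ifelse(is.finite(ub), ub, .Machine$double.xmax)
  for (round in seq_len(rounds)) {
    scale <- 1 + abs(x)
    at_l <- (x - lb) < act_tol * scale
    at_u <- is.finite(ub) & (ub - x) < act_tol * scale
    x[at_l] <- lb[at_l]; x[at_u] <- ub[at_u]
    free <- which(!(at_l | at_u))
    if (!length(free)) break
    Ff <- A[, free, drop = FALSE]
    M <- Matrix::tcrossprod(Ff)
    M <- Matrix::forceSymmetric(M + Matrix::Diagonal(nrow(M), 1e-12 * (1 + Matrix::diag(M))))
    ch <- tryCatch(Matrix::Cholesky(M, LDL = FALSE, perm = TRUE),
                   error = function(e) NULL)
    if (is.null(ch)) break
    for (k in 1:2) {
      res <- b - as.numeric(A %*% x)
      dx <- as.numeric(Matrix::t(Ff) %*% Matrix::solve(ch, res))
      x[free] <- x[free] + dx
    }
    viol <- max(0, max(lb - x), max(x - ubf))
    res1 <- max(abs(b - as.numeric(A %*% x)))
    if (viol < 1e-10 * (1 + max(abs(x)))) {
      if (res1 < 1e-12) break
    } else {
      ## clamp and try again with the enlarged active set
      x <- pmin(pmax(x, lb), ub)
    }
  }
  res1 <- max(abs(b - as.numeric(A %*% x)))
  viol1 <- max(0, max(lb - x), max(x - ubf))
  ## equality feasibility is driven to machine precision; bound violations
  ## of the order of the pre-polish residual are ordinary solver tolerance
  if (res1 <= max(res0, 1e-12) && viol1 < 3e-6 * (1 + max(abs(x)))) x else x0
}

## Elastic feasibility probe: min sum(t+ + t-) s.t. Ax + t+ - t- = b.
## Returns TRUE when the system {Ax=b, lb<=x<=ub} is provably infeasible;
## an unconverged probe proves nothing.
elastic_infeasible <- function(A, b, lb, ub, tol = 1e-6) {
  pr <- elastic_probe(A, b, lb, ub)
  if (pr$status != "optimal") return(FALSE)
  pr$violation > tol * (1 + max(abs(b)))
}

elastic_probe <- function(A, b, lb, ub) {
  m <- nrow(A); n <- ncol(A)
  E <- Matrix::Diagonal(m)
  A2 <- cbind(A, E, -E)
  cv <- c(numeric(n), rep(1, 2 * m))
  lb2 <- c(lb, numeric(2 * m))
  ub2 <- c(ub, rep(Inf, 2 * m))
  r <- ipm_core(cv, numeric(n + 2 * m), A2, b, lb2, ub2,
                control = list(polish = FALSE, tol_p = 1e-9, tol_d = 1e-7,
                               tol_gap = 1e-9, max_iter = 150))
  tpos <- r$x[(n + 1):(n + 2 * m)]
  row_viol <- abs(tpos[1:m] - tpos[(m + 1):(2 * m)])
  list(violation = sum(tpos), row_violation = row_viol, status = r$status)
}
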