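test_that("LP optima agree with an independent simplex implementation", {
  skip_if_not_installed("pracma")
  set.seed(11)
  for (k in 1:12) {
    n <- sample(3:8, 1); m <- sample(2:5, 1)
    A <- matrix(round(runif(m * n, 0.1, 2), 2), m, n)
    b <- round(runif(m, 1, 5), 2)
    cc <- round(runif(n, -3, 1), 2)
    got <- solve_program(cc, A, b, sense = rep("<=", m),
                         lb = numeric(n), ub = rep(Inf, n))
    want <- pracma::linprog(cc, A = A, b = b, maximize = FALSE)
    expect_equal(got$objval, want$fval, tolerance = 1e-6)
    expect_equal(got$status, "optimal")
  }
})

test_that("diagonal QP optima agree with a dual active-set solver", {
  skip_if_not_installed("quadprog")
  set.seed(7)
  for (k in 1:8) {
    n <- 6
    q <- runif(n, 0.5, 2); d <- runif(n, -1, 1)
    A <- matrix(runif(2 * n), 2, n)
    b <- as.numeric(A %*% runif(n, 0, 3))
    got <- solve_program(d, A, b, sense = c("=", "="), lb = numeric(n),
                         ub = rep(10, n), qdiag = q)
    want <- tryCatch(
      quadprog::solve.QP(diag(q), -d, cbind(t(A), diag(n), -diag(n)),
                         c(b, numeric(n), rep(-10, n)), meq = 2),
      error = function(e) NULL)
    if (is.null(want)) next
    expect_equal(got$objval, want$value, tolerance = 1e-6)
  }
})

test_that("infeasible systems are detected, feasible ones solved exactly", {
  r <- solve_program(c(1, 1), matrix(c(1, 1, 1, 1), 2, 2, byrow = TRUE),
                     c(1, 5), sense = c("=", "="), lb = c(0, 0),
                     ub = c(10, 10))
  expect_equal(r$status, "infeasible")
  r2 <- solve_program(c(1, 2), matrix(c(1, 1), 1, 2), 4, sense = "<=",
                      lb = c(0, 0), ub = c(3, 3), maximize = TRUE)
  expect_equal(r2$objval, 7)
  expect_equal(r2$x, c(1, 3), tolerance = 1e-7)
})

test_that("equality residuals of structured solves reach near machine precision", {
  set.seed(3)
  S <- Matrix::rsparsematrix(40, 55, 0.08)
  blocks <- lapply(1:4, function(t) S)
  A <- Matrix::bdiag(blocks)
  x0 <- runif(ncol(A), 0, 5)
  b <- as.numeric(A %*% x0)
  r <- solve_program(runif(ncol(A)), A, b, sense = rep("=", nrow(A)),
                     lb = rep(-10, ncol(A)), ub = rep(10, ncol(A)))
  expect_equal(r$status, "optimal")
  expect_lt(r$residual, 1e-9)
})

test_that("diel LP optima match brute-force vertex enumeration on tiny instances", {
  ## 2-step diel expansion of a 4-reaction chain: 10 variables in total
  net <- tiny_chain_net(ub_uptake = 3)
  env <- diel_environment(n_steps = 2, i_max = 250, daylength = 12)
  cs <- diel_constraints(co2_uptake_max = 15, maintenance_k = 0)
  ## bypass role tags: assemble the cyclic system by hand from the network
  S <- stoich_matrix(net)
  N <- 2
  R <- nrow(net$reactions)
  A <- Matrix::bdiag(S, S)
  ## linker columns: consume M_v at t, produce at t+1 (cyclic)
  mv <- match("M_v", rownames(S))
  L <- matrix(0, nrow(S) * N, N)
  L[mv, 1] <- -1; L[nrow(S) + mv, 1] <- 1
  L[nrow(S) + mv, 2] <- -1; L[mv, 2] <- 1
  A <- cbind(A, L)
  n <- ncol(A)
  lb <- c(rep(net$reactions$lb, N), 0, 0)
  ub <- c(rep(net$reactions$ub, N), 10, 10)
  ## demand must run at step 2 only; uptake only at step 1
  ub[R + match("UPT", net$reactions$id)] <- 0
  lb[R + match("DEMAND", net$reactions$id)] <- 1
  obj <- numeric(n)
  obj[match("DEMAND", net$reactions$id) + c(0, R)] <- 1
  r <- solve_program(obj, A, numeric(nrow(A)), sense = rep("=", nrow(A)),
                     lb = lb, ub = ub, maximize = TRUE)
  want <- vertex_enum_lp(obj, A, numeric(nrow(A)), lb, ub, maximize = TRUE)
  expect_equal(r$status, "optimal")
  expect_equal(r$objval, want$val, tolerance = 1e-7)
  ## the optimum is pinned by the step-1 uptake cap feeding both demands
  expect_equal(r$objval, 3, tolerance = 1e-7)
})
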