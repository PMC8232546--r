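test_that("BDF coefficients are the exact rationals and sum to one", {
  b1 <- bdf_coefficients(1L)
  expect_identical(b1$alpha, 1)
  expect_identical(b1$beta, 1)
  b2 <- bdf_coefficients(2L)
  expect_equal(b2$alpha, c(4 / 3, -1 / 3))
  expect_equal(b2$beta, 2 / 3)
  expect_equal(sum(b1$alpha), 1)
  expect_equal(sum(b2$alpha), 1)
  expect_error(bdf_coefficients(3L), "unsupported")
})

test_that("BDF residual matches a brute-force evaluation on a dense system", {
  set.seed(7)
  n <- 8L
  H <- crossprod(matrix(rnorm(n * n), n)) + diag(n)
  A <- matrix(rnorm(n * n), n)
  f <- rnorm(n)
  Fdot <- function(t, Y) f * t - as.numeric(A %*% Y)
  sch <- bdf_scheme(2L, 0.01)
  Y <- rnorm(n)
  hist <- list(rnorm(n), rnorm(n))
  r <- bdf_residual(H, sch, 0.3, Y, hist, Fdot)
  r_oracle <- H %*% (Y - 4 / 3 * hist[[1]] + 1 / 3 * hist[[2]]) -
    0.01 * 2 / 3 * (f * 0.3 - A %*% Y)
  expect_equal(r, as.numeric(r_oracle), tolerance = 1e-13)
  # equal states, zero forcing: residual vanishes because sum(alpha) = 1
  r0 <- bdf_residual(H, sch, 0, Y, list(Y, Y), function(t, Y) numeric(n))
  expect_lt(max(abs(r0)), 1e-12)
  expect_error(bdf_residual(H, sch, 0, Y, list(Y), Fdot), "history")
})

test_that("Newton: one-step convergence on affine problems, quadratic decay on a cubic", {
  # affine residual with exact tangent: single iteration
  A <- matrix(c(2, 1, 0, 3), 2)
  b <- c(1, -1)
  out <- newton_solve(function(y) as.numeric(A %*% y) - b,
                      function(y) A, c(5, 5), tol = 1e-12)
  expect_equal(out$iterations, 1L)
  expect_equal(out$Y, solve(A, b), tolerance = 1e-12)
  # scalar cubic R(y) = y^3 - 8: iterates match the hand formula
  out3 <- newton_solve(function(y) y^3 - 8,
                       function(y) matrix(3 * y^2), 3,
                       tol = 1e-14, maxit = 50L,
                       linear_solver = function(J, r) r / J[1, 1])
  expect_equal(out3$Y, 2, tolerance = 1e-12)
  y <- 3
  for (k in 1:3) y <- y - (y^3 - 8) / (3 * y^2)
  errs <- abs(out3$residuals[1:3])
  # quadratic convergence: error roughly squares each iteration
  expect_lt(errs[3], errs[2]^1.7)
})

test_that("the cosine ramp hits its endpoints and midpoint", {
  spec <- inflow_spec(6, t_ramp = -0.02, t0 = 0)
  expect_equal(ramp_flow(spec, -0.02), 0)
  expect_equal(ramp_flow(spec, 0), 6)
  expect_equal(ramp_flow(spec, -0.01), 3)         # cos(pi/2) = 0
  expect_error(ramp_flow(spec, 1), "outside")
  expect_equal(inflow_rate(spec, -1), 0)
  expect_equal(inflow_rate(spec, 0.5), 6)
  spec2 <- inflow_spec(function(t) 5 + sin(t), t_ramp = -0.02, t0 = 0)
  expect_equal(inflow_rate(spec2, 0.3), 5 + sin(0.3))
  expect_equal(ramp_flow(spec2, 0), 5)
})

test_that("BDF schemes attain their nominal temporal orders on a manufactured ODE system", {
  # linear system M y' + A y = f(t) driven through the package's BDF
  # residual and Newton solver; exact solution y(t) chosen smooth.
  set.seed(9)
  n <- 6L
  M <- crossprod(matrix(rnorm(n * n), n)) + n * diag(n)
  A <- crossprod(matrix(rnorm(n * n), n)) + diag(n)
  v1 <- rnorm(n); v2 <- rnorm(n)
  yex <- function(t) sin(3 * t) * v1 + cos(2 * t) * v2
  ypex <- function(t) 3 * cos(3 * t) * v1 - 2 * sin(2 * t) * v2
  fex <- function(t) as.numeric(M %*% ypex(t) + A %*% yex(t))
  run <- function(sigma, dt) {
    sch <- bdf_scheme(sigma, dt)
    nt <- round(0.5 / dt)
    # exact history seeding isolates the asymptotic order
    hist <- if (sigma == 2L) list(yex(dt), yex(0)) else list(yex(0))
    y <- hist[[1]]
    k0 <- if (sigma == 2L) 2L else 1L
    for (k in k0:nt) {
      tk <- k * dt
      Fdot <- function(t, Y) fex(t) - as.numeric(A %*% Y)
      res <- function(Y) bdf_residual(M, sch, tk, Y, hist, Fdot)
      J <- M + dt * sch$beta * A
      y <- newton_solve(res, function(Y) J, y, tol = 1e-13)$Y
      hist <- c(list(y), hist)[1:2]
    }
    sqrt(sum((y - yex(nt * dt))^2))
  }
  dts <- 0.5 / c(8, 16, 32)
  e1 <- vapply(dts, function(dt) run(1L, dt), 1)
  e2 <- vapply(dts, function(dt) run(2L, dt), 1)
  expect_lt(abs(observed_order(dts, e1) - 1), 0.2)
  expect_lt(abs(observed_order(dts, e2) - 2), 0.2)
})

test_that("unsteady Stokes with constant inflow approaches the steady state", {
  # unit viscosity: the viscous timescale rho R^2 / mu is then ~0.25 s,
  # so a 2 s horizon reaches the steady state to solver accuracy
  g <- build_tree_geometry(list(list(kind = "T1"), list(kind = "T1")), 0.25)
  sys <- assemble_global_system(g, fix_basis5(), fluid_properties(1, 1))
  infl <- inflow_spec(1, t_ramp = -0.02, t0 = 0)
  tr <- fom_time_loop(sys, infl, T_end = 2, scheme = bdf_scheme(1L, 0.05),
                      stokes = TRUE)
  nc <- ncol(tr$states)
  d_last <- sqrt(sum((tr$states[, nc] - tr$states[, nc - 1])^2))
  d_mid <- sqrt(sum((tr$states[, 4] - tr$states[, 3])^2))
  expect_lt(d_last, 1e-6 * max(abs(tr$states[, nc])))
  expect_lt(d_last, d_mid)
  steady <- solve_steady(sys, Q = 1, stokes = TRUE)
  expect_lt(max(abs(tr$states[, nc] - steady$Y)) / max(abs(steady$Y)), 1e-5)
})

test_that("zero inflow and zero data give the identically zero trajectory", {
  tt <- fix_two_tube()
  infl <- inflow_spec(0)
  tr <- fom_time_loop(tt$sys, infl, T_end = 0.005, scheme = bdf_scheme(2L, 2.5e-3))
  expect_equal(max(abs(tr$states)), 0)
})

test_that("the frozen Stokes tangent needs at least as many Newton iterations as the exact one", {
  tt <- fix_two_tube()
  sys <- tt$sys
  infl <- inflow_spec(8, t_ramp = -0.02, t0 = 0)
  sch <- bdf_scheme(1L, 2.5e-3)
  # advance a few steps to a nonlinear regime, then compare one step
  tr <- fom_time_loop(sys, infl, T_end = -0.005, scheme = sch)
  hist <- list(tr$states[, ncol(tr$states)])
  tk <- -0.005 + sch$dt
  resid <- function(Y) fom_residual(sys, sch, tk, Y, hist, infl)
  exact <- newton_solve(resid, function(Y) fom_tangent(sys, sch, Y, exact = TRUE),
                        hist[[1]], tol = 1e-10)
  frozen <- newton_solve(resid, function(Y)
    sys_tangent_matrix(sys, NULL, convective = FALSE,
                       scale_A = sch$dt * sch$beta, scale_B = sch$dt * sch$beta,
                       add_H = TRUE), hist[[1]], tol = 1e-10, maxit = 60L)
  expect_true(exact$converged)
  expect_true(frozen$converged)
  expect_gte(frozen$iterations, exact$iterations)
})

test_that("multiplier-multiplier tangent block is identically zero and FD-consistent", {
  tt <- fix_two_tube()
  sys <- tt$sys
  sch <- bdf_scheme(1L, 1e-2)
  set.seed(13)
  Y <- rnorm(sys$n) * 0.1
  J <- fom_tangent(sys, sch, Y, exact = TRUE)
  lidx <- sys$nW + seq_len(sys$nL)
  expect_equal(max(abs(J[lidx, lidx])), 0)
  # directional finite-difference check of the full BDF residual
  infl <- inflow_spec(1)
  hist <- list(rnorm(sys$n) * 0.1)
  dY <- rnorm(sys$n)
  h <- 1e-6
  r0 <- fom_residual(sys, sch, 0.1, Y, hist, infl)
  r1 <- fom_residual(sys, sch, 0.1, Y + h * dY, hist, infl)
  fd <- (r1 - r0) / h
  an <- as.numeric(J %*% dY)
  expect_lt(max(abs(fd - an)) / max(abs(an)), 1e-5)
})
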