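#' BDF coefficients
#'
#' Backward differentiation formulas of order 1 (backward Euler:
#' `alpha = 1`, `beta = 1`) and 2 (`alpha = (4/3, -1/3)`, `beta = 2/3`).
#' The consistency identity `sum(alpha) = 1` holds for both.
#'
#' @param sigma BDF order, 1 or 2.
#' @return list with `alpha` (numeric vector) and `beta`.
#' @export
bdf_coefficients <- function(sigma) {
  if (sigma == 1L) {
    out <- list(alpha = 1, beta = 1)
  } else if (sigma == 2L) {
    out <- list(alpha = c(4 / 3, -1 / 3), beta = 2 / 3)
  } else {
    stop("unsupported BDF order: ", sigma)
  }
  stopifnot(abs(sum(out$alpha) - 1) < 1e-14)
  out
}

#' BDF scheme descriptor
#'
#' @param sigma order (1 or 2).
#' @param dt timestep size.
#' @return object of class `rbe_bdf`.
#' @export
bdf_scheme <- function(sigma = 2L, dt = 2.5e-3) {
  stopifnot(dt > 0)
  co <- bdf_coefficients(sigma)
  structure(list(sigma = as.integer(sigma), dt = dt,
                 alpha = co$alpha, beta = co$beta), class = "rbe_bdf")
}

#' BDF residual of a generic first-order system
#'
#' `R(Y) = H (Y - sum_j alpha_j Y_hist_j) - dt beta Fdot(t, Y)` where
#' `Fdot(t, Y)` is the right-hand side of `H dY/dt = Fdot(t, Y)` and
#' `history` lists the previous states, most recent first.
#'
#' @param H mass operator (sparse matrix).
#' @param scheme an `rbe_bdf`.
#' @param t evaluation time.
#' @param Y current state.
#' @param history list of previous states, `history[[1]]` the most recent;
#'   must contain at least `sigma` entries.
#' @param Fdot function `(t, Y) -> vector`.
#' @return residual vector.
#' @export
bdf_residual <- function(H, scheme, t, Y, history, Fdot) {
  if (length(history) < scheme$sigma) stop("history holds fewer than sigma states")
  acc <- Y
  for (j in seq_len(scheme$sigma)) acc <- acc - scheme$alpha[j] * history[[j]]
  as.numeric(H %*% acc) - scheme$dt * scheme$beta * Fdot(t, Y)
}

#' Newton-Raphson solver
#'
#' Iterates `Y <- Y - J(Y)^{-1} R(Y)` until the relative residual
#' `||R(Y)|| / ||R(Y0)||` drops below the tolerance. One non-monotone
#' residual step is tolerated before declaring divergence.
#'
#' @param residual function `Y -> vector`.
#' @param tangent function `Y -> operator` handed to `linear_solver`.
#' @param Y0 initial guess.
#' @param tol relative tolerance.
#' @param atol absolute residual floor: a residual norm below `atol`
#'   counts as converged regardless of the relative criterion (useful
#'   near steady states, where the initial residual is already at
#'   roundoff level).
#' @param maxit maximum iterations.
#' @param linear_solver function `(J, r) -> delta` (default: sparse direct
#'   solve).
#' @return list with `Y`, `iterations`, `residuals` (relative residual
#'   history), `converged`, and the initial residual norm `r0`.
#' @export
newton_solve <- function(residual, tangent, Y0, tol = 1e-6, atol = 0,
                         maxit = 20L, linear_solver = NULL) {
  if (is.null(linear_solver))
    linear_solver <- function(J, r) as.numeric(Matrix::solve(J, r))
  Y <- Y0
  r <- residual(Y)
  r0 <- sqrt(sum(r^2))
  if (!is.finite(r0)) stop("non-finite initial residual")
  if (r0 <= atol) {
    return(list(Y = Y, iterations = 0L, residuals = numeric(0),
                converged = TRUE, r0 = r0))
  }
  hist <- numeric(0)
  grew <- 0L
  for (it in seq_len(maxit)) {
    J <- tangent(Y)
    Y <- Y - linear_solver(J, r)
    r <- residual(Y)
    rn <- sqrt(sum(r^2))
    rel <- rn / r0
    hist <- c(hist, rel)
    if (!is.finite(rel)) {
      return(list(Y = Y, iterations = it, residuals = hist, converged = FALSE,
                  r0 = r0))
    }
    if (rel < tol || rn < atol) {
      return(list(Y = Y, iterations = it, residuals = hist, converged = TRUE,
                  r0 = r0))
    }
    if (it > 1L && rel > hist[it - 1L]) {
      grew <- grew + 1L
      if (grew > 1L)
        return(list(Y = Y, iterations = it, residuals = hist,
                    converged = FALSE, r0 = r0))
    }
  }
  list(Y = Y, iterations = maxit, residuals = hist, converged = FALSE, r0 = r0)
}

#' Inflow specification with cosine start-up ramp
#'
#' The flow rate is 0 up to `t_ramp`, follows
#' `Q0 [1 - cos((t - t_ramp) pi / (t0 - t_ramp))] / 2` on
#' `[t_ramp, t0]`, and equals `waveform(t)` afterwards; `Q0 = waveform(t0)`
#' so the law is continuous at both ends.
#'
#' @param waveform function `t -> Q` (or a single number for constant
#'   inflow).
#' @param t_ramp ramp start time (default `-2e-2` s).
#' @param t0 ramp end time (default 0 s).
#' @return object of class `rbe_inflow`; call it via [inflow_rate()].
#' @export
inflow_spec <- function(waveform, t_ramp = -2e-2, t0 = 0) {
  stopifnot(t0 > t_ramp)
  if (is.numeric(waveform)) {
    q0 <- waveform
    waveform <- function(t) rep(q0, length(t))
  }
  structure(list(waveform = waveform, t_ramp = t_ramp, t0 = t0,
                 Q0 = waveform(t0)), class = "rbe_inflow")
}

#' Ramp law evaluated inside the ramp interval
#'
#' @param spec an `rbe_inflow`.
#' @param t time in `[t_ramp, t0]`.
#' @return flow rate.
#' @export
ramp_flow <- function(spec, t) {
  if (any(t < spec$t_ramp - 1e-14) || any(t > spec$t0 + 1e-14))
    stop("t outside the ramp interval")
  spec$Q0 * (1 - cos((t - spec$t_ramp) * pi / (spec$t0 - spec$t_ramp))) / 2
}

#' @rdname ramp_flow
#' @export
inflow_rate <- function(spec, t) {
  ifelse(t <= spec$t_ramp, 0,
         ifelse(t < spec$t0, spec$Q0 * (1 - cos((t - spec$t_ramp) * pi /
                                               (spec$t0 - spec$t_ramp))) / 2,
                spec$waveform(t)))
}

# FOM BDF residual/tangent on an rbe_system. Fdot(t, Y) = -steady_residual
# (forcing and inlet data included there with their signs).
fom_residual <- function(sys, scheme, t, Y, history, inflow, forcing = NULL) {
  Fdot <- function(t, Y)
    -sys_steady_residual(sys, t, Y, Qt = inflow_rate(inflow, t), forcing = forcing)
  bdf_residual(sys$H, scheme, t, Y, history, Fdot)
}

fom_tangent <- function(sys, scheme, Y, exact = TRUE) {
  sys_tangent_matrix(sys, Y, convective = TRUE, newton_prime = exact,
                     scale_A = scheme$dt * scheme$beta,
                     scale_B = scheme$dt * scheme$beta, add_H = TRUE)
}

#' Run the coupled finite-element time loop
#'
#' BDF time integration of the coupled Navier-Stokes system with Newton
#' iteration per step. With `sigma = 2` the first step falls back to
#' backward Euler (one-state history); with the default start at `t_ramp`
#' the solution is still smooth there because the inflow ramps from zero.
#'
#' @param sys an `rbe_system`.
#' @param inflow an `rbe_inflow`.
#' @param T_end final time.
#' @param scheme an `rbe_bdf`.
#' @param t_start initial time (default `inflow$t_ramp`).
#' @param Y0 initial state (default zero).
#' @param newton_tol,newton_maxit Newton controls.
#' @param exact_tangent use the full convective linearization (default) or
#'   the frozen Stokes tangent.
#' @param stokes drop the convective term entirely (linear unsteady
#'   Stokes).
#' @param solver `"direct"` (monolithic sparse LU) or an
#'   `rbe_saddle_policy` from [saddle_policy()] for the block Schur
#'   preconditioned Krylov path.
#' @param forcing optional per-subdomain forcing list.
#' @param keep_states if `TRUE` (default) store the full trajectory.
#' @return object of class `rbe_trajectory`: `times`, `states` (one column
#'   per step, if kept), `diagnostics` data.frame.
#' @export
fom_time_loop <- function(sys, inflow, T_end, scheme = bdf_scheme(),
                          t_start = NULL, Y0 = NULL,
                          newton_tol = 1e-6, newton_maxit = 20L,
                          exact_tangent = TRUE, stokes = FALSE,
                          solver = "direct", forcing = NULL,
                          keep_states = TRUE) {
  if (is.null(t_start)) t_start <- inflow$t_ramp
  if (is.null(Y0)) Y0 <- numeric(sys$n)
  nt <- as.integer(round((T_end - t_start) / scheme$dt))
  times <- t_start + scheme$dt * (0:nt)
  history <- list(Y0)
  Y <- Y0
  states <- if (keep_states) matrix(0, sys$n, nt + 1L) else NULL
  if (keep_states) states[, 1L] <- Y0
  diag_rows <- vector("list", nt)
  lin_solver <- make_linear_solver(sys, solver)
  res_scale <- 0
  for (k in seq_len(nt)) {
    tk <- times[k + 1L]
    sch_k <- if (scheme$sigma == 2L && length(history) < 2L)
      bdf_scheme(1L, scheme$dt) else scheme
    resid <- function(Y) {
      r <- fom_residual(sys, sch_k, tk, Y, history, inflow, forcing)
      if (stokes) r <- r - sch_k$dt * sch_k$beta * conv_only_residual(sys, Y)
      r
    }
    tang <- function(Y) {
      if (stokes) {
        sys_tangent_matrix(sys, Y, convective = FALSE,
                           scale_A = sch_k$dt * sch_k$beta,
                           scale_B = sch_k$dt * sch_k$beta, add_H = TRUE)
      } else {
        fom_tangent(sys, sch_k, Y, exact = exact_tangent)
      }
    }
    ns <- newton_solve(resid, tang, Y, tol = newton_tol,
                       atol = newton_tol * res_scale,
                       maxit = newton_maxit, linear_solver = lin_solver)
    if (!ns$converged)
      stop("Newton failed to converge at step ", k, " (t = ", tk, ")")
    res_scale <- max(res_scale, ns$r0)
    Y <- ns$Y
    history <- c(list(Y), history)
    if (length(history) > 2L) history <- history[1:2]
    if (keep_states) states[, k + 1L] <- Y
    diag_rows[[k]] <- data.frame(step = k, t = tk, newton_iters = ns$iterations,
                                 rel_residual = if (length(ns$residuals))
                                   utils::tail(ns$residuals, 1L) else 0)
  }
  structure(list(times = times, states = states,
                 diagnostics = do.call(rbind, diag_rows), system = sys),
            class = "rbe_trajectory")
}

#' @export
print.rbe_trajectory <- function(x, ...) {
  cat(sprintf("<rbe_trajectory> %d steps, t in [%g, %g], mean Newton iters %.2f\n",
              nrow(x$diagnostics), min(x$times), max(x$times),
              mean(x$diagnostics$newton_iters)))
  invisible(x)
}

# Build the linear-solver callback used inside Newton.
make_linear_solver <- function(sys, solver) {
  if (identical(solver, "direct")) {
    function(J, r) as.numeric(Matrix::solve(J, r))
  } else if (inherits(solver, "rbe_saddle_policy")) {
    function(J, r) saddle_krylov_solve(sys, J, r, solver)$x
  } else {
    stop("unknown solver specification")
  }
}
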