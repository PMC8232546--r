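#' Piola pushforward of a reference velocity basis onto a subdomain
#'
#' Applies [piola_pushforward()] to every column (free velocity DOFs on
#' the reference block) and returns the basis on the deformed subdomain's
#' free DOFs.
#'
#' @param entry a block entry of an `rbe_archive`.
#' @param map the subdomain's `rbe_map`.
#' @return matrix of the same shape as `entry$Vu`.
#' @export
pushforward_basis <- function(entry, map) {
  space <- entry$space
  out <- entry$Vu
  for (c_i in seq_len(ncol(out))) {
    vfull <- numeric(space$nu)
    vfull[entry$ufree] <- entry$Vu[, c_i]
    out[, c_i] <- piola_pushforward(map, space, vfull)[entry$ufree]
  }
  out
}

#' Assemble the reduced coupled model for a target geometry
#'
#' Builds, per subdomain, the Piola-pushforward velocity basis, projects
#' the (deformed-mesh) FE operators onto the reduced spaces
#' (`M^N = V^T M V`, etc.; coupling matrices are projected on the velocity
#' side only, the multiplier space is kept at full size), and precomputes
#' the reduced convective tensor used by the truncated evaluation of the
#' convective term.
#'
#' @param sys the `rbe_system` of the target geometry (FE operators on the
#'   deformed subdomains).
#' @param archive an `rbe_archive` covering every block kind in the
#'   geometry (reference meshes must match).
#' @param Nc convective truncation size: `NULL` (default) keeps all modes;
#'   a single integer applies to every subdomain.
#' @param conv_strategy `"tensor"` (precomputed integrals, default) or
#'   `"project"` (assemble the full-order convective term each evaluation
#'   and project).
#' @return object of class `rbe_rom`.
#' @export
build_rom <- function(sys, archive, Nc = NULL,
                      conv_strategy = c("tensor", "project")) {
  conv_strategy <- match.arg(conv_strategy)
  ns <- length(sys$sub)
  sub <- vector("list", ns)
  for (j in seq_len(ns)) {
    sb <- sys$sub[[j]]
    entry <- archive$blocks[[sb$kind]]
    if (is.null(entry)) stop("archive has no basis for block kind ", sb$kind)
    if (!identical(mesh_fingerprint(sys$geometry$subdomains[[j]]$block$mesh),
                   entry$mesh_fp))
      stop("reference mesh of subdomain ", j, " does not match the archive")
    V <- pushforward_basis(entry, sys$geometry$subdomains[[j]]$map)
    Vp <- entry$Vp
    Nu <- ncol(V); Np <- ncol(Vp)
    Mn <- as.matrix(Matrix::crossprod(V, sb$Mff %*% V))
    Kn <- as.matrix(Matrix::crossprod(V, sb$Kff %*% V))
    Dn <- as.matrix(Matrix::crossprod(Vp, sb$Df %*% V))
    ncj <- if (is.null(Nc)) Nu else min(Nc, Nu)
    Tn <- NULL
    if (conv_strategy == "tensor") {
      Tn <- build_convective_tensor(sb, sys$props, V, ncj)
    }
    sub[[j]] <- list(V = V, Vp = Vp, Nu = Nu, Np = Np, nW = Nu + Np,
                     Mn = Mn, Kn = Kn, Dn = Dn, Tn = Tn, Nc = ncj,
                     kind = sb$kind)
  }
  Woff <- cumsum(c(0L, vapply(sub, `[[`, numeric(1), "nW")))
  nW <- Woff[ns + 1L]
  mult <- vector("list", length(sys$mult))
  for (i in seq_along(sys$mult)) {
    mi <- sys$mult[[i]]
    sides <- lapply(mi$sides, function(sd)
      list(j = sd$j, sign = sd$sign,
           Bn = as.matrix(sd$B %*% sub[[sd$j]]$V)))
    mult[[i]] <- list(type = mi$type, sides = sides, rhs_unit = mi$rhs_unit)
  }
  Loff <- nW + (seq_along(mult) - 1L) * sys$nl_per
  structure(list(sys = sys, archive = archive, sub = sub, mult = mult,
                 Woff = Woff, Loff = Loff, nW = nW, nl_per = sys$nl_per,
                 nL = sys$nL, n = nW + sys$nL,
                 conv_strategy = conv_strategy,
                 tangent_cache = new.env(parent = emptyenv())),
            class = "rbe_rom")
}

#' @export
print.rbe_rom <- function(x, ...) {
  cat(sprintf("<rbe_rom> %d subdomains, %d reduced DOFs + %d multipliers (convective: %s)\n",
              length(x$sub), x$nW, x$nL, x$conv_strategy))
  invisible(x)
}

#' Precomputed reduced convective tensor of one subdomain
#'
#' `T[i, l, m] = int rho_f [(zeta_m . grad) zeta_l] . zeta_i` for the
#' pushed-forward velocity basis `zeta`, with `l, m` limited to the first
#' `Nc` modes and `i` ranging over the full basis.
#'
#' @param sb subdomain entry of an `rbe_system` (fields `space`, `ufree`).
#' @param props fluid properties.
#' @param V reduced velocity basis on the free DOFs.
#' @param Nc truncation size (`0` gives an empty tensor, i.e. a vanishing
#'   convective contribution).
#' @return array of dim `(ncol(V), Nc, Nc)`.
#' @export
build_convective_tensor <- function(sb, props, V, Nc) {
  N <- ncol(V)
  if (Nc > N) stop("Nc exceeds the basis size")
  Tn <- array(0, c(N, Nc, Nc))
  if (Nc == 0L) return(Tn)
  for (m in seq_len(Nc)) {
    vfull <- numeric(sb$space$nu)
    vfull[sb$ufree] <- V[, m]
    Cm <- assemble_convective(sb$space, props, vfull)[sb$ufree, sb$ufree]
    Tn[, , m] <- as.matrix(Matrix::crossprod(V, Cm %*% V[, seq_len(Nc), drop = FALSE]))
  }
  Tn
}

# Convective part of the reduced residual for subdomain j at reduced
# velocity coefficients u.
rom_convective <- function(rom, j, u) {
  e <- rom$sub[[j]]
  if (rom$conv_strategy == "tensor") {
    nc <- min(e$Nc, dim(e$Tn)[2L])
    if (nc == 0L) return(numeric(e$Nu))
    ut <- u[seq_len(nc)]
    acc <- numeric(e$Nu)
    for (m in seq_len(nc)) {
      Tm <- matrix(e$Tn[, seq_len(nc), m], nrow = e$Nu)
      acc <- acc + u[m] * as.numeric(Tm %*% ut)
    }
    acc
  } else {
    sb <- rom$sys$sub[[j]]
    Vu <- as.numeric(e$V %*% u)
    vfull <- numeric(sb$space$nu)
    vfull[sb$ufree] <- Vu
    Cu <- assemble_convective(sb$space, rom$sys$props, vfull)[sb$ufree, sb$ufree]
    as.numeric(crossprod(e$V, as.numeric(Cu %*% Vu)))
  }
}

#' Reduced state-vector index helpers
#'
#' Analogues of [sys_u_idx()] for the reduced ordering: velocity and
#' pressure coefficients of subdomain `j`, and the multiplier block of
#' interface `i`.
#'
#' @param rom an `rbe_rom`.
#' @param j subdomain index.
#' @param i multiplier index.
#' @return integer index vector into a reduced state.
#' @export
rom_u_idx <- function(rom, j) rom$Woff[j] + seq_len(rom$sub[[j]]$Nu)

#' @rdname rom_u_idx
#' @export
rom_p_idx <- function(rom, j) rom$Woff[j] + rom$sub[[j]]$Nu + seq_len(rom$sub[[j]]$Np)

#' @rdname rom_u_idx
#' @export
rom_l_idx <- function(rom, i) rom$Loff[i] + seq_len(rom$nl_per)

# Steady reduced residual: [A^N(W) B^NT; B^N 0] Y - [0; G(t)].
rom_steady_residual <- function(rom, t, Y, Qt = NULL) {
  R <- numeric(rom$n)
  for (j in seq_along(rom$sub)) {
    e <- rom$sub[[j]]
    u <- Y[rom_u_idx(rom, j)]
    p <- Y[rom_p_idx(rom, j)]
    R[rom_u_idx(rom, j)] <- as.numeric(e$Kn %*% u) + rom_convective(rom, j, u) +
      as.numeric(crossprod(e$Dn, p))
    R[rom_p_idx(rom, j)] <- as.numeric(e$Dn %*% u)
  }
  for (i in seq_along(rom$mult)) {
    lam <- Y[rom_l_idx(rom, i)]
    mi <- rom$mult[[i]]
    cons <- numeric(rom$nl_per)
    for (sd in mi$sides) {
      u <- Y[rom_u_idx(rom, sd$j)]
      cons <- cons + as.numeric(sd$Bn %*% u)
      R[rom_u_idx(rom, sd$j)] <- R[rom_u_idx(rom, sd$j)] +
        as.numeric(crossprod(sd$Bn, lam))
    }
    if (mi$type == "inlet") cons <- cons - (if (is.null(Qt)) 0 else Qt) * mi$rhs_unit
    R[rom_l_idx(rom, i)] <- cons
  }
  R
}

rom_residual <- function(rom, scheme, t, Y, history, inflow) {
  acc <- Y
  for (j in seq_len(scheme$sigma)) acc <- acc - scheme$alpha[j] * history[[j]]
  R <- numeric(rom$n)
  for (j in seq_along(rom$sub)) {
    idx <- rom_u_idx(rom, j)
    R[idx] <- as.numeric(rom$sub[[j]]$Mn %*% acc[idx])
  }
  R + scheme$dt * scheme$beta *
    rom_steady_residual(rom, t, Y, Qt = inflow_rate(inflow, t))
}

# Frozen (Stokes-linearized) reduced tangent, factorized via the block
# Schur decomposition over the multipliers; cached per (dt * beta).
rom_frozen_tangent <- function(rom, scheme) {
  key <- sprintf("%.16e", scheme$dt * scheme$beta)
  cache <- rom$tangent_cache
  if (!is.null(cache[[key]])) return(cache[[key]])
  g <- scheme$dt * scheme$beta
  Ainv <- vector("list", length(rom$sub))
  for (j in seq_along(rom$sub)) {
    e <- rom$sub[[j]]
    At <- rbind(cbind(e$Mn + g * e$Kn, g * t(e$Dn)),
                cbind(g * e$Dn, matrix(0, e$Np, e$Np)))
    Ainv[[j]] <- qr(At)
  }
  widx_of <- function(j) rom$Woff[j] + seq_len(rom$sub[[j]]$nW)
  # dense multiplier coupling rows (scaled)
  Bg <- matrix(0, rom$nL, rom$nW)
  for (i in seq_along(rom$mult)) {
    rows <- (i - 1L) * rom$nl_per + seq_len(rom$nl_per)
    for (sd in rom$mult[[i]]$sides) {
      cols <- rom$Woff[sd$j] + seq_len(rom$sub[[sd$j]]$Nu)
      Bg[rows, cols] <- Bg[rows, cols] + g * sd$Bn
    }
  }
  apply_Ainv <- function(v) {
    out <- numeric(rom$nW)
    for (j in seq_along(rom$sub)) {
      idx <- widx_of(j)
      out[idx] <- qr.solve(Ainv[[j]], v[idx])
    }
    out
  }
  S <- matrix(0, rom$nL, rom$nL)
  if (rom$nL) {
    for (l in seq_len(rom$nL)) S[, l] <- -Bg %*% apply_Ainv(Bg[l, ])
  }
  qrS <- if (rom$nL) qr(S) else NULL
  solver <- function(rhs) {
    bw <- rhs[seq_len(rom$nW)]
    zw <- apply_Ainv(bw)
    if (rom$nL) {
      bl <- rhs[rom$nW + seq_len(rom$nL)]
      xl <- qr.solve(qrS, bl - as.numeric(Bg %*% zw))
      xw <- zw - apply_Ainv(as.numeric(crossprod(Bg, xl)))
      c(xw, xl)
    } else {
      zw
    }
  }
  cache[[key]] <- solver
  solver
}

# Exact reduced tangent (dense), for debugging Newton convergence.
rom_exact_tangent <- function(rom, scheme, Y) {
  g <- scheme$dt * scheme$beta
  n <- rom$n
  J <- matrix(0, n, n)
  for (j in seq_along(rom$sub)) {
    e <- rom$sub[[j]]
    ui <- rom_u_idx(rom, j); pi_ <- rom_p_idx(rom, j)
    sb <- rom$sys$sub[[j]]
    vfull <- numeric(sb$space$nu)
    vfull[sb$ufree] <- as.numeric(e$V %*% Y[ui])
    Cf <- assemble_convective(sb$space, rom$sys$props, vfull)[sb$ufree, sb$ufree] +
      assemble_convective_prime(sb$space, rom$sys$props, vfull)[sb$ufree, sb$ufree]
    Cn <- as.matrix(Matrix::crossprod(e$V, Cf %*% e$V))
    J[ui, ui] <- e$Mn + g * (e$Kn + Cn)
    J[ui, pi_] <- g * t(e$Dn)
    J[pi_, ui] <- g * e$Dn
  }
  for (i in seq_along(rom$mult)) {
    li <- rom_l_idx(rom, i)
    for (sd in rom$mult[[i]]$sides) {
      ui <- rom_u_idx(rom, sd$j)
      J[li, ui] <- J[li, ui] + g * sd$Bn
      J[ui, li] <- J[ui, li] + g * t(sd$Bn)
    }
  }
  J
}

#' Run the reduced-order time loop
#'
#' BDF/Newton time integration of the reduced coupled system. By default
#' Newton uses the frozen Stokes tangent (constant in time, factorized
#' once per `dt * beta` through the reduced Schur-complement
#' decomposition), which converges linearly; the exact reduced tangent is
#' available for debugging.
#'
#' @param rom an `rbe_rom`.
#' @param inflow an `rbe_inflow`.
#' @param T_end final time.
#' @param scheme an `rbe_bdf`.
#' @param t_start start time (default `inflow$t_ramp`).
#' @param newton_tol,newton_maxit Newton controls.
#' @param frozen_tangent use the frozen tangent (default) or the exact one.
#' @return `rbe_rom_trajectory`: reduced `states` (one column per step),
#'   `times`, `diagnostics`.
#' @export
rom_time_loop <- function(rom, inflow, T_end, scheme = bdf_scheme(),
                          t_start = NULL, newton_tol = 1e-8,
                          newton_maxit = 60L, frozen_tangent = TRUE) {
  if (is.null(t_start)) t_start <- inflow$t_ramp
  nt <- as.integer(round((T_end - t_start) / scheme$dt))
  times <- t_start + scheme$dt * (0:nt)
  Y <- numeric(rom$n)
  states <- matrix(0, rom$n, nt + 1L)
  history <- list(Y)
  diag_rows <- vector("list", nt)
  res_scale <- 0
  for (k in seq_len(nt)) {
    tk <- times[k + 1L]
    sch_k <- if (scheme$sigma == 2L && length(history) < 2L)
      bdf_scheme(1L, scheme$dt) else scheme
    solver <- if (frozen_tangent) rom_frozen_tangent(rom, sch_k) else NULL
    resid <- function(Y) rom_residual(rom, sch_k, tk, Y, history, inflow)
    if (frozen_tangent) {
      ns <- newton_solve(resid, function(Y) NULL, Y, tol = newton_tol,
                         atol = newton_tol * res_scale, maxit = newton_maxit,
                         linear_solver = function(J, r) solver(r))
    } else {
      ns <- newton_solve(resid, function(Y) rom_exact_tangent(rom, sch_k, Y),
                         Y, tol = newton_tol, atol = newton_tol * res_scale,
                         maxit = newton_maxit,
                         linear_solver = function(J, r) solve(J, r))
    }
    if (!ns$converged)
      stop("reduced Newton failed at step ", k, " (t = ", tk, ")")
    res_scale <- max(res_scale, ns$r0)
    Y <- ns$Y
    history <- c(list(Y), history)
    if (length(history) > 2L) history <- history[1:2]
    states[, k + 1L] <- Y
    diag_rows[[k]] <- data.frame(step = k, t = tk, newton_iters = ns$iterations,
                                 rel_residual = if (length(ns$residuals))
                                   utils::tail(ns$residuals, 1L) else 0)
  }
  structure(list(times = times, states = states,
                 diagnostics = do.call(rbind, diag_rows), rom = rom),
            class = "rbe_rom_trajectory")
}

#' @export
print.rbe_rom_trajectory <- function(x, ...) {
  cat(sprintf("<rbe_rom_trajectory> %d steps, mean Newton iters %.2f\n",
              nrow(x$diagnostics), mean(x$diagnostics$newton_iters)))
  invisible(x)
}

#' Reconstruct FE fields from a reduced state
#'
#' @param rom an `rbe_rom`.
#' @param Y reduced state vector.
#' @return the corresponding FE state over the `(W)` ordering of the
#'   underlying `rbe_system` (free velocity DOFs and pressures per
#'   subdomain); multipliers are appended unchanged.
#' @export
rom_reconstruct <- function(rom, Y) {
  sys <- rom$sys
  W <- numeric(sys$n)
  for (j in seq_along(rom$sub)) {
    e <- rom$sub[[j]]
    W[sys_u_idx(sys, j)] <- as.numeric(e$V %*% Y[rom_u_idx(rom, j)])
    W[sys_p_idx(sys, j)] <- as.numeric(e$Vp %*% Y[rom_p_idx(rom, j)])
  }
  if (rom$nL) W[sys$nW + seq_len(sys$nL)] <- Y[rom$nW + seq_len(rom$nL)]
  W
}

#' @rdname rom_reconstruct
#' @param traj an `rbe_rom_trajectory`.
#' @export
rom_reconstruct_states <- function(rom, traj) {
  out <- matrix(0, rom$sys$n, ncol(traj$states))
  for (k in seq_len(ncol(traj$states)))
    out[, k] <- rom_reconstruct(rom, traj$states[, k])
  out
}

#' Time-integrated relative broken-norm errors
#'
#' `e_u^2 = int ||u_ref - u_test||_b^2 dt / int ||u_ref||_b^2 dt` with the
#' broken H^1 velocity norm (root sum of per-subdomain squared norms), and
#' the analogous `e_p` with the broken L^2 pressure norm. Time integration
#' is trapezoidal over the common timesteps.
#'
#' @param sys the underlying `rbe_system`.
#' @param times common time vector.
#' @param W_ref,W_test state matrices over the system ordering (columns =
#'   timesteps); multiplier rows are ignored.
#' @param t_min only times `>= t_min` enter the integrals (default: all).
#' @return object of class `rbe_error_report` with `e_u`, `e_p` and
#'   per-timestep traces.
#' @export
broken_norm_errors <- function(sys, times, W_ref, W_test, t_min = -Inf) {
  stopifnot(ncol(W_ref) == length(times), ncol(W_test) == length(times))
  keep <- which(times >= t_min)
  tw <- trapezoid_weights(times[keep])
  num_u <- den_u <- num_p <- den_p <- 0
  tr_u <- numeric(length(keep)); tr_p <- numeric(length(keep))
  for (ki in seq_along(keep)) {
    k <- keep[ki]
    su <- du <- sp <- dp <- 0
    for (j in seq_along(sys$sub)) {
      sb <- sys$sub[[j]]
      ur <- W_ref[sys_u_idx(sys, j), k]; ut <- W_test[sys_u_idx(sys, j), k]
      pr <- W_ref[sys_p_idx(sys, j), k]; pt <- W_test[sys_p_idx(sys, j), k]
      e <- ur - ut
      du <- du + sum(e * as.numeric(sb$Xuff %*% e))
      su <- su + sum(ur * as.numeric(sb$Xuff %*% ur))
      ep <- pr - pt
      dp <- dp + sum(ep * as.numeric(sb$ops$Xp %*% ep))
      sp <- sp + sum(pr * as.numeric(sb$ops$Xp %*% pr))
    }
    num_u <- num_u + tw[ki] * du; den_u <- den_u + tw[ki] * su
    num_p <- num_p + tw[ki] * dp; den_p <- den_p + tw[ki] * sp
    tr_u[ki] <- sqrt(du); tr_p[ki] <- sqrt(dp)
  }
  structure(list(e_u = sqrt(num_u / den_u), e_p = sqrt(num_p / den_p),
                 times = times[keep], trace_u = tr_u, trace_p = tr_p),
            class = "rbe_error_report")
}

#' @export
print.rbe_error_report <- function(x, ...) {
  cat(sprintf("<rbe_error_report> e_u = %.4g, e_p = %.4g over %d timesteps\n",
              x$e_u, x$e_p, length(x$times)))
  invisible(x)
}

trapezoid_weights <- function(t) {
  n <- length(t)
  if (n == 1L) return(1)
  w <- numeric(n)
  dt <- diff(t)
  w[1L] <- dt[1L] / 2
  w[n] <- dt[n - 1L] / 2
  if (n > 2L) w[2:(n - 1L)] <- (dt[-length(dt)] + dt[-1L]) / 2
  w
}

#' Time-averaged reduced velocity coefficient magnitudes
#'
#' Average over timesteps of `|u_i^N|`, normalized by the first
#' coefficient, per subdomain — the decay diagnostic justifying the
#' truncation of the convective tensor.
#'
#' @param rom an `rbe_rom`.
#' @param traj an `rbe_rom_trajectory`.
#' @param t_min only times `>= t_min` enter the average.
#' @return list of numeric vectors, one per subdomain.
#' @export
coefficient_decay <- function(rom, traj, t_min = -Inf) {
  keep <- which(traj$times >= t_min)
  lapply(seq_along(rom$sub), function(j) {
    M <- abs(traj$states[rom_u_idx(rom, j), keep, drop = FALSE])
    avg <- rowMeans(M)
    avg / avg[1L]
  })
}
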