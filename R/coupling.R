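#' Coupling matrix between a multiplier basis and a subdomain trace
#'
#' Computes `B_pq = sign * int_Gamma xi_p . phi_q` by quadrature over the
#' boundary facets of the side mesh carrying `tag`. One-sided: no
#' information from the opposite side of the interface is used.
#'
#' @param space an `rbe_space` for the side subdomain.
#' @param basis an `rbe_interface_basis` (`d = 2`).
#' @param interface interface descriptor (fields `centre`, `normal`,
#'   `radius`) of the physical interface.
#' @param tag boundary tag identifying the interface facets on the side
#'   mesh.
#' @param sign orientation sign `c = +/-1`.
#' @param nq number of Gauss points per facet.
#' @return sparse `N_lambda x nu` matrix.
#' @export
assemble_interface_coupling <- function(space, basis, interface, tag,
                                        sign = 1, nq = 8L) {
  fi <- space$facet_info
  sel <- which(fi$tag == tag)
  if (!length(sel)) stop("interface facets with tag '", tag, "' not found on the side mesh")
  mapped <- map_to_interface(basis, interface, sign)
  g <- pracma::gaussLegendre(nq, 0, 1)
  nsc <- space$n_scalar
  nm <- basis$n_scalar
  # trace shape functions at the facet quadrature points
  trN <- cbind((1 - g$x) * (1 - 2 * g$x), g$x * (2 * g$x - 1), 4 * g$x * (1 - g$x))
  ii <- list(); jj <- list(); xx <- list()
  for (f in sel) {
    pa <- fi$pa[f, ]; pb <- fi$pb[f, ]
    pts <- cbind(pa[1L] + g$x * (pb[1L] - pa[1L]), pa[2L] + g$x * (pb[2L] - pa[2L]))
    s <- as.numeric(mapped$theta_inv(pts))
    wq <- g$w * fi$length[f]
    dofs <- c(fi$a[f], fi$b[f], fi$mid_dof[f])
    scal <- vapply(seq_len(nm), function(m)
      ridge_polynomial(basis$scalar_modes$degree[m], basis$scalar_modes$k[m], s),
      numeric(nq))
    loc <- crossprod(scal * wq, trN)  # nm x 3
    for (comp in 1:2) {
      rows <- (comp - 1L) * nm + seq_len(nm)
      cols <- (comp - 1L) * nsc + dofs
      ii[[length(ii) + 1L]] <- rep(rows, times = 3L)
      jj[[length(jj) + 1L]] <- rep(cols, each = nm)
      xx[[length(xx) + 1L]] <- as.numeric(loc)
    }
  }
  sign * Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                              dims = c(basis$n_lambda, space$nu))
}

#' Parabolic inflow profile
#'
#' Velocity profile normal to the inlet, zero at the rim, with prescribed
#' total flux `Q` (positive = into the domain, i.e. opposite to the outward
#' normal). In 2D (per unit depth) the peak speed is `3 Q / (4 R)` for
#' half-width `R`.
#'
#' @param interface inlet descriptor (fields `centre`, `normal` (outward),
#'   `radius`).
#' @param Q flow rate.
#' @return function of an `n x 2` coordinate matrix returning `n x 2`
#'   velocity values.
#' @export
parabolic_inflow <- function(interface, Q) {
  if (interface$radius <= 0) stop("degenerate inlet: zero radius")
  ctr <- interface$centre; nrm <- interface$normal; R <- interface$radius
  tang <- c(nrm[2L], -nrm[1L])
  umax <- parabolic_peak(Q, R, d = 2L)
  function(X) {
    s <- (sweep(X, 2L, ctr) %*% tang) / R
    mag <- umax * pmax(0, 1 - s^2)
    cbind(-mag * nrm[1L], -mag * nrm[2L])
  }
}

#' Peak speed of a parabolic profile with prescribed flux
#'
#' `3Q/(4R)` in 2D (per unit depth, half-width `R`); `2Q/(pi R^2)` in 3D
#' (circular section of radius `R`).
#'
#' @param Q flow rate.
#' @param R inlet radius / half-width.
#' @param d spatial dimension.
#' @return peak (centreline) speed.
#' @export
parabolic_peak <- function(Q, R, d = 2L) {
  if (R <= 0) stop("degenerate inlet: zero radius")
  if (d == 2L) 3 * Q / (4 * R) else 2 * Q / (pi * R^2)
}

#' Weak inlet Dirichlet data
#'
#' Builds the inlet coupling matrix (multiplier basis against the inlet
#' traces, sign +1) and the interpolated inlet profile DOF vector for unit
#' flow rate; the constraint is `B_in u = Q(t) * (B_in g_unit)`.
#'
#' @param space side subdomain space.
#' @param basis multiplier basis.
#' @param interface inlet descriptor.
#' @param tag boundary tag of the inlet on the side mesh.
#' @return list with `B` (sparse), `g_unit` (DOF vector for `Q = 1`),
#'   `rhs_unit = B %*% g_unit`.
#' @export
assemble_inlet_coupling <- function(space, basis, interface, tag) {
  B <- assemble_interface_coupling(space, basis, interface, tag, sign = 1)
  g_unit <- interpolate_velocity(space, parabolic_inflow(interface, 1))
  list(B = B, g_unit = g_unit, rhs_unit = as.numeric(B %*% g_unit))
}

#' Assemble the global coupled block system
#'
#' Builds, for every subdomain, the Taylor-Hood space and constant
#' operators on its deformed mesh (wall no-slip eliminated strongly), the
#' coupling matrices of every internal interface (one per side, the lower
#' subdomain index being the "+" side) and of every inlet, and the global
#' block bookkeeping: unknown ordering `(u^1, p^1, ..., u^N, p^N,
#' lambda^[1], ..., lambda_in^[1], ...)`, the block mass `H`, and
#' right-hand-side builders.
#'
#' @param geometry an `rbe_geometry`.
#' @param basis an `rbe_interface_basis` (`d = 2`).
#' @param props an `rbe_fluid`.
#' @param resolution ignored (meshes already live on the geometry).
#' @return an object of class `rbe_system`.
#' @export
assemble_global_system <- function(geometry, basis, props = fluid_properties()) {
  ns <- length(geometry$subdomains)
  sub <- vector("list", ns)
  for (j in seq_len(ns)) {
    sd <- geometry$subdomains[[j]]
    space <- build_taylor_hood_space(sd$mesh)
    ops <- assemble_constant_operators(space, props)
    wall <- space$boundary[[sd$block$wall_tag]]
    ufree_sc <- setdiff(seq_len(space$n_scalar), wall)
    ufree <- c(ufree_sc, space$n_scalar + ufree_sc)
    nf <- length(ufree)
    sub[[j]] <- list(space = space, ops = ops, ufree = ufree, nf = nf,
                     np = space$np, nW = nf + space$np,
                     Mff = ops$M[ufree, ufree], Kff = ops$K[ufree, ufree],
                     Df = ops$D[, ufree, drop = FALSE],
                     Xuff = ops$Xu[ufree, ufree], kind = sd$block$kind)
  }
  Woff <- cumsum(c(0L, vapply(sub, `[[`, numeric(1), "nW")))
  nW <- Woff[ns + 1L]
  mult <- list()
  for (ifc in geometry$interfaces) {
    sides <- list()
    for (side in list(c(ifc$plus, sign = 1), c(ifc$minus, sign = -1))) {
      j <- side$sub
      B <- assemble_interface_coupling(sub[[j]]$space, basis, ifc$desc,
                                       side$name, sign = side$sign)
      sides[[length(sides) + 1L]] <- list(j = j, sign = side$sign,
                                          B = B[, sub[[j]]$ufree, drop = FALSE])
    }
    mult[[length(mult) + 1L]] <- list(type = "internal", desc = ifc$desc,
                                      sides = sides, rhs_unit = NULL)
  }
  for (inl in geometry$inlets) {
    j <- inl$sub
    ic <- assemble_inlet_coupling(sub[[j]]$space, basis, inl$desc, inl$name)
    mult[[length(mult) + 1L]] <- list(
      type = "inlet", desc = inl$desc,
      sides = list(list(j = j, sign = 1, B = ic$B[, sub[[j]]$ufree, drop = FALSE])),
      rhs_unit = ic$rhs_unit, g_unit = ic$g_unit)
  }
  nl <- basis$n_lambda
  # feasibility: each interface must offer at least N_lambda free trace
  # DOFs, otherwise the constraint block is rank deficient
  for (mi in mult) {
    nfree_trace <- sum(vapply(mi$sides, function(sd)
      sum(Matrix::colSums(abs(sd$B)) > 0), 0L))
    if (nfree_trace < nl)
      stop("interface '", mi$desc$name, "' has only ", nfree_trace,
           " free trace DOFs for ", nl,
           " multiplier basis functions; refine the mesh or lower the degree")
  }
  Loff <- nW + (seq_along(mult) - 1L) * nl
  Hd <- numeric(nW + length(mult) * nl)
  # H carries the (density-weighted) velocity mass; zero for p and lambda
  Hblocks <- vector("list", ns)
  for (j in seq_len(ns)) {
    z1 <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                               dims = c(sub[[j]]$np, sub[[j]]$np))
    Hblocks[[j]] <- Matrix::bdiag(sub[[j]]$Mff, z1)
  }
  zl <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(length(mult) * nl, length(mult) * nl))
  H <- Matrix::bdiag(c(Hblocks, list(zl)))
  structure(list(geometry = geometry, basis = basis, props = props,
                 sub = sub, mult = mult, Woff = Woff, Loff = Loff,
                 nW = nW, nl_per = nl, nL = length(mult) * nl,
                 n = nW + length(mult) * nl,
                 H = methods::as(H, "CsparseMatrix")),
            class = "rbe_system")
}

#' @export
print.rbe_system <- function(x, ...) {
  cat(sprintf("<rbe_system> %d subdomains, %d velocity+pressure DOFs, %d multiplier DOFs (%d interfaces x %d)\n",
              length(x$sub), x$nW, x$nL, length(x$mult), x$nl_per))
  invisible(x)
}

# --- indexing helpers ------------------------------------------------------

#' State-vector index helpers
#'
#' Locate the blocks of the global unknown ordering `(u^1, p^1, ...,
#' lambda^[1], ...)`: velocity+pressure of subdomain `j` (`sys_w_idx`),
#' its free velocity (`sys_u_idx`) or pressure (`sys_p_idx`) DOFs, and the
#' multiplier block of interface `i` (`sys_l_idx`).
#'
#' @param sys an `rbe_system`.
#' @param j subdomain index.
#' @param i multiplier (interface) index.
#' @return integer index vector into a global state.
#' @export
sys_w_idx <- function(sys, j) sys$Woff[j] + seq_len(sys$sub[[j]]$nW)

#' @rdname sys_w_idx
#' @export
sys_u_idx <- function(sys, j) sys$Woff[j] + seq_len(sys$sub[[j]]$nf)

#' @rdname sys_w_idx
#' @export
sys_p_idx <- function(sys, j) sys$Woff[j] + sys$sub[[j]]$nf + seq_len(sys$sub[[j]]$np)

#' @rdname sys_w_idx
#' @export
sys_l_idx <- function(sys, i) sys$Loff[i] + seq_len(sys$nl_per)

#' Full-length velocity DOF vector of a subdomain
#'
#' Expands the free (non-wall) velocity DOFs of subdomain `j` stored in a
#' global state `Y` into a full-length vector with zeros on the wall.
#'
#' @param sys an `rbe_system`.
#' @param j subdomain index.
#' @param Y global state vector.
#' @return numeric vector of length `sys$sub[[j]]$space$nu`.
#' @export
sys_full_u <- function(sys, j, Y) {
  u <- numeric(sys$sub[[j]]$space$nu)
  u[sys$sub[[j]]$ufree] <- Y[sys_u_idx(sys, j)]
  u
}

# Stationary operator application: [A(W) B^T; B 0] Y - [F(t); G(t)].
# Returns the steady residual; `forcing` is an optional list of per-
# subdomain functions f(X, t) -> n x 2.
sys_steady_residual <- function(sys, t, Y, Qt = NULL, forcing = NULL) {
  R <- numeric(sys$n)
  for (j in seq_along(sys$sub)) {
    sb <- sys$sub[[j]]
    uf <- Y[sys_u_idx(sys, j)]
    p <- Y[sys_p_idx(sys, j)]
    ufull <- sys_full_u(sys, j, Y)
    Cu <- assemble_convective(sb$space, sys$props, ufull)[sb$ufree, sb$ufree]
    rm <- as.numeric(sb$Kff %*% uf) + as.numeric(Cu %*% uf) +
          as.numeric(Matrix::crossprod(sb$Df, p))
    if (!is.null(forcing) && !is.null(forcing[[j]])) {
      fv <- assemble_load_vector(sb$space, function(X) forcing[[j]](X, t))
      rm <- rm - fv[sb$ufree]
    }
    R[sys_u_idx(sys, j)] <- rm
    R[sys_p_idx(sys, j)] <- as.numeric(sb$Df %*% uf)
  }
  for (i in seq_along(sys$mult)) {
    lam <- Y[sys_l_idx(sys, i)]
    mi <- sys$mult[[i]]
    cons <- numeric(sys$nl_per)
    for (sd in mi$sides) {
      uf <- Y[sys_u_idx(sys, sd$j)]
      cons <- cons + as.numeric(sd$B %*% uf)
      R[sys_u_idx(sys, sd$j)] <- R[sys_u_idx(sys, sd$j)] +
        as.numeric(Matrix::crossprod(sd$B, lam))
    }
    if (mi$type == "inlet") {
      q <- if (is.null(Qt)) 0 else Qt
      cons <- cons - q * mi$rhs_unit
    }
    R[sys_l_idx(sys, i)] <- cons
  }
  R
}

# Assemble the sparse global tangent of the steady operator at state Y:
# [[K + C(u) + C'(u), D^T, B^T], [D, 0, 0], [B, 0, 0]] (signs included in B).
# With convective = FALSE (or newton_prime = FALSE) the corresponding terms
# are dropped; `scale_A`/`scale_B` premultiply the blocks (used by the BDF
# tangent, where A and B carry a factor dt*beta).
sys_tangent_matrix <- function(sys, Y = NULL, convective = TRUE,
                               newton_prime = TRUE, scale_A = 1, scale_B = 1,
                               add_H = FALSE) {
  blocks <- vector("list", length(sys$sub))
  for (j in seq_along(sys$sub)) {
    sb <- sys$sub[[j]]
    Auu <- sb$Kff
    if (convective && !is.null(Y)) {
      ufull <- sys_full_u(sys, j, Y)
      Auu <- Auu + assemble_convective(sb$space, sys$props, ufull)[sb$ufree, sb$ufree]
      if (newton_prime)
        Auu <- Auu + assemble_convective_prime(sb$space, sys$props, ufull)[sb$ufree, sb$ufree]
    }
    zp <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                               dims = c(sb$np, sb$np))
    Ablk <- scale_A * rbind(cbind(Auu, Matrix::t(sb$Df)), cbind(sb$Df, zp))
    if (add_H) Ablk <- Ablk + Matrix::bdiag(sb$Mff, zp)
    blocks[[j]] <- Ablk
  }
  A <- Matrix::bdiag(blocks)
  # multiplier coupling rows
  trip_i <- list(); trip_j <- list(); trip_x <- list()
  for (i in seq_along(sys$mult)) {
    rows <- sys_l_idx(sys, i)
    for (sd in sys$mult[[i]]$sides) {
      Bs <- methods::as(sd$B, "TsparseMatrix")
      trip_i[[length(trip_i) + 1L]] <- rows[1L] - 1L + Bs@i + 1L
      trip_j[[length(trip_j) + 1L]] <- sys$Woff[sd$j] + Bs@j + 1L
      trip_x[[length(trip_x) + 1L]] <- Bs@x
    }
  }
  if (length(trip_i)) {
    Bg <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                               x = unlist(trip_x), dims = c(sys$n, sys$n))
    Bg <- scale_B * Bg
    M <- Matrix::bdiag(A, Matrix::sparseMatrix(
      i = integer(0), j = integer(0), x = numeric(0),
      dims = c(sys$nL, sys$nL)))
    M <- M + Bg + Matrix::t(Bg)
  } else {
    M <- A
  }
  methods::as(M, "CsparseMatrix")
}

#' Steady coupled solve
#'
#' Solves the stationary coupled problem (Stokes or Navier-Stokes) with a
#' prescribed constant inflow rate by Newton iteration on the steady
#' residual, using a monolithic sparse direct solve per iteration.
#'
#' @param sys an `rbe_system`.
#' @param Q inflow flow rate.
#' @param stokes if `TRUE`, omit the convective term (linear solve).
#' @param tol relative Newton tolerance.
#' @param maxit maximum Newton iterations.
#' @param forcing optional per-subdomain forcing functions `f(X, t)`.
#' @return list with the state vector `Y` and Newton diagnostics.
#' @export
solve_steady <- function(sys, Q, stokes = FALSE, tol = 1e-10, maxit = 25L,
                         forcing = NULL) {
  Y <- numeric(sys$n)
  res <- function(Y) {
    r <- sys_steady_residual(sys, 0, Y, Qt = Q, forcing = forcing)
    if (stokes) {
      # remove the convective contribution by recomputing without it
      r <- r - conv_only_residual(sys, Y)
    }
    r
  }
  r <- res(Y)
  r0 <- sqrt(sum(r^2))
  if (r0 == 0) r0 <- 1
  hist <- numeric(0)
  for (it in seq_len(maxit)) {
    J <- sys_tangent_matrix(sys, Y, convective = !stokes)
    Y <- Y - as.numeric(Matrix::solve(J, r))
    r <- res(Y)
    hist <- c(hist, sqrt(sum(r^2)) / r0)
    if (hist[it] < tol) break
  }
  list(Y = Y, iterations = length(hist), residuals = hist,
       converged = utils::tail(hist, 1L) < tol)
}

conv_only_residual <- function(sys, Y) {
  R <- numeric(sys$n)
  for (j in seq_along(sys$sub)) {
    sb <- sys$sub[[j]]
    ufull <- sys_full_u(sys, j, Y)
    Cu <- assemble_convective(sb$space, sys$props, ufull)[sb$ufree, sb$ufree]
    R[sys_u_idx(sys, j)] <- as.numeric(Cu %*% Y[sys_u_idx(sys, j)])
  }
  R
}

#' Flux of a subdomain velocity through a tagged boundary
#'
#' @param space an `rbe_space`.
#' @param u full-length velocity DOF vector.
#' @param tag boundary tag.
#' @return net outward flux `int u . n`.
#' @export
boundary_flux <- function(space, u, tag) {
  fi <- space$facet_info
  sel <- which(fi$tag == tag)
  if (!length(sel)) stop("no facets tagged '", tag, "'")
  g <- pracma::gaussLegendre(6L, 0, 1)
  trN <- cbind((1 - g$x) * (1 - 2 * g$x), g$x * (2 * g$x - 1), 4 * g$x * (1 - g$x))
  nsc <- space$n_scalar
  tot <- 0
  for (f in sel) {
    dofs <- c(fi$a[f], fi$b[f], fi$mid_dof[f])
    un <- (trN %*% u[dofs]) * fi$normal[f, 1L] +
          (trN %*% u[nsc + dofs]) * fi$normal[f, 2L]
    tot <- tot + sum(g$w * un) * fi$length[f]
  }
  tot
}
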