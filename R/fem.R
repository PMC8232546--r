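#' Fluid properties
#'
#' Density and dynamic viscosity in CGS units. Defaults are typical values
#' for blood.
#'
#' @param rho_f density (g cm^-3).
#' @param mu_f dynamic viscosity (g cm^-1 s^-1).
#' @return an object of class `rbe_fluid`.
#' @export
fluid_properties <- function(rho_f = 1.06, mu_f = 4e-2) {
  stopifnot(rho_f > 0, mu_f > 0)
  structure(list(rho_f = rho_f, mu_f = mu_f), class = "rbe_fluid")
}

# Degree-5 (7 point) quadrature on the reference triangle; weights sum to
# 1/2 = reference area, so physical integrals are sum(w * detJ * f).
triangle_quadrature <- function() {
  a1 <- 0.0597158717897698; b1 <- 0.4701420641051151
  a2 <- 0.7974269853530873; b2 <- 0.1012865073234563
  lam <- rbind(c(1, 1, 1) / 3,
               c(a1, b1, b1), c(b1, a1, b1), c(b1, b1, a1),
               c(a2, b2, b2), c(b2, a2, b2), c(b2, b2, a2))
  w <- c(9 / 40, rep(0.1323941527885062, 3L), rep(0.1259391805448271, 3L)) / 2
  list(lambda = lam, w = w)
}

# P2 shape functions and reference gradients at barycentric points.
# Local dof order: vertices 1,2,3 then midpoints of edges (2,3),(3,1),(1,2).
p2_shape <- function(lam) {
  l1 <- lam[, 1L]; l2 <- lam[, 2L]; l3 <- lam[, 3L]
  N <- cbind(l1 * (2 * l1 - 1), l2 * (2 * l2 - 1), l3 * (2 * l3 - 1),
             4 * l2 * l3, 4 * l3 * l1, 4 * l1 * l2)
  # gradients w.r.t. reference coords (xi, eta): l1 = 1-xi-eta, l2 = xi, l3 = eta
  dl <- rbind(c(-1, -1), c(1, 0), c(0, 1))
  G <- array(0, c(nrow(lam), 6L, 2L))
  for (b in 1:2) {
    G[, 1L, b] <- (4 * l1 - 1) * dl[1L, b]
    G[, 2L, b] <- (4 * l2 - 1) * dl[2L, b]
    G[, 3L, b] <- (4 * l3 - 1) * dl[3L, b]
    G[, 4L, b] <- 4 * (l3 * dl[2L, b] + l2 * dl[3L, b])
    G[, 5L, b] <- 4 * (l1 * dl[3L, b] + l3 * dl[1L, b])
    G[, 6L, b] <- 4 * (l2 * dl[1L, b] + l1 * dl[2L, b])
  }
  list(N = N, G = G)
}

#' Taylor-Hood P2-P1 space on a simplicial mesh
#'
#' Velocity: continuous piecewise quadratics (scalar DOFs at vertices and
#' edge midpoints), vector-valued with component-blocked DOF ordering (all
#' x-component DOFs first, then y). Pressure: continuous piecewise linears
#' at the vertices. For 2D meshes the returned object also carries the
#' precomputed per-element quadrature data used by the assembly routines;
#' for 3D meshes only the DOF bookkeeping is provided.
#'
#' @param mesh an `rbe_mesh` with tagged boundary facets.
#' @return an object of class `rbe_space` with (among others) fields
#'   `n_scalar`, `nu` (velocity DOFs), `np` (pressure DOFs), `elemdof`,
#'   `dof_coords`, `boundary` (per-tag scalar DOF sets) and `facet_info`.
#' @export
build_taylor_hood_space <- function(mesh) {
  d <- mesh$dim
  nv <- nrow(mesh$nodes)
  el <- mesh$elems
  ne <- nrow(el)
  if (d == 2L) {
    eraw <- rbind(el[, c(2L, 3L)], el[, c(3L, 1L)], el[, c(1L, 2L)])
  } else {
    eraw <- rbind(el[, c(1L, 2L)], el[, c(1L, 3L)], el[, c(1L, 4L)],
                  el[, c(2L, 3L)], el[, c(2L, 4L)], el[, c(3L, 4L)])
  }
  esort <- cbind(pmin(eraw[, 1L], eraw[, 2L]), pmax(eraw[, 1L], eraw[, 2L]))
  ekey <- paste(esort[, 1L], esort[, 2L])
  uk <- !duplicated(ekey)
  edges <- esort[uk, , drop = FALSE]
  eid <- match(ekey, ekey[uk])
  nE <- nrow(edges)
  nsc <- nv + nE
  nper <- if (d == 2L) 3L else 6L
  elemdof <- cbind(el, matrix(nv + eid, ne, nper))
  midpts <- (mesh$nodes[edges[, 1L], , drop = FALSE] +
             mesh$nodes[edges[, 2L], , drop = FALSE]) / 2
  dof_coords <- rbind(mesh$nodes, midpts)
  # boundary scalar dofs per tag
  tags <- unique(mesh$facet_tag)
  edge_lookup <- stats::setNames(seq_len(nE), paste(edges[, 1L], edges[, 2L]))
  boundary <- list()
  facet_info <- NULL
  if (d == 2L) {
    fa <- mesh$facets[, 1L]; fb <- mesh$facets[, 2L]
    fkey <- paste(pmin(fa, fb), pmax(fa, fb))
    fmid <- nv + as.integer(edge_lookup[fkey])
    for (tg in tags) {
      sel <- mesh$facet_tag == tg
      boundary[[tg]] <- sort(unique(c(fa[sel], fb[sel], fmid[sel])))
    }
    # owner element of each boundary facet
    ge <- cbind(rep(seq_len(ne), times = 3L), eid)  # element, edge id rows
    eowner <- integer(nE)
    eowner[ge[, 2L]] <- ge[, 1L]
    owner <- eowner[fmid - nv]
    pa <- mesh$nodes[fa, , drop = FALSE]; pb <- mesh$nodes[fb, , drop = FALSE]
    len <- sqrt(rowSums((pb - pa)^2))
    tangent <- (pb - pa) / len
    normal <- cbind(tangent[, 2L], -tangent[, 1L])
    ecent <- (mesh$nodes[el[, 1L], , drop = FALSE] +
              mesh$nodes[el[, 2L], , drop = FALSE] +
              mesh$nodes[el[, 3L], , drop = FALSE]) / 3
    mid <- (pa + pb) / 2
    flip <- rowSums((mid - ecent[owner, , drop = FALSE]) * normal) < 0
    normal[flip, ] <- -normal[flip, ]
    facet_info <- list(a = fa, b = fb, mid_dof = fmid, owner = owner,
                       length = len, tangent = tangent, normal = normal,
                       pa = pa, pb = pb, tag = mesh$facet_tag)
  } else {
    for (tg in tags) {
      sel <- mesh$facet_tag == tg
      fc <- mesh$facets[sel, , drop = FALSE]
      vs <- unique(as.integer(fc))
      eon <- rbind(fc[, c(1L, 2L)], fc[, c(1L, 3L)], fc[, c(2L, 3L)])
      ekys <- paste(pmin(eon[, 1L], eon[, 2L]), pmax(eon[, 1L], eon[, 2L]))
      boundary[[tg]] <- sort(unique(c(vs, nv + as.integer(edge_lookup[ekys]))))
    }
  }
  sp <- structure(list(mesh = mesh, d = d, nv = nv, ne = ne, n_scalar = nsc,
                       nu = d * nsc, np = nv, elemdof = elemdof,
                       edges = edges, dof_coords = dof_coords,
                       boundary = boundary, facet_info = facet_info),
                  class = "rbe_space")
  if (d == 2L) sp <- precompute_quadrature(sp)
  sp
}

#' @export
print.rbe_space <- function(x, ...) {
  cat(sprintf("<rbe_space> Taylor-Hood P2-P1, %dD: N_u = %d, N_p = %d\n",
              x$d, x$nu, x$np))
  invisible(x)
}

# Per-element affine geometry + P2 basis data at quadrature points.
precompute_quadrature <- function(sp) {
  qr <- triangle_quadrature()
  sh <- p2_shape(qr$lambda)
  nq <- length(qr$w)
  el <- sp$mesh$elems; nd <- sp$mesh$nodes; ne <- sp$ne
  a <- nd[el[, 1L], , drop = FALSE]
  b <- nd[el[, 2L], , drop = FALSE]
  cc <- nd[el[, 3L], , drop = FALSE]
  J11 <- b[, 1L] - a[, 1L]; J21 <- b[, 2L] - a[, 2L]
  J12 <- cc[, 1L] - a[, 1L]; J22 <- cc[, 2L] - a[, 2L]
  detJ <- J11 * J22 - J12 * J21
  iJ11 <-  J22 / detJ; iJ12 <- -J12 / detJ
  iJ21 <- -J21 / detJ; iJ22 <-  J11 / detJ
  # physical gradients: grad_a = iJ[1,a] dN/dxi + iJ[2,a] dN/deta
  gphys <- array(0, c(ne, nq, 6L, 2L))
  qpts <- array(0, c(ne, nq, 2L))
  for (q in seq_len(nq)) {
    for (i in 1:6) {
      gphys[, q, i, 1L] <- iJ11 * sh$G[q, i, 1L] + iJ21 * sh$G[q, i, 2L]
      gphys[, q, i, 2L] <- iJ12 * sh$G[q, i, 1L] + iJ22 * sh$G[q, i, 2L]
    }
    lam <- qr$lambda[q, ]
    qpts[, q, 1L] <- lam[1L] * a[, 1L] + lam[2L] * b[, 1L] + lam[3L] * cc[, 1L]
    qpts[, q, 2L] <- lam[1L] * a[, 2L] + lam[2L] * b[, 2L] + lam[3L] * cc[, 2L]
  }
  sp$quad <- list(w = qr$w, nq = nq, N = sh$N, lambda = qr$lambda,
                  detJ = detJ, gphys = gphys, qpts = qpts)
  sp
}

check_2d_assembly <- function(sp) {
  if (sp$d != 2L) stop("operator assembly is implemented for 2D meshes")
}

# Triplet assembly helper: local (ne x nloc x nloc) contributions given as
# a function loc(i, j) -> numeric(ne); rows/cols from index matrices.
assemble_pairs <- function(rowdof, coldof, loc, dims) {
  nr <- ncol(rowdof); ncl <- ncol(coldof)
  ne <- nrow(rowdof)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  ii <- vector("list", nr * ncl); jj <- ii; xx <- ii
  k <- 1L
  for (i in seq_len(nr)) for (j in seq_len(ncl)) {
    ii[[k]] <- rowdof[, i]; jj[[k]] <- coldof[, j]; xx[[k]] <- loc(i, j)
    k <- k + 1L
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx), dims = dims)
}

# Scalar P2 mass, P2 grad-grad blocks A[[a]][[b]] (int d_a phi_j d_b phi_i),
# P1 mass, and P1(test) x d_c P2(trial) divergence blocks.
scalar_operators <- function(sp) {
  check_2d_assembly(sp)
  qd <- sp$quad; ed <- sp$elemdof; nsc <- sp$n_scalar
  wdet <- outer(qd$detJ, qd$w)  # ne x nq
  Msc <- assemble_pairs(ed, ed, function(i, j)
    rowSums(wdet * outer(rep(1, sp$ne), qd$N[, i] * qd$N[, j])), c(nsc, nsc))
  A <- lapply(1:2, function(a) lapply(1:2, function(b)
    assemble_pairs(ed, ed, function(i, j)
      rowSums(wdet * qd$gphys[, , j, a] * qd$gphys[, , i, b]), c(nsc, nsc))))
  elp1 <- sp$mesh$elems
  Mp1 <- assemble_pairs(elp1, elp1, function(i, j)
    rowSums(wdet * outer(rep(1, sp$ne), qd$lambda[, i] * qd$lambda[, j])),
    c(sp$nv, sp$nv))
  Dc <- lapply(1:2, function(cc)
    assemble_pairs(elp1, ed, function(i, j)
      -rowSums(wdet * qd$gphys[, , j, cc] * outer(rep(1, sp$ne), qd$lambda[, i])),
      c(sp$nv, nsc)))
  list(Msc = Msc, A = A, Mp1 = Mp1, Dc = Dc)
}

#' Assemble the constant (velocity-independent) operators
#'
#' Mass `M` (density weighted), stiffness `K` (strain-rate form, `2 mu_f
#' eps(u):eps(v)`), divergence `D` and the norm matrices `X_u` (full H^1
#' inner product) and `X_p` (pressure L^2 mass), all sparse. The momentum
#' mass matrix carries the density `rho_f`, consistently with the weak form
#' of the time-derivative term.
#'
#' @param space an `rbe_space` (2D).
#' @param props an `rbe_fluid`.
#' @return an object of class `rbe_operators`.
#' @export
assemble_constant_operators <- function(space, props = fluid_properties()) {
  check_2d_assembly(space)
  so <- scalar_operators(space)
  nsc <- space$n_scalar
  z <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(nsc, nsc))
  Lsc <- so$A[[1L]][[1L]] + so$A[[2L]][[2L]]
  M <- props$rho_f * Matrix::bdiag(so$Msc, so$Msc)
  # strain-rate stiffness blocks: mu (delta_{ci cj} Lsc + A[ci][cj])
  K <- props$mu_f * rbind(
    cbind(Lsc + so$A[[1L]][[1L]], so$A[[1L]][[2L]]),
    cbind(so$A[[2L]][[1L]], Lsc + so$A[[2L]][[2L]]))
  D <- cbind(so$Dc[[1L]], so$Dc[[2L]])
  Xu <- Matrix::bdiag(so$Msc + Lsc, so$Msc + Lsc)
  structure(list(space = space, props = props,
                 M = methods::as(M, "CsparseMatrix"),
                 K = methods::as(K, "CsparseMatrix"),
                 D = methods::as(D, "CsparseMatrix"),
                 Xu = methods::as(Xu, "CsparseMatrix"),
                 Xp = methods::as(so$Mp1, "CsparseMatrix")),
            class = "rbe_operators")
}

#' @export
print.rbe_operators <- function(x, ...) {
  cat(sprintf("<rbe_operators> N_u = %d, N_p = %d (rho_f = %g, mu_f = %g)\n",
              x$space$nu, x$space$np, x$props$rho_f, x$props$mu_f))
  invisible(x)
}

# Velocity field values at quadrature points: list(ux, uy) each ne x nq.
velocity_at_quad <- function(space, u) {
  qd <- space$quad; ed <- space$elemdof; nsc <- space$n_scalar
  ux <- matrix(0, space$ne, qd$nq); uy <- ux
  for (i in 1:6) {
    ux <- ux + outer(u[ed[, i]], qd$N[, i])
    uy <- uy + outer(u[nsc + ed[, i]], qd$N[, i])
  }
  list(ux = ux, uy = uy)
}

#' Assemble the convective matrix `C(u)`
#'
#' `C(u)_ij = int rho_f [(u . grad) phi_j] . phi_i`, linear in the velocity
#' DOF vector `u`.
#'
#' @param space an `rbe_space`.
#' @param props an `rbe_fluid`.
#' @param u velocity DOF vector of length `space$nu`.
#' @return sparse `nu x nu` matrix.
#' @export
assemble_convective <- function(space, props, u) {
  check_2d_assembly(space)
  if (length(u) != space$nu) stop("velocity DOF vector has wrong length")
  qd <- space$quad; ed <- space$elemdof; nsc <- space$n_scalar
  uq <- velocity_at_quad(space, u)
  wdet <- outer(qd$detJ, qd$w)
  Nsc <- assemble_pairs(ed, ed, function(i, j)
    rowSums(wdet * outer(rep(1, space$ne), qd$N[, i]) *
            (uq$ux * qd$gphys[, , j, 1L] + uq$uy * qd$gphys[, , j, 2L])),
    c(nsc, nsc))
  props$rho_f * Matrix::bdiag(Nsc, Nsc)
}

#' Assemble the directional convective derivative
#'
#' The Newton linearization of `C(u) u` is `C(u) + Cprime(u)` where
#' `Cprime(u)_((ci,i),(cj,j)) = int rho_f phi_j (d_cj u_ci) phi_i`.
#'
#' @inheritParams assemble_convective
#' @return sparse `nu x nu` matrix.
#' @export
assemble_convective_prime <- function(space, props, u) {
  check_2d_assembly(space)
  qd <- space$quad; ed <- space$elemdof; nsc <- space$n_scalar
  wdet <- outer(qd$detJ, qd$w)
  # gradient of each velocity component at quadrature points
  gu <- array(0, c(space$ne, qd$nq, 2L, 2L))  # [e, q, comp a, deriv b]
  for (i in 1:6) for (b in 1:2) {
    gu[, , 1L, b] <- gu[, , 1L, b] + u[ed[, i]] * qd$gphys[, , i, b]
    gu[, , 2L, b] <- gu[, , 2L, b] + u[nsc + ed[, i]] * qd$gphys[, , i, b]
  }
  blocks <- lapply(1:2, function(ca) lapply(1:2, function(cb)
    assemble_pairs(ed, ed, function(i, j)
      rowSums(wdet * outer(rep(1, space$ne), qd$N[, i] * qd$N[, j]) *
              gu[, , ca, cb]), c(nsc, nsc))))
  props$rho_f * rbind(cbind(blocks[[1L]][[1L]], blocks[[1L]][[2L]]),
                      cbind(blocks[[2L]][[1L]], blocks[[2L]][[2L]]))
}

#' Norm matrices for velocity and pressure
#'
#' `X_u` discretizes the full H^1 inner product of vector fields (unit
#' coefficients), `X_p` the pressure L^2 inner product.
#'
#' @param space an `rbe_space`.
#' @return list with sparse `Xu` and `Xp`.
#' @export
assemble_norm_matrices <- function(space) {
  so <- scalar_operators(space)
  Lsc <- so$A[[1L]][[1L]] + so$A[[2L]][[2L]]
  list(Xu = Matrix::bdiag(so$Msc + Lsc, so$Msc + Lsc), Xp = so$Mp1)
}

#' Interpolate an analytic velocity field onto the P2 DOFs
#'
#' @param space an `rbe_space`.
#' @param fun function taking an `n x 2` coordinate matrix and returning an
#'   `n x 2` matrix of velocity values (or a length-n vector for scalar
#'   fields via [interpolate_scalar()]).
#' @return velocity DOF vector (length `nu`).
#' @export
interpolate_velocity <- function(space, fun) {
  v <- fun(space$dof_coords)
  c(v[, 1L], v[, 2L])
}

#' @rdname interpolate_velocity
#' @export
interpolate_scalar <- function(space, fun) {
  as.numeric(fun(space$mesh$nodes))
}

#' Assemble a momentum source vector
#'
#' `f_i = int f . phi_i` for an analytic forcing `f`.
#'
#' @param space an `rbe_space`.
#' @param fun function of an `n x 2` coordinate matrix returning `n x 2`
#'   forcing values.
#' @return numeric vector of length `nu`.
#' @export
assemble_load_vector <- function(space, fun) {
  check_2d_assembly(space)
  qd <- space$quad; ed <- space$elemdof; nsc <- space$n_scalar
  wdet <- outer(qd$detJ, qd$w)
  out <- numeric(space$nu)
  fx <- matrix(0, space$ne, qd$nq); fy <- fx
  for (q in seq_len(qd$nq)) {
    fv <- fun(cbind(qd$qpts[, q, 1L], qd$qpts[, q, 2L]))
    fx[, q] <- fv[, 1L]; fy[, q] <- fv[, 2L]
  }
  for (i in 1:6) {
    vi <- rowSums(wdet * fx * outer(rep(1, space$ne), qd$N[, i]))
    wi <- rowSums(wdet * fy * outer(rep(1, space$ne), qd$N[, i]))
    out[seq_len(nsc)] <- out[seq_len(nsc)] + tapply_sum(ed[, i], vi, nsc)
    out[nsc + seq_len(nsc)] <- out[nsc + seq_len(nsc)] + tapply_sum(ed[, i], wi, nsc)
  }
  out
}

tapply_sum <- function(idx, vals, n) {
  out <- numeric(n)
  agg <- rowsum(vals, idx)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' Quadrature errors of a discrete velocity/pressure pair against analytic
#' fields
#'
#' @param space an `rbe_space`.
#' @param u velocity DOF vector; `uex(X)` analytic velocity (`n x 2`);
#'   `graduex(X)` analytic velocity gradient, returning an `n x 4` matrix
#'   with columns `(du1/dx, du1/dy, du2/dx, du2/dy)`; may be `NULL`.
#' @param p pressure DOF vector and `pex(X)` analytic pressure; may be `NULL`.
#' @param uex,graduex,pex analytic fields (see above).
#' @return list with `u_l2`, `u_h1` (seminorm-inclusive full H1 error),
#'   `p_l2`.
#' @export
fem_errors <- function(space, u = NULL, uex = NULL, graduex = NULL,
                       p = NULL, pex = NULL) {
  check_2d_assembly(space)
  qd <- space$quad; ed <- space$elemdof; nsc <- space$n_scalar
  wdet <- outer(qd$detJ, qd$w)
  out <- list()
  if (!is.null(u)) {
    uq <- velocity_at_quad(space, u)
    gu <- array(0, c(space$ne, qd$nq, 2L, 2L))
    for (i in 1:6) for (b in 1:2) {
      gu[, , 1L, b] <- gu[, , 1L, b] + u[ed[, i]] * qd$gphys[, , i, b]
      gu[, , 2L, b] <- gu[, , 2L, b] + u[nsc + ed[, i]] * qd$gphys[, , i, b]
    }
    el2 <- 0; esemi <- 0
    for (q in seq_len(qd$nq)) {
      X <- cbind(qd$qpts[, q, 1L], qd$qpts[, q, 2L])
      ue <- uex(X)
      el2 <- el2 + sum(wdet[, q] * ((uq$ux[, q] - ue[, 1L])^2 +
                                    (uq$uy[, q] - ue[, 2L])^2))
      if (!is.null(graduex)) {
        ge <- graduex(X)
        esemi <- esemi + sum(wdet[, q] * ((gu[, q, 1L, 1L] - ge[, 1L])^2 +
                                          (gu[, q, 1L, 2L] - ge[, 2L])^2 +
                                          (gu[, q, 2L, 1L] - ge[, 3L])^2 +
                                          (gu[, q, 2L, 2L] - ge[, 4L])^2))
      }
    }
    out$u_l2 <- sqrt(el2)
    out$u_h1 <- sqrt(el2 + esemi)
    out$u_h1_semi <- sqrt(esemi)
  }
  if (!is.null(p)) {
    pl2 <- 0
    elp1 <- space$mesh$elems
    for (q in seq_len(qd$nq)) {
      X <- cbind(qd$qpts[, q, 1L], qd$qpts[, q, 2L])
      ph <- qd$lambda[q, 1L] * p[elp1[, 1L]] + qd$lambda[q, 2L] * p[elp1[, 2L]] +
            qd$lambda[q, 3L] * p[elp1[, 3L]]
      pl2 <- pl2 + sum(wdet[, q] * (ph - pex(X))^2)
    }
    out$p_l2 <- sqrt(pl2)
  }
  out
}

#' Wall shear stress magnitude on the wall facets
#'
#' Evaluates the viscous traction `sigma(u, p) n = 2 mu_f eps(u) n - p n`
#' at each wall facet midpoint (using the gradient of the P2 field in the
#' owning element) and returns the magnitude of its tangential part
#' `sigma n - (n . sigma n) n`.
#'
#' @param space an `rbe_space`.
#' @param props an `rbe_fluid`.
#' @param u velocity DOF vector.
#' @param p pressure DOF vector.
#' @param wall_tag boundary tag of the wall (default `"wall"`).
#' @return data.frame with facet midpoint coordinates and `wss` magnitude,
#'   one row per wall facet.
#' @export
wall_shear_stress <- function(space, props, u, p, wall_tag = "wall") {
  check_2d_assembly(space)
  fi <- space$facet_info
  sel <- which(fi$tag == wall_tag)
  if (!length(sel)) stop("no wall facets with tag '", wall_tag, "'")
  nsc <- space$n_scalar
  el <- space$mesh$elems; nd <- space$mesh$nodes; ed <- space$elemdof
  out <- matrix(0, length(sel), 3L)
  for (r in seq_along(sel)) {
    f <- sel[r]
    e <- fi$owner[f]
    mid <- (fi$pa[f, ] + fi$pb[f, ]) / 2
    # barycentric coordinates of the midpoint in element e
    a <- nd[el[e, 1L], ]; b <- nd[el[e, 2L], ]; cc <- nd[el[e, 3L], ]
    Tm <- cbind(b - a, cc - a)
    xi <- solve(Tm, mid - a)
    lam <- matrix(c(1 - sum(xi), xi), 1L)
    sh <- p2_shape(lam)
    iT <- solve(Tm)
    # physical gradient of each local shape function at the midpoint
    G <- matrix(0, 6L, 2L)
    for (i in 1:6) G[i, ] <- as.numeric(t(iT) %*% sh$G[1L, i, ])
    dofs <- ed[e, ]
    gradu <- matrix(0, 2L, 2L)  # gradu[a, b] = d u_a / d x_b
    for (i in 1:6) {
      gradu[1L, ] <- gradu[1L, ] + u[dofs[i]] * G[i, ]
      gradu[2L, ] <- gradu[2L, ] + u[nsc + dofs[i]] * G[i, ]
    }
    pmid <- sum(lam * p[el[e, ]])
    eps <- (gradu + t(gradu)) / 2
    n <- fi$normal[f, ]
    trac <- as.numeric(2 * props$mu_f * eps %*% n - pmid * n)
    tt <- trac - sum(trac * n) * n
    out[r, ] <- c(mid, sqrt(sum(tt^2)))
  }
  data.frame(x = out[, 1L], y = out[, 2L], wss = out[, 3L])
}

#' Velocity DOF indices on tagged boundaries
#'
#' @param space an `rbe_space`.
#' @param tags character vector of boundary tags.
#' @return integer vector of velocity DOF indices (both components).
#' @export
boundary_velocity_dofs <- function(space, tags) {
  sc <- sort(unique(unlist(space$boundary[tags])))
  c(sc, space$n_scalar + sc)
}
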