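#' Reference building blocks
#'
#' The geometry library contains straight tubes with aspect ratio
#' length/diameter 1:1 (`T1`), 1:2 (`T2`), 1:3 (`T3`) and a symmetric
#' bifurcation (`B`). All blocks have unit diameter (reference radius
#' `R = 0.5`). In 2D a tube `Tk` is the rectangle `[0, k] x [-R, R]` with
#' inlet at `x = 0` and outlet at `x = k`; the bifurcation is a symmetric
#' three-way junction (an equilateral core with three channels at 120
#' degrees), with one channel acting as inlet and two as outlets.
#'
#' @param kind one of `"T1"`, `"T2"`, `"T3"`, `"B"`.
#' @param resolution target mesh size `h` (in diameters). The number of
#'   cells across the channel is `max(2, round(1/h))`.
#' @param d spatial dimension; meshes are generated for `d = 2`.
#' @return an object of class `rbe_block` with fields `kind`, `mesh`,
#'   `interfaces` (list of interface descriptors), `wall_tag`, `param_spec`.
#' @export
build_reference_block <- function(kind, resolution = 0.25, d = 2L) {
  kind <- match.arg(kind, c("T1", "T2", "T3", "B"))
  if (d != 2L) stop("reference meshes are generated in 2D; see block_param_spec() for 3D parameter metadata")
  if (resolution <= 0) stop("resolution must be positive")
  R <- 0.5
  ny <- max(2L, as.integer(round(2 * R / resolution)))
  if (kind %in% c("T1", "T2", "T3")) {
    k <- as.integer(substring(kind, 2L))
    L <- k * 2 * R  # axial length = k diameters
    nx <- max(2L, as.integer(round(L / resolution)))
    mesh <- mesh_rectangle(nx, ny, 0, L, -R, R,
                           tags = c("inlet", "outlet", "wall", "wall"))
    interfaces <- list(
      list(name = "inlet", role = "inlet", centre = c(0, 0),
           normal = c(-1, 0), radius = R),
      list(name = "outlet", role = "outlet", centre = c(L, 0),
           normal = c(1, 0), radius = R))
  } else {
    mesh <- bifurcation_mesh(ny)
    a <- 1 / (2 * sqrt(3))  # apothem of the unit-side core triangle
    Lc <- 1
    rot <- function(th) matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
    c1 <- c(0, -a - Lc); n1 <- c(0, -1)
    interfaces <- list(
      list(name = "inlet", role = "inlet", centre = c1, normal = n1, radius = R),
      list(name = "outlet1", role = "outlet",
           centre = as.numeric(rot(2 * pi / 3) %*% c1),
           normal = as.numeric(rot(2 * pi / 3) %*% n1), radius = R),
      list(name = "outlet2", role = "outlet",
           centre = as.numeric(rot(-2 * pi / 3) %*% c1),
           normal = as.numeric(rot(-2 * pi / 3) %*% n1), radius = R))
  }
  structure(list(kind = kind, mesh = mesh, interfaces = interfaces,
                 wall_tag = "wall", param_spec = block_param_spec(kind, d)),
            class = "rbe_block")
}

#' @export
print.rbe_block <- function(x, ...) {
  cat(sprintf("<rbe_block> kind %s: %d nodes, %d elements, interfaces: %s\n",
              x$kind, nrow(x$mesh$nodes), nrow(x$mesh$elems),
              paste(vapply(x$interfaces, `[[`, "", "name"), collapse = ", ")))
  invisible(x)
}

# Conforming 2D symmetric bifurcation: equilateral core triangle of unit
# side plus three channels (width 1, length 1) attached to its edges.
# m = number of cells across a channel (= subdivisions of a core edge).
bifurcation_mesh <- function(m) {
  a <- 1 / (2 * sqrt(3))
  Lc <- 1
  rot <- function(th) matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  nlen <- max(2L, m)
  # channel 1 (inlet) in its own frame: x in [-.5,.5], y in [-a-Lc, -a]
  chan <- mesh_rectangle(m, nlen, -0.5, 0.5, -a - Lc, -a,
                         tags = c("wall", "wall", "end", "junction"))
  rotate_mesh <- function(mesh, th) {
    mesh$nodes <- mesh$nodes %*% t(rot(th))
    mesh
  }
  chans <- list(chan, rotate_mesh(chan, 2 * pi / 3), rotate_mesh(chan, -2 * pi / 3))
  # core: uniform refinement of the triangle with vertices v1, v2, v3
  v <- rbind(c(-0.5, -a), c(0.5, -a), c(0, 1 / sqrt(3)))
  core <- refine_triangle(v, m)
  merged <- mesh_merge(c(chans, list(core)))
  # retag: channel ends -> inlet/outlet1/outlet2 by position, rest -> wall
  ends <- list(inlet = c(0, -a - Lc),
               outlet1 = as.numeric(rot(2 * pi / 3) %*% c(0, -a - Lc)),
               outlet2 = as.numeric(rot(-2 * pi / 3) %*% c(0, -a - Lc)))
  dirs <- list(inlet = c(0, -1),
               outlet1 = as.numeric(rot(2 * pi / 3) %*% c(0, -1)),
               outlet2 = as.numeric(rot(-2 * pi / 3) %*% c(0, -1)))
  tag <- rep("wall", nrow(merged$facets))
  mid <- (merged$nodes[merged$facets[, 1L], ] + merged$nodes[merged$facets[, 2L], ]) / 2
  for (nm in names(ends)) {
    onend <- abs((mid[, 1L] - ends[[nm]][1L]) * dirs[[nm]][1L] +
                 (mid[, 2L] - ends[[nm]][2L]) * dirs[[nm]][2L]) < 1e-9
    tag[onend] <- nm
  }
  merged$facet_tag <- tag
  merged
}

# Uniform m-fold refinement of a single triangle into m^2 subtriangles.
refine_triangle <- function(v, m) {
  nodes <- list(); id <- matrix(0L, m + 1L, m + 1L)
  k <- 0L
  for (i in 0:m) for (j in 0:(m - i)) {
    k <- k + 1L
    id[i + 1L, j + 1L] <- k
    lam <- c(1 - (i + j) / m, i / m, j / m)
    nodes[[k]] <- as.numeric(lam %*% v)
  }
  elems <- list()
  for (i in 0:(m - 1L)) for (j in 0:(m - 1L - i)) {
    elems[[length(elems) + 1L]] <- c(id[i + 1L, j + 1L], id[i + 2L, j + 1L], id[i + 1L, j + 2L])
    if (j < m - 1L - i)
      elems[[length(elems) + 1L]] <- c(id[i + 2L, j + 1L], id[i + 2L, j + 2L], id[i + 1L, j + 2L])
  }
  # boundary facets of the macro triangle (they all become interior junction
  # edges after merging with the channels)
  fc <- list()
  for (i in 0:(m - 1L)) {
    fc[[length(fc) + 1L]] <- c(id[i + 1L, 1L], id[i + 2L, 1L])            # edge v1-v2
    fc[[length(fc) + 1L]] <- c(id[1L, i + 1L], id[1L, i + 2L])            # edge v1-v3
    fc[[length(fc) + 1L]] <- c(id[i + 1L, m - i + 1L], id[i + 2L, m - i]) # edge v2-v3
  }
  rbe_mesh(do.call(rbind, nodes), do.call(rbind, elems),
           do.call(rbind, fc), rep("junction", length(fc)))
}

#' Geometric parameter specification of a building block
#'
#' Tubes have three nonaffine parameters: axial length ratio, outlet radius
#' ratio, and bending angle of the centreline. The bifurcation is
#' parametrized by rotations of its two outlet normals: one angle per outlet
#' in 2D, three Euler angles per outlet (six parameters) in 3D.
#'
#' @param kind block kind.
#' @param d spatial dimension (2 or 3).
#' @return data.frame with columns `name`, `min`, `max`, `default`.
#' @export
block_param_spec <- function(kind, d = 2L) {
  kind <- match.arg(kind, c("T1", "T2", "T3", "B"))
  if (kind != "B") {
    data.frame(name = c("length_ratio", "radius_ratio", "bend"),
               min = c(0.5, 0.5, -0.4), max = c(2, 2, 0.4),
               default = c(1, 1, 0), stringsAsFactors = FALSE)
  } else if (d == 2L) {
    data.frame(name = c("outlet1_angle", "outlet2_angle"),
               min = c(-0.3, -0.3), max = c(0.3, 0.3),
               default = c(0, 0), stringsAsFactors = FALSE)
  } else {
    data.frame(name = as.vector(t(outer(c("outlet1", "outlet2"),
                                        c("_alpha", "_beta", "_gamma"), paste0))),
               min = rep(-0.3, 6L), max = rep(0.3, 6L),
               default = rep(0, 6L), stringsAsFactors = FALSE)
  }
}

#' Deformation parameters for a building block
#'
#' Bundles the nonaffine parameters with the rigid motion `Q`, `t` of the
#' composite map `Phi(x) = Q chi(x) + t`.
#'
#' @param kind block kind.
#' @param ... named nonaffine parameters (see [block_param_spec()]);
#'   unnamed parameters default to the spec defaults.
#' @param rotation rigid rotation angle in radians (2D).
#' @param translation rigid translation vector.
#' @param check if `TRUE`, error when a parameter is outside its admissible
#'   range.
#' @return an object of class `rbe_params`.
#' @export
deformation_params <- function(kind, ..., rotation = 0,
                               translation = c(0, 0), check = TRUE) {
  spec <- block_param_spec(kind, 2L)
  mu <- stats::setNames(spec$default, spec$name)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), spec$name)
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    mu[names(dots)] <- unlist(dots)
  }
  if (check) {
    out <- mu < stats::setNames(spec$min, spec$name) | mu > stats::setNames(spec$max, spec$name)
    if (any(out)) stop("parameter(s) outside admissible range: ",
                       paste(names(mu)[out], collapse = ", "))
  }
  Q <- matrix(c(cos(rotation), sin(rotation), -sin(rotation), cos(rotation)), 2L)
  structure(list(kind = kind, mu = mu, Q = Q, t = as.numeric(translation),
                 rotation = rotation),
            class = "rbe_params")
}

#' Build the geometric map of a deformed building block
#'
#' The composite map is `Phi(x) = Q chi(x; mu) + t` with `Q` a rotation and
#' `chi` the nonaffine deformation. For tubes `chi` is analytic: axial
#' scaling by the length ratio, linear taper of the cross-section from the
#' inlet radius to `radius_ratio` times it, and circular-arc bending of the
#' centreline by the bend angle, with cross-sections kept normal to the
#' centreline; its Jacobian is available in closed form. For the
#' bifurcation, `chi` is a componentwise harmonic extension of boundary
#' displacements that rotate each outlet about its centre; its Jacobian is
#' treated as the identity (small-deformation regime), which is also the
#' approximation used in the Piola transformation for this block.
#'
#' @param block an `rbe_block`.
#' @param params an `rbe_params` (see [deformation_params()]).
#' @return an object of class `rbe_map` with fields `phi`, `chi`,
#'   `jac_chi`, `det_jphi` (functions of an `n x 2` coordinate matrix),
#'   `Q`, `t`.
#' @export
nonaffine_map <- function(block, params) {
  stopifnot(inherits(block, "rbe_block"), inherits(params, "rbe_params"))
  if (params$kind != block$kind) stop("parameter kind does not match block kind")
  Q <- params$Q; tv <- params$t
  if (block$kind != "B") {
    k <- as.integer(substring(block$kind, 2L))
    Lhat <- k
    s <- params$mu[["length_ratio"]]
    r1 <- params$mu[["radius_ratio"]]
    alpha <- params$mu[["bend"]]
    chi <- function(X) tube_chi(X, Lhat, s, r1, alpha)$pos
    jac_chi <- function(X) tube_chi(X, Lhat, s, r1, alpha)$jac
    detj <- function(X) tube_chi(X, Lhat, s, r1, alpha)$det
    # admissibility: det Jchi = r (s - y r alpha / Lhat) > 0 on the block
    worst <- min(detj(rbind(c(Lhat, 0.5 * sign(alpha + (alpha == 0))),
                            c(0, 0.5), c(0, -0.5), c(Lhat, -0.5), c(Lhat, 0.5))))
    if (worst <= 0) stop("inadmissible tube parameters: map would invert elements")
  } else {
    disp <- bifurcation_displacement(block, params)
    chi <- chi_lookup_table(block$mesh, disp)
    jac_chi <- function(X) {
      J <- array(0, c(nrow(X), 2L, 2L)); J[, 1L, 1L] <- 1; J[, 2L, 2L] <- 1; J
    }
    detj <- function(X) rep(1, nrow(X))
  }
  phi <- function(X) sweep(chi(X) %*% t(Q), 2L, tv, `+`)
  structure(list(kind = block$kind, params = params, Q = Q, t = tv,
                 phi = phi, chi = chi, jac_chi = jac_chi, det_jchi = detj,
                 # Jacobian of Phi = Q Jchi; det unchanged by rotation
                 jac_phi = function(X) {
                   J <- jac_chi(X)
                   out <- J
                   for (a in 1:2) for (b in 1:2)
                     out[, a, b] <- Q[a, 1L] * J[, 1L, b] + Q[a, 2L] * J[, 2L, b]
                   out
                 },
                 det_jphi = detj),
            class = "rbe_map")
}

# Analytic tube deformation. Reference axis x in [0, Lhat], cross-section
# coordinate y. Returns positions, Jacobians (n x 2 x 2) and determinants.
tube_chi <- function(X, Lhat, s, r1, alpha) {
  x <- X[, 1L]; y <- X[, 2L]
  phi <- alpha * x / Lhat
  r <- 1 + (r1 - 1) * x / Lhat
  rp <- (r1 - 1) / Lhat
  Tx <- cos(phi); Ty <- sin(phi)
  Nx <- -sin(phi); Ny <- cos(phi)
  if (abs(alpha) < 1e-14) {
    cx <- s * x; cy <- rep(0, length(x))
  } else {
    rho <- s * Lhat / alpha
    cx <- rho * sin(phi); cy <- rho * (1 - cos(phi))
  }
  pos <- cbind(cx + y * r * Nx, cy + y * r * Ny)
  ax <- s - y * r * alpha / Lhat   # tangential stretch factor
  J <- array(0, c(length(x), 2L, 2L))
  J[, 1L, 1L] <- ax * Tx + y * rp * Nx
  J[, 2L, 1L] <- ax * Ty + y * rp * Ny
  J[, 1L, 2L] <- r * Nx
  J[, 2L, 2L] <- r * Ny
  list(pos = pos, jac = J, det = r * ax)
}

# Harmonic (componentwise Laplace) extension of the outlet-rotation
# boundary displacement on the bifurcation reference mesh. Dirichlet data:
# zero on the inlet, rigid rotation about the outlet centre on each outlet;
# homogeneous Neumann on the walls.
bifurcation_displacement <- function(block, params) {
  mesh <- block$mesh
  nn <- nrow(mesh$nodes)
  fixed <- integer(0); vals <- matrix(0, 0L, 2L)
  for (iface in block$interfaces) {
    nodes_on <- unique(as.integer(mesh$facets[mesh$facet_tag == iface$name, ]))
    if (iface$role == "inlet") {
      dv <- matrix(0, length(nodes_on), 2L)
    } else {
      th <- params$mu[[paste0(iface$name, "_angle")]]
      Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
      rel <- sweep(mesh$nodes[nodes_on, , drop = FALSE], 2L, iface$centre)
      dv <- rel %*% t(Rm) - rel
    }
    fixed <- c(fixed, nodes_on)
    vals <- rbind(vals, dv)
  }
  K <- p1_stiffness(mesh)
  free <- setdiff(seq_len(nn), fixed)
  disp <- matrix(0, nn, 2L)
  disp[fixed, ] <- vals
  if (length(free)) {
    Kff <- K[free, free, drop = FALSE]
    rhs <- -K[free, fixed, drop = FALSE] %*% disp[fixed, , drop = FALSE]
    disp[free, ] <- as.matrix(Matrix::solve(Kff, rhs))
  }
  disp
}

# P1 stiffness matrix on a triangle mesh (constant per-element gradients).
p1_stiffness <- function(mesh) {
  el <- mesh$elems; nd <- mesh$nodes
  a <- nd[el[, 1L], ]; b <- nd[el[, 2L], ]; cc <- nd[el[, 3L], ]
  det2 <- (b[, 1L] - a[, 1L]) * (cc[, 2L] - a[, 2L]) -
          (cc[, 1L] - a[, 1L]) * (b[, 2L] - a[, 2L])
  area <- det2 / 2
  # gradients of barycentric coordinates
  gx <- cbind(b[, 2L] - cc[, 2L], cc[, 2L] - a[, 2L], a[, 2L] - b[, 2L]) / det2
  gy <- cbind(cc[, 1L] - b[, 1L], a[, 1L] - cc[, 1L], b[, 1L] - a[, 1L]) / det2
  ii <- jj <- xx <- vector("list", 9L)
  k <- 1L
  for (i in 1:3) for (j in 1:3) {
    ii[[k]] <- el[, i]; jj[[k]] <- el[, j]
    xx[[k]] <- area * (gx[, i] * gx[, j] + gy[, i] * gy[, j])
    k <- k + 1L
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(nrow(nd), nrow(nd)))
}

# Coordinate-keyed lookup table for a nodal map: evaluates chi at mesh
# vertices and edge midpoints (the only points where the nonanalytic
# bifurcation map is needed).
chi_lookup_table <- function(mesh, disp) {
  nd <- mesh$nodes
  ed <- mesh_edges(mesh$elems)
  mids <- (nd[ed[, 1L], ] + nd[ed[, 2L], ]) / 2
  dmid <- (disp[ed[, 1L], ] + disp[ed[, 2L], ]) / 2
  pts <- rbind(nd, mids)
  dall <- rbind(disp, dmid)
  key <- coord_key(pts)
  fn <- function(X) {
    idx <- match(coord_key(X), key)
    if (anyNA(idx)) stop("bifurcation map evaluated away from mesh vertices/midpoints")
    X + dall[idx, , drop = FALSE]
  }
  fn
}

coord_key <- function(X) {
  apply(round(X * 1e9) / 1e9, 1L, paste, collapse = "|")
}

# Unique element edges, as a 2-column matrix of sorted node pairs.
mesh_edges <- function(elems) {
  e <- rbind(elems[, c(2L, 3L)], elems[, c(3L, 1L)], elems[, c(1L, 2L)])
  e <- t(apply(e, 1L, sort))
  unique(e)
}

#' Deform a reference block into a subdomain
#'
#' Applies `Phi = Q chi + t` to the reference mesh nodes (connectivity is
#' preserved) and recomputes the interface descriptors (centre, half-width,
#' outward normal) from the deformed boundary facets.
#'
#' @param block an `rbe_block`.
#' @param map an `rbe_map` built with [nonaffine_map()] for this block.
#' @return an object of class `rbe_subdomain` with fields `block`, `map`,
#'   `mesh` (deformed) and `interfaces`.
#' @export
apply_deformation <- function(block, map) {
  stopifnot(inherits(map, "rbe_map"))
  if (map$kind != block$kind) stop("map was not built for this block kind")
  mesh <- block$mesh
  newnodes <- map$phi(mesh$nodes)
  def <- mesh
  def$nodes <- newnodes
  vol <- element_volumes(def)
  if (any(vol <= 0)) stop("deformation inverted ", sum(vol <= 0), " element(s)")
  ifaces <- lapply(block$interfaces, function(ifc) {
    dsc <- fit_segment_descriptor(def, ifc$name)
    dsc$role <- ifc$role
    dsc
  })
  names(ifaces) <- vapply(ifaces, `[[`, "", "name")
  structure(list(block = block, map = map, mesh = def, interfaces = ifaces),
            class = "rbe_subdomain")
}

#' @export
print.rbe_subdomain <- function(x, ...) {
  cat(sprintf("<rbe_subdomain> %s block, %d nodes\n", x$block$kind, nrow(x$mesh$nodes)))
  invisible(x)
}

# Fit a straight-segment descriptor (centre, radius = half-width, outward
# unit normal, fit residual) to the boundary facets carrying `tag`.
fit_segment_descriptor <- function(mesh, tag) {
  sel <- which(mesh$facet_tag == tag)
  if (!length(sel)) stop("no boundary facets tagged '", tag, "'")
  fcs <- mesh$facets[sel, , drop = FALSE]
  nodes_on <- unique(as.integer(fcs))
  P <- mesh$nodes[nodes_on, , drop = FALSE]
  centre <- colMeans(P)
  rel <- sweep(P, 2L, centre)
  # principal direction of the node cloud = interface tangent
  sv <- svd(rel)
  tang <- sv$v[, 1L]
  proj <- rel %*% tang
  radius <- (max(proj) - min(proj)) / 2
  centre <- centre + as.numeric((max(proj) + min(proj)) / 2) * tang
  resid <- max(abs(rel %*% sv$v[, 2L]))
  normal <- c(tang[2L], -tang[1L])
  # orient outward: away from the centroid of an adjacent element
  f1 <- fcs[1L, ]
  el <- mesh$elems
  owner <- which(rowSums(matrix(el %in% f1, nrow(el))) >= 2L)[1L]
  ec <- colMeans(mesh$nodes[el[owner, ], ])
  fmid <- colMeans(mesh$nodes[f1, , drop = FALSE])
  if (sum((fmid - ec) * normal) < 0) normal <- -normal
  list(name = tag, centre = as.numeric(centre), normal = as.numeric(normal),
       radius = radius, fit_residual = resid)
}

#' Compose placed subdomains into a modular geometry
#'
#' Pairs interface descriptors of distinct subdomains according to
#' `topology` and verifies that matched descriptors agree (centre, radius,
#' opposite normals) within `tol * radius`. Unpaired interfaces with role
#' `"inlet"` become global inlets, unpaired outlets become Neumann outlets.
#' The side with the lower subdomain index is the "+" side of each internal
#' interface (orientation sign +1).
#'
#' @param subdomains list of `rbe_subdomain` objects (already placed in
#'   physical space).
#' @param topology data.frame with columns `j`, `iface_j`, `m`, `iface_m`
#'   pairing interface names of subdomains `j` and `m`. May have zero rows.
#' @param tol relative matching tolerance (default `1e-6`).
#' @param check_overlap if `TRUE` (default), verify that no element
#'   centroid of one subdomain lies inside another subdomain.
#' @return an object of class `rbe_geometry`.
#' @export
compose_modular_geometry <- function(subdomains, topology = NULL, tol = 1e-6,
                                     check_overlap = TRUE) {
  stopifnot(all(vapply(subdomains, inherits, TRUE, "rbe_subdomain")))
  ns <- length(subdomains)
  if (is.null(topology))
    topology <- data.frame(j = integer(0), iface_j = character(0),
                           m = integer(0), iface_m = character(0))
  used <- matrix(FALSE, 0L, 2L)
  interfaces <- list()
  usedk <- character(0)
  for (r in seq_len(nrow(topology))) {
    j <- topology$j[r]; m <- topology$m[r]
    if (j == m) stop("an interface must join two distinct subdomains")
    dj <- subdomains[[j]]$interfaces[[topology$iface_j[r]]]
    dm <- subdomains[[m]]$interfaces[[topology$iface_m[r]]]
    if (is.null(dj) || is.null(dm)) stop("dangling interface reference in topology")
    tolr <- tol * dj$radius
    if (sqrt(sum((dj$centre - dm$centre)^2)) > tolr ||
        abs(dj$radius - dm$radius) > tolr ||
        sum(dj$normal * dm$normal) > -1 + tol)
      stop(sprintf("interface mismatch between subdomain %d ('%s') and %d ('%s')",
                   j, dj$name, m, dm$name))
    # '+' side = lower index
    if (j <= m) {
      plus <- list(sub = j, name = dj$name, desc = dj)
      minus <- list(sub = m, name = dm$name, desc = dm)
    } else {
      plus <- list(sub = m, name = dm$name, desc = dm)
      minus <- list(sub = j, name = dj$name, desc = dj)
    }
    interfaces[[length(interfaces) + 1L]] <- list(
      id = length(interfaces) + 1L, plus = plus, minus = minus, desc = plus$desc)
    usedk <- c(usedk, paste(j, dj$name), paste(m, dm$name))
  }
  inlets <- list(); outlets <- list()
  for (j in seq_len(ns)) {
    for (ifc in subdomains[[j]]$interfaces) {
      if (paste(j, ifc$name) %in% usedk) next
      entry <- list(sub = j, name = ifc$name, desc = ifc)
      if (ifc$role == "inlet") {
        entry$id <- length(inlets) + 1L
        inlets[[length(inlets) + 1L]] <- entry
      } else {
        outlets[[length(outlets) + 1L]] <- entry
      }
    }
  }
  if (check_overlap && ns > 1L) check_no_overlap(subdomains)
  neighbours <- lapply(seq_len(ns), function(j) integer(0))
  for (ifc in interfaces) {
    neighbours[[ifc$plus$sub]] <- union(neighbours[[ifc$plus$sub]], ifc$minus$sub)
    neighbours[[ifc$minus$sub]] <- union(neighbours[[ifc$minus$sub]], ifc$plus$sub)
  }
  structure(list(subdomains = subdomains, interfaces = interfaces,
                 inlets = inlets, outlets = outlets, neighbours = neighbours),
            class = "rbe_geometry")
}

#' @export
print.rbe_geometry <- function(x, ...) {
  cat(sprintf("<rbe_geometry> %d subdomains (%s), %d internal interfaces, %d inlet(s), %d outlet(s)\n",
              length(x$subdomains),
              paste(vapply(x$subdomains, function(s) s$block$kind, ""), collapse = "-"),
              length(x$interfaces), length(x$inlets), length(x$outlets)))
  invisible(x)
}

# Cheap pairwise overlap check: no element centroid of subdomain m may lie
# strictly inside an element of subdomain j.
check_no_overlap <- function(subdomains) {
  cents <- lapply(subdomains, function(s) {
    el <- s$mesh$elems; nd <- s$mesh$nodes
    (nd[el[, 1L], ] + nd[el[, 2L], ] + nd[el[, 3L], ]) / 3
  })
  bbs <- lapply(subdomains, function(s) apply(s$mesh$nodes, 2L, range))
  for (j in seq_along(subdomains)) for (m in seq_along(subdomains)) {
    if (j == m) next
    bj <- bbs[[j]]; bm <- bbs[[m]]
    if (bj[2L, 1L] < bm[1L, 1L] || bm[2L, 1L] < bj[1L, 1L] ||
        bj[2L, 2L] < bm[1L, 2L] || bm[2L, 2L] < bj[1L, 2L]) next
    if (any(points_in_mesh(cents[[m]], subdomains[[j]]$mesh)))
      stop(sprintf("subdomains %d and %d overlap", j, m))
  }
  invisible(TRUE)
}

# Strict point-in-triangle test over all elements (small meshes only).
points_in_mesh <- function(P, mesh, eps = 1e-10) {
  el <- mesh$elems; nd <- mesh$nodes
  inside <- rep(FALSE, nrow(P))
  for (e in seq_len(nrow(el))) {
    a <- nd[el[e, 1L], ]; b <- nd[el[e, 2L], ]; cc <- nd[el[e, 3L], ]
    det2 <- (b[1L] - a[1L]) * (cc[2L] - a[2L]) - (cc[1L] - a[1L]) * (b[2L] - a[2L])
    l2 <- ((P[, 1L] - a[1L]) * (cc[2L] - a[2L]) - (P[, 2L] - a[2L]) * (cc[1L] - a[1L])) / det2
    l3 <- ((P[, 2L] - a[2L]) * (b[1L] - a[1L]) - (P[, 1L] - a[1L]) * (b[2L] - a[2L])) / det2
    inside <- inside | (l2 > eps & l3 > eps & l2 + l3 < 1 - eps)
    if (all(inside)) break
  }
  inside
}

#' Build a tree-structured modular geometry from a block specification
#'
#' Each entry of `spec` describes one subdomain: its block `kind`, optional
#' nonaffine parameters `params` (named list), its `parent` index (0 for
#' the root) and the parent interface name `parent_outlet` it attaches to.
#' Rigid motions are computed so that each child's inlet coincides with its
#' parent's outlet (matching centre, radius and opposite normal).
#'
#' @param spec list of lists with fields `kind`, `params`, `parent`,
#'   `parent_outlet` (defaults: no params, parent = previous entry,
#'   `parent_outlet = "outlet"`).
#' @param resolution mesh size passed to [build_reference_block()].
#' @param blocks optional named list of prebuilt reference blocks, keyed by
#'   kind (avoids remeshing, and guarantees that subdomains of the same
#'   kind share one reference mesh).
#' @return an `rbe_geometry`.
#' @export
build_tree_geometry <- function(spec, resolution = 0.25, blocks = NULL) {
  kinds <- unique(vapply(spec, `[[`, "", "kind"))
  if (is.null(blocks)) {
    blocks <- lapply(kinds, build_reference_block, resolution = resolution)
    names(blocks) <- kinds
  }
  subs <- vector("list", length(spec))
  topo <- NULL
  for (i in seq_along(spec)) {
    nd <- spec[[i]]
    blk <- blocks[[nd$kind]]
    pr <- if (is.null(nd$params)) list() else nd$params
    parent <- if (!is.null(nd$parent)) nd$parent else i - 1L
    if (parent == 0L) {
      pars <- do.call(deformation_params, c(list(kind = nd$kind), pr))
    } else {
      pout <- if (!is.null(nd$parent_outlet)) nd$parent_outlet else "outlet"
      pd <- subs[[parent]]$interfaces[[pout]]
      if (is.null(pd)) stop("parent subdomain has no interface '", pout, "'")
      # inlet of the child in the chi-frame: fixed by construction
      cin <- blk$interfaces[[1L]]$centre
      nin <- blk$interfaces[[1L]]$normal
      th <- atan2(-pd$normal[2L], -pd$normal[1L]) - atan2(nin[2L], nin[1L])
      Qr <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
      tv <- pd$centre - as.numeric(Qr %*% cin)
      pars <- do.call(deformation_params,
                      c(list(kind = nd$kind, rotation = th, translation = tv), pr))
      topo <- rbind(topo, data.frame(j = parent, iface_j = pout,
                                     m = i, iface_m = "inlet",
                                     stringsAsFactors = FALSE))
    }
    subs[[i]] <- apply_deformation(blk, nonaffine_map(blk, pars))
  }
  compose_modular_geometry(subs, topo)
}

#' Number of Lagrange-multiplier degrees of freedom of a geometry
#'
#' Equals `(number of internal interfaces + number of inlets) * n_lambda`.
#'
#' @param geometry an `rbe_geometry`.
#' @param basis an `rbe_interface_basis`, or an integer giving the number of
#'   multiplier basis functions per interface.
#' @return integer DOF count.
#' @export
multiplier_dof_count <- function(geometry, basis) {
  nl <- if (inherits(basis, "rbe_interface_basis")) basis$n_lambda else as.integer(basis)
  (length(geometry$interfaces) + length(geometry$inlets)) * nl
}
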