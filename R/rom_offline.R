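#' POD / offline-phase configuration
#'
#' @param eps_u,eps_p POD truncation tolerances for velocity and pressure
#'   (relative information content `1 - eps^2`, see [weighted_pod()]).
#' @param n_config number of randomly perturbed geometries to sample.
#' @param seed RNG seed for configuration sampling.
#' @param halfwidths named numeric vector of sampling half-widths per
#'   parameter name; parameters not listed keep their base value. Defaults:
#'   10% for tube length ratios, 0.1745 rad (10 degrees) for tube bends and
#'   bifurcation outlet angles. Radius ratios are not perturbed, which
#'   keeps all interface radii matched across the composition.
#' @param max_basis optional cap on the number of POD modes per field.
#' @param stride snapshot subsampling stride in timesteps (1 = every step).
#' @return object of class `rbe_pod_config`.
#' @export
pod_config <- function(eps_u = 1e-3, eps_p = 1e-5, n_config = 5L, seed = 1L,
                       halfwidths = NULL, max_basis = Inf, stride = 1L) {
  stopifnot(eps_u > 0, eps_u < 1, eps_p > 0, eps_p < 1)
  hw <- c(length_ratio = 0.1, bend = 0.1745, radius_ratio = 0,
          outlet1_angle = 0.1745, outlet2_angle = 0.1745)
  if (!is.null(halfwidths)) hw[names(halfwidths)] <- halfwidths
  structure(list(eps_u = eps_u, eps_p = eps_p, n_config = as.integer(n_config),
                 seed = as.integer(seed), halfwidths = hw,
                 max_basis = max_basis, stride = as.integer(stride)),
            class = "rbe_pod_config")
}

#' Sample perturbed geometry configurations
#'
#' Draws each subdomain's nonaffine parameters from uniform distributions
#' centred on the base specification values, with the half-widths of the
#' POD configuration, clipped draws being resampled (up to a cap) so that
#' every parameter stays in its admissible range.
#'
#' @param spec base tree specification (see [build_tree_geometry()]).
#' @param config an `rbe_pod_config`.
#' @return list of `n_config` perturbed specifications.
#' @export
sample_configurations <- function(spec, config) {
  set.seed(config$seed)
  hw <- config$halfwidths
  out <- vector("list", config$n_config)
  for (c_i in seq_len(config$n_config)) {
    sp <- spec
    for (j in seq_along(sp)) {
      ps <- block_param_spec(sp[[j]]$kind, 2L)
      base <- stats::setNames(ps$default, ps$name)
      if (!is.null(sp[[j]]$params)) base[names(sp[[j]]$params)] <- unlist(sp[[j]]$params)
      for (nm in ps$name) {
        h <- if (nm %in% names(hw)) hw[[nm]] else 0
        if (h == 0) next
        lo <- ps$min[ps$name == nm]; hi <- ps$max[ps$name == nm]
        val <- NA_real_
        for (try in 1:50) {
          cand <- base[[nm]] + stats::runif(1, -h, h)
          if (cand >= lo && cand <= hi) { val <- cand; break }
        }
        if (is.na(val)) stop("could not sample parameter '", nm, "' inside its range")
        base[[nm]] <- val
      }
      sp[[j]]$params <- as.list(base)
    }
    out[[c_i]] <- sp
  }
  out
}

#' Piola pullback of a velocity DOF vector to the reference block
#'
#' `vhat(xhat) = |J_Phi(xhat)| J_Phi(xhat)^{-1} v(Phi(xhat))`, evaluated
#' DOF-wise at the reference P2 DOF coordinates. Preserves discrete
#' divergence-freeness (exactly for affine maps, up to the map-quadrature
#' error otherwise). For the bifurcation `J_chi` is approximated by the
#' identity, so the pullback reduces to a rotation by `Q^T`.
#'
#' @param map an `rbe_map`.
#' @param space the reference-block `rbe_space`.
#' @param v velocity DOF vector on the deformed subdomain (same DOF
#'   indexing as the reference block).
#' @return pulled-back velocity DOF vector.
#' @export
piola_pullback <- function(map, space, v) {
  nsc <- space$n_scalar
  P <- space$dof_coords
  J <- map$jac_phi(P)
  dt <- map$det_jphi(P)
  if (any(!is.finite(1 / dt))) stop("singular Jacobian at a DOF")
  vx <- v[seq_len(nsc)]; vy <- v[nsc + seq_len(nsc)]
  # det * J^{-1} = [[J22, -J12], [-J21, J11]] for 2x2
  c(J[, 2L, 2L] * vx - J[, 1L, 2L] * vy,
    -J[, 2L, 1L] * vx + J[, 1L, 1L] * vy)
}

#' Piola pushforward (inverse of the pullback)
#'
#' `v(Phi(xhat)) = J_Phi(xhat) vhat(xhat) / |J_Phi(xhat)|`.
#'
#' @inheritParams piola_pullback
#' @param vhat velocity DOF vector on the reference block.
#' @return velocity DOF vector on the deformed subdomain.
#' @export
piola_pushforward <- function(map, space, vhat) {
  nsc <- space$n_scalar
  P <- space$dof_coords
  J <- map$jac_phi(P)
  dt <- map$det_jphi(P)
  vx <- vhat[seq_len(nsc)]; vy <- vhat[nsc + seq_len(nsc)]
  c((J[, 1L, 1L] * vx + J[, 1L, 2L] * vy) / dt,
    (J[, 2L, 1L] * vx + J[, 2L, 2L] * vy) / dt)
}

#' Norm-weighted proper orthogonal decomposition
#'
#' Given snapshots `S` and an SPD norm matrix `X = H^T H`, computes modes
#' that are `X`-orthonormal and minimize the `X`-norm projection error of
#' the snapshots (via SVD of `H S`). Truncation keeps the smallest `N` with
#' relative information content `sum_{i<=N} sigma_i^2 / sum_i sigma_i^2 >=
#' 1 - eps^2`.
#'
#' @param S snapshot matrix (`Nh x Ns`).
#' @param X SPD norm matrix (sparse or dense); `NULL` or identity reduces
#'   to plain economy SVD.
#' @param eps truncation tolerance in (0, 1); `eps = 0` keeps all modes.
#' @param method `"auto"` picks the Cholesky route for `Ns >= Nh/4`, else
#'   the Gram-matrix (method-of-snapshots) route; both agree to solver
#'   tolerance.
#' @param max_modes optional cap on the retained modes.
#' @return list with `modes` (`Nh x N`), `sv` (all singular values),
#'   `n` (retained count).
#' @export
weighted_pod <- function(S, X = NULL, eps = 0, method = c("auto", "chol", "snapshots"),
                         max_modes = Inf) {
  method <- match.arg(method)
  S <- as.matrix(S)
  Ns <- ncol(S); Nh <- nrow(S)
  if (method == "auto") method <- if (Ns >= Nh / 4) "chol" else "snapshots"
  if (is.null(X)) {
    sv <- svd(S)
    U <- sv$u; sigs <- sv$d
  } else if (method == "chol") {
    ch <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(X), "CsparseMatrix"),
                           LDL = FALSE, perm = TRUE)
    ex <- Matrix::expand(ch)
    HS <- as.matrix(Matrix::t(ex$L) %*% (ex$P %*% S))
    sv <- svd(HS)
    U <- as.matrix(Matrix::t(ex$P) %*% Matrix::solve(Matrix::t(ex$L), sv$u))
    sigs <- sv$d
  } else {
    G <- as.matrix(Matrix::t(S) %*% (X %*% S))
    G <- (G + t(G)) / 2
    eg <- eigen(G, symmetric = TRUE)
    pos <- eg$values > max(eg$values) * 1e-13
    sigs <- sqrt(pmax(eg$values, 0))
    U <- S %*% eg$vectors[, pos, drop = FALSE] %*%
      diag(1 / sigs[pos], sum(pos))
    sigs <- c(sigs[pos], rep(0, Ns - sum(pos)))
  }
  tot <- sum(sigs^2)
  if (eps > 0) {
    content <- cumsum(sigs^2) / tot
    n <- which(content >= 1 - eps^2)[1L]
  } else {
    n <- sum(sigs > max(sigs) * 1e-12)
  }
  n <- min(n, max_modes, length(sigs))
  modes <- U[, seq_len(n), drop = FALSE]
  # deterministic sign: largest-magnitude entry of each mode positive
  for (i in seq_len(n)) {
    m <- which.max(abs(modes[, i]))
    if (modes[m, i] < 0) modes[, i] <- -modes[, i]
  }
  list(modes = modes, sv = sigs, n = n)
}

#' Supremizer enrichment vectors for one reference block
#'
#' Pressure supremizers solve `Xu s_l = D^T eta_l` for every pressure mode
#' `eta_l`; coupling supremizers solve `Xu z_l = B^T e_l` for every
#' multiplier basis function of every interface of the block. All systems
#' use the H^1 velocity norm matrix restricted to the free (non-wall)
#' velocity DOFs.
#'
#' @param Xuff free-DOF velocity norm matrix.
#' @param Df free-DOF divergence matrix (`np x nf`).
#' @param Vp pressure modes (`np x Np`).
#' @param Bints list of free-DOF interface coupling matrices
#'   (`N_lambda x nf`), one per block interface.
#' @return list with `pressure` (`nf x Np`), `coupling` (`nf x (N_lambda *
#'   n_interfaces)`) and the factorization residual `max_residual`.
#' @export
compute_supremizers <- function(Xuff, Df, Vp, Bints) {
  ch <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(Xuff), "CsparseMatrix"),
                         LDL = FALSE)
  rhs_p <- Matrix::t(Df) %*% Vp
  Sp <- as.matrix(Matrix::solve(ch, rhs_p, system = "A"))
  Sc <- NULL
  for (B in Bints) {
    Sc <- cbind(Sc, as.matrix(Matrix::solve(ch, Matrix::t(B), system = "A")))
  }
  res <- max(
    if (ncol(Vp)) max(abs(Xuff %*% Sp - rhs_p)) else 0,
    if (!is.null(Sc) && ncol(Sc)) {
      Bt <- do.call(cbind, lapply(Bints, function(B) as.matrix(Matrix::t(B))))
      max(abs(Xuff %*% Sc - Bt))
    } else 0)
  list(pressure = Sp, coupling = Sc, max_residual = res)
}

#' X-orthonormalize a basis (modified Gram-Schmidt with drop tolerance)
#'
#' Concatenates POD modes and supremizers and orthonormalizes the columns
#' against the inner product `X`, dropping near-dependent vectors whose
#' norm after orthogonalization falls below `droptol` times the original
#' norm.
#'
#' @param V matrix of columns to orthonormalize (POD modes first).
#' @param X SPD inner-product matrix.
#' @param droptol relative drop tolerance.
#' @return matrix with X-orthonormal columns.
#' @export
finalize_basis <- function(V, X, droptol = 1e-8) {
  if (ncol(V) == 0L) stop("empty basis")
  kept <- NULL
  Xkept <- NULL  # X %*% kept, cached
  for (i in seq_len(ncol(V))) {
    v <- V[, i]
    nrm0 <- sqrt(abs(sum(v * as.numeric(X %*% v))))
    if (nrm0 == 0) next
    for (pass in 1:2) {
      if (!is.null(kept)) {
        coef <- as.numeric(crossprod(Xkept, v))
        v <- v - kept %*% coef
      }
    }
    Xv <- as.numeric(X %*% v)
    nrm <- sqrt(abs(sum(v * Xv)))
    if (nrm < droptol * nrm0) next
    v <- as.numeric(v) / nrm
    kept <- cbind(kept, v)
    Xkept <- cbind(Xkept, Xv / nrm)
  }
  colnames(kept) <- NULL
  kept
}

#' Generate snapshots over randomly perturbed modular geometries
#'
#' Runs the coupled FE model on each sampled configuration and collects,
#' for every building-block kind, the Piola pullbacks of the velocity
#' snapshots and the raw pressure snapshots on the reference block (free
#' velocity DOFs, all pressure DOFs). Snapshots are taken at every
#' `stride`-th timestep after the inflow ramp.
#'
#' @param spec base tree specification.
#' @param config an `rbe_pod_config`.
#' @param basis multiplier basis (`d = 2`).
#' @param inflow an `rbe_inflow`.
#' @param T_end final time of each snapshot run.
#' @param scheme an `rbe_bdf`.
#' @param props fluid properties.
#' @param resolution reference mesh size.
#' @param verbose print progress.
#' @return object of class `rbe_snapshots` with per-kind matrices `Su`
#'   (`nf x Ns`), `Sp` (`np x Ns`), provenance, the shared reference
#'   blocks/spaces/operators, and run metadata.
#' @export
offline_snapshots <- function(spec, config, basis, inflow, T_end,
                              scheme = bdf_scheme(), props = fluid_properties(),
                              resolution = 0.25, verbose = FALSE) {
  kinds <- unique(vapply(spec, `[[`, "", "kind"))
  blocks <- lapply(kinds, build_reference_block, resolution = resolution)
  names(blocks) <- kinds
  ref <- lapply(blocks, function(b) {
    space <- build_taylor_hood_space(b$mesh)
    ops <- assemble_constant_operators(space, props)
    wall <- space$boundary[[b$wall_tag]]
    ufree_sc <- setdiff(seq_len(space$n_scalar), wall)
    ufree <- c(ufree_sc, space$n_scalar + ufree_sc)
    list(block = b, space = space, ops = ops, ufree = ufree)
  })
  configs <- sample_configurations(spec, config)
  Su <- stats::setNames(vector("list", length(kinds)), kinds)
  Sp <- Su; prov <- Su
  failed <- 0L
  for (ci in seq_along(configs)) {
    geo <- tryCatch(build_tree_geometry(configs[[ci]], blocks = blocks),
                    error = function(e) e)
    if (inherits(geo, "error")) { failed <- failed + 1L; next }
    sys <- assemble_global_system(geo, basis, props)
    tr <- tryCatch(
      fom_time_loop(sys, inflow, T_end, scheme, keep_states = TRUE),
      error = function(e) e)
    if (inherits(tr, "error")) { failed <- failed + 1L; next }
    keep <- which(tr$times >= inflow$t0 - 1e-12)
    keep <- keep[seq(1L, length(keep), by = config$stride)]
    for (j in seq_along(sys$sub)) {
      kind <- sys$sub[[j]]$kind
      rf <- ref[[kind]]
      map <- geo$subdomains[[j]]$map
      for (k in keep) {
        Y <- tr$states[, k]
        ufull <- sys_full_u(sys, j, Y)
        uhat <- piola_pullback(map, rf$space, ufull)
        Su[[kind]] <- cbind(Su[[kind]], uhat[rf$ufree])
        Sp[[kind]] <- cbind(Sp[[kind]], Y[sys_p_idx(sys, j)])
        prov[[kind]] <- rbind(prov[[kind]],
                              data.frame(config = ci, sub = j, t = tr$times[k]))
      }
    }
    if (verbose) message("configuration ", ci, "/", length(configs), " done")
  }
  structure(list(Su = Su, Sp = Sp, provenance = prov, ref = ref,
                 blocks = blocks, kinds = kinds, basis = basis, props = props,
                 config = config, n_failed = failed, spec = spec,
                 resolution = resolution),
            class = "rbe_snapshots")
}

#' @export
print.rbe_snapshots <- function(x, ...) {
  cat("<rbe_snapshots>\n")
  for (k in x$kinds)
    cat(sprintf("  %s: %d velocity x %d snapshots\n", k,
                nrow(x$Su[[k]]), ncol(x$Su[[k]])))
  invisible(x)
}

#' Build the per-block reduced bases from a snapshot set
#'
#' Norm-weighted POD per building block (H^1 for velocity, L^2 for
#' pressure) at the given tolerances, followed by supremizer enrichment of
#' the velocity basis (pressure and coupling stabilization) and
#' X-orthonormalization by Gram-Schmidt.
#'
#' @param snaps an `rbe_snapshots`.
#' @param eps_u,eps_p POD tolerances (default: those of the snapshot
#'   configuration).
#' @param enrich apply supremizer enrichment (default `TRUE`).
#' @param max_basis cap on POD modes per field.
#' @return object of class `rbe_archive` with one entry per block kind:
#'   `Vu` (free velocity DOFs x enriched basis), `Vp`, singular values,
#'   mode counts, reference space/operators and bookkeeping.
#' @export
build_reduced_basis <- function(snaps, eps_u = NULL, eps_p = NULL,
                                enrich = TRUE, max_basis = Inf) {
  if (is.null(eps_u)) eps_u <- snaps$config$eps_u
  if (is.null(eps_p)) eps_p <- snaps$config$eps_p
  entries <- list()
  for (k in snaps$kinds) {
    rf <- snaps$ref[[k]]
    Xuff <- rf$ops$Xu[rf$ufree, rf$ufree]
    Df <- rf$ops$D[, rf$ufree, drop = FALSE]
    pu <- weighted_pod(snaps$Su[[k]], Xuff, eps_u, max_modes = max_basis)
    pp <- weighted_pod(snaps$Sp[[k]], rf$ops$Xp, eps_p, max_modes = max_basis)
    n_sup_p <- 0L; n_sup_c <- 0L
    Vu <- pu$modes
    if (enrich) {
      Bints <- lapply(rf$block$interfaces, function(ifc)
        assemble_interface_coupling(rf$space, snaps$basis, ifc, ifc$name,
                                    sign = 1)[, rf$ufree, drop = FALSE])
      sup <- compute_supremizers(Xuff, Df, pp$modes, Bints)
      n_sup_p <- ncol(sup$pressure); n_sup_c <- if (is.null(sup$coupling)) 0L else ncol(sup$coupling)
      Vu <- cbind(Vu, sup$pressure, sup$coupling)
    }
    Vu <- finalize_basis(Vu, Xuff)
    entries[[k]] <- list(kind = k, Vu = Vu, Vp = pp$modes,
                         sv_u = pu$sv, sv_p = pp$sv,
                         n_pod_u = pu$n, n_pod_p = pp$n,
                         n_sup_p = n_sup_p, n_sup_c = n_sup_c,
                         block = rf$block, space = rf$space, ops = rf$ops,
                         ufree = rf$ufree,
                         mesh_fp = mesh_fingerprint(rf$block$mesh))
  }
  structure(list(blocks = entries, kinds = snaps$kinds, basis = snaps$basis,
                 props = snaps$props, eps_u = eps_u, eps_p = eps_p,
                 seed = snaps$config$seed, resolution = snaps$resolution),
            class = "rbe_archive")
}

#' @export
print.rbe_archive <- function(x, ...) {
  cat(sprintf("<rbe_archive> eps_u = %g, eps_p = %g\n", x$eps_u, x$eps_p))
  for (k in x$kinds) {
    e <- x$blocks[[k]]
    cat(sprintf("  %s: N_u = %d (POD %d + sup %d+%d), N_p = %d\n", k,
                ncol(e$Vu), e$n_pod_u, e$n_sup_p, e$n_sup_c, ncol(e$Vp)))
  }
  invisible(x)
}

#' Run the complete offline phase
#'
#' Convenience wrapper: generate snapshots with [offline_snapshots()] and
#' build the reduced basis archive with [build_reduced_basis()].
#'
#' @inheritParams offline_snapshots
#' @param ... passed to [build_reduced_basis()].
#' @return an `rbe_archive` (the snapshot set is attached as attribute
#'   `"snapshots"`).
#' @export
run_offline <- function(spec, config, basis, inflow, T_end,
                        scheme = bdf_scheme(), props = fluid_properties(),
                        resolution = 0.25, ...) {
  snaps <- offline_snapshots(spec, config, basis, inflow, T_end, scheme,
                             props, resolution)
  arc <- build_reduced_basis(snaps, ...)
  attr(arc, "snapshots") <- snaps
  arc
}

#' Save / load a basis archive as a directory
#'
#' Arrays are stored as R-native serialized containers, one per block and
#' field, next to a plain-text YAML manifest recording kinds, sizes,
#' tolerances, seeds and reference-mesh fingerprints. On load, the
#' fingerprints are checked against the stored meshes.
#'
#' @param archive an `rbe_archive`.
#' @param dir target directory (created if absent).
#' @return `dir` (save) or the archive (load), invisibly/visibly.
#' @export
save_basis_archive <- function(archive, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(eps_u = archive$eps_u, eps_p = archive$eps_p,
                   seed = archive$seed, resolution = archive$resolution,
                   basis_n = archive$basis$n, basis_d = archive$basis$d,
                   kinds = as.list(archive$kinds),
                   blocks = lapply(archive$blocks, function(e)
                     list(kind = e$kind, n_u = ncol(e$Vu), n_p = ncol(e$Vp),
                          mesh_fingerprint = e$mesh_fp)))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  saveRDS(archive, file.path(dir, "archive.rds"))
  invisible(dir)
}

#' @rdname save_basis_archive
#' @export
load_basis_archive <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  arc <- readRDS(file.path(dir, "archive.rds"))
  for (k in arc$kinds) {
    fp <- man$blocks[[k]]$mesh_fingerprint
    if (!identical(fp, arc$blocks[[k]]$mesh_fp) ||
        !identical(fp, mesh_fingerprint(arc$blocks[[k]]$block$mesh)))
      stop("mesh fingerprint mismatch for block '", k, "' in archive at ", dir)
  }
  arc
}
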