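test_that("configuration sampling is deterministic, centred, and respects ranges", {
  spec <- list(list(kind = "T1"), list(kind = "B"))
  cfg0 <- pod_config(n_config = 3L, seed = 5L,
                     halfwidths = c(length_ratio = 0, bend = 0,
                                    outlet1_angle = 0, outlet2_angle = 0))
  cs0 <- sample_configurations(spec, cfg0)
  for (s in cs0) {
    expect_equal(s[[1]]$params$length_ratio, 1)
    expect_equal(s[[1]]$params$bend, 0)
    expect_equal(s[[2]]$params$outlet1_angle, 0)
  }
  cfg <- pod_config(n_config = 200L, seed = 9L)
  csA <- sample_configurations(spec, cfg)
  csB <- sample_configurations(spec, cfg)
  expect_identical(csA, csB)                      # fixed seed reproducibility
  lens <- vapply(csA, function(s) s[[1]]$params$length_ratio, 1)
  bends <- vapply(csA, function(s) s[[1]]$params$bend, 1)
  ps <- block_param_spec("T1")
  expect_true(all(lens >= ps$min[1] & lens <= ps$max[1]))
  # CLT check: sample mean within 3 standard errors of the base value
  se_len <- (0.1 / sqrt(3)) / sqrt(200)
  expect_lt(abs(mean(lens) - 1), 3 * se_len)
  se_bend <- (0.1745 / sqrt(3)) / sqrt(200)
  expect_lt(abs(mean(bends) - 0), 3 * se_bend)
})

test_that("Piola pullback: identity, rigid motions, and round trips", {
  blk <- build_reference_block("T1", 0.3)
  space <- build_taylor_hood_space(blk$mesh)
  set.seed(6)
  v <- rnorm(space$nu)
  mid <- nonaffine_map(blk, deformation_params("T1"))
  expect_equal(piola_pullback(mid, space, v), v, tolerance = 1e-13)
  # rigid motion: vhat = Q^T v, unit Jacobian determinant
  th <- 0.9
  mr <- nonaffine_map(blk, deformation_params("T1", rotation = th,
                                              translation = c(2, -1)))
  expect_equal(mr$det_jphi(space$dof_coords), rep(1, space$n_scalar))
  vh <- piola_pullback(mr, space, v)
  nsc <- space$n_scalar
  Q <- mr$Q
  expect_equal(vh[1:nsc], Q[1, 1] * v[1:nsc] + Q[2, 1] * v[nsc + 1:nsc],
               tolerance = 1e-12)
  # pushforward inverts pullback for a genuinely nonaffine map
  mn <- nonaffine_map(blk, deformation_params("T1", length_ratio = 1.4,
                                              radius_ratio = 0.8, bend = 0.3))
  expect_equal(piola_pushforward(mn, space, piola_pullback(mn, space, v)), v,
               tolerance = 1e-11)
})

test_that("Piola pullback preserves discrete divergence-freeness under affine stretches", {
  # solve a coupled Stokes flow on a stretched tube, pull the (discretely
  # divergence-free) velocity back to the reference block
  blk <- build_reference_block("T1", 0.25)
  mp <- nonaffine_map(blk, deformation_params("T1", length_ratio = 1.5))
  sd <- apply_deformation(blk, mp)
  geo <- compose_modular_geometry(list(sd))
  sys <- assemble_global_system(geo, build_basis_set(2L, 3L), fluid_properties())
  sol <- solve_steady(sys, Q = 1, stokes = TRUE)
  u_def <- sys_full_u(sys, 1, sol$Y)
  space_ref <- build_taylor_hood_space(blk$mesh)
  ops_ref <- assemble_constant_operators(space_ref, fluid_properties())
  expect_lt(max(abs(sys$sub[[1]]$ops$D %*% u_def)), 1e-9)   # div-free where solved
  uhat <- piola_pullback(mp, space_ref, u_def)
  # affine map: the pullback is exactly discretely divergence-free
  expect_lt(max(abs(ops_ref$D %*% uhat)), 1e-9)
  # nonaffine taper: divergence residual stays at interpolation-error scale
  mp2 <- nonaffine_map(blk, deformation_params("T1", radius_ratio = 1.3))
  sd2 <- apply_deformation(blk, mp2)
  sys2 <- assemble_global_system(compose_modular_geometry(list(sd2)),
                                 build_basis_set(2L, 3L), fluid_properties())
  sol2 <- solve_steady(sys2, Q = 1, stokes = TRUE)
  uhat2 <- piola_pullback(mp2, space_ref, sys_full_u(sys2, 1, sol2$Y))
  interp_scale <- max(abs(ops_ref$D %*%
    interpolate_velocity(space_ref, function(X)
      cbind(1 - (2 * X[, 2])^2, 0 * X[, 1]))))
  expect_lt(max(abs(ops_ref$D %*% uhat2)), 10 * max(interp_scale, 1e-3))
})

test_that("weighted POD reduces to plain SVD for X = I and satisfies the projection-error identity", {
  set.seed(20)
  S <- matrix(rnorm(40 * 12), 40)
  p1 <- weighted_pod(S, NULL, eps = 0)
  sv <- svd(S)
  expect_equal(p1$sv[1:12], sv$d, tolerance = 1e-12)
  for (i in 1:5) {
    expect_equal(abs(sum(p1$modes[, i] * sv$u[, i])), 1, tolerance = 1e-10)
  }
  # projection-error identity, with a random SPD weight
  X <- crossprod(matrix(rnorm(40 * 40), 40)) / 40 + diag(40)
  for (method in c("chol", "snapshots")) {
    pw <- weighted_pod(S, Matrix::Matrix(X, sparse = TRUE), eps = 0, method = method)
    expect_lt(max(abs(crossprod(pw$modes, X %*% pw$modes) - diag(ncol(pw$modes)))),
              1e-8)
    for (N in c(3L, 7L)) {
      V <- pw$modes[, 1:N]
      P <- V %*% crossprod(V, X)
      lhs <- sum(vapply(seq_len(ncol(S)), function(i) {
        r <- S[, i] - P %*% S[, i]
        sum(r * (X %*% r))
      }, 1))
      rhs <- sum(pw$sv[(N + 1):length(pw$sv)]^2)
      expect_equal(lhs, rhs, tolerance = 1e-8 * rhs)
    }
  }
})

test_that("POD truncation keeps the boundary case of the information-content rule", {
  # singular values (2, 1): one mode holds 4/5 of the energy; with
  # eps = sqrt(0.2) the rule 1 - eps^2 = 0.8 is met exactly at N = 1
  U <- qr.Q(qr(matrix(rnorm(16), 4)))
  S <- U[, 1:2] %*% diag(c(2, 1)) %*% t(qr.Q(qr(matrix(rnorm(4), 2))))
  p <- weighted_pod(S, NULL, eps = sqrt(0.2))
  expect_equal(p$n, 1L)
  p2 <- weighted_pod(S, NULL, eps = sqrt(0.2) * 0.999)
  expect_equal(p2$n, 2L)
})

test_that("supremizers solve their defining systems and raise the reduced inf-sup constant", {
  arc <- fix_archive()
  e <- arc$blocks[["T1"]]
  Xuff <- e$ops$Xu[e$ufree, e$ufree]
  Df <- e$ops$D[, e$ufree, drop = FALSE]
  Bints <- lapply(e$block$interfaces, function(ifc)
    assemble_interface_coupling(e$space, arc$basis, ifc, ifc$name,
                                sign = 1)[, e$ufree, drop = FALSE])
  sup <- compute_supremizers(Xuff, Df, e$Vp, Bints)
  expect_lt(sup$max_residual, 1e-10)
  # a tube has 2 interfaces: N_lambda coupling supremizers per interface
  expect_equal(ncol(sup$coupling), 2L * arc$basis$n_lambda)
  expect_equal(ncol(sup$pressure), ncol(e$Vp))
  # reduced inf-sup constant before/after enrichment (bases X-orthonormal,
  # so beta = smallest singular value of the reduced divergence matrix)
  snaps <- fix_snaps()
  pu <- weighted_pod(snaps$Su[["T1"]], Xuff, arc$eps_u)
  Vplain <- finalize_basis(pu$modes, Xuff)
  Venr <- finalize_basis(cbind(pu$modes, sup$pressure), Xuff)
  Xp <- e$ops$Xp
  pp <- weighted_pod(snaps$Sp[["T1"]], Xp, arc$eps_p)
  beta_of <- function(V) {
    Dn <- as.matrix(Matrix::crossprod(pp$modes, Df %*% V))
    min(svd(Dn)$d)
  }
  expect_gt(beta_of(Venr), beta_of(Vplain) + 1e-8)
})

test_that("Gram-Schmidt finalization is idempotent and drops duplicates", {
  arc <- fix_archive()
  e <- arc$blocks[["T1"]]
  Xuff <- e$ops$Xu[e$ufree, e$ufree]
  G <- as.matrix(Matrix::crossprod(e$Vu, Xuff %*% e$Vu))
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  again <- finalize_basis(e$Vu, Xuff)
  expect_equal(ncol(again), ncol(e$Vu))
  expect_lt(max(abs(again - e$Vu)), 1e-10)
  dup <- finalize_basis(cbind(e$Vu[, 1], e$Vu), Xuff)
  expect_equal(ncol(dup), ncol(e$Vu))             # exactly one copy survives
  expect_error(finalize_basis(e$Vu[, 0, drop = FALSE], Xuff), "empty")
})

test_that("offline archive passes its certificates; tighter tolerances enlarge the basis", {
  snaps <- fix_snaps()
  arc <- fix_archive()
  for (k in arc$kinds) {
    e <- arc$blocks[[k]]
    expect_true(all(diff(e$sv_u) <= 1e-12))       # non-increasing singular values
    expect_true(all(diff(e$sv_p) <= 1e-12))
    Xuff <- e$ops$Xu[e$ufree, e$ufree]
    G <- as.matrix(Matrix::crossprod(e$Vu, Xuff %*% e$Vu))
    expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
    Gp <- as.matrix(Matrix::crossprod(e$Vp, e$ops$Xp %*% e$Vp))
    expect_lt(max(abs(Gp - diag(ncol(Gp)))), 1e-8)
  }
  loose <- build_reduced_basis(snaps, eps_u = 1e-1, eps_p = 1e-2, enrich = FALSE)
  tight <- build_reduced_basis(snaps, eps_u = 1e-5, eps_p = 1e-7, enrich = FALSE)
  for (k in arc$kinds) {
    expect_gte(tight$blocks[[k]]$n_pod_u, loose$blocks[[k]]$n_pod_u)
    expect_gte(tight$blocks[[k]]$n_pod_p, loose$blocks[[k]]$n_pod_p)
  }
})

test_that("basis archives round-trip through disk with fingerprint checks", {
  arc <- fix_archive()
  dir <- tempfile("archive")
  save_basis_archive(arc, dir)
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  back <- load_basis_archive(dir)
  expect_equal(back$blocks[["T1"]]$Vu, arc$blocks[["T1"]]$Vu)
  # corrupt the manifest fingerprint: loading must fail loudly
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  man$blocks[["T1"]]$mesh_fingerprint <- "0-0-0-0"
  yaml::write_yaml(man, file.path(dir, "manifest.yaml"))
  expect_error(load_basis_archive(dir), "fingerprint mismatch")
  unlink(dir, recursive = TRUE)
})
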