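test_that("reference blocks satisfy their shape contracts", {
  for (k in 1:3) {
    blk <- build_reference_block(paste0("T", k), 0.25)
    bb <- apply(blk$mesh$nodes, 2, range)
    expect_equal(bb[2, 1] - bb[1, 1], k)       # axial extent = k diameters
    expect_equal(bb[2, 2] - bb[1, 2], 1)       # diameter 1
    expect_length(blk$interfaces, 2L)
    expect_equal(blk$interfaces[[1]]$role, "inlet")
  }
  b <- build_reference_block("B", 0.25)
  expect_length(b$interfaces, 3L)
  expect_equal(sum(vapply(b$interfaces, `[[`, "", "role") == "outlet"), 2L)
  expect_true(all(element_volumes(b$mesh) > 0))
  expect_error(build_reference_block("X"), "arg")
  expect_error(build_reference_block("T1", resolution = -1), "positive")
})

test_that("bifurcation parameter count is 6 in 3D and 2 in 2D", {
  expect_equal(nrow(block_param_spec("B", 3L)), 6L)
  expect_equal(nrow(block_param_spec("B", 2L)), 2L)
  expect_equal(nrow(block_param_spec("T2", 2L)), 3L)
})

test_that("identity parameters give the identity map", {
  blk <- build_reference_block("T2", 0.3)
  mp <- nonaffine_map(blk, deformation_params("T2"))
  X <- blk$mesh$nodes
  expect_equal(mp$phi(X), X, tolerance = 1e-14)
  J <- mp$jac_phi(X[1:5, , drop = FALSE])
  expect_equal(J[, 1, 1], rep(1, 5))
  expect_equal(J[, 1, 2], rep(0, 5))
  expect_equal(mp$det_jphi(X[1:5, , drop = FALSE]), rep(1, 5))
})

test_that("rigid motions preserve pairwise distances to machine precision", {
  blk <- build_reference_block("T1", 0.3)
  mp <- nonaffine_map(blk, deformation_params("T1", rotation = 0.8,
                                              translation = c(-3, 2)))
  X <- blk$mesh$nodes
  expect_equal(as.numeric(dist(mp$phi(X))), as.numeric(dist(X)),
               tolerance = 1e-13)
})

test_that("tube deformation scales, tapers and bends as prescribed", {
  blk <- build_reference_block("T1", 0.25)
  # axial scaling multiplies the bounding box extent
  mp <- nonaffine_map(blk, deformation_params("T1", length_ratio = 1.7))
  bb <- apply(mp$phi(blk$mesh$nodes), 2, range)
  expect_equal(bb[2, 1] - bb[1, 1], 1.7)
  # taper: deformed outlet radius = ratio x reference radius
  sd <- apply_deformation(blk, nonaffine_map(blk,
    deformation_params("T1", radius_ratio = 0.8)))
  expect_equal(sd$interfaces$outlet$radius, 0.4, tolerance = 1e-12)
  # bend: outlet normal rotated by the bend angle
  sdb <- apply_deformation(blk, nonaffine_map(blk,
    deformation_params("T1", bend = 0.3)))
  expect_equal(sdb$interfaces$outlet$normal, c(cos(0.3), sin(0.3)),
               tolerance = 1e-12)
  # Jacobian determinant positive at random interior points
  mpb <- nonaffine_map(blk, deformation_params("T1", length_ratio = 0.6,
                                               radius_ratio = 1.8, bend = 0.4))
  set.seed(1)
  P <- cbind(runif(200, 0, 1), runif(200, -0.5, 0.5))
  expect_true(all(mpb$det_jphi(P) > 0))
})

test_that("deformation parameters outside their admissible range error", {
  expect_error(deformation_params("T1", length_ratio = 5), "admissible")
  expect_error(deformation_params("T1", nonsense = 1), "unknown")
  expect_error(deformation_params("B", outlet1_angle = 2), "admissible")
})

test_that("apply_deformation keeps connectivity and rotates interface frames", {
  blk <- build_reference_block("T1", 0.3)
  id <- apply_deformation(blk, nonaffine_map(blk, deformation_params("T1")))
  expect_identical(id$mesh$elems, blk$mesh$elems)
  expect_equal(id$mesh$nodes, blk$mesh$nodes, tolerance = 1e-14)
  th <- 1.2
  rot <- apply_deformation(blk, nonaffine_map(blk,
    deformation_params("T1", rotation = th)))
  Q <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(rot$interfaces$outlet$normal,
               as.numeric(Q %*% blk$interfaces[[2]]$normal), tolerance = 1e-12)
  # deformed interfaces pass the segment fit test
  bent <- apply_deformation(blk, nonaffine_map(blk,
    deformation_params("T1", bend = 0.35, radius_ratio = 1.5)))
  for (ifc in bent$interfaces)
    expect_lt(ifc$fit_residual, 1e-8 * ifc$radius)
})

test_that("bifurcation deformation rotates outlet normals via harmonic extension", {
  blk <- build_reference_block("B", 0.25)
  sd <- apply_deformation(blk, nonaffine_map(blk,
    deformation_params("B", outlet1_angle = 0.25, outlet2_angle = -0.15)))
  rot <- function(th) matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(sd$interfaces$outlet1$normal,
               as.numeric(rot(0.25) %*% blk$interfaces[[2]]$normal),
               tolerance = 1e-9)
  expect_equal(sd$interfaces$outlet2$normal,
               as.numeric(rot(-0.15) %*% blk$interfaces[[3]]$normal),
               tolerance = 1e-9)
  # inlet untouched, all elements remain positively oriented
  expect_equal(sd$interfaces$inlet$centre, blk$interfaces[[1]]$centre,
               tolerance = 1e-12)
  expect_true(all(element_volumes(sd$mesh) > 0))
})

test_that("modular composition builds the interface graph", {
  g2 <- build_tree_geometry(list(list(kind = "T1"), list(kind = "T2")), 0.3)
  expect_length(g2$interfaces, 1L)
  expect_equal(g2$neighbours[[1]], 2L)
  expect_equal(g2$neighbours[[2]], 1L)
  expect_length(g2$inlets, 1L)
  # a tree of 9 blocks has 8 internal interfaces
  g9 <- build_tree_geometry(make_fixtures("tree9"), 0.34)
  expect_length(g9$interfaces, 8L)
  expect_length(g9$inlets, 1L)
  expect_equal(multiplier_dof_count(g9, 63L), 567L)
})

test_that("mismatched interfaces are rejected", {
  blk <- build_reference_block("T1", 0.3)
  s1 <- apply_deformation(blk, nonaffine_map(blk, deformation_params("T1")))
  # second tube offset sideways: interfaces do not match
  s2 <- apply_deformation(blk, nonaffine_map(blk,
    deformation_params("T1", translation = c(1, 0.1))))
  topo <- data.frame(j = 1, iface_j = "outlet", m = 2, iface_m = "inlet")
  expect_error(compose_modular_geometry(list(s1, s2), topo), "mismatch")
  # radius mismatch
  s3 <- apply_deformation(blk, nonaffine_map(blk,
    deformation_params("T1", radius_ratio = 0.7)))
  s4 <- apply_deformation(blk, nonaffine_map(blk,
    deformation_params("T1", translation = c(0.7, 0))))
  expect_error(compose_modular_geometry(
    list(s3, s4), data.frame(j = 1, iface_j = "outlet", m = 2, iface_m = "inlet")),
    "mismatch")
  # overlapping subdomains
  s5 <- apply_deformation(blk, nonaffine_map(blk,
    deformation_params("T1", translation = c(0.5, 0))))
  expect_error(compose_modular_geometry(list(s1, s5)), "overlap")
})

test_that("mesh I/O round-trips through Gmsh format", {
  blk <- build_reference_block("T1", 0.4)
  f <- tempfile(fileext = ".msh")
  write_msh(blk$mesh, f)
  back <- read_msh(f)
  expect_equal(back$nodes, blk$mesh$nodes, tolerance = 1e-12)
  expect_identical(back$elems, blk$mesh$elems)
  expect_identical(sort(back$facet_tag), sort(blk$mesh$facet_tag))
  unlink(f)
})
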