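# Shared small fixtures, built once per test run.
.fix <- new.env(parent = emptyenv())

fix_once <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

fix_square_space <- function() fix_once("square_space", function() {
  build_taylor_hood_space(mesh_rectangle(8, 8, 0, 1, 0, 1))
})

fix_square_ops <- function() fix_once("square_ops", function() {
  assemble_constant_operators(fix_square_space(), fluid_properties(1, 1))
})

fix_basis5 <- function() fix_once("basis5", function() build_basis_set(2L, 5L))

fix_two_tube <- function() fix_once("two_tube", function() {
  g <- build_tree_geometry(list(list(kind = "T1"), list(kind = "T1")), 0.2)
  sys <- assemble_global_system(g, fix_basis5(), fluid_properties(1, 0.04))
  list(geometry = g, sys = sys)
})

# Divergence-free, no-slip velocity on the unit square (curl of a bubble).
fix_divfree_field <- function(space) {
  psi <- function(x, y) (x * (1 - x) * y * (1 - y))^2
  h <- 1e-6
  interpolate_velocity(space, function(X)
    cbind((psi(X[, 1], X[, 2] + h) - psi(X[, 1], X[, 2] - h)) / (2 * h),
          -(psi(X[, 1] + h, X[, 2]) - psi(X[, 1] - h, X[, 2])) / (2 * h)))
}

# Small offline snapshot set shared by the ROM tests: two perturbed
# configurations of a two-tube chain, short horizon, coarse meshes.
fix_snaps <- function() fix_once("snaps", function() {
  spec <- list(list(kind = "T1"), list(kind = "T2"))
  cfg <- pod_config(eps_u = 1e-4, eps_p = 1e-6, n_config = 2L, seed = 42L)
  infl <- inflow_spec(5, t_ramp = -0.02, t0 = 0)
  offline_snapshots(spec, cfg, fix_basis5(), infl, T_end = 0.025,
                    scheme = bdf_scheme(2L, 2.5e-3), resolution = 0.25)
})

fix_archive <- function() fix_once("archive", function() {
  build_reduced_basis(fix_snaps())
})

fix_rom_sys <- function() fix_once("rom_sys", function() {
  snaps <- fix_snaps()
  geo <- build_tree_geometry(snaps$spec, blocks = snaps$blocks)
  assemble_global_system(geo, fix_basis5(), snaps$props)
})

# Observed convergence order from errors on a refinement ladder.
observed_order <- function(h, err) {
  stats::coef(stats::lm(log(err) ~ log(h)))[[2]]
}
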