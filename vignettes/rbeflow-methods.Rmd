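---
title: "Methods: a reduced-basis element solver for flow in modular vessel geometries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a reduced-basis element solver for flow in modular vessel geometries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Blood is modelled as an incompressible Newtonian fluid. On a domain
$\Omega$ with inlets, outlets and a rigid wall, the velocity $u$ and
pressure $p$ satisfy

$$\rho_f \partial_t u + \rho_f (u\cdot\nabla)u - \nabla\cdot\sigma(u,p) = f,
\qquad \nabla\cdot u = 0,$$

with Cauchy stress $\sigma(u,p) = 2\mu_f\,\varepsilon(u) - pI$ and
strain rate $\varepsilon(u) = (\nabla u + \nabla u^T)/2$. No-slip holds
on the wall, a velocity profile is prescribed on the inlets, and
homogeneous natural (traction) conditions on the outlets. All
quantities are in CGS units; the defaults $\rho_f = 1.06$ g cm$^{-3}$
and $\mu_f = 4\cdot 10^{-2}$ g cm$^{-1}$ s$^{-1}$ are standard values
for blood. The implementation works in two space dimensions; the
formulation is dimension-independent and the spectral interface basis
is also provided in its three-dimensional form (used for counting and
parameter metadata).

A note on a convention: the momentum mass matrix is weighted by the
density $\rho_f$, consistently with the $\rho_f\,\partial_t u$ term of
the weak form (the viscosity belongs to the stiffness term only).

## Modular geometry

A target vessel is composed of subdomains
$\Omega^j = \Phi(\hat\Omega^{z_j};\mu^j)$, deformed copies of reference
building blocks: tubes `T1`, `T2`, `T3` of unit diameter and
length/diameter ratios 1, 2, 3, and a symmetric bifurcation `B` (an
equilateral junction core with three unit-width channels at 120°). The
map is $\Phi(\hat x) = Q\,\chi(\hat x;\tilde\mu) + t$ with $Q$ a
rotation and $t$ a translation.

For tubes, $\chi$ is analytic with three parameters: an axial length
ratio $s$, an outlet-radius ratio $r_1$ (linear taper from the inlet),
and a bend angle $\alpha$ that wraps the centreline around a circular
arc of length $s\hat L$ while keeping cross-sections normal to it. Its
Jacobian is closed-form,
$J_\chi = R(\varphi)\,\begin{pmatrix} s - \hat y\, r \alpha/\hat L & 0\\ \hat y\, r' & r\end{pmatrix}$
in the rotating tangent/normal frame, so $\det J_\chi =
r\,(s - \hat y\, r\,\alpha/\hat L)$, and admissibility of the
parameters (no inverted elements) reduces to positivity of that
expression; the admissible bend range $|\alpha| \le 0.4$ rad keeps it
positive for all admissible ratio combinations of every tube kind. The
concrete form of $\chi$ (scaling + linear taper + circular-arc bend)
was chosen as the simplest map that realizes exactly these three
parameters with a closed-form Jacobian; any smooth map with the same
boundary behaviour would serve.

The composite Jacobian used everywhere (in particular in the Piola
transformation) is $J_\Phi = Q\,J_\chi$, the derivative of
$\Phi = Q\chi + t$; its correctness is verified numerically by the
divergence-preservation property of the Piola pullback rather than
assumed.

For the bifurcation, $\chi$ rotates each outlet about its centre by a
prescribed angle and extends the boundary displacement into the volume
by a componentwise harmonic (Laplace) solve with zero displacement on
the inlet and natural conditions on the walls — cheaper than a full
linear-elasticity extension and adequate in the small-rotation regime
($|\theta| \le 0.3$ rad) to which this block is restricted. In that
regime the Jacobian is approximated by the identity wherever it is
needed pointwise (Piola), which is consistent with the
small-deformation restriction.

Blocks are placed by a tree specification: each child's inlet is
matched to its parent's outlet by a rigid motion computed from the
interface descriptors (centre, half-width, normal). Matched interfaces
must agree to a relative tolerance of $10^{-6}$; the deformed
interfaces remain straight segments (circles in 3D) by construction of
the admissible deformations, and this is verified by a segment-fit
residual on the deformed boundary facets. The side with the lower
subdomain index is the "+" side of each internal interface
(orientation sign $+1$) — an arbitrary but fixed convention that makes
multiplier coefficients reproducible.

## Discretization

Each subdomain carries Taylor–Hood P2–P1 elements on a triangulation of
its reference block mapped to the deformed configuration (the meshes
are generated as structured triangulations; Gmsh 2.2 import/export is
provided as an alternative path). Assembly happens directly on the
deformed meshes; element integrals use a 7-point degree-5 rule, exact
for every bilinear form with P2 data including the convective
trilinear form on affine elements. Wall no-slip is eliminated strongly
(the wall DOFs are removed from the unknowns); inlets are imposed
weakly through multipliers; outlets are natural.

Weak interface continuity
$\int_\Gamma \eta\cdot(u^j - u^m) = 0$ is discretized one-sidedly: the
integral is split into two one-sided contributions, each evaluated with
that side's own mesh and trace functions against the mapped multiplier
basis, with opposite orientation signs. This is what makes the
nonconforming coupling projection- and interpolation-free.

**Interface basis.** On the 3D reference disk the scalar modes are
ridge polynomials $P^n_k(x,y) = U_n(x\cos\omega_k + y\sin\omega_k)$,
$\omega_k = k\pi/(n+1)$, $0\le k\le n$, with $U_n$ the Chebyshev
polynomials of the second kind; the family is orthonormal under the
weight $W = 1/\pi$ on the disk with normalization constant 1 (the
package certifies this numerically: the Gram matrix under a
tensorized Gauss–Legendre rule in radius/angle of order $\ge 2n+2$
equals the identity to $10^{-8}$; the orthonormality statement, not a
printed constant, is treated as the defining property). The
vector-valued set multiplies every scalar mode by each canonic vector,
giving $N_\lambda = d(n+1)(n+2)/2$. In 2D the reference interface is
$[-1,1]$, the scalar modes are $U_0,\dots,U_n$ — orthonormal under
$(2/\pi)\sqrt{1-x^2}$, integrated exactly with the Gauss–Chebyshev
(second kind) rule — and $N_\lambda = 2(n+1)$; this is the natural
one-dimensional analogue of the disk construction. The default degree
is $n = 5$ in both dimensions. Ordering is degree-major within each
Cartesian component and component-major overall, fixed so coupling
matrices are bit-for-bit reproducible.

A practical constraint worth knowing: each interface must expose at
least $N_\lambda$ free trace DOFs, otherwise the constraint block is
rank-deficient; the assembler checks this and reports which interface
is too coarse. With $n = 5$ in 2D this requires at least 4 elements
across a channel.

**Multiplier interpretation.** For the converged coupled solution the
multiplier equals the negative interface traction of the "+" side,
$\lambda = -\sigma(u,p)\,n^+$, projected onto the spectral span — the
sign follows from adding the coupling term to the momentum residual;
only the orientation convention differs from stating that the
multiplier *is* the interface stress. The acceptance suite verifies
this quantitatively on a conforming Poiseuille flow.

## Time stepping and the nonlinear solver

BDF schemes of order 1 ($\alpha = 1, \beta = 1$) and 2
($\alpha = (4/3, -1/3), \beta = 2/3$) discretize the global residual
$R(Y_{k+1}) = H Y_{k+1} - \sum_j \alpha_j H Y_{k-j+1} -
\Delta t\,\beta\, F_\circ(t_{k+1}, Y_{k+1})$ over the unknowns
$Y = (u^1, p^1, \dots, \lambda^{[1]}, \dots)$, with $H$ carrying the
velocity mass blocks only. With BDF2 the first step falls back to
backward Euler; since runs start from rest inside the inflow ramp this
costs no observable accuracy. The default timestep is
$\Delta t = 2.5\cdot10^{-3}$ s.

Start-up uses the cosine ramp
$Q(t) = Q_0\,[1 - \cos((t - t_0^{\mathrm{ramp}})\pi/(t_0 -
t_0^{\mathrm{ramp}}))]/2$ on $[t_0^{\mathrm{ramp}}, t_0]$ (defaults
$-2\cdot10^{-2}$ s to 0 s), continuous at both ends, so the impulsive
start of the inflow never excites the scheme.

Newton's method solves each step with the exact convective
linearization $C(u) + C'(u)$ by default (the frozen Stokes tangent is
available behind a flag and is the reduced model's default, see below).
Convergence is declared at a relative residual of $10^{-6}$ (at most
20 iterations, one non-monotone step tolerated); an absolute floor
scaled by the largest initial step residual seen so far prevents
spurious failures at steady states where the step residual is already
at roundoff.

**Linear solves.** The tangent has a saddle-point structure over
(velocity–pressure, multipliers). The block preconditioner eliminates
the multipliers through the Schur complement
$S = -\tilde B \tilde A^{-1}\tilde B^T$, assembled column-by-column by
applying per-subdomain (approximate) local inverses — the
block-diagonality of $\tilde A$ makes every column a sum of local
solves. $S$ is small (multiplier count squared), stored dense, QR
factorized, and by default refreshed only every 20 applications; local
inverses are exact sparse LU, inner GMRES (tolerances $5\cdot10^{-1}$
or $10^{-2}$ in the robustness study), or a single SIMPLE sweep (exact
momentum predictor, pressure Schur complement built from the momentum
diagonal). With exact local solves the preconditioner *is* the system
inverse and the outer flexible GMRES (restart 100, tolerance
$10^{-8}$, chosen below the Newton tolerance) converges in one or two
iterations; that exactness is asserted in the tests. For desk-scale
problems the default time loop simply uses a monolithic sparse LU —
identical results, and the preconditioner paths are exercised
separately by the solver studies.

## The reduced model

**Snapshots.** The offline phase runs the coupled FE model on
configurations drawn by perturbing each subdomain's nonaffine
parameters with uniform distributions centred on the base values.
Default half-widths: 10% for tube length ratios, 10° (0.1745 rad) for
tube bends and bifurcation outlet angles; radius ratios are *not*
perturbed by default because a tapered outlet would break the exact
interface-radius matching that the composition requires — a deliberate
trade of sampling richness for geometric consistency (taper is still
exercised directly in the unit tests). Draws falling outside the
admissible ranges are redrawn (capped). Every timestep after the ramp
contributes a snapshot (configurable stride); velocity snapshots are
pulled back to the reference block with the discrete Piola
transformation evaluated at the P2 DOF coordinates, pressure snapshots
are used as-is.

What this synthetic campaign emulates — and what it does not: it
reproduces the geometric variability of a vessel segment family around
a base anatomy, a pulsatile-free inflow with a smooth ramp, rigid
walls, and Newtonian rheology. It does not emulate patient-specific
anatomies outside the deformation family, wall compliance, flow
waveform variability, or measurement noise; a basis that passes the
self-consistency studies here is therefore validated for the
*method*, not for any particular clinical geometry.

**Weighted POD.** For an SPD norm matrix $X = H^TH$ (sparse Cholesky),
the modes are $U = H^{-1}\tilde U$ with $\tilde U$ from the SVD of
$HS$; they are $X$-orthonormal and minimize the $X$-norm snapshot
projection error, whose value equals the sum of squared discarded
singular values (asserted to $10^{-8}$ in the tests). A Gram-matrix
(method-of-snapshots) route gives identical results and is selected
automatically when snapshots are few relative to the DOF count.
Truncation keeps the smallest $N$ whose relative information content
$\sum_{i\le N}\sigma_i^2 / \sum_i \sigma_i^2$ reaches $1-\varepsilon^2$;
the boundary case (content exactly at the threshold) is kept. Velocity
uses the $H^1$ norm, pressure the $L^2$ norm. Mode signs are fixed
(largest-magnitude entry positive) for reproducibility.

**Supremizers.** Reduced saddle-point problems lose inf–sup stability
even when the underlying FE pair is stable, so the velocity basis is
enriched with one velocity lifting per pressure mode
($X_u s_l = D^T\eta_l$) and one per multiplier basis function of
*every* interface of the block ($X_u z_l = B^{[m]T}e_l$, $m = 1,2$ for
tubes, the three interfaces for the bifurcation — inlet interfaces use
the same machinery as internal ones, so enriching all of them covers
both roles a tube interface can play in a composition). The
concatenation (POD modes first, then pressure and coupling
supremizers) is $X_u$-orthonormalized by modified Gram–Schmidt with two
passes and a relative drop tolerance of $10^{-8}$ for near-dependent
columns. The tests verify that enrichment strictly increases the
reduced inf–sup constant.

**Online phase.** Per subdomain, the reference velocity basis is pushed
forward by the Piola map of that subdomain's deformation (recomputed
online, since it depends on the geometric parameters), and the FE
operators assembled on the deformed mesh are projected:
$M^N = V^TMV$, etc. Coupling matrices are projected on the velocity
side only — the multiplier space is never reduced; it is already small.
The reduced Newton iteration uses the frozen (Stokes) tangent: constant
in time, so its per-subdomain blocks and the reduced multiplier Schur
complement are factorized once per $\Delta t\beta$ and reused by every
step. The frozen tangent is inconsistent, so Newton converges linearly
rather than quadratically (typically 5–10 iterations per step at a
$10^{-8}$ tolerance); an exact reduced tangent exists for debugging.

The convective term is evaluated either by projecting a freshly
assembled full-order convective product (reference strategy) or by
contracting the precomputed tensor
$T[i,l,m] = \int_{\Omega^j}\rho_f[(\zeta_m\cdot\nabla)\zeta_l]\cdot\zeta_i$
— the density is included, consistently with the convective matrix it
replaces. Both strategies agree to solver precision when the tensor is
untruncated, and the tensor's double sum may be truncated to the first
$N_c$ modes (default: no truncation), justified by the rapid decay of
the reduced velocity coefficients; the acceptance study measures the
error inflation at $N_c = N/4$.

**Error metrics.** Reported errors are time-integrated relative broken
norms: $e_u^2 = \int \|u^h - u^N\|^2_{b,V}\,/\int\|u^h\|^2_{b,V}$ with
the broken norm the root-sum-of-squares of per-subdomain $H^1$ norms
(analogously $e_p$ with $L^2$), trapezoidal in time, by default over
the post-ramp interval.

## Study sizes and numerical choices in the test suite

The suite runs desk-scale versions of the full studies; the sizes were
chosen once as the smallest problems on which the measured properties
are in their asymptotic regime:

- Spatial convergence: steady Stokes with a manufactured solution on
  the unit square, meshes $16^2, 32^2, 64^2$ cells with interior nodes
  perturbed by up to $0.28h$ — a perfectly structured grid
  superconverges in pressure and would mask the generic order. The
  observed order is measured on the finest mesh pair, where the
  preasymptotic transient of the pressure error has decayed.
- Temporal convergence: a six-dimensional manufactured linear system
  driven through the package's BDF residual and Newton solver, halving
  $\Delta t$ three times, with exact history seeding so the start-up
  does not pollute the order.
- ROM convergence: five perturbed configurations of a three-tube chain
  (`T1–T2–T1`, mesh size 0.25 diameters), BDF2 with
  $\Delta t = 2.5\cdot10^{-3}$ s, ramp plus 32 post-ramp steps;
  a 3×3 grid of POD tolerances
  $\varepsilon_u \in \{1.6\cdot10^{-2}, 2\cdot10^{-3},
  2.5\cdot10^{-4}\}$, $\varepsilon_p \in \{10^{-3}, 10^{-4}, 10^{-5}\}$
  spanning the same orders of magnitude as the full-scale tolerance
  studies.
- Preconditioner robustness: chains of 2–8 `T1` tubes, one BDF-scaled
  Stokes tangent solve each, SIMPLE policy, at multiplier degrees
  $n = 0$ and $n = 5$.

Degenerate and invalid inputs fail loudly by design: inadmissible
deformation parameters, inverted elements, mismatched or dangling
interfaces, overlapping subdomains, zero-radius interfaces, too-coarse
interfaces relative to $N_\lambda$, and basis archives whose reference
meshes do not match the target geometry (checked through mesh
fingerprints recorded in the archive manifest).

## Known limitations

- The finite-element solver is two-dimensional; the 3D code paths
  cover the interface basis, DOF counting on tetrahedra and parameter
  metadata, not assembly.
- Physical parameters ($\rho_f$, $\mu_f$) are inputs of both phases
  but are not sampled in the offline campaign; a basis is tied to the
  fluid it was generated with.
- The convective term of the reduced residual is evaluated exactly
  (projected or tensor-contracted), not hyper-reduced; the setup cost
  of the tensor grows quadratically with the retained modes.
- Outlet radius ratios are excluded from random sampling (interface
  matching, see above), and the bifurcation deformation is limited to
  small outlet rotations.
- Walls are rigid; there is no fluid–structure interaction.
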