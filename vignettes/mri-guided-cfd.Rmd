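---
title: "MRI-guided finite-volume hemodynamics: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MRI-guided finite-volume hemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowfusion)
```

# The problem

Phase-contrast MRI (PC-MRI) measures three-component velocity maps of blood
flow directly, but at limited resolution, with partial-volume blurring and
Gaussian velocity noise, and the measured field does not satisfy the
equations of fluid motion (its discrete divergence is visibly nonzero inside
the vessel lumen).  Conventional CFD solves those equations at arbitrary
resolution but inherits every modeling assumption (rigid walls, Newtonian
viscosity, idealized geometry).  `flowfusion` fuses the two: a finite-volume
incompressible Navier–Stokes solver whose momentum solves are replaced by the
closed-form minimizers of a generalized-Tikhonov objective that pulls the
solution toward the measured velocity volumes.

# Flow model and discretization

Blood is modeled as an incompressible, isothermal Newtonian fluid with
constant density $\rho$ and dynamic viscosity $\mu$:

$$\rho\left(\frac{\partial \vec\nu}{\partial t}
   + \vec\nu\cdot\nabla\vec\nu\right) = -\nabla p + \mu\,\Delta\vec\nu,
  \qquad \nabla\cdot\vec\nu = 0,$$

with $\vec\nu = (u, v, w)$.  The domain is a uniform Cartesian grid of
$N = n_x n_y n_z$ pressure cells; velocities live on cell faces (the
staggered/MAC arrangement, which suppresses checkerboard pressure modes).
Cell labels (`WALL`, `FLUID`, `INLET`, `OUTLET`) embed the vessel lumen in
the rectangular box; inlet and outlet layers sit on the boundary z-planes,
which is the through-vessel axis by convention.

Finite-volume momentum assembly uses Patankar's power-law
convection–diffusion scheme,
$a_{nb} = D\,\max\!\big(0, (1 - 0.1|P|)^5\big) + \max(\mp F, 0)$ with
$P = F/D$, the canonical choice for this solver family: it reduces to central
differencing at low cell Péclet number and to upwinding at high, and keeps
every momentum matrix an M-matrix (positive diagonal, nonpositive
off-diagonals, at most seven nonzeros per row under the fixed x-fastest
ordering).  A pseudo-transient term $\rho\,\Delta V/\delta t$ on the diagonal
(and the previous step's velocity in the source) provides implicit
relaxation; steady states are reached by pseudo-time continuation.

## Masked-box wall treatment

The solver works on the full rectangular box; faces between two FLUID cells
are unknowns and every other face carries a Dirichlet value.  Faces on a
fluid–wall interface enforce no-slip exactly at their own location; wall
ghost faces (both neighbor cells solid) act at half a cell spacing, so their
diffusive conductance is doubled — this is what lets the lid-driven cavity
impose a moving-wall velocity without a body-fitted mesh.  This first-order
immersed (staircase) treatment is the simplest representation consistent
with a mask-only geometry description.  Its cost is an $O(h)$ velocity error
in the cells touching a voxelized curved wall: on a 16-cell-diameter pipe the
wall-adjacent cells are off by up to $\sim 7\%$ of the peak velocity purely
because the staircase wall is not the circular wall, while cells one layer in
agree with the analytic parabola to better than $3\%$.  For this reason all
profile comparisons against smooth-geometry analytic solutions in the tests
are made on the *resolved* interior (`resolved_fluid_cells()`), and the
wall-adjacent layer should be treated as geometrically uncertain in any
downstream analysis.

## SIMPLER coupling

Each coupling pass follows the standard SIMPLER sequence: (1) momentum
coefficients and pseudo-velocities $\hat u = (\sum a_{nb} u_{nb} + b)/a_P$;
(2) a pressure equation driven by the pseudo-velocity mass imbalance;
(3) momentum solves using that pressure (the stage where measurement
regularization enters); (4) a pressure-correction equation from the starred
velocities; (5) additive velocity correction, which restores discrete
continuity to linear-solver accuracy.  The pressure is taken from the
pressure equation and never corrected — the feature that distinguishes
SIMPLER from SIMPLE and removes the need for an initial pressure guess; the
initial condition is a velocity estimate (a flux-matched plug profile by
default).

Because prescribed-velocity boundaries make the pressure system pure-Neumann,
one reference FLUID cell is pinned to zero, and outlet profiles are rescaled
at setup so the outlet volume flux balances the inlet flux exactly
(otherwise the discrete Poisson problem is incompatible and continuity can
never converge).

Linear systems are solved with BiCGSTAB (Jacobi-preconditioned, warm-started
from the previous iterate), matching the nonsymmetric structure of the
convection–diffusion systems.

## Convergence accounting

Two nested criteria are recorded separately, because they measure different
things: inside a pseudo-time step, SIMPLER passes repeat until
$\max |\nabla\cdot\vec\nu| \le$ `div_tol` over FLUID cells (usually one to
two passes, since the velocity correction enforces continuity by
construction); across steps, the run stops when the rate
$\lVert\vec\nu(t+\delta t)-\vec\nu(t)\rVert/\delta t$ (RMS over solver
unknowns, so the measure is grid-size independent) drops below `eps`.
Solver results carry both counters plus full residual histories, so either
accounting of "iterations to convergence" can be reported.  Runs that hit
the caps are flagged `converged = FALSE`, never silently returned.

# Fusing the measurements

Let $\mathbf S\,\mathbf x = \mathbf f$ be one component's momentum system and
$\mathbf m$ the stacked measured voxel values of that component.  The guided
solve minimizes

$$J(\mathbf x) = \tfrac12\lVert \mathbf S \mathbf x - \mathbf f\rVert^2
  + \tfrac{\lambda}{2}\lVert \Gamma \mathbf x - \mathbf m\rVert^2,$$

whose minimizer solves
$(\mathbf S^T\mathbf S + \lambda \Gamma^T\Gamma)\,\mathbf x =
 \mathbf S^T\mathbf f + \lambda\Gamma^T\mathbf m$.  The normal equations are
solved matrix-free with preconditioned conjugate gradients (only products
with $\mathbf S$, $\Gamma$ and their transposes are formed), to a residual
tolerance far below the requested solution accuracy because the normal
equations square the conditioning.  With $\lambda = 0$ the solve reduces
exactly to the plain momentum solve, and the whole solver to the pure-CFD
pathway.  Because the velocity-correction stage runs after every guided
momentum solve, the converged field satisfies discrete continuity regardless
of $\lambda$: the result is the divergence-free flow closest, in this
weighted least-squares sense, to the measurements.

## The operator $\Gamma$

For a Cartesian 3DFT acquisition the point-spread function is the separable
sinc $\psi(x,y,z) = \mathrm{sinc}(x/\delta_x)\,\mathrm{sinc}(y/\delta_y)\,
\mathrm{sinc}(z/\delta_z)$ with $\delta$ the MRI voxel size, truncated to
$|x| \le 2\delta_x$ (etc.) by a box window.  Each row of $\Gamma$ samples
this kernel, centered on one MRI voxel, at the CFD cell centers.  Three
design choices are worth stating explicitly:

* **Row normalization.**  Rows are scaled to unit sum.  The raw sampled
  kernel does not sum to one (and edge rows lose part of their support), so
  without normalization a constant velocity field would not be a fixed point
  of the operator — physically untenable for velocity data.  Edge rows are
  renormalized over their clipped support; this is an assumption about how
  volume boundaries were reconstructed, and is the package's choice.
* **Staggered-to-centered composition.**  The objective compares solver
  unknowns (face velocities) with voxel data (cell-centered).  The penalty
  operator used internally is $\Gamma A$, where $A$ is the two-point
  face-to-center averaging map: this preserves the closed-form solution with
  $\Gamma \leftarrow \Gamma A$ and is the minimal consistent reading.
* **Missing data.**  Rows for unmeasured voxels (or whole components) are
  simply omitted, giving $M < N$; per-component row masks express
  reduced-coverage protocols.  By default the penalty is restricted to lumen
  voxels — static tissue carries no flow information.

When the MRI and CFD grids coincide, the sampled truncated sinc is 1 at zero
offset and 0 at every other grid point, so $\Gamma$ is the identity — the
equal-resolution phantom configuration, also available explicitly via
`identity = TRUE`.

## $\lambda$ and its scale

$\lambda$ is dimensionless but *not* scale-free: it balances
$\lVert\mathbf S\mathbf x - \mathbf f\rVert^2$, whose magnitude is set by the
momentum coefficients (dominated by $\rho\Delta V/\delta t$ plus diffusive
conductances), against a velocity-squared misfit.  Guided runs at equal
resolution use $\lambda = 1$, which is deep in the data-dominated regime —
appropriate when the measurement is trusted (high-SNR phantom data) and the
aim is the divergence-free field closest to it; this is also what makes
guided runs converge in a handful of pseudo-time steps.  The denoising
study instead sweeps $\lambda \in \{5\times10^{-9},\dots,5\times10^{-6}\}$,
which brackets the balance point of the default solver configuration
($\delta t = 2\,\mathrm{ms}$, $0.5\times0.5\times1\,\mathrm{mm}$ cells),
putting the classic Tikhonov trade-off on display: SER against the clean
truth rises from the pure-CFD value, peaks at an interior $\lambda$, and
falls toward the (continuity-projected) noisy data as $\lambda$ grows.

# The synthetic PC-MRI generator

The generator exists so that every pipeline stage is testable without scan
data.  It emulates, in order: face-to-center averaging of the true field;
truncated-sinc blurring (zero-padded — velocities genuinely vanish outside
the lumen, so zero extension is the physically correct boundary model);
box-average resampling onto a coarser MRI grid when requested; i.i.d.
zero-mean Gaussian noise per component and voxel (the standard PC-MRI noise
model at reasonable SNR), seeded for exact reproducibility; optional VENC
aliasing $((v + \mathrm{VENC}) \bmod 2\,\mathrm{VENC}) - \mathrm{VENC}$,
single-wrap by design since clinical wraps are corrected one period at a
time; and optional linear per-component velocity offsets
$ax + by + cz + d$ emulating eddy-current residuals.

Default study conditions follow the acquisition they emulate: noise
$\sigma = 8\ \mathrm{cm/s}$ for the denoising study, VENC $= 50\ \mathrm{cm/s}$,
$0.5\times0.5\times1.0$ mm voxels, phantom fluid $\rho = 1100$ kg/m³ and
$\mu = 0.005$ Pa·s, blood $\rho = 1060$ kg/m³ and $\mu = 0.0032$ Pa·s.

What the generator does *not* emulate: magnitude-dependent noise (velocity
noise grows where signal magnitude is low), k-space raw data and coil
combination, eddy-current physics beyond the linear term, motion, and
geometric distortion.  Passing tests therefore demonstrate correctness of
the solver and of the stated measurement model — not robustness to every
artifact of real scans.

## Phantoms and ground truth

* **Pipe** (`generate_poiseuille()`): circular lumen along z with the
  analytic profile $w(r) = w_{\max}(1 - (r/R)^q)$.  $q = 2$ is the steady
  Hagen–Poiseuille parabola used for solver validation.  The denoising study
  uses $q = 4$, a flattened (blunted) profile of the kind produced by
  pulsatile inflow at peak systole: this builds genuine *model mismatch*
  into the synthetic truth — the steady solver relaxes toward a parabola
  downstream, just as real CFD deviates from real vessels — without which a
  denoising comparison would be vacuous (the pure-CFD solution would equal
  the truth by construction).
* **Bifurcation** (`generate_bifurcation()`): a voxelized planar Y-geometry
  with parabolic inflow.  Its ground truth is the solver's own converged
  solution (declared as such); it is used for the convergence-acceleration
  comparison, where the question is how fast each mode reaches *a* steady
  state, not whose steady state is right.
* **Cavity** (`generate_cavity()`): the classical 2-D lid-driven benchmark,
  run as a one-cell-thick slab (the spanwise direction is a symmetry plane)
  with explicit wall layers carrying the lid velocity.

# Numerical choices and problem sizes

Defaults: `relax_u = 0.7` and `relax_p = 0.3` (standard practice for this
solver family; the cavity benchmark sets `relax_p = 1`, which is safe in
SIMPLER because pressure is recomputed each pass, and converges faster
there); `lin_tol = 1e-8` relative for all inner solves; `div_tol` and `eps`
are physical tolerances the user sets per problem — the shipped study
configurations use `div_tol = 1e-4` s⁻¹ and `eps` of $10^{-4}$–$10^{-3}$
(m/s)/s, at which the remaining transient amplitude is far below the
discretization error.  The pseudo-time step trades stability for steps to
convergence; the study configurations use $\delta t$ between 2 and 50 ms,
roughly a tenth of the viscous relaxation time of each problem.  Ties and
degenerate inputs: the pressure nullspace is pinned at the first FLUID cell;
an all-zero right-hand side short-circuits to a zero solution; BiCGSTAB
breakdown raises an error carrying the residual rather than returning
silently.

Study problem sizes are chosen so a full regularized run takes seconds to a
couple of minutes on one core: pipes of $16\times16\times48$ and
$12\times12\times32$ cells, a $20\times12\times32$ bifurcation, cavities of
$33^2$ and $65^2$.  These are deliberately smaller than clinical volumes;
nothing in the architecture changes at larger $N$ beyond solve time, since
all operators are sparse and matrix-free where it matters.

# Known limitations

Rigid walls, Newtonian viscosity, uniform grids (no local refinement near
walls, so wall shear stress is out of reach), steady states per cardiac
phase rather than time-accurate pulsatile solutions, first-order staircase
geometry, and manual $\lambda$ (no L-curve/GCV selection).  The in-plane
velocity components of a one-cell-thick inlet layer are imposed on the
layer's internal faces only, a half-cell approximation of the measured
boundary plane.  These match the scope of the method as a proof of concept;
the regularized-solve construction itself is discretization-agnostic and
would transfer unchanged to finite-element or body-fitted solvers.
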