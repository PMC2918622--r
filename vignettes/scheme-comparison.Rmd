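---
title: "Convection scheme choice and aneurysm mass transport: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Convection scheme choice and aneurysm mass transport: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Blood-side mass transport (BSMT) studies ask how the flowing blood carries a
species — oxygen, free radicals, drugs, tracers — toward and along the vessel
wall.  At physiological Schmidt numbers (Sc ~ 10^3) the transport is strongly
convection dominated: with Re = 800 and Sc = 3200 the Peclet number is
Pe = Re Sc = 2,560,000.  A finite-volume discretisation of the scalar
transport equation

    d(rho phi)/dt V + sum_f (rho v . A)_f phi_f = sum_f Gamma (grad phi . A)_f + S V

needs a *face value* `phi_f` interpolated from cell-centre values, and at
high Pe the interpolation rule — the convection-diffusion discretisation
scheme — controls the answer.  First-order upwinding introduces *false
(numerical) diffusion* wherever the flow crosses the grid obliquely, which
in a recirculating aneurysm sac means everywhere that matters.  This package
implements the full desk-scale pipeline to demonstrate and quantify that
effect: an idealised axisymmetric aneurysm, a steady laminar flow solver, an
unsteady passive-species solver with four interchangeable face-interpolation
schemes, and a hemispherical probe emulating a fluid-extraction measurement.

## Geometry and mesh

The idealised aneurysm is a 25.1 mm diameter tube whose wall bulges to a
maximum diameter of 50.2 mm over a sac 75.3 mm long.  Only the three
defining dimensions are fixed by the model; the bulge profile itself is
taken as the raised-cosine curve

    r_w(z) = r_in + (r_max - r_in) sin^2(pi z / L),   0 <= z <= L,

which is smooth, symmetric, and meets the straight tube tangentially.  No
claim is made that this matches any particular glass model's curvature;
sensitivity to the profile is not asserted.  Straight extensions (default 2
inlet diameters upstream, 4 downstream) keep the outflow boundary away from
the recirculation.

The structured quadrilateral mesh is body fitted: uniform axial stations,
radial lines scaled to the local wall radius, optional geometric grading
toward the wall (`wall_stretch`, the axis-cell to wall-cell height ratio;
grading preserves the relative height distribution under refinement, so
refinement sequences stay geometrically similar).  All axisymmetric measures
are stored per radian of revolved angle: the 2*pi factor cancels in every
balance.  Face areas are the exact per-radian swept areas (`mean(r) *
segment length` along the segment normal) and cell volumes the exact swept
volumes (second Pappus rule, evaluated edgewise).  One representational
subtlety: the per-radian closure of a control volume includes the two flat
wedge side faces, whose radial projected area equals the planar cell area.
The Green-Gauss gradient and the radial pressure force both carry this
wedge term; with planar-centroid cell centres the gradient of a linear
field is then exact on uniform grids, which is the property the
second-order upwind scheme relies on.

Mesh quality is reported as the equiangle skew
`max((theta_max - 90)/90, (90 - theta_min)/90)` and the opposite-edge-pair
aspect ratio.  The default 240 x 60 aneurysm mesh has maximum skew 0.307
and maximum aspect ratio 4.5, inside the usual quadrilateral quality bounds
(skew < 0.7, aspect <= 5).

## The four schemes

All four schemes are exposed both as pure face-value functions
(`fou_face()`, `power_law_face()`, `sou_face()`, `quick_face()`) and inside
the assembled solver:

* **First-order upwind (FOU)** — the face value is the upstream cell value.
  Unconditionally bounded, and the reference against which the deferred
  correction is measured.
* **Power law** — the face value is read from the exact exponential solution
  of the 1-D constant-coefficient convection-diffusion equation between the
  two adjacent cell centres, `(e^(Pe s) - 1)/(e^Pe - 1)`.  The package
  evaluates the exponential form exactly (shifted-exponential rescaling, no
  overflow to |Pe| = 10^7); Patankar's quintic `A(|Pe|) = max(0,
  (1 - 0.1|Pe|)^5)` is available as `power_law_method = "patankar"`,
  converted to the equivalent face weight.  As |Pe_face| grows the weight
  collapses onto pure upwinding — the high-Pe equivalence with FOU that the
  field-level runs reproduce.
* **Second-order upwind (SOU)** — Taylor extrapolation `phi_P + grad phi .
  delta_s` with the upwind-cell Green-Gauss gradient.
* **QUICK** — three-point upstream-weighted quadratic interpolation on a
  possibly non-uniform stencil with blend weight `psi`.

**The psi question.**  Expanding the blended QUICK formula at uniform
spacing gives Leonard's classical coefficients (6/8, 3/8, -1/8) at
`psi = 3/4` — not at 1/8, the value sometimes quoted (apparently inherited
from solver documentation).  The package default is therefore `psi = 3/4`;
`psi` is a configuration knob and both values are regression-tested.  The
discrepancy is flagged, not resolved.

## Assembly and time stepping

The implicit part of every transport system is FOU convection plus central
diffusion (two-point face-normal gradient with the over-relaxed
`|A|^2 / (A . d)` conductance; the cross-diffusion correction for the
mildly non-orthogonal sloped faces is neglected).  Higher-order schemes
enter as an explicit deferred-correction source — the face-flux difference
between the high-order and upwind values evaluated at the previous outer
iterate.  This keeps the matrix an M-matrix (diagonally dominant,
non-positive off-diagonals) for every scheme, so the sparse LU
factorisation is robust, and for the transient it is performed once and
reused every step.  Near-boundary QUICK faces lacking a second upwind cell
fall back to SOU; in the 1-D benchmark the Dirichlet boundary value is
applied as the deferred high-order convective face value at the outflow
end, which preserves second-order convergence there.

Time integration is first-order implicit Euler with `dt = 1 s` by default;
each step iterates the deferred correction until the scaled residual
(Fluent-style: summed absolute residual over summed |diagonal * phi|)
drops below `tol` (default 1e-3, the conventional engineering criterion;
the test-suite uses 1e-6 to 1e-12 where accuracy statements are made).

Measured convergence orders on the 1-D benchmark at Pe = 10 (N = 20...320,
exact exponential profile as oracle): FOU 0.92, power law 2.08, SOU 2.10,
QUICK 2.09.  The power-law variant here is genuinely second order because
the exact face interpolation is combined with central diffusion; it is the
*face-Peclet* limit, not smooth-solution order, that makes it behave like
FOU in the convection-dominated aneurysm runs.

## Flow solver

Steady laminar axisymmetric incompressible flow, solved segregated
(SIMPLE-type) on the collocated grid: implicit under-relaxed momentum
(QUICK deferred correction by default, relaxation 0.7), Rhie-Chow-type
momentum-weighted face-velocity interpolation, an exact sparse pressure
correction solve per iteration (relaxation 0.3), outflow with global mass
correction, no-slip walls, a fully developed Hagen-Poiseuille inlet whose
discrete flux integral matches the requested flow rate to round-off, and
the axisymmetric `-mu v / r^2` sink plus wedge pressure term in the radial
momentum equation.  A SIMPLE rather than PISO loop is used deliberately:
the transient behaviour of this problem lives entirely in the concentration
field, the flow boundary conditions are constant, and the converged steady
state is identical — the flow is solved once and frozen for every species
run.  After the final iteration one exact pressure-correction projection
makes every cell satisfy continuity to linear-solver precision, so the
species solver always sees conservative fluxes.

Validation: the straight-tube solve at Re = 100 on a 200 x 20 grid
recovers the Poiseuille profile within 1% L2 and a centreline-to-mean
velocity ratio of 2.0 within 2%; at Re = 800 in the aneurysm the solver
produces the expected single sac recirculation (reversed near-wall axial
velocity).  Residual-level artefacts remain near the outflow boundary
(radial velocity up to ~2% of the mean there) and the cell-centred radial
velocity adjacent to the axis vanishes under refinement at second order
rather than being identically zero — both ordinary collocated-solver
behaviour.

## Species transport, sac time, and the probe

The species is a passive scalar (one-way coupling; trace mass fractions do
not alter the fluid).  The inlet carries normalised concentration 1, the
outlet is zero-gradient, the axis is symmetric, and the wall is inert
(zero diffusive flux) — the glass-wall condition.  "Sac time" zero is the
instant the tracer front reaches the sac inlet, computed as the
mean-velocity transit of the entrance extension (`entrance_length / U`);
an optional threshold-crossing definition (sac-inlet section mean >= 1% of
inlet) was considered and rejected as scheme-dependent — the arrival time
would then differ between schemes, breaking the matched-settings
comparison.  A global balance (inflow - outflow - accumulation) is audited
every step and closes to within ten times the linear-solve tolerance.

The probe emulates the fluid-extraction measurement: a hemisphere of the
withdrawn volume (0.8 ml) sits flat on the wall at the maximum sac
diameter, axis radially inward; it is divided into 5 equal-height slabs;
the concentration at each slab's on-axis volumetric centroid
(closed-form cap-slab integrals) is volume weighted.  Each one-minute
withdrawal is represented by an instantaneous sample at the withdrawal
mid-time (t + 30 s), reported at the nominal start time; fluid removal is
not modelled (0.8 ml is negligible against the sac volume).  Note one
numerical inconsistency inherited from the source material: a hemisphere
of 0.8 ml has radius 7.2558 mm, not 3.37 mm as sometimes printed
((2/3) pi (3.37 mm)^3 is about 0.08 ml); the package computes the exact
radius and `radius_override` can force any other value.

## Synthetic reference data

No tabulated experimental series exists, so the generator module supplies
structure-matched stand-ins:

* `generate_pseudo_experiment()` — a well-mixed recirculation-compartment
  fill `C(t) = 1 - e^(-t/tau)` with `tau = 240 s`, additive Gaussian noise,
  clipping to [0, 1.05], and seed determinism.  `tau = 240 s` was chosen
  once as a realistic sac-exchange time at these flow conditions (a few
  sac turnovers over the 6-minute protocol); no fidelity to the real dye
  kinetics is claimed.  What passing comparisons against it show is that
  the *pipeline machinery* ranks schemes correctly against a monotone
  fill-in reference — not that any scheme matches the real experiment.
* `generate_1d_benchmark()` — the exact-solution oracle problem.
* `generate_oblique_step()` — uniform flow at 45 degrees to a Cartesian
  grid with a step inflow and zero diffusion: the canonical false-diffusion
  fixture.  At 64 x 64 the 0.1-0.9 transition widths are FOU 0.319,
  SOU 0.083, QUICK 0.073 domain units — the first-order scheme smears the
  interface more than fourfold.

## Desk-scale study conditions

Resolving Pe = 2.56e6 boundary layers needs the order of the original
280,000-cell grid; this package's defaults are deliberately desk scale and
all scheme comparisons are made scheme-vs-scheme at matched settings:

* pipeline default: 96 x 28 grid, Sc = 100 (set `species$schmidt = 3200`
  for the full dye value), Re = 800, dt = 1 s, probe schedule 0/120/240/360 s;
* the acceptance-style comparison run uses 72 x 20; at these settings the
  pairwise probe-series differences cluster exactly as expected — FOU and
  power law within ~0.1% of each other, SOU and QUICK within ~5%, the two
  families 40-50% apart, with FOU over-predicting the sac concentration at
  every sampled time;
* the Sherwood grid-independence study uses Re = 800, Sc = 100, QUICK,
  wall-graded meshes (`wall_stretch = 20`) of 60 x 20, 120 x 40 and
  240 x 80 cells, each finer flow initialised from the interpolated
  coarser solution.

**On Sherwood grid independence.**  The Dirichlet-wall (zero wall
concentration) variant exists solely for this study; the inert wall of the
headline runs transfers nothing.  On the three desk-scale grids the
sac-wall area-averaged Sherwood number still changes by roughly 16%
between the two finest levels (the acceptance script recomputes this
number).  The package's own diagnosis is a resolution argument: the
sac-wall transfer rate is set by diffusion across the separated shear
layer, whose concentration-layer thickness scales like
`D (Re Sc)^(-1/2)` — about 0.1 mm here, an order of magnitude below the
finest desk grid's axial spacing — so the limiting length is the shear
layer, not the wall-cell height that the grading already resolves.
Establishing the 2% independence that full-scale studies quote
therefore genuinely requires grids of the order of 10^5-10^6 cells; the
package reports the honestly computed change rather than tuning the
conditions until the number looks converged.

## Numerical choices and degenerate inputs

* `exact_1d_solution()` switches to the `x/L` diffusion limit below
  |Pe| = 1e-10 and to the shifted-exponential form above Pe = 500.
* Zero diffusivity makes the face Peclet number undefined; the power-law
  weight then falls back to pure upwinding (documented in the function).
* Degenerate geometry (non-positive radii, areas or volumes) and
  out-of-domain probe centroids raise validation errors naming the
  offending quantity; the Sherwood number refuses inert-wall fields and
  equal inlet/wall concentrations (0/0).
* Mesh generation, the solvers, and the pipeline are deterministic;
  the only random element anywhere is the seeded pseudo-experiment noise.
* Tie-break on snapshot capture: a snapshot is stored at the first step
  whose sac time reaches the requested instant (dt-resolution).

## Known limitations

Steady flow only (no pulsatility), laminar Newtonian fluid, rigid inert
walls, 2-D axisymmetry, no flux limiters (QUICK/SOU over/undershoots are
reported, not clipped), no non-orthogonal diffusion correction, and the
desk-scale grids discussed above.  These bound what the green test suite
demonstrates: correct scheme behaviour and correct machinery at desk
scale, not grid-converged absolute transfer rates at physiological Peclet
numbers.
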