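---
title: "Methods: stabilized hemodynamics in parametric aortic roots"
author: "rootflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stabilized hemodynamics in parametric aortic roots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and model

`rootflow` simulates pulsatile blood flow through idealized aortic-root
geometries and quantifies the hemodynamic consequences of three surgical
configurations: a surgical valve replacement matched to the native annulus
(baseline), a Y-incision annular enlargement carrying a larger prosthesis,
and a transcatheter valve-in-valve implant inside the surgical valve. The
quantities of interest are the transvalvular peak velocity, the mean
transvalvular pressure gradient (TPG), and the blood residence-time (RT)
field used as a stasis/thrombosis surrogate.

Blood is an incompressible Newtonian fluid with density 1.026 g/ml and
dynamic viscosity 0.004 Pa s, flowing in a rigid, no-slip lumen. Velocity
$\mathbf v$ and pressure $p$ satisfy

$$\rho\,\partial_t \mathbf v + \rho\,\mathbf v\cdot\nabla\mathbf v
  - \nabla\cdot\boldsymbol\sigma = \mathbf 0,\qquad
  \nabla\cdot\mathbf v = 0,$$

with the standard incompressible Cauchy stress
$\boldsymbol\sigma = \mu_f(\nabla\mathbf v + \nabla\mathbf v^{T}) - p\,\mathbf I$
(the sign of the pressure term follows the universal convention), Neumann
tractions on the outflow/inflow planes and Dirichlet data on walls, inlet
(systole) and the valve plane. The package works throughout in mm-g-s
units, in which pressures land natively in Pa and no conversion constants
enter the Windkessel coupling.

## Discretization

Equal-order linear (P1-P1) finite elements on simplicial meshes (triangles
in the planar mode, tetrahedra in 3-D) with residual-based stabilization:
SUPG on the momentum residual, PSPG on the continuity equation, and an
optional grad-div term. The stabilization parameter per element is
$$\tau_e = \Big[(2/\Delta t)^2 + (2\lvert\bar{\mathbf a}\rvert/h_e)^2 +
  (12\,\nu/h_e^2)^2\Big]^{-1/2},$$
with $\bar{\mathbf a}$ the element-mean advective velocity, $h_e$ the
longest edge and $\nu = \mu_f/\rho$. Time integration is implicit Euler
with Picard linearization of advection; each step converges the relative
velocity update below `nonlinear_tolerance` (CI profile: 1e-3, at most 6
sweeps; the full-fidelity profile tightens this to 1e-6 / 10 sweeps).
Diverging Picard histories abort the step with the residual trace. Outflow
(and, in diastole, inflow) Neumann boundaries carry a backflow penalty
$\tfrac{\rho\beta}{2}(\mathbf a\cdot\mathbf n)_-\,\mathbf u$ that prevents
the well-known divergence under flow deceleration.

Mass bookkeeping uses exact P1 facet quadrature; because constant pressure
test functions eliminate every stabilization term, the discrete solution
closes the global flux balance to solver precision, and the per-cycle
imbalance reported by `check_mass_balance()` is at round-off level.

## The orifice-plane valve and its discrete pitfalls

The aortic valve is an orifice plane at the annulus: open during systole
(zero velocity only on the annulus ring outside the geometric orifice
area), shut during diastole. Two non-obvious discrete measures are needed
to make this model airtight, and both are structural rather than tunable:

* **Closed-valve band.** Constraining a single node layer does stop the
  advective flux, but the PSPG term acts as a pressure-driven porosity: the
  continuity rows of plane nodes span elements on both sides, and with an
  aorta-to-ventricle pressure difference of ~13 kPa the scheme pumped a
  spurious diastolic leak comparable to the stroke volume. The valve
  therefore closes as a *band*: the plane layer plus the adjacent upstream
  layer. The strip of cells between them has every vertex constrained, is
  exactly divergence-free, and has its stabilization masked, which severs
  the cross-plane pressure path. With this in place the sealed ventricular
  side exchanges ~1e-12 of the stroke volume per cycle and the diastolic
  coronary draw is fed entirely by aortic-side backflow, as a rigid
  incompressible model requires.

* **Orphan pressure dofs.** A node whose every incident cell is masked has
  a structurally free pressure unknown; such nodes are detected and their
  pressure pinned (the value is immaterial: every row that references it
  belongs to a Dirichlet velocity dof).

The geometric orifice area follows the device rule `GOA diameter =
implanted internal diameter - 6.0 mm`; a transverse node ring is snapped
onto the orifice radius so the discrete open area equals the GOA exactly.

## Boundary-condition suite

* **Inlet.** Prescribed flux during systole as a parabolic profile
  renormalized so its *discrete* facet integral matches the target flux
  exactly; prescribed pressure (default constant 1067 Pa ≈ 8 mmHg, a
  typical LV filling pressure; configurable ramp) during diastole. Heart
  rate 70 bpm, stroke volume 73.5 mL, systolic fraction 0.35 (the
  ejection-phase idealization; only HR and SV are physiologic inputs, and
  both flux shapes — half-sine and trapezoid — integrate to SV within
  0.1%).
* **Outlet.** Two-element Windkessel, R = 0.121 Pa s/mm³ and
  C = 9.37 mm³/Pa (compliance carries mm³/Pa, the only unit in which a
  resistance-compliance pair defines a time constant; RC = 1.134 s). The
  coupling is implicit: within each Picard sweep the outlet traction uses
  the Windkessel pressure driven by the current iterate's outlet flux. The
  ODE advance is the exponential integrator
  $P^{n+1} = QR + (P^n - QR)\,e^{-\Delta t/RC}$, exact for stepwise-constant
  inflow — a first-order generic scheme at Δt = 1 ms leaves a relative
  error of order 4e-4 against the analytic relaxation, which would dominate
  every verification of this component. The initial pressure is the
  steady-state value (mean flow × R) to shorten start-up transients. The
  resulting aortic pressure envelope is 66–111 mmHg at CI resolution.
* **Coronaries.** Two ostia on the sinus wall draw a constant flux during
  diastole only, together 4% of mean cardiac output (so per-cycle coronary
  volume is 4% of stroke volume), split equally and imposed as discrete
  flux-exact plug profiles. Magnitude, timing and placement are modeling
  choices; no literature values are implied.

In the planar 2-D mode all volumetric fluxes convert by mean-velocity
equivalence, $q_{2D} = Q\,/\,(\pi w/4)$ for a lumen of width $w$: flux
ratios (and hence mass-balance fractions, Windkessel time constants and
stroke-normalized quantities) are preserved exactly.

## Geometry synthesis

Patient anatomies are replaced by a parametric root: LVOT tube, annulus,
three sinus bulges (`0.7 + 0.3 cos 3θ` azimuthal modulation in 3-D), a
sinotubular junction, and a straight ascending aorta at least 30 mm long so
the downstream TPG plane exists. Defaults: annulus 23 mm, bulge 4 mm over a
20 mm sinus, STJ 26 mm, aorta 30 mm diameter. Meshes are structured
(transverse fractions scaled by the local profile radius; extruded disk
prisms split into tetrahedra by the minimum-vertex rule, which is
conforming across neighbours), watertight by construction and verified by a
facet-adjacency census. Meshing is deterministic; the seed is recorded in
provenance metadata only.

Scenarios transform the parameters: the enlargement scales annulus, sinus
and STJ by the implanted/native valve-size ratio (29/23 by default); the
valve-in-valve scenario attaches a funnel insert whose throat reduces the
GOA area by 20% (the middle of the reported device range). The funnel
truncates the lumen *below* the valve plane (stent frame and held-open
leaflets); above it the skirt is an immersed thin solid — two reserved node
columns (inner surface at the throat radius, wall thickness 0.6 mm) whose
in-between cells are fully constrained and stabilization-masked, plus a
two-layer floor band above the valve plane. The annular recess between
skirt and sinus wall remains fluid, open only at its mouth above the skirt
top (8 mm above the annulus, the sealed-inflow height of a self-expanding
device in this size range): this is the neo-sinus pocket. Without the
masked thin-solid construction the PSPG porosity pumps the pocket at
hundreds of mm/s and no stasis can form; with it the pocket accumulates
relative RT 1.0.

## Residence time

The RT field solves $\partial_t\phi + \mathbf v\cdot\nabla\phi = 1$ with
zero diffusivity, $\phi = 0$ on the inflow and outflow planes (coronary
ostia default to the natural zero-flux condition, configurable), SUPG
stabilization and implicit Euler. The mass matrix is row-sum lumped: the
pure-source update is then exact ($\phi \to \phi + \Delta t$ at every free
node when $\mathbf v = 0$), which also removes boundary-induced mass
coupling and reduces undershoots; remaining undershoots are clipped at
output with the clipped fraction logged. The advective field replays the
stored final flow cycle periodically (linear interpolation between
snapshots; records whose end state differs from their start state by more
than 25% relative are rejected as non-periodic). The RT step is 4x the flow
step; per-phase system factorizations are cached across the replayed
cycles. Runs last 14 cycles and report the per-cycle volume-weighted mean
residence time together with the convergence verdict (relative change
below 5% over the final cycle pair); a fully washed domain converges once
transport balances the unit source, a stagnant region once its linear
growth is small against the accumulated mean.

## Metrics

Peak velocity is the maximum velocity magnitude between the valve plane and
the plane 30 mm downstream (configurable to the whole downstream lumen);
the selection follows the stored mesh axis, so the metric is invariant
under rigid rotation. Mean TPG is the forward-flow time average of the
positive part of (area-averaged inlet-plane pressure minus area-averaged
pressure 30 mm downstream of the valve); plane averages use the
generator's lumped cross-section weights, making the metric exactly
gauge-invariant. "Forward flow" is operationalized as time steps with
positive transvalvular flux (equivalently, valve open). RT statistics are
volume-weighted by lumped nodal volumes ($V_e/(d{+}1)$ per vertex) and
report the mean, the pointwise maximum and the percentage of volume with
relative RT above 0.2. Percent changes follow the clinical convention
$100\,(\mathrm{control}-\mathrm{treatment})/\mathrm{control}$ (positive =
decrease); group normalization divides by the group maximum. mmHg
reporting uses 1 mmHg = 133.322 Pa with Pa canonical.

# Problem sizes and fidelity profiles

Three profiles bundle the numerical settings:

| profile | mode | edge (mm) | dt (s) | Picard tol | purpose |
|---------|------|-----------|--------|------------|---------|
| `ci`    | 2-D planar | 2   | 2e-3 | 1e-3 | test suite, quick studies |
| `desk`  | 3-D coarse | 2.5 | 2e-3 | 1e-3 | workstation exploration |
| `paper` | 3-D        | 1   | 8e-4 | 1e-6 | full-fidelity operating point |

The test suite and the bundled acceptance script run the `ci` profile
(roughly 700 vertices, 429 steps per cycle, 3 flow cycles, 14 RT cycles per
scenario) plus 3-D verification fixtures; these sizes are the package's
choice of routine-verification scale. All flow verdicts at this scale
converge below the 5% cycle-to-cycle criterion by cycle 3.

# What the synthetic geometry does and does not capture

The parametric root preserves the features the metrics depend on — a
defined orifice with the correct GOA, sinus recesses, the 30 mm TPG plane,
coronary ostia, and (for valve-in-valve) a sealed neo-sinus pocket — while
remaining deterministic and meshable at any resolution. It does not
reproduce any patient's magnitudes: eccentric jets along curved aortas,
calcified leaflet remnants, boundary-layer prism resolution (0.15 mm in
the reference operating point) and leaflet kinematics are all absent.
Consequently the package's controlled comparisons are *directional*:
identical boundary conditions across scenarios isolate the effect of
geometry, which is the study design the pipeline mirrors.

Observed directions at the CI scale: enlarging root and valve (GOA 23 mm vs
17 mm) lowers peak velocity by ~40% and mean TPG by ~49%; the valve-in-valve
insert (GOA area −20%) raises peak velocity ~43% and mean TPG strongly, the
maximum relative RT reaches exactly 1.0 in the sealed pocket, and the
volume fraction with relative RT > 0.2 rises. One direction is *not*
reproduced in the planar mode and is reported as such by the acceptance
suite: the domain-mean relative RT decreases slightly after the insert,
because the 43% faster jet washes the downstream aorta and its wall layers
harder than the added pocket stasis accumulates within the 14-cycle
horizon. The pocket-localized stasis signatures are reproduced; the
domain-mean direction should be interpreted as a known limitation of the
planar surrogate at this horizon (a revolved-volume weighting was evaluated
as an alternative statistic and does not change the sign; extending the
horizon widens the gap because the washed fraction keeps decaying).

# Numerical edge cases

* Degenerate resolutions (edge length above a quarter annulus diameter),
  infeasible inserts (throat wider than the annulus) and too-short aortas
  fail fast with parameter errors before any compute.
* With zero inlet flux, zero initial state and a closed valve the discrete
  rest state is exact.
* Valve transitions are instantaneous state flips at the systole
  boundaries; the first step after a flip reuses the previous velocity as
  the Picard initial guess with no impulsive correction. The closing
  instant itself is diastolic (closed-interval convention, documented in
  `inlet_condition_at()`).
* The residence-time step warns when the advective CFL number exceeds 20
  and suggests a step size; accuracy of the plug-flow characteristics
  solution is verified to 5% at the shipped settings.
* All assembled systems are solved with sparse LU (Matrix); no iterative
  tolerances enter the linear algebra.

# Verification summary

The test suite verifies each layer against independent closed forms:
exponential Windkessel relaxation (machine precision), Hagen-Poiseuille
pipe pressure drop (below 10% at 0.5 mm edges with monotone decay under
refinement), plane-Poiseuille centreline velocity (5%), discrete
divergence-free flux closure (round-off), residence-time cavity saturation
(exact), plug-flow characteristics (5%), and brute-force quadrature oracles
for every statistic. The scenario-level directions above are asserted in
`tests/testthat/test-acceptance.R`, and `scripts/acceptance.R` recomputes
all of them from scratch.
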