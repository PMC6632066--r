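---
title: "Models and methods in blendsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in blendsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(blendsim)
```

`blendsim` couples a quality-by-design (QbD) statistical workflow for a
powder blending process with a soft-sphere discrete-element (DEM)
simulator.  This vignette is the package's account of the underlying
models, the parameters that matter, the numerical choices, and what the
scaled-down test fixtures can and cannot demonstrate.

## The process and its quality attributes

The target process blends a low-dose amlodipine besylate formulation
(6.935% w/w API, 77.065% SMCC 90, 4.5% PVP K25, 10% CCM-Na, 1.5%
magnesium stearate) in rotating shell blenders.  The intermediate quality
attributes are the drug content (assayed content as a percent of label
claim), the content uniformity (CU, percent RSD of drug content across
samples, target at most 5%), and the Carr index
`(rho_tap - rho_bulk)/rho_tap x 100`, a flowability indicator.

## FMEA risk scoring

Each process parameter is scored against each quality attribute for
severity, probability of occurrence and detectability on the odd ladder
1/3/5/7/9, and the risk priority number is their product, so
`RPN` spans 1 to 729.  Risk bands are `low` below 82, `medium` 82-245 and
`high` at 246 and above; the boundary values 82 and 245 fall in `medium`
and 246 in `high`, reading the published band edges literally.  The
Pareto screening threshold is `max_RPN x (1 - confidence)`, 72.9 at the
default 90% confidence.  Ties in the Pareto ranking keep input order
(documented stable sort); the permissive mode accepting any integer score
1-9 exists but is off by default.

## Box-Behnken response surfaces

The three control factors (filling level 30-70%, rotational speed 15-25
rpm, blending time 9-24 min) are coded as
`x = (natural - centre)/half-width`, with centres (50, 20, 16.5) and
half-widths (20, 5, 7.5) inferred from the design levels.  The 3-factor
Box-Behnken design is the canonical set of 12 edge midpoints (coded
entries in {-1, 0, +1}, exactly one zero per run) plus replicated centre
runs, 15 runs in total by default.

Fits are ordinary least squares on caller-specified term subsets of the
full quadratic polynomial.  On this orthogonal design the partial
(type-III) term sums of squares equal the sequential ones, and the
intercept equals the response mean.  ANOVA reports per-term and model
sums of squares, `F = MS_model / MS_residual`, p values from the F
distribution, `R^2 = SS_model / SS_total`, adjusted R-squared, and
predicted R-squared `1 - PRESS/SS_total` with PRESS from leave-one-out
leverages — the standard formula used by commercial DoE packages, stated
here because only the quantity's name is usually reported.

Term selection is explicit: the shipped reduced models for drug content
(`x1, x2, x3, x1x2, x2x3`) and CU (`x1, x2, x3, x1x3, x2x3`) are the
published ones, and optional backward elimination at p > 0.05 is
available.  One subtlety the package preserves: the published CU ANOVA
table corresponds to the four-term model with the insignificant speed
main effect removed (model DF 4, residual DF 10), while the published CU
coefficient equation retains all five terms.  Because the design is
orthogonal the shared coefficients are identical; `anova_rsm()` on either
fit is self-consistent, and the test suite pins both.

The design space accepts a grid cell when every response's prediction
satisfies its specification limits (drug content 95-105%, CU at most 5%);
a strict mode uses the 95% confidence bound instead of the point
prediction.  Optimisation is a ranked grid search by geometric-mean
desirability with ties broken toward lower filling level, then higher
speed — a transparent stand-in for proprietary desirability optimisers.

## Monte-Carlo operating space

The operating space is the subset of the design space whose failure
probability under operational variability stays below 1%.  Factor
settings are drawn from independent normals around each grid setpoint,
truncated to the factor ranges; the default setpoint SD is 5% of each
factor's half-range, configurable because the magnitude of setpoint
noise is a site-specific choice.  Response residual noise (SD equal to
each fit's residual SD) is added by default: without it a strictly
interior setpoint could never fail and the 1% criterion would degenerate
to the deterministic boundary.  The default is 10,000 draws per cell; the
binomial standard error is always reported so that reduced-draw desk runs
remain honest.  With zero SDs and residual noise off, the Monte-Carlo
region equals the deterministic design space exactly — a property the
tests exploit.

## The DEM contact model

Particles are single spheres (the deliberate simplification for fine
pharmaceutical powders at upscaled size).  For a contact with normal
overlap `dn`:

* normal elastic force `F_n = (4/3) E* sqrt(R*) dn^{3/2}` (Hertz), with
  `1/E* = (1-nu_a^2)/E_a + (1-nu_b^2)/E_b`, `E = 2G(1+nu)`,
  `1/R* = 1/R_a + 1/R_b`; a wall partner has infinite mass and radius;
* normal damping `-2 sqrt(5/6) beta sqrt(S_n m*) v_n` with
  `S_n = 2 E* sqrt(R* dn)` and
  `beta = -ln e / sqrt(ln^2 e + pi^2)` in [0, 1), which reproduces the
  coefficient of restitution `e` nearly exactly for the Hertzian spring;
* tangential spring `-S_t dt` with `S_t = 8 G* sqrt(R* dn)`
  (`1/G* = (2-nu_a)/G_a + (2-nu_b)/G_b`), matching damping, and a Coulomb
  cap at `mu_s |F_n|` that rescales the stored displacement onto the
  friction cone;
* rolling resistance torque `-mu_r |F_n| R_p unit(omega)` opposing each
  particle's spin;
* for cohesive materials (magnesium stearate, surface energy
  `gamma = 0.02 J/m^2`) the JKR normal force
  `F = -4 sqrt(pi gamma E*) a^{3/2} + (4E*/3R*) a^3` as a function of
  contact radius `a`, advanced from the overlap through
  `dn = a^2/R* - sqrt(4 pi gamma a / E*)` by a safeguarded Newton solve on
  the stable branch.  Contacts form on touch, persist in tension until
  the detachment overlap, and the pull-off force is `3 pi gamma R*`
  (verified against grid minimisation to 0.1%).  At `gamma = 0` the JKR
  path reduces bit-for-bit to Hertz.

Unlike pairs of particle materials combine restitution and friction by
the arithmetic mean of their particle-particle values and surface energy
by the geometric mean (zero against a cohesionless partner);
particle-wall pairs use each material's own wall coefficients against
stainless steel (`G = 7e10 Pa`, `nu = 0.30`, density 7.80 g/cm^3).

### Integration and stability

The default integrator is semi-implicit (symplectic) Euler, standard DEM
practice; velocity Verlet (kick-drift-kick, two force evaluations per
step) is available behind `integrator = "verlet"` and is used where
impact accuracy matters — it recovers configured restitution within 1.2%
at a time step of 10% of the Rayleigh time, where first-order stepping
errs by up to 4% at the lowest `e`.  The stable step is a fraction
(default 25%, 30% for the long blending demos, both common choices) of
the Rayleigh time
`pi R sqrt(rho/G) / (0.1631 nu + 0.8766)` of the smallest particle.
Gravity is 9.81 m/s^2.

Neighbour search is a uniform-grid broad phase plus Verlet skin lists
(pair list and per-particle wall-triangle candidates, rebuilt when
accumulated relative motion could cover half the skin); the candidate set
provably contains every touching pair and the tests compare it against
brute force on randomized scenes.

### Mesh walls

Walls are triangle meshes (ASCII/binary STL, or parametric builders for
plate, funnel, vessel, drum, V-blender and double-cone) moving as rigid
bodies: constant-speed rotation about an axis plus constant translation.
Contacts are evaluated in the mesh's body frame against a static triangle
grid built once per run; the wall surface velocity `omega x r + v` enters
the relative-velocity terms, and reaction loads (torque about the axis,
axial force) are accumulated per wall for the rheometer test.  Per-sphere
contacts are deduplicated by closest-point feature: face contacts are
kept, and edge/vertex contacts that duplicate an accepted smooth patch
(shared feature vertices, or normals within 35 degrees) are dropped, so a
flat floor split into triangles yields one contact while a 90-degree
wedge correctly yields two.

The V-blender shell is built as a mitred pipe elbow: two cylindrical arms
cut by the symmetry plane and joined along the shared ellipse, so each
arm's volume is exactly `pi r^2 L` and the shell is watertight by
construction (verified: every edge shared by exactly two triangles, and
signed-tetrahedron volume within 5% of nominal; the same checks run on
the double-cone built as a surface of revolution).  Published blender
dimensions are photographs only, so the parametric proportions (arm
length 4 radii at a 40-degree half-angle from vertical; double-cone
cylinder 0.6 radii, cones 1 radius) were chosen once as typical shell
proportions that hit the nominal volumes, and any geometry can be
supplied as STL instead.

## Virtual bulk tests and calibration

* **Static angle of repose.** Particles seeded inside a funnel cone
  discharge onto a plate; rest is declared when mean kinetic energy per
  particle stays below 1e-8 J for 0.2 s.  The funnel orifice clears the
  tallest admissible heap, and stray particles that roll off the plate
  are removed between settling chunks so their free fall cannot mask
  rest.  The heap angle is a radial height regression (bin surface = top
  of highest particle, outer 10% trimmed) — an estimator defined here,
  since the published procedure only states that angles were measured as
  in the physical test; it reads a synthetic 25-degree cone correctly and
  is rotation-invariant about gravity.
* **Dynamic angle of repose.** A closed drum (axis horizontal) filled to
  30% v/v rotates at 25 rpm; after spin-up the free-surface angle is a
  line fit to binned surface heights, averaged over at least five
  snapshots with its SD, flagged when the fit's R-squared drops below 0.8
  (cataracting).
* **Basic flow energy.** A two-bladed impeller pitched at the -5 degree
  helix angle descends through the bed while rotating (test cycle
  counterclockwise at 100 mm/s tip speed; conditioning clockwise at
  40 mm/s between cycles, which heals size-segregation introduced by a
  test pass).  Torque and axial force on the blade are time-averaged per
  save interval and integrated as `E = int (T/(R tan|a|) + F) dh` by the
  trapezoid rule over the downward traverse (exact for linear traces,
  verified to 1e-6).

Calibration is coordinate descent with step halving over the adjustable
parameters (static and rolling friction by default — the coefficients
that dominate repose angles — applied to both pairings), accepting a
candidate when it lowers the worst relative bias across all targets, and
converging when every response is within the 10% relative-bias tolerance.
The full evaluation log is returned; along accepted iterations the worst
bias is non-increasing.  Shear modulus stays pinned (bulk behaviour is
insensitive over a wide range) and restitution and Poisson's ratio are
held at plausible defaults unless explicitly listed as adjustable.

## Blending pipeline

Filling allocates per-component particle counts so realized mass
fractions match the recipe within 1% (components are monodisperse at
their scaled median diameter, which keeps the count audit exact and
avoids artificial size segregation), seeds them on a lattice inside the
shell with a wall-clearance margin, layers components in recipe order
(the segregated state of a real charge; a premixed option interleaves
randomly), and settles under gravity.  The realized bed volume is checked
against `fill_fraction x nominal volume` assuming 0.58 random close
packing.

Sampling uses eight vertical cylinder bins in a 4 x 2 grid.  Bin centres
sit on position quantiles and each bin's vertical extent follows the
local bed, so bins stay on powder even mid-cascade; snapshots are rotated
back to the blender's home orientation before binning (sampling fixed in
the bed frame — the published layout does not state the convention, and
this one keeps the grid aligned with the bed at every instant).  Per bin,
drug content is the API mass fraction over the nominal 6.935%, times 100,
so a perfect mix reads 100%; CU is `100 x sd/mean` over non-empty bins
(at least four required).  The T-index series evaluates the metrics at
`T_i = 1, 2, ...` (default interval: run duration / 7) and reports the
first index meeting the specification, or not-reached.  Regression
comparison of simulated against experimental series is ordinary least
squares with slope, intercept, residual SD, R-squared, adjusted
R-squared and slope p value; initial points can be dropped, as early
blending states carry large variability.

## Desk-scale fixtures: what they show and what they cannot

The production-scale study conditions (179k-802k particles, hours-long
wall-clock per simulated minute) are far outside a test suite.  The
shipped fixtures therefore scale three things, each documented as the
package's own choice:

* **Particle size.** The five formulation components get per-component
  upscale factors (400/40/64/80/700 against the measured micrometre
  sizes) so every particle lands near 2 mm radius; the generic
  `desk_powder` used by the repose and drum fixtures is 3 mm diameter.
  The production-grade default upscale is 100x for all components.
* **Shear modulus.** Desk materials use `G = 1e5 Pa` instead of the
  pinned 1e7 Pa; bulk behaviour is insensitive to G over several orders
  of magnitude, and the softer value lengthens the Rayleigh step about
  10-fold, which is what makes the fixtures fast.  Overlaps stay below a
  few percent of the radius at rest.
* **Problem sizes.** Repose and calibration runs use 400-1200 particles;
  the blending demo uses 2,000 particles in a ~0.4 L V-blender for 10 s
  (four revolutions at 24 rpm), and the recipe-audit check fills a
  3 L shell with ~1,100 coarser particles.

Consequences to keep in mind.  With ~160 API particles split over eight
bins, the binomial sampling floor for CU is tens of percent, so the demo
can never reach the 5% production specification — its `t_index_met` is
honestly reported as not reached, and what the demo does establish is the
qualitative physics: mass conservation, a content-uniformity series that
falls from the segregated start toward its plateau, and friction-driven
heap and surface angles that respond monotonically to the friction
coefficients.  Likewise the desk repose angles (about 20 degrees for the
`desk_powder` at `mu_s = 0.5`, `mu_r = 0.3`) sit below typical cohesive
pharmaceutical powders; they are calibration test-beds, not material
predictions.  Production-scale claims (e.g. which T-index meets
specification at which scale) require the full particle counts and real
blender geometry, which this package accepts but does not ship.

## Numerical notes and edge cases

* Printed forms of the Hertz normal force and the damping prefactor in
  the source literature contain typesetting artifacts; the package
  implements the canonical Hertz-Mindlin (no-slip) expressions given
  above, which reduce to the printed ones under the obvious corrections.
* Degenerate (zero-area) wall triangles are skipped with a warning;
  non-finite state or particles beyond the domain radius abort the run
  with a step diagnostic (the usual symptom of an oversized time step).
* Tangential-history slots are carried across neighbour-list rebuilds;
  chained runs (settling in chunks, rheometer cycles) restart tangential
  springs at zero, a negligible effect at rest and between cycles.
* The coded-factor solver refuses rank-deficient term sets and names the
  aliased terms; factor settings outside [-1, 1] are allowed for
  prediction but flagged as extrapolation.
* Monte-Carlo draws truncate to the factor ranges by default; the
  truncation can be disabled, which the analytic Gaussian-tail tests use.
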