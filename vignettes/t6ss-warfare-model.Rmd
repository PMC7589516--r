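---
title: "Modelling T6SS duels: the agent-based patch model and its invasion analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling T6SS duels: the agent-based patch model and its invasion analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t6duel)
```

## The system being modelled

The type VI secretion system (T6SS) is a contact-dependent bacterial weapon:
a spring-loaded, effector-tipped needle that a cell fires through its own
envelope into whatever sits next to it. Species differ strikingly in how they
use it. Some (e.g. *Vibrio cholerae*) assemble and fire the apparatus
continuously at random positions; *Pseudomonas aeruginosa* instead holds its
fire and launches counterattacks from the very spot where it was just stabbed
— a behavioural tit-for-tat. `t6duel` implements an individual-based model of
competing firing strategies in dense surface-attached communities, together
with the evolutionary (adaptive-dynamics) machinery needed to ask which
strategies can actually invade and persist.

## The agent-based patch model

**Cells and mechanics.** A cell is a rigid spherocylinder of radius
`R_cell` confined to the plane (the model deliberately restricts itself to
monolayer, surficial competition; 3-D stacking is out of scope). Cell
positions and axes are three-vectors with the z-components pinned to zero.
After every growth phase, overlaps created by elongation, division and death
are resolved by an overdamped, quasi-static relaxation: contacts between
capsules are found (broad-phase spatial binning, exact segment–segment
narrow phase) and impulses `p` solve the regularized least-squares system

$$ (A^\top A + \alpha M)\,p = -A^\top d, $$

where each row of `A` is the contact-normal Jacobian of one overlapping pair
(planar rigid-body degrees of freedom $x, y, \theta$, with lever-arm terms
coupling rotation), `d` collects the signed overlaps and `M` is a diagonal
drag matrix (translational drag proportional to cell length, rotational drag
to length³/12). Applying `p` and re-finding contacts is iterated until the
worst residual overlap falls below `relax_tol` (default 0.02 µm, cap 50
iterations). The system is solved by Jacobi-preconditioned conjugate
gradients; because the regularized operator is positive definite this cannot
be singular, but if the solver ever fails to converge the regularization
weight is escalated tenfold and the solve retried (with a warning).
Relaxation is deterministic and consumes no random numbers.

**Growth, division, resources.** Volumes grow as $dV/dt = k_{grow} V$,
integrated exactly per step ($V \mapsto V e^{k_{grow}\,dt}$), elongating the
cylindrical section at fixed radius. A cell divides when it reaches its
personal target $2V_0 + \eta$, with $\eta \sim U[0, \eta_{division})$ drawn
once at birth; daughters take half the volume each, sit end-to-end along the
parent axis, and have their axes nudged by an angle
$U(-\eta_{orient}, \eta_{orient})$. The shared patch resource depletes with
zeroth-order kinetics, $dE/dt = -k_{max}\sum_i V_i$ over living, non-lysing
cells, and the simulation ends when `E` hits zero. Two modelling choices
worth flagging: initial volumes get the same uniform jitter as the division
noise (otherwise every cell in a fresh patch divides on the same step, which
no real inoculum does), and daughters inherit their parent's cumulative
toxin count (translocated effectors live in the cytoplasm and do not vanish
at septation) but not its pending-retaliation queue.

**Firing strategies.** A strategy bundles: carriage of the weapon
(`carries_t6ss`), a constitutive Poisson firing rate `k_fire` (random firers
draw $N \sim \text{Pois}(k_{fire}\,dt)$ needles per step from uniform
points on the cell perimeter, aimed along the outward normal), a
retaliation multiplicity (n needles fired back per hit sustained, answered
one step after the hit), an `aiming` flag (counterattacks leave from the
recorded entry point, reversed along the incoming needle; the knockout
fires the same number from random surface points), and a `cost_saving` flag
(pay `c` per realized firing versus paying like a reference random firer
regardless of actual firings). Unarmed cells pay nothing and cannot fire;
cheaters carry the genes (and pay `c_upfront`) but never fire. Growth costs
enter as $k_{grow} = k_{max}(1 - c_{upfront} - c\,N_{firings}/dt)$, clamped
so growth never goes negative.

**Hit detection and intoxication.** A needle of length `L_needle` hits a
cell if the needle segment passes within $R - L_{penetration}$ of the
cell's axis segment; the entry point is the nearest crossing of the
capsule surface along the needle (solved by bisection between the origin
and the closest approach, so it is exact to solver precision for the
cylindrical flank and both polar caps), and a needle stops at the first
cell it enters. Clonemates (same genotype) are mutually immune; genotype
pairs can additionally be declared mutually immune ("primed" pairings), in
which case hits perturb the membrane — and therefore still provoke
retaliators — without intoxicating. A susceptible cell that accumulates
`N_hits` translocations commits to lysis and is removed after `1/k_lysis`;
while lysing it neither grows, fires, retaliates nor consumes resources,
but it remains a mechanical obstacle and can still absorb needles. A hit
that itself pushes a cell over the lysis threshold does not queue a
counterattack: commitment to lysis pre-empts retaliation. This choice makes
single-hit-lethal toxins (`N_hits = 1`) silence retaliators entirely, which
is exactly the regime in which the strong retaliator loses its edge.

**Step order.** Each `step_patch()` applies: firing (retaliations queued
last step fire now) → hit detection → intoxication → removal of expired
lysing cells → growth-rate update from this step's firing counts → growth
and division → resource depletion → mechanical relaxation → clock advance.
Combat precedes growth so that relaxation, which the mechanical story puts
after the growth phase, closes the step.

## Determinism and random-number policy

Every patch carries its own RNG state; `step_patch()` and the other
stochastic operations restore it, draw from it, and store it back, leaving
the caller's RNG untouched. Identical `(params, strategies, counts, seed)`
give bit-identical trajectories, and replicates differ only through the
seed. All stochastic kernels (Poisson firing counts, perimeter sampling,
division noise) draw through R's RNG; the compiled mechanics and hit
detection are deterministic.

## The adaptive-dynamics layer

A competition's outcome is summarized by the invasion fitness
$\omega_X = \ln(\Sigma V_X(t_{end}) / \Sigma V_X(t_{start}))$ per
strategist; extinction maps to $-\infty$ and propagates through every index
as "cannot invade" (or, for a resident, "trivially invadable"). Fitness
tables hold per-replicate $\omega$ values for mixed, self- and
mutually-immune ("primed") pairings, and the index functions implement the
local ratio test, the two-part global (metapopulation) test with its strict
entry and non-strict re-invasion guard, the mutual-immunity weighting in
`p_s`, the cheater triplets, and the within-patch relatedness weighting in
`I`. Two conventions are worth stating because they are easy to trip over:
the entry denominator of the weighted global test is the resident's
*unweighted* self fitness whenever the resident is an armed retaliator or
the weighting cannot apply (unarmed strains can never be immune and are
pinned to `p_s = 0`); and the weighted re-invasion guards are written with
the resident's fitness on top, so they block re-invasion when `<= 1` — the
reciprocal of the unweighted guard's `>= 1` orientation. The limit checks
(`p_s = 0`, `I = 0`) in the test suite pin both conventions down exactly.

Pairwise invasibility plots are matrices of invasion indices over resident
× mutant firing-rate grids, filled by replicated simulations (or any
user-supplied simulator — the tests use analytic stubs with known optima).
An ESS is a grid rate whose whole row of mutant indices lies at or below 1
within a stated noise tolerance; `find_ess()` also traces the
incremental-mutation walk from both grid ends, which should converge onto
the ESS from either side. Uninvadable rates sitting on the grid *boundary*
are reported separately as `boundary_candidates`, not as ESSes: with
selection monotone up to the edge, apparent stability there is
indistinguishable from grid truncation, and the honest remedy is a wider
grid. ESS localization is deliberately left at grid resolution — every
matrix entry is a stochastic simulation, and polishing a root between
simulated points would manufacture precision.

## Parameter choices

Defaults aim at *Escherichia coli*-scale magnitudes on a desk-scale patch;
all are overridable per call.

| parameter | default | units | why |
|---|---|---|---|
| `k_max` | 2.08 | h⁻¹ | 20-minute doubling time |
| `V_0` | 1.57 | µm³ | birth volume of a 1 µm rod of radius 0.5 µm |
| `R_cell` | 0.5 | µm | typical rod radius |
| `dt` | 0.005 | h | keeps `k_max·dt` ≈ 0.01 (growth exact anyway; combat and mechanics need small steps) |
| `E_0` | 4700 | µm³ | an uncontested patch saturates at ≈ 2000 cells |
| `L_needle` | 1.0 | µm | about one cell length |
| `L_penetration` | 0.05 | µm | grazing-hit tolerance, 10% of R |
| `N_hits` | 2 | – | resilient default; 1 = single-hit lethality, Inf = immune |
| `k_lysis` | 20 | h⁻¹ | 3-minute corpse persistence |
| `c_upfront`, `c` | 0.05, 0.001 | – | carriage and pro-rata firing costs; at `k_fire` = 50 h⁻¹ the two contributions match |
| `eta_division` | 0.3 | µm³ | ≈ 20% of V₀; desynchronizes divisions |
| `eta_orientations` | 0.1 | rad | slight division-axis disorder |
| `alpha` | 0.01 | – | relaxation regularization; small enough not to bias equilibria |
| `arena_radius` | 20 | µm | fixed arena; density scales with the inoculum |

The initial-placement arena is fixed and the inoculum size sets density:
20 cells ≈ 4% area coverage ("low density"), 200 cells ≈ 35% ("high
density", comfortably below the jamming threshold of random sequential
placement). Competition experiments in the test-suite and the acceptance
script run at `E_0 = 1500` (final populations of roughly 500–800 cells) with
up to 100 cells per strain — a deliberate scale-down of the original
10,000-cell patches. The package's qualitative claims (density dependence,
the strong retaliator's dominance, its collapse at `N_hits = 1`) are
insensitive to this scaling, but absolute proportions and fitness values are
configuration-specific and should not be read as quantitative predictions.

## What the synthetic patches do and do not emulate

`make_initial_patch()` scatters cells uniformly in a disc with uniform
random orientations and rejects overlaps — a well-mixed inoculum with no
initial spatial structure, clonal microcolonies, or density gradients. The
resource model is a shared, well-mixed quota with zeroth-order kinetics:
there are no nutrient gradients, no diffusion, no growth-rate dependence on
remaining resource, and no death other than by intoxication. Passing tests
therefore demonstrate the internal logic of contact-dependent warfare under
these idealizations, not calibrated predictions for any particular
organism; in real colonies nutrient shielding, adhesion and 3-D buckling
all modulate the contact structure that drives these dynamics.

## Numerical choices and degenerate inputs

* Growth uses the exact per-step exponential, so volume trajectories carry
  no integration bias; resource depletion uses the spec's explicit Euler
  form `E ← E − k_max ΣV dt`, whose bias over a whole run is under one
  timestep of depletion time.
* Segment–segment closest points fall back to the midpoint of the projected
  overlap interval for (near-)parallel axes — the symmetric, deterministic
  tie-break — and handle degenerate point segments (spheres) exactly.
* Needle entry points are found by bisection (60 iterations) between the
  needle origin and its closest approach, rather than by case-splitting the
  cylinder/cap quadratics; one code path covers all geometries at ~1e-12 µm
  precision.
* Contact normals of deeply coincident witness points fall back to the
  centre-to-centre direction, then to a fixed axis.
* Per-step rotations from the impulse solver are clamped at 0.5 rad; this
  only engages in pathological hand-built configurations.
* `N_hits = Inf` is a first-class value (immune strains accumulate
  translocations but never lyse); `E_0 = 0` terminates a run at step zero;
  empty patches and zero counts are legal everywhere.
* Extinction gives $\omega = -\infty$, and every invasion index maps that
  sentinel to the biologically forced verdict instead of propagating NaNs.

## Known limitations

Monolayer only; no friction, adhesion or substrate forces; one victim per
needle (the first capsule entered); effector diversity is reduced to a
genotype-level immunity relation, so toxin-specific retaliation triggers
are out of scope; the retaliation queue is answered with a one-step latency
(same-step duel recursion is deliberately avoided; at `dt` = 18 s this is
well under observed response times); and ESS estimates are grid-resolution
statements about a stochastic simulator, not roots of a smooth invasion
function.
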