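---
title: "Methods: a hybrid discrete-cell / continuum-oxygen growth simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a hybrid discrete-cell / continuum-oxygen growth simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridcell)
```

`hybridcell` simulates avascular multicellular growth by coupling a
center-based discrete cell model to a continuum oxygen field on a shared
Cartesian voxel lattice. This vignette is the package's account of the model,
its numerical treatment, the parameters that matter, and the choices made
where the design was genuinely open. The worked growth studies themselves are
run by `scripts/acceptance.R` and the test suite; this document explains what
they compute.

## The cell model

### Phases and stochastic transitions

Each cell is in one of six phases. Three are alive — *premitotic* (growing
toward division), *postmitotic* (the post-division recovery interval) and
*quiescent* (resting, division-competent) — and three are dead: *apoptotic*,
*early necrotic* and *late necrotic*. Necrosis is split in two because an
oxygen-starved cell first swells by taking up fluid (oncosis) and only later,
after membrane rupture, loses volume; the two-stage treatment is what lets
necrotic debris with realistic volumes accumulate in a spheroid core.

Premitotic and postmitotic residence are deterministic with durations
`T_prem = 13 h` and `T_postm = 2.5 h`. Every other transition is stochastic:
in a phase step of length $\Delta t$ a transition with rate $r$ fires with
probability $r\,\Delta t$ (one uniform draw per test; this is the
discretization of an exponential waiting time, and the calibration test
checks that a 10-h apoptosis-only experiment reproduces
$1 - e^{-r t}$ to within binomial error). The rates are:

* apoptosis: constant `r_apop = 0.0060/h` for all living cells;
* quiescent-to-premitotic activation: $r_{pro}(p)$ rises linearly from 0 at
  `Th_pro = 5 mmHg` of local oxygen to its maximum `r_pro_max = 0.1176/h` at
  `Sa_pro = 10 mmHg`;
* necrosis: $r_{nec}(p)$ is zero above `Th_nec = 5 mmHg` and rises linearly
  to `r_nec_max = 0.1667/h` at and below `Sa_nec = 2.5 mmHg`.

Within one phase step the per-cell order of tests is fixed and documented
(death first, then division marking, postmitotic maturation, quiescent
activation, early-to-late necrotic rupture, clock advance). The ordering is
not externally prescribed; at the default `dt_phase = 6 min` any ordering
effect is $O(\Delta t^2)$ and the fixed order makes runs bit-reproducible.

### Component volumes

The total volume $V$ of a cell is the sum of fluid ($V_F$), nuclear solid
($V_{NS}$) and cytoplasmic solid ($V_{CS}$) components. Each component
relaxes toward a phase-dependent target at a phase-dependent rate:

$$\frac{dV_i}{dt} = -r_{p,i}\,(V_i - V_i^p).$$

Written with the opposite sign this relation would diverge from the target;
the package implements the relaxation form, which is the only reading
consistent with cells *gaining* mass toward their targets. The fluid target
is $f_F V$ (with $f_F = 0.7502$) for living phases, the **current total
volume** for early necrotic cells — which is what makes them swell while
$V_F/V < 1$ — and zero for apoptotic and late necrotic cells. Solid targets
double from the quiescent values (135 and 488 µm³) to the premitotic ones
(270 and 976 µm³) when a cell activates for division; growth then follows
the ODE, so volume doubling takes a few hours, not an instant. The quiescent
standard volume implied by these numbers is
$V_{std} = (135 + 488)/(1 - f_F) \approx 2494\ \mu m^3$ (radius 8.41 µm).

Two derived thresholds close the life cycle, neither of which is externally
specified: an early necrotic cell ruptures once $V \ge 2\,V_{std}$
(`rupture_ratio = 2`), and any dead cell is deleted from the population once
$V < 0.02\,V_{std}$ (`removal_fraction = 0.02`). Both are configurable.

The ODEs are integrated with one explicit Euler step per phase step. The
fastest rate (3/h) at `dt_phase = 6 min` gives $r\,\Delta t = 0.3$, safely
inside the stability region; a convergence test verifies first-order
approach to the closed-form solution.

### Division

Division is instantaneous: a mature premitotic cell is replaced by two
postmitotic daughters, each with exactly half of every component volume
(total volume is conserved to the bit), placed at
$x \pm (R - R/2^{1/3})\,\theta$ with $\theta$ a uniformly random unit
vector, so the two daughter spheres of half volume span the parent's
diameter. Daughters inherit the parent's velocity history.

## Cell mechanics

Cells are elastic spheres interacting over short ranges. For a pair at
distance $d$ with radii $R_i, R_j$, with contact distance $R_R = R_i + R_j$
and adhesive reach $R_A = 1.25\,R_R$:

* adhesion, pulling $i$ toward $j$: magnitude $C_{cca}(1 - d/R_A)^2$ for
  $d \le R_A$;
* repulsion, pushing apart: magnitude $C_{ccr}(1 - d/R_R)^2$ for
  $d \le R_R$.

In the overdamped (inertialess) limit the drag balances the total force, so
each cell's velocity is the force sum divided by the drag coefficient
$\eta$. The source model never prints $\eta$ or the force constants; the
package follows the common center-based convention of absorbing the drag
into the coefficients ($\eta = 1$, forces in µm/min), with defaults
`C_ccr = 10`, `C_cca = 0.4`, `adhesion_distance_factor = 1.25` — all
configurable. A closed-form consequence used as a test: two identical cells
of radius 8.41 µm settle at the separation solving
$\sqrt{C_{ccr}}(1 - d/R_R) = \sqrt{C_{cca}}(1 - d/R_A)$, about 16.0 µm, i.e.
a slight overlap maintained by adhesion.

Positions advance with the two-step Adams–Bashforth rule
$x \leftarrow x + \tfrac{\Delta t}{2}(3v_{now} - v_{prev})$. The first
mechanics step of a run has no velocity history and falls back to forward
Euler; newly created daughters inherit the parent's `previous_velocity`.

### Linear-time force aggregation

Forces are short-ranged, so each cell only interacts with cells in the
3×3×3 block of voxels around its own, provided the voxel side is at least
the maximum interaction distance. Construction of the grid enforces
`dx >= adhesion_distance_factor * 2 * R(V_std)` (21.0 µm at the defaults,
against the 25-µm voxel). A swollen early necrotic cell can transiently
exceed the nominal radius, so a rare pair can reach slightly past one voxel;
such tails are truncated exactly as in the reference 25-µm setup.

Each mechanics step the cell arrays are reordered by ascending Morton
(Z-order) key of the containing voxel — bit $b$ of the x-index goes to key
bit $3b$, of y to $3b+1$, of z to $3b+2$ — using a stable radix sort, after
which cells sharing a voxel are contiguous and each voxel knows its index
range. The original design uses the same sort on a GPU for memory-coalescing
reasons; on a CPU the contract (ascending keys, contiguous ranges) is what
matters and a stable comparison/radix sort provides it. The mandatory
equivalence test checks the 27-voxel gather against an all-pairs $O(N^2)$
oracle to $10^{-10}$.

Coincident cell centers (possible only through degenerate input) get a pure
repulsion of magnitude $C_{ccr}$ along a fixed fallback axis, lower array
index pushed toward $-x$, preserving pairwise antisymmetry; the event is
counted and warned about.

### Confinement

All scenarios clamp cell centers into the domain box (a hair inside the
faces so voxel lookup stays valid). The duct scenario additionally projects
centers so the whole cell fits in the lumen: radial distance at most
$R_{duct} - R_{cell}$, axial coordinate at least the closed end plus
$R_{cell}$.

## The extracellular microenvironment

Oxygen (the only substance exercised, though the data model is per-field)
obeys

$$\partial_t \rho = D \nabla^2 \rho - \lambda \rho + S(\rho^* - \rho) - U \rho$$

on the shared lattice. Cells couple in through the uptake map: voxel $v$
has $U_v = \sum_{j \in v,\ living} (V_j / V_{voxel})\, U_o$ with
`U_o = 10/min`; dead cells do not consume. Cells read back the concentration
of their containing voxel (nearest-voxel, floor convention, no
interpolation).

Numerically, each diffusion tick applies first-order operator splitting:

1. **Diffusion–decay** via the locally-one-dimensional (LOD) method: three
   sequential implicit 1-D sweeps (x, then y, then z), each carrying a third
   of the decay and solving one tridiagonal system per perpendicular strip
   with the Thomas algorithm. The finite-volume stencil has interior
   diagonal $1 + \Delta t \lambda/3 + 2\Delta t D/\Delta x^2$, off-diagonals
   $-\Delta t D/\Delta x^2$, and end rows with a single flux term — the
   zero-flux (Neumann) closure. Because the factorization is identical for
   every strip of an axis it is computed once per sweep; the sweeps for the
   y and z axes eliminate across whole contiguous lines/planes so memory
   access stays sequential.
2. **Supply/uptake**, implicitly:
   $\rho \leftarrow (\rho + \Delta t\, S \rho^*)/(1 + \Delta t\,(S + U))$.

Dirichlet boundaries are realized as *pinned voxel sets* re-imposed after
every sweep and after the supply/uptake update: the domain faces for the
spheroid scenario, the duct-wall shell for the duct scenario, or any
interior mask. This keeps the sweep structure uniform (no per-row boundary
special cases) and makes mixed geometries trivial.

Properties verified by the suite: exact conservation of total substrate
under zero decay and all-Neumann closure; exact $(1 + \Delta t\lambda/3)^{-3}$
decay when $D = 0$; convergence of a 1-D delta to the Gaussian kernel within
2 % in $L_2$; second-order-in-$\Delta t$ sensitivity to the sweep order;
non-negativity; and agreement of the Thomas solver with dense linear algebra
to $10^{-10}$.

The transport constants are not printed in the source model; the package
inherits the reference values of the finite-volume framework that model
follows: $D = 10^5\ \mu m^2/min$, $\lambda = 0.1/min$, boundary oxygen
38 mmHg with $\rho^*$ equal to it. All are configurable.

## Multiscale scheduling

Diffusion, mechanics and phase updates run at their own cadences
(`dt_diff <= dt_mech <= dt_phase`, integer ratios enforced). Every diffusion
tick recomputes the uptake map (cached bit-identically between cell
updates), then the LOD step, then supply/uptake; at the mechanics cadence
the population is sorted, forces gathered, velocities and positions updated,
confinement applied; at the phase cadence oxygen is sampled and the cycle,
volume, division and removal logic runs. When cadences coincide the order
within a tick is diffusion, then mechanics, then phases. One RNG stream
drives the whole run in a fixed consumption order (step, module, array
index), so a seed fixes every result bit-for-bit — asserted by a
double-run test.

### Time-step defaults and the splitting bias

The reference cadence of the source model is mechanics/phases every 0.1 min
and diffusion every 0.01 min. The first-order split between diffusion and
uptake has $O(\Delta t\, U)$ steady-state error, and inside confluent tissue
$U \approx 6/min$, so the diffusion step controls how deep oxygen appears to
penetrate: coarser `dt_diff` biases interior oxygen low (a thinner viable
rim), and even the reference 0.01 min retains a residual bias of order 10 %.
The package defaults to `dt_diff = dt_mech = 0.1 min`, `dt_phase = 6 min` —
the multiscale design with phases every few minutes — and the scaled duct
study overrides `dt_diff` to the reference 0.01 min (its lattice is small,
so this is cheap) because the 7.2-mmHg wall condition sits so close to the
5-mmHg proliferation threshold that the splitting bias would otherwise
decide whether the tumor grows at all.

## Scenarios and what the scaled studies show

`initHDS()` seeds `n` quiescent cells at the standard volume uniformly in a
sphere packed at the random-close-packing fraction 0.64 (the radius follows
from the count unless given explicitly), with phase clocks drawn uniform in
$[0, 1/r_{pro,max}]$ to avoid an artificial division wave, and a uniform
oxygen field pinned at the boundary value on all faces. `initDCIS()` packs a
seed plug at the closed end of a cylindrical duct along $+x$, pins the
one-voxel shell of wall voxels (including the closed-end cap) at 7.2 mmHg,
and leaves the open end on the domain face with the zero-flux closure. A
flood-fill test verifies the shell is topologically closed around the lumen.

The desk-scale studies in `scripts/acceptance.R` use
`hdsScenarioConfig()` (500 seed cells, $60^3$ voxels of 25 µm, 72 h) and
`dcisScenarioConfig()` (duct radii 100/150/200 µm, 48 h, $32{\times}20{\times}20$
voxels). These sizes were chosen for single-CPU runtimes of minutes; the
full-size configurations (`scale = "paper"`: 2347 seeds, $10^6$ voxels,
450 h) are provided but involve of order $10^6$ cells and are intended for
long runs or accelerated hardware.

Two caveats on interpreting the scaled spheroid study. Starting from 500
cells (initial radius ~85 µm), 72 h of growth does not reach the
oxygen-limited radius at which a necrotic core forms (the minimum interior
oxygen stays near 10 mmHg, twice the necrosis threshold), so the run
exercises threshold-*consistent* behavior — no necrosis while oxygen is
everywhere above `Th_nec` — and near-linear radius growth, but not core
formation itself; core formation and rupture dynamics are exercised by the
unit tests and appear in longer or larger runs. Second, with all cells
oxygen-saturated the population grows exponentially, and the radius curve
(proportional to $N^{1/3}$) is only approximately linear; the linear-fit
$R^2$ reported by the acceptance script quantifies exactly this.

The scaled duct study reproduces the qualitative clinical/computational
observation that the axial advance rate of a duct-confined tumor *decreases*
with duct radius: oxygen enters through the wall, so the proliferative
fraction scales like perimeter over cross-section, $\sim 1/R$. The advance
rate is the least-squares slope of the front position (99th percentile of
living-cell axial coordinates) against time, in µm/day.

## What the generators do not emulate

Synthetic populations are homogeneous: one phenotype, no mutation or
lineage effects, no motility ($F_{mot}$ defaults to zero and is a hook, not
a model), no cell–matrix mechanics beyond scalar drag, no deformable
shapes, a single diffusible substance, and no vasculature or angiogenesis —
growth is strictly diffusion-limited. Passing tests therefore demonstrate
the numerical and algorithmic fidelity of the engine and the emergent
diffusion-limited growth phenomenology, not agreement with any particular
cell line's biology.

## Known limitations

* The diffusion/uptake splitting is first order; quantitative oxygen
  profiles depend visibly on `dt_diff` (see above). Within-step uptake uses
  the pre-step cell state, a choice that is first-order equivalent to the
  alternative.
* Radius metrics on a discrete population are estimators; the default is
  the 97.5th percentile of center distances from the centroid plus the mean
  cell radius (robust to stragglers), with `max` and other percentiles
  available.
* The explicit volume integrator requires `dt_phase * max(rate) < 1`;
  the validator does not currently enforce this jointly, but default and
  scenario configurations satisfy it with a wide margin.
* Populations are dense in memory; runs beyond ~$10^5$ cells on a single
  CPU are better served by the full-scale configurations on faster
  hardware.
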