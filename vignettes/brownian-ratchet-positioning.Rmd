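---
title: "A Brownian-ratchet model of McdA/McdB carboxysome positioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Brownian-ratchet model of McdA/McdB carboxysome positioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcdpos)
```

## The model

Carboxysomes in rod-shaped cyanobacteria are kept equidistant along the
nucleoid by a two-protein system: McdA, a ParA-like ATPase that binds the
nucleoid, and McdB, which coats the carboxysome and stimulates McdA's ATPase
activity, releasing it from the DNA. `mcdpos` implements this as a
Brownian-ratchet model with four coupled pieces:

1. **Geometry.** The nucleoid is a 2D domain: a rounded rectangle
   (rectangle with two spherical caps on its long axis; default
   2.5 µm × 0.6 µm, tip-to-tip × width) or a circle (default 1.7 µm
   diameter). Cargos are disks of diameter 175 nm moving on this surface
   with reflective boundaries. We read "2.5 µm by 0.6 µm" as the overall
   bounding box (body 1.9 µm plus two caps of radius 0.3 µm); the
   alternative reading (2.5 µm body plus caps) would only lengthen the
   domain without changing any mechanism.

2. **McdA surface chemistry.** Nucleoid-bound McdA lives on a square lattice
   of binding sites (spacing 0.01 µm, ~14,500 sites on the default rod).
   McdA dimers partition into three conserved pools: bound (= occupied
   sites), free (cytosolic, binding-competent, well mixed), and refractory
   (post-hydrolysis, temporarily unable to rebind DNA). Empty sites bind
   free McdA at `k_on · n_free/n_total` per site; occupied untethered sites
   release basally at `k_off_basal` (to the free pool); refractory dimers
   reset at `1/tau_reset`. The slow reset is the essential delay: McdA
   released around a cargo cannot immediately rebind, so the cargo digs a
   local depletion zone into the bound-McdA field.

3. **Tethers.** Each cargo carries `n_mcdb` McdB tether slots. An occupied,
   untethered site within `r_capture` of the cargo center can form a
   Hookean tether (`k_attach` per eligible pair); each tether breaks at
   `k_detach`, and every break *is* a stimulated hydrolysis: the site's McdA
   leaves the nucleoid into the refractory pool. Tethered McdA is held by
   its bond and is exempt from basal unbinding; a site holds at most one
   tether. Tether geometry uses the cargo center (McdB is not spatially
   resolved on the shell).

4. **Motion.** Cargos follow overdamped Langevin dynamics in kBT = 1 units
   (mobility = `D_free` by the Einstein relation):
   `x' = reflect(x + D F dt + sqrt(2 D dt) ξ)`, with `F` the summed tether
   spring force, plus pairwise hard-disk exclusion. The update order within
   each fixed timestep is chemistry → tethers → motion → exclusion, with
   cargo order randomized each step.

The net effect is the classic ParA-type ratchet: transient tethers pull the
cargo toward wherever bound McdA remains, the cargo consumes McdA where it
sits, and the self-generated asymmetry rectifies Brownian motion into
directed movement — away from other cargos (which also deplete) and away
from boundaries (beyond which there are no sites at all).

## Default parameters and how they were chosen

The experimental literature fixes the geometry, cargo size, trajectory
length (600 s) and ensemble size (36), but not the microscopic rates, which
published work on this model class defers to prior ParA/ParB fits. The
package therefore treats the kinetic and mechanical constants as model
parameters whose defaults must place the system in the *directed
segregation* regime — cargos move apart, then become relatively stationary —
which is a genuinely narrow corner of parameter space. The shipped defaults
are:

| parameter | default | units | role |
|---|---|---|---|
| `chemistry.n_total` | 8000 | dimers | total McdA |
| `chemistry.k_on` | 1.0 | 1/s | per-site binding at full free pool |
| `chemistry.k_off_basal` | 0.01 | 1/s | basal unbinding |
| `chemistry.tau_reset` | 20 | s | refractory (hydrolysis-reset) delay |
| `tethers.r_capture` | 0.3 | µm | tether formation radius |
| `tethers.k_attach` | 10 | 1/s | per eligible pair |
| `tethers.k_detach` | 0.1 | 1/s | per tether; every break releases McdA |
| `tethers.k_spring` | 100 | kBT/µm² | tether stiffness |
| `cargo.n_mcdb` | 400 | slots | McdB per carboxysome |
| `cargo.D_free` | 1e-6 | µm²/s | free cargo diffusivity |
| `motion.dt` | 1e-3 | s | timestep |
| `simulation.lattice_spacing` | 0.01 | µm | McdA site spacing |

Three timescale arguments pin these numbers down; each is the resolution of
a real tension we hit while calibrating:

* **Parking versus oscillating.** A cargo keeps moving as long as its wake
  refills quickly: if the per-site rebinding time `n_total/(k_on · n_free)`
  is shorter than a domain transit, the cargo ping-pongs end-to-end
  (the oscillatory regime of this model family) and never passes a
  stationarity test. Directed-then-stationary behavior needs a McdA-starved
  free pool (deep depletion wakes that outlive the run) *and* a cargo that
  responds more slowly than it eats: with `D_free` = 1e-6 µm²/s the drift
  speed during segregation (~4×10⁻³ µm/s with saturated tethers) still
  crosses a half-nucleoid well within 600 s, but the residual creep at the
  parked state stays below the 0.05 µm / 60 s stationarity resolution.
  Carboxysomes are in fact among the least mobile cargos measured in
  bacteria, so the small diffusivity is also the physically sensible
  choice.

* **Arrest noise floor.** A parked cargo jitters with per-axis variance
  `1/(n_tether · k_spring)` (thermal) plus the wander of its anchor
  centroid, whose scale is `r_capture/(2·sqrt(n_tether))`. Both must sit
  well under the 0.05 µm stationarity window, which forces hundreds of
  simultaneous tethers — hence `n_mcdb = 400` slots, a fine 0.01 µm lattice
  so that many occupied sites exist inside the capture disk, and the large
  `n_total`. (McdB copy number per carboxysome is unmeasured; hundreds of
  dimers on a 175 nm shell is geometrically reasonable.)

* **Depletion contrast.** The depletion index around a pinned cargo
  compares annulus to bulk occupancy; with tethered sites counting as
  occupied, the standing tether density `n_mcdb / (sites in capture disk)`
  bounds the achievable contrast from below, and the eating rate
  `n_tether · k_detach` must beat the local rebinding flux. `k_detach` =
  0.1/s balances visible depletion (index ≈ 0.2 under defaults) against the
  global McdA budget: the total stimulated-release flux times `tau_reset`
  must stay well under `n_total`, or the whole pool collapses into the
  refractory state at high cargo counts.

* **Transverse structure.** `r_capture` ≈ the nucleoid half-width makes the
  capture disk graze the long walls as soon as a cargo leaves the axis, so
  site truncation centers isolated cargos (the linear arrangement), while
  the capture-disk diameter (0.6 µm) sets the crowding scale at which
  staggering pays: for spacings below ~0.5 µm (six or more cargos on a
  2.5 µm nucleoid) a zig-zag recovers nearest-neighbor distance faster than
  it loses wall clearance.

All of these are exposed in the configuration file; none is special-cased in
code.

## Classifying arrangements

The packing classes are defined quantitatively (the field's descriptions
are visual):

* **clustered** — mean nearest-neighbor distance < 2.5 × cargo radius;
* **linear** — transverse spread (SD of y) ≤ `t_lin` = 0.05 µm;
* **staggered** — consecutive x-sorted cargos alternate sides of the long
  axis in ≥ 75% of adjacent pairs *and* consecutive-neighbor distances are
  near-equal (CV ≤ `spacing_cv_max` = 0.25);
* **other** — anything else.

The equidistance gate deserves a note. Alternation alone cannot separate a
zig-zag from chance: for six independent transverse positions the
probability that signs alternate in ≥ 75% of adjacent pairs is 6/32 ≈ 0.19,
so a rule without a regularity condition would mislabel about a fifth of
random configurations as staggered. Hexagonal packing, by contrast, *means*
near-equidistant neighbors. Measured on this package's own output, simulated
zig-zag steady states have consecutive-distance CVs of 0.03–0.28 while
random hard-core configurations that happen to alternate have a median CV
near 0.45, so the 0.25 default separates the populations; it is exposed as a
threshold for users whose geometries differ. (An x-gap-ratio gate was tried
first and rejected: adjacent opposite-row cargos in a genuine zig-zag can
have nearly equal x, which explodes a max/min gap ratio.)

Stationarity (`steady_state_time`) is the earliest record after which no
cargo moves more than `eps` = 0.05 µm between any two records inside any
subsequent 60 s window; anchor windows must fit inside the record span,
because a window anchored at the final record is degenerate and would
declare any trajectory stationary at its last sample. Motility regimes
(`classify_motility`) follow from stationarity plus the separation gain
(> 0.3 µm → directed segregation) or, failing stationarity, from the
log-log slope of the ensemble MSD over short lags (slope within [0.8, 1.2]
→ diffusive). Lags are capped at 30 records because confinement saturates
the MSD — most quickly across the 0.6 µm width — and long lags bias the
fitted exponent down.

## The packing oracle

As an independent check that "linear below six, staggered from six" is a
geometric fact and not a simulator artifact, `maxmin_arrangement()` solves a
disk-packing problem: place N disks of radius 0.0875 µm in the domain
maximizing the minimum over pairwise center distances *and doubled wall
clearances*. The wall term matters: with pairwise distances alone, adding
transverse amplitude never costs longitudinal spacing, so zig-zags win from
N = 3 — an objective that provably cannot reproduce a linear optimum for
2 < N ≤ 5. Counting the wall as a mirror neighbor is the standard
equal-disk-packing objective and the physically right one here (the
nucleoid edge truncates a cargo's McdA supply exactly as a neighbor's
depletion zone does). Under that objective the optimum on the default rod
is collinear through N = 5 and staggers from N = 6, which is what the
acceptance suite asserts. A lexicographic tie-break (maximize the pairwise
minimum among wall-optimal configurations) handles small N, where the side
wall saturates the objective and would otherwise leave the spread arbitrary.
The solver is multi-start stochastic relaxation (24 starts × 1500 steps by
default); for N ≤ 8 restarts agree to ~1% in the objective.

## Numerical scheme and its validation

The engine is a fixed-step hybrid: per-step tau-leaping for all chemistry
(binding, unbinding, resets, attach, detach — probabilities `1 − exp(−r·dt)`
with guards requiring `dt · max rate ≤ 0.1`) coupled to Euler–Maruyama
Langevin motion. Three approximations are deliberate and tested:

* **Leaping bias.** Tau-leaping at the guard boundary carries an O(dt) bias
  (about +0.006 occupancy at `dt` = 0.1 s for the cargo-free chemistry,
  +0.0008 at 0.02 s); the test suite compares the production code path
  against an exact event-driven Gillespie oracle and against the closed-form
  stationary law of the cargo-free birth–death chain. At the simulator's
  `dt` = 1e-3 s the bias is negligible.
* **Attachment thinning.** Inside the compiled loop, per-pair attachment
  Bernoulli draws are replaced by binomially-thinned uniform proposals over
  the capture-disk cells (identical rates to O(p²) ≈ 0.005% per pair,
  ~30× faster). The R-level `tether_step()` keeps exact per-pair semantics
  and the two are statistically cross-checked.
* **Reflection.** Boundary crossings reflect specularly about the local
  tangent, iterated until interior; tests pin this against a small-step
  rejection oracle to 10⁻³ µm.

Determinism is part of the contract: everything draws from R's RNG, a run is
a pure function of `(config, master_seed)`, ensemble trajectory *i* uses
`master_seed + i − 1`, and trajectory files are written with fixed 9-digit
formatting so identical runs are byte-identical.

## What the synthetic generators emulate

`gen_arrangement()`, `gen_field()` and `gen_trajectory()` produce idealized
arrangements (collinear, zig-zag, clustered, hard-core random), occupancy
fields with imposed depletion zones, and trajectories of known motility
class (reflected random walks; deterministic separate-then-freeze; static),
in the simulator's exact file formats. They give every analysis operation a
ground truth that does not depend on the simulator being right. They do
*not* emulate microscopy: no localization error, no photophysics, no
z-projection, no cargo size variation — so classifier accuracies measured on
fixtures bound what the analysis layer can do on clean coordinates, not on
segmented images. Fixture defaults (transverse noise 0.02 µm, stagger
amplitude 0.15 µm, n = 6) match the regime the classifier is designed for;
pushing `noise_sd` toward `t_lin` degrades linear/staggered separation, as
it must.

## Problem sizes

The shipped validation runs use the full model at full resolution: 600 s
trajectories at `dt` = 1e-3 s on the ~14,500-site default lattice; 8 seeds
per cargo count for the packing transition (N = 2…8), 16 seeds for the
two-cargo segregation check, a 300 s pinned-cargo run for the depletion
index, a 10,000 s chemistry-only comparison against the Gillespie oracle on
a ~100-site lattice, and 12-start packing-oracle solves. A full 36-member
ensemble (`run_ensemble()` default, matching the published ensemble size)
takes a few minutes on one core.

## Known limitations

* Bound McdA does not diffuse along the nucleoid, and the free/refractory
  pools are well mixed; the depletion zone is therefore exactly the eaten
  region, with no spreading by surface diffusion. End-to-end McdA
  oscillations — which in vivo require several carboxysomes — are outside
  what this closure can produce, and are not claimed.
* Tethers are linear springs with force-independent detachment (no
  catch/slip behavior) and unresolved McdB positions on the shell.
* The nucleoid is static; hyperelongated cells with multiple nucleoid
  lobes are not modeled.
* The directed-segregation defaults are one calibrated point in a narrow
  regime, not a fit to measured rate constants; conclusions should be read
  as "the mechanism suffices", not "these are the in vivo rates".
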