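---
title: "Methods: a block-decomposed cellular Potts model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a block-decomposed cellular Potts model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blockcpm)
```

## The model

blockcpm simulates tissues with the cellular Potts model (CPM): every voxel
of a 3D lattice holds an integer cell identifier, and a biological cell is
the set of voxels sharing one id.  Id 0 is the liquid medium cells grow
into; a reserved sentinel marks immutable wall padding at the domain border;
`solid` cell types (vessels, matrix) occupy the lattice, adhere and pass
signals, but take no part in the Potts dynamics.

Dynamics are single-voxel copy attempts: a voxel may adopt the id of a
randomly chosen stencil neighbor (6 or 26 neighbors), accepted with the
Metropolis rule at temperature $T$ — probability 1 when the energy change
$\Delta E$ is negative or zero, $e^{-\Delta E/T}$ otherwise.  The energy is
a sum of exchangeable terms:

* **adhesion** — each lattice face between *different* cells costs
  $A_{\tau,\tau'}$, the coupling of the two cell types (same-cell faces cost
  nothing; this realises the Kronecker-delta convention);
* **volume** — $\lambda_V (v - V_0)^2$ per cell, with $v$ the voxel count
  and $V_0$ the cell's *effective* target volume;
* **surface** — $\lambda_S (s - S_0)^2$, with $s$ measured under the
  configured surface metric.

Targets are stored per cell (initialised from the type) so that growth
("size change") and apoptotic shrinking can move them independently.
Liquid and solid compartments carry no volume or surface constraint.

## Surface metrics

The traditional Manhattan metric counts exposed voxel faces.  It makes a
digital sphere and a cube of equal volume indistinguishable by surface, so
cell clusters drift toward cubic shapes.  As an isotropy-preserving
alternative, the package measures the 0.5 iso-surface of a cell's binary
indicator (cell voxels 1, everything else 0) over the marching cubes that
span each $2\times2\times2$ voxel neighborhood — every voxel contributes to
eight cubes, crossings lie at edge midpoints.

The per-configuration geometry is *constructed*, not tabulated: for each of
the 256 corner configurations the marching-squares cut segments of the six
cube faces are oriented (inside region on the left, seen from outside) and
chained into closed loops; each loop is fan-triangulated from its centroid.
Ambiguous (saddle) faces connect the inside corners ("inside wins"),
applied uniformly, which makes the surface globally closed and consistently
oriented across neighboring cubes — enclosed volumes then follow from the
divergence theorem (a single voxel measures area $\sqrt3$ and volume $1/6$,
the octahedron through its face midpoints).  Non-planar loops are
fan-triangulated by convention; this reproduces all planar-case areas
exactly and differs from other published triangulations only in warped
saddle cases.  The same tables drive the full-field measurement and the
incremental single-flip deltas, so the two can never drift apart.

Pairwise *shared* surfaces (used for adhesion bookkeeping and signal
transport) are always side-counted faces, even when the energy metric is
marching cubes: an iso-surface element cannot be attributed unambiguously
to one neighbor pair.  Under the marching metric the adhesion difference of
a flip therefore scales the exact side-counted pairwise changes by the
local ratio of marching to side-count boundary change — a documented
approximation; with side counting, adhesion bookkeeping is exact, and the
incremental $\Delta E$ equals a full-Hamiltonian recompute to $10^{-9}$
(property-tested).

## Blocks, checkerboards, and the cell-data exchange

The domain is decomposed into equal blocks, each carrying a one-voxel halo
copied from its neighbors' interiors (wall at the domain border).  To allow
all blocks to sweep concurrently without reading each other's writes,
voxels are colored like a checkerboard from their *global* parity: two
colors suffice for the 7-point stencil; the 27-point stencil — and the
marching metric, whose incremental update reads the full
$3\times3\times3$ neighborhood — require the eight-coloring
$(x \bmod 2) + 2(y \bmod 2) + 4(z \bmod 2)$.  One Monte Carlo sweep (MCS)
visits one color; a *cycle* of `n_colors` sweeps gives every voxel exactly
one chance.  During a sweep all cell properties stay at their last
committed values; changes accumulate in per-block delta stores.

Each commit performs the halo exchange and the ACD ("additional cell
data") exchange: every block sends, to its up-to-26 neighbors, a message
with its cells' committed absolutes, this sweep's deltas, interior-presence
flags, pending cell events and Message-of-Death notices.  Receivers fold
all deltas into the absolutes, seed records for cells that newly enter
their halo, and drop records for cells that left.  The package runs these
exchanges serially but message-faithfully — who sends what, when, is the
same protocol a distributed-memory implementation would use, so the
correctness tests exercise the real consistency surface.  This protocol is
sound only while every cell spans at most two blocks per dimension; a cell
reported with interior presence from *opposite* sides of an axis has
outgrown that bound, and a Message of Death is issued: forwarded two
commits over the 26-neighbor topology it reaches the full (clipped)
$5^3$ block neighborhood — 125 blocks in the interior — and all of them
delete the cell in the same commit.

The sanity action cleans single voxels detached from their cell (replaced
by liquid, with exact bookkeeping); an optional radius rule deletes voxels
beyond a configured distance from the cell's center of mass.  Larger
detached fragments are deliberately left to the radius rule or the MoD
path: identifying an arbitrary detached segment is not a block-local
computation.

## Sampling: the visitor pattern

Within the active color, voxels are visited in array order with i.i.d.
random jumps, uniform on $\{1,\dots,2m-1\}$ for a mean stride $m$ — linear
traversal keeps the sweep cache-friendly, and subsampling (one in $m$
voxels per sweep) bounds how far a cell's true volume and surface can run
ahead of their committed values within one MCS.  The first index is drawn
from the renewal process's stationary-delay distribution,
$P(k) \propto 2m-1-k$, which makes every index selected with probability
exactly $1/m$ (chi-square-tested).  Each block owns an independent,
seedable RNG stream (xoshiro256++ seeded from the base seed and the block
index); all of a block's random choices — jumps, neighbor directions,
acceptance draws — consume its own stream, and runs are byte-reproducible
under a fixed seed.

## Cell events

Agent-based events use a two-step protocol: at each cycle boundary, events
are *determined* only in the block owning the cell's integer
center-of-mass voxel, travel with the ACD exchange, and are *executed* one
cycle later in all blocks holding the cell.

* **Division** fires with rate $R_\mathrm{Div}$ per cycle when
  $v > 0.9\,V_0$, the cell is older than the minimum division age, and all
  configured signal channels lie inside their division windows.  A plane
  with uniformly random orientation through the center of mass is fixed at
  determination; at execution, voxels on the non-negative side keep the
  mother's id (ties to the mother), the rest take a fresh id allocated from
  the determining block's disjoint range.  Both daughters are re-measured
  from the field, their age resets to zero, targets re-initialise from the
  type, and the mother's signal content is split in proportion to the
  daughter volumes.  A plane leaving one side empty aborts the division.
* **Mutation**: with probability $R_\mathrm{Mut}$ the daughter type is
  drawn from the mother type's row of the transition matrix; otherwise it
  inherits the mother's type.
* **Death** fires with rate $R_\mathrm{Death}$ when the cell is starved
  (signals inside the configured death windows, e.g. nutrient below a
  threshold) and old enough, plus a background rate $R_\mathrm{Death}/1000$
  for natural death — the age gate applies to both paths (the background
  path's age gating is our reading of an ambiguous rule).  Execution
  switches the cell to its apoptotic type with age reset; each cycle the
  effective target volume follows
  $V_{0,\mathrm{apop}} = \max(0,\, V_0 - \chi\,\mathrm{age})$ and the
  target surface scales as $(V_{0,\mathrm{apop}}/V_0)^{2/3} S_0$ — the
  two-thirds power keeps the shrinking cell compact (the shrinking-surface
  law is this package's choice).  At $v = 0$ the cell and its records are
  deleted everywhere.

Event *determination* and the per-MCS delta exchange are strictly
message-local.  Event *execution* (the division split and the post-event
re-measurement) updates all involved blocks synchronously from the
reassembled field: events are rare relative to sweeps, and the serial
runner makes the globally-consistent update exact rather than re-deriving
it from block-local measurements.

## Signal transport

Each cell carries a concentration vector; the liquid medium participates
as a single well-mixed compartment.  Diffusion is approximated as flux
through shared surfaces: for a contacting pair,
$$J_{ij} = \left(\frac{S_{ij}}{S_i} + \frac{S_{ij}}{S_j}\right)
  D_{\tau(i)\tau(j)}\,(\sigma_j - \sigma_i),$$
added to one cell and subtracted from the other, so closed systems
conserve total signal exactly (antisymmetry).  Constant suppliers (e.g.
vessels) never change.  Decay applies a per-type relative factor and
absolute subtraction, clamped at zero:
$\sigma \leftarrow \max(0,\, d\,\sigma - a)$.  Two numerical guards: the
update is sub-divided whenever any pair coupling
$(S_{ij}/S_i + S_{ij}/S_j) D$ exceeds $1/2$ (explicit-update contraction),
and diffusion runs once per color cycle on freshly swept shared surfaces.
$D$ is a dimensionless per-update rate; no physical time scale is implied.

## The placement-bias harness

The validation experiment asks whether the block decomposition biases the
dynamics: two non-interacting cells with $V_0 = 1000$, $S_0 = 1400$ under
the marching metric, one at the center of a block, one at the common
corner of all eight blocks of a $2\times2\times2$ grid, so every exchange
path is exercised.  Per color cycle the harness records $v/V_0$, $s/S_0$
and the displacement of the integer center-of-mass voxel; after burn-in it
reports pooled relative standard deviations, displacement summaries, and
two-sample Kolmogorov–Smirnov tests between the placements on thinned
(decorrelated) samples.

Scaled study conditions, chosen once: blocks of $32^3$ (domain $64^3$),
12 replicates, 5000 cycles with a 1000-cycle burn-in, KS thinning of 400
cycles.  The pinned `bias-test.json` sets $T = 14$, $\lambda_V = 0.02$,
$\lambda_S = 0.01$, sampling stride 100.  Rationale: the temperature and
couplings put the temporal fluctuations of volume and surface in the
few-percent band (about 2% of the targets here) with the cell's mean
surface close to its target.  In this regime boundary flips cost much less
than $T$, so acceptance is high and each cell's center executes a slow,
free random walk; the *replicate-averaged* center trajectory — the
quantity an ensemble-averaged movement plot shows — stays within a
fraction of a voxel.  The harness therefore reports both: the displacement
of the replicate-averaged center (the headline number) and the
per-replicate scalar wander.  Two deliberate geometry choices remove
artifacts from the headline number: seed cells are digital balls
(radius 6.2, ~1000 voxels) centered on lattice points, because a
$10^3$ cube starts with its center on a half-voxel boundary and integer
rounding alone would contribute ~0.8 voxels of spurious displacement; and
the stride of 100 (rather than the dense-tissue default of 5) slows the
per-cycle flip rate so that 12 replicates suffice for the ensemble average
to settle — the reference regime was established with 60 replicates.  All
bias *conclusions* (equality of the two placements) are parameter-free;
only the fluctuation magnitudes depend on the pinned file.

What the harness does and does not show: synthetic single-cell runs probe
the parallel machinery (halo staleness, delta folding, placement
independence), not biological realism — no chemotaxis, no cell-cell
interactions during the bias runs, and lattice anisotropy is only
mitigated, not removed, by the marching metric.

## Numerical and design notes

* Volume bookkeeping uses voxel counting by default even under the
  marching surface (division and death arithmetic stays integer-exact);
  marching volume measurement is available.
* One "MCS" is one color sweep; rates are per cycle (`n_colors` sweeps).
  Event rates, size-change rates and decay are evaluated at cycle
  boundaries.
* Walls never adhere, never count toward surfaces or shared surfaces, and
  are never copy sources or targets.
* Daughter ids come from per-block disjoint ranges
  (`10^6 * block + counter`), so ids stay globally unique without
  coordination.
* The action schedule per cycle boundary is configurable; the default is
  sanity, execute events, determine events, size change, diffusion, decay,
  writers.
* Problem sizes in the shipped tests: property tests run on $5^3$ fields;
  engine audits on $16\times8\times8$ two-block domains; the bias harness
  on the $64^3$ conditions above.
* Known limitations: messages are in-memory objects delivered serially (no
  true distributed transport); the marching-metric adhesion scaling is
  approximate; detached multi-voxel fragments are handled only by the
  radius rule or the MoD path; periodic boundaries and non-uniform blocks
  are unsupported.

## A minimal run

```{r example, eval = FALSE}
cfg <- cpm_config(list(
  domain = list(size = c(32, 32, 32), blocks = c(2, 2, 2), temperature = 10,
                mean_step = 5, seed = 1),
  celltypes = list(
    liquid = list(liquid = TRUE),
    cell = list(V0 = 512, S0 = 500, lambda_V = 1, lambda_S = 0.2,
                adhesion = list(liquid = 4, cell = 8))),
  init = list(list(shape = "cube", corner = c(12, 12, 12), size = 8,
                   type = "cell")),
  output = list(every = 50, csv = TRUE, vti = TRUE, path = "out")))
sim <- run_simulation(cfg, cycles = 200, seed = 1)
cellinfo(sim)
```
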