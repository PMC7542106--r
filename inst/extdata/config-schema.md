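# blockcpm configuration schema (v1)

A simulation is configured by one JSON object.  `load_config()` validates
it and fills the defaults noted below; errors name the offending key path.

## domain

| key           | type        | default    | meaning |
|---------------|-------------|------------|---------|
| size          | int[3]      | required   | interior extent in voxels |
| blocks        | int[3]      | [1,1,1]    | block grid; must divide `size` |
| colors        | 2 or 8      | 8          | checkerboard classes |
| stencil       | 7 or 27     | 27         | copy-source neighborhood (D3C7/D3C27) |
| metric        | "side" \| "marching" | "marching" | surface metric of the energy |
| volume_method | "count" \| "marching" | "count" | volume measurement |
| mean_step     | int >= 1    | 5          | mean visitor jump width |
| temperature   | number > 0  | 10         | Metropolis temperature |
| seed          | int         | 1          | base seed (per-block streams derive from it) |

Constraints: the 27-point stencil and the marching metric both require 8
colors (read safety).

## signals

Array of channel names (may be empty).  All per-channel maps below are
keyed by these names.

## celltypes

Named object; exactly one type must set `"liquid": true`.  Per type:

| key             | meaning |
|-----------------|---------|
| V0, S0          | target volume and surface (defaults 0) |
| lambda_V, lambda_S | coupling strengths (defaults 0) |
| adhesion        | map type -> coupling; symmetric; if any type specifies adhesion, every pair must be resolvable (liquid-liquid defaults to 0) |
| diffusion       | map type -> diffusion constant (symmetric, defaults 0) |
| size_change     | {V0, S0}: per-cycle additive change of the effective targets |
| decay           | map channel -> {relative (default 1), absolute (default 0)} |
| constant_signal | fixed signal supplier (flux never changes it) |
| start_signal    | map channel -> initial concentration |
| division        | {rate, min_age, signal_min, signal_max, mutation_rate, mutation (map type -> prob, sums to 1), excluded} |
| death           | {rate, min_age, signal_min, signal_max, apoptotic_type, chi} |
| liquid, solid   | compartment flags |

Rates are probabilities per color cycle, evaluated in the block owning the
cell's center of mass.  Division requires `v > 0.9 * V0_eff`, age >=
`min_age` (cycles) and all configured channels inside
`[signal_min, signal_max]`.  Death fires at `rate` when the signal window
holds (e.g. nutrient below a threshold via `signal_max`) and at
`rate/1000` regardless of signals; `chi` is the per-cycle target-volume
shrink rate of the apoptotic type.

## init

Array of placements (cells get sequential ids from 1):

* `{"shape": "single", "position": [x,y,z], "type": T}`
* `{"shape": "cube", "corner": [x,y,z], "size": n, "type": T, "cell_edge": e?}`
* `{"shape": "sphere", "center": [x,y,z], "radius": r, "type": T, "cell_edge": e?}`
* `{"shape": "fill", "corner": [x,y,z], "size": n, "cell_volume": v, "type": T}` —
  a cubic region densely tiled with equal-volume cubic cells
  (`cell_edge = v^(1/3)`, which must be an integer)

Without `cell_edge` the region is one cell; with it, the region is tiled
into cubic cells of edge `e` (clipped to the sphere).  Every cell must be
smaller than the block edge per dimension; overlaps are errors.

## output

`{every, csv, vti, path, int64}` — a frame every `every` cycles (0 = no
output): `cellinfo_NNNNNN.csv` (id, type, age in MCS, volume, surface,
integer CoM voxel, one column per signal) and `frame_NNNNNN.vti` (VTK
ImageData, cell ids as Int32/Int64 point data named `cellID`).

## schedule / sanity

`schedule`: ordered subset of `sanity`, `execute_events`,
`determine_events`, `size_change`, `diffusion`, `decay`, `output`
(default: that order), run at every cycle boundary.
`sanity`: `{single_voxel (default true), radius (off), every (1)}`.
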