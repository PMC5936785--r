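---
title: "ventriflow: trabeculated-ventricle hemodynamics at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ventriflow: trabeculated-ventricle hemodynamics at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventriflow)
```

ventriflow asks a single question end to end: how much of the hemodynamic
effect of endocardial trabeculation — the sponge-like muscular ridges lining
the left ventricle — can a thin porous layer on a smoothed cavity reproduce?
The package builds paired smoothed/trabeculated synthetic ventricles, runs an
incompressible flow solver through both, quantifies pressure drop, wall shear
stress and vortex structure, and sweeps a Darcy porous-layer surrogate
against the trabeculated reference.

The repository is organized as an analysis workflow: the reusable machinery
lives in the package under `R/`, while the study itself is driven by the
numbered scripts under `analysis/`, run in order (each stage reads its
predecessor's output from `analysis/output/`).

## Paired geometries

A smoothed cavity is a tilted half-ellipsoid with two flow-development tubes
(mitral-side inlet, aortic-side outlet) meeting the basal plane; its
trabeculated counterpart is generated from the same surface by a seeded
displacement field of inward bumps plus papillary-muscle-like protrusions,
calibrated to a target trabecular volume fraction.

```{r geometries, eval = FALSE}
smoothed <- build_smoothed_cavity(cavity_params())
detailed <- add_trabeculation(
  smoothed, trabeculation_params(target_volume_fraction = 0.30, seed = 1))
compute_markers(detailed)$trabecular_volume_pct
```

Because both surfaces share vertices and caps, every downstream difference
is attributable to the trabeculation alone. `compute_markers()` reports the
trabecular volume fraction (hull-based, so it is near zero for the smoothed
surface), inlet/outlet areas, the inter-valve angle, and the inlet Reynolds
number.

## Meshing and the flow solver

`tetrahedralize()` is an isosurface-stuffing lattice mesher: it fills the
surface with a Freudenthal tetrahedral lattice, optionally bisects cells
near the wall (`near_wall_refinement`), and tags boundary faces as `wall`,
`inlet_cap` or `outlet_cap` by inheritance from the surface labels.

The solver is an equal-order P1 finite-element scheme: explicit
strong-stability-preserving Runge–Kutta in time, a choice of convective
(`CONV`) or energy-conserving (`EMAC`) nonlinear form, non-incremental
pressure projection for incompressibility, and an implicit Darcy drag term
for porous cells. `flow_bcs()` turns the mesh tags into boundary conditions:
a ramped plug inflow on the inlet cap, flux-matched outflow on the outlet
cap, no-slip on walls and cap rims.

```{r solve, eval = FALSE}
mesh <- tetrahedralize(smoothed, max_cell_volume = 1.1e-8,
                       near_wall_refinement = 2, jitter = 0)
fem <- build_fem(mesh$vertices, mesh$cells)
prob <- setup_solver(fem, fluid_properties(),
                     solver_config(max_time = 0.12),
                     flow_bcs(mesh, function(t) constant_inflow(t),
                              outlet_model()))
run <- solve_transient(prob, probes = tube_probes(mesh, fem))
```

## Hemodynamic read-outs

`summarize_run()` reduces a transient run to three scalars:

* **pressure drop** — per-frame difference of the Freedman–Diaconis
  histogram modes of the inlet- and outlet-tube pressure probes, averaged
  over the final frames;
* **WSS median** — median wall shear stress over informative cavity wall
  faces (faces whose owning cell has an interior vertex; fully-boundary
  cells carry an identically zero P1 gradient and are excluded);
* **vortex surface** — total area of the Q-criterion isosurface,
  `vortex_surface()`, at a threshold tied to the run's own positive-Q level
  by `cavity_q_threshold()`.

## The porous surrogate

`porous_layer_spec(thickness, sigma)` links the porosity parameter
`sigma = mu / K` to the hydraulic conductivity and intrinsic permeability
exactly; `porous_layer_cells()` selects the near-wall cells (with a basal
standoff mirroring the trabeculation taper), and `run_sweep()` solves one
transient per (thickness, sigma) grid point.

`reproduce_desk()` chains all of the above for one seed and scores the
result: does trabeculation raise the pressure drop, lower the WSS median,
and enlarge the vortex surface — and does some porous grid point move all
three smoothed-model metrics toward the detailed reference?

```{r desk, eval = FALSE}
ds <- reproduce_desk(seed = 1)
ds$comparisons
```

## Validation surface

The solver and post-processing are validated against closed forms, all
exercised in the test suite: Taylor–Green vortex decay, plane Poiseuille
flow, kinetic-energy conservation of the EMAC form on an inviscid jittered
mesh, the Darcy pressure-gradient/drag balance, Q-criterion values for rigid
rotation and pure shear, and the area of a spherical isosurface.
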