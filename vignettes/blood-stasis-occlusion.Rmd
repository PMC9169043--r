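---
title: "Blood stasis and occlusion-position analysis for coronary arterial fistulas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blood stasis and occlusion-position analysis for coronary arterial fistulas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caflow)
```

## The problem

A coronary arterial fistula (CAF) is an abnormal connection between a
coronary artery and a heart chamber or another vessel. Large fistulas steal
blood from the coronary and systemic circulation and are commonly treated by
occluding the fistula. When the fistula ends in a saccular terminal
aneurysm, the surgeon chooses between a **distal occlusion** at the fistula
terminus, which keeps the aneurysm connected (the *aneurysm-reserved*
configuration), and a **proximal occlusion**, which excludes the aneurysm
and part of the distal fistula (the *aneurysm-removed* configuration).
Either way the occluded fistula becomes a dead-end pouch in which blood
stagnates — the stasis arm of Virchow's triad — and may thrombose, with risk
of myocardial infarction. A proximal occlusion removes more of the stagnant
volume but can sacrifice coronary branches supplied through the
fistula-bearing artery.

`caflow` implements, at desk scale, the simulation chain needed to compare
those options quantitatively: pulsatile hemodynamics with lumped-parameter
outlet models, a two-fluid blood-washout ("old blood") simulation, four
thrombosis metrics, and a decision rule for the occlusion position.

## Model overview

### Geometry

Patient anatomies are replaced by an idealized, parametric 2D geometry
(`geometry_spec()`): a straight parent vessel (aorta, width `D_aorta`,
default 25 mm) with a fistula of entrance diameter `D_E` branching at a
right angle, running a length `L_F` to a terminal aneurysm bulge of width
`D_MA` and length `L_A`. All shapes are axis-aligned rectangles rasterized
on a uniform Cartesian grid by cell-center membership; "volumes" are planar
areas times a 1 mm out-of-plane depth, so every metric definition carries
over dimension-agnostically. A resolution floor (at least 8 cells across
`D_E`) replaces boundary-layer meshing as the single wall-resolution knob.

An optional coronary side branch (width `D_branch`) leaves the proximal
fistula, `branch_offset` (default `2 * D_E`) below the junction, and stands
for the coronary territory that remains fed through the fistula-bearing
artery. Its placement is a structural requirement, not a free choice: with
rigid walls and an incompressible fluid a dead-end fistula carries exactly
zero net flow, so without a sacrificeable branch both occluded variants
would return identical (100%) aortic outflow shares, and with a *distal*
take-off the reserved fistula would become a through-flow path that washes
out better than the removed stub — inverting the physics the comparison is
about. The branch is tagged as parent-vessel ("rest of domain") territory,
so the fistula measure `V_F` covers the fistula proper (channel plus
aneurysm), consistent with the convention that `V_F` includes `V_A`.

The three variants differ only in the terminal segment:

* **untreated** — fistula outlet (bottom drainage segment) open;
* **aneurysm_reserved** — fistula outlet relabelled as wall (distal
  occlusion);
* **aneurysm_removed** — all cells distal of an occlusion plane just
  proximal of the branch take-off are converted to solid (proximal
  occlusion: aneurysm, neck and branch are gone).

### Inflow and outlet models

The inlet carries a parabolic velocity profile scaled to a parametric
pulsatile waveform: a half-sine systolic pulse of duration
`systolic_fraction x period` (default 0.35 x 1 s) over a diastolic plateau,
renormalized so the cycle mean is `Q_mean` and the peak-to-mean ratio is
`pulsatility` (default 3). The analyses depend on cycle-averaged and
oscillatory structure, not on the exact shape of a literature curve.

Outlets close through 0D models: a three-element Windkessel at the aortic
(and, untreated, fistula) outlet with the conventional split `R_p = 0.09
R_total`, `R_d = 0.91 R_total` and compliance 0.001 cm^5/dyne (1e-8
m^3/Pa), and a two-compliance coronary lumped-parameter network (LPN) at
coronary outlets, whose intramyocardial pressure pulse (sin^2-shaped, 16 kPa
peak, scaled 1.0/0.5 for left/right territory) squeezes the microcirculation
during systole. The coronary element split (`R_a : R_am : R_v` =
0.32 : 0.52 : 0.16 of `R_total`, `C_a` = 1e-10, `C_im` = 1e-9 m^3/Pa)
follows standard coronary-LPN practice; only the per-outlet total
resistances are study-specific inputs. All 0D states advance by backward
Euler, and a pure-0D mode (`solve_0d_flow_split()`) integrates the coupled
network alone to periodicity.

### Flow solver

Incompressible Newtonian flow (density 1055 kg/m^3, viscosity 3.5 mPa s) is
solved on a staggered (MAC) finite-volume grid: second-order central
diffusion, van Leer flux-limited second-order upwind advection, and a
pressure projection per stage of a strong-stability-preserving second-order
Runge-Kutta (Heun) step. SSP time stepping was chosen over a multistep
scheme with extrapolated advection because the extrapolation interacts
destructively with the nonlinear limiter (in our channel experiments the
multistep variant blows up after ~100 steps at advective CFL 0.6, while the
SSP pairing is the standard stable combination for limited schemes). The
time step (default 10 ms, 100 steps per cycle), the sub-iteration cap (50)
and the RMS residual tolerance (1e-5) follow common practice for transient
vascular runs.

The outlet coupling needs no fixed-point iteration: within a step the
projected outlet flux is exactly affine in the outlet pressures (the Poisson
solve is linear, with a prefactorized sparse Cholesky), and each
backward-Euler 0D model is affine `Q(P)`, so the coupled outlet pressures
solve a small linear system exactly; the configured sub-iteration loop then
verifies that the residual is below tolerance on the first pass. Mass
conservation is enforced to solver precision by the projection, and the 0D
states are initialized at the steady resistive-divider operating point of
`Q_mean` so the multi-second Windkessel RC transients do not dominate the
warm-up. The flow is declared periodic when two consecutive cycles differ
by less than 0.5% RMS in velocity, with a 10-cycle cap.

Two desk-scale substitutions are deliberate: the solver is laminar (the
fixture Reynolds number is kept at a few hundred by the choice of `Q_mean`,
instead of a turbulence model with wall functions), and the inlet profile is
parabolic. Both are documented limits of the 2D model: only flow-topology
conclusions (stagnation in occluded pouches, direction of metric changes)
are claimed transferable, never patient-level numbers.

### Washout (two-fluid stasis) model

Blood residue is quantified by a two-fluid experiment: at washout start the
whole domain is "old blood" (volume fraction `alpha = 1`) and the inlet
feeds "new blood" (`alpha = 0`). Because the two fluids share all material
properties and surface tension is zero, volume-of-fluid transport reduces
*exactly* to conservative passive-scalar advection of `alpha`; that
equivalence is the implementation contract, so no interface reconstruction
is used. `alpha` is advected through the frozen periodic flow cycle (two
identical fluids cannot alter the flow, so re-solving momentum each washout
cycle would change nothing) with the same van Leer limiter, sub-stepped so
the scalar CFL stays below 0.8. Boundedness (`alpha` in [0, 1] to 1e-6) is
asserted every step, and with inflowing `alpha = 0` the total old-blood
content is provably non-increasing.

The per-cycle record of the **old blood volume fraction**

OBVF = 100 x (sum of `alpha` over fistula cells) / (fistula measure)

is the washout history; the run stops when the OBVF dropped by less than
one absolute percentage point over the trailing 10 cycles ("dropped within
1%" read as absolute, since a relative reading diverges as OBVF approaches
zero), with a 60-cycle cap mirroring the 10-60 cycles such washouts need.
At the cap the slowest variants here (untreated side lobes, removed stub)
still drain 1-4 points per trailing window; the capped value is reported
with a warning.

### Thrombosis metrics

From the periodic cycle, wall shear stress is sampled per wall face as
`tau = mu * 2 * u_t1 / h` (the half-cell one-sided gradient, which is the
discrete wall flux consistent with the solver's ghost-reflection no-slip
and measures second-order accurate on the Poiseuille oracle), signed by a
fixed per-face tangent. The standard definitions follow:

* TAWSS = (1/T) integral |tau| dt (trapezoid on the periodic samples), with
  a low-TAWSS threshold of 10 dyne/cm^2 (1 Pa);
* OSI = 0.5 (1 - |integral tau dt| / integral |tau| dt) in [0, 0.5], high
  above 0.3;
* thresholded **area** (face measures summed) and **proportion** (% of the
  scope's wall), scoped by default to the fistula wall - the region whose
  thrombosis the analysis quantifies - with a whole-wall option;
* OBVF as above and OBV = OBVF/100 x V_F, the volumetric stasis metric;
* the cycle-averaged outlet flow split as percentages of inlet flow.

### Decision rule

`compare_treatments()` derives the relative OBV difference
`100 x (OBV_reserved - OBV_removed) / OBV_reserved` and the morphological
ratio `V_A / V_F`; `recommend_occlusion()` then applies: a difference at or
above 50% selects **proximal** occlusion directly; below it, a small
aneurysm (`V_A/V_F < 0.25`) makes **either** treatment acceptable while a
dominant aneurysm favours **distal** occlusion (its removal would sacrifice
the supply fed through the terminal segment). Both thresholds are exposed
as arguments: the 50% cutoff mirrors the clinical reasoning the rule
formalizes, and the `V_A/V_F = 0.25` default turns a qualitative morphology
tie-break into a number (representative anatomies bracket it at 0.35 and
0.03). A fistula entrance above 8 mm additionally raises an
anticoagulation-indicated flag, following the guideline that such fistulas
warrant postoperative anticoagulation.

## The standard fixture and what it shows

`standard_fixture_config()` fixes the study conditions: a representative
clinical morphology (D_E 16, L_F 130, D_MA 40, L_A 40 mm) at 2 mm spacing
with a 6 mm branch; `Q_mean` = 5e-4 m^3/s per unit depth, chosen so the
advective CFL stays below one half at the 10 ms step and the parent-vessel
Reynolds number stays laminar (~250); aortic and fistula outlets with
total resistances 2.3171e8 and 6.8721e8 Pa s/m^3; and a coronary branch
whose `R_total` = 1.0781e9 Pa s/m^3 is the parallel aggregate of the
matching coronary outlet-resistance column, so one branch stands for the
retained tree.
The full three-variant pipeline (about 1900 fluid cells per variant, 10
warm-up cycles, up to 60 washout cycles) runs in roughly two minutes on one
CPU.

On this fixture the package reproduces the directional findings: the aortic
outflow share rises strictly from untreated to aneurysm-reserved to
aneurysm-removed; the final OBVF orders untreated < removed <= reserved;
residue concentrates at the distal dead-end segment; and three of the four
thrombosis metrics (high-OSI area, OBVF, OBV) decrease after aneurysm
removal. The fourth, the *proportion* of high-OSI wall, does not decrease
here: in a 2D laminar model the oscillatory forcing penetrates only a few
entrance diameters into a dead end, so the short removed stub is entirely
oscillatory wall while the reserved variant's large, deep, quasi-steady
aneurysm wall dilutes its proportion. The proportion is normalized by
exactly the wall area that the occlusion removes — the same normalization
artefact that makes absolute metrics (area of high OSI, and especially OBV)
the more reliable discriminators, which is the central methodological point
of the analysis.

## Numerical choices and degenerate inputs

* Uniform Cartesian grid, cell-centered labels, right-angle branch: the
  simplest stencil machinery that supports every metric; no claim of
  anatomical fidelity (tortuosity and entrance angle are out of scope).
* Rasterization is by cell-center membership, so rectangle-composed
  geometries converge to their analytic areas at first order in `h` (the
  tests bound the change under 2x refinement by 2%).
* The projection uses a Dirichlet pressure at outlet faces and homogeneous
  Neumann elsewhere; with at least one outlet present the system is
  nonsingular. A fully walled domain is rejected at geometry validation
  (the untreated variant must expose a fistula outlet).
* The scalar limiter falls back to first order at boundaries and across
  wall corners; the plug-flow acceptance bound (5 OBVF points at
  mid-washout on 128 axial cells) budgets the resulting numerical
  diffusion.
* Degenerate metric inputs are defined, not errors: an all-zero shear
  series has OSI 0; an empty threshold scope returns zero area and
  proportion; OBV rejects OBVF outside [0, 100]; a comparison with
  OBV_reserved = 0 recommends "either" with a degenerate-input token.
* Pulsatility is capped at `pi / (2 x systolic_fraction)` so the diastolic
  baseline cannot go negative; `pulsatility = 1` degenerates to constant
  inflow, which the verification fixtures use.
* Everything is deterministic: no random numbers are drawn anywhere in the
  pipeline, so identical configurations reproduce byte-identical artifacts.

## What the synthetic generator does and does not emulate

The generator reproduces the *morphological parameters* of patient
anatomies (entrance diameter, fistula length, aneurysm size, the volume
ratio `V_A/V_F`) and the *topological* difference between occlusion
strategies, which is what the metrics and the decision rule consume. It
does not emulate vessel curvature or tortuosity, 3D secondary flows,
turbulence in the parent vessel, wall compliance, or non-Newtonian
rheology (the last excluded deliberately, as its influence on coronary
hemodynamic parameters is reported to be minor). Passing tests therefore
demonstrate correctness of the numerics and the direction of
occlusion-induced changes, not patient-level predictive accuracy.

## Known limitations

* 2D unit-depth "volumes" and laminar desk-scale flow: absolute metric
  values are not comparable to 3D patient simulations; only orderings and
  ratios are meaningful.
* The stasis model captures one element of Virchow's triad; it does not
  model clot formation kinetics, platelets or coagulation chemistry.
* The coronary LPN element split and intramyocardial waveform are
  literature-standard conventions, not patient data; flow splits are
  dominated by the prescribed total resistances.
* The washout cap can truncate slowly draining variants; the reported
  capped OBVF is then an upper bound on the converged value.
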