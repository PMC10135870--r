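---
title: "Methods: digital DCE perfusion phantoms and tracer-kinetic inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: digital DCE perfusion phantoms and tracer-kinetic inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dcephantom)
```

`dcephantom` builds an end-to-end, fully synthetic benchmark for dynamic
contrast-enhanced (DCE) perfusion imaging: it constructs a microvascular
network with known architecture, simulates the spread of a contrast-agent
bolus through it, renders the result as a voxelized image series, and then
asks how much of the known truth standard tracer-kinetic (TK) models can
recover from that series. This vignette documents the model, the numerical
choices, and the limits of what the synthetic data can show.

## 1. Vascular architecture

**Lattice embedding.** The tissue is a regular lattice of cubic voxels of
side $l = 60\,\mu m$; vessel nodes sit at voxel centres and vessels are
axis-aligned cylinders of length $l$. The spacing is of the order of the
oxygen diffusion distance, i.e. the typical inter-capillary distance, and
it bounds the largest representable vessel: radii are capped at $l/2$.

**Tree growth.** Arterial and venous trees grow from root sites by
directed branching walkers: active tips advance one site per sweep in a
persistent direction, turn when blocked, and branch sideways with
probability `p_branch` (default 0.1). We chose this rule over plain
stochastic (Eden-type) surface growth after observing that compact growth
segregates the two trees into disjoint territories, leaving almost no
arterial/venous tip pairs within capillary-connection range; thin
persistent branches interdigitate, which is also the morphology real
arterioles and venules exhibit. The growth rule is isolated behind
`grow_trees()` and can be swapped. Each tree stops at a target occupancy
(default 0.4 of the lattice sites).

**Capillary connection and remodeling.** Terminal or pass-through tree
segments of opposite trees that are axis neighbours (directly, or through
one free intermediate site) are joined by capillaries of radius
$r_{cap} = 4\,\mu m$ with the region's sprouting probability and
multiplicity: normal tissue $p^{spr} = 0.5, n = 1$; tumor rim
$p^{spr} = 1, n = 10$; necrotic core $p^{spr} = 0.1, n = 10$. A
multiplicity-$n$ edge stands for $n$ parallel vessels and contributes
$n\times$ conductance, surface, volume, and $n$ children in the radius
recursion. Remodeling then iterates (default 30 rounds): sprout, assign
radii, solve flow, and remove each capillary with the shear-dependent
degeneration probability — the linear ramp
$(\tau_{max}-\tau)/(\tau_{max}-\tau_{min})$ clamped to $[0,1]$, divided by
10 in the tumor (growth-factor-stabilized vessels), multiplied by 10 in
the necrotic core. The shear bounds default to the 10th/90th percentiles
of the current flowing-capillary wall shear stress; fixed bounds can be
configured. The percentile rule keeps the ramp informative at any pressure
scale, which matters because the true bounds are not identifiable from
published data.

After the final round every zero-flow edge — dead-end capillary or
non-functional tree branch — is pruned. Two reasons: a resistive network
carries flow on an edge exactly when that edge lies on a root-to-root
pressure path, so zero-flow edges are precisely the non-functional part;
and retaining them would put plasma volume into voxels the contrast agent
can never reach, biasing the ground-truth maps against anything an imaging
method could in principle see. The final phantom is a fully perfused
network with zero plasma volume where all vessels degenerated (notably the
necrotic core).

**Radii.** Capillaries keep $r_{cap}$; tree radii follow the branching
power law $r_p^{\alpha} = \sum_c n_c r_c^{\alpha}$ from the capillaries up
to the roots, with $\alpha^{art} = 3$ and $\alpha^{ven} = 2.7$. On an
idealized tree this makes flow scale as $d^{\alpha}$ with diameter, which
the test suite verifies on a constructed hierarchical "comb" network; on
stochastic networks large vessels carry disproportionately more flow, so
wall shear stress and velocity increase with diameter, as observed in
microvascular measurements.

## 2. Hemodynamics

Each edge is a Poiseuille resistor, $g = n \pi r^4 / (8 \mu l)$ with
constant effective viscosity $\mu = 4\times10^{-3}$ Pa s (no
Fåhræus–Lindqvist correction; the system stays linear). Node pressures
solve the sparse Kirchhoff system with Dirichlet pressures at the roots.
Per parallel vessel, $v = |f|/(n\pi r^2)$ and
$\tau = 4\mu|f|/(n\pi r^3)$.

`boundary_conditions()` defaults to the physiological arteriole/venule
range (60/15 mmHg). The benchmark presets instead use a 1000 Pa drop,
calibrated so that the bolus reaches a region of interest with a delay of
a few seconds — resolvable at the 1 s frame interval — while the ROI
curves remain mildly dispersed copies of the input function. With a
physiological drop across this small (6 mm) domain, transit is
near-instant and the delay-based flow recovery degenerates; the published
boundary values for this class of phantom are not available, so the drop
is set by the observable dynamics rather than by pressure realism. Only
the drop matters for the linear solve.

## 3. Contrast-agent transport

The plasma concentration $c_P$ obeys advection along the directed edge
fluxes with exchange $-k_{PS}(c_P - c_I)/\phi_P$; the interstitial
concentration $c_I$ obeys lattice diffusion with effective coefficient
$\phi_I D_I$ ($D_I = 10^3\,\mu m^2/s$), no-flux domain boundaries, and the
mirrored exchange source. The arterial input function (AIF) is imposed at
the arterial roots; venous roots are free outflow.

The AIF is the standard patient-derived population form — two Gaussian
bolus passes plus a sigmoid-gated exponential washout — with the published
population parameters (converted to seconds). Its raw peak is about
6 mM; presets use the raw curve, which puts the ROI peak concentrations
(roughly $\phi_P \times 6$ mM, i.e. 0.4–1 mM for typical plasma
fractions) on the scale clinical DCE measurements report. Peak normalization (`peak_mM`) is available; all fits are invariant
to the scale.

**Discretization.** Operator-split first-order stepping: explicit
first-order upwind advection under a CFL bound (safety factor 0.9),
then the plasma–interstitium exchange solved implicitly per voxel (an
exact $2\times2$ linear update, unconditionally stable — needed for the
high-permeability regime $P = 100\,\mu m/s$), then implicit diffusion via
a pre-factorized sparse Cholesky. The step is the CFL-admissible step
capped at 0.1 s; frames are stored on the acquisition grid. Upwinding
keeps concentrations in $[0, \max c_A]$; the implicit stages conserve
tracer exactly, so the global balance (injected = stored + outflowed)
closes to round-off, and the only discretization error is advective
smearing, first-order in the step (verified against the 1d traveling
wave $c_P(x,t) = c_A(t - x\,\phi_P L^2/F)$). Arterial root nodes are
boundary conditions, not tissue: they do not exchange with the
interstitium, which keeps the mass bookkeeping closed.

Voxels with $\phi_P = 0$ carry $c_P = 0$ by convention and skip advection
and exchange.

## 4. Image synthesis

Ground truth per voxel: $\phi_{P,i} = \pi/(2l^2)\sum_j n_{ij} r_{ij}^2$
(each edge contributes half its volume to each endpoint; an overfull voxel
is an error, not a clip), $\phi_I = 1-\phi_P$, $F_i$ = sum of entering
fluxes, $K_{PS,i} = \sum_j n_{ij} P \pi l r_{ij}$. The image signal is
taken directly as the total concentration
$c_i = \phi_{P,i} c_{P,i} + \phi_{I,i} c_{I,i}$ — no MR/CT signal physics.
ROI measurements are unweighted voxel means; ROI ground truth uses the
volume-weighted mean for $\phi_P$ (a plain sum of fractions would exceed 1
for any large ROI and cannot be the tabulated quantity), the extensive sum
for $K_{PS}$, and boundary-crossing influx for $F$ (interior fluxes
cancel; arterial roots inside the ROI count their external feed).
Measurement noise is multiplicative Gaussian, $c(1 + \sigma\eta)$, clipped
at zero, matching the "relative noise level" convention; additive noise is
available.

The standard measurement region is the 709-voxel circular ROI (radius 15
voxels ≈ 2 mm diameter); coarse acquisition is emulated by
$300\times300\times3000\,\mu m$ block ROIs (200 of them on the 3d preset).

## 5. Tracer-kinetic inference

Both models impose $\phi_I = 1 - \phi_P$ and are fitted by box-bounded
Levenberg–Marquardt (`minpack.lm`), 100-iteration cap, minimizing the
quadratic error on the acquisition grid. The AIF used in fitting is the
same closed form as in the simulation; no AIF re-estimation.

* **Brix II (2CXM)**: $\beta = (\phi_P, F, K_{PS})$, implicit-Euler
  integration of the two-compartment exchange system on the measurement
  grid (substeps configurable; degenerate $\phi_P \in \{0, 1\}$ handled by
  compartment elimination).
* **DE-Tofts**: $\beta = (\phi_P, K^{trans}V, t_0)$, blood pool plus
  exponential-kernel leakage, evaluated by the recursive trapezoidal
  convolution of the continuously interpolated, $t_0$-shifted AIF — the
  delay is continuous, not grid-quantized, because sub-frame delays carry
  the flow information at voxel scale.

Initialization: $\phi_P$ starts at the curve/AIF peak ratio (the blood
pool dominates the first pass, and this anchor prevents the
leakage-dominated regime from collapsing $\phi_P$ to zero), $F/V = 0.01$
s$^{-1}$, $K_{PS}/V = 10^{-3}$ s$^{-1}$, $t_0 = 5$ s; optional
multi-start. Bounds $\phi_P \in [0,1]$, rates $\ge 0$,
$t_0 \in [0, T]$. An all-zero curve is flagged, not fitted.

**Flow recovery and rescaling.** Both models feed the ROI directly from
the AIF, so the recovered flow absorbs the bolus travel delay:
$F_{recov} \approx F/N_i$ with $N_i$ the distance to the feeding point in
voxel widths. `rescale_flow()` multiplies by
$N_i = \max(1, \|x - x_{feed}\|/l)$ (Euclidean; a graph-distance variant
would be the natural refinement; the Euclidean work-around is the
definition used throughout the package). For DE-Tofts, $F_{recov} = \phi_P V / t_0$, with
$t_0 = 0$ flagged as not rescalable.

## 6. Problem sizes and frozen protocol choices

The test suite and acceptance script run at these sizes, chosen to
exercise every pathway at full fidelity where it is cheap and at reduced
scale where it is not:

* 1d tube: 100 voxels (6 mm), flow $10^4\,\mu m^3/s$ (capillary velocity
  ≈ 200 µm/s, bolus transit ≈ 30 s), the full protocol including a
  100-replicate noise study;
* traveling-wave convergence at $l = 60, 30\,\mu m$;
* the 2d benchmark at its native $100\times100$ voxels, one frozen
  realization (seed 11) for the four-zone ROI protocol; the four
  709-voxel zones (one containing the tumor, three normal) were placed
  once where the ground-truth $\phi_P$ and $F$ are separated by at least
  ~25 %, so that rank comparisons are meaningful, and then frozen;
* the enhancement-signature comparison on a $60\times60$ slab;
* the 3d presets are exercised geometrically (voxel and ROI counts); a
  full 3d transport-plus-$2.5\times10^5$-fit run is supported but not part
  of the default suite.

## 7. What the synthetic data do and do not show

The phantom reproduces the structural hallmarks it targets —
hypervascular rim with order-of-magnitude elevated plasma fraction,
avascular necrotic core crossed by surviving large vessels, early rim
enhancement for high microvascular density versus late diffuse
enhancement for high permeability — and gives exact ground truth for
$\phi_P$, $F$, $K_{PS}$. Passing tests therefore show that the inference
machinery behaves as claimed *under the model's own physics*: advection,
wall exchange, interstitial diffusion, and a shared, exactly-known AIF.

They do not show robustness to anything the model omits: MR signal
nonlinearity and noise correlations, AIF measurement error, hematocrit
and non-Newtonian rheology, pulsatility, interstitial filtration and
lymphatics, intracellular uptake, off-lattice vessel geometry, or tumors
larger than a few millimetres (the lattice constant bounds vessel
diameter, so the domain must stay small). The maximum MVD multiplicity is
also bounded by voxel packing: at $n \gtrsim 30$ a voxel's vessel volume
can exceed the voxel, which the package treats as an error.

## 8. Numerical edge cases

* Degenerate geometry: a zero tumor radius labels everything normal; a
  core radius equal to the tumor radius leaves no rim.
* Equal root pressures give a valid all-zero flow; a component with no
  root is an error listing the offending nodes.
* CFL steps below `dt_floor` abort (they indicate an unreasonable
  flow/geometry combination rather than a meaningful simulation).
* Negative concentrations beyond round-off abort — they would indicate a
  scheme bug, not data.
* Fits on curves with no signal are flagged; per-voxel fit errors are
  recorded per voxel and never abort a map run.
* All stochastic stages take explicit seeds and restore the caller's RNG
  state; identical configuration and seed reproduce every output
  bit-for-bit.
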