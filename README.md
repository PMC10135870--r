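# dcephantom

Digital perfusion phantoms for dynamic contrast-enhanced (DCE) imaging:
synthetic tumor-bearing microvascular networks, simulated contrast-agent
bolus transport, and inverse tracer-kinetic (TK) fitting with known ground
truth.

## The problem

DCE imaging estimates tissue perfusion by fitting low-dimensional
tracer-kinetic models — here the **Brix II / two-compartment exchange model
(2CXM)** and the **delay-extended Tofts model (DE-Tofts)** — to the
contrast-agent concentration curve of each voxel or region of interest
(ROI). How well the fitted parameters (plasma volume fraction φ_P, flow F,
plasma–interstitium exchange rate K_PS) reflect the true microvascular
state of the tissue is hard to validate in vivo, because the microscopic
truth is inaccessible. `dcephantom` builds that truth in silico:

1. **Vasculature** — interpenetrating arterial and venous trees are grown
   on a regular lattice (voxels of (60 µm)³), connected by capillaries
   under region-specific sprouting/degeneration rules (normal tissue,
   hypervascular tumor rim with `n` parallel capillaries, degraded necrotic
   core), with vessel radii set by the branching power law
   r_p^α = Σ n·r_c^α (α_art = 3, α_ven = 2.7).
2. **Hemodynamics** — steady Poiseuille flow `g = nπr⁴/(8µl)` on the
   network graph; wall shear stress drives capillary degeneration during
   remodeling.
3. **Transport** — the bolus (population arterial input function) is
   advected along the vessels, exchanges through the wall at rate
   K_PS = Σ n·P·π·l·r (permeability P times half the vessel surface), and
   diffuses in the interstitium with effective coefficient φ_I·D_I.
4. **Image synthesis** — per-voxel ground-truth maps
   φ_P = π/(2l²)·Σ n r², φ_I = 1 − φ_P, F = Σ entering fluxes, K_PS, and
   the DCE series c(t) = φ_P c_P + φ_I c_I sampled every Δt.
5. **Inference** — Levenberg–Marquardt fits of both TK models
   (box-bounded, 100-iteration cap, φ_I = 1 − φ_P imposed), recovered-flow
   rescaling by the voxel's distance to the feeding artery in voxel widths
   (N_i), and error/ranking tables against the ground truth.

The central quantitative behaviour the package demonstrates is the
**distance-rescaling law**: a TK model that feeds every voxel directly from
the AIF underestimates flow by the travel delay, F_recov ≈ F/N_i, and
multiplying by N_i recovers the true flow (exact in the 1d benchmark,
where the intravascular concentration is the traveling wave
c_P(x,t) = c_A(t − x·φ_P·L²/F)).

## Worked example: the 1d tube benchmark

A 6 mm straight capillary (radius 4 µm) in a 60 µm × 60 µm tissue cuboid,
flow 10⁴ µm³/s, intravascular agent:

```r
library(dcephantom)
aif <- aif_population()                     # population AIF, peak ~6 mM
res <- run_benchmark("tube1d", seed = 1, aif = aif, fit = "none")

res$maps$phi_P[50, 1, 1]
#> [1] 0.01396263                            # pi r^2 / L^2, i.e. ~0.014

# fit the DE-Tofts model to the voxel 50 lattice steps from the inlet
ser <- res$series
fit <- fit_tk("detofts", ser$times, ser$c[51, ], aif, V = 216000)
fit$par
#>      phi_P     KtransV          t0
#> 0.01335848  0.49980136 15.04427658        # delay t0 = N phi_P V / F ~ 15.1 s

# the raw recovered flow underestimates F = 1e4 by ~N; rescaling fixes it
fit$F_recov
#> [1] 191.796                               # ~ F / 50
as.numeric(rescale_flow(fit$F_recov, c(50.5 * 60, 30, 30), c(30, 30, 30), 60))
#> [1] 9589.802                              # within ~4 % of the true 1e4
```

The numbers printed above are what the code produces at seed 1: the
plasma volume fraction is recovered within a few percent, the fitted
delay matches the advective travel time, and the distance-rescaled flow
is within 10 % of truth.

2d/3d tumor phantoms are run the same way
(`run_benchmark("grid2d", ...)`, `"quasi3d"`, `"block3d"`, `"coarse3d"`);
`sweep_benchmark()` repeats a run across, e.g., permeabilities
P ∈ {0, 0.01, 0.1, 1} µm/s. A thin command-line wrapper is installed as
`exec/dcephantom` (`dcephantom benchmark --preset tube1d --out runs/t1`).

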