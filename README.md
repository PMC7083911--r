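# ebnstrack

Quantitative analysis of near-infrared (NIR) fluorescent **Egyptian Blue
nanosheets** (EB-NS, exfoliated CaCuSi₄O₁₀) for single-particle imaging:
how many Cu²⁺ luminescent centers a particle carries, how big it is, and
whether its motion in a living sample is purely thermal.

It is written for microscopists and biophysicists who track nanoscale NIR
emitters: people fitting saturation curves from photon-counting
experiments, sizing particles from their Brownian motion in viscous media,
or running passive microrheology inside embryos.

## What it computes

**Photon budget.** Emission vs excitation power follows the saturation law
*I(P) = I_sat · P / (P + P_sat)*. Detected rates are divided by the
detection-efficiency chain (collection × optics × detector QE, default
0.70 × 0.50 × 0.05 = 0.0175) so the fitted *I_sat* is the emitted rate,
and the center count follows from the excited-state lifetime τ (100 µs)
and quantum yield Φ (0.1):

> N = I_sat · τ / Φ,  square monolayer side = √(N / 3.8 nm⁻²)

**Brownian sizing.** Spots are detected (band-pass + centroid refinement,
blob diameter 11 px) and linked (greedy nearest neighbour, search range
9 px, memory 300 frames); the time-averaged MSD is fitted as
*MSD = 4Dτ* up to 25 s, and the Stokes–Einstein radius
*R = k_B T / (6πηD)* is multiplied by the spheroid anisotropy factor
*A = 1.49* to give the hydrodynamic radius. Brightness (max trajectory
"mass") vs diameter is fitted as a power law in log–log space with a
bootstrap CI.

**Van Hove microrheology.** Per-axis displacements at lag 0.1 s are pooled
into a symmetric histogram; a Gaussian is fitted to the central
[−0.03, +0.03] µm window; probability mass in the tails beyond the
Gaussian's prediction ("tail excess") flags active, non-thermal transport.
Displacements are also partitioned by distance to the nearest nucleus
border.

**Synthetic data.** Seeded generators for nanosheet populations
(20–300 nm diameters, ~1 nm monolayer quantisation, 3.8 Cu²⁺ nm⁻²),
Brownian/active trajectories, diffraction-limited 16-bit TIFF movies with
exact ground truth, shot-noised saturation sweeps, and hexagonal nucleus
maps — every analysis is validated against these.

## Worked example

```r
library(ebnstrack)

# photon budget of the two measured bounds of the saturation emission rate
count_luminescent_centers(122e3,  lifetime_s = 100e-6, quantum_yield = 0.1)
count_luminescent_centers(1250e3, lifetime_s = 100e-6, quantum_yield = 0.1)
```

```
<EmitterEstimate: N = 122 centers (tau = 0.0001 s, Phi = 0.1); square monolayer side 5.67 nm (~6 nm)>
<EmitterEstimate: N = 1250 centers (tau = 0.0001 s, Phi = 0.1); square monolayer side 18.1 nm (~18 nm)>
```

A particle emitting 122×10³ photons/s at saturation therefore contains
~122 emitting Cu²⁺ ions — the size of a ~6 nm square monolayer sheet; the
brightest measured particles (1250×10³ photons/s) correspond to ~18 nm.

```r
# simulate a shot-noised power sweep through the real efficiency chain,
# refit it, and recover the emitter count
sw  <- simulate_saturation_sweep(5e5, 200, c(1, 2, 5, 10, 20, 50, 75, 100,
                                             150, 200, 350, 500),
                                 efficiency = detection_efficiency(), seed = 7)
fit <- fit_saturation(sw)
round(c(I_sat = fit$I_sat_per_s, P_sat = fit$P_sat_uW))
#>  I_sat  P_sat
#> 512965    206
count_luminescent_centers(fit)$N_centers   # truth: 500
#> [1] 512.9646
```

End-to-end scenario drivers live under `analysis/` (they write their
tables to `results/`):

```sh
Rscript analysis/01_sheet_population.R   # synthetic nanosheet cohort
Rscript analysis/02_photon_budget.R      # saturation fits -> center counts
Rscript analysis/03_glycerol_sizing.R    # movie -> tracking -> sizes -> scaling
Rscript analysis/04_embryo_vanhove.R     # Van Hove + nucleus proximity
```

e.g. stage 4 prints, for a thermal control and a 5% burst-active cohort:

```
thermal control: sigma = 0.0143 um, tail excess = 0.0015, active = FALSE
burst-active:    sigma = 0.0145 um, tail excess = 0.025, active = TRUE
```

— the Gaussian core (thermal motion, σ² = 2Dτ) is unchanged, while the
burst admixture puts ~2.5% of probability mass into tails the Gaussian
cannot explain, which is exactly the signature used to detect active
processes in vivo.

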