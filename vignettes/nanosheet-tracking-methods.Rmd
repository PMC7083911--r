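---
title: "Methods: photon budgets, Brownian sizing and Van Hove analysis of NIR nanosheets"
author: "ebnstrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: photon budgets, Brownian sizing and Van Hove analysis of NIR nanosheets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebnstrack)
```

# Scope

`ebnstrack` implements the quantitative analysis chain for near-infrared
(NIR) fluorescent Egyptian Blue nanosheets (EB-NS, exfoliated
CaCuSi~4~O~10~): every Cu^2+^ ion in the silicate lattice is a potential
NIR emitter at ~910 nm, so a nanosheet's brightness should track its size.
The package covers three linked analyses plus the synthetic data needed to
validate them end to end:

1. **Photon budget** — fit single-particle saturation curves, normalise
   detected to emitted photon rates, count luminescent centers.
2. **Brownian sizing** — detect and link diffraction-limited spots, compute
   mean-square displacements (MSD), convert diffusion coefficients to
   anisotropy-corrected hydrodynamic radii, and correlate size with
   brightness.
3. **In-vivo microrheology** — instantaneous velocities, nucleus-proximity
   partitioning, Van Hove displacement histograms with Gaussian-core fits
   and non-Gaussian tail detection.

No measurement data ship with the package; all validation inputs are
produced by seeded generators with known ground truth, and real data enter
through the CSV/TIFF readers.

# Models

## Fluorescence saturation and the center count

Emission under increasing excitation power $P$ follows the two-level
saturation law

$$ I(P) = I_{\mathrm{sat}} \frac{P}{P + P_{\mathrm{sat}}}, $$

where $I_{\mathrm{sat}}$ is the emitted photon rate at saturation and
$P_{\mathrm{sat}}$ the half-saturation power. Detected count rates are
divided by the overall detection efficiency **before** fitting — the
product of objective collection (default 0.70 for randomly oriented
dipoles), optical transmissivity (0.50) and detector quantum efficiency
(0.05; overall 0.0175) — so the fitted amplitude is always the *emitted*
rate. Division before or after fitting is equivalent by linearity; fitting
the emitted rate keeps `SaturationFit$I_sat_per_s` physically
interpretable.

With an excited-state lifetime $\tau$ (default $100\,\mu s$) and quantum
yield $\Phi$ (default 0.1 — the commonly used approximation of the bulk
value 0.105; `quantum_yield` is a free argument if the finer value is
preferred), a single center cannot emit faster than $\Phi/\tau$, so

$$ N = \frac{I_{\mathrm{sat}}}{\Phi\,\tau^{-1}} $$

counts the independently emitting Cu^2+^ centers. For the monolayer-size
equivalent the package assumes a **square** single-layer sheet with an
areal center density $\sigma_{\mathrm{Cu}} = 3.8\ \mathrm{nm^{-2}}$, giving
a side $\sqrt{N/\sigma_{\mathrm{Cu}}}$ (reported unrounded and rounded to
the nearest nm). Note the deliberate asymmetry in shape conventions: the
*population generator* models sheet area as a **disc** of the stated
diameter (the natural reading of a "diameter"), while the *photophysics
back-calculation* uses a square. Both are stated here because neither
convention is derivable from the other; they differ by a factor
$\pi/4$ in area.

Saturation fitting uses Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`) with initial values $I_{\mathrm{sat}}^0 = 2\max I$,
$P_{\mathrm{sat}}^0 = \mathrm{median}(P)$ and relative tolerance
$10^{-10}$. Up- and down-sweep points are pooled in one fit; a hysteresis
diagnostic (maximum |up − down| rate difference at matched powers) is
reported because power is stepped both ways in the measurement protocol,
and `plateau_reached` records whether the maximum power exceeded the
fitted $P_{\mathrm{sat}}$ — in the real experiment the plateau was not
reachable, which the flag makes explicit.

## MSD, Stokes–Einstein and the spheroid correction

For a 2-D trajectory sampled at uniform interval, the default MSD
estimator is the overlapping time average at integer lag $k$:

$$ \mathrm{MSD}(k\,\Delta t) = \frac{1}{N-k} \sum_{i=1}^{N-k}
   \left[ (x_{i+k}-x_i)^2 + (y_{i+k}-y_i)^2 \right]. $$

The classical single-step definition (mean of consecutive-step square
displacements only) is available as `estimator = "single_step"`; it yields
one value at the frame interval and cannot produce the lag-resolved curve
needed for a 25 s fit window, which is why the overlapping estimator is
the default.

The diffusion coefficient comes from weighted least squares of
$\mathrm{MSD} = 4 D \tau$ over lags $\le$ 25 s with weights equal to the
pair count per lag; the through-origin fit is the default, and an optional
intercept absorbs the static localisation-noise offset $4\sigma_{loc}^2$.
A negative fitted $D$ (possible on short noisy tracks) is clipped to zero,
flagged, and such particles are excluded from the size–brightness table
with a logged reason.

The sphere-equivalent Stokes radius is
$R = k_B T / (6 \pi \eta D)$ with $k_B = 1.380649\times10^{-23}$ J/K, and
the hydrodynamic radius of a disc-like spheroid is $R_h = A \cdot R$ with
$A = 1.49$ by default. The value 1.49 is treated as a given constant for
thin nanosheets (its spheroid derivation is not reproduced here); a
clearly auxiliary Perrin oblate-spheroid friction calculator
(`perrin_oblate_friction()`) is provided for exploration but is **not**
used to derive it. Because it is ambiguous whether a size–brightness plot
axis carries radius or diameter, the table stores `R_stokes_nm`,
`R_hydro_nm` and `d_hydro_nm` side by side.

Solvent viscosity for glycerol–water mixtures uses the Cheng (2008)
temperature–composition correlation, cross-checked in the tests against
standard water (1.002 mPa s at 20 °C) and glycerol (≈1.41 Pa s at 20 °C)
table values; the experimentally measured viscosity can always be passed
directly.

## Tracking

Spot detection band-pass filters each frame (Gaussian noise smoothing,
$\sigma = 1$ px, minus a boxcar background over the blob diameter), takes
local maxima above a percentile threshold (default 64, configurable;
minimum mass defaults to 0 because the measurement protocol states none),
and refines each candidate by iterated intensity centroiding within the
circular blob window (default diameter 11 px). Mass is the
background-subtracted raw-intensity sum over the window, using the frame
median as the background estimate — on synthetic ground truth this
reproduces the analytic Gaussian flux $2\pi A \sigma^2$ to within the
~4–5% truncation of the circular window.

Linking is greedy global nearest-neighbour per frame pair: candidate
(track, spot) pairs within the search range (default 9 px) are sorted by
squared displacement with ties broken by the spot's $(x, y)$ lexicographic
order and then track id, which makes the assignment deterministic and
permutation-invariant. Identities persist through detection gaps up to
`memory_frames` (default 300); trajectories shorter than `min_length`
(default 300 points for glycerol movies, 200 for embryo recordings) are
discarded. This is adequate at the sparse particle densities of the
emulated experiments (a handful of spots per field); crossing-trajectory
disambiguation is explicitly out of scope. 2×2 sum binning of large
recordings is offered as an explicit pre-processing option (`bin2x2()`),
not silently assumed.

The particle's fluorescence intensity is the **maximum** mass along its
trajectory, which is robust against transient out-of-focus excursions and
rotations of a flat particle.

## Van Hove analysis

Displacements at one lag (default 0.1 s) are pooled **per axis** ($x$ and
$y$ together) across trajectories — histograms of this kind span negative
and positive values, which a vector-magnitude pooling could not produce.
The probability histogram uses symmetric bins of width 0.005 µm (default;
the experimental bin width is not documented, so this is configurable) and
a Gaussian $p(x) = a\,e^{-x^2/2\sigma^2}$ is fitted by unweighted least
squares to the bins inside the central window (default
$[-0.03, +0.03]\ \mu m$) — a fit on binned heights, matching how such fits
are overlaid on histograms; a maximum-likelihood alternative was
considered and rejected because the tails would then dominate exactly the
region the fit must ignore.

Thermal motion predicts $\sigma^2 = 2 D \tau$ and zero excess kurtosis;
active, motor-driven transport fattens the tails. The `tail_excess` is
defined as the observed probability mass outside the window minus the
fitted Gaussian's prediction there, floored at zero, and the
`active_processes_detected` flag fires when it exceeds a threshold —
by default 3× its bootstrap standard error (200 seeded resamples), an
absolute threshold being accepted as well. Nucleus-proximity partitioning
assigns each displacement by its **starting** point's unsigned distance to
the nearest nucleus border (points inside a nucleus get their distance to
the border, not zero); the near/far threshold defaults to the median
distance over all displacement start points because no threshold is
documented, and it is always reported in the output. The group comparison
reports a Wilcoxon rank-sum test on displacement magnitudes plus the
near/far variance ratio, and is marked underpowered when a group has
fewer than 50 displacements rather than being silently computed.

# Synthetic data: what it emulates and what it does not

The generators reproduce the *statistical structure* of the measurements:

* **Sheet populations** — log-uniform diameters over 20–300 nm, heights
  linear in diameter (slope 13/300 by default, so the default range maps
  onto the observed ~1–13 nm height band) with lognormal scatter,
  quantised to whole ~1 nm monolayers; Cu^2+^ counts from the 3.8 nm^−2^
  areal density over a disc times the layer count; brightness a power law
  of diameter (default exponent 0.5) with multiplicative lognormal noise.
* **Trajectories** — Gaussian increments of per-axis variance
  $2 D \Delta t$ (8 fps × 1000 frames for the glycerol scenario, 10 fps ×
  60 s for the embryo scenario), additive i.i.d. localisation noise, and
  optionally sparse "active" bursts: with a per-step rate, an extra
  Laplace-distributed displacement of configurable scale is added to each
  axis. The Laplace choice is a package decision — no generative model of
  active motion is documented, only its heavy-tailed Van Hove signature,
  which any sparse heavy-tailed admixture reproduces.
* **Movies** — spots rendered as integrated symmetric Gaussians (exact
  per-pixel erf integrals, so the noise-free intensity budget closes to
  0.1%), constant background, optional Poisson or Gaussian noise, 16-bit
  multi-page TIFF output with a JSON sidecar. Positions falling outside
  the frame are recorded in a `clipped` table, never silently dropped.
* **Nucleus maps** — ≥24-gon circles on a jittered hexagonal grid,
  regenerated (bounded retries) on overlap, emulating the regular nuclear
  array under the syncytial blastoderm membrane.
* **Saturation sweeps** — the saturation law scaled by the efficiency
  chain and integration time with Poisson shot noise, swept up then down.

Not emulated: PSF aberrations and depth-dependent defocus, rotational
diffusion of flat sheets (the out-of-focus/rotation brightness flicker
that motivates the max-mass rule), camera fixed-pattern noise, sample
drift, hydrodynamic wall effects, and 3-D motion. Passing tests therefore
demonstrate the correctness of the *estimators* under the stated
generative assumptions, not robustness to every real-data artifact.

All lengths are stored in µm and times in s internally; pixel units occur
only at I/O boundaries. Every generator takes an explicit seed and
restores the caller's RNG state, and identical seeds give bit-identical
outputs.

# Numerical choices and degenerate inputs

* Linking ties broken lexicographically; new tracks opened in $(x, y)$
  order — determinism over optimality at these densities.
* MSD requires uniform sampling and signals otherwise (no silent
  resampling); an all-zero MSD yields $D = 0$ flagged degenerate;
  $\eta = \infty$ is the explicit frozen-particle limit.
* The Gaussian-core fit requires ≥3 bins in the window and signals
  otherwise; histogram edges are exactly symmetric about zero so that the
  analysis is invariant under displacement reflection.
* A perfectly flat bleaching trace makes the exponential fit's gradient
  singular; the code falls back to the (then exact) log-linear fit. A
  decay rate whose 95% CI covers zero — or whose implied loss over the
  trace is below numerical precision — is classified "no detectable
  bleaching".
* File writes are atomic (write to a temp file in the target directory,
  then rename).
* The camera pixel size of the 100× NIR setup is not documented anywhere;
  it is a required configuration input with no derivable default
  (`pixel_size_um = 0.1` is used for synthetic scenarios only).

# Validation problem sizes

The test-suite and acceptance checks run at desk scale, chosen to keep the
whole suite under a minute while leaving comfortable statistical margins:
step-variance and Van Hove checks at $10^5$ samples; sizing recovery at
200 trajectories per radius in {25, 50, 100, 200} nm under the glycerol
protocol (1000 frames, 8 fps, 25 s window); saturation recovery over 100
shot-noised replicates; burst-detection over 20 seeded replicates; MSD
oracle equivalence over 100 random tracks against a brute-force double
loop at $10^{-10}$ relative tolerance.

One deliberate deviation from the acquisition protocol: the power-law
*exponent* cohorts use 3000-frame recordings. With 1000-frame recordings
the per-particle size estimate carries ~45% log-scale noise, and
regression of log-brightness on a noisy log-diameter attenuates the slope
(errors-in-variables) from 0.5 to ≈0.4 — an estimator-independent
statistical effect that any cohort of this design would share, including a
real one. Longer recordings shrink the size noise so that the check
isolates what it is meant to test, the imposed 20% brightness scatter.
The radius-recovery check itself keeps the exact 1000-frame protocol.

# Known limitations

* The greedy linker does not resolve crossing trajectories; it is not a
  general-purpose tracker.
* The anisotropy factor 1.49 is a constant, valid for the disc-like
  aspect ratios it was derived for; strongly prolate particles need a
  different correction (see `perrin_oblate_friction()` for intuition).
* The detected-mass scale depends on the PSF window truncation (~4–5% at
  the defaults); absolute brightness comparisons across different blob
  diameters require recalibration.
* Log–log power-law fits on tracked sizes are attenuated by
  errors-in-variables when per-particle size noise is comparable to the
  cohort's size spread (see above); exponents from short recordings are
  lower bounds.
* The embryo scenario models nuclei as static obstacles for distance
  computation only; no hydrodynamic or steric interaction with the
  walkers is simulated.
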