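---
title: "Membrane mechanics from bilayer trajectories: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane mechanics from bilayer trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memmech)
```

## Scope and model

`memmech` analyzes planar, two-leaflet lipid-bilayer trajectories with an
orthorhombic box whose z axis is the membrane normal. It answers one
scientific question: how does bilayer composition change mechanical
softness, and through which structural channels? The observables are

* **geometry** — area per lipid (APL), phosphorus–phosphorus thickness, and
  a surface-unevenness statistic;
* **elasticity** — the area compressibility modulus $K_A$ from a series of
  simulations at imposed surface tensions, with a two-sample $t$ comparison
  between systems;
* **ordering** — per-carbon acyl-tail order parameters, relative-order
  profiles, and terminal-methyl (TMG) vertical distributions;
* **dynamics** — lateral self-diffusion from mean squared displacements and
  a Kolmogorov–Smirnov check for anomalous diffusion;
* **lateral organization** — periodic Voronoi cell areas, the mixed-contact
  fraction $f_{mix}$, and neighbor-composition tables.

Units are fixed package-wide (`mm_units()`): angstrom, ps, bar, mN/m, and
$10^{-9}\,\mathrm{cm^2/s}$ for diffusivities. All unit conversions live in
one table because silent unit drift — especially in the
pressure-tensor-to-tension route — is the dominant failure mode of this
kind of pipeline.

## Estimators

### Surface tension and $K_A$

With the normal pressure $P_{zz}$ held fixed, the instantaneous surface
tension of a frame is
$\gamma = L_z\,[P_{zz} - (P_{xx}+P_{yy})/2]$, converted at
$1\,\mathrm{bar\,\mathring{A}} = 0.01\,\mathrm{mN/m}$.

$K_A$ is the derivative of tension with respect to area strain
$\epsilon_A = (A - A_0)/A_0$, where $A_0$ is the APL of the tensionless
run. `fit_area_compressibility()` therefore (a) takes $A_0$ from the
$\gamma = 0$ point, so $(0, 0)$ lies on the curve by construction and the
fit is pinned through the origin — a free intercept would double-count
$A_0$; and (b) uses weighted least squares with weights
$1/\mathrm{se}(\epsilon)^2$ propagated from the per-run APL standard
errors, because the tension runs fluctuate unequally. Both choices are
switchable (`zero_intercept`, `weighted`). The slope uncertainty combines,
in quadrature, the delta-method variance from the per-point strain errors
and the numerically propagated uncertainty of $A_0$ itself. With
noiseless input the fit returns the generating slope exactly; under the
synthetic AR(1) world the $\pm 2\,\mathrm{se}$ interval covers the truth
in ≈95 of 100 seeds (the acceptance suite requires ≥90).

Standard errors of trajectory means use `stationary_se()`: the integrated
autocorrelation time $\hat\tau$ is the sum of the empirical
autocorrelation function from lag 1 until it first drops below zero,
$n_\mathrm{eff} = N/(1+2\hat\tau)$, and
$\mathrm{se} = s/\sqrt{n_\mathrm{eff}}$. This truncation rule is biased
low for very long-memory series but is simple, parameter-free, and
accurate to ~20–30% for AR(1)-like fluctuations, which is what box-area
series look like in practice.

The $t$ comparison of two $K_A$ values follows the four-tension design:
each estimate is treated as a mean of $n = 4$ condition-level values whose
group SD is reconstructed as $\mathrm{se}\sqrt{n}$, pooled-variance $t$
with $df = n_1 + n_2 - 2 = 6$ and two-tailed critical value
$t_{0.975,6} = 2.447$. How the group SDs should be reconstructed from
reported SEs is genuinely underdetermined; the reconstruction above is the
documented default and a direct normal comparison
$z = \Delta K_A/\sqrt{\mathrm{se}_1^2+\mathrm{se}_2^2}$ is available via
`method = "z"`.

### Order parameters

The per-carbon order parameter is
$S_C(i) = \langle (3\cos^2\theta_i - 1)/2 \rangle$ with $\theta_i$ the
angle between z and the chord joining heavy atoms $i-1$ and $i+1$ of the
same tail. This is the *carbon-skeleton* estimator: no hydrogens are
used, so it is not the NMR $S_{CD}$, and the first and last carbons carry
no value. $S_C = 1$ for a chord along the normal, $0$ for isotropic
orientations, $-0.5$ for in-plane chords. Relative-order profiles divide a
mixed-system profile by a pure reference and multiply by the carbon index,
so "identical to pure" is the diagonal line.

TMG histograms are taken relative to the per-frame midplane (mean
phosphorus z), which removes box drift, separately per leaflet and
combined, density-normalized.

### Lateral diffusion

Tracks are unwrapped by accumulating minimum-imaged frame-to-frame
increments; the per-frame selection centroid is subtracted by default to
remove collective drift (per-leaflet drift removal was considered and
rejected as the default because the estimators are leaflet-agnostic; drift
removal can be disabled). MSD uses every particle and every overlapping
time origin, computed by the standard FFT decomposition and verified
against an $O(T^2)$ brute-force oracle. $D$ is the OLS slope over a fit
window (default 10–50% of the available lags) divided by 4. A
covariance-aware generalized-least-squares MSD estimator would have
smaller variance; it is deliberately out of scope and the OLS window
estimator is the documented substitute — parameter recovery on Brownian
ground truth (within 5% of $D$ over 50 seeds at three diffusivities) is
the accepted evidence that it suffices at this package's scale.

The anomalous-diffusion check pools x- and y-increments at one lag and
KS-tests them against a zero-mean Gaussian whose variance comes from the
same increments. Two deliberate deviations from the naive construction
were forced by calibration measurements: increments are taken at
**non-overlapping** windows (overlapping increments share steps, are
autocorrelated, and push the false-positive rate above 0.4), and the
p-value is **bootstrap-calibrated** (estimating the variance from the
tested sample makes the textbook p conservative — the Lilliefors effect —
with a measured false-positive rate of ~0.02–0.03 at nominal 0.05). With
both corrections the measured false-positive rate is within 0.02–0.08.

### Lateral organization

Voronoi cells are computed per leaflet from the phosphate (x, y) seeds
under periodic boundaries: seeds are tiled into the 8 surrounding images
and each central cell is obtained by half-plane clipping against
neighbors in distance order, stopping when the bisector of the next
neighbor cannot intersect the current cell (distance > twice the farthest
vertex). The tiling is exact while every cell diameter is below the box
length, which holds for any physically sensible leaflet. Cell areas
partition the box to ≤ 1e-6 relative error on every tested frame, and
per-cell areas agree with a 2000×2000 nearest-seed pixel rasterization to
better than 0.5% on generator frames. (Uniformly random seed sets can
contain near-coincident pairs whose sliver cells no raster resolves at
any sensible resolution; physical headgroup configurations do not.)

Contacts use the full 3D minimum-image distance between reference beads
(phosphates at ≤ 11 Å for $f_{mix}$; first tail beads at ≤ 15 Å for
neighbor composition), restricted to same-leaflet pairs by default. The
mixed fraction is $C_{AB}/(C_{AA}+C_{AB}+C_{BB})$ — the
all-contacts denominator; the like-only denominator variant is available
(`denominator = "unlike_over_like"`) because the field is not consistent
about this convention. Production counting is vectorized $O(N^2)$ and is
tested for exact equality against an explicit pair-loop oracle.

## The synthetic world

`make_bilayer()` generates the stated world every recovery test measures
against. Defaults are all-atom-like: 100 lipids per leaflet at
$A_0 = 68\,\mathring{A}^2$ (≈ 8×8 nm box), P–P thickness 38 Å with 2 Å
per-leaflet headgroup z-scatter, 18-carbon tails, TMG means 3 Å past the
midplane with 2 Å spread, $D = 100\times10^{-9}\,\mathrm{cm^2/s}$ sampled
every 100 ps, 75:25 binary composition, tensions {−7, 0, 7, 15} mN/m and
$K_A = 245$ mN/m for the tension-series generator. The CG-like preset
scales to 1520 lipids per leaflet on a ~30×30 nm box with 4-bead tails.

Deliberate idealizations, and hence what a green test does *not*
establish:

* Tails are **rigid straight chains** whose axis is redrawn per lipid,
  tail and frame from the mixture "aligned with probability $w$ /
  isotropic otherwise". The chord estimator then returns exactly $w$ at
  every interior carbon, making order-parameter recovery a closed-form
  test. A per-segment mixture draw — arguably the more literal reading —
  does *not* have this property, because each chord spans two segments
  and the $P_2$ of a two-segment sum is not $w$; exactness of the ground
  truth was chosen over geometric realism. Real chains have correlated,
  position-dependent segment order; the generator does not emulate an
  order *profile*, only a flat one.
* TMG z-positions are drawn directly from their target Normal and the
  chain is translated to end there, while headgroup z is drawn
  independently: the synthetic lipid is a statistical object, not a
  bonded geometry. No analysis in scope uses head–tail connectivity.
* Lateral motion is ideal 2D Brownian motion — no subdiffusive caging, no
  hydrodynamics, no finite-size corrections. The diffusion criterion
  checks estimator correctness, not membrane physics.
* APL streams in `make_tension_series()` are AR(1) with stationary SD
  1 Å² and correlation time 20 frames, because AR(1) has a closed-form
  effective sample size against which `stationary_se()` can be scored.
  Box area in `make_bilayer()` itself is constant; elasticity tests run
  on the stream generator.
* Headgroup scatter is i.i.d. Gaussian per frame: there are no capillary
  undulations, so the unevenness statistic converges to exactly
  $2\sigma_z$ — which is the point of the test, not a claim about real
  membranes.

All generators are bit-deterministic under their seed.

## Numerical and procedural choices

* **Leaflet assignment**: midplane = unweighted mean of all phosphorus z;
  upper iff above. Assignment is computed on a reference frame (default
  frame 1) and reused — flip-flop is not modeled on these time scales.
  Degenerate monolayers raise an error rather than returning an empty
  leaflet.
* **Unevenness**: the statistic pools each phosphorus's deviation from
  its own frame-and-leaflet mean, takes one SD per leaflet over the
  pooled deviations of 500 randomly sampled frames (seeded, recorded) and
  sums the two SDs. The alternative literal reading — the SD of the 500
  per-frame leaflet means — measures frame-to-frame plane breathing
  (~$\sigma/\sqrt{n}$), not roughness, and is exposed as
  `mode = "frame_means"` for comparison without being the default.
  Neither mode is asserted to reproduce any published figure numerically.
* **Voronoi degeneracies**: coincident seeds (minimum-image distance
  < 1e-6 Å) are an error naming the lipids; ties in the raster oracle are
  broken deterministically.
* **Fit windows**: the diffusion window defaults to 10–50% of the
  available lag range — below, ballistic/initial transients; above,
  noise-dominated long-time lags. Fewer than 5 lags in a window is an
  error, not a silent fit.
* **Short series**: SE helpers fall back to $s/\sqrt{N}$ below 10
  observations and to 0 for constant series; the autocorrelation
  machinery needs a minimum length to mean anything.
* **File formats**: GRO, PDB and DCD are parsed natively (DCD verified
  byte-exactly against an independent writer); XTC — a compressed XDR
  format — is decoded through the MDAnalysis Python library as an
  infrastructure service. The portable fixture format is one JSON header
  line plus plain-text coordinate blocks, chosen to be diffable,
  language-neutral and binary-free; it round-trips coordinates to
  ≤ 1e-6 Å. The pipeline configuration format is JSON for the same
  reason.

## Worked example

```{r example, eval = FALSE}
spec <- synthetic_spec(seed = 42)           # AA-like stated world
bl   <- make_bilayer(spec)
asg  <- assign_leaflets(get_frame(bl$trajectory, 1), bl$trajectory$topology)

area_per_lipid(bl$trajectory, spec$n_per_leaflet)
bilayer_thickness(bl$trajectory, asg)
order_parameter_profile(bl$trajectory, "DOPC", "SN1")

ts <- make_tension_series(245, 68, seed = 42)
fit_area_compressibility(ts$points)
```

## Known limitations

Triclinic boxes, trajectory alignment, flip-flop, membrane undulation
spectra, bending moduli, hydrodynamic/finite-size diffusion corrections
and nanodomain clustering algorithms are out of scope. The $t$-test
protocol treats tension conditions as replicates, which is statistically
unconventional but matches the four-tension design it models; the z
alternative is provided for users who prefer a direct SE-based
comparison. Published system-specific numbers from long production
trajectories are not reproduction targets of the test suite — recovery is
asserted against the synthetic ground truth only, plus the arithmetic and
protocol facts that are seed-independent.
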