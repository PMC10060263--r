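---
title: "Porewater nitrogen zonation and diffusive fluxes: models and choices"
author: "poreNitrogen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Porewater nitrogen zonation and diffusive fluxes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poreNitrogen)
```

## The problem

In many marine sediments, porewater nitrate decreases with depth and
disappears at a *depletion depth*; ammonium, released by organic-matter
degradation at depth, diffuses upward. Between them lies the
nitrate–ammonium transition zone (NATZ), the habitat of anaerobic
ammonium-oxidising (anammox) bacteria. In some cores, nitrite — usually an
invisible, fast-cycling intermediate — accumulates to a few µM around the
nitrate-depletion zone. Quantifying that phenomenon needs four ingredients,
each implemented here as an explicit, testable operation:

1. a reproducible *zonation* of each core from its censored solute profiles;
2. *diffusive boundary fluxes* by Fick's first law, to budget how much of
   the nitrate consumed in the depletion zone escapes as nitrite;
3. *absolute microbial abundances* and anammox niche-partitioning metrics;
4. a *forward model* that generates profiles from a known steady-state
   truth, so that 1–2 can be verified without field data.

## Zonation: definitions and numerical choices

All zonation operates on censored profiles: a point is censored when its
concentration is below the solute's detection limit; censored points store
concentration 0 (a `"half-dl"` option stores DL/2) and keep their flag.

* **Depletion depth** (`findDepletionDepth`): the shallowest depth where a
  solute is censored while the point above is not. The raw first-censored
  sample depth is biased deep by up to one sample spacing, so the reported
  value linearly interpolates the detection-limit crossing between the two
  bracketing points; both values are kept.
* **Oxic zone** (`findOxicZone`): surface to the oxygen depletion depth;
  the whole core if oxygen never depletes; an empty surface interval when
  oxygen is censored everywhere (a recovered core may already be anoxic at
  its top).
* **Nitrite interval** (`findNitriteInterval`): the longest contiguous run
  of non-censored nitrite points, ties to the shallowest run. The profile
  is *coherent* when the run has at least 3 depths — the strict reading of
  "more than two consecutive detects". The maximum breaks ties to the
  shallowest depth so output is deterministic.
* **NATZ** (`findNATZ`): between the nitrate depletion depth and the
  (interpolated) shallowest ammonium appearance; *separated* when ammonium
  appears below the depletion depth (the interval is the gap), *overlap*
  otherwise (the interval is the co-occurrence zone).
* **Consumption zones** (`classifyConsumptionZones`): the net-rate profile
  `R(z) = −φ Ds C''(z)` is computed by central second differences on the
  (possibly non-uniform) grid; within the nitrite interval, the contiguous
  runs of net consumption nearest to and strictly above/below the maximum
  are the upper and lower consumption zones. Because discrete curvature is
  noisy, points with `|R|` below a threshold fraction (default 10 %) of the
  interval's largest `|R|` count as "no signal"; if no run is found on a
  limb the zone falls back to the corresponding half of the interval. The
  interval's two edge points are excluded from the rate profile: their
  difference stencils touch censored (zeroed) neighbours and would fake
  large curvature.

Zonation is invariant under rescaling all concentrations and detection
limits by a common positive factor (a units sanity check enforced in the
tests).

## Fluxes

Fick's first law for sediment porewater, with depth `z` positive downward
(metres internally; interfaces are cm below seafloor):

\[ J = \varphi\, D_s\, \frac{\partial [C]}{\partial z} \]

* **Gradient**: ordinary least-squares slope of concentration (µM ≡
  mmol m⁻³) on depth over *exactly three* consecutive points. Windows: the
  nitrate influx uses the 3 detected points immediately above the depletion
  crossing; the nitrite effluxes use the 3 shallowest and 3 deepest points
  of the nitrite interval. Because the anchoring is a methodological choice
  the paper-style analysis does not fix, a `"bracketing"` alternative
  (shifted one point outward across the interval edge) is provided, and
  `runCompilation(sensitivity = TRUE)` reports the mean ratio under all
  anchoring × tortuosity combinations.
* **Free-solution diffusivity** (`d0InfiniteDilution`): the linear fits
  `D0 = (m0 + m1 T) × 10⁻⁶ cm² s⁻¹` to published tracer-diffusion tables —
  nitrate (9.50, 0.388), nitrite (10.3, 0.331), ammonium (9.50, 0.413);
  oxygen (11.0, 0.47) is a linear fit to published O₂-in-water values and
  is never used in a reported flux. Conversion to m² yr⁻¹ uses a Julian
  year. Salinity/pressure correction is Stokes–Einstein scaling by the
  pure-water/seawater dynamic-viscosity ratio (Kukulka polynomial).
  Temperatures outside −2 to 30 °C warn as extrapolation.
* **Tortuosity** (`sedimentDiffusivity`): default
  `Ds = D0 / (1 − ln φ²)`; the Archie power law `Ds = D0 φ^(m−1)` (default
  m = 2) is a config alternative. Both are increasing in φ with `Ds → D0`
  as `φ → 1`.
* **Signs**: fluxes are computed signed (positive gradient ⇒ upward
  diffusion) with direction labels, but all reported quantities — influx,
  effluxes, their ratio `r = (J_up + J_down)/J_in` — are magnitudes, which
  is what a flux compilation plots regardless of sign convention.
* **Cross-site summary** (`ratioSummary`): arithmetic mean and Student-t
  95 % half-width `t₀.₉₇₅,ₙ₋₁ · sd/√n`; `n = 1` yields a mean with an
  undefined CI; sites with `r ≥` a threshold (default 1) are flagged.
* **Environmental defaults** when a site lacks metadata: T = 2 °C, S = 35,
  hydrostatic pressure from water depth — typical deep-sea bottom water.
  Porosity defaults to a constant 0.7 (with a warning) when a table has no
  porosity column; detection limits default to 0.1 µM for the nitrogen
  species and 2 µM for optode oxygen. All are configurable; every applied
  default is named in the run log.

## Absolute abundance and niche partitioning

Total cells per gram are the sum of archaeal and bacterial 16S rRNA gene
copies under the single-copy assumption; a taxon's absolute abundance is
total cells × its relative amplicon abundance. The anammox fraction is the
sum of the two marine anammox families (*Ca.* Scalinduaceae, *Ca.*
Bathyanammoxibiaceae). Family peaks use *absolute* abundance — a relative
peak can be an artifact of other taxa decaying — with ties to the
shallowest depth; the separation Δz between two family peaks converts to a
duration `Δz/ω × 1000` yr at sedimentation rate ω. Peaks are compared
within one core only. qPCR/amplicon concordance reports per-depth
`log10(qPCR/amplicon)` (zeros replaced by half the smallest nonzero value,
configurable) with the median and the fraction of depths within one order
of magnitude — an explicit operationalisation of "general agreement",
which the field usually leaves qualitative.

## The synthetic generator

`solveSteadyState` solves, per solute,
`d/dz(φ Ds dC/dz) + φ R = 0` on `[0, L]` with piecewise-constant rates `R`
(per porewater volume; negative = consumption), constant φ and `Ds`, and
Dirichlet ends. The solution is piecewise quadratic; concentration and flux
continuity at interfaces give a small linear system with closed-form
boundary fluxes (`ScenarioTruth`). Scenarios whose solution goes negative
anywhere are rejected — zeroth-order consumption is not self-limiting, so
positivity is a validity constraint, not an afterthought. Note the rate
bookkeeping: scenario rates are per porewater volume, while
`netReactionRate` returns the bulk-sediment rate `φR`, which is what the
flux-divergence identity `J(top) − J(bottom) = Σ φ R Δz` uses.

`generateProfile` samples the analytic solution on a regular grid, adds
additive Gaussian noise (truncated at zero) from one seeded generator —
one vector of normals per solute in boundary-condition order, so identical
seeds give byte-identical output — then censors at the detection limits.
Additive truncated noise mimics colorimetric error near the detection
limit; a lognormal alternative was considered and rejected as the default
because nutrient autoanalyser error is approximately absolute at the µM
scale.

Two presets exercise the two observed core topologies. *GS14-like*
(separated NATZ): oxygen consumed within ~24 cm, a nitrate limb reaching
the detection limit near 130 cm with a thin intense sink just below the
crossing (so the boundary flux is well defined and recoverable from a
three-point window; rates are derived in closed form from the targeted
crossing slope), a nitrite source zone at 90–120 cm flanked by two sinks,
and ammonium held below detection until ~180 cm by a deep consumption
zone. *GS16-like* (overlap NATZ): deeper oxygen penetration (~110 cm),
nitrate depleting near 190 cm, a smaller ~1 µM nitrite bump, ammonium
appearing near 120 cm. Magnitudes (nitrite maxima of a few µM, nitrate
10–15 µM, fluxes of order 0.01–0.1 mmol m⁻² yr⁻¹) sit in the range of
deep-sea porewater observations; they were fixed once when the presets
were designed.

`generateCommunity` builds per-depth expected compositions from Gaussian
family peaks over a background simplex (Dirichlet weights drawn once per
scenario), draws counts multinomially at a fixed read depth (default
20,000 reads per horizon, matching common subsampling practice), declines
total cells log-linearly from the surface value, and derives a qPCR marker
series from the truth with lognormal noise.

**What the generator does not emulate:** advection/compaction and
bioturbation; temperature gradients; coupled multi-species kinetics (the
ammonium and nitrite sinks are independent prescriptions, not an anammox
stoichiometry); depth-dependent porosity; compositional correlation
between taxa beyond the multinomial; primer or extraction bias. Passing
tests on synthetic data therefore demonstrate the *estimators* are
correct, not that real cores satisfy steady state.

## Estimator behaviour worth knowing

* The three-point OLS gradient is exact for quadratic profiles within one
  reaction zone, so on noise-free synthetic data the flux error comes only
  from the window sitting a grid-dependent offset away from the detected
  boundary; it shrinks like O(h) and the tests check it is below 5 % at a
  2 cm grid and monotonically decreasing over 4, 2, 1, 0.5 cm.
* Reported fluxes are magnitudes. When the true gradient is small relative
  to the measurement noise (signal-to-noise below ~2 on a window), taking
  magnitudes folds the noise distribution and biases |J| upward — visible
  in noisy synthetic replicates near the detection limit. The replicate
  test therefore checks that noise adds no bias *beyond* the deterministic
  grid-level estimate at a noise level where the windows have adequate
  signal-to-noise (0.005–0.01 µM); at 0.05 µM noise the nitrite windows of
  the GS14-like preset are noise-dominated and their magnitude is
  systematically high. Real compilations at coarse sampling have larger
  window signals, but the same caveat applies to very flat limbs.
* The detected nitrite interval is a longest run of detects, so isolated
  noise-flipped points near the edges can shift windows by a few grid
  steps; this is an O(noise) selection effect on the ratio.

## Test and script problem sizes

The suite verifies the solver on 100 random three-zone scenarios against
an interface-aligned finite-volume discretisation (exact for piecewise
quadratics, agreement required to 10⁻⁶ relative; flux continuity and mass
balance to 10⁻⁸), runs the grid-refinement study at 4–0.5 cm spacing, and
uses 100–200 Monte-Carlo replicates for the statistical properties —
sizes chosen so the whole suite completes in well under a minute while
leaving the Monte-Carlo bounds (3 standard errors) meaningful. The
acceptance script uses a 20-site synthetic compilation at 0.01 µM noise.

## Known limitations

* The supplementary field datasets of the motivating study are not
  redistributed; the two tests that reproduce its published numbers
  (30-site mean ratio, GS14-GC04 nitrite maximum and depletion depth)
  remain unmet until those tables are dropped into `inst/extdata/`.
* Steady state is assumed throughout; transient diagenesis, bioirrigation
  and advection are out of scope.
* The flux windows implement the "nearby three data points" rule literally;
  with very coarse or very fine sampling a different window width may be
  more appropriate, and only the anchoring is configurable.
* `Ds` uses bottom-water temperature for the whole core; porewater warming
  with depth is ignored (the in-situ-versus-lab temperature question is
  exposed as the `temperature` argument, not resolved).
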