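# poreNitrogen

Depth-resolved porewater nitrogen analysis for marine sediment cores, built
for biogeochemists and geomicrobiologists working with gravity/piston-core
nutrient profiles and paired microbial abundance data.

Marine sediments can accumulate nitrite — normally a fleeting intermediate —
in the depth interval where porewater nitrate disappears. Interpreting that
phenomenon requires a small set of quantitative steps that this package
implements as one tested pipeline:

* **Profile handling** — read delimited porewater tables (depth, NO₃⁻,
  NO₂⁻, NH₄⁺, O₂ in µM, porosity), with explicit detection-limit censoring
  ("bd" cells) and validation.
* **Zonation** — derive the oxic zone, the nitrate depletion depth (linear
  interpolation of the detection-limit crossing), the nitrite accumulation
  interval (coherent when nitrite is detectable at more than two consecutive
  depths) and its maximum, the nitrate–ammonium transition zone (NATZ,
  tagged *separated* or *overlap*), and the two net nitrite consumption
  zones flanking the nitrite maximum.
* **Diffusive fluxes** — Fick's first law for porewater,

  ```
  J = φ · Ds · ∂[C]/∂z
  ```

  with the concentration gradient taken as the least-squares slope over
  three neighbouring data points, the sediment diffusivity
  `Ds = D0 / (1 − ln φ²)` (tortuosity correction; Archie power law available
  as an option), and `D0` from published linear temperature fits corrected
  to in-situ salinity and pressure by the seawater/pure-water viscosity
  ratio. Per site the pipeline reports the nitrate influx into the
  depletion zone, the upward and downward nitrite effluxes, and the ratio
  `r = (J_NO2_up + J_NO2_down) / J_NO3_in`; across sites it reports the
  mean ratio with a Student-t 95 % confidence interval.
* **Net reaction rates** — the steady-state diagenetic estimator
  `R(z) = −φ · Ds · C''(z)` (central differences), whose sign pattern
  defines net production and consumption zones.
* **Microbial metrics** — total cells from archaeal + bacterial 16S copies
  (single-copy assumption), absolute abundances as total cells × relative
  amplicon abundance, anammox fractions as the sum of the *Ca.*
  Scalinduaceae and *Ca.* Bathyanammoxibiaceae families, qPCR/amplicon
  concordance, and niche-partitioning metrics: the vertical separation Δz
  of two family abundance maxima and the implied duration
  `Δz / ω × 1000` years at sedimentation rate ω (cm/kyr).
* **Synthetic truth** — a closed-form 1-D steady-state reaction–diffusion
  generator (piecewise-constant rates ⇒ piecewise-quadratic profiles with
  exact boundary fluxes) so every estimator above can be verified against a
  known ground truth, plus a multinomial community generator at fixed read
  depth.

## Worked example

A synthetic core (generated by the package's own forward model, stored as a
plain CSV) runs through the whole pipeline:

```r
library(poreNitrogen)

path <- system.file("extdata", "synthetic_GS14like_porewater.csv",
                    package = "poreNitrogen")
p <- readProfileTable(path, site = siteMetadata("example",
                                                waterDepth = 1050,
                                                sedimentationRate = 2))
p <- censorToDetection(p)
deriveZones(p)
#> ZoneSet 'example'
#>   oxic zone:               [0, 21.07] cm
#>   nitrate depletion:       128.5 cm
#>   nitrite interval:        [20, 230] cm (coherent: TRUE)
#>   nitrite maximum:         3.33 uM at 110 cm
#>   NATZ (separated):       [128.5, 179.7] cm
#>   ...
siteFluxes(p)
#> FluxResult 'example' (mmol m-2 yr-1)
#>   nitrate influx   0.06422
#>   nitrite efflux   up 0.02804, down 0.01239
#>   nitrite/nitrate flux ratio r = 0.6296
```

Reading: oxygen is gone by ~21 cm, nitrate by ~129 cm, yet nitrite
accumulates to 3.3 µM at 110 cm and ammonium only appears below ~180 cm
(a *separated* NATZ). The combined nitrite efflux out of the
nitrate-depletion zone carries ~63 % of the nitrate influx in this noisy
synthetic core; the remainder must leave by further reduction. Multi-site
summaries come from `runCompilation()`, and
`partitionDuration(110, 2)` converts a 110 cm anammox family peak
separation into the 55,000-year duration it implies at 2 cm/kyr.

## Vignette

`vignettes/porewater-nitrogen.Rmd` documents the model assumptions, the
default parameters and their provenance, what the synthetic generator does
and does not emulate, and the package's numerical choices and limitations.
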