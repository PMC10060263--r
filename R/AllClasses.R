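#' @import methods
NULL

# Interval slots use length-2 numerics in cm below seafloor; c(NA, NA) means
# "not defined for this core". Helpers in utils.R keep that convention honest.

#' Solute description for porewater work
#'
#' A \code{SoluteSpec} names a porewater solute and carries the two pieces of
#' physical metadata the flux machinery needs: the coefficients of the linear
#' infinite-dilution diffusivity model \eqn{D_0 = (m_0 + m_1 T) \times 10^{-6}}
#' cm\eqn{^2} s\eqn{^{-1}} (temperature \eqn{T} in degrees Celsius), and the
#' analytical detection limit in micromolar used for censoring.
#'
#' @slot name solute name, one of \code{"nitrate"}, \code{"nitrite"},
#'   \code{"ammonium"}, \code{"oxygen"} (other names are allowed but carry no
#'   default coefficients).
#' @slot m0 intercept of the diffusivity model, 1e-6 cm^2/s. Must be > 0.
#' @slot m1 slope of the diffusivity model, 1e-6 cm^2/s per degree C. Must be
#'   >= 0 so diffusivity never decreases with temperature.
#' @slot detectionLimit detection limit, micromolar (>= 0).
#'
#' @seealso [soluteSpec()], [defaultSolutes()], [d0InfiniteDilution()]
#' @export
setClass("SoluteSpec",
  representation(
    name = "character",
    m0 = "numeric",
    m1 = "numeric",
    detectionLimit = "numeric"
  )
)

setValidity("SoluteSpec", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@m0) != 1L || !is.finite(object@m0) || object@m0 <= 0)
    msg <- c(msg, "'m0' must be a single positive number")
  if (length(object@m1) != 1L || !is.finite(object@m1) || object@m1 < 0)
    msg <- c(msg, "'m1' must be a single non-negative number")
  if (length(object@detectionLimit) != 1L || !is.finite(object@detectionLimit) ||
      object@detectionLimit < 0)
    msg <- c(msg, "'detectionLimit' must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' Site metadata for a sediment core
#'
#' Environmental context of a coring site: position, water depth, and the
#' bottom-water conditions (temperature, salinity, pressure) that set the
#' free-solution diffusivity, plus the sedimentation rate used to convert
#' depth separations into durations.
#'
#' @slot siteId site identifier.
#' @slot latitude,longitude decimal degrees.
#' @slot waterDepth water depth in metres (> 0).
#' @slot bottomTemperature bottom-water temperature, degrees Celsius.
#' @slot salinity practical salinity (>= 0).
#' @slot pressure pressure in bar; defaults to hydrostatic pressure at the
#'   seafloor (about 1 bar per 10 m of water plus 1 atm).
#' @slot sedimentationRate cm per kyr; \code{NA} when unknown, must be > 0
#'   when given.
#' @slot sourceLabel free-text provenance tag.
#'
#' @seealso [siteMetadata()]
#' @export
setClass("SiteMetadata",
  representation(
    siteId = "character",
    latitude = "numeric",
    longitude = "numeric",
    waterDepth = "numeric",
    bottomTemperature = "numeric",
    salinity = "numeric",
    pressure = "numeric",
    sedimentationRate = "numeric",
    sourceLabel = "character"
  )
)

setValidity("SiteMetadata", function(object) {
  msg <- character()
  if (length(object@siteId) != 1L) msg <- c(msg, "'siteId' must be length 1")
  if (!is.na(object@waterDepth) && object@waterDepth <= 0)
    msg <- c(msg, "'waterDepth' must be positive")
  if (!is.na(object@salinity) && object@salinity < 0)
    msg <- c(msg, "'salinity' must be non-negative")
  if (!is.na(object@sedimentationRate) && object@sedimentationRate <= 0)
    msg <- c(msg, "'sedimentationRate' must be positive when present")
  if (length(msg)) msg else TRUE
})

#' Depth-resolved porewater profile
#'
#' The central container: one site's porewater solute concentrations on a
#' strictly increasing depth grid (cm below seafloor, positive downward),
#' with a parallel censoring mask (below detection limit), per-depth porosity,
#' and the solute specifications used to interpret the columns. Censored
#' entries hold concentration 0 so that downstream gradient fits treat them as
#' "not above detection"; the flag is preserved in all outputs.
#'
#' @slot site a [SiteMetadata-class].
#' @slot depth numeric vector, cm below seafloor, strictly increasing.
#' @slot conc numeric matrix, depths x solutes, micromolar; column names are
#'   solute names. Non-censored values must be >= 0.
#' @slot censored logical matrix, same shape as \code{conc}.
#' @slot porosity numeric vector per depth, in (0, 1].
#' @slot solutes named list of [SoluteSpec-class], one per concentration
#'   column.
#'
#' @seealso [depthProfile()], [readProfileTable()], [censorToDetection()]
#' @export
setClass("DepthProfile",
  representation(
    site = "SiteMetadata",
    depth = "numeric",
    conc = "matrix",
    censored = "matrix",
    porosity = "numeric",
    solutes = "list"
  )
)

setValidity("DepthProfile", function(object) {
  msg <- character()
  n <- length(object@depth)
  if (n > 0 && any(diff(object@depth) <= 0))
    msg <- c(msg, "depths must be strictly increasing")
  if (!identical(dim(object@conc), dim(object@censored)))
    msg <- c(msg, "'conc' and 'censored' must have identical dimensions")
  if (nrow(object@conc) != n)
    msg <- c(msg, "'conc' must have one row per depth")
  if (length(object@porosity) != n)
    msg <- c(msg, "'porosity' must have one value per depth")
  if (length(object@porosity) &&
      (any(!is.finite(object@porosity)) || any(object@porosity <= 0) ||
       any(object@porosity > 1)))
    msg <- c(msg, "porosity must lie in (0, 1]")
  ok <- !object@censored
  if (any(object@conc[ok] < 0, na.rm = TRUE))
    msg <- c(msg, "non-censored concentrations must be >= 0")
  if (is.null(colnames(object@conc)))
    msg <- c(msg, "'conc' must have solute column names")
  if (!all(colnames(object@conc) %in% names(object@solutes)))
    msg <- c(msg, "every concentration column needs a matching SoluteSpec")
  if (length(msg)) msg else TRUE
})

#' Geochemical zonation of one core
#'
#' Derived zonation of a [DepthProfile-class]: the oxic zone, the nitrate
#' depletion depth, the nitrite accumulation interval with its concentration
#' maximum and coherence flag, the nitrate-ammonium transition zone (NATZ)
#' with its topology tag, and the upper/lower net nitrite consumption zones
#' flanking the nitrite maximum. Undefined elements are \code{NA}.
#'
#' @slot siteId site identifier.
#' @slot oxicZone length-2 numeric, cm: \code{[shallowest sample, O2 depletion]}.
#' @slot nitrateDepletionDepth cm, interpolated crossing of the nitrate
#'   detection limit; \code{NA} if nitrate never depletes.
#' @slot nitrateFirstCensoredDepth cm, shallowest sampled depth at which
#'   nitrate is censored (the un-interpolated companion value).
#' @slot nitriteInterval length-2 numeric, cm: longest contiguous run of
#'   detectable nitrite.
#' @slot coherentNitrite logical: run length >= 3 ("more than two consecutive
#'   depths with detectable nitrite").
#' @slot nitriteMaximum length-2 numeric: (depth cm, concentration uM) of the
#'   largest nitrite value in the run, ties broken shallow.
#' @slot natz length-2 numeric, cm: gap or overlap interval between nitrate
#'   depletion and first ammonium appearance.
#' @slot natzRelation \code{"separated"}, \code{"overlap"} or
#'   \code{"undefined"}.
#' @slot upperConsumptionZone,lowerConsumptionZone length-2 numerics, cm.
#'
#' @seealso [deriveZones()], [classifyConsumptionZones()]
#' @export
setClass("ZoneSet",
  representation(
    siteId = "character",
    oxicZone = "numeric",
    nitrateDepletionDepth = "numeric",
    nitrateFirstCensoredDepth = "numeric",
    nitriteInterval = "numeric",
    coherentNitrite = "logical",
    nitriteMaximum = "numeric",
    natz = "numeric",
    natzRelation = "character",
    upperConsumptionZone = "numeric",
    lowerConsumptionZone = "numeric"
  )
)

setValidity("ZoneSet", function(object) {
  msg <- character()
  chk2 <- function(x, what) {
    if (length(x) != 2L) return(sprintf("'%s' must have length 2", what))
    NULL
  }
  for (s in c("oxicZone", "nitriteInterval", "nitriteMaximum", "natz",
              "upperConsumptionZone", "lowerConsumptionZone")) {
    m <- chk2(slot(object, s), s)
    if (!is.null(m)) msg <- c(msg, m)
  }
  iv <- object@nitriteInterval
  mx <- object@nitriteMaximum
  if (all(is.finite(iv)) && is.finite(mx[1]) &&
      (mx[1] < iv[1] || mx[1] > iv[2]))
    msg <- c(msg, "nitrite maximum must lie within the nitrite interval")
  if (!object@natzRelation %in% c("separated", "overlap", "undefined"))
    msg <- c(msg, "natzRelation must be 'separated', 'overlap' or 'undefined'")
  if (length(msg)) msg else TRUE
})

#' Per-site boundary fluxes and nitrite/nitrate flux ratio
#'
#' Fick's-law diffusive fluxes at the boundaries of the nitrate-depletion
#' zone of one core: the downward nitrate influx and the upward and downward
#' nitrite effluxes, each computed from a three-point gradient window, plus
#' the dimensionless ratio r = (J_NO2_up + J_NO2_down) / J_NO3_in. All
#' paper-facing fluxes are magnitudes (mmol m-2 yr-1); signed values and
#' direction labels are kept in \code{windows}.
#'
#' @slot siteId site identifier.
#' @slot JNO3In,JNO2Up,JNO2Down flux magnitudes, mmol m-2 yr-1.
#' @slot ratio dimensionless nitrite/nitrate flux ratio (>= 0).
#' @slot windows named list; for each flux, the three (depth cm, conc uM)
#'   points used, the signed flux, and the direction label.
#' @slot DsUsed named numeric, sediment diffusivity m2 yr-1 per solute.
#'
#' @seealso [siteFluxes()], [ratioSummary()]
#' @export
setClass("FluxResult",
  representation(
    siteId = "character",
    JNO3In = "numeric",
    JNO2Up = "numeric",
    JNO2Down = "numeric",
    ratio = "numeric",
    windows = "list",
    DsUsed = "numeric"
  )
)

setValidity("FluxResult", function(object) {
  msg <- character()
  for (s in c("JNO3In", "JNO2Up", "JNO2Down", "ratio")) {
    v <- slot(object, s)
    if (length(v) != 1L || (is.finite(v) && v < 0))
      msg <- c(msg, sprintf("'%s' must be a single non-negative number", s))
  }
  for (w in object@windows) {
    if (!is.null(w$points) && nrow(w$points) != 3L)
      msg <- c(msg, "each gradient window must hold exactly 3 points")
  }
  if (length(msg)) msg else TRUE
})

#' Cross-site summary of nitrite/nitrate flux ratios
#'
#' Arithmetic mean of the per-site ratios and a Student-t 95% confidence
#' half-width, with sites whose ratio reaches a configurable outlier
#' threshold listed separately.
#'
#' @slot nSites number of sites summarised.
#' @slot ratios named numeric, per-site ratio r.
#' @slot mean arithmetic mean of \code{ratios}.
#' @slot ci95Halfwidth \eqn{t_{0.975, n-1} \cdot sd/\sqrt{n}}; \code{NA}
#'   when n < 2.
#' @slot outlierSites site ids whose ratio is at or above the threshold used.
#'
#' @seealso [ratioSummary()]
#' @export
setClass("RatioSummary",
  representation(
    nSites = "integer",
    ratios = "numeric",
    mean = "numeric",
    ci95Halfwidth = "numeric",
    outlierSites = "character"
  )
)

setValidity("RatioSummary", function(object) {
  msg <- character()
  if (object@nSites != length(object@ratios))
    msg <- c(msg, "'nSites' must equal length(ratios)")
  if (length(object@ratios) &&
      !isTRUE(all.equal(object@mean, mean(object@ratios))))
    msg <- c(msg, "'mean' must equal the arithmetic mean of 'ratios'")
  if (is.finite(object@ci95Halfwidth) && object@ci95Halfwidth < 0)
    msg <- c(msg, "'ci95Halfwidth' must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Per-depth microbial abundance table
#'
#' Community observations for one core: archaeal and bacterial 16S rRNA gene
#' copies (assumed single-copy, so copies equal cells), functional-gene qPCR
#' series with triplicate standard deviations, and per-taxon relative
#' amplicon abundances.
#'
#' @slot depths cm below seafloor, strictly increasing.
#' @slot archaeal16S,bacterial16S gene copies per g wet sediment (>= 0).
#' @slot functionalGenes named list, gene -> data.frame(depth, copies, sd).
#' @slot relAbundance numeric matrix, depths x taxa, fractions in [0, 1]
#'   summing to <= 1 per depth.
#'
#' @seealso [communityTable()], [generateCommunity()]
#' @export
setClass("CommunityTable",
  representation(
    depths = "numeric",
    archaeal16S = "numeric",
    bacterial16S = "numeric",
    functionalGenes = "list",
    relAbundance = "matrix"
  )
)

setValidity("CommunityTable", function(object) {
  msg <- character()
  n <- length(object@depths)
  if (n > 1 && any(diff(object@depths) <= 0))
    msg <- c(msg, "depths must be strictly increasing")
  for (s in c("archaeal16S", "bacterial16S")) {
    v <- slot(object, s)
    if (length(v) != n) msg <- c(msg, sprintf("'%s' must match depths", s))
    if (any(v < 0, na.rm = TRUE)) msg <- c(msg, sprintf("'%s' must be >= 0", s))
  }
  ra <- object@relAbundance
  if (nrow(ra) != n) msg <- c(msg, "'relAbundance' must have one row per depth")
  if (length(ra) && (any(ra < 0, na.rm = TRUE) || any(ra > 1, na.rm = TRUE)))
    msg <- c(msg, "relative abundances must lie in [0, 1]")
  if (length(ra) && any(rowSums(ra, na.rm = TRUE) > 1 + 1e-8))
    msg <- c(msg, "per-depth relative abundances must sum to <= 1")
  for (g in object@functionalGenes) {
    if (!all(c("depth", "copies", "sd") %in% names(g)))
      msg <- c(msg, "functional gene entries need depth/copies/sd columns")
    else if (any(g$copies < 0, na.rm = TRUE) || any(g$sd < 0, na.rm = TRUE))
      msg <- c(msg, "functional gene copies and sd must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Anammox family niche-partitioning metrics
#'
#' Peak depths of the absolute-abundance maxima of two anammox families, the
#' vertical separation between them, and the duration of the partitioning
#' implied by the sedimentation rate (depth separation divided by the rate).
#'
#' @slot familyPeaks numeric matrix, one row per family with columns
#'   \code{depth} (cm) and \code{cells} (cells per g).
#' @slot separation vertical separation of the two peaks, cm (>= 0).
#' @slot sedimentationRate cm per kyr; \code{NA} when unknown.
#' @slot duration separation / rate, years; \code{NA} without a rate.
#' @slot zonesHit named character: zone label containing each peak (empty
#'   when no [ZoneSet-class] was supplied).
#'
#' @seealso [familyPeaks()], [partitionDuration()]
#' @export
setClass("NichePartitionResult",
  representation(
    familyPeaks = "matrix",
    separation = "numeric",
    sedimentationRate = "numeric",
    duration = "numeric",
    zonesHit = "character"
  )
)

setValidity("NichePartitionResult", function(object) {
  msg <- character()
  if (is.finite(object@separation) && object@separation < 0)
    msg <- c(msg, "'separation' must be >= 0")
  if (is.finite(object@duration) && is.finite(object@separation) &&
      is.finite(object@sedimentationRate)) {
    want <- object@separation / object@sedimentationRate * 1000
    if (!isTRUE(all.equal(object@duration, want)))
      msg <- c(msg, "'duration' must equal separation/rate in years")
  }
  if (length(msg)) msg else TRUE
})

#' Specification of a steady-state reaction-diffusion truth
#'
#' Everything needed to forward-generate a synthetic porewater profile: the
#' depth domain and grid, ordered internal zone boundaries, a per-zone net
#' reaction rate per solute (constant within each zone; negative means
#' consumption, in mmol per m3 of porewater per yr), Dirichlet concentration
#' boundary conditions at the core top and bottom, a constant porosity, the
#' solute specifications, the additive measurement noise, and the RNG seed.
#'
#' @slot length core length L, cm.
#' @slot spacing grid spacing h, cm (> 0).
#' @slot boundaries ordered internal zone boundaries, cm, strictly inside
#'   (0, L).
#' @slot rates named list, solute -> numeric of per-zone rates (length =
#'   number of zones = length(boundaries) + 1), mmol m-3 yr-1.
#' @slot bcTop,bcBottom named numerics, solute -> concentration (uM) at z = 0
#'   and z = L.
#' @slot porosity single value in (0, 1].
#' @slot solutes named list of [SoluteSpec-class].
#' @slot noiseSd additive Gaussian noise sd, uM (>= 0).
#' @slot temperature,salinity,pressure bottom-water conditions used for the
#'   diffusivities.
#' @slot seed integer RNG seed.
#'
#' @seealso [syntheticScenario()], [solveSteadyState()], [generateProfile()]
#' @export
setClass("SyntheticScenario",
  representation(
    length = "numeric",
    spacing = "numeric",
    boundaries = "numeric",
    rates = "list",
    bcTop = "numeric",
    bcBottom = "numeric",
    porosity = "numeric",
    solutes = "list",
    noiseSd = "numeric",
    temperature = "numeric",
    salinity = "numeric",
    pressure = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticScenario", function(object) {
  msg <- character()
  L <- object@length
  if (length(L) != 1L || L <= 0) msg <- c(msg, "'length' must be positive")
  if (length(object@spacing) != 1L || object@spacing <= 0)
    msg <- c(msg, "'spacing' must be positive")
  b <- object@boundaries
  if (length(b) && (any(diff(b) <= 0) || any(b <= 0) || any(b >= L)))
    msg <- c(msg, "zone boundaries must be strictly increasing inside (0, L)")
  nz <- length(b) + 1L
  for (nm in names(object@rates)) {
    if (length(object@rates[[nm]]) != nz)
      msg <- c(msg, sprintf("rates for '%s' must have one value per zone", nm))
    if (!nm %in% names(object@solutes))
      msg <- c(msg, sprintf("no SoluteSpec for rate series '%s'", nm))
    if (!(nm %in% names(object@bcTop)) || !(nm %in% names(object@bcBottom)))
      msg <- c(msg, sprintf("missing boundary condition for '%s'", nm))
  }
  if (length(object@porosity) != 1L || object@porosity <= 0 ||
      object@porosity > 1)
    msg <- c(msg, "'porosity' must be a single value in (0, 1]")
  if (object@noiseSd < 0) msg <- c(msg, "'noiseSd' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Analytic solution of a synthetic scenario
#'
#' Closed-form piecewise-quadratic steady-state solution of a
#' [SyntheticScenario-class]: per-zone polynomial coefficients, exact
#' diffusive fluxes at the core top, the core bottom, and every internal zone
#' boundary, and the sediment diffusivity used per solute. Serves as the
#' independent ground truth ("oracle") for the zonation and flux estimators.
#'
#' @slot scenario the generating [SyntheticScenario-class].
#' @slot coefficients named list, solute -> matrix of per-zone (a, b, c) with
#'   C(z) = a + b z + c z^2, z in metres.
#' @slot fluxes named list, solute -> numeric of signed fluxes phi Ds dC/dz
#'   (mmol m-2 yr-1) evaluated at c(0, boundaries, L).
#' @slot Ds named numeric, sediment diffusivity per solute, m2 yr-1.
#'
#' @seealso [solveSteadyState()], [truthConcentration()], [truthFlux()]
#' @export
setClass("ScenarioTruth",
  representation(
    scenario = "SyntheticScenario",
    coefficients = "list",
    fluxes = "list",
    Ds = "numeric"
  )
)
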