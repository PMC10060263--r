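#' Create a SoluteSpec
#'
#' @param name solute name.
#' @param m0,m1 linear infinite-dilution diffusivity coefficients,
#'   1e-6 cm^2/s and 1e-6 cm^2/s per degree C.
#' @param detectionLimit detection limit, uM.
#' @return a [SoluteSpec-class].
#' @examples
#' soluteSpec("nitrate", 9.5, 0.388, 0.1)
#' @export
soluteSpec <- function(name, m0, m1, detectionLimit = 0) {
  new("SoluteSpec", name = name, m0 = m0, m1 = m1,
      detectionLimit = detectionLimit)
}

#' Default solute set
#'
#' The four porewater solutes the pipeline knows about, with
#' infinite-dilution diffusivity coefficients from the published linear fits
#' to tracer-diffusion tables (nitrate, nitrite, ammonium) and a linear fit
#' to dissolved-oxygen tables, plus default detection limits (0.1 uM for the
#' nitrogen species, 2 uM for the optode oxygen measurement), all typical for
#' the colorimetric/optode methods used at sea and configurable per solute.
#'
#' @param detectionLimits optional named numeric overriding detection limits
#'   (uM) by solute name.
#' @return named list of [SoluteSpec-class].
#' @examples
#' defaultSolutes()
#' defaultSolutes(c(nitrite = 0.05))
#' @export
defaultSolutes <- function(detectionLimits = NULL) {
  sol <- list(
    nitrate  = soluteSpec("nitrate",  9.50, 0.388, 0.1),
    nitrite  = soluteSpec("nitrite",  10.3, 0.331, 0.1),
    ammonium = soluteSpec("ammonium", 9.50, 0.413, 0.1),
    oxygen   = soluteSpec("oxygen",   11.0, 0.470, 2.0)
  )
  if (!is.null(detectionLimits)) {
    for (nm in names(detectionLimits)) {
      if (!nm %in% names(sol))
        .stopf("unknown solute '%s' in detectionLimits", nm)
      sol[[nm]]@detectionLimit <- unname(detectionLimits[[nm]])
    }
  }
  sol
}

#' Create site metadata
#'
#' Missing environmental fields fall back to deep-sea bottom-water defaults:
#' temperature 2 C, salinity 35, and hydrostatic pressure computed from the
#' water depth (1 atm + ~1 bar per 10 m).
#'
#' @param siteId site identifier.
#' @param latitude,longitude decimal degrees.
#' @param waterDepth metres.
#' @param bottomTemperature degrees Celsius.
#' @param salinity practical salinity.
#' @param pressure bar; computed hydrostatically from \code{waterDepth} when
#'   omitted.
#' @param sedimentationRate cm per kyr.
#' @param sourceLabel provenance tag.
#' @return a [SiteMetadata-class].
#' @examples
#' siteMetadata("GS14-like", waterDepth = 1050, sedimentationRate = 2)
#' @export
siteMetadata <- function(siteId = "site", latitude = NA_real_,
                         longitude = NA_real_, waterDepth = NA_real_,
                         bottomTemperature = 2, salinity = 35,
                         pressure = NULL, sedimentationRate = NA_real_,
                         sourceLabel = "") {
  if (is.null(pressure)) {
    pressure <- if (is.finite(waterDepth)) 1.013253 + waterDepth / 10
                else 1.013253
  }
  new("SiteMetadata", siteId = siteId, latitude = latitude,
      longitude = longitude, waterDepth = waterDepth,
      bottomTemperature = bottomTemperature, salinity = salinity,
      pressure = pressure, sedimentationRate = sedimentationRate,
      sourceLabel = sourceLabel)
}

#' Create a depth profile
#'
#' @param depth depths, cm below seafloor, strictly increasing.
#' @param conc matrix or data.frame of concentrations (uM), one column per
#'   solute, named.
#' @param censored logical matrix of the same shape; defaults to nothing
#'   censored. Censored cells are stored with concentration 0.
#' @param porosity per-depth porosity in (0, 1]; a single value is recycled.
#' @param solutes named list of [SoluteSpec-class]; defaults fill in any
#'   column matching a default solute name.
#' @param site a [SiteMetadata-class].
#' @return a [DepthProfile-class].
#' @examples
#' depthProfile(c(0, 10, 20),
#'              cbind(nitrate = c(20, 10, 0.5)), porosity = 0.7)
#' @export
depthProfile <- function(depth, conc, censored = NULL, porosity = 0.7,
                         solutes = defaultSolutes(), site = siteMetadata()) {
  conc <- as.matrix(conc)
  if (is.null(colnames(conc))) .stopf("'conc' must have solute column names")
  if (is.null(censored))
    censored <- matrix(FALSE, nrow(conc), ncol(conc),
                       dimnames = dimnames(conc))
  censored <- as.matrix(censored)
  dimnames(censored) <- dimnames(conc)
  conc[censored] <- 0
  if (length(porosity) == 1L) porosity <- rep(porosity, length(depth))
  missing <- setdiff(colnames(conc), names(solutes))
  if (length(missing))
    .stopf("no SoluteSpec for column(s): %s", paste(missing, collapse = ", "))
  new("DepthProfile", site = site, depth = as.numeric(depth), conc = conc,
      censored = censored, porosity = as.numeric(porosity),
      solutes = solutes[colnames(conc)])
}

#' Create a community table
#'
#' @param depths cm below seafloor, strictly increasing.
#' @param archaeal16S,bacterial16S gene copies per g wet sediment.
#' @param relAbundance matrix or data.frame, depths x taxa, fractions.
#' @param functionalGenes named list, gene -> data.frame(depth, copies, sd).
#' @return a [CommunityTable-class].
#' @export
communityTable <- function(depths, archaeal16S, bacterial16S,
                           relAbundance, functionalGenes = list()) {
  ra <- as.matrix(relAbundance)
  new("CommunityTable", depths = as.numeric(depths),
      archaeal16S = as.numeric(archaeal16S),
      bacterial16S = as.numeric(bacterial16S),
      functionalGenes = functionalGenes, relAbundance = ra)
}

#' Create a synthetic reaction-diffusion scenario
#'
#' Defines a 1-D steady-state diagenetic truth on \code{[0, length]} cm with
#' piecewise-constant net reaction rates. Solutes without a rate series get
#' zero reaction in every zone. See [solveSteadyState()] for the governing
#' equation and [generateProfile()] for sampling.
#'
#' @param length core length L, cm.
#' @param spacing sampling grid spacing h, cm.
#' @param boundaries internal zone boundaries, cm, strictly increasing inside
#'   (0, L).
#' @param rates named list, solute -> per-zone net reaction rate (mmol per m3
#'   porewater per yr; negative = consumption).
#' @param bcTop,bcBottom named numerics, boundary concentrations (uM) at the
#'   sediment surface and the core bottom.
#' @param porosity constant porosity in (0, 1].
#' @param solutes named list of [SoluteSpec-class].
#' @param noiseSd additive Gaussian measurement noise sd, uM.
#' @param temperature,salinity,pressure bottom-water conditions for the
#'   diffusivities.
#' @param seed RNG seed (integer) consumed by [generateProfile()].
#' @return a [SyntheticScenario-class].
#' @examples
#' syntheticScenario(100, 2, boundaries = 50,
#'                   rates = list(nitrate = c(-1, 0)),
#'                   bcTop = c(nitrate = 15), bcBottom = c(nitrate = 0))
#' @export
syntheticScenario <- function(length, spacing, boundaries = numeric(),
                              rates, bcTop, bcBottom, porosity = 0.7,
                              solutes = defaultSolutes(), noiseSd = 0,
                              temperature = 2, salinity = 35,
                              pressure = 1.013253, seed = 1L) {
  nz <- base::length(boundaries) + 1L
  for (nm in names(rates)) {
    if (base::length(rates[[nm]]) == 1L)
      rates[[nm]] <- rep(rates[[nm]], nz)
  }
  new("SyntheticScenario", length = length, spacing = spacing,
      boundaries = as.numeric(boundaries), rates = rates,
      bcTop = bcTop, bcBottom = bcBottom, porosity = porosity,
      solutes = solutes, noiseSd = noiseSd, temperature = temperature,
      salinity = salinity, pressure = pressure, seed = as.integer(seed))
}
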