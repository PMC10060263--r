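# Forward generation: closed-form 1-D steady-state reaction-diffusion
# solutions, noisy sampled profiles, and synthetic community tables.

#' Solve a scenario's steady state in closed form
#'
#' Solves, per solute, the 1-D steady-state diagenetic equation
#' \deqn{\frac{d}{dz}\left(\varphi D_s \frac{dC}{dz}\right) + \varphi R = 0}
#' on \code{[0, L]} with piecewise-constant net reaction rates R (per m3 of
#' porewater), constant porosity and diffusivity, and Dirichlet ends. The
#' solution is piecewise quadratic, \eqn{C_k(z) = a_k + b_k z + c_k z^2}
#' with \eqn{c_k = -R_k/(2 D_s)}; the \eqn{(a_k, b_k)} come from a linear
#' system enforcing concentration and flux continuity at the internal zone
#' boundaries. Scenarios whose solution goes negative anywhere are rejected,
#' as are degenerate interface systems.
#'
#' @param scenario a [SyntheticScenario-class].
#' @return a [ScenarioTruth-class] with per-zone coefficients (z in metres)
#'   and exact signed fluxes \eqn{\varphi D_s C'(z)} at the top, every
#'   internal boundary, and the bottom.
#' @examples
#' sc <- syntheticScenario(100, 2, rates = list(nitrate = 0),
#'                         bcTop = c(nitrate = 10), bcBottom = c(nitrate = 0))
#' solveSteadyState(sc)  # linear profile, constant flux
#' @export
solveSteadyState <- function(scenario) {
  validObject(scenario)
  edgesM <- .cm2m(c(0, scenario@boundaries, scenario@length))
  K <- length(edgesM) - 1L
  phi <- scenario@porosity
  solNames <- names(scenario@bcTop)
  coefs <- list(); fluxes <- list(); DsAll <- numeric()

  for (nm in solNames) {
    spec <- scenario@solutes[[nm]]
    if (is.null(spec)) .stopf("scenario error: no SoluteSpec for '%s'", nm)
    d0 <- d0InfiniteDilution(spec, scenario@temperature, scenario@salinity,
                             scenario@pressure)
    Ds <- sedimentDiffusivity(d0, phi)
    R <- scenario@rates[[nm]]
    if (is.null(R)) R <- rep(0, K)
    cc <- -R / (2 * Ds)  # known quadratic coefficients per zone

    # unknowns x = (a_1, b_1, ..., a_K, b_K)
    A <- matrix(0, 2 * K, 2 * K)
    rhs <- numeric(2 * K)
    A[1, 1:2] <- c(1, edgesM[1]); rhs[1] <- scenario@bcTop[[nm]] -
      cc[1] * edgesM[1]^2
    row <- 2L
    for (k in seq_len(K - 1L)) {
      zi <- edgesM[k + 1L]
      ia <- 2L * k - 1L
      A[row, ia:(ia + 3L)] <- c(1, zi, -1, -zi)
      rhs[row] <- (cc[k + 1L] - cc[k]) * zi^2
      row <- row + 1L
      A[row, ia:(ia + 3L)] <- c(0, 1, 0, -1)
      rhs[row] <- 2 * (cc[k + 1L] - cc[k]) * zi
      row <- row + 1L
    }
    L <- edgesM[K + 1L]
    A[row, (2L * K - 1L):(2L * K)] <- c(1, L)
    rhs[row] <- scenario@bcBottom[[nm]] - cc[K] * L^2

    ab <- tryCatch(solve(A, rhs), error = function(e)
      .stopf("scenario error: singular interface system for '%s'", nm))
    coef <- cbind(a = ab[seq(1, 2 * K, by = 2)],
                  b = ab[seq(2, 2 * K, by = 2)], c = cc)

    # positivity check: per zone the quadratic's minimum over the zone
    for (k in seq_len(K)) {
      zl <- edgesM[k]; zr <- edgesM[k + 1L]
      vals <- coef[k, "a"] + coef[k, "b"] * c(zl, zr) +
        coef[k, "c"] * c(zl, zr)^2
      if (coef[k, "c"] != 0) {
        zv <- -coef[k, "b"] / (2 * coef[k, "c"])
        if (zv > zl && zv < zr)
          vals <- c(vals, coef[k, "a"] + coef[k, "b"] * zv +
                      coef[k, "c"] * zv^2)
      }
      if (min(vals) < -1e-9 * max(1, abs(scenario@bcTop[[nm]]),
                                  abs(scenario@bcBottom[[nm]])))
        .stopf("scenario error: negative %s concentration (zone %d); adjust rates or boundaries",
               nm, k)
    }

    # signed flux phi Ds C'(z) at every edge (continuous at interfaces)
    J <- vapply(seq_len(K + 1L), function(i) {
      k <- min(max(i - 1L, 1L), K)  # zone left of edge i (zone 1 for top)
      phi * Ds * (coef[k, "b"] + 2 * coef[k, "c"] * edgesM[i])
    }, numeric(1))

    coefs[[nm]] <- coef
    fluxes[[nm]] <- J
    DsAll[nm] <- Ds
  }
  new("ScenarioTruth", scenario = scenario, coefficients = coefs,
      fluxes = fluxes, Ds = DsAll)
}

#' Analytic concentration of a scenario truth
#'
#' @param truth a [ScenarioTruth-class].
#' @param solute solute name.
#' @param depth depths, cm below seafloor (vectorised).
#' @return concentrations, uM.
#' @export
truthConcentration <- function(truth, solute, depth) {
  sc <- truth@scenario
  edges <- c(0, sc@boundaries, sc@length)
  coef <- truth@coefficients[[solute]]
  if (is.null(coef)) .stopf("no truth for solute '%s'", solute)
  zM <- .cm2m(depth)
  k <- findInterval(depth, edges, rightmost.closed = TRUE,
                    all.inside = TRUE)
  unname(coef[k, "a"] + coef[k, "b"] * zM + coef[k, "c"] * zM^2)
}

#' Analytic diffusive flux of a scenario truth
#'
#' Signed flux \eqn{\varphi D_s \, dC/dz} (depth positive downward),
#' mmol m-2 yr-1, at arbitrary depth.
#'
#' @inheritParams truthConcentration
#' @return signed fluxes, mmol m-2 yr-1.
#' @export
truthFlux <- function(truth, solute, depth) {
  sc <- truth@scenario
  edges <- c(0, sc@boundaries, sc@length)
  coef <- truth@coefficients[[solute]]
  if (is.null(coef)) .stopf("no truth for solute '%s'", solute)
  zM <- .cm2m(depth)
  k <- findInterval(depth, edges, rightmost.closed = TRUE, all.inside = TRUE)
  unname(sc@porosity * truth@Ds[[solute]] *
           (coef[k, "b"] + 2 * coef[k, "c"] * zM))
}

#' Generate a noisy censored profile from a scenario
#'
#' Samples the analytic steady state on the regular grid, adds independent
#' Gaussian measurement noise (sd \code{noiseSd}) from the scenario's seeded
#' generator, truncates at zero, and applies detection-limit censoring. All
#' stochastic draws consume one generator seeded from the scenario: one
#' vector of normals per solute, in the order the solutes appear in the
#' boundary conditions — so identical scenarios give byte-identical output.
#'
#' @param scenario a [SyntheticScenario-class].
#' @param truth optional pre-computed [ScenarioTruth-class].
#' @return list with \code{profile} (a censored [DepthProfile-class]) and
#'   \code{truth} (the [ScenarioTruth-class]).
#' @examples
#' out <- generateProfile(presetScenario("GS14-like"))
#' deriveZones(out$profile)
#' @export
generateProfile <- function(scenario, truth = NULL) {
  if (is.null(truth)) truth <- solveSteadyState(scenario)
  z <- seq(0, scenario@length, by = scenario@spacing)
  solNames <- names(scenario@bcTop)
  conc <- matrix(0, length(z), length(solNames),
                 dimnames = list(NULL, solNames))
  for (nm in solNames) conc[, nm] <- truthConcentration(truth, nm, z)
  if (scenario@noiseSd > 0) {
    withr::with_seed(scenario@seed, {
      for (nm in solNames)
        conc[, nm] <- conc[, nm] +
          stats::rnorm(length(z), sd = scenario@noiseSd)
    })
  }
  conc[conc < 0] <- 0
  site <- siteMetadata(siteId = "synthetic",
                       bottomTemperature = scenario@temperature,
                       salinity = scenario@salinity,
                       pressure = scenario@pressure,
                       sedimentationRate = 2,
                       sourceLabel = "synthetic scenario")
  prof <- depthProfile(z, conc, porosity = scenario@porosity,
                       solutes = scenario@solutes, site = site)
  prof <- censorToDetection(prof)
  list(profile = prof, truth = truth)
}

#' Named preset scenarios
#'
#' Two ready-made reaction-diffusion truths exercising the two observed
#' core topologies:
#' \describe{
#'   \item{GS14-like}{vertically separated NATZ: oxygen consumed in a thin
#'     surface zone, nitrate consumed down to ~130 cm, a nitrite source zone
#'     (90-120 cm) flanked by two nitrite sinks, and ammonium held below
#'     detection until ~212 cm by a deep consumption zone.}
#'   \item{GS16-like}{overlapping NATZ: deeper oxygen penetration, nitrate
#'     depleting near ~190 cm, a smaller nitrite bump (150-200 cm), and
#'     ammonium already appearing near ~120 cm, above the nitrate depletion
#'     depth.}
#' }
#' Rates were chosen once to give non-negative solutions with magnitudes in
#' the range of deep-sea porewater observations (nitrite maxima of a few uM,
#' nitrate tens of uM).
#'
#' @param name \code{"GS14-like"} or \code{"GS16-like"}.
#' @param spacing grid spacing, cm (default 2).
#' @param noiseSd additive noise sd, uM (default 0).
#' @param seed RNG seed.
#' @return a [SyntheticScenario-class].
#' @export
presetScenario <- function(name = c("GS14-like", "GS16-like"), spacing = 2,
                           noiseSd = 0, seed = 1L) {
  name <- match.arg(name)
  temperature <- 2; salinity <- 35; pressure <- 1.013253 + 1050 / 10
  phi <- 0.7
  sol <- defaultSolutes()
  DsOf <- function(nm) sedimentDiffusivity(
    d0InfiniteDilution(sol[[nm]], temperature, salinity, pressure), phi)

  # Rate of a single zeroth-order consumption zone [0, zB] (m) that brings a
  # surface concentration C0 down to c1 at zB, with a reaction-free linear
  # tail to 0 at L (from concentration + flux continuity at zB):
  surfaceSink <- function(nm, C0, zB, L, c1) {
    u <- (C0 - c1 * (1 + zB / (L - zB))) / zB^2
    2 * DsOf(nm) * u
  }
  # Rate of a deep consumption zone [zA, zB] (m) that keeps the upward
  # ammonium leak to a residual linear slope s (uM/m) above zA, given the
  # bottom boundary concentration Cb at L:
  deepSink <- function(nm, zA, zB, L, Cb, s) {
    d2 <- zB - zA; d3 <- L - zB
    u <- (Cb - s * L) / (d2 * (d2 + 2 * d3))
    2 * DsOf(nm) * u
  }

  if (name == "GS14-like") {
    # zones: [0,24,50,90,120,130,134,180,212,240] cm
    boundaries <- c(24, 50, 90, 120, 130, 134, 180, 212)
    rO2 <- surfaceSink("oxygen", 15, 0.24, 2.4, 1.8)
    # Nitrate: a steep limb from 12 uM at the surface reaching the 0.1 uM
    # detection limit at 130 cm with slope 5 uM/m (mild curvature c = 1 in
    # the 40 cm above the crossing so the three-point window reads the
    # boundary flux), then a thin intense sink over 130-134 cm whose vertex
    # lands exactly at zero (c = s/(2*0.04) with drop s*0.04/2 = DL), and a
    # reaction-free zero tail below. Curvatures c here are in uM/m^2;
    # volumetric rates are r = 2 Ds c.
    sNO3 <- 5; cB <- 1
    c09 <- 0.1 + sNO3 * 0.4 + cB * 0.16      # concentration at 90 cm
    s09 <- -sNO3 - 2 * cB * 0.4              # slope at 90 cm
    cA <- (12 + 0.9 * s09 - c09) / 0.81      # limb curvature, 0-90 cm
    cS <- sNO3 / (2 * 0.04)                  # 130-134 cm sink
    DsNO3 <- DsOf("nitrate")
    rNO3a <- 2 * DsNO3 * cA; rNO3b <- 2 * DsNO3 * cB
    rNO3s <- 2 * DsNO3 * cS
    rNH4 <- deepSink("ammonium", 1.80, 2.12, 2.4, 25, 0.04)
    rates <- list(
      oxygen   = c(-rO2, 0, 0, 0, 0, 0, 0, 0, 0),
      nitrate  = c(-rNO3a, -rNO3a, -rNO3a, -rNO3b, -rNO3b, -rNO3s, 0, 0, 0),
      nitrite  = c(0, -0.168, -0.168, 0.84, -0.168, -0.168, -0.168, 0, 0),
      ammonium = c(0, 0, 0, 0, 0, 0, 0, -rNH4, 0)
    )
    bcTop <- c(oxygen = 15, nitrate = 12, nitrite = 0, ammonium = 0)
    bcBottom <- c(oxygen = 0, nitrate = 0, nitrite = 0, ammonium = 25)
  } else {
    # zones: [0,110,120,150,170,185,190,200,240] cm
    boundaries <- c(110, 120, 150, 170, 185, 190, 200)
    rO2 <- surfaceSink("oxygen", 40, 1.10, 2.4, 1.8)
    rNO3 <- surfaceSink("nitrate", 14, 1.90, 2.4, 0.09)
    rNH4 <- deepSink("ammonium", 1.10, 1.20, 2.4, 18, 0.04)
    rates <- list(
      oxygen   = c(-rO2, 0, 0, 0, 0, 0, 0, 0),
      nitrate  = c(-rNO3, -rNO3, -rNO3, -rNO3, -rNO3, -rNO3, 0, 0),
      nitrite  = c(0, 0, 0, -0.5, 1.5, -0.75, -0.75, 0),
      ammonium = c(0, -rNH4, 0, 0, 0, 0, 0, 0)
    )
    bcTop <- c(oxygen = 40, nitrate = 14, nitrite = 0, ammonium = 0)
    bcBottom <- c(oxygen = 0, nitrate = 0, nitrite = 0, ammonium = 18)
  }
  syntheticScenario(240, spacing, boundaries = boundaries, rates = rates,
                    bcTop = bcTop, bcBottom = bcBottom, porosity = phi,
                    solutes = sol, noiseSd = noiseSd,
                    temperature = temperature, salinity = salinity,
                    pressure = pressure, seed = seed)
}

#' Generate a synthetic community table
#'
#' Builds per-depth expected community composition as Gaussian
#' depth-profiles ("bumps") for the named families over a background simplex
#' of nuisance taxa, draws observed counts multinomially at a fixed read
#' depth (emulating subsampling each horizon to the same number of reads),
#' derives total cell counts as a log-linear decline from the surface value,
#' and derives a qPCR series for the anammox marker gene from the truth with
#' lognormal noise. Stochastic draws consume one seeded generator in a fixed
#' order: background weights, per-depth multinomial counts (shallow to
#' deep), then the qPCR noise.
#'
#' @param depths sampled depths, cm.
#' @param families named list, family -> c(peak = cm, fraction = peak
#'   relative abundance, width = Gaussian sd in cm).
#' @param backgroundTaxa number of nuisance taxa filling the remainder.
#' @param totalCellsSurface total cells per g at the surface.
#' @param decayPerCm fractional decline of total cells per cm of depth.
#' @param readDepth reads per horizon after subsampling (default 20000).
#' @param qpcrSdLog sdlog of the lognormal qPCR noise on the anammox marker
#'   gene series.
#' @param archaealFraction fraction of total 16S copies assigned to
#'   archaea.
#' @param seed RNG seed.
#' @return list with \code{table} (a [CommunityTable-class]) and
#'   \code{truth} (expected fractions matrix and total cells).
#' @examples
#' out <- generateCommunity(seq(0, 240, 20),
#'   families = list(Scalinduaceae = c(peak = 160, fraction = 0.18, width = 30),
#'                   Bathyanammoxibiaceae = c(peak = 50, fraction = 0.11, width = 25)))
#' out$table
#' @export
generateCommunity <- function(depths,
                              families = list(
                                Scalinduaceae =
                                  c(peak = 160, fraction = 0.18, width = 30),
                                Bathyanammoxibiaceae =
                                  c(peak = 50, fraction = 0.11, width = 25)),
                              backgroundTaxa = 20,
                              totalCellsSurface = 1e9, decayPerCm = 0.02,
                              readDepth = 20000, qpcrSdLog = 0.3,
                              archaealFraction = 0.2, seed = 1L) {
  if (readDepth <= 0) .stopf("read_depth must be positive")
  depths <- sort(as.numeric(depths))
  nd <- length(depths)
  fam <- names(families)
  expected <- matrix(0, nd, length(fam) + backgroundTaxa,
                     dimnames = list(NULL, c(fam,
                       sprintf("background_%02d", seq_len(backgroundTaxa)))))
  for (f in fam) {
    p <- families[[f]]
    expected[, f] <- p[["fraction"]] *
      exp(-(depths - p[["peak"]])^2 / (2 * p[["width"]]^2))
  }
  famSum <- rowSums(expected[, fam, drop = FALSE])
  if (any(famSum > 1))
    .stopf("scenario error: family fractions exceed 1 at depth %.4g cm",
           depths[which(famSum > 1)[1L]])

  totalCells <- totalCellsSurface * (1 - decayPerCm)^depths
  anammoxTruth <- famSum * totalCells

  counts <- matrix(0L, nd, ncol(expected), dimnames = dimnames(expected))
  hzo <- numeric(nd)
  withr::with_seed(as.integer(seed), {
    w <- stats::rgamma(backgroundTaxa, shape = 1)
    w <- w / sum(w)
    for (i in seq_len(nd)) {
      expected[i, -seq_along(fam)] <- (1 - famSum[i]) * w
      counts[i, ] <- stats::rmultinom(1, readDepth, expected[i, ])
    }
    hzo <- anammoxTruth * stats::rlnorm(nd, meanlog = 0, sdlog = qpcrSdLog)
  })

  rel <- counts / readDepth
  tab <- communityTable(
    depths = depths,
    archaeal16S = archaealFraction * totalCells,
    bacterial16S = (1 - archaealFraction) * totalCells,
    relAbundance = rel,
    functionalGenes = list(
      hzo = data.frame(depth = depths, copies = hzo, sd = 0.1 * hzo)))
  list(table = tab,
       truth = list(expected = expected, totalCells = totalCells,
                    anammoxCells = anammoxTruth))
}
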