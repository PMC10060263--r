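# Diffusion coefficients, gradients, Fick's-law boundary fluxes, net
# reaction rates, and cross-site flux-ratio statistics.

#' Infinite-dilution diffusion coefficient at in-situ conditions
#'
#' Computes the free-solution diffusion coefficient of a solute from its
#' linear temperature model \eqn{D_0 = (m_0 + m_1 T) \times 10^{-6}}
#' cm\eqn{^2} s\eqn{^{-1}}, converts it to m\eqn{^2} yr\eqn{^{-1}}, and
#' corrects it from pure water to seawater at in-situ salinity and pressure
#' by the pure-water/seawater dynamic-viscosity ratio (Stokes-Einstein
#' scaling, [seawaterViscosity()]). \eqn{D_0} is monotonically increasing in
#' temperature for any solute with \eqn{m_1 > 0}.
#'
#' @param solute a [SoluteSpec-class].
#' @param temperature degrees Celsius. Values outside the linear model's
#'   calibration range (default -2 to 30) trigger an extrapolation warning.
#' @param salinity practical salinity.
#' @param pressure bar.
#' @param calibrationRange length-2 numeric, degrees C.
#' @return D0 in m^2 yr^-1.
#' @examples
#' d0InfiniteDilution(defaultSolutes()$nitrate, 25, salinity = 0)
#' @export
d0InfiniteDilution <- function(solute, temperature, salinity = 35,
                               pressure = 1.013253,
                               calibrationRange = c(-2, 30)) {
  if (temperature < calibrationRange[1] || temperature > calibrationRange[2])
    .warnf("temperature %.3g C outside the linear model's calibration range [%g, %g]; extrapolating",
           temperature, calibrationRange[1], calibrationRange[2])
  d0fw <- (solute@m0 + solute@m1 * temperature) * D0_UNIT_TO_M2YR
  ratio <- seawaterViscosity(temperature, 0, 1.013253) /
    seawaterViscosity(temperature, salinity, pressure)
  d0fw * ratio
}

#' Sediment diffusivity from porosity
#'
#' Tortuosity correction of the free-solution diffusivity. The default is
#' \eqn{D_s = D_0 / (1 - \ln \varphi^2)}, the standard correction used with
#' porewater flux tooling; the Archie power-law alternative
#' \eqn{D_s = D_0 \varphi^{m-1}} is available via \code{model = "power"}.
#' Both satisfy \eqn{D_s \le D_0}, \eqn{D_s \to D_0} as \eqn{\varphi \to 1},
#' and are strictly increasing in porosity.
#'
#' @param D0 free-solution diffusivity, m^2 yr^-1.
#' @param porosity porosity in (0, 1].
#' @param model \code{"log"} (default) or \code{"power"}.
#' @param m Archie exponent for the power model (default 2).
#' @return Ds, m^2 yr^-1.
#' @examples
#' sedimentDiffusivity(0.03, 0.6)  # 0.03 / (1 - ln 0.36)
#' @export
sedimentDiffusivity <- function(D0, porosity, model = c("log", "power"),
                                m = 2) {
  model <- match.arg(model)
  if (any(porosity <= 0) || any(porosity > 1))
    .stopf("domain error: porosity must lie in (0, 1]")
  switch(model,
    log = D0 / (1 - log(porosity^2)),
    power = D0 * porosity^(m - 1))
}

# Closed-form OLS slope and intercept of conc (mmol/m3) on depth (m).
.olsSlope <- function(zM, conc) {
  zbar <- mean(zM); cbar <- mean(conc)
  sxx <- sum((zM - zbar)^2)
  if (sxx == 0) .stopf("gradient error: need >= 2 distinct depths")
  slope <- sum((zM - zbar) * (conc - cbar)) / sxx
  n <- length(zM)
  resid <- conc - cbar - slope * (zM - zbar)
  se <- if (n > 2) sqrt(sum(resid^2) / (n - 2) / sxx) else NA_real_
  list(slope = slope, se = se)
}

#' Local concentration gradient from a three-point window
#'
#' Ordinary least-squares slope of concentration (mmol m\eqn{^{-3}}, i.e.
#' uM) against depth (m) over exactly three consecutive sampled depths — the
#' "nearby three data points" gradient. Censored points enter at their
#' stored (zero) concentration and are flagged in the output.
#'
#' @param profile a [DepthProfile-class].
#' @param solute solute name.
#' @param window integer vector of exactly 3 consecutive row indices.
#' @return list with \code{gradient} (mmol m-4), \code{se} (standard error),
#'   \code{points} (matrix depth_cm/conc_uM/censored), \code{meanDepth} (cm).
#' @examples
#' p <- depthProfile(c(0, 1, 2), cbind(nitrate = c(0, 1, 2)))
#' localGradient(p, "nitrate", 1:3)$gradient  # 1 uM/cm = 100 mmol m-4
#' @export
localGradient <- function(profile, solute, window) {
  if (length(window) != 3L || any(diff(window) != 1L))
    .stopf("gradient error: window must be 3 consecutive indices")
  n <- length(profile@depth)
  if (any(window < 1L) || any(window > n))
    .stopf("gradient error: window out of range (profile has %d depths)", n)
  if (!solute %in% colnames(profile@conc))
    .stopf("configuration error: solute '%s' absent from profile", solute)
  zM <- .cm2m(profile@depth[window])
  conc <- profile@conc[window, solute]
  fit <- .olsSlope(zM, conc)
  list(gradient = fit$slope, se = fit$se,
       points = cbind(depth_cm = profile@depth[window], conc_uM = conc,
                      censored = as.numeric(profile@censored[window, solute])),
       meanDepth = mean(profile@depth[window]))
}

#' Fick's-law diffusive flux
#'
#' \eqn{J = \varphi D_s \, \partial [C] / \partial z} with depth positive
#' downward. The sign is retained internally: a positive gradient
#' (concentration increasing downward) means the solute diffuses upward.
#' Reported quantities are the magnitude plus a direction label, since all
#' paper-facing fluxes (influx, effluxes, their ratio) are magnitudes.
#'
#' @param gradient concentration gradient, mmol m-4.
#' @param porosity porosity in (0, 1].
#' @param Ds sediment diffusivity, m^2 yr^-1 (> 0).
#' @return list with \code{J} (signed, mmol m-2 yr-1), \code{magnitude} and
#'   \code{direction} (\code{"upward"}, \code{"downward"} or \code{"none"}).
#' @examples
#' boundaryFlux(100, 0.8, 0.01)$magnitude  # 0.8 mmol m-2 yr-1
#' @export
boundaryFlux <- function(gradient, porosity, Ds) {
  if (porosity <= 0 || porosity > 1)
    .stopf("domain error: porosity must lie in (0, 1]")
  if (Ds <= 0) .stopf("domain error: Ds must be positive")
  J <- porosity * Ds * gradient
  list(J = J, magnitude = abs(J),
       direction = if (J > 0) "upward" else if (J < 0) "downward" else "none")
}

#' Discrete net reaction rate profile
#'
#' Steady-state diagenetic rate estimator: at each interior depth,
#' \eqn{R(z_i) = -\varphi D_s C''(z_i)} with the second derivative by
#' central differences on the (possibly non-uniform) grid. This is the net
#' volumetric rate per bulk sediment (mmol m\eqn{^{-3}} yr\eqn{^{-1}});
#' \eqn{R > 0} means net production, \eqn{R < 0} net consumption, and the
#' flux-divergence identity \eqn{J_{top} - J_{bottom} = \int R \, dz} holds
#' on smooth profiles up to discretization error. Endpoints are \code{NA}.
#'
#' @param profile a [DepthProfile-class] with at least 3 depths.
#' @param solute solute name.
#' @param Ds per-depth sediment diffusivity (m^2 yr^-1), a scalar, or
#'   \code{NULL} to compute it from the site metadata and porosity.
#' @param tortuosity tortuosity model passed to [sedimentDiffusivity()].
#' @return numeric vector of rates per depth (endpoints \code{NA}).
#' @export
netReactionRate <- function(profile, solute, Ds = NULL,
                            tortuosity = c("log", "power")) {
  tortuosity <- match.arg(tortuosity)
  z <- .cm2m(profile@depth)
  n <- length(z)
  if (n < 3L) .stopf("rate error: need at least 3 depths")
  conc <- concentrations(profile, solute)
  phi <- profile@porosity
  if (is.null(Ds)) {
    site <- profile@site
    d0 <- d0InfiniteDilution(profile@solutes[[solute]],
                             site@bottomTemperature, site@salinity,
                             site@pressure)
    Ds <- sedimentDiffusivity(d0, phi, model = tortuosity)
  }
  if (length(Ds) == 1L) Ds <- rep(Ds, n)
  R <- rep(NA_real_, n)
  for (i in 2:(n - 1L)) {
    hl <- z[i] - z[i - 1L]; hr <- z[i + 1L] - z[i]
    cdd <- 2 * ((conc[i + 1L] - conc[i]) / hr -
                (conc[i] - conc[i - 1L]) / hl) / (hl + hr)
    R[i] <- -phi[i] * Ds[i] * cdd
  }
  R
}

# Ds per solute at the site's bottom-water conditions.
.siteDs <- function(profile, solute, phi, tortuosity = "log") {
  site <- profile@site
  d0 <- d0InfiniteDilution(profile@solutes[[solute]], site@bottomTemperature,
                           site@salinity, site@pressure)
  sedimentDiffusivity(d0, phi, model = tortuosity)
}

.windowFlux <- function(profile, solute, window, tortuosity) {
  g <- localGradient(profile, solute, window)
  phi <- mean(profile@porosity[window])
  Ds <- .siteDs(profile, solute, phi, tortuosity)
  fl <- boundaryFlux(g$gradient, phi, Ds)
  c(fl, list(points = g$points, gradient = g$gradient, Ds = Ds, phi = phi,
             meanDepth = g$meanDepth))
}

#' Boundary fluxes and flux ratio for one site
#'
#' Computes the three Fick's-law boundary fluxes of the nitrate-depletion
#' zone and their ratio: the nitrate influx from the 3 points immediately
#' above the nitrate depletion crossing, the upward nitrite efflux from the
#' 3 shallowest points of the nitrite interval, the downward nitrite efflux
#' from its 3 deepest points, and
#' \eqn{r = (J_{NO_2,up} + J_{NO_2,down}) / J_{NO_3,in}} on magnitudes.
#' When nitrite is censored at every depth both effluxes and the ratio are
#' zero. Window anchoring is configurable because the gradient's exact
#' placement is a methodological choice: \code{"above"} uses the 3 detected
#' points above the crossing, \code{"bracketing"} shifts one point deeper so
#' the window brackets the crossing (the censored point enters at 0).
#'
#' @param profile a censored [DepthProfile-class].
#' @param zones a [ZoneSet-class]; derived from the profile when omitted.
#' @param tortuosity tortuosity model for [sedimentDiffusivity()].
#' @param anchor \code{"above"} (default) or \code{"bracketing"}.
#' @return a [FluxResult-class].
#' @examples
#' prof <- generateProfile(presetScenario("GS14-like"))$profile
#' siteFluxes(prof)
#' @export
siteFluxes <- function(profile, zones = NULL,
                       tortuosity = c("log", "power"),
                       anchor = c("above", "bracketing")) {
  tortuosity <- match.arg(tortuosity)
  anchor <- match.arg(anchor)
  if (is.null(zones)) zones <- deriveZones(profile)
  siteId <- profile@site@siteId

  if (!is.finite(zones@nitrateDepletionDepth))
    .stopf("flux error: nitrate depletion depth undefined for '%s'", siteId)
  z <- profile@depth
  ic <- which(z == zones@nitrateFirstCensoredDepth)[1L]
  if (is.na(ic))  # nitrate censored from the very top
    .stopf("flux error: nitrate window unavailable (no detected points above crossing)")
  no3win <- if (anchor == "above") (ic - 3L):(ic - 1L) else (ic - 2L):ic
  if (no3win[1L] < 1L)
    .stopf("flux error: nitrate window unavailable (needs 3 points above the crossing)")
  no3 <- .windowFlux(profile, "nitrate", no3win, tortuosity)

  nitriteAllCensored <- "nitrite" %in% colnames(profile@conc) &&
    all(profile@censored[, "nitrite"])
  if (nitriteAllCensored || !"nitrite" %in% colnames(profile@conc)) {
    windows <- list(nitrate_in = no3[c("points", "J", "direction", "Ds")])
    return(new("FluxResult", siteId = siteId, JNO3In = no3$magnitude,
               JNO2Up = 0, JNO2Down = 0, ratio = 0, windows = windows,
               DsUsed = c(nitrate = no3$Ds)))
  }

  iv <- findNitriteInterval(profile)
  i1 <- iv$indices[1L]; i2 <- iv$indices[2L]
  if (i2 - i1 + 1L < 3L)
    .stopf("flux error: nitrite windows unavailable (interval has < 3 points)")
  upWin <- i1:(i1 + 2L)
  downWin <- (i2 - 2L):i2
  if (anchor == "bracketing") {
    if (i1 > 1L) upWin <- (i1 - 1L):(i1 + 1L)
    if (i2 < length(z)) downWin <- (i2 - 1L):(i2 + 1L)
  }
  up <- .windowFlux(profile, "nitrite", upWin, tortuosity)
  down <- .windowFlux(profile, "nitrite", downWin, tortuosity)

  ratio <- (up$magnitude + down$magnitude) / no3$magnitude
  new("FluxResult", siteId = siteId,
      JNO3In = no3$magnitude, JNO2Up = up$magnitude,
      JNO2Down = down$magnitude, ratio = ratio,
      windows = list(
        nitrate_in = no3[c("points", "J", "direction", "Ds")],
        nitrite_up = up[c("points", "J", "direction", "Ds")],
        nitrite_down = down[c("points", "J", "direction", "Ds")]),
      DsUsed = c(nitrate = no3$Ds, nitrite = up$Ds))
}

#' Cross-site flux-ratio summary
#'
#' Arithmetic mean of the per-site nitrite/nitrate flux ratios and the
#' Student-t 95% confidence half-width
#' \eqn{t_{0.975, n-1} \, sd/\sqrt{n}}. With a single site the mean is that
#' site's ratio and the half-width is undefined (\code{NA}).
#'
#' @param results list of [FluxResult-class] (or a bare numeric vector of
#'   ratios, named by site).
#' @param outlierThreshold sites with ratio at or above this value are listed
#'   in \code{outlierSites} (default 1: nitrite efflux exceeding nitrate
#'   influx).
#' @return a [RatioSummary-class].
#' @examples
#' ratioSummary(c(a = 0.1, b = 0.2, c = 0.3, d = 0.4, e = 0.5))
#' @export
ratioSummary <- function(results, outlierThreshold = 1) {
  if (is.list(results)) {
    ratios <- vapply(results, function(r) r@ratio, numeric(1))
    names(ratios) <- vapply(results, function(r) r@siteId, character(1))
  } else ratios <- results
  n <- length(ratios)
  if (n == 0L) .stopf("summary error: no flux results supplied")
  m <- mean(ratios)
  hw <- if (n >= 2L)
    stats::qt(0.975, df = n - 1L) * stats::sd(ratios) / sqrt(n)
  else NA_real_
  out <- names(ratios)[ratios >= outlierThreshold]
  new("RatioSummary", nSites = as.integer(n), ratios = ratios, mean = m,
      ci95Halfwidth = hw, outlierSites = as.character(out %||% character()))
}
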