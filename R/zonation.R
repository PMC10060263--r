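# Geochemical zonation of a core from its censored porewater profile.

#' Depletion depth of a solute
#'
#' The shallowest depth at which a solute is censored (below detection) while
#' the preceding point is not, refined by linear interpolation of the
#' detection-limit crossing between the two bracketing points. Returns
#' \code{NA} when the solute never depletes. The un-interpolated first
#' censored sample depth is attached as attribute \code{"firstCensored"},
#' since grid spacing can bias the raw value by up to one sample interval.
#'
#' @param profile a censored [DepthProfile-class].
#' @param solute solute name.
#' @param interpolate if \code{FALSE}, return the first censored sample depth
#'   itself.
#' @return depletion depth, cm, or \code{NA}.
#' @examples
#' p <- depthProfile(c(0, 100, 200), cbind(nitrate = c(20, 10, 0)),
#'                   censored = cbind(nitrate = c(FALSE, FALSE, TRUE)))
#' findDepletionDepth(p, "nitrate")  # crossing of DL between 100 and 200 cm
#' @export
findDepletionDepth <- function(profile, solute, interpolate = TRUE) {
  if (!solute %in% colnames(profile@conc))
    .stopf("configuration error: solute '%s' absent from profile", solute)
  cens <- profile@censored[, solute]
  conc <- profile@conc[, solute]
  z <- profile@depth
  if (length(z) < 2L) .stopf("need at least 2 depths")
  idx <- which(cens[-1L] & !cens[-length(cens)])
  if (!length(idx)) {
    # censored from the very top counts as depleted at the shallowest sample
    if (cens[1L]) {
      out <- z[1L]
      attr(out, "firstCensored") <- z[1L]
      return(out)
    }
    return(NA_real_)
  }
  i <- idx[1L] + 1L  # first censored point with a detected point above
  dl <- profile@solutes[[solute]]@detectionLimit
  zc <- z[i]
  if (interpolate && conc[i - 1L] > dl) {
    # linear crossing of C = DL between (z[i-1], C[i-1]) and (z[i], C[i]);
    # the censored point enters at its stored (0 or DL/2) value
    frac <- (conc[i - 1L] - dl) / (conc[i - 1L] - conc[i])
    zc <- z[i - 1L] + frac * (z[i] - z[i - 1L])
  }
  attr(zc, "firstCensored") <- z[i]
  zc
}

#' Oxic zone of a core
#'
#' The interval from the shallowest sampled depth down to the oxygen
#' depletion depth; extends to the core bottom when oxygen never depletes,
#' and collapses to an empty interval at the top when oxygen is censored in
#' every sample.
#'
#' @param profile a censored [DepthProfile-class] with an oxygen series.
#' @return length-2 numeric interval, cm.
#' @export
findOxicZone <- function(profile) {
  if (!"oxygen" %in% colnames(profile@conc))
    .stopf("configuration error: no oxygen series in profile")
  z <- profile@depth
  if (profile@censored[1L, "oxygen"])
    return(c(z[1L], z[1L]))
  zd <- findDepletionDepth(profile, "oxygen")
  if (is.na(zd)) c(z[1L], z[length(z)]) else c(z[1L], as.numeric(zd))
}

#' Nitrite accumulation interval
#'
#' The longest contiguous run of depths with detectable (non-censored)
#' nitrite; ties between equally long runs break to the shallowest. The
#' profile is called coherent when the run spans at least 3 depths ("more
#' than two consecutive depths with detectable nitrite"). The maximum is the
#' largest nitrite concentration in the run, ties broken to the shallowest
#' depth.
#'
#' @param profile a censored [DepthProfile-class] with a nitrite series.
#' @return list with \code{interval} (length-2 cm), \code{coherent}
#'   (logical), \code{maximum} (length-2: depth cm, concentration uM); the
#'   interval and maximum are \code{NA} when nitrite is nowhere detected.
#' @export
findNitriteInterval <- function(profile) {
  if (!"nitrite" %in% colnames(profile@conc))
    .stopf("configuration error: no nitrite series in profile")
  det <- !profile@censored[, "nitrite"]
  z <- profile@depth
  if (!any(det))
    return(list(interval = .naInterval(), coherent = FALSE,
                maximum = .naInterval()))
  r <- rle(det)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]  # which.max takes the first: shallowest tie
  i1 <- starts[best]; i2 <- ends[best]
  conc <- profile@conc[, "nitrite"]
  imax <- i1 - 1L + which.max(conc[i1:i2])  # first max: shallowest tie
  list(interval = c(z[i1], z[i2]),
       coherent = (i2 - i1 + 1L) >= 3L,
       maximum = c(z[imax], conc[imax]),
       indices = c(i1, i2), maxIndex = imax)
}

#' Nitrate-ammonium transition zone
#'
#' The interval between the nitrate depletion depth and the shallowest
#' detectable ammonium. When ammonium first appears below the nitrate
#' depletion depth the two species are vertically separated and the interval
#' is the gap between them (tag \code{"separated"}); when ammonium appears
#' above it the interval is the co-occurrence zone (tag \code{"overlap"}).
#'
#' @param profile a censored [DepthProfile-class] with nitrate and ammonium
#'   series.
#' @return list with \code{interval}, \code{relation} (one of
#'   \code{"separated"}, \code{"overlap"}, \code{"undefined"}) and
#'   \code{reason} when undefined.
#' @export
findNATZ <- function(profile) {
  for (s in c("nitrate", "ammonium"))
    if (!s %in% colnames(profile@conc))
      .stopf("configuration error: no %s series in profile", s)
  zNO3 <- findDepletionDepth(profile, "nitrate")
  if (is.na(zNO3))
    return(list(interval = .naInterval(), relation = "undefined",
                reason = "nitrate never depletes"))
  det <- !profile@censored[, "ammonium"]
  if (!any(det))
    return(list(interval = .naInterval(), relation = "undefined",
                reason = "ammonium never detected"))
  i <- which(det)[1L]
  z <- profile@depth
  zNH4 <- z[i]
  if (i > 1L) {
    # interpolate the appearance (DL crossing) between the last censored
    # point above and the first detected point, mirroring findDepletionDepth
    dl <- profile@solutes[["ammonium"]]@detectionLimit
    c0 <- profile@conc[i - 1L, "ammonium"]
    c1 <- profile@conc[i, "ammonium"]
    if (c1 > dl)
      zNH4 <- z[i - 1L] + (dl - c0) / (c1 - c0) * (z[i] - z[i - 1L])
  }
  zNO3 <- as.numeric(zNO3)
  if (zNH4 >= zNO3)
    list(interval = c(zNO3, zNH4), relation = "separated")
  else
    list(interval = c(zNH4, zNO3), relation = "overlap")
}

#' Net nitrite consumption zones
#'
#' Splits the nitrite accumulation interval into the two zones of net
#' nitrite consumption flanking the concentration maximum, using the
#' discrete net-reaction-rate profile ([netReactionRate()]): the contiguous
#' runs of interior points with net consumption (R below a noise threshold)
#' nearest to and strictly above/below the maximum. Points with |R| below
#' \code{noiseFrac} times the largest |R| in the interval are treated as
#' indistinguishable from zero curvature. When no consumption run can be
#' resolved on a limb, the zone falls back to the corresponding half of the
#' interval (top-to-maximum or maximum-to-bottom).
#'
#' @param profile a censored [DepthProfile-class].
#' @param zones list as returned by [findNitriteInterval()], or a
#'   [ZoneSet-class]; must contain a coherent nitrite interval.
#' @param Ds optional per-depth sediment diffusivity for nitrite, m2 yr-1;
#'   computed from the site metadata and porosity when omitted.
#' @param noiseFrac curvature noise threshold as a fraction of the maximum
#'   |R| in the interval (default 0.1).
#' @return list with \code{upper} and \code{lower} length-2 intervals (cm)
#'   and \code{fallback} logicals.
#' @export
classifyConsumptionZones <- function(profile, zones = NULL, Ds = NULL,
                                     noiseFrac = 0.1) {
  if (is.null(zones) || is(zones, "ZoneSet")) {
    iv <- findNitriteInterval(profile)
  } else iv <- zones
  if (!isTRUE(iv$coherent))
    .stopf("zone error: no coherent nitrite interval")
  z <- profile@depth
  R <- netReactionRate(profile, "nitrite", Ds = Ds)
  i1 <- iv$indices[1L]; i2 <- iv$indices[2L]; im <- iv$maxIndex
  # the interval's edge points have stencils touching censored (zeroed)
  # neighbours, which fakes huge curvature there; use interior points only
  j1 <- i1 + 1L; j2 <- i2 - 1L
  inside <- seq_len(length(z)) >= j1 & seq_len(length(z)) <= j2 &
    is.finite(R)
  if (!any(inside)) .stopf("zone error: interval has no interior points")
  thr <- noiseFrac * max(abs(R[inside]))

  runFrom <- function(idx) {
    # idx: candidate interior indices ordered moving away from the maximum;
    # skip until consumption starts, then extend while it lasts
    state <- "seek"
    run <- integer()
    for (i in idx) {
      consuming <- is.finite(R[i]) && R[i] < -thr
      if (state == "seek" && consuming) state <- "in"
      if (state == "in") {
        if (!consuming) break
        run <- c(run, i)
      }
    }
    run
  }

  upperIdx <- if (im - 1L >= j1) runFrom(rev(seq(j1, im - 1L))) else integer()
  lowerIdx <- if (im + 1L <= j2) runFrom(seq(im + 1L, j2)) else integer()
  upper <- if (length(upperIdx)) c(z[min(upperIdx)], z[max(upperIdx)])
           else c(z[i1], iv$maximum[1L])
  lower <- if (length(lowerIdx)) c(z[min(lowerIdx)], z[max(lowerIdx)])
           else c(iv$maximum[1L], z[i2])
  list(upper = upper, lower = lower,
       fallback = c(upper = !length(upperIdx), lower = !length(lowerIdx)))
}

#' Derive the full zonation of a core
#'
#' Runs all zonation detectors on a censored profile and assembles a
#' [ZoneSet-class]: oxic zone, nitrate depletion depth (interpolated and
#' first-censored), nitrite interval with coherence and maximum, NATZ with
#' its topology tag, and — when a coherent nitrite interval exists — the two
#' net nitrite consumption zones.
#'
#' @param profile a censored [DepthProfile-class].
#' @param noiseFrac see [classifyConsumptionZones()].
#' @return a [ZoneSet-class].
#' @examples
#' prof <- generateProfile(presetScenario("GS14-like"))$profile
#' deriveZones(prof)
#' @export
deriveZones <- function(profile, noiseFrac = 0.1) {
  has <- function(s) s %in% colnames(profile@conc)
  oxic <- if (has("oxygen")) findOxicZone(profile) else .naInterval()
  zNO3 <- if (has("nitrate")) findDepletionDepth(profile, "nitrate")
          else NA_real_
  iv <- if (has("nitrite")) findNitriteInterval(profile)
        else list(interval = .naInterval(), coherent = FALSE,
                  maximum = .naInterval())
  natz <- if (has("nitrate") && has("ammonium")) findNATZ(profile)
          else list(interval = .naInterval(), relation = "undefined")
  upper <- .naInterval(); lower <- .naInterval()
  if (isTRUE(iv$coherent)) {
    cz <- classifyConsumptionZones(profile, iv, noiseFrac = noiseFrac)
    upper <- cz$upper; lower <- cz$lower
  }
  new("ZoneSet",
      siteId = profile@site@siteId,
      oxicZone = oxic,
      nitrateDepletionDepth = as.numeric(zNO3),
      nitrateFirstCensoredDepth =
        if (is.na(zNO3)) NA_real_
        else as.numeric(attr(zNO3, "firstCensored") %||% zNO3),
      nitriteInterval = iv$interval,
      coherentNitrite = iv$coherent,
      nitriteMaximum = iv$maximum,
      natz = natz$interval,
      natzRelation = natz$relation,
      upperConsumptionZone = upper,
      lowerConsumptionZone = lower)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export zones as interval rows
#'
#' Flattens a [ZoneSet-class] to a BED-like three-column-plus-label table
#' (site_id, start_cm, end_cm, zone_label) for plotting tools.
#'
#' @param zones a [ZoneSet-class].
#' @return data.frame with one row per defined zone.
#' @export
zonesToIntervals <- function(zones) {
  rows <- list()
  add <- function(iv, label) {
    if (.isInterval(iv))
      rows[[length(rows) + 1L]] <<- data.frame(
        site_id = zones@siteId, start_cm = iv[1], end_cm = iv[2],
        zone_label = label, stringsAsFactors = FALSE)
  }
  add(zones@oxicZone, "oxic")
  add(zones@nitriteInterval, "nitrite_interval")
  add(zones@natz, paste0("natz_", zones@natzRelation))
  add(zones@upperConsumptionZone, "upper_consumption")
  add(zones@lowerConsumptionZone, "lower_consumption")
  if (!length(rows))
    return(data.frame(site_id = character(), start_cm = numeric(),
                      end_cm = numeric(), zone_label = character()))
  do.call(rbind, rows)
}
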