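# Generics, accessors and show methods.

#' @name accessors
#' @title Accessors for poreNitrogen classes
#' @description Slot accessors; user code should use these rather than
#'   reaching into slots.
#' @param object a poreNitrogen S4 object.
#' @param solute solute name.
#' @return the requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("depths", function(object) standardGeneric("depths"))

#' @rdname accessors
#' @export
setGeneric("concentrations",
           function(object, solute) standardGeneric("concentrations"))

#' @rdname accessors
#' @export
setGeneric("isCensored", function(object, solute) standardGeneric("isCensored"))

#' @rdname accessors
#' @export
setGeneric("porosity", function(object) standardGeneric("porosity"))

#' @rdname accessors
#' @export
setGeneric("siteInfo", function(object) standardGeneric("siteInfo"))

#' @rdname accessors
#' @export
setGeneric("soluteNames", function(object) standardGeneric("soluteNames"))

#' @rdname accessors
#' @export
setGeneric("fluxRatio", function(object) standardGeneric("fluxRatio"))

#' @rdname accessors
#' @export
setMethod("depths", "DepthProfile", function(object) object@depth)

#' @rdname accessors
#' @export
setMethod("concentrations", "DepthProfile", function(object, solute) {
  if (missing(solute)) return(object@conc)
  if (!solute %in% colnames(object@conc))
    .stopf("solute '%s' not present in profile", solute)
  object@conc[, solute]
})

#' @rdname accessors
#' @export
setMethod("isCensored", "DepthProfile", function(object, solute) {
  if (missing(solute)) return(object@censored)
  if (!solute %in% colnames(object@censored))
    .stopf("solute '%s' not present in profile", solute)
  object@censored[, solute]
})

#' @rdname accessors
#' @export
setMethod("porosity", "DepthProfile", function(object) object@porosity)

#' @rdname accessors
#' @export
setMethod("siteInfo", "DepthProfile", function(object) object@site)

#' @rdname accessors
#' @export
setMethod("soluteNames", "DepthProfile",
          function(object) colnames(object@conc))

#' @rdname accessors
#' @export
setMethod("depths", "CommunityTable", function(object) object@depths)

#' @rdname accessors
#' @export
setMethod("fluxRatio", "FluxResult", function(object) object@ratio)

#' @rdname accessors
#' @export
setMethod("fluxRatio", "RatioSummary", function(object) object@ratios)

.fmtInterval <- function(iv, unit = "cm") {
  if (!.isInterval(iv)) "undefined"
  else sprintf("[%.4g, %.4g] %s", iv[1], iv[2], unit)
}

setMethod("show", "SoluteSpec", function(object) {
  cat(sprintf("SoluteSpec '%s': D0 = (%.3g + %.3g T) 1e-6 cm2/s, DL = %.3g uM\n",
              object@name, object@m0, object@m1, object@detectionLimit))
})

setMethod("show", "SiteMetadata", function(object) {
  cat(sprintf("SiteMetadata '%s'\n", object@siteId))
  cat(sprintf("  water depth %.4g m; T %.4g C; S %.4g; P %.4g bar\n",
              object@waterDepth, object@bottomTemperature, object@salinity,
              object@pressure))
  if (is.finite(object@sedimentationRate))
    cat(sprintf("  sedimentation rate %.4g cm/kyr\n",
                object@sedimentationRate))
})

setMethod("show", "DepthProfile", function(object) {
  cat(sprintf("DepthProfile '%s': %d depths (%.4g-%.4g cm bsf)\n",
              object@site@siteId, length(object@depth),
              min(object@depth), max(object@depth)))
  for (s in colnames(object@conc)) {
    cens <- sum(object@censored[, s])
    cat(sprintf("  %-9s max %.4g uM, %d/%d censored\n", s,
                max(object@conc[, s]), cens, length(object@depth)))
  }
})

setMethod("show", "ZoneSet", function(object) {
  cat(sprintf("ZoneSet '%s'\n", object@siteId))
  cat("  oxic zone:              ", .fmtInterval(object@oxicZone), "\n")
  cat(sprintf("  nitrate depletion:       %s\n",
              if (is.finite(object@nitrateDepletionDepth))
                sprintf("%.4g cm", object@nitrateDepletionDepth)
              else "none"))
  cat("  nitrite interval:       ", .fmtInterval(object@nitriteInterval),
      sprintf("(coherent: %s)\n", object@coherentNitrite))
  if (is.finite(object@nitriteMaximum[1]))
    cat(sprintf("  nitrite maximum:         %.4g uM at %.4g cm\n",
                object@nitriteMaximum[2], object@nitriteMaximum[1]))
  cat(sprintf("  NATZ (%s):       %s\n", object@natzRelation,
              .fmtInterval(object@natz)))
  cat("  upper consumption zone: ",
      .fmtInterval(object@upperConsumptionZone), "\n")
  cat("  lower consumption zone: ",
      .fmtInterval(object@lowerConsumptionZone), "\n")
})

setMethod("show", "FluxResult", function(object) {
  cat(sprintf("FluxResult '%s' (mmol m-2 yr-1)\n", object@siteId))
  cat(sprintf("  nitrate influx   %.4g\n", object@JNO3In))
  cat(sprintf("  nitrite efflux   up %.4g, down %.4g\n",
              object@JNO2Up, object@JNO2Down))
  cat(sprintf("  nitrite/nitrate flux ratio r = %.4g\n", object@ratio))
})

setMethod("show", "RatioSummary", function(object) {
  cat(sprintf("RatioSummary over %d sites\n", object@nSites))
  cat(sprintf("  mean ratio %.4g +/- %.4g (95%% CI halfwidth)\n",
              object@mean, object@ci95Halfwidth))
  if (length(object@outlierSites))
    cat("  outlier sites:", paste(object@outlierSites, collapse = ", "), "\n")
})

setMethod("show", "CommunityTable", function(object) {
  cat(sprintf("CommunityTable: %d depths, %d taxa, genes: %s\n",
              length(object@depths), ncol(object@relAbundance),
              paste(names(object@functionalGenes), collapse = ", ")))
})

setMethod("show", "NichePartitionResult", function(object) {
  cat("NichePartitionResult\n")
  for (i in seq_len(nrow(object@familyPeaks)))
    cat(sprintf("  %-22s peak %.4g cells/g at %.4g cm\n",
                rownames(object@familyPeaks)[i],
                object@familyPeaks[i, "cells"],
                object@familyPeaks[i, "depth"]))
  cat(sprintf("  separation %.4g cm", object@separation))
  if (is.finite(object@duration))
    cat(sprintf(" -> %.5g yr at %.4g cm/kyr", object@duration,
                object@sedimentationRate))
  cat("\n")
})

setMethod("show", "SyntheticScenario", function(object) {
  cat(sprintf("SyntheticScenario: L = %.4g cm, h = %.4g cm, %d zone(s)\n",
              object@length, object@spacing, length(object@boundaries) + 1L))
  cat(sprintf("  solutes with reactions: %s; noise sd %.3g uM; seed %d\n",
              paste(names(object@rates), collapse = ", "),
              object@noiseSd, object@seed))
})

setMethod("show", "ScenarioTruth", function(object) {
  cat("ScenarioTruth (piecewise-quadratic steady state)\n")
  for (s in names(object@fluxes))
    cat(sprintf("  %-9s J(top) = %.4g, J(bottom) = %.4g mmol m-2 yr-1\n",
                s, object@fluxes[[s]][1],
                object@fluxes[[s]][length(object@fluxes[[s]])]))
})
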