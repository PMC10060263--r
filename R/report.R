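# Per-site and multi-site orchestration with JSON/CSV reports.

.zonesToList <- function(z) {
  iv <- function(x) if (.isInterval(x)) x else NULL
  list(site_id = z@siteId,
       oxic_zone_cm = iv(z@oxicZone),
       nitrate_depletion_depth_cm =
         if (is.finite(z@nitrateDepletionDepth)) z@nitrateDepletionDepth
         else NULL,
       nitrate_first_censored_depth_cm =
         if (is.finite(z@nitrateFirstCensoredDepth))
           z@nitrateFirstCensoredDepth else NULL,
       nitrite_interval_cm = iv(z@nitriteInterval),
       coherent_nitrite = z@coherentNitrite,
       nitrite_maximum =
         if (is.finite(z@nitriteMaximum[1]))
           list(depth_cm = z@nitriteMaximum[1],
                concentration_uM = z@nitriteMaximum[2]) else NULL,
       natz_cm = iv(z@natz),
       natz_relation = z@natzRelation,
       upper_consumption_zone_cm = iv(z@upperConsumptionZone),
       lower_consumption_zone_cm = iv(z@lowerConsumptionZone))
}

.fluxToRow <- function(fl) {
  data.frame(site_id = fl@siteId, J_NO3_in = fl@JNO3In,
             J_NO2_up = fl@JNO2Up, J_NO2_down = fl@JNO2Down,
             ratio = fl@ratio, stringsAsFactors = FALSE)
}

#' Run the full pipeline on one site
#'
#' Executes read (when given a path), detection-limit censoring, zonation,
#' and boundary fluxes for one core, optionally followed by the community
#' metrics, logging every default applied and window chosen. With
#' \code{outDir} set, writes \code{<site>_report.json} and
#' \code{<site>_fluxes.csv}; partial outputs are retained when a later
#' stage fails (the failing stage is named in the report).
#'
#' @param profile a [DepthProfile-class] or a file path readable by
#'   [readProfileTable()].
#' @param outDir output directory, or \code{NULL} for no files.
#' @param solutes solute specs used for reading/censoring.
#' @param site [SiteMetadata-class] used when reading from a path.
#' @param tortuosity,anchor flux options, see [siteFluxes()].
#' @param noiseFrac consumption-zone threshold, see
#'   [classifyConsumptionZones()].
#' @param community optional [CommunityTable-class]; adds anammox absolute
#'   abundances and niche-partitioning metrics to the report.
#' @param familyNames anammox family columns used for the community
#'   metrics.
#' @return list with \code{site_id}, \code{zones} ([ZoneSet-class]),
#'   \code{fluxes} ([FluxResult-class] or \code{NULL}), \code{niche}
#'   ([NichePartitionResult-class] or \code{NULL}), \code{log} (character)
#'   and \code{errors} (named character of failed stages).
#' @examples
#' prof <- generateProfile(presetScenario("GS14-like"))$profile
#' rep <- runSite(prof)
#' rep$fluxes
#' @export
runSite <- function(profile, outDir = NULL, solutes = defaultSolutes(),
                    site = siteMetadata(), tortuosity = "log",
                    anchor = "above", noiseFrac = 0.1, community = NULL,
                    familyNames = c("Scalinduaceae",
                                    "Bathyanammoxibiaceae")) {
  log <- character(); errors <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  if (is.character(profile)) {
    note("reading profile from %s", profile)
    profile <- readProfileTable(profile, solutes = solutes, site = site)
  }
  profile <- censorToDetection(profile, solutes = solutes)
  for (s in colnames(profile@conc))
    note("censoring %s at DL %.3g uM (%d censored)", s,
         profile@solutes[[s]]@detectionLimit,
         sum(profile@censored[, s]))
  note("site defaults: T = %.3g C, S = %.3g, P = %.4g bar",
       profile@site@bottomTemperature, profile@site@salinity,
       profile@site@pressure)

  zones <- deriveZones(profile, noiseFrac = noiseFrac)
  note("zonation: coherent nitrite = %s", zones@coherentNitrite)

  fluxes <- tryCatch(
    siteFluxes(profile, zones, tortuosity = tortuosity, anchor = anchor),
    error = function(e) {
      errors <<- c(errors, fluxes = conditionMessage(e))
      NULL
    })
  if (!is.null(fluxes)) {
    for (w in names(fluxes@windows))
      note("%s window: depths %s cm", w,
           paste(fluxes@windows[[w]]$points[, "depth_cm"], collapse = "/"))
    note("flux options: tortuosity = %s, anchor = %s", tortuosity, anchor)
  }

  niche <- NULL
  if (!is.null(community)) {
    niche <- tryCatch({
      profs <- lapply(familyNames, function(f)
        absoluteAbundanceProfile(community, f))
      names(profs) <- familyNames
      familyPeaks(profs,
                  sedimentationRate = profile@site@sedimentationRate,
                  zones = zones)
    }, error = function(e) {
      errors <<- c(errors, community = conditionMessage(e))
      NULL
    })
  }

  report <- list(site_id = profile@site@siteId, zones = zones,
                 fluxes = fluxes, niche = niche, log = log,
                 errors = errors)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    json <- list(
      schema_version = "1.0",
      site_id = report$site_id,
      zones = .zonesToList(zones),
      fluxes = if (is.null(fluxes)) NULL else list(
        J_NO3_in = fluxes@JNO3In, J_NO2_up = fluxes@JNO2Up,
        J_NO2_down = fluxes@JNO2Down, ratio = fluxes@ratio,
        Ds_m2yr = as.list(fluxes@DsUsed)),
      niche = if (is.null(niche)) NULL else list(
        peaks = as.data.frame(niche@familyPeaks),
        separation_cm = niche@separation,
        duration_yr = if (is.finite(niche@duration)) niche@duration
                      else NULL),
      log = log,
      errors = as.list(errors))
    jsonlite::write_json(json,
                         file.path(outDir,
                                   paste0(report$site_id, "_report.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    if (!is.null(fluxes))
      utils::write.csv(.fluxToRow(fluxes),
                       file.path(outDir,
                                 paste0(report$site_id, "_fluxes.csv")),
                       row.names = FALSE)
  }
  report
}

#' Compile flux ratios across sites
#'
#' Runs [siteFluxes()] on every site, excludes (and reports) sites failing
#' the zonation prerequisites, and summarises the surviving ratios with
#' [ratioSummary()]. With \code{sensitivity = TRUE} the mean ratio is
#' recomputed under every combination of tortuosity model and window
#' anchoring, since both are under-determined methodological choices.
#'
#' @param profiles named list of censored [DepthProfile-class] objects (or
#'   file paths).
#' @param outDir output directory, or \code{NULL}.
#' @param solutes solute specs used when reading paths.
#' @param tortuosity,anchor flux options for the headline summary.
#' @param outlierThreshold see [ratioSummary()].
#' @param sensitivity also report the mean ratio under all four
#'   tortuosity/anchoring combinations.
#' @return list with \code{summary} ([RatioSummary-class]), \code{table}
#'   (per-site data.frame), \code{failed} (named character of excluded
#'   sites with reasons) and, when requested, \code{sensitivity}
#'   (data.frame of option combinations and mean ratios).
#' @examples
#' profs <- lapply(1:3, function(i)
#'   generateProfile(presetScenario("GS14-like", noiseSd = 0.1,
#'                                  seed = i))$profile)
#' names(profs) <- paste0("rep", 1:3)
#' runCompilation(profs)$summary
#' @export
runCompilation <- function(profiles, outDir = NULL,
                           solutes = defaultSolutes(), tortuosity = "log",
                           anchor = "above", outlierThreshold = 1,
                           sensitivity = FALSE) {
  if (!length(profiles)) .stopf("compilation error: no sites supplied")
  if (is.null(names(profiles)))
    names(profiles) <- sprintf("site%02d", seq_along(profiles))

  loaded <- list(); failed <- character()
  for (nm in names(profiles)) {
    p <- profiles[[nm]]
    res <- tryCatch({
      if (is.character(p))
        p <- readProfileTable(p, solutes = solutes,
                              site = siteMetadata(siteId = nm))
      p <- censorToDetection(p, solutes = solutes)
      p@site@siteId <- nm
      p
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) failed[nm] <- res else loaded[[nm]] <- res
  }

  results <- list()
  for (nm in names(loaded)) {
    res <- tryCatch(siteFluxes(loaded[[nm]], tortuosity = tortuosity,
                               anchor = anchor),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) failed[nm] <- res else results[[nm]] <- res
  }
  if (!length(results))
    .stopf("compilation error: all %d sites failed zone prerequisites",
           length(profiles))
  summary <- ratioSummary(results, outlierThreshold = outlierThreshold)
  table <- do.call(rbind, lapply(results, .fluxToRow))
  rownames(table) <- NULL

  sens <- NULL
  if (sensitivity) {
    grid <- expand.grid(tortuosity = c("log", "power"),
                        anchor = c("above", "bracketing"),
                        stringsAsFactors = FALSE)
    sens <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      rs <- lapply(loaded, function(p) tryCatch(
        siteFluxes(p, tortuosity = grid$tortuosity[i],
                   anchor = grid$anchor[i]),
        error = function(e) NULL))
      rs <- Filter(Negate(is.null), rs)
      data.frame(tortuosity = grid$tortuosity[i], anchor = grid$anchor[i],
                 n_sites = length(rs),
                 mean_ratio = if (length(rs)) ratioSummary(rs)@mean
                              else NA_real_)
    }))
  }

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(table, file.path(outDir, "compilation_fluxes.csv"),
                     row.names = FALSE)
    json <- list(schema_version = "1.0",
                 n_sites = summary@nSites,
                 mean_ratio = summary@mean,
                 ci95_halfwidth = summary@ci95Halfwidth,
                 outlier_sites = as.list(summary@outlierSites),
                 failed_sites = as.list(failed),
                 sensitivity = sens)
    jsonlite::write_json(json,
                         file.path(outDir, "compilation_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  list(summary = summary, table = table, failed = failed,
       sensitivity = sens)
}
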