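# Reading, validating, censoring and serializing porewater profile tables.

.defaultSchema <- function() {
  c(depth = "depth_cm", nitrate = "no3_uM", nitrite = "no2_uM",
    ammonium = "nh4_uM", oxygen = "o2_uM", porosity = "porosity")
}

# Parse one raw column: numeric stays numeric; "bd"/"bdl"/"<dl"/blank are
# below-detection sentinels; anything else is a parse error.
.parseSoluteColumn <- function(x, column) {
  raw <- trimws(as.character(x))
  sentinel <- raw %in% c("bd", "BD", "bdl", "BDL", "<dl", "<DL", "", "NA") |
    is.na(x)
  val <- suppressWarnings(as.numeric(raw))
  bad <- !sentinel & is.na(val)
  if (any(bad))
    .stopf("column '%s': unparseable cell(s): %s", column,
           paste(unique(raw[bad]), collapse = ", "))
  val[sentinel] <- 0
  list(value = val, censored = sentinel)
}

#' Read a porewater profile table
#'
#' Reads a delimited text table (comma or tab, auto-detected) with one row
#' per depth into a validated [DepthProfile-class]. Cells holding a
#' below-detection sentinel (\code{"bd"}, \code{"bdl"}, \code{"<dl"}, or
#' blank) become censored points with stored concentration 0. Rows are sorted
#' by depth; duplicate depths are rejected. A missing porosity column falls
#' back to a constant default with a warning, so literature tables that only
#' report concentrations remain usable.
#'
#' @param path file path of the delimited table.
#' @param schema named character remapping canonical roles to column names;
#'   defaults to \code{depth_cm, no3_uM, no2_uM, nh4_uM, o2_uM, porosity}.
#'   Roles absent from the file are skipped (depth is mandatory).
#' @param solutes named list of [SoluteSpec-class] for the solute columns.
#' @param site a [SiteMetadata-class] attached to the profile.
#' @param defaultPorosity constant used when the table has no porosity
#'   column.
#' @param depthUnit \code{"cm"} (default) or \code{"m"}; depths are stored in
#'   cm below seafloor.
#' @return a [DepthProfile-class].
#' @seealso [writeProfileTable()], [censorToDetection()]
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("depth_cm,no3_uM", "0,20", "10,10", "20,bd"), tf)
#' readProfileTable(tf)
#' @export
readProfileTable <- function(path, schema = .defaultSchema(),
                             solutes = defaultSolutes(),
                             site = siteMetadata(),
                             defaultPorosity = 0.7, depthUnit = c("cm", "m")) {
  depthUnit <- match.arg(depthUnit)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  full <- .defaultSchema()
  full[names(schema)] <- schema
  schema <- full
  if (!schema[["depth"]] %in% names(tab))
    .stopf("schema error: depth column '%s' not found in %s",
           schema[["depth"]], path)
  depth <- suppressWarnings(as.numeric(tab[[schema[["depth"]]]]))
  if (any(is.na(depth))) .stopf("non-numeric depth values in %s", path)
  if (depthUnit == "m") depth <- depth * CM_PER_M
  if (anyDuplicated(depth))
    .stopf("validation error: duplicate depths in %s", path)
  ord <- order(depth)
  tab <- tab[ord, , drop = FALSE]
  depth <- depth[ord]

  soluteCols <- intersect(names(solutes), names(schema))
  soluteCols <- soluteCols[vapply(soluteCols, function(s)
    schema[[s]] %in% names(tab), logical(1))]
  if (!length(soluteCols))
    .stopf("no recognised solute columns in %s", path)
  conc <- matrix(NA_real_, length(depth), length(soluteCols),
                 dimnames = list(NULL, soluteCols))
  cens <- matrix(FALSE, length(depth), length(soluteCols),
                 dimnames = list(NULL, soluteCols))
  for (s in soluteCols) {
    parsed <- .parseSoluteColumn(tab[[schema[[s]]]], schema[[s]])
    if (any(parsed$value[!parsed$censored] < 0))
      .stopf("validation error: negative %s concentration in %s", s, path)
    conc[, s] <- parsed$value
    cens[, s] <- parsed$censored
  }

  if (schema[["porosity"]] %in% names(tab)) {
    phi <- suppressWarnings(as.numeric(tab[[schema[["porosity"]]]]))
    if (any(is.na(phi))) .stopf("non-numeric porosity values in %s", path)
  } else {
    .warnf("no porosity column in %s; using constant default %.3g",
           path, defaultPorosity)
    phi <- rep(defaultPorosity, length(depth))
  }

  depthProfile(depth, conc, censored = cens, porosity = phi,
               solutes = solutes, site = site)
}

#' Write a porewater profile table
#'
#' Serializes a [DepthProfile-class] back to the canonical delimited dialect
#' read by [readProfileTable()]: censored cells are written as \code{"bd"} so
#' that a write/read round trip reproduces depths, values and censoring flags
#' exactly.
#'
#' @param profile a [DepthProfile-class].
#' @param path output file path.
#' @param sep field separator (default comma).
#' @return \code{path}, invisibly.
#' @export
writeProfileTable <- function(profile, path, sep = ",") {
  schema <- .defaultSchema()
  num <- function(x) sprintf("%.15g", x)
  cols <- list(depth_cm = num(profile@depth))
  for (s in colnames(profile@conc)) {
    v <- num(profile@conc[, s])
    v[profile@censored[, s]] <- "bd"
    cols[[schema[[s]]]] <- v
  }
  cols[["porosity"]] <- num(profile@porosity)
  lines <- c(paste(names(cols), collapse = sep),
             do.call(paste, c(unname(cols), sep = sep)))
  writeLines(lines, path)
  invisible(path)
}

#' Apply detection-limit censoring
#'
#' Flags every point whose concentration falls below its solute's detection
#' limit as censored. Censored points carry concentration 0 for downstream
#' gradient fitting (the flag is preserved); setting
#' \code{censoredValue = "half-dl"} stores half the detection limit instead.
#' Censoring is monotone in the detection limit: raising a limit can only
#' enlarge the censored set.
#'
#' @param profile a [DepthProfile-class].
#' @param solutes named list of [SoluteSpec-class] carrying the detection
#'   limits; defaults to the profile's own specs.
#' @param censoredValue \code{"zero"} (default) or \code{"half-dl"}.
#' @return the censored [DepthProfile-class].
#' @examples
#' p <- depthProfile(c(0, 10, 20), cbind(nitrite = c(0.05, 0.5, 1.0)))
#' isCensored(censorToDetection(p), "nitrite")
#' @export
censorToDetection <- function(profile, solutes = NULL,
                              censoredValue = c("zero", "half-dl")) {
  censoredValue <- match.arg(censoredValue)
  if (is.null(solutes)) solutes <- profile@solutes
  known <- union(colnames(profile@conc), names(defaultSolutes()))
  unknown <- setdiff(names(solutes), known)
  if (length(unknown))
    .stopf("configuration error: unknown solute '%s'", unknown[1])
  for (s in colnames(profile@conc)) {
    spec <- solutes[[s]]
    if (is.null(spec)) next
    dl <- spec@detectionLimit
    below <- profile@conc[, s] < dl
    flag <- profile@censored[, s] | below
    profile@censored[, s] <- flag
    profile@conc[flag, s] <-
      if (censoredValue == "zero") 0 else dl / 2
    profile@solutes[[s]] <- spec
  }
  validObject(profile)
  profile
}

#' Validation report for a profile
#'
#' Summarises what was read and which defaults were applied, as a list
#' suitable for JSON serialization.
#'
#' @param profile a [DepthProfile-class].
#' @return a named list (site, depth range, per-solute censored counts,
#'   porosity range).
#' @export
profileValidationReport <- function(profile) {
  list(
    site_id = profile@site@siteId,
    n_depths = length(profile@depth),
    depth_range_cm = range(profile@depth),
    porosity_range = range(profile@porosity),
    solutes = lapply(colnames(profile@conc), function(s) list(
      name = s,
      detection_limit_uM = profile@solutes[[s]]@detectionLimit,
      n_censored = sum(profile@censored[, s]),
      max_uM = max(profile@conc[, s])
    ))
  )
}
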