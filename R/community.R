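# Absolute microbial abundances and anammox niche-partitioning metrics.

#' Total cell count from 16S gene copies
#'
#' Under the single-copy assumption (one 16S rRNA gene per bacterial or
#' archaeal genome) gene copies equal cells, so the total cell count is the
#' sum of the archaeal and bacterial 16S copy numbers.
#'
#' @param archaeal16S,bacterial16S gene copies per g wet sediment (>= 0,
#'   vectorised).
#' @return total cells per g.
#' @examples
#' totalCellCount(2e7, 8e7)  # 1e8
#' @export
totalCellCount <- function(archaeal16S, bacterial16S) {
  if (any(archaeal16S < 0, na.rm = TRUE) ||
      any(bacterial16S < 0, na.rm = TRUE))
    .stopf("domain error: gene copies must be non-negative")
  archaeal16S + bacterial16S
}

#' Absolute abundance of a taxon
#'
#' The product of the total cell abundance and the taxon's relative
#' amplicon abundance.
#'
#' @param totalCells cells per g.
#' @param relativeAbundance fraction in [0, 1] (vectorised).
#' @return cells per g.
#' @examples
#' absoluteAbundance(1e8, 0.18)  # 1.8e7
#' @export
absoluteAbundance <- function(totalCells, relativeAbundance) {
  if (any(relativeAbundance < 0, na.rm = TRUE) ||
      any(relativeAbundance > 1, na.rm = TRUE))
    .stopf("domain error: relative abundance must lie in [0, 1]")
  totalCells * relativeAbundance
}

#' Anammox relative abundance per depth
#'
#' The total anammox fraction is the per-depth sum of the relative
#' abundances of the two marine anammox families, Ca. Scalinduaceae and
#' Ca. Bathyanammoxibiaceae. A family column missing from the table is
#' treated as zero with a warning.
#'
#' @param table a [CommunityTable-class].
#' @param familyNames the two family column names.
#' @return numeric vector, one fraction per depth.
#' @export
anammoxRelativeAbundance <- function(table,
    familyNames = c("Scalinduaceae", "Bathyanammoxibiaceae")) {
  ra <- table@relAbundance
  out <- numeric(length(table@depths))
  for (f in familyNames) {
    if (f %in% colnames(ra)) out <- out + unname(ra[, f])
    else .warnf("family '%s' absent from table; treated as 0", f)
  }
  out
}

#' Absolute-abundance depth profile of one taxon
#'
#' Convenience wrapper combining [totalCellCount()] and
#' [absoluteAbundance()] for one taxon of a [CommunityTable-class].
#'
#' @param table a [CommunityTable-class].
#' @param taxon taxon (column) name.
#' @return data.frame with \code{depth} (cm), \code{cells} (cells per g),
#'   \code{taxon} and \code{method} (\code{"amplicon-derived"}).
#' @export
absoluteAbundanceProfile <- function(table, taxon) {
  if (!taxon %in% colnames(table@relAbundance))
    .stopf("taxon '%s' absent from table", taxon)
  total <- totalCellCount(table@archaeal16S, table@bacterial16S)
  data.frame(depth = table@depths,
             cells = absoluteAbundance(total, table@relAbundance[, taxon]),
             taxon = taxon, method = "amplicon-derived",
             stringsAsFactors = FALSE)
}

#' Abundance peaks and vertical separation of two families
#'
#' Locates each family's absolute-abundance maximum (ties break to the
#' shallowest depth — absolute rather than relative abundance is used
#' because relative peaks can be artifacts of other taxa's decay) and
#' reports the vertical separation between the two peak depths. When a
#' sedimentation rate is supplied the separation is converted to the
#' implied duration via [partitionDuration()]; when a [ZoneSet-class] is
#' supplied each peak is tagged with the zone containing it.
#'
#' @param profiles named list of per-family profiles as returned by
#'   [absoluteAbundanceProfile()] (data.frames with \code{depth} and
#'   \code{cells}); at least one depth per family.
#' @param sedimentationRate cm per kyr, optional.
#' @param zones a [ZoneSet-class], optional.
#' @return a [NichePartitionResult-class].
#' @examples
#' a <- data.frame(depth = c(0, 50, 100), cells = c(1, 5, 2))
#' b <- data.frame(depth = c(0, 50, 160), cells = c(1, 2, 9))
#' familyPeaks(list(A = a, B = b), sedimentationRate = 2)
#' @export
familyPeaks <- function(profiles, sedimentationRate = NA_real_,
                        zones = NULL) {
  if (length(profiles) < 1L) .stopf("peak error: no family profiles")
  peaks <- t(vapply(profiles, function(p) {
    if (!nrow(p)) .stopf("peak error: empty family profile")
    ord <- order(p$depth)
    p <- p[ord, , drop = FALSE]
    i <- which.max(p$cells)  # first max: shallowest tie
    c(depth = p$depth[i], cells = p$cells[i])
  }, numeric(2)))
  sep <- if (nrow(peaks) >= 2L) abs(peaks[1L, "depth"] - peaks[2L, "depth"])
         else NA_real_
  dur <- if (is.finite(sep) && is.finite(sedimentationRate))
    partitionDuration(sep, sedimentationRate) else NA_real_
  hit <- character()
  if (!is.null(zones)) {
    lab <- function(z) {
      iv <- zonesToIntervals(zones)
      inZone <- iv$start_cm <= z & z <= iv$end_cm
      if (any(inZone)) paste(iv$zone_label[inZone], collapse = "+")
      else "unzoned"
    }
    hit <- vapply(peaks[, "depth"], lab, character(1))
    names(hit) <- rownames(peaks)
  }
  new("NichePartitionResult", familyPeaks = peaks, separation = sep,
      sedimentationRate = sedimentationRate, duration = dur,
      zonesHit = hit)
}

#' Duration implied by a peak separation
#'
#' Converts a vertical separation between two abundance maxima into the
#' duration of the niche partitioning it records, given the sedimentation
#' rate: duration = (separation / rate) * 1000 years.
#'
#' @param separation vertical peak separation, cm (>= 0).
#' @param sedimentationRate cm per kyr (> 0).
#' @return duration, years.
#' @examples
#' partitionDuration(110, 2)  # 55000 yr
#' partitionDuration(45, 2)   # 22500 yr
#' @export
partitionDuration <- function(separation, sedimentationRate) {
  if (any(sedimentationRate <= 0))
    .stopf("domain error: sedimentation rate must be positive")
  if (any(separation < 0))
    .stopf("domain error: separation must be non-negative")
  separation / sedimentationRate * 1000
}

#' Concordance between qPCR- and amplicon-derived abundances
#'
#' Per-depth log10 ratio of the qPCR functional-gene series to the
#' amplicon-derived absolute abundance on the overlapping depths, with a
#' configurable pseudo-count replacing zeros (default: half the smallest
#' nonzero value across both series). The summary reports the median log10
#' ratio and the fraction of depths agreeing within one order of magnitude
#' — an explicit operationalisation of "general agreement" between the two
#' quantification methods.
#'
#' @param ampliconDerived data.frame with \code{depth} and \code{cells}
#'   (e.g. from [absoluteAbundanceProfile()]).
#' @param qpcrDerived data.frame with \code{depth} and \code{copies} (e.g.
#'   one element of a [CommunityTable-class] functionalGenes list).
#' @param pseudoCount value replacing zeros before taking logs;
#'   \code{NULL} (default) uses half the smallest nonzero value.
#' @return list with \code{depths}, \code{log10Ratio},
#'   \code{medianLog10Ratio} and \code{fractionWithin1Order}.
#' @export
qpcrConcordance <- function(ampliconDerived, qpcrDerived,
                            pseudoCount = NULL) {
  common <- intersect(ampliconDerived$depth, qpcrDerived$depth)
  if (!length(common)) .stopf("concordance error: no overlapping depths")
  a <- ampliconDerived$cells[match(common, ampliconDerived$depth)]
  q <- qpcrDerived$copies[match(common, qpcrDerived$depth)]
  if (is.null(pseudoCount)) {
    nz <- c(a[a > 0], q[q > 0])
    pseudoCount <- if (length(nz)) min(nz) / 2 else 1
  }
  a[a == 0] <- pseudoCount
  q[q == 0] <- pseudoCount
  lr <- log10(q / a)
  list(depths = common, log10Ratio = lr,
       medianLog10Ratio = stats::median(lr),
       fractionWithin1Order = mean(abs(lr) <= 1))
}
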