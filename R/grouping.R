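#' Group peaks across spots by single-linkage m/z clustering
#'
#' Pools every peak in the dataset, sorts by m/z and cuts at consecutive
#' gaps larger than the linkage distance — the one-dimensional equivalent of
#' single-linkage agglomeration with the cut at \code{linkage}. Every peak
#' lands in exactly one group; groups are ordered (and numbered) by their
#' S/N-weighted mean m/z.
#'
#' @param dataset an \linkS4class{MsiDataset}.
#' @param linkage gap-cut distance in Da (default 0.1).
#' @return a \linkS4class{PeakGroups}.
#' @export
groupPeaks <- function(dataset, linkage = 0.1) {
  if (linkage <= 0) stop("linkage must be > 0")
  p <- peakData(dataset)
  if (!nrow(p)) {
    return(new("PeakGroups",
               peaks = cbind(p, group = integer(0)),
               groups = data.frame(group_id = integer(), awm_mz = numeric(),
                                   mz_min = numeric(), mz_max = numeric(),
                                   n_peaks = integer(), snr_weighted = logical()),
               linkage = linkage))
  }
  p <- p[order(p$mz), , drop = FALSE]
  grp <- cumsum(c(1L, as.integer(diff(p$mz) > linkage)))
  w <- p$snr
  awm <- vapply(split(seq_along(grp), grp), function(i) {
    if (sum(w[i]) > 0) sum(p$mz[i] * w[i]) / sum(w[i]) else mean(p$mz[i])
  }, numeric(1))
  summary <- data.frame(
    group_id = seq_along(awm),
    awm_mz = unname(awm),
    mz_min = as.numeric(tapply(p$mz, grp, min)),
    mz_max = as.numeric(tapply(p$mz, grp, max)),
    n_peaks = as.integer(tabulate(grp)),
    snr_weighted = as.logical(tapply(w, grp, sum) > 0))
  ## groups occupy disjoint ascending m/z intervals, so awm order = mz order
  p$group <- grp
  rownames(p) <- NULL
  new("PeakGroups", peaks = p, groups = summary, linkage = linkage)
}

#' @describeIn groupPeaks per-group summary table accessor.
#' @param groups a \code{PeakGroups}.
#' @export
groupSummary <- function(groups) groups@groups

#' @describeIn groupPeaks S/N-weighted mean m/z per group.
#' @export
awmMz <- function(groups) groups@groups$awm_mz

setMethod("show", "PeakGroups", function(object) {
  cat("PeakGroups:", nrow(object@groups), "groups from",
      nrow(object@peaks), "peaks (linkage", object@linkage, "Da)\n")
})

#' Per-region spot-occurrence counts and proportions
#'
#' A spot counts at most once per group even when it contributes several
#' member peaks; proportions divide by the number of spots carrying the
#' region label (NA when a region is absent from the dataset).
#'
#' @param groups a \linkS4class{PeakGroups}.
#' @param dataset the \linkS4class{MsiDataset} the groups came from.
#' @return data.frame with one row per group: \code{group_id, awm_mz},
#'   per-region counts \code{n_treated, n_control, n_calibrant, n_none},
#'   total distinct-spot occurrence \code{n_spectra}, and proportions
#'   \code{p_treated, p_control}.
#' @export
occurrenceTable <- function(groups, dataset) {
  spots <- spotData(dataset)
  p <- groups@peaks
  hit <- unique(p[c("group", "spot_id")])
  hit$region <- spots$region[match(hit$spot_id, spots$spot_id)]
  ng <- nrow(groups@groups)
  counts <- sapply(.regionLevels, function(r)
    tabulate(hit$group[hit$region == r], nbins = ng))
  if (ng == 1L) counts <- matrix(counts, nrow = 1L, dimnames = list(NULL, .regionLevels))
  size <- vapply(.regionLevels, function(r) sum(spots$region == r), integer(1))
  out <- data.frame(group_id = groups@groups$group_id,
                    awm_mz = groups@groups$awm_mz)
  for (r in .regionLevels) out[[paste0("n_", r)]] <- counts[, r]
  out$n_spectra <- as.integer(tabulate(hit$group, nbins = ng))
  out$p_treated <- if (size["treated"] > 0) counts[, "treated"] / size["treated"] else NA_real_
  out$p_control <- if (size["control"] > 0) counts[, "control"] / size["control"] else NA_real_
  out
}

#' Occurrence-based profiling candidate filter
#'
#' Keeps peak groups seen in at least \code{minTreated} treated spots, at
#' most \code{maxControl} control spots, and above an m/z floor — the rule
#' that isolates enzymatically released N-glycan candidates from a
#' treated/control profiling layout. All thresholds are inclusive.
#'
#' @param occurrence the table from \code{\link{occurrenceTable}}.
#' @param minTreated minimum treated-spot count (default 2).
#' @param maxControl maximum control-spot count (default 1).
#' @param minMz AWM m/z floor, exclusive (default 1000).
#' @param conservativeMin optional stricter treated-count minimum (e.g. 4)
#'   that replaces \code{minTreated}.
#' @return the filtered occurrence table.
#' @export
profilingCandidates <- function(occurrence, minTreated = 2, maxControl = 1,
                                minMz = 1000, conservativeMin = NULL) {
  if (!is.null(conservativeMin)) minTreated <- conservativeMin
  stopifnot(minTreated >= 0, maxControl >= 0)
  keep <- occurrence$n_treated >= minTreated &
    occurrence$n_control <= maxControl &
    occurrence$awm_mz > minMz
  occurrence[keep, , drop = FALSE]
}

#' Minimum-occurrence filter for imaging data
#'
#' Keeps groups occurring in at least \code{minSpectra} spectra (distinct
#' spots, all regions pooled); the boundary is inclusive.
#'
#' @inheritParams profilingCandidates
#' @param minSpectra minimum total spot occurrence (default 100).
#' @return the filtered occurrence table.
#' @export
minOccurrenceFilter <- function(occurrence, minSpectra = 100) {
  if (minSpectra < 1) stop("minSpectra must be >= 1")
  occurrence[occurrence$n_spectra >= minSpectra, , drop = FALSE]
}
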