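#' Difference in proportions of spectra (DIPPS)
#'
#' For each peak group, DIPPS is the proportion of treated-region spectra
#' exhibiting the group minus the proportion of control-region spectra doing
#' so; values near 1 flag analytes essentially exclusive to the treated
#' region (released N-glycans), values near 0 analytes indifferent to
#' treatment. Groups are ranked by descending DIPPS with ties broken by
#' ascending AWM m/z for determinism.
#'
#' @param occurrence table from \code{\link{occurrenceTable}}; both the
#'   treated and control regions must be present in the dataset.
#' @return data.frame \code{group_id, awm_mz, p_treated, p_control, dipps,
#'   rank}, sorted by rank.
#' @export
dippsTable <- function(occurrence) {
  if (!nrow(occurrence)) stop("empty occurrence table")
  if (anyNA(occurrence$p_treated) || anyNA(occurrence$p_control))
    stop("DIPPS needs non-empty treated and control regions")
  out <- occurrence[c("group_id", "awm_mz", "p_treated", "p_control")]
  out$dipps <- out$p_treated - out$p_control
  o <- order(-out$dipps, out$awm_mz)
  out <- out[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' DIPPS map: per-spot count of selected peak groups
#'
#' Counts, at every acquired spot, how many of the selected groups have at
#' least one member peak there, and places the counts on the grid.
#'
#' @param dataset an \linkS4class{MsiDataset}.
#' @param groups the \linkS4class{PeakGroups} the selection refers to.
#' @param selected group ids to count (non-empty).
#' @return a \linkS4class{SpatialMap} of integer counts (0 where none).
#' @export
dippsMap <- function(dataset, groups, selected) {
  if (!length(selected)) stop("selection is empty")
  p <- groups@peaks
  hit <- unique(p[p$group %in% selected, c("group", "spot_id")])
  counts <- table(factor(hit$spot_id, levels = spotData(dataset)$spot_id))
  v <- stats::setNames(as.numeric(counts), names(counts))
  spatialMap(dataset, v, what = "dipps_count")
}

#' Data-dependent heuristic DIPPS cutoff
#'
#' Scans every observed DIPPS value as a candidate cutoff c. For each c the
#' groups with DIPPS >= c are mapped with \code{\link{dippsMap}} and scored
#' by the per-group-normalised occupancy contrast
#' s(c) = mean(count | treated) / k - mean(count | control) / k
#' where k is the number of selected groups; the c maximising s wins, with
#' ties resolved towards larger c (fewer groups). One admissible heuristic,
#' not the reproduction of any particular published rule.
#'
#' @param dipps table from \code{\link{dippsTable}}.
#' @inheritParams dippsMap
#' @return list with \code{cutoff}, \code{selected} (group ids),
#'   \code{score}, and the scanned \code{candidates} data.frame.
#' @export
selectHeuristic <- function(dipps, groups, dataset) {
  if (!nrow(dipps)) stop("no DIPPS results to select from")
  spots <- spotData(dataset)
  treated <- spots$spot_id[spots$region == "treated"]
  control <- spots$spot_id[spots$region == "control"]
  cand <- sort(unique(dipps$dipps), decreasing = TRUE)
  score <- vapply(cand, function(c) {
    sel <- dipps$group_id[dipps$dipps >= c]
    m <- dippsMap(dataset, groups, sel)
    v <- mapValues(m)
    idx <- cbind(spots$y + 1L, spots$x + 1L)
    cnt <- stats::setNames(v[idx], spots$spot_id)
    (mean(cnt[treated]) - mean(cnt[control])) / length(sel)
  }, numeric(1))
  best <- which(score == max(score))[1]   # candidates descend, so first = larger c
  list(cutoff = cand[best],
       selected = dipps$group_id[dipps$dipps >= cand[best]],
       score = score[best],
       candidates = data.frame(cutoff = cand, score = score))
}

#' Top-N DIPPS selection
#'
#' User-selected alternative to the heuristic cutoff: the n groups with the
#' highest DIPPS rank.
#'
#' @param dipps table from \code{\link{dippsTable}}.
#' @param n number of groups to keep (default 13).
#' @return group ids of the n top-ranked groups.
#' @export
selectTopN <- function(dipps, n = 13) {
  dipps$group_id[dipps$rank <= n]
}

#' Log ion-intensity map for one peak group
#'
#' Per-spot value log(1 + summed member-peak intensity); log1p keeps spots
#' without the analyte at exactly zero.
#'
#' @inheritParams dippsMap
#' @param group a single group id.
#' @return a \linkS4class{SpatialMap}.
#' @export
logIntensityMap <- function(dataset, groups, group) {
  p <- groups@peaks
  p <- p[p$group == group, , drop = FALSE]
  if (!nrow(p)) stop("group ", group, " has no member peaks")
  tot <- tapply(p$intensity, p$spot_id, sum)
  v <- stats::setNames(rep(0, nrow(spotData(dataset))), spotData(dataset)$spot_id)
  v[names(tot)] <- log1p(as.numeric(tot))
  spatialMap(dataset, v, what = paste0("log_intensity_g", group))
}
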