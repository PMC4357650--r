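#' TopHat morphological baseline subtraction
#'
#' Subtracts the grayscale opening (erosion then dilation with a flat,
#' centred window) from an intensity profile. The opening never exceeds the
#' profile, so the result is nonnegative; isolated peaks narrower than the
#' window pass through unchanged while broad baseline structure is removed.
#' Windows are truncated symmetrically at the profile ends.
#'
#' @param intensity numeric intensity vector (a profile sampled on an
#'   ascending m/z axis).
#' @param window structuring-element width in points; odd, >= 3 and smaller
#'   than the profile length. Default 101 points, wide enough to pass under
#'   glycan isotope envelopes at typical TOF sampling.
#' @return baseline-subtracted intensity vector.
#' @export
tophatBaseline <- function(intensity, window = 101L) {
  n <- length(intensity)
  if (window < 3 || window %% 2 == 0) stop("window must be odd and >= 3")
  if (window >= n) stop("window must be smaller than the profile length")
  h <- (window - 1L) %/% 2L
  slide <- function(x, fun, fill) {
    out <- x
    for (k in seq_len(h)) {
      out <- fun(out,
                 c(x[-seq_len(k)], rep(fill, k)),        # shift left
                 c(rep(fill, k), x[seq_len(n - k)]))     # shift right
    }
    out
  }
  eroded  <- slide(intensity, pmin, Inf)
  opened  <- slide(eroded, pmax, -Inf)
  pmax(intensity - opened, 0)
}

#' Total-ion-current normalisation
#'
#' Divides intensities by their sum so that the output sums to one. On an
#' \linkS4class{MsiDataset}, every spot's peak list is normalised
#' independently; spots without peaks are left alone.
#'
#' @param x numeric intensity vector or an \linkS4class{MsiDataset}.
#' @return the same type, normalised.
#' @export
normalizeTic <- function(x) {
  if (is(x, "MsiDataset")) return(.normalizeDataset(x, normalizeTic))
  tot <- sum(x)
  if (tot <= 0) stop("cannot TIC-normalise an all-zero spectrum")
  x / tot
}

#' Root-mean-square normalisation
#'
#' Divides intensities by sqrt(mean(x^2)) so that the output has RMS one.
#'
#' @inheritParams normalizeTic
#' @return the same type, normalised.
#' @export
normalizeRms <- function(x) {
  if (is(x, "MsiDataset")) return(.normalizeDataset(x, normalizeRms))
  rms <- sqrt(mean(x^2))
  if (rms <= 0) stop("cannot RMS-normalise an all-zero spectrum")
  x / rms
}

.normalizeDataset <- function(dataset, fun) {
  p <- peakData(dataset)
  if (nrow(p))
    p$intensity <- unsplit(lapply(split(p$intensity, p$spot_id), fun),
                           p$spot_id)
  initialize(dataset, peaks = p)
}

#' Peak-preserving profile reduction
#'
#' Resamples a raw profile onto \code{nPoints} equally spaced m/z nodes,
#' keeping the maximum intensity within each node's half-open interval so
#' that peak apexes are never lost. Profiles already at or below the target
#' size are returned unchanged. Intervals containing no input point get
#' intensity zero.
#'
#' @param profile data.frame with ascending \code{mz} and \code{intensity}.
#' @param nPoints target number of points (>= 2).
#' @return data.frame with \code{mz} (interval centres) and \code{intensity}.
#' @export
reduceProfile <- function(profile, nPoints) {
  if (nPoints < 2) stop("nPoints must be >= 2")
  n <- nrow(profile)
  if (n <= nPoints) return(profile)
  edges <- seq(min(profile$mz), max(profile$mz), length.out = nPoints + 1L)
  idx <- findInterval(profile$mz, edges, rightmost.closed = TRUE)
  intensity <- rep(0, nPoints)
  mx <- tapply(profile$intensity, idx, max)
  intensity[as.integer(names(mx))] <- mx
  data.frame(mz = (edges[-1L] + edges[-(nPoints + 1L)]) / 2, intensity = intensity)
}

#' Fit a quadratic internal recalibration
#'
#' Matches each reference calibrant mass to the nearest observed peak within
#' a search tolerance, then least-squares fits
#' corrected = a*m^2 + b*m + c mapping observed to reference. At least three
#' matched pairs are required; with exactly three the fit interpolates and
#' residuals are zero.
#'
#' @param observed observed calibrant-spectrum m/z values (Da).
#' @param reference reference masses (e.g. the calibration standard's
#'   sodiated masses).
#' @param tolerancePpm match search tolerance (default 500 ppm).
#' @return a \linkS4class{CalibrationModel}.
#' @export
fitRecalibration <- function(observed, reference, tolerancePpm = 500) {
  obs <- vapply(reference, function(r) {
    d <- abs(observed - r)
    i <- which.min(d)
    if (length(i) && d[i] / r * 1e6 <= tolerancePpm) observed[i] else NA_real_
  }, numeric(1))
  ok <- !is.na(obs)
  if (sum(ok) < 3) stop("need at least 3 matched calibrant pairs, got ", sum(ok))
  obs <- obs[ok]; ref <- reference[ok]
  if (anyDuplicated(obs)) stop("degenerate calibration: duplicate observed masses")
  fit <- stats::lm(ref ~ obs + I(obs^2))
  cf <- stats::setNames(as.numeric(stats::coef(fit)), c("c", "b", "a"))
  corrected <- cf["c"] + cf["b"] * obs + cf["a"] * obs^2
  new("CalibrationModel", coefficients = cf,
      residualsPpm = 1e6 * (corrected - ref) / ref,
      calibrants = data.frame(observed = obs, reference = ref))
}

#' Evaluate a calibration model at observed m/z values
#'
#' @param model a \linkS4class{CalibrationModel}.
#' @param mz observed m/z values.
#' @return corrected m/z values.
#' @export
predictMz <- function(model, mz) {
  cf <- model@coefficients
  unname(cf["c"] + cf["b"] * mz + cf["a"] * mz^2)
}

#' Apply a calibration model to a dataset
#'
#' Transforms every peak m/z for the spots in scope. The model must be
#' monotone increasing over the acquisition range so peak order is
#' preserved; corrected peaks pushed outside the range are dropped.
#'
#' @param model a \linkS4class{CalibrationModel}.
#' @param dataset an \linkS4class{MsiDataset}.
#' @param scope spot ids to transform; default all spots ("the best
#'   calibration is copied to all MS spots").
#' @return the recalibrated \linkS4class{MsiDataset}.
#' @export
applyRecalibration <- function(model, dataset, scope = NULL) {
  cf <- model@coefficients
  r <- mzRange(dataset)
  ## derivative 2a*m + b is linear: positive at both ends => positive throughout
  if (2 * cf["a"] * r[1] + cf["b"] <= 0 || 2 * cf["a"] * r[2] + cf["b"] <= 0)
    stop("calibration model is not monotone increasing over the acquisition range")
  p <- peakData(dataset)
  if (is.null(scope)) scope <- spotData(dataset)$spot_id
  sel <- p$spot_id %in% scope
  p$mz[sel] <- predictMz(model, p$mz[sel])
  keep <- p$mz >= r[1] & p$mz < r[2]
  MsiDataset(spotData(dataset), p[keep, , drop = FALSE], r)
}

#' Bin peak lists into a spot-by-m/z matrix
#'
#' Sums each spot's peak intensities into fixed-width half-open bins
#' \code{[lo, hi)}; total in-range intensity is conserved. The result is a
#' \link[SummarizedExperiment]{SummarizedExperiment} with bins as rows
#' (rowData \code{mz_lo}, \code{mz_hi}) and spots as columns (colData from
#' \code{\link{spotData}}), assay \code{"intensity"}.
#'
#' @param dataset an \linkS4class{MsiDataset}.
#' @param width bin width in Da (default 0.5).
#' @param range binning range \code{c(lo, hi)}; default the acquisition
#'   range.
#' @return a SummarizedExperiment.
#' @export
binSpectra <- function(dataset, width = 0.5, range = mzRange(dataset)) {
  if (width <= 0) stop("width must be > 0")
  if (diff(range) <= 0) stop("range must be increasing")
  nbin <- ceiling((range[2] - range[1]) / width)
  spots <- spotData(dataset)
  p <- peakData(dataset)
  m <- matrix(0, nrow = nbin, ncol = nrow(spots),
              dimnames = list(NULL, spots$spot_id))
  if (nrow(p)) {
    inr <- p$mz >= range[1] & p$mz < range[2]
    p <- p[inr, , drop = FALSE]
    bin <- floor((p$mz - range[1]) / width) + 1L
    col <- match(p$spot_id, spots$spot_id)
    key <- (col - 1L) * nbin + bin   # linear index into m
    sums <- rowsum(p$intensity, key)
    m[as.integer(rownames(sums))] <- sums
  }
  lo <- range[1] + width * (seq_len(nbin) - 1L)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = m),
    rowData = S4Vectors::DataFrame(mz_lo = lo, mz_hi = lo + width),
    colData = S4Vectors::DataFrame(spots, row.names = spots$spot_id))
}
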