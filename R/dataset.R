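#' Construct a spatial peak-list dataset
#'
#' @param spots data.frame with columns \code{spot_id, x, y, region}.
#' @param peaks data.frame with columns \code{spot_id, mz, intensity, snr}.
#'   Peaks are sorted by m/z within spot on construction; peaks outside
#'   \code{mzRange} are an error (filter on read instead).
#' @param mzRange acquisition m/z window, default 800-4500.
#' @return an \linkS4class{MsiDataset}.
#' @export
MsiDataset <- function(spots, peaks, mzRange = c(800, 4500)) {
  spots <- as.data.frame(spots, stringsAsFactors = FALSE)
  spots$spot_id <- as.character(spots$spot_id)
  peaks <- as.data.frame(peaks, stringsAsFactors = FALSE)
  if (nrow(peaks)) {
    peaks$spot_id <- as.character(peaks$spot_id)
    peaks <- peaks[order(peaks$spot_id, peaks$mz), , drop = FALSE]
    rownames(peaks) <- NULL
  }
  new("MsiDataset", spots = spots, peaks = peaks, mzRange = as.numeric(mzRange))
}

#' @describeIn MsiDataset spot metadata accessor.
#' @param object,x an \code{MsiDataset}.
#' @export
spotData <- function(object) object@spots

#' @describeIn MsiDataset pooled peak table accessor.
#' @export
peakData <- function(object) object@peaks

#' @describeIn MsiDataset acquisition m/z range accessor.
#' @export
mzRange <- function(object) object@mzRange

setMethod("show", "MsiDataset", function(object) {
  cat("MsiDataset:", nrow(object@spots), "spots,", nrow(object@peaks),
      "peaks, m/z range [", object@mzRange[1], ",", object@mzRange[2], ")\n")
  print(table(region = object@spots$region))
})

.parseError <- function(file, line, msg) {
  stop(sprintf("%s (file %s, line %d)", msg, file, line), call. = FALSE)
}

#' Read a spatial peak-list dataset from a manifest
#'
#' The manifest is a CSV with columns \code{spot_id, x, y, region, file};
#' each \code{file} is a tab-separated peak list with header
#' \code{mz\\tintensity\\tsnr}, one peak per line, resolved relative to
#' \code{dir} (default: the manifest's directory). Peaks are sorted on load;
#' peaks outside \code{mzRange} are dropped, mirroring the instrument's
#' acquisition window and matrix suppression.
#'
#' @param manifest manifest CSV path.
#' @param dir directory holding the peak-list files.
#' @param mzRange acquisition window applied on read.
#' @return an \linkS4class{MsiDataset}.
#' @export
readImagingDataset <- function(manifest, dir = dirname(manifest),
                               mzRange = c(800, 4500)) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("spot_id", "x", "y", "region", "file")
  if (!all(need %in% names(man)))
    stop("manifest ", manifest, " must have columns: ", paste(need, collapse = ", "))
  dup <- duplicated(man$spot_id)
  if (any(dup))
    .parseError(manifest, which(dup)[1] + 1L,
                paste0("duplicate spot id '", man$spot_id[which(dup)[1]], "'"))
  bad <- !man$region %in% .regionLevels
  if (any(bad))
    .parseError(manifest, which(bad)[1] + 1L,
                paste0("unknown region label '", man$region[which(bad)[1]], "'"))
  pk <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    f <- file.path(dir, man$file[i])
    if (!file.exists(f)) .parseError(manifest, i + 1L, paste("missing peak file", f))
    p <- utils::read.delim(f, stringsAsFactors = FALSE)
    if (!all(c("mz", "intensity", "snr") %in% names(p)))
      .parseError(f, 1L, "peak list must have header mz<TAB>intensity<TAB>snr")
    if (nrow(p)) {
      badrow <- which(!is.finite(p$mz) | !is.finite(p$intensity) | !is.finite(p$snr))
      if (length(badrow)) .parseError(f, badrow[1] + 1L, "malformed peak row")
      p <- p[p$mz >= mzRange[1] & p$mz < mzRange[2], , drop = FALSE]
    }
    if (nrow(p)) pk[[i]] <- data.frame(spot_id = man$spot_id[i], p[c("mz", "intensity", "snr")],
                                       stringsAsFactors = FALSE)
  }
  peaks <- do.call(rbind, pk[!vapply(pk, is.null, logical(1))])
  if (is.null(peaks))
    peaks <- data.frame(spot_id = character(), mz = numeric(),
                        intensity = numeric(), snr = numeric())
  MsiDataset(man[c("spot_id", "x", "y", "region")], peaks, mzRange)
}

#' Write a dataset as manifest plus peak-list files
#'
#' Inverse of \code{\link{readImagingDataset}}; used to materialise phantom
#' datasets in the on-disk interchange format.
#'
#' @param dataset an \linkS4class{MsiDataset}.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeImagingDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- spotData(dataset)
  man$file <- paste0(man$spot_id, ".txt")
  byspot <- split(peakData(dataset), peakData(dataset)$spot_id)
  for (i in seq_len(nrow(man))) {
    p <- byspot[[man$spot_id[i]]]
    if (is.null(p)) p <- data.frame(mz = numeric(), intensity = numeric(), snr = numeric())
    utils::write.table(p[c("mz", "intensity", "snr")],
                       file.path(dir, man$file[i]),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(man, manifest, row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
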