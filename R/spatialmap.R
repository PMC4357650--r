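#' Build a spatial map from per-spot values
#'
#' Places a named per-spot value vector onto the acquisition grid implied by
#' the dataset's 0-based (x, y) coordinates (x rightward, y downward).
#' Grid cells without an acquired spot are NA and masked out.
#'
#' @param dataset an \linkS4class{MsiDataset}.
#' @param values numeric vector named by spot id (spots absent from
#'   \code{values} get NA).
#' @param what short label for the mapped quantity.
#' @return a \linkS4class{SpatialMap}.
#' @export
spatialMap <- function(dataset, values, what = "value") {
  spots <- spotData(dataset)
  nx <- max(spots$x) + 1L
  ny <- max(spots$y) + 1L
  v <- matrix(NA_real_, nrow = ny, ncol = nx)
  mask <- matrix(FALSE, nrow = ny, ncol = nx)
  idx <- cbind(spots$y + 1L, spots$x + 1L)
  mask[idx] <- TRUE
  v[idx] <- unname(values[spots$spot_id])
  new("SpatialMap", values = v, mask = mask, what = what)
}

#' @describeIn spatialMap value matrix accessor (ny x nx).
#' @param map a \code{SpatialMap}.
#' @export
mapValues <- function(map) map@values

#' @describeIn spatialMap acquisition mask accessor.
#' @export
mapMask <- function(map) map@mask

setMethod("show", "SpatialMap", function(object) {
  cat("SpatialMap (", object@what, "): ", ncol(object@values), " x ",
      nrow(object@values), " grid, ", sum(object@mask), " acquired spots\n",
      sep = "")
})

#' 3x3 spatial median filter
#'
#' Optional smoothing for display maps: each on-mask value is replaced by
#' the median of the on-mask values in its 3x3 neighbourhood. A crude
#' stand-in for the heavier proprietary smoothing of commercial MSI
#' software; documented as non-equivalent.
#'
#' @param map a \linkS4class{SpatialMap}.
#' @return the filtered \linkS4class{SpatialMap}.
#' @export
medianFilterMap <- function(map) {
  v <- map@values; out <- v
  ny <- nrow(v); nx <- ncol(v)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    if (!map@mask[i, j]) next
    nb <- v[max(1, i - 1):min(ny, i + 1), max(1, j - 1):min(nx, j + 1)]
    out[i, j] <- stats::median(nb, na.rm = TRUE)
  }
  initialize(map, values = out)
}
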