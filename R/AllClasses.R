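#' @import methods
NULL

.regionLevels <- c("treated", "control", "calibrant", "none")

#' Glycan composition
#'
#' Counts of monosaccharide residue classes defining a neutral N-glycan:
#' hexose (Man/Gal/Glc), N-acetylhexosamine (GlcNAc/GalNAc), deoxyhexose
#' (fucose), N-acetylneuraminic acid and N-glycolylneuraminic acid. The
#' all-zero composition is legal and has the mass of one water.
#'
#' @slot hex,hexnac,dhex,neuac,neugc non-negative integer residue counts.
#' @export
setClass("GlycanComposition",
  representation(hex = "integer", hexnac = "integer", dhex = "integer",
                 neuac = "integer", neugc = "integer"),
  prototype(hex = 0L, hexnac = 0L, dhex = 0L, neuac = 0L, neugc = 0L))

setValidity("GlycanComposition", function(object) {
  n <- c(object@hex, object@hexnac, object@dhex, object@neuac, object@neugc)
  if (length(n) != 5L || anyNA(n)) return("all five residue counts must be single non-missing integers")
  if (any(n < 0L)) return("residue counts must be non-negative")
  TRUE
})

#' Spatially referenced peak-list dataset
#'
#' One centroided peak list (m/z, intensity, S/N) per acquisition spot, plus
#' spot metadata: unique spot id, integer grid coordinates (0-based, x
#' rightward, y downward) and a region label from
#' \code{c("treated", "control", "calibrant", "none")}.
#'
#' @slot spots data.frame with columns \code{spot_id, x, y, region}.
#' @slot peaks data.frame with columns \code{spot_id, mz, intensity, snr},
#'   sorted by m/z within spot.
#' @slot mzRange numeric(2), the acquisition m/z window; peaks outside it are
#'   rejected on construction.
#' @export
setClass("MsiDataset",
  representation(spots = "data.frame", peaks = "data.frame",
                 mzRange = "numeric"))

setValidity("MsiDataset", function(object) {
  s <- object@spots; p <- object@peaks
  need <- c("spot_id", "x", "y", "region")
  if (!all(need %in% names(s))) return("spots must have columns spot_id, x, y, region")
  if (anyDuplicated(s$spot_id)) return("duplicate spot ids")
  if (anyDuplicated(s[c("x", "y")])) return("duplicate spot coordinates")
  if (!all(s$region %in% .regionLevels))
    return(sprintf("region labels must be one of: %s", paste(.regionLevels, collapse = ", ")))
  needp <- c("spot_id", "mz", "intensity", "snr")
  if (!all(needp %in% names(p))) return("peaks must have columns spot_id, mz, intensity, snr")
  if (nrow(p)) {
    if (anyNA(p$mz) || anyNA(p$intensity) || anyNA(p$snr)) return("NA in peak table")
    if (!all(p$spot_id %in% s$spot_id)) return("peaks reference unknown spot ids")
    if (any(p$intensity < 0) || any(p$snr < 0)) return("negative intensity or snr")
    if (length(object@mzRange) == 2 &&
        (any(p$mz < object@mzRange[1]) || any(p$mz >= object@mzRange[2])))
      return("peak m/z outside acquisition range")
    if (any(vapply(split(p$mz, p$spot_id), is.unsorted, logical(1))))
      return("peaks must be sorted by m/z within spot")
  }
  if (length(object@mzRange) != 2 || diff(object@mzRange) <= 0)
    return("mzRange must be an increasing numeric(2)")
  TRUE
})

#' Quadratic mass recalibration model
#'
#' Maps observed to corrected m/z via corrected = a*m^2 + b*m + c, fit by
#' least squares to matched calibrant pairs.
#'
#' @slot coefficients named numeric(3): \code{c} (intercept), \code{b}
#'   (linear), \code{a} (quadratic).
#' @slot residualsPpm signed ppm residuals at the calibrants after correction.
#' @slot calibrants data.frame of the matched (observed, reference) pairs.
#' @export
setClass("CalibrationModel",
  representation(coefficients = "numeric", residualsPpm = "numeric",
                 calibrants = "data.frame"))

setValidity("CalibrationModel", function(object) {
  if (length(object@coefficients) != 3) return("coefficients must be numeric(3)")
  if (!identical(names(object@coefficients), c("c", "b", "a")))
    return("coefficients must be named c, b, a")
  TRUE
})

#' Peak groups from single-linkage m/z clustering
#'
#' @slot peaks the pooled peak table with an added integer \code{group}
#'   column assigning every peak to exactly one group.
#' @slot groups per-group summary: \code{group_id}, S/N-weighted mean m/z
#'   \code{awm_mz}, m/z span, member count, and whether S/N weights were
#'   usable (\code{snr_weighted}; groups whose S/N sum is zero fall back to
#'   the unweighted mean and are flagged).
#' @slot linkage the gap-cut distance in Da.
#' @export
setClass("PeakGroups",
  representation(peaks = "data.frame", groups = "data.frame",
                 linkage = "numeric"))

setValidity("PeakGroups", function(object) {
  g <- object@groups
  if (nrow(g)) {
    if (any(g$awm_mz < g$mz_min - 1e-9) || any(g$awm_mz > g$mz_max + 1e-9))
      return("awm outside member m/z span")
    if (is.unsorted(g$awm_mz)) return("groups must be ordered by awm_mz")
  }
  if (nrow(object@peaks) != sum(g$n_peaks)) return("group sizes do not partition the peaks")
  TRUE
})

#' Per-spot scalar field on the acquisition grid
#'
#' @slot values numeric matrix (ny rows, nx columns); NA off the mask.
#' @slot mask logical matrix of acquired spots.
#' @slot what short description of the quantity (e.g. "dipps_count").
#' @export
setClass("SpatialMap",
  representation(values = "matrix", mask = "matrix", what = "character"))

setValidity("SpatialMap", function(object) {
  if (!identical(dim(object@values), dim(object@mask)))
    return("values and mask dimensions differ")
  if (any(!is.na(object@values[!object@mask])))
    return("values defined off the acquisition mask")
  TRUE
})

#' Bisecting k-means segmentation tree
#'
#' Binary tree over the spot set; each node holds its member spots and
#' within-node inertia (summed correlation distance to the node mean
#' spectrum). Cutting after any number of splits yields a partition.
#'
#' @slot nodes list of nodes (id, parent, children, spots, inertia).
#' @slot splitOrder node ids in the order they were split.
#' @slot spotIds all spot ids the tree was built on.
#' @export
setClass("SegmentationTree",
  representation(nodes = "list", splitOrder = "integer", spotIds = "character"))

#' Probabilistic latent semantic analysis model
#'
#' Multinomial aspect model p(spot, bin) = sum_z p(z) p(spot|z) p(bin|z),
#' fit by EM with random initialisation.
#'
#' @slot k number of components.
#' @slot pComponent length-k simplex p(z).
#' @slot pSpot nSpot x k column-stochastic matrix p(spot|z).
#' @slot pBin nBin x k column-stochastic matrix p(bin|z).
#' @slot logLik per-iteration log-likelihood trace (nondecreasing).
#' @slot spotIds spots included in the fit (zero-total spots are excluded).
#' @slot excluded spot ids excluded for zero total intensity.
#' @export
setClass("PlsaModel",
  representation(k = "integer", pComponent = "numeric", pSpot = "matrix",
                 pBin = "matrix", logLik = "numeric", spotIds = "character",
                 excluded = "character"))

setValidity("PlsaModel", function(object) {
  tol <- 1e-9
  if (abs(sum(object@pComponent) - 1) > tol) return("p(z) must sum to 1")
  if (any(object@pComponent < -tol) || any(object@pSpot < -tol) || any(object@pBin < -tol))
    return("negative probabilities")
  if (any(abs(colSums(object@pSpot) - 1) > 1e-9)) return("p(spot|z) columns must sum to 1")
  if (any(abs(colSums(object@pBin) - 1) > 1e-9)) return("p(bin|z) columns must sum to 1")
  if (length(object@logLik) > 1 && any(diff(object@logLik) < -1e-6))
    return("log-likelihood trace must be nondecreasing")
  TRUE
})

#' Phantom tissue-section specification
#'
#' Describes a synthetic two-region (cortex annulus / medulla core) tissue
#' section with a PNGase F-treated zone, a buffer-control rectangle and
#' calibrant spots, plus the glycans planted in it with per-zone prevalence,
#' m/z jitter, S/N and intensity models, and a uniform noise-peak rate.
#'
#' @slot nx,ny grid dimensions.
#' @slot masks list of ny x nx logical matrices: \code{cortex},
#'   \code{medulla}, \code{control}, \code{calibrant} (pairwise disjoint).
#' @slot glycans data.frame: name, hex, hexnac, dhex, neuac, neugc,
#'   prev_cortex, prev_medulla, prev_control (prevalences in [0, 1]).
#' @slot jitterSd m/z jitter standard deviation (Da).
#' @slot noiseRate expected uniform noise peaks per spectrum (Poisson mean).
#' @slot snrMean,noiseSnrMean mean excess S/N above the picking floor of 3
#'   for planted and noise peaks (exponential).
#' @slot intensityMeanlog,intensitySdlog log-normal intensity parameters.
#' @slot mzRange acquisition window (Da).
#' @slot glycosylamineFraction fraction of planted peaks emitted as the
#'   -0.984 Da glycosylamine satellite instead of the free reducing end.
#' @export
setClass("PhantomSpec",
  representation(nx = "integer", ny = "integer", masks = "list",
                 glycans = "data.frame", jitterSd = "numeric",
                 noiseRate = "numeric", snrMean = "numeric",
                 noiseSnrMean = "numeric", intensityMeanlog = "numeric",
                 intensitySdlog = "numeric", mzRange = "numeric",
                 glycosylamineFraction = "numeric"))

setValidity("PhantomSpec", function(object) {
  m <- object@masks
  need <- c("cortex", "medulla", "control", "calibrant")
  if (!all(need %in% names(m))) return("masks must contain cortex, medulla, control, calibrant")
  dims <- vapply(m[need], dim, integer(2))
  if (!all(dims[1, ] == object@ny) || !all(dims[2, ] == object@nx))
    return("all masks must be ny x nx")
  overlap <- m$cortex + m$medulla + m$control + m$calibrant
  if (any(overlap > 1)) return("masks must be pairwise disjoint")
  g <- object@glycans
  pcols <- c("prev_cortex", "prev_medulla", "prev_control")
  if (!all(pcols %in% names(g))) return("glycans must carry per-zone prevalences")
  pv <- unlist(g[pcols])
  if (length(pv) && (any(pv < 0) || any(pv > 1))) return("prevalences must lie in [0, 1]")
  if (object@jitterSd < 0 || object@noiseRate < 0) return("jitterSd and noiseRate must be >= 0")
  if (object@glycosylamineFraction < 0 || object@glycosylamineFraction > 1)
    return("glycosylamineFraction must lie in [0, 1]")
  TRUE
})

#' Ground truth for a generated phantom
#'
#' @slot glycans data.frame: name, true_mz (sodiated), p_treated (prevalence
#'   averaged over the treated tissue zones by area), p_control, and
#'   expected_dipps = p_treated - p_control.
#' @slot masks the region masks the phantom was generated from.
#' @export
setClass("PhantomTruth",
  representation(glycans = "data.frame", masks = "list"))
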