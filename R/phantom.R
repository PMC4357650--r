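.ellipseMask <- function(nx, ny, cx, cy, rx, ry) {
  x <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
  y <- matrix(rep(0:(ny - 1), nx), ny, nx)
  ((x - cx) / rx)^2 + ((y - cy) / ry)^2 <= 1
}

.rectMask <- function(nx, ny, x0, x1, y0, y1) {
  x <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
  y <- matrix(rep(0:(ny - 1), nx), ny, nx)
  x >= x0 & x <= x1 & y >= y0 & y <= y1
}

#' Construct a phantom specification
#'
#' @param nx,ny grid dimensions.
#' @param masks list of ny x nx logical matrices \code{cortex},
#'   \code{medulla}, \code{control}, \code{calibrant}.
#' @param glycans data.frame with composition counts and per-zone
#'   prevalences (see \linkS4class{PhantomSpec}).
#' @param jitterSd m/z jitter SD in Da; the default 0.02 keeps jitter well
#'   below a quarter of the 0.1 Da grouping linkage.
#' @param noiseRate expected uniform noise peaks per spectrum.
#' @param snrMean,noiseSnrMean mean excess S/N above the picking floor of 3.
#' @param intensityMeanlog,intensitySdlog log-normal intensity parameters
#'   for planted peaks (noise peaks use a quarter of the median intensity).
#' @param mzRange acquisition window.
#' @param glycosylamineFraction fraction of planted peaks emitted as the
#'   -0.984 Da glycosylamine satellite.
#' @return a validated \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(nx, ny, masks, glycans, jitterSd = 0.02,
                        noiseRate = 5, snrMean = 12, noiseSnrMean = 2,
                        intensityMeanlog = log(50), intensitySdlog = 0.6,
                        mzRange = c(800, 4500), glycosylamineFraction = 0) {
  new("PhantomSpec", nx = as.integer(nx), ny = as.integer(ny), masks = masks,
      glycans = glycans, jitterSd = jitterSd, noiseRate = noiseRate,
      snrMean = snrMean, noiseSnrMean = noiseSnrMean,
      intensityMeanlog = intensityMeanlog, intensitySdlog = intensitySdlog,
      mzRange = as.numeric(mzRange),
      glycosylamineFraction = glycosylamineFraction)
}

#' Default kidney-section phantom specification
#'
#' A 60 x 40 grid holding an elliptical tissue section with a cortex
#' annulus around a medulla core (the whole section PNGase F-treated), a
#' buffer-control rectangle on the right, and four calibrant spots. The
#' nine murine-kidney N-glycans are planted at their sodiated masses:
#' cortex-restricted species (the fucosylated complex glycans, mirroring the
#' cortex-specific 2304.9 signal), medulla-enriched oligomannose species,
#' and shared species; the control rectangle carries no glycans.
#'
#' @return a \linkS4class{PhantomSpec}.
#' @export
defaultKidneySpec <- function() {
  nx <- 60L; ny <- 40L
  outer <- .ellipseMask(nx, ny, cx = 14, cy = 19.5, rx = 12.5, ry = 16.5)
  inner <- .ellipseMask(nx, ny, cx = 14, cy = 19.5, rx = 6.5, ry = 9)
  masks <- list(cortex = outer & !inner,
                medulla = inner,
                control = .rectMask(nx, ny, 34, 57, 8, 31),
                calibrant = .rectMask(nx, ny, 30, 31, 36, 37))
  lib <- readGlycanLibrary(system.file("extdata", "kidney_glycans.csv",
                                       package = "glycoMSI"))
  plant <- data.frame(
    name = c("Hex5HexNAc5dHex3", "Hex5HexNAc5dHex2", "Hex4HexNAc5dHex1",
             "Hex5HexNAc4dHex1", "Man9GlcNAc2", "Man6GlcNAc2",
             "Man5GlcNAc2", "Man8GlcNAc2", "Man7GlcNAc2"),
    prev_cortex  = c(0.90, 0.90, 0.85, 0.85, 0.10, 0.10, 0.80, 0.80, 0.80),
    prev_medulla = c(0.00, 0.00, 0.05, 0.05, 0.90, 0.90, 0.80, 0.80, 0.80),
    prev_control = 0)
  glycans <- merge(plant, lib[c("name", "hex", "hexnac", "dhex", "neuac", "neugc")],
                   by = "name", sort = FALSE)
  phantomSpec(nx, ny, masks, glycans)
}

#' GLY3 calibrant-spot peak lists under a known mass distortion
#'
#' Emits, for each calibrant spot, the three calibration-standard sodiated
#' masses pushed through the distortion observed = c + b*m + a*m^2 (identity
#' by default), enabling end-to-end recalibration round trips.
#'
#' @param distortion named numeric(3) \code{c(c=, b=, a=)}; must be monotone
#'   increasing over the standard's mass range.
#' @param nSpots number of calibrant spots (default 2).
#' @return list of \code{nSpots} peak-list data.frames (mz, intensity, snr).
#' @export
makeGly3CalibrantSpots <- function(distortion = c(c = 0, b = 1, a = 0), nSpots = 2L) {
  lib <- readGlycanLibrary(system.file("extdata", "gly3_standards.csv",
                                       package = "glycoMSI"))
  m <- sort(lib$sodiated_mz)
  obs <- distortion["c"] + distortion["b"] * m + distortion["a"] * m^2
  if (is.unsorted(obs, strictly = TRUE))
    stop("distortion must be monotone increasing over the calibrant range")
  replicate(nSpots,
            data.frame(mz = unname(obs), intensity = 1000, snr = 50),
            simplify = FALSE)
}

#' Generate a phantom imaging dataset with ground truth
#'
#' For every spot and planted glycan, presence is a Bernoulli draw at the
#' zone prevalence; present glycans emit a peak at the sodiated mass plus
#' Normal(0, jitterSd) jitter, with log-normal intensity and S/N of 3 plus
#' an exponential excess (the truncation mirroring an S/N > 3 picking
#' threshold). Every non-calibrant spot also receives Poisson(noiseRate)
#' uniform noise peaks; calibrant spots carry the calibration standard.
#' Fully reproducible from \code{seed}.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param seed integer RNG seed.
#' @return list with \code{dataset} (an \linkS4class{MsiDataset}) and
#'   \code{truth} (a \linkS4class{PhantomTruth}).
#' @export
makePhantom <- function(spec, seed = 1L) {
  validObject(spec)
  set.seed(seed)
  nx <- spec@nx; ny <- spec@ny
  x <- rep(0:(nx - 1), each = ny); y <- rep(0:(ny - 1), nx)
  idx <- cbind(y + 1L, x + 1L)
  zone <- ifelse(spec@masks$cortex[idx], "cortex",
          ifelse(spec@masks$medulla[idx], "medulla",
          ifelse(spec@masks$control[idx], "control",
          ifelse(spec@masks$calibrant[idx], "calibrant", "none"))))
  region <- ifelse(zone %in% c("cortex", "medulla"), "treated",
            ifelse(zone == "control", "control",
            ifelse(zone == "calibrant", "calibrant", "none")))
  spot_id <- sprintf("s%02d_%02d", x, y)
  spots <- data.frame(spot_id = spot_id, x = x, y = y, region = region,
                      stringsAsFactors = FALSE)
  g <- spec@glycans
  trueMz <- vapply(seq_len(nrow(g)), function(i)
    sodiatedMz(GlycanComposition(g$hex[i], g$hexnac[i], g$dhex[i],
                                 g$neuac[i], g$neugc[i])), numeric(1))
  ## planted peaks: Bernoulli presence per (glycan, spot) at zone prevalence
  prev <- rbind(cortex = g$prev_cortex, medulla = g$prev_medulla,
                control = g$prev_control, calibrant = 0, none = 0)
  pmat <- prev[zone, , drop = FALSE]                   # nspots x nglycan
  present <- matrix(stats::runif(length(pmat)) < pmat, nrow(pmat))
  spotIdx <- which(present, arr.ind = TRUE)
  nP <- nrow(spotIdx)
  glyMz <- trueMz[spotIdx[, 2]]
  if (spec@glycosylamineFraction > 0) {
    amine <- stats::runif(nP) < spec@glycosylamineFraction
    glyMz[amine] <- glyMz[amine] + .glycosylamineIncrement
  }
  planted <- data.frame(
    spot_id = spot_id[spotIdx[, 1]],
    mz = glyMz + stats::rnorm(nP, 0, spec@jitterSd),
    intensity = stats::rlnorm(nP, spec@intensityMeanlog, spec@intensitySdlog),
    snr = 3 + stats::rexp(nP, 1 / spec@snrMean))
  ## uniform noise peaks on every non-calibrant spot
  noiseSpots <- which(zone != "calibrant")
  nNoise <- stats::rpois(length(noiseSpots), spec@noiseRate)
  noise <- data.frame(
    spot_id = rep(spot_id[noiseSpots], nNoise),
    mz = stats::runif(sum(nNoise), spec@mzRange[1], spec@mzRange[2]),
    intensity = stats::rlnorm(sum(nNoise), spec@intensityMeanlog - 2,
                              spec@intensitySdlog),
    snr = 3 + stats::rexp(sum(nNoise), 1 / spec@noiseSnrMean))
  ## calibrant spots carry the calibration standard
  calSpots <- which(zone == "calibrant")
  calPeaks <- NULL
  if (length(calSpots)) {
    cal <- makeGly3CalibrantSpots(nSpots = length(calSpots))
    calPeaks <- do.call(rbind, Map(function(id, p)
      data.frame(spot_id = id, p), spot_id[calSpots], cal))
  }
  peaks <- rbind(planted, noise, calPeaks)
  peaks <- peaks[peaks$mz >= spec@mzRange[1] & peaks$mz < spec@mzRange[2], ]
  dataset <- MsiDataset(spots, peaks, spec@mzRange)
  nCortex <- sum(spec@masks$cortex); nMedulla <- sum(spec@masks$medulla)
  pTreated <- (g$prev_cortex * nCortex + g$prev_medulla * nMedulla) /
    (nCortex + nMedulla)
  truth <- new("PhantomTruth",
               glycans = data.frame(name = g$name, true_mz = trueMz,
                                    p_treated = pTreated,
                                    p_control = g$prev_control,
                                    expected_dipps = pTreated - g$prev_control),
               masks = spec@masks)
  list(dataset = dataset, truth = truth)
}

#' @describeIn makePhantom ground-truth glycan table accessor.
#' @param truth a \code{PhantomTruth}.
#' @export
truthGlycans <- function(truth) truth@glycans
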