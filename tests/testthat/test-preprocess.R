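test_that("TopHat baseline equals the brute-force morphological opening", {
  # constant profile: opening is the profile, residual all zero
  expect_equal(tophatBaseline(rep(3.5, 50), 5), rep(0, 50))
  # isolated spike narrower than the window passes through at full height
  spike <- rep(0, 30); spike[12] <- 7
  expect_equal(tophatBaseline(spike, 5), spike)
  # ramp residual matches the direct min/max filter
  ramp <- as.numeric(0:9)
  expect_equal(tophatBaseline(ramp, 3), ramp - bruteOpening(ramp, 3))
  # random profiles of varied length and window
  set.seed(11)
  for (i in 1:60) {
    n <- sample(10:200, 1)
    w <- sample(c(3, 5, 7, 9), 1)
    x <- pmax(rnorm(n, 10, 4), 0) + 5 * sin(seq(0, 3, length.out = n))
    expect_equal(tophatBaseline(x, w), x - bruteOpening(x, w))
  }
  expect_error(tophatBaseline(rep(1, 10), 4), "odd")
  expect_error(tophatBaseline(rep(1, 10), 11), "smaller")
})

test_that("TIC and RMS normalisation have their defining properties", {
  expect_equal(normalizeTic(c(1, 3)), c(0.25, 0.75))
  expect_equal(normalizeRms(c(3, 4)), c(0.84853, 1.13137), tolerance = 1e-5)
  expect_equal(normalizeRms(rep(7, 6)), rep(1, 6))
  set.seed(3)
  x <- runif(40, 0, 100)
  expect_equal(sum(normalizeTic(x)), 1, tolerance = 1e-12)
  expect_equal(sqrt(mean(normalizeRms(x)^2)), 1, tolerance = 1e-12)
  # idempotence
  expect_equal(normalizeTic(normalizeTic(x)), normalizeTic(x))
  expect_equal(normalizeRms(normalizeRms(x)), normalizeRms(x))
  expect_error(normalizeTic(c(0, 0)), "all-zero")
  expect_error(normalizeRms(c(0, 0)), "all-zero")
})

test_that("dataset normalisation works spot-wise", {
  d <- makeTestDataset(
    data.frame(spot_id = c("a", "a", "b"), mz = c(1000, 1200, 1100),
               intensity = c(1, 3, 5), snr = 1),
    c(a = "treated", b = "control"))
  out <- peakData(normalizeTic(d))
  expect_equal(out$intensity[out$spot_id == "a"], c(0.25, 0.75))
  expect_equal(out$intensity[out$spot_id == "b"], 1)
})

test_that("profile reduction is peak-preserving interval max-pooling", {
  short <- data.frame(mz = seq(1000, 1099), intensity = runif(100))
  expect_identical(reduceProfile(short, 200), short)
  # a single spike survives reduction in its containing interval
  prof <- data.frame(mz = seq(1000, 1199, by = 1), intensity = 0)
  prof$intensity[73] <- 9
  red <- reduceProfile(prof, 10)
  expect_identical(nrow(red), 10L)
  expect_equal(max(red$intensity), 9)
  expect_equal(sum(red$intensity > 0), 1L)
  # max-pooling preserves monotonicity
  mono <- data.frame(mz = seq(1000, 1999), intensity = seq(0, 999) ^ 1.5)
  expect_false(is.unsorted(reduceProfile(mono, 50)$intensity))
  expect_error(reduceProfile(short, 1), ">= 2")
})

test_that("quadratic recalibration interpolates three calibrants exactly", {
  obs <- c(1256.9225, 1542.0551, 2393.3457)
  ref <- obs + 0.5  # pure shift
  model <- fitRecalibration(obs, ref)
  expect_equal(unname(model@coefficients), c(0.5, 1, 0), tolerance = 1e-8)
  expect_equal(model@residualsPpm, rep(0, 3), tolerance = 1e-6)
  expect_error(fitRecalibration(obs[1:2], ref[1:2]), "at least 3")
})

test_that("recalibration recovers a planted quadratic distortion", {
  truth <- c(c = 0.3, b = 0.9999, a = 2e-8)
  ref <- c(1257.4225, 1542.5551, 2393.8457, 1900.0)
  # distort reference -> observed by inverting the (monotone) truth numerically
  invert <- function(y) vapply(y, function(yy)
    uniroot(function(m) truth["c"] + truth["b"] * m + truth["a"] * m^2 - yy,
            c(500, 5000), tol = 1e-12)$root, numeric(1))
  obs <- invert(ref)
  model <- fitRecalibration(obs[1:3], ref[1:3])
  # held-out fourth point recovered to numerical precision
  expect_equal(predictMz(model, obs[4]), ref[4], tolerance = 1e-9 / ref[4])
  expect_error(fitRecalibration(c(1000, 1000, 2000), c(1000, 1000.1, 2000)),
               "degenerate|at least 3")
})

test_that("applying a calibration transforms peaks and preserves order", {
  d <- makeTestDataset(
    data.frame(spot_id = "a", mz = c(1000.2, 1500.7, 2200.1),
               intensity = 1, snr = 1),
    c(a = "treated"))
  ident <- fitRecalibration(c(1000, 1500, 2000), c(1000, 1500, 2000))
  expect_equal(peakData(applyRecalibration(ident, d))$mz, peakData(d)$mz)
  shift <- fitRecalibration(c(1000, 1500, 2000), c(1000.5, 1500.5, 2000.5))
  expect_equal(peakData(applyRecalibration(shift, d))$mz, peakData(d)$mz + 0.5)
  quad <- fitRecalibration(c(1000, 1500, 2000), c(1000.1, 1500.25, 2000.6))
  cf <- quad@coefficients
  expect_equal(peakData(applyRecalibration(quad, d))$mz,
               cf["c"] + cf["b"] * peakData(d)$mz + cf["a"] * peakData(d)$mz^2,
               ignore_attr = TRUE)
  # a model that folds back over the range is rejected
  bad <- new("CalibrationModel", coefficients = c(c = 0, b = 1, a = -2e-4),
             residualsPpm = numeric(3), calibrants = data.frame())
  expect_error(applyRecalibration(bad, d), "monotone")
})

test_that("binning sums intensities into half-open intervals and conserves mass", {
  d <- makeTestDataset(
    data.frame(spot_id = c("a", "a", "a"), mz = c(1000.2, 1000.4, 1000.5),
               intensity = c(1, 2, 4), snr = 1),
    c(a = "treated"))
  se <- binSpectra(d, width = 0.5, range = c(1000, 1001))
  m <- SummarizedExperiment::assay(se, "intensity")
  expect_equal(dim(m), c(2L, 1L))
  expect_equal(m[, 1], c(3, 4))  # 1000.5 goes to the upper bin
  # conservation on a larger random dataset
  set.seed(5)
  pk <- data.frame(spot_id = sample(c("a", "b"), 200, TRUE),
                   mz = runif(200, 900, 4400), intensity = rexp(200), snr = 1)
  d2 <- makeTestDataset(pk, c(a = "treated", b = "control"))
  se2 <- binSpectra(d2, width = 0.5)
  expect_equal(sum(SummarizedExperiment::assay(se2)), sum(pk$intensity),
               tolerance = 1e-9)
})

test_that("datasets round-trip through the manifest format with validation", {
  dir <- tempfile()
  spots <- data.frame(spot_id = c("s1", "s2"), x = 0:1, y = 0L,
                      region = c("treated", "control"))
  peaks <- data.frame(spot_id = c("s1", "s1", "s2"),
                      mz = c(1200.5, 1100.1, 2000.2),
                      intensity = c(5, 1, 2), snr = c(4, 3, 6))
  d <- MsiDataset(spots, peaks)
  manifest <- writeImagingDataset(d, dir)
  back <- readImagingDataset(manifest)
  expect_equal(spotData(back), spotData(d), ignore_attr = TRUE)
  expect_equal(peakData(back), peakData(d), ignore_attr = TRUE)
  # unsorted input files come back sorted
  expect_false(is.unsorted(peakData(back)$mz[peakData(back)$spot_id == "s1"]))
  # duplicate spot ids are a parse error naming the line
  man <- read.csv(manifest)
  man$spot_id <- "s1"
  write.csv(man, file.path(dir, "dup.csv"), row.names = FALSE)
  expect_error(readImagingDataset(file.path(dir, "dup.csv")), "duplicate spot id")
  # missing peak file
  man2 <- read.csv(manifest)
  man2$file[2] <- "nope.txt"
  write.csv(man2, file.path(dir, "missing.csv"), row.names = FALSE)
  expect_error(readImagingDataset(file.path(dir, "missing.csv")), "missing peak file")
  # malformed peak row is reported with file and line
  writeLines(c("mz\tintensity\tsnr", "1000.1\t2\t3", "oops\t1\t1"),
             file.path(dir, "s1.txt"))
  expect_error(readImagingDataset(manifest), "malformed peak row")
  # acquisition-range filter applies on read
  writeLines(c("mz\tintensity\tsnr", "700.0\t2\t3", "1000.1\t2\t3"),
             file.path(dir, "s1.txt"))
  back2 <- readImagingDataset(manifest)
  expect_equal(nrow(peakData(back2)), 2L)  # the 700 Da peak is suppressed
})
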