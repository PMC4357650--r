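test_that("composition masses reproduce the calibration-standard table", {
  # [M] and [M+Na]+ for the three-component standard, to 0.001 Da
  std <- list(Man5GlcNAc2    = list(GlycanComposition(5, 2), 1234.4333, 1257.4225),
              Man3GlcNAc5    = list(GlycanComposition(3, 5), 1519.5659, 1542.5551),
              Man3Gal4GlcNAc6 = list(GlycanComposition(7, 6), 2370.8565, 2393.8457))
  for (s in std) {
    expect_equal(compositionMass(s[[1]]), s[[2]], tolerance = 0.001 / s[[2]])
    expect_equal(sodiatedMz(s[[1]]), s[[3]], tolerance = 0.001 / s[[3]])
  }
})

test_that("composition mass arithmetic handles edge and derived cases", {
  expect_equal(compositionMass(GlycanComposition()), 18.010565)  # bare water
  expect_equal(compositionMass(GlycanComposition(9, 2)), 1882.6447, tolerance = 1e-7)
  expect_equal(sodiatedMz(GlycanComposition()), 40.9998, tolerance = 1e-4)
  expect_error(GlycanComposition(hex = -1), "non-negative")
  expect_error(GlycanComposition(hex = 1.5), "non-negative integers")
})

test_that("composition mass is additive up to one shared water", {
  set.seed(42)
  for (i in 1:20) {
    a <- GlycanComposition(sample(0:9, 1), sample(0:9, 1), sample(0:4, 1),
                           sample(0:3, 1), sample(0:3, 1))
    b <- GlycanComposition(sample(0:9, 1), sample(0:9, 1), sample(0:4, 1),
                           sample(0:3, 1), sample(0:3, 1))
    ab <- GlycanComposition(a@hex + b@hex, a@hexnac + b@hexnac, a@dhex + b@dhex,
                            a@neuac + b@neuac, a@neugc + b@neugc)
    expect_equal(compositionMass(ab),
                 compositionMass(a) + compositionMass(b) - 18.010565)
    # sodiation adds sodium minus one electron (to double rounding)
    expect_equal(sodiatedMz(a) - compositionMass(a),
                 massConstants()$sodiated_increment, tolerance = 1e-12)
    expect_equal(massConstants()$sodiated_increment, 22.9892, tolerance = 1e-6)
  }
})

test_that("glycosylamine form sits 0.984016 Da below the sodiated ion", {
  m5 <- GlycanComposition(5, 2)
  expect_equal(glycosylamineSodiatedMz(m5), 1256.4386, tolerance = 1e-4)
  big <- GlycanComposition(5, 5, 3)
  expect_equal(sodiatedMz(big) - glycosylamineSodiatedMz(big), 0.984016)
  expect_equal(glycosylamineSodiatedMz(big), 2303.85, tolerance = 1e-2)
  expect_error(glycosylamineSodiatedMz(GlycanComposition(hex = 5)), "reducing-end")
})

test_that("reduced-alditol negative ions follow the charge-state algebra", {
  m5 <- GlycanComposition(5, 2)
  expect_equal(alditolIonMz(m5, charge = 1), 1235.4418, tolerance = 1e-4)
  c4 <- GlycanComposition(5, 4)
  expect_equal(alditolIonMz(c4, charge = 2), 820.2968, tolerance = 1e-4)
  # 2 * mz2 + 2 * mH == mz1 + mH == reduced neutral mass, for any composition
  p <- massConstants()$proton
  expect_equal(2 * alditolIonMz(c4, 2) + 2 * p, alditolIonMz(c4, 1) + p)
  expect_error(alditolIonMz(m5, charge = 3), "unsupported charge")
})

test_that("ppm errors are signed relative deviations", {
  expect_identical(ppmError(1500, 1500), 0)
  expect_equal(ppmError(1257.473, 1257.4226), 40.1, tolerance = 0.002)
  expect_equal(ppmError(1000.0, 1000.1), -99.99, tolerance = 1e-4)
  expect_error(ppmError(1000, 0), "positive")
})

test_that("mass annotation agrees with a brute-force scan over forms and records", {
  lib <- readGlycanLibrary(system.file("extdata", "kidney_glycans.csv",
                                       package = "glycoMSI"))
  hits <- annotateMass(1257.473, lib, forms = "M+Na", tolerancePpm = 100)
  expect_identical(hits$name[1], "Man5GlcNAc2")
  expect_identical(nrow(annotateMass(1257.473, lib, forms = "M+Na",
                                     tolerancePpm = 0.001)), 0L)
  exact <- annotateMass(lib$sodiated_mz[3], lib, forms = "M+Na", tolerancePpm = 1)
  expect_equal(exact$ppm[1], 0)

  # brute force from raw constants, random libraries and queries
  k <- massConstants()
  forms <- c("M", "M+Na", "M-H", "M-2H(2-)", "glycosylamine+Na")
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(1:100, 1)
    rl <- data.frame(name = paste0("g", 1:n),
                     hex = sample(0:9, n, TRUE), hexnac = sample(0:9, n, TRUE),
                     dhex = sample(0:3, n, TRUE), neuac = sample(0:2, n, TRUE),
                     neugc = sample(0:2, n, TRUE))
    obs <- runif(1, 800, 3500)
    tol <- sample(c(50, 500, 5000), 1)
    expected <- do.call(rbind, lapply(seq_len(n), function(i) {
      M <- sum(unlist(rl[i, c("hex", "hexnac", "dhex", "neuac", "neugc")]) *
                 k$residues) + k$water
      mred <- M + k$alditol_increment
      mz <- c("M" = M, "M+Na" = M + k$sodium - k$electron,
              "M-H" = mred - k$proton, "M-2H(2-)" = (mred - 2 * k$proton) / 2,
              "glycosylamine+Na" = M + k$sodium - k$electron + k$glycosylamine_increment)
      ok <- abs(1e6 * (obs - mz) / mz) <= tol
      if (rl$hexnac[i] == 0) ok["glycosylamine+Na"] <- FALSE
      if (!any(ok)) return(NULL)
      data.frame(name = rl$name[i], form = names(mz)[ok],
                 ppm = 1e6 * (obs - mz[ok]) / mz[ok])
    }))
    got <- annotateMass(obs, rl, forms = forms, tolerancePpm = tol)
    if (is.null(expected)) {
      expect_identical(nrow(got), 0L)
    } else {
      expect_setequal(paste(got$name, got$form), paste(expected$name, expected$form))
      expect_equal(sort(abs(got$ppm)), sort(abs(expected$ppm)))
      expect_true(!is.unsorted(abs(got$ppm)))   # sorted by |ppm|
    }
  }
})

test_that("composition strings parse in both total and delta-plus-core notation", {
  expect_equal(.compositionCounts(parseComposition("Man_5_GlcNAc_2_")),
               c(hex = 5L, hexnac = 2L, dhex = 0L, neuac = 0L, neugc = 0L))
  expect_equal(sodiatedMz(parseComposition("(Hex)2(HexNAc)2 + (Man)3(GlcNAc)2")),
               sodiatedMz(GlycanComposition(5, 4)))
  expect_equal(.compositionCounts(parseComposition("Hex2HexNAc3(Deoxyhexose)3Man3GlcNAc2")),
               c(hex = 5L, hexnac = 5L, dhex = 3L, neuac = 0L, neugc = 0L))
  expect_error(parseComposition("Xyl5"), "parse|unrecognised")
})

test_that("glycan library reader validates reference sodiated masses", {
  lib <- readGlycanLibrary(system.file("extdata", "gly3_standards.csv",
                                       package = "glycoMSI"))
  expect_identical(nrow(lib), 3L)
  expect_true(all(abs(lib$reference_sodiated_mz - lib$sodiated_mz) <= 0.002))
  bad <- tempfile(fileext = ".csv")
  writeLines(c("name,hex,hexnac,dhex,neuac,neugc,reference_sodiated_mz",
               "broken,5,2,0,0,0,1258.9"), bad)
  expect_error(readGlycanLibrary(bad), "disagrees")
})
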