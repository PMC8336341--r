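# Local baselines, region integration, Voigt fitting, feature tables.

test_that("local baseline is exact on flat and linear spectra", {
  g <- seq(1.8, 2.3, by = 2.5e-4)
  flat <- NMRSpectrum(g, rep(3.5, length(g)))
  bl <- localBaseline(flat, c(2.005, 2.086))
  expect_equal(unname(bl["slope"]), 0, tolerance = 1e-9)
  expect_equal(unname(bl["intercept"]), 3.5, tolerance = 1e-9)
  ramp <- NMRSpectrum(g, 2 * g)
  bl2 <- localBaseline(ramp, c(2.005, 2.086))
  expect_equal(unname(bl2["slope"]), 2, tolerance = 1e-6)
  expect_equal(unname(bl2["intercept"]), 0, tolerance = 1e-6)
})

test_that("the chord removes most of the lipoprotein envelope", {
  lp <- defaultBaseAreas()
  lp[] <- 0
  lip <- grep("^lipid", names(defaultBaseAreas()), value = TRUE)
  lp[lip] <- defaultBaseAreas()[lip]
  s <- generateSpectrum(lp, noiseSd = 0)$spectrum
  raw <- specIntegral(s, c(2.005, 2.054))
  resid <- integrateAboveBaseline(s, c(2.005, 2.054),
                                  baselineRegion = c(2.005, 2.086))
  expect_lt(abs(resid) / raw, 0.10)
})

test_that("integration above baseline recovers Glyc areas on the envelope", {
  s <- generateSpectrum(defaultBaseAreas(), noiseSd = 0)$spectrum
  a <- integrateAboveBaseline(s, c(2.005, 2.054),
                              baselineRegion = c(2.005, 2.086))
  b <- integrateAboveBaseline(s, c(2.054, 2.086),
                              baselineRegion = c(2.005, 2.086))
  expect_equal(a, defaultBaseAreas()[["GlycA"]], tolerance = 0.03)
  expect_equal(b, defaultBaseAreas()[["GlycB"]], tolerance = 0.03)
})

test_that("integration handles degenerate and invalid input", {
  g <- seq(1.8, 2.3, by = 1e-3)
  zero <- NMRSpectrum(g, numeric(length(g)))
  expect_equal(integrateAboveBaseline(zero, c(2.005, 2.054),
                                      baselineRegion = c(2.005, 2.086)), 0)
  expect_error(integrateAboveBaseline(zero, c(5, 6)), "invalid-region")
  expect_error(localBaseline(zero, c(1.80, 2.08)), "invalid-region")
})

test_that("integration is additive over subregions and linear", {
  s <- generateSpectrum(defaultBaseAreas(), noiseSd = 0)$spectrum
  whole <- integrateAboveBaseline(s, c(2.005, 2.086),
                                  baselineRegion = c(2.005, 2.086))
  a <- integrateAboveBaseline(s, c(2.005, 2.054),
                              baselineRegion = c(2.005, 2.086))
  b <- integrateAboveBaseline(s, c(2.054, 2.086),
                              baselineRegion = c(2.005, 2.086))
  expect_equal(a + b, whole, tolerance = 0.01 * abs(whole))
})

test_that("amide quantification is a plain integral and linear", {
  s1 <- generateSpectrum(c(protein_amides = 150), noiseSd = 0)$spectrum
  expect_equal(quantifyAmides(s1), 150, tolerance = 0.02 * 150)
  s2 <- generateSpectrum(c(protein_amides = 300), noiseSd = 0)$spectrum
  expect_equal(quantifyAmides(s2), 2 * quantifyAmides(s1),
               tolerance = 1e-6 * 300)
  g <- seq(6.5, 9, by = 1e-3)
  expect_error(quantifyAmides(NMRSpectrum(g, numeric(length(g)))),
               "invalid-region")
  zero <- generateSpectrum(setNames(numeric(0), character(0)),
                           noiseSd = 0, grid = seq(5, 10.2, by = 1e-3))
  expect_equal(quantifyAmides(zero$spectrum), 0)
})

test_that("a noiseless isolated singlet is fitted essentially exactly", {
  lib <- defaultSignalLibrary()
  s <- calibratedSpectrum(c(glycine = 2.5), noiseSd = 0)
  fr <- fitSignal(s, lib[["glycine"]])
  expect_true(fr$converged)
  expect_equal(fr$area, 2.5, tolerance = 1e-4)
  expect_equal(fr$center, 3.560, tolerance = 1e-4)
})

test_that("fit model recovers all parameters on its own model class", {
  lib <- defaultSignalLibrary()
  s <- calibratedSpectrum(c(lactate = 8), noiseSd = 0)
  fr <- fitSignal(s, lib[["lactate"]])
  expect_true(fr$converged)
  expect_equal(fr$area, 8, tolerance = 1e-3)
  w <- nmrMetabotyping:::.classWidths$metabolite
  expect_equal(fr$sigma, unname(w["sigma"]), tolerance = 0.05)
  expect_equal(fr$gamma, unname(w["gamma"]), tolerance = 0.05)
})

test_that("two overlapping signals 0.03 ppm apart are both recovered", {
  lib <- defaultSignalLibrary()
  set.seed(4)
  s <- generateSpectrum(c(glutamate = 2.5, pyruvate = 1), noiseSd = 0.4,
                        seed = 4)$spectrum
  s@calibrated <- TRUE
  fg <- fitSignal(s, lib[["glutamate"]])
  fp <- fitSignal(s, lib[["pyruvate"]])
  expect_equal(fg$area, 2.5, tolerance = 0.05 * 2.5)
  expect_equal(fp$area, 1, tolerance = 0.05)
})

test_that("histidine and the unidentified 7.14 signal quantify separately", {
  lib <- defaultSignalLibrary()
  s <- calibratedSpectrum(c(histidine = 1.5, `unidentified_7.14` = 0.8,
                            protein_amides = 150), noiseSd = 0)
  fh <- fitSignal(s, lib[["histidine"]])
  fu <- fitSignal(s, lib[["unidentified_7.14"]])
  expect_equal(fh$area, 1.5, tolerance = 0.05 * 1.5)
  expect_equal(fu$area, 0.8, tolerance = 0.05 * 0.8)
})

test_that("fitSignal validates inputs and windows", {
  lib <- defaultSignalLibrary()
  g <- seq(1, 2, by = 1e-3)
  s <- NMRSpectrum(g, numeric(length(g)), calibrated = TRUE)
  expect_error(fitSignal(s, lib[["glycine"]]), "invalid-region")
  expect_error(fitSignal(s, lib[["GlycA"]]), "fit-mode")
})

test_that("feature tables have the contracted shape and masking", {
  lib <- defaultSignalLibrary()
  specs <- lapply(1:2, function(i)
    calibratedSpectrum(defaultBaseAreas(), noiseSd = 0,
                       sampleId = paste0("s", i)))
  ft <- buildFeatureTable(specs, lib)
  expect_s4_class(ft, "SummarizedExperiment")
  expect_equal(dim(ft), c(41L, 2L))
  expect_equal(rownames(ft), signalNames(lib))
  X <- featureMatrix(ft)
  expect_equal(dim(X), c(2L, 41L))
  expect_true(all(c("GlycA", "GlycB", "protein_amides") %in% colnames(X)))
})

test_that("uncalibrated spectra are refused with a useful message", {
  s <- generateSpectrum(defaultBaseAreas(), noiseSd = 0,
                        sampleId = "raw1")$spectrum
  expect_error(buildFeatureTable(list(s)), "raw1")
  expect_error(buildFeatureTable(list(s)), "calibrateSpectrum")
})

test_that("quantification is invariant to the injected offset", {
  base <- defaultBaseAreas()
  s0 <- generateSpectrum(base, noiseSd = 0, calibrationOffset = 0)$spectrum
  s1 <- generateSpectrum(base, noiseSd = 0,
                         calibrationOffset = 0.03)$spectrum
  ft0 <- buildFeatureTable(list(calibrateSpectrum(s0)))
  ft1 <- buildFeatureTable(list(calibrateSpectrum(s1)))
  a0 <- featureMatrix(ft0)[1, ]
  a1 <- featureMatrix(ft1)[1, ]
  keep <- !is.na(a0) & !is.na(a1) & a0 > 0.3
  expect_gt(sum(keep), 30)
  expect_lt(median(abs(a1[keep] / a0[keep] - 1)), 0.01)
})
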