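# Synthetic spectrum and cohort generator.

test_that("default library has the contracted panel structure", {
  lib <- defaultSignalLibrary()
  expect_length(lib, 41L)
  nm <- signalNames(lib)
  expect_false(anyDuplicated(nm) > 0)
  expect_true(all(c("GlycA", "GlycB", "protein_amides", "glucose",
                    "histidine", "mannose", "unidentified_7.14") %in% nm))
  expect_equal(lib[["GlycA"]]@integrationRegion, c(2.005, 2.054))
  expect_equal(lib[["GlycB"]]@integrationRegion, c(2.054, 2.086))
  expect_equal(lib[["protein_amides"]]@integrationRegion, c(6, 10))
  glc <- lib[["glucose"]]@multiplets[[1]]
  expect_equal(glc$center, 5.24)
  expect_equal(glc$pattern, "doublet")
})

test_that("zero concentrations give an identically zero noiseless trace", {
  g <- defaultPpmGrid(by = 1e-3)
  out <- generateSpectrum(setNames(numeric(0), character(0)),
                          grid = g, noiseSd = 0)
  expect_true(all(intensity(out$spectrum) == 0))
})

test_that("a GlycA-only spectrum integrates back to the planted area", {
  out <- generateSpectrum(c(GlycA = 7), noiseSd = 0)
  a <- specIntegral(out$spectrum, c(2.005, 2.054))
  expect_equal(a, 7, tolerance = 0.01)
})

test_that("generation is bit-identical under a fixed seed", {
  a <- generateSpectrum(c(glucose = 5), noiseSd = 3, seed = 11,
                        grid = defaultPpmGrid(by = 1e-3))
  b <- generateSpectrum(c(glucose = 5), noiseSd = 3, seed = 11,
                        grid = defaultPpmGrid(by = 1e-3))
  expect_identical(intensity(a$spectrum), intensity(b$spectrum))
})

test_that("noiseless spectra are additive and scale linearly", {
  g <- defaultPpmGrid(by = 1e-3)
  c1 <- c(glucose = 10, GlycA = 4)
  c2 <- c(lactate = 6, GlycB = 2)
  s12 <- generateSpectrum(c(glucose = 10, GlycA = 4, lactate = 6,
                            GlycB = 2), grid = g, noiseSd = 0)
  s1 <- generateSpectrum(c1, grid = g, noiseSd = 0)
  s2 <- generateSpectrum(c2, grid = g, noiseSd = 0)
  expect_equal(intensity(s12$spectrum),
               intensity(s1$spectrum) + intensity(s2$spectrum),
               tolerance = 1e-12)
  sHalf <- generateSpectrum(c1 / 2, grid = g, noiseSd = 0)
  expect_equal(intensity(s1$spectrum), 2 * intensity(sHalf$spectrum),
               tolerance = 1e-12)
})

test_that("negative areas are rejected", {
  expect_error(generateSpectrum(c(glucose = -1)), "invalid-input")
})

test_that("empty cohorts come back empty without error", {
  coh <- generateCohort(cohortConfig(nPerGroup = c(0, 0, 0, 0)))
  expect_equal(nrow(coh$truth), 0L)
  expect_equal(nrow(coh$clinical), 0L)
})

test_that("cohort truth follows the planted effect template", {
  coh <- generateCohort(cohortConfig(nPerGroup = c(25, 25, 25, 25),
                                     seed = 5))
  g <- coh$clinical$metabotype_true
  base <- defaultBaseAreas()
  # IV plants +3 SD GlycA: group means separated accordingly
  glycA <- coh$truth[, "GlycA"]
  expect_gt(mean(glycA[g == "IV"]),
            mean(glycA[g == "I"]) + 2 * 0.15 * base[["GlycA"]])
  # IV histidine reduced, III lipids reduced, II lipids raised
  expect_lt(mean(coh$truth[g == "IV", "histidine"]),
            mean(coh$truth[g == "I", "histidine"]))
  expect_lt(mean(coh$truth[g == "III", "lipid_CH2_VLDL"]),
            mean(coh$truth[g == "II", "lipid_CH2_VLDL"]))
  expect_true(all(coh$truth >= 0))
})

test_that("planted IV GlycA effect is detectable by a rank test", {
  # two-sample rank test on true GlycA areas, IV vs rest, 20/group
  rejected <- vapply(1:25, function(s) {
    coh <- generateCohort(cohortConfig(nPerGroup = c(20, 20, 20, 20),
                                       seed = 400 + s))
    g <- coh$clinical$metabotype_true
    wilcoxonRankSum(coh$truth[g == "IV", "GlycA"],
                    coh$truth[g != "IV", "GlycA"])$p < 0.001
  }, logical(1))
  expect_gte(mean(rejected), 0.99)
})

test_that("cohort generation is deterministic and CRP tracks GlycA", {
  a <- generateCohort(cohortConfig(seed = 8))
  b <- generateCohort(cohortConfig(seed = 8))
  expect_identical(a$truth, b$truth)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$lipoproteins, b$lipoproteins)
  ct <- spearmanCorrelation(a$crp, a$truth[, "GlycA"])
  expect_gt(ct$statistic, 0.3)
  expect_lt(ct$p, 0.01)
  # synthetic lipoprotein panel carries the named subset
  expect_true(all(c("VLDL_particle_number", "HDL_particle_number", "ApoA1",
                    "ApoA2", "LDL1_triglycerides", "LDL2_triglycerides")
                  %in% names(a$lipoproteins)))
})

test_that("clinical severity rises from metabotype I to IV", {
  coh <- generateCohort(cohortConfig(nPerGroup = c(40, 40, 40, 40),
                                     seed = 21))
  clin <- withRisk(coh$clinical)
  sev <- tapply(clin$risk_group %in% c("very_high", "metastatic"),
                clin$metabotype_true, mean)
  expect_true(sev[["I"]] < sev[["III"]])
  expect_true(sev[["II"]] < sev[["IV"]])
  expect_gte(sev[["IV"]], 0.9)
})
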