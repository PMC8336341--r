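# Shared helpers: small in-code fixtures for fast unit tests.

# A narrow grid around a region of interest.
gridAround <- function(center, half = 0.3, by = 2.5e-4)
  seq(center - half, center + half, by = by)

# A noiseless spectrum flagged calibrated (offset 0 by construction).
calibratedSpectrum <- function(concentrations, ...) {
  s <- generateSpectrum(concentrations, ...)$spectrum
  s@calibrated <- TRUE
  s
}

# Attach the derived NCCN-like risk group to a generated clinical table.
withRisk <- function(clinical) {
  clinical$risk_group <- mapply(classifyRisk, clinical$psa,
                                clinical$gleason_primary,
                                clinical$gleason_secondary,
                                clinical$stage, clinical$metastasis)
  clinical
}

# Trapezoid integral shorthand on a spectrum.
specIntegral <- function(s, region)
  trapezoidIntegral(ppm(s), intensity(s), region)

hasMclust <- requireNamespace("mclust", quietly = TRUE)
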