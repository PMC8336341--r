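# The shipped 41-signal panel.  The panel mechanics (fit vs integrate
# dispatch, fixed Glyc/amide regions, exactly 41 named features) are the
# contract; the metabolite identities and shifts are a documented default
# assembled from common plasma assignments and can be overridden by passing
# a different SignalLibrary anywhere one is accepted.

#' Default linewidths by signal class
#'
#' Generator linewidths (ppm) used when a SignalDefinition does not override
#' them: metabolites are narrow mixed Gauss/Lorentz lines, glycoproteins
#' broader Gaussian-dominated composites, the protein amide envelope a very
#' broad hump, and lipid envelope components pure broad Lorentzians.
#' @keywords internal
.classWidths <- list(
  metabolite   = c(sigma = 6e-4, gamma = 6e-4),
  glycoprotein = c(sigma = 5e-3, gamma = 2e-4),
  protein      = c(sigma = 0.32, gamma = 0),
  lipid        = c(sigma = 0, gamma = 0.05)
)

#' @rdname SignalLibrary-class
#' @export
setGeneric("lineWidths", function(object) standardGeneric("lineWidths"))

#' @rdname SignalLibrary-class
#' @export
setMethod("lineWidths", "SignalDefinition", function(object) {
  w <- attr(object@multiplets, "widths")
  if (!is.null(w)) w else .classWidths[[object@signalClass]]
})

.withWidths <- function(mps, sigma, gamma) {
  attr(mps, "widths") <- c(sigma = sigma, gamma = gamma)
  mps
}

#' The default 41-signal plasma library
#'
#' Thirty-three fit-mode metabolite signals (Voigt multiplets over a local
#' linear baseline), five broad lipid envelope groups, the glycoprotein
#' inflammation markers GlycA (integration region 2.005--2.054 ppm) and
#' GlycB (2.054--2.086 ppm), and the protein amide region (6.000--10.000
#' ppm).  Contains the alpha-glucose anomeric doublet at 5.24 ppm used for
#' chemical-shift calibration and the unidentified aromatic signal at
#' 7.14 ppm.
#'
#' @return a \linkS4class{SignalLibrary} with exactly 41 entries.
#' @examples
#' lib <- defaultSignalLibrary()
#' length(lib)
#' @export
defaultSignalLibrary <- function() {
  met <- function(name, pattern, center, J = 0)
    signalDefinition(name, list(multiplet(pattern, center, J)),
                     mode = "fit", class = "metabolite")
  lip <- function(name, center, gamma, region) {
    d <- signalDefinition(name, list(multiplet("generic", center)),
                          mode = "integrate", integrationRegion = region,
                          class = "lipid")
    d@multiplets <- .withWidths(d@multiplets, 0, gamma)
    d
  }
  glycA <- signalDefinition("GlycA",
    list(multiplet("generic", 2.025, weight = 1),
         multiplet("generic", 2.035, weight = 1)),
    mode = "integrate", integrationRegion = c(2.005, 2.054),
    class = "glycoprotein")
  glycA@multiplets <- .withWidths(glycA@multiplets, 5e-3, 2e-4)
  glycB <- signalDefinition("GlycB",
    list(multiplet("generic", 2.070)),
    mode = "integrate", integrationRegion = c(2.054, 2.086),
    class = "glycoprotein")
  glycB@multiplets <- .withWidths(glycB@multiplets, 4e-3, 2e-4)
  amides <- signalDefinition("protein_amides",
    list(multiplet("generic", 7.30, weight = 0.45),
         multiplet("generic", 8.10, weight = 0.55)),
    mode = "integrate", integrationRegion = c(6.000, 10.000),
    class = "protein")

  SignalLibrary(list(
    met("leucine",          "doublet", 0.960, 6.9),
    met("isoleucine",       "doublet", 1.000, 7.0),
    met("valine",           "doublet", 1.040, 7.0),
    met("hydroxybutyrate",  "doublet", 1.200, 6.3),
    met("lactate",          "doublet", 1.330, 6.9),
    met("alanine",          "doublet", 1.480, 7.2),
    met("acetate",          "singlet", 1.920),
    met("methionine",       "singlet", 2.140),
    met("acetone",          "singlet", 2.230),
    met("acetoacetate",     "singlet", 2.290),
    met("glutamate",        "generic", 2.340),
    met("pyruvate",         "singlet", 2.370),
    met("glutamine",        "generic", 2.450),
    met("citrate",          "doublet", 2.540, 16.0),
    met("asparagine",       "generic", 2.950),
    met("lysine",           "generic", 3.020),
    met("creatinine",       "singlet", 3.045),
    met("choline",          "singlet", 3.200),
    met("betaine",          "singlet", 3.260),
    met("proline",          "generic", 3.330),
    met("taurine",          "generic", 3.420),
    met("glycine",          "singlet", 3.560),
    met("glycerol",         "generic", 3.650),
    met("serine",           "generic", 3.940),
    met("threonine",        "generic", 4.250),
    met("glucose_beta",     "doublet", 4.640, 7.9),
    met("mannose",          "doublet", 5.180, 1.8),
    met("glucose",          "doublet", 5.240, 3.8),
    met("tyrosine",         "doublet", 6.890, 8.5),
    met("histidine",        "singlet", 7.060),
    met("unidentified_7.14","singlet", 7.140),
    met("phenylalanine",    "generic", 7.370),
    met("formate",          "singlet", 8.460),
    lip("lipid_CH3_VLDL",    0.87, 0.04, c(0.80, 0.92)),
    lip("lipid_CH2_VLDL",    1.28, 0.05, c(1.22, 1.34)),
    lip("lipid_allylic",     2.02, 0.20, c(1.90, 2.00)),
    lip("lipid_diallylic",   2.76, 0.05, c(2.70, 2.82)),
    lip("lipid_unsaturated", 5.30, 0.04, c(5.26, 5.36)),
    glycA,
    glycB,
    amides
  ))
}

#' Default ppm grid for synthetic spectra
#'
#' The default spacing of 2.5e-4 ppm mirrors the digital resolution of a
#' high-field plasma acquisition (a ~128k-point processed spectrum over a
#' ~30 ppm sweep), giving ~8 grid points per metabolite linewidth.
#'
#' @param from,to,by grid limits and spacing (ppm).
#' @return ascending numeric axis covering the plasma window.
#' @export
defaultPpmGrid <- function(from = -0.5, to = 10.5, by = 2.5e-4)
  seq(from, to, by = by)

#' Default per-signal base areas for the synthetic cohort
#'
#' Arbitrary NMR area units chosen to emulate the relative intensities of a
#' plasma spectrum (dominant glucose and lipid envelopes, a large protein
#' amide hump, and minor metabolites).
#' @return named numeric vector over all 41 default signals.
#' @export
defaultBaseAreas <- function() {
  c(leucine = 3, isoleucine = 1.5, valine = 2.5, hydroxybutyrate = 1.5,
    lactate = 12, alanine = 4, acetate = 1.5, methionine = 1,
    acetone = 0.8, acetoacetate = 0.6, glutamate = 2.5, pyruvate = 1,
    glutamine = 4, citrate = 1.5, asparagine = 1, lysine = 2.5,
    creatinine = 2, choline = 1.2, betaine = 1.5, proline = 2,
    taurine = 1.5, glycine = 2.5, glycerol = 2, serine = 1.5,
    threonine = 1.5, glucose_beta = 20, mannose = 1, glucose = 30,
    tyrosine = 1.2, histidine = 1.5, `unidentified_7.14` = 0.8,
    phenylalanine = 1.2, formate = 0.4,
    lipid_CH3_VLDL = 12, lipid_CH2_VLDL = 25, lipid_allylic = 3,
    lipid_diallylic = 2, lipid_unsaturated = 4,
    GlycA = 10, GlycB = 4, protein_amides = 150)
}
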