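# Synthetic plasma spectra and cohorts with known ground truth.  The
# generator is first-class, tested code: every downstream stage of the
# pipeline is exercised against the truth it records.

#' Generate one synthetic plasma spectrum
#'
#' Renders every signal in \code{library} at the area given in
#' \code{concentrations} (signals absent from the map get area 0), applies a
#' global chemical-shift miscalibration \code{calibrationOffset} to all
#' signal positions (so the alpha-glucose anomeric doublet appears at
#' 5.24 + offset ppm), optionally adds a slowly varying baseline and
#' additive i.i.d. Gaussian noise, and returns the spectrum together with
#' its ground-truth row.
#'
#' @param concentrations named numeric map signal name -> true area (>= 0).
#' @param library a \linkS4class{SignalLibrary}
#'   (default \code{\link{defaultSignalLibrary}()}).
#' @param grid ascending ppm axis (default covers -0.5..10.5 ppm).
#' @param noiseSd additive Gaussian noise standard deviation (intensity
#'   units, 0 = noiseless).
#' @param baselineAmplitude amplitude of a sinusoidal baseline
#'   \code{A * (0.5 + 0.5 sin(2 pi ppm / period))}.
#' @param baselinePeriod baseline period in ppm (default 4).
#' @param calibrationOffset injected miscalibration (ppm).
#' @param seed optional integer seed; fixing it makes the output
#'   bit-identical across calls.
#' @param sampleId sample identifier.
#' @return list with elements \code{spectrum} (\linkS4class{NMRSpectrum})
#'   and \code{truth} (list: areas, offset, sampleId).
#' @examples
#' out <- generateSpectrum(c(glucose = 30), noiseSd = 0, seed = 1)
#' out$spectrum
#' @export
generateSpectrum <- function(concentrations,
                             library = defaultSignalLibrary(),
                             grid = defaultPpmGrid(),
                             noiseSd = 0, baselineAmplitude = 0,
                             baselinePeriod = 4,
                             calibrationOffset = 0, seed = NULL,
                             sampleId = "synthetic") {
  if (any(concentrations < 0))
    stop("invalid-input: signal areas must be non-negative")
  if (!is.null(seed)) set.seed(as.integer(seed))
  trace <- numeric(length(grid))
  nm <- signalNames(library)
  areas <- setNames(numeric(length(nm)), nm)
  hit <- intersect(names(concentrations), nm)
  areas[hit] <- concentrations[hit]
  for (i in seq_along(nm)) {
    a <- areas[[i]]
    if (a == 0) next
    def <- library[[i]]
    w <- lineWidths(def)
    trace <- trace + .renderSignal(def, a, w[["sigma"]], w[["gamma"]],
                                   grid, centerShift = calibrationOffset)
  }
  if (baselineAmplitude != 0)
    trace <- trace + baselineAmplitude *
      (0.5 + 0.5 * sin(2 * pi * grid / baselinePeriod))
  if (noiseSd > 0)
    trace <- trace + rnorm(length(grid), sd = noiseSd)
  spec <- NMRSpectrum(grid, trace, sampleId = sampleId,
                      calibrated = FALSE,
                      provenance = sprintf(
                        "synthetic: offset=%.5f ppm, noiseSd=%.4g",
                        calibrationOffset, noiseSd))
  list(spectrum = spec,
       truth = list(sampleId = sampleId, areas = areas,
                    offset = calibrationOffset))
}

#' Default metabotype effect template
#'
#' Per-signal group mean shifts in within-group standard-deviation units for
#' the four planted metabotypes.  Directions follow the published metabotype
#' portraits: the inflammatory metabotype IV has strongly elevated GlycA and
#' GlycB, elevated mannose and the unidentified 7.14 ppm signal, reduced
#' histidine, reduced protein amides and a broad reduction of amino acids
#' (with ketone-body and creatinine elevations of a catabolic state);
#' metabotype III pairs elevated GlycB with a marked reduction of the lipid
#' envelope (low VLDL) and of lipid-associated metabolites; metabotype II
#' shows the opposite lipid pattern (high VLDL, mildly reduced GlycB) with
#' the branched-chain amino acid, lactate and aromatic amino-acid
#' elevations of a higher-adiposity, insulin-resistant phenotype;
#' metabotype I carries mild opposite-direction shifts of the least
#' inflamed state.  Each metabotype is a broad multivariate signature:
#' autoscaling absorbs between-group variance, so separability comes from
#' signature breadth rather than from a few large shifts; with these
#' defaults all pairwise group-mean separations in the prepared (clustered)
#' feature space are about 5-8 pooled SD units.
#'
#' @return named list of named numeric vectors for groups "I".."IV".
#' @export
defaultEffectTemplate <- function() {
  aa <- c("leucine", "isoleucine", "valine", "alanine", "lysine",
          "glutamine", "glutamate", "glycine", "threonine", "tyrosine",
          "phenylalanine", "methionine", "asparagine", "proline", "serine",
          "taurine")
  lipids <- c("lipid_CH3_VLDL", "lipid_CH2_VLDL", "lipid_allylic",
              "lipid_diallylic", "lipid_unsaturated")
  list(
    I = c(histidine = 1, acetate = 1, glycine = 0.8, glutamine = 0.8,
          betaine = 0.8),
    II = c(setNames(rep(3, length(lipids)), lipids),
           glycerol = 1.5, leucine = 2.5, isoleucine = 2.5, valine = 2.5,
           alanine = 1.5, lactate = 1.5, pyruvate = 1.2, glutamate = 1,
           tyrosine = 1, phenylalanine = 1, choline = 1, creatinine = 1,
           histidine = -0.5, acetate = -0.5, betaine = -0.5,
           glycine = -0.5, glucose_beta = 0.8, GlycB = -0.5),
    III = c(setNames(rep(-4, length(lipids)), lipids),
            glycerol = -2, acetone = -1.5, hydroxybutyrate = -1.5,
            acetate = -1.2, choline = -1.2, betaine = -1, citrate = -1,
            methionine = -1, glutamine = -0.8, pyruvate = -1.2,
            lactate = -1, taurine = -1, threonine = -0.8,
            glucose_beta = -0.8, serine = -0.8, GlycB = 1),
    IV = c(setNames(rep(-1.5, length(aa)), aa),
           GlycA = 3, GlycB = 3, mannose = 1, histidine = -1.5,
           protein_amides = -1, `unidentified_7.14` = 1,
           hydroxybutyrate = 1.2, acetone = 1, creatinine = 1,
           citrate = -1, formate = 0.8)
  )
}

#' Cohort generator configuration
#'
#' @param nPerGroup integer(4), samples per metabotype I..IV.
#' @param effectTemplate named list of per-signal shifts in SD units per
#'   group (default \code{\link{defaultEffectTemplate}()}).
#' @param baseAreas named base areas (default
#'   \code{\link{defaultBaseAreas}()}).
#' @param cv within-group coefficient of variation defining the SD unit
#'   (default 0.15).
#' @param noiseSd spectral noise SD, or \code{NULL} to use 0.5\% of the
#'   tallest metabolite peak of the base render.
#' @param baselineAmplitude spectral baseline amplitude (default 0).
#' @param calibrationOffsetSd SD of the per-sample calibration offset (ppm).
#' @param seed integer seed fixing all randomness end to end.
#' @param emitSpectra logical; render spectra (slow) or only truth tables.
#' @param emitLipoproteins,emitCRP logical; emit the synthetic lipoprotein
#'   subclass table / CRP values.
#' @param library the \linkS4class{SignalLibrary} to render from.
#' @return a list with class \code{"cohortConfig"}.
#' @export
cohortConfig <- function(nPerGroup = c(15, 15, 15, 15),
                         effectTemplate = defaultEffectTemplate(),
                         baseAreas = defaultBaseAreas(),
                         cv = 0.15, noiseSd = NULL,
                         baselineAmplitude = 0,
                         calibrationOffsetSd = 0.008,
                         seed = 1L, emitSpectra = FALSE,
                         emitLipoproteins = TRUE, emitCRP = TRUE,
                         library = defaultSignalLibrary()) {
  stopifnot(length(nPerGroup) == 4L, all(nPerGroup >= 0),
            cv > 0, calibrationOffsetSd >= 0)
  structure(list(nPerGroup = as.integer(nPerGroup),
                 effectTemplate = effectTemplate, baseAreas = baseAreas,
                 cv = cv, noiseSd = noiseSd,
                 baselineAmplitude = baselineAmplitude,
                 calibrationOffsetSd = calibrationOffsetSd,
                 seed = as.integer(seed), emitSpectra = emitSpectra,
                 emitLipoproteins = emitLipoproteins, emitCRP = emitCRP,
                 library = library),
            class = "cohortConfig")
}

# Default spectral noise: 0.5% of the tallest metabolite peak in a
# noiseless base-area render (documented generator convention).
.autoNoiseSd <- function(config) {
  lib <- config$library
  keep <- vapply(lib@signals, function(s) s@signalClass == "metabolite",
                 logical(1))
  metLib <- SignalLibrary(lib@signals[keep])
  base <- config$baseAreas[signalNames(metLib)]
  out <- generateSpectrum(base, library = metLib, noiseSd = 0)
  0.005 * max(intensity(out$spectrum))
}

# Draw clinical covariates consistent with metabotype severity.  Fields are
# drawn so that the simplified NCCN mapper reproduces increasing shares of
# very-high/metastatic disease from group I to IV.
.drawClinical <- function(group, id) {
  sev <- switch(group,
    I   = sample(c("low", "intermediate"), 1, prob = c(0.45, 0.55)),
    II  = sample(c("low", "intermediate", "high", "very_high"), 1,
                 prob = c(0.10, 0.40, 0.30, 0.20)),
    III = sample(c("low", "intermediate", "high", "very_high"), 1,
                 prob = c(0.10, 0.25, 0.30, 0.35)),
    IV  = sample(c("very_high", "metastatic"), 1, prob = c(0.80, 0.20)))
  gl <- switch(sev,
    low          = c(3, 3),
    intermediate = if (runif(1) < 0.5) c(3, 4) else c(4, 3),
    high         = c(4, 4),
    very_high    = rbind(c(4, 5), c(5, 4), c(5, 5),
                         c(3, 5))[sample(4, 1), ],
    metastatic   = rbind(c(4, 5), c(5, 5))[sample(2, 1), ])
  psa <- switch(sev,
    low          = runif(1, 2, 9.9),
    intermediate = runif(1, 10, 19.9),
    high         = exp(runif(1, log(21), log(90))),
    very_high    = exp(runif(1, log(25), log(2000))),
    metastatic   = exp(runif(1, log(200), log(5000))))
  stage <- switch(sev,
    low          = "T1c",
    intermediate = sample(c("T2b", "T2c"), 1),
    high         = sample(c("T1c", "T2a", "T2b"), 1),
    very_high    = sample(c("T3", "T4", "T3/T4"), 1),
    metastatic   = sample(c("T3", "T4"), 1))
  collection <- as.Date("2014-01-01") + sample.int(1500, 1)
  followup <- ceiling(switch(sev,
    metastatic = rexp(1, 1 / 60), very_high = rexp(1, 1 / 250),
    rexp(1, 1 / 900)) + 1)
  data.frame(
    patient_id = id, metabotype_true = group,
    ancestry = sample(c("Black", "Colored", "White"), 1,
                      prob = c(0.22, 0.61, 0.17)),
    age = round(rnorm(1, 68, 8), 1),
    psa = round(psa, 2), psa_censored = psa >= 5000,
    gleason_primary = gl[1], gleason_secondary = gl[2],
    stage = stage, metastasis = sev == "metastatic",
    collection_date = format(collection, "%Y/%m/%d"),
    last_visit_date = format(collection + followup, "%Y/%m/%d"),
    death_date = NA_character_,
    diabetes = runif(1) < 0.2, hypertension = runif(1) < 0.35,
    smoker = runif(1) < 0.25,
    stringsAsFactors = FALSE)
}

#' Generate a synthetic metabotyped cohort
#'
#' Draws per-sample true signal areas as
#' \code{Normal(base * (1 + cv * shift), cv * base)} (truncated at zero)
#' following the group effect template, clinical covariates whose severity
#' mirrors the metabotype (group IV very-high/metastatic), a synthetic
#' lipoprotein subclass panel (VLDL/HDL particle numbers, Apo-A1, Apo-A2,
#' LDL-1/LDL-2 triglycerides) and CRP values positively associated with
#' GlycA.  Optionally renders the full spectra.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return list with elements \code{truth} (sample x signal matrix of true
#'   areas), \code{clinical} (data.frame), \code{offsets}, \code{spectra}
#'   (list of \linkS4class{NMRSpectrum} or NULL), \code{lipoproteins},
#'   \code{crp}, \code{noiseSd}.
#' @examples
#' coh <- generateCohort(cohortConfig(nPerGroup = c(4, 4, 4, 4)))
#' dim(coh$truth)
#' @export
generateCohort <- function(config = cohortConfig()) {
  stopifnot(inherits(config, "cohortConfig"))
  set.seed(config$seed)
  groups <- rep(c("I", "II", "III", "IV"), times = config$nPerGroup)
  n <- length(groups)
  nm <- signalNames(config$library)
  base <- setNames(numeric(length(nm)), nm)
  hit <- intersect(names(config$baseAreas), nm)
  base[hit] <- config$baseAreas[hit]

  empty <- list(
    truth = matrix(numeric(0), 0, length(nm), dimnames = list(NULL, nm)),
    clinical = data.frame(), offsets = numeric(0), spectra = NULL,
    lipoproteins = data.frame(), crp = numeric(0), noiseSd = 0)
  if (n == 0L) return(empty)

  ids <- sprintf("SYN%04d", seq_len(n))
  truth <- matrix(0, n, length(nm), dimnames = list(ids, nm))
  for (i in seq_len(n)) {
    shift <- setNames(numeric(length(nm)), nm)
    eff <- config$effectTemplate[[groups[i]]]
    if (length(eff)) {
      hit <- intersect(names(eff), nm)
      shift[hit] <- eff[hit]
    }
    mu <- base * (1 + config$cv * shift)
    truth[i, ] <- pmax(0, rnorm(length(nm), mu, config$cv * base))
  }
  offsets <- rnorm(n, 0, config$calibrationOffsetSd)

  clinical <- do.call(rbind, lapply(seq_len(n), function(i)
    .drawClinical(groups[i], ids[i])))

  lipo <- NULL
  if (config$emitLipoproteins) {
    g4 <- groups == "IV"
    vldl <- truth[, "lipid_CH2_VLDL"] / base[["lipid_CH2_VLDL"]]
    lipo <- data.frame(
      patient_id = ids,
      VLDL_particle_number = round(80 * vldl * exp(rnorm(n, 0, 0.10)), 2),
      HDL_particle_number = round(
        ifelse(g4, 14, 18) * exp(rnorm(n, 0, 0.12)), 2),
      ApoA1 = round(ifelse(g4, 115, 140) * exp(rnorm(n, 0, 0.10)), 1),
      ApoA2 = round(ifelse(g4, 26, 32) * exp(rnorm(n, 0, 0.10)), 1),
      LDL1_triglycerides = round(
        ifelse(g4, 14, 10) * exp(rnorm(n, 0, 0.15)), 2),
      LDL2_triglycerides = round(
        ifelse(g4, 9, 6) * exp(rnorm(n, 0, 0.15)), 2),
      stringsAsFactors = FALSE)
  }
  crp <- NULL
  if (config$emitCRP) {
    glyca <- truth[, "GlycA"] / base[["GlycA"]]
    crp <- setNames(round(3 * glyca^2 * exp(rnorm(n, 0, 0.35)), 2), ids)
  }

  noiseSd <- if (is.null(config$noiseSd)) .autoNoiseSd(config)
             else config$noiseSd
  spectra <- NULL
  if (config$emitSpectra) {
    spectra <- lapply(seq_len(n), function(i)
      generateSpectrum(truth[i, ], library = config$library,
                       noiseSd = noiseSd,
                       baselineAmplitude = config$baselineAmplitude,
                       calibrationOffset = offsets[i],
                       sampleId = ids[i])$spectrum)
    names(spectra) <- ids
  }
  list(truth = truth, clinical = clinical, offsets = setNames(offsets, ids),
       spectra = spectra, lipoproteins = lipo, crp = crp, noiseSd = noiseSd)
}
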