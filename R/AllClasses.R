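#' @import methods
#' @importFrom stats approx median mad sd quantile setNames runif rnorm
#'   hclust cutree cmdscale dist cor wilcox.test kruskal.test fisher.test
#'   cor.test p.adjust pbinom optimize
#' @importFrom utils head tail
NULL

#' One-dimensional NMR spectrum
#'
#' Holds a calibrated or uncalibrated 1D spectrum as a strictly ascending
#' chemical-shift axis (ppm) and an intensity trace of equal length, together
#' with a sample identifier, a calibration flag and a provenance log.  The
#' ascending-axis convention is canonical throughout the package; the usual
#' NMR display order (high ppm left) is a plotting concern only.
#'
#' @slot ppm numeric, strictly ascending chemical shifts in ppm.
#' @slot intensity numeric, same length as \code{ppm}, arbitrary units.
#' @slot sampleId character(1) sample identifier.
#' @slot calibrated logical(1), \code{TRUE} once the axis has been referenced
#'   to the alpha-glucose anomeric doublet at 5.24 ppm.
#' @slot provenance character vector of processing-log entries.
#'
#' @export
setClass("NMRSpectrum",
  representation(
    ppm = "numeric",
    intensity = "numeric",
    sampleId = "character",
    calibrated = "logical",
    provenance = "character"
  ),
  prototype(sampleId = "sample", calibrated = FALSE, provenance = character())
)

setValidity("NMRSpectrum", function(object) {
  msg <- character()
  if (length(object@ppm) != length(object@intensity))
    msg <- c(msg, "ppm and intensity must have equal length")
  if (length(object@ppm) >= 2 && any(diff(object@ppm) <= 0))
    msg <- c(msg, "ppm axis must be strictly ascending")
  if (anyNA(object@ppm) || anyNA(object@intensity))
    msg <- c(msg, "ppm and intensity must not contain NA")
  if (length(object@sampleId) != 1L)
    msg <- c(msg, "sampleId must be a single string")
  if (length(object@calibrated) != 1L)
    msg <- c(msg, "calibrated must be a single logical")
  if (length(msg)) msg else TRUE
})

#' Construct an NMRSpectrum
#'
#' @param ppm strictly ascending numeric ppm axis.
#' @param intensity numeric trace, same length as \code{ppm}.
#' @param sampleId sample identifier.
#' @param calibrated logical calibration flag.
#' @param provenance character vector of log entries.
#' @return an \linkS4class{NMRSpectrum}.
#' @examples
#' s <- NMRSpectrum(seq(0, 10, by = 0.01), rnorm(1001))
#' s
#' @export
NMRSpectrum <- function(ppm, intensity, sampleId = "sample",
                        calibrated = FALSE, provenance = character()) {
  new("NMRSpectrum", ppm = as.numeric(ppm), intensity = as.numeric(intensity),
      sampleId = as.character(sampleId), calibrated = as.logical(calibrated),
      provenance = as.character(provenance))
}

#' @describeIn NMRSpectrum-class ppm axis accessor
#' @param object,x an \code{NMRSpectrum}
#' @export
setGeneric("ppm", function(object) standardGeneric("ppm"))
#' @rdname NMRSpectrum-class
#' @export
setMethod("ppm", "NMRSpectrum", function(object) object@ppm)

#' @rdname NMRSpectrum-class
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))
#' @rdname NMRSpectrum-class
#' @export
setMethod("intensity", "NMRSpectrum", function(object) object@intensity)

#' @rdname NMRSpectrum-class
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
#' @rdname NMRSpectrum-class
#' @export
setMethod("sampleId", "NMRSpectrum", function(object) object@sampleId)

#' @rdname NMRSpectrum-class
#' @export
setGeneric("isCalibrated", function(object) standardGeneric("isCalibrated"))
#' @rdname NMRSpectrum-class
#' @export
setMethod("isCalibrated", "NMRSpectrum", function(object) object@calibrated)

#' @rdname NMRSpectrum-class
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @rdname NMRSpectrum-class
#' @export
setMethod("provenance", "NMRSpectrum", function(object) object@provenance)

setMethod("show", "NMRSpectrum", function(object) {
  cat("NMRSpectrum '", object@sampleId, "': ", length(object@ppm),
      " points, ", sprintf("%.3f..%.3f", min(object@ppm), max(object@ppm)),
      " ppm, ", if (object@calibrated) "calibrated" else "uncalibrated",
      "\n", sep = "")
})

## ---------------------------------------------------------------------------

#' Definition of one quantifiable NMR signal
#'
#' A signal is either fitted (\code{mode = "fit"}: a set of multiplets sharing
#' Voigt linewidths over a local linear baseline) or quantified by plain
#' region integration above a local baseline chord (\code{mode = "integrate"},
#' used for the heterogeneous glycoprotein signals GlycA/GlycB and the
#' protein-amide region, which cannot be separated from the lipoprotein
#' background by fitting).
#'
#' @slot name unique signal name.
#' @slot multiplets list of multiplet descriptors (see \code{\link{multiplet}}).
#' @slot mode "fit" or "integrate".
#' @slot integrationRegion numeric(2) [low, high] ppm, used when
#'   \code{mode == "integrate"}.
#' @slot searchWindow ppm half-width of the fitting window around the
#'   library shift.
#' @slot class one of "metabolite", "lipid", "glycoprotein", "protein".
#' @export
setClass("SignalDefinition",
  representation(
    name = "character",
    multiplets = "list",
    mode = "character",
    integrationRegion = "numeric",
    searchWindow = "numeric",
    signalClass = "character"
  )
)

setValidity("SignalDefinition", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a non-empty string")
  if (!object@mode %in% c("fit", "integrate"))
    msg <- c(msg, "mode must be 'fit' or 'integrate'")
  if (!object@signalClass %in% c("metabolite", "lipid", "glycoprotein", "protein"))
    msg <- c(msg, "class must be metabolite/lipid/glycoprotein/protein")
  if (object@mode == "integrate") {
    if (length(object@integrationRegion) != 2L ||
        object@integrationRegion[1] >= object@integrationRegion[2])
      msg <- c(msg, "integrationRegion must be [low, high] with low < high")
  }
  if (object@mode == "fit" && length(object@multiplets) < 1L)
    msg <- c(msg, "fit-mode signals need at least one multiplet")
  if (length(msg)) msg else TRUE
})

#' Multiplet descriptor
#'
#' Describes one multiplet: a splitting pattern with binomial component
#' ratios, a centre chemical shift and a scalar coupling constant.  Component
#' spacing in ppm is \code{J / spectrometerFrequency}.
#'
#' @param pattern one of "singlet", "doublet", "triplet", "quartet",
#'   "generic".
#' @param center centre chemical shift (ppm).
#' @param J coupling constant (Hz); ignored for singlets.
#' @param spectrometerFrequency proton Larmor frequency in MHz
#'   (default 600.13).
#' @param weight relative weight of this multiplet within its signal
#'   (multiplets of one signal share the signal's total area in proportion).
#' @return a list with class \code{"multiplet"}.
#' @examples
#' multiplet("doublet", center = 5.24, J = 3.8)
#' @export
multiplet <- function(pattern = c("singlet", "doublet", "triplet", "quartet",
                                  "generic"),
                      center, J = 0, spectrometerFrequency = 600.13,
                      weight = 1) {
  pattern <- match.arg(pattern)
  stopifnot(is.numeric(center), length(center) == 1L, J >= 0,
            spectrometerFrequency > 0, weight > 0)
  structure(list(pattern = pattern, center = center, J = J,
                 spectrometerFrequency = spectrometerFrequency,
                 weight = weight),
            class = "multiplet")
}

#' Relative component amplitudes of a multiplet pattern
#'
#' Binomial (Pascal-triangle) ratios normalised to sum to one.
#' @param pattern multiplet pattern name.
#' @return numeric vector of relative amplitudes summing to 1.
#' @export
multipletAmplitudes <- function(pattern) {
  n <- switch(pattern,
    singlet = 0L, doublet = 1L, triplet = 2L, quartet = 3L, generic = 0L,
    stop("unknown multiplet pattern: ", pattern))
  a <- choose(n, 0:n)
  a / sum(a)
}

#' Construct a SignalDefinition
#'
#' @param name unique signal name.
#' @param multiplets list of \code{\link{multiplet}} descriptors.
#' @param mode "fit" or "integrate".
#' @param integrationRegion numeric(2) ppm region for integrate mode.
#' @param searchWindow ppm half-width of the fit window (default 0.015).
#' @param class signal class.
#' @return a \linkS4class{SignalDefinition}.
#' @export
signalDefinition <- function(name, multiplets = list(),
                             mode = c("fit", "integrate"),
                             integrationRegion = numeric(),
                             searchWindow = 0.015,
                             class = c("metabolite", "lipid", "glycoprotein",
                                       "protein")) {
  mode <- match.arg(mode)
  class <- match.arg(class)
  new("SignalDefinition", name = name, multiplets = multiplets, mode = mode,
      integrationRegion = as.numeric(integrationRegion),
      searchWindow = searchWindow, signalClass = class)
}

#' Ordered library of quantifiable signals
#'
#' @slot signals list of \linkS4class{SignalDefinition}, unique names.
#' @export
setClass("SignalLibrary", representation(signals = "list"))

setValidity("SignalLibrary", function(object) {
  msg <- character()
  if (!all(vapply(object@signals, is, logical(1), "SignalDefinition")))
    msg <- c(msg, "all entries must be SignalDefinition objects")
  nm <- vapply(object@signals, function(s) s@name, character(1))
  if (anyDuplicated(nm))
    msg <- c(msg, "signal names must be unique")
  if (length(msg)) msg else TRUE
})

#' @param signals list of SignalDefinition objects.
#' @rdname SignalLibrary-class
#' @export
SignalLibrary <- function(signals) new("SignalLibrary", signals = signals)

#' @rdname SignalLibrary-class
#' @param object,x a SignalLibrary
#' @export
setGeneric("signalNames", function(object) standardGeneric("signalNames"))
#' @rdname SignalLibrary-class
#' @export
setMethod("signalNames", "SignalLibrary", function(object)
  vapply(object@signals, function(s) s@name, character(1)))

#' @rdname SignalLibrary-class
#' @export
setMethod("length", "SignalLibrary", function(x) length(x@signals))

#' @rdname SignalLibrary-class
#' @param i index or signal name
#' @export
setMethod("[[", "SignalLibrary", function(x, i) {
  if (is.character(i)) i <- match(i, signalNames(x))
  x@signals[[i]]
})

setMethod("show", "SignalLibrary", function(object) {
  cls <- table(vapply(object@signals, function(s) s@signalClass, character(1)))
  cat("SignalLibrary with", length(object@signals), "signals (",
      paste(names(cls), cls, sep = ": ", collapse = ", "), ")\n")
})

## ---------------------------------------------------------------------------

#' Result of unsupervised metabotype discovery
#'
#' @slot proximity n x n co-classification frequency matrix in [0, 1],
#'   symmetric with unit diagonal.
#' @slot scores n x 2 metric-MDS embedding of 1 - proximity.
#' @slot dendrogram an \code{hclust} object (Ward D2 on the scores).
#' @slot k chosen number of clusters.
#' @slot silhouettes named numeric of median silhouette widths per candidate k.
#' @slot labels factor of metabotype labels ("I".."k"), one per sample,
#'   ordered by clinical severity when clinical data were supplied.
#' @export
setClass("MetabotypeResult",
  representation(
    proximity = "matrix",
    scores = "matrix",
    dendrogram = "ANY",
    k = "integer",
    silhouettes = "numeric",
    labels = "factor"
  )
)

setValidity("MetabotypeResult", function(object) {
  msg <- character()
  P <- object@proximity
  if (nrow(P) != ncol(P)) msg <- c(msg, "proximity must be square")
  if (any(P < -1e-9) || any(P > 1 + 1e-9))
    msg <- c(msg, "proximity entries must lie in [0, 1]")
  if (max(abs(P - t(P))) > 1e-9) msg <- c(msg, "proximity must be symmetric")
  if (any(abs(diag(P) - 1) > 1e-9))
    msg <- c(msg, "proximity diagonal must be 1")
  if (nrow(object@scores) != nrow(P) || ncol(object@scores) != 2L)
    msg <- c(msg, "scores must be n x 2")
  if (length(object@labels) && length(object@labels) != nrow(P))
    msg <- c(msg, "labels length must equal n")
  if (length(object@silhouettes) &&
      (any(object@silhouettes < -1 - 1e-9) ||
       any(object@silhouettes > 1 + 1e-9)))
    msg <- c(msg, "silhouette medians must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MetabotypeResult", function(object) {
  cat("MetabotypeResult:", nrow(object@proximity), "samples, k =",
      object@k, "\n")
  if (length(object@labels)) print(table(object@labels))
})

#' @rdname MetabotypeResult-class
#' @param object a MetabotypeResult
#' @export
setGeneric("metabotypeLabels",
           function(object) standardGeneric("metabotypeLabels"))
#' @rdname MetabotypeResult-class
#' @export
setMethod("metabotypeLabels", "MetabotypeResult",
          function(object) object@labels)

#' @rdname MetabotypeResult-class
#' @export
setGeneric("proximityMatrix",
           function(object) standardGeneric("proximityMatrix"))
#' @rdname MetabotypeResult-class
#' @export
setMethod("proximityMatrix", "MetabotypeResult",
          function(object) object@proximity)

#' @rdname MetabotypeResult-class
#' @export
setGeneric("kodamaScoresOf", function(object) standardGeneric("kodamaScoresOf"))
#' @rdname MetabotypeResult-class
#' @export
setMethod("kodamaScoresOf", "MetabotypeResult", function(object) object@scores)

#' @rdname MetabotypeResult-class
#' @export
setGeneric("chosenK", function(object) standardGeneric("chosenK"))
#' @rdname MetabotypeResult-class
#' @export
setMethod("chosenK", "MetabotypeResult", function(object) object@k)
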