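# End-to-end orchestration: simulate -> preprocess -> quantify ->
# metabotype -> stats -> pls under one config with a single global seed
# fanned out to stable per-stage child seeds, and a machine-readable
# JSON + CSV report.

# Stable string hash -> small positive integer; fans the global seed out to
# per-stage seeds so toggling one stage leaves the others' randomness alone.
.stageSeed <- function(globalSeed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003
  as.integer((as.numeric(globalSeed) * 7919 + h) %% 2147483647L)
}

#' Pipeline configuration
#'
#' @param seed global integer seed.
#' @param nPerGroup samples per planted metabotype for the simulate stage.
#' @param stages character subset of
#'   c("simulate", "preprocess", "quantify", "metabotype", "stats", "pls")
#'   to run; later stages need their inputs, so the set must be a prefix of
#'   the full order.
#' @param fromSpectra logical; quantify from rendered spectra (slower) or
#'   from the generator's true areas.
#' @param iterations proximity-learning restarts.
#' @param plsRepeats double-CV repetitions.
#' @param fdrThreshold FDR threshold for the comparison tables.
#' @param outdir optional output directory for \code{\link{writeReport}}.
#' @return list with class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(seed = 1L, nPerGroup = c(15, 15, 15, 15),
                           stages = c("simulate", "preprocess", "quantify",
                                      "metabotype", "stats", "pls"),
                           fromSpectra = FALSE, iterations = 100,
                           plsRepeats = 5, fdrThreshold = 0.10,
                           outdir = NULL) {
  order_ <- c("simulate", "preprocess", "quantify", "metabotype", "stats",
              "pls")
  unknown <- setdiff(stages, order_)
  if (length(unknown))
    stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  structure(list(seed = as.integer(seed), nPerGroup = nPerGroup,
                 stages = intersect(order_, stages),
                 fromSpectra = fromSpectra, iterations = iterations,
                 plsRepeats = plsRepeats, fdrThreshold = fdrThreshold,
                 outdir = outdir),
            class = "pipelineConfig")
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order on a synthetic cohort and returns a
#' report: feature table, metabotype labels and silhouettes, metabotype
#' IV-vs-rest comparison table, clinical summary and PLS-DA metrics, plus a
#' structured per-stage log.  Re-running with the same config reproduces
#' all numbers bit-identically.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return list report; see \code{\link{writeReport}} for serialisation.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "pipelineConfig"))
  report <- list(config = list(seed = config$seed,
                               nPerGroup = config$nPerGroup,
                               stages = config$stages,
                               fdrThreshold = config$fdrThreshold),
                 log = list())
  logStage <- function(stage, nIn, nOut)
    report$log[[stage]] <<- list(stage = stage, nIn = nIn, nOut = nOut)
  if (!length(config$stages)) return(report)

  cohort <- NULL
  if ("simulate" %in% config$stages) {
    cohort <- generateCohort(cohortConfig(
      nPerGroup = config$nPerGroup,
      seed = .stageSeed(config$seed, "simulate"),
      emitSpectra = config$fromSpectra))
    report$truthGroups <- cohort$clinical$metabotype_true
    logStage("simulate", sum(config$nPerGroup), nrow(cohort$truth))
  }
  if (is.null(cohort)) stop("stage failure: later stages need 'simulate'")

  X <- cohort$truth  # samples x signals true areas
  if (config$fromSpectra && "preprocess" %in% config$stages) {
    specs <- lapply(cohort$spectra, function(s)
      calibrateSpectrum(s))
    logStage("preprocess", length(cohort$spectra), length(specs))
    if ("quantify" %in% config$stages) {
      ft <- buildFeatureTable(specs)
      X <- featureMatrix(ft)
      report$featureTable <- ft
      logStage("quantify", length(specs), nrow(X))
    }
  } else if ("quantify" %in% config$stages) {
    logStage("quantify", nrow(X), nrow(X))
  }
  report$features <- X

  clin <- cohort$clinical
  clin$risk_group <- vapply(seq_len(nrow(clin)), function(i)
    classifyRisk(clin$psa[i], clin$gleason_primary[i],
                 clin$gleason_secondary[i], clin$stage[i],
                 clin$metastasis[i]), character(1))
  report$clinical <- clin

  if ("metabotype" %in% config$stages) {
    mt <- discoverMetabotypes(X, clinical = clin,
                              iterations = config$iterations,
                              seed = .stageSeed(config$seed, "metabotype"))
    report$metabotype <- mt
    report$k <- chosenK(mt)
    report$labels <- as.character(metabotypeLabels(mt))
    logStage("metabotype", nrow(X), chosenK(mt))
  }

  if ("stats" %in% config$stages && !is.null(report$labels)) {
    top <- utils::tail(levels(metabotypeLabels(report$metabotype)), 1)
    report$comparison <- compareGroupVsRest(
      X, report$labels, target = top, threshold = config$fdrThreshold)
    report$summary <- summarizeCohort(clin, report$labels)
    report$fdrThreshold <- config$fdrThreshold
    logStage("stats", nrow(X), nrow(report$comparison))
  }

  if ("pls" %in% config$stages && !is.null(report$labels)) {
    top <- utils::tail(levels(metabotypeLabels(report$metabotype)), 1)
    y <- factor(ifelse(report$labels == top, top, "rest"))
    Xs <- scale(log1p(sweep(X, 2, pmax(apply(X, 2, median), 1e-12), "/")))
    Xs <- Xs[, apply(Xs, 2, function(v) all(is.finite(v))), drop = FALSE]
    report$pls <- doubleCV(Xs, y, repeats = config$plsRepeats,
                           seed = .stageSeed(config$seed, "pls"))
    logStage("pls", nrow(X), length(unique(y)))
  }
  report
}

#' Serialise a pipeline report
#'
#' Writes a JSON summary plus CSVs (features, labels, silhouettes,
#' comparison table, PLS metrics) into \code{outdir}.
#'
#' @param report the list from \code{\link{runPipeline}}.
#' @param outdir destination directory (created if needed).
#' @return invisible character vector of files written.
#' @export
writeReport <- function(report, outdir) {
  if (!length(report)) stop("invalid-input: empty report")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  wcsv <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  if (!is.null(report$features))
    wcsv(data.frame(sample_id = rownames(report$features),
                    report$features, check.names = FALSE),
         "feature_table.csv")
  if (!is.null(report$labels))
    wcsv(data.frame(sample_id = rownames(report$features),
                    metabotype = report$labels), "metabotypes.csv")
  if (!is.null(report$metabotype))
    wcsv(data.frame(k = names(report$metabotype@silhouettes),
                    median_silhouette = report$metabotype@silhouettes),
         "silhouettes.csv")
  if (!is.null(report$comparison))
    wcsv(report$comparison, "comparison_iv_vs_rest.csv")
  summary <- list(seed = report$config$seed,
                  stages = report$config$stages,
                  fdrThreshold = report$fdrThreshold,
                  k = report$k,
                  labelCounts = if (!is.null(report$labels))
                    as.list(table(report$labels)),
                  pls = if (!is.null(report$pls))
                    report$pls[c("accuracy", "accuracyCI", "R2", "Q2",
                                 "ncomp")])
  jpath <- file.path(outdir, "report.json")
  jsonlite::write_json(summary, jpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, jpath)
  invisible(files)
}
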