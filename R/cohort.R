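# Clinical data model: record parsing and validation, follow-up-day
# arithmetic, and a simplified NCCN-style risk mapper.  The published
# patient-level table of the very-high-risk / inflammatory-metabotype
# subset ships as a plain-text fixture (see clinicalFixturePath()).

.riskLevels <- c("very_low", "low", "intermediate", "high", "very_high",
                 "metastatic")

.parseDate <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(as.Date(NA))
  x <- trimws(x)
  d <- as.Date(x, format = "%Y/%m/%d")
  if (is.na(d)) d <- as.Date(x, format = "%Y-%m-%d")
  if (is.na(d)) stop("invalid date: ", x, " (expected YYYY/MM/DD)")
  d
}

#' Exact calendar days between two dates
#'
#' Leap-aware difference in whole calendar days, used for the follow-up
#' time between sample collection and the last hospital visit or death.
#'
#' @param start,end dates (Date or "YYYY/MM/DD" / ISO strings);
#'   \code{end >= start}.
#' @return integer number of days.
#' @examples
#' daysBetween("2014/09/26", "2020/06/04")
#' @export
daysBetween <- function(start, end) {
  if (!inherits(start, "Date")) start <- .parseDate(as.character(start))
  if (!inherits(end, "Date")) end <- .parseDate(as.character(end))
  if (is.na(start) || is.na(end)) return(NA_integer_)
  d <- as.integer(end - start)
  if (d < 0) stop("invalid-input: end date precedes start date")
  d
}

.parseStage <- function(stage) {
  stage <- trimws(as.character(stage))
  ok <- c("T1", "T1a", "T1b", "T1c", "T2", "T2a", "T2b", "T2c",
          "T3", "T3a", "T3b", "T4", "T3/T4")
  if (!stage %in% ok)
    stop("unparseable stage token '", stage, "'; accepted: ",
         paste(ok, collapse = ", "))
  stage
}

#' Simplified NCCN-style risk classification
#'
#' A deliberately simplified mapper over PSA, Gleason primary+secondary and
#' clinical T stage (full NCCN v2.2020 would additionally need biopsy-core
#' counts and PSA density): metastasis dominates; Gleason sum 9-10 or any
#' T3/T4 stage gives very_high (a bare "T3" is treated as
#' very-high-qualifying); Gleason sum 8 or PSA > 20 gives high; Gleason
#' 4+3 / 3+4, PSA 10-20 or stage T2b/T2c gives intermediate; everything
#' else is low (very_low needs an explicit flag not derivable from these
#' fields).
#'
#' @param psa PSA in ng/mL.
#' @param gleasonPrimary,gleasonSecondary Gleason patterns in 3..5.
#' @param stage clinical T stage token (T1c..T4, "T3/T4" accepted).
#' @param metastasis logical; regional/distant metastasis.
#' @return one of "low", "intermediate", "high", "very_high", "metastatic".
#' @examples
#' classifyRisk(6.3, 3, 3, "T1c")        # low
#' classifyRisk(41.68, 4, 5, "T2a")      # very_high
#' @export
classifyRisk <- function(psa, gleasonPrimary, gleasonSecondary, stage,
                         metastasis = FALSE) {
  if (isTRUE(metastasis)) return("metastatic")
  if (!gleasonPrimary %in% 3:5 || !gleasonSecondary %in% 3:5)
    stop("invalid-input: Gleason patterns must be in 3..5")
  if (!is.finite(psa) || psa < 0)
    stop("invalid-input: PSA must be non-negative")
  stage <- .parseStage(stage)
  gsum <- gleasonPrimary + gleasonSecondary
  t34 <- grepl("^T3|^T4|T3/T4", stage)
  if (gsum >= 9 || t34) return("very_high")
  if (gsum == 8 || psa > 20) return("high")
  if ((gleasonPrimary == 4 && gleasonSecondary == 3) ||
      (gleasonPrimary == 3 && gleasonSecondary == 4) ||
      (psa >= 10 && psa <= 20) || stage %in% c("T2b", "T2c"))
    return("intermediate")
  "low"
}

#' Load and validate a clinical CSV
#'
#' Mandatory columns: \code{patient_id}, \code{collection_date},
#' \code{last_visit_date}, \code{psa}, \code{gleason_primary},
#' \code{gleason_secondary}, \code{stage}.  Optional columns:
#' \code{death_date}, \code{ancestry}, \code{age}, \code{metastasis},
#' \code{metabotype}, \code{diabetes}, \code{hypertension}, \code{smoker}.
#' Censored PSA entries (">5000") are parsed as the cap value with
#' \code{psa_censored = TRUE}.  Follow-up days (collection to last visit,
#' or to death when recorded) and the simplified NCCN-style risk group are
#' derived.
#'
#' @param path CSV path.
#' @return validated data.frame of clinical records.
#' @export
loadClinicalCSV <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  mandatory <- c("patient_id", "collection_date", "last_visit_date",
                 "psa", "gleason_primary", "gleason_secondary", "stage")
  miss <- setdiff(mandatory, names(df))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  psaRaw <- trimws(as.character(df$psa))
  censored <- grepl("^>", psaRaw)
  psa <- suppressWarnings(as.numeric(sub("^>", "", psaRaw)))
  if (anyNA(psa))
    stop("row-level error: non-numeric PSA in row(s) ",
         paste(which(is.na(psa)), collapse = ", "))
  df$psa <- psa
  df$psa_censored <- censored
  bad <- !(df$gleason_primary %in% 3:5) | !(df$gleason_secondary %in% 3:5)
  if (any(bad))
    stop("row-level error: invalid Gleason pattern in row(s) ",
         paste(which(bad), collapse = ", "))
  if (is.null(df$metastasis)) df$metastasis <- FALSE
  df$metastasis <- as.logical(df$metastasis)
  coll <- vapply(df$collection_date,
                 function(d) as.numeric(.parseDate(d)), numeric(1))
  lastv <- vapply(df$last_visit_date,
                  function(d) as.numeric(.parseDate(d)), numeric(1))
  death <- if (!is.null(df$death_date)) {
    vapply(df$death_date, function(d)
      as.numeric(.parseDate(if (is.na(d)) NA_character_ else d)),
      numeric(1))
  } else rep(NA_real_, nrow(df))
  bad <- which(!is.na(lastv) & lastv < coll)
  if (length(bad))
    stop("row-level error: last visit before collection in row(s) ",
         paste(bad, collapse = ", "))
  bad <- which(!is.na(death) & death < coll)
  if (length(bad))
    stop("row-level error: death before collection in row(s) ",
         paste(bad, collapse = ", "))
  endDate <- ifelse(is.na(death), lastv, death)
  df$followup_days <- as.integer(endDate - coll)
  df$risk_group <- vapply(seq_len(nrow(df)), function(i)
    classifyRisk(df$psa[i], df$gleason_primary[i],
                 df$gleason_secondary[i], df$stage[i],
                 df$metastasis[i]), character(1))
  df
}

#' Path to the shipped patient-level clinical fixture
#'
#' A 14-patient transcription of the published table of inflammatory
#' metabotype (IV) members and very-high-risk non-members, used by the
#' worked examples and the exact summary checks.
#'
#' @return file path of the CSV inside the installed package.
#' @export
clinicalFixturePath <- function() {
  system.file("extdata", "very_high_risk_patients.csv",
              package = "nmrMetabotyping", mustWork = TRUE)
}
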