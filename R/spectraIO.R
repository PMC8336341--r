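# Portable spectrum I/O.  The contract format is a two-column TSV
# (ppm, intensity); a best-effort reader for processed Bruker 1D
# directories (1r + procs) is provided for convenience.

#' Read a spectrum from two-column TSV
#'
#' The file holds two numeric columns, ppm and intensity, with an optional
#' header line.  Files stored in NMR display order (descending ppm) are
#' reversed so the in-memory axis is always ascending.
#'
#' @param path file path.
#' @param sampleId sample identifier (default: file name without extension).
#' @return an \linkS4class{NMRSpectrum}.
#' @export
readSpectrumTSV <- function(path, sampleId = NULL) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("parse error: empty spectrum file: ", path)
  first <- strsplit(trimws(lines[[1]]), "[\t ,]+")[[1]]
  if (suppressWarnings(anyNA(as.numeric(first)))) lines <- lines[-1]
  if (!length(lines)) stop("parse error: no data rows in ", path)
  parts <- strsplit(trimws(lines), "[\t ]+")
  bad <- which(vapply(parts, length, integer(1)) < 2L)
  if (length(bad))
    stop("parse error at line ", bad[1], ": expected two columns")
  x <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 1L)))
  y <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  bad <- which(is.na(x) | is.na(y))
  if (length(bad))
    stop("parse error at line ", bad[1], ": non-numeric value")
  if (length(x) < 16L)
    stop("too-short: spectrum has fewer than 16 points")
  if (x[1] > x[length(x)]) {
    x <- rev(x)
    y <- rev(y)
  }
  if (is.null(sampleId))
    sampleId <- sub("\\.[^.]*$", "", basename(path))
  NMRSpectrum(x, y, sampleId = sampleId,
              provenance = paste0("read: ", path))
}

#' Write a spectrum as two-column TSV
#'
#' Values are written with 12 significant digits so a write/read round trip
#' is an identity well past the 9-digit contract.
#'
#' @param s an \linkS4class{NMRSpectrum}.
#' @param path destination path.
#' @return \code{path}, invisibly.
#' @export
writeSpectrumTSV <- function(s, path) {
  stopifnot(is(s, "NMRSpectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("ppm\tintensity", con)
  writeLines(sprintf("%.12g\t%.12g", ppm(s), intensity(s)), con)
  invisible(path)
}

# Parse a Bruker JCAMP-style parameter file into a named list.
.readBrukerParams <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hits <- grep("^##\\$", lines, value = TRUE)
  out <- list()
  for (ln in hits) {
    m <- regmatches(ln, regexec("^##\\$([^=]+)= *(.*)$", ln))[[1]]
    if (length(m) == 3L) out[[m[2]]] <- trimws(m[3])
  }
  out
}

#' Read a processed Bruker 1D spectrum directory
#'
#' Best-effort reader for a Topspin `pdata/<n>` directory containing the
#' processed real part (`1r`, 32-bit little-endian integers) and its `procs`
#' parameter file.  Intensities are scaled by 2^-NC_proc; the ppm axis is
#' reconstructed from OFFSET (ppm of the first, highest-ppm point), SW_p and
#' SF (Hz) and SI, and returned ascending.
#'
#' @param directory path to a pdata directory holding `1r` and `procs`.
#' @param sampleId sample identifier (default: directory name).
#' @return an \linkS4class{NMRSpectrum}.
#' @export
readBrukerProcessed <- function(directory, sampleId = NULL) {
  if (!dir.exists(directory))
    stop("I/O error: no such directory: ", directory)
  f1r <- file.path(directory, "1r")
  fpr <- file.path(directory, "procs")
  if (!file.exists(fpr))
    stop("format error: missing parameter file 'procs' in ", directory)
  if (!file.exists(f1r))
    stop("format error: missing data file '1r' in ", directory)
  p <- .readBrukerParams(fpr)
  need <- c("OFFSET", "SW_p", "SF", "SI", "NC_proc")
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop("format error: procs lacks parameter(s): ",
         paste(miss, collapse = ", "))
  si <- as.integer(p$SI)
  offset <- as.numeric(p$OFFSET)
  swp <- as.numeric(p$SW_p)
  sf <- as.numeric(p$SF)
  ncp <- as.integer(p$NC_proc)
  endian <- if (!is.null(p$BYTORDP) && p$BYTORDP == "1") "big" else "little"
  raw <- readBin(f1r, what = "integer", n = si, size = 4L, endian = endian)
  if (length(raw) < si)
    stop("format error: 1r holds ", length(raw), " points, SI = ", si)
  y <- raw * 2^ncp
  # axis: point i (1-based) at OFFSET - (i-1) * SW_p / SF / SI, descending
  x <- offset - (seq_len(si) - 1) * swp / sf / si
  if (is.null(sampleId)) sampleId <- basename(normalizePath(directory))
  NMRSpectrum(rev(x), rev(y), sampleId = sampleId,
              provenance = paste0("read-bruker: ", directory))
}
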