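# File formats: FASTA in, two-column peak lists, TSV tables, JSON reports.
# All residue coordinates are 1-based inclusive in every file and report.

#' Read protein sequences from FASTA
#'
#' The accession is the header token before the first whitespace;
#' sequences are upper-cased; stop characters (`*`) are stripped with a
#' warning; any remaining non-letter character is an error naming the
#' record and position.
#'
#' @param path FASTA file.
#' @return data.frame with columns `accession`, `sequence`, in file order.
#' @export
readFastaProteins <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("empty FASTA file: ", path)
  acc <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(acc))
    stop("duplicate accession(s) in FASTA: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  if (any(grepl("*", seqs, fixed = TRUE))) {
    warning("stop character '*' stripped from sequence(s)")
    seqs <- gsub("*", "", seqs, fixed = TRUE)
  }
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^A-Z]", seqs[i])
    if (bad > 0L)
      stop(sprintf("illegal character '%s' in record '%s' at position %d",
                   substr(seqs[i], bad, bad), acc[i], bad))
  }
  data.frame(accession = acc, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Read a peak list from plain text
#'
#' One peak per line, whitespace- or tab-separated `m/z intensity`; `#`
#' starts a comment; blank lines are skipped; order is not required.
#' Single-column files are accepted with unit intensities and a warning.
#'
#' @param path peak-list text file.
#' @param sourceId provenance label (default: the file name).
#' @return a \linkS4class{PeakList} (uncalibrated).
#' @export
readPeakList <- function(path, sourceId = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  stripped <- trimws(sub("#.*$", "", lines))
  keep <- which(nzchar(stripped))
  mzs <- numeric(length(keep)); ints <- numeric(length(keep))
  singleCol <- FALSE
  for (k in seq_along(keep)) {
    ln <- keep[k]
    fields <- strsplit(stripped[ln], "[ \t]+")[[1L]]
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals[seq_len(min(2L, length(vals)))]))
      stop(sprintf("non-numeric token at line %d of %s: '%s'", ln, path,
                   fields[which(is.na(vals))[1L]]))
    mzs[k] <- vals[1L]
    if (length(vals) >= 2L) ints[k] <- vals[2L]
    else { ints[k] <- 1; singleCol <- TRUE }
  }
  if (singleCol)
    warning("single-column peak list: intensities set to 1 (", path, ")")
  peakList(mzs, ints, sourceId = sourceId)
}

#' Write a peak list as plain text
#'
#' Emits the two-column format sorted by m/z, with a comment header.
#'
#' @param peaks a \linkS4class{PeakList}.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePeakList <- function(peaks, path) {
  stopifnot(is(peaks, "PeakList"))
  o <- order(peaks@mz)
  lines <- c(sprintf("# peak list (%s); m/z intensity; calibrated=%s",
                     peaks@sourceId, peaks@calibrated),
             sprintf("%.10g\t%.10g", peaks@mz[o], peaks@intensity[o]))
  writeLines(lines, path)
  invisible(path)
}

dfToJsonable <- function(df) {
  if (!nrow(df)) return(list())
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

#' Write an identification report as JSON
#'
#' Versioned schema (`pmfkit-report/1`); [readReport()] restores the
#' \linkS4class{MatchReport} exactly.
#'
#' @param report a \linkS4class{MatchReport}.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path) {
  stopifnot(is(report, "MatchReport"))
  obj <- list(
    schema = "pmfkit-report/1",
    accession = report@accession,
    proteinLength = report@proteinLength,
    parameters = report@parameters,
    coveragePercent = report@coveragePercent,
    matchedSignalFraction = report@matchedSignalFraction,
    calibrantSignalFraction = report@calibrantSignalFraction,
    calibration = if (is.null(report@calibration)) NULL else list(
      slope = report@calibration@slope,
      intercept = report@calibration@intercept,
      nCalibrants = report@calibration@nCalibrants,
      residualsPpm = report@calibration@residualsPpm),
    calibrants = report@calibrants,
    matches = report@matches,
    unmatched = report@unmatched)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

rebuildDf <- function(cols, template) {
  if (is.null(cols) || !length(cols) ||
      (is.list(cols) && !length(cols[[1L]]))) return(template)
  df <- as.data.frame(lapply(cols, unlist), stringsAsFactors = FALSE)
  for (nm in names(template)) {
    if (!nm %in% names(df)) df[[nm]] <- template[[nm]][0]
    mode(df[[nm]]) <- mode(template[[nm]])
    if (is.integer(template[[nm]])) df[[nm]] <- as.integer(df[[nm]])
  }
  df[, names(template), drop = FALSE]
}

#' Read an identification report from JSON
#'
#' @param path JSON file produced by [writeReport()].
#' @return a \linkS4class{MatchReport}.
#' @export
readReport <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$schema, "pmfkit-report/1"))
    stop("not a pmfkit report (schema: ", obj$schema %||% "absent", ")")
  model <- if (is.null(obj$calibration)) NULL else
    new("CalibrationModel", slope = obj$calibration$slope,
        intercept = obj$calibration$intercept,
        nCalibrants = as.integer(obj$calibration$nCalibrants),
        residualsPpm = as.numeric(unlist(obj$calibration$residualsPpm)))
  params <- obj$parameters
  params$maxMissed <- as.integer(params$maxMissed)
  params$nPeaks <- as.integer(params$nPeaks)
  params$modifications <- as.character(unlist(params$modifications))
  new("MatchReport", accession = obj$accession,
      proteinLength = as.integer(obj$proteinLength),
      matches = rebuildDf(obj$matches, emptyMatches()),
      coveragePercent = obj$coveragePercent,
      matchedSignalFraction = obj$matchedSignalFraction,
      calibrantSignalFraction = obj$calibrantSignalFraction,
      calibrants = rebuildDf(obj$calibrants, emptyCalibrantAssignment()),
      unmatched = rebuildDf(obj$unmatched,
                            data.frame(mz = numeric(), intensity = numeric())),
      parameters = params, calibration = model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a truncation call as JSON
#'
#' @param call a \linkS4class{TruncationCall}.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
writeTruncationCall <- function(call, path) {
  stopifnot(is(call, "TruncationCall"))
  obj <- list(schema = "pmfkit-truncation/1", terminus = call@terminus,
              boundaryInterval = call@boundary, nMissing = call@nMissing,
              proteinLength = call@proteinLength,
              missingPeptides = call@missingPeptides,
              retainedPeptides = call@retainedPeptides)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' Read / write spot-quantity tables as TSV
#'
#' The first column is the spot id; the header row carries the group label
#' of each sample column.
#'
#' @param path TSV file.
#' @param x a \linkS4class{SpotTable} (for writing).
#' @return `readSpotTable()`: a \linkS4class{SpotTable}.
#' @export
readSpotTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("spot table needs an id column plus >= 2 samples")
  groups <- sub("(\\.\\d+)?$", "", names(df)[-1L])  # tolerate dedup suffixes
  spotTable(as.matrix(df[, -1L, drop = FALSE]), groups, df[[1L]])
}

#' @rdname readSpotTable
#' @export
writeSpotTable <- function(x, path) {
  stopifnot(is(x, "SpotTable"))
  q <- SummarizedExperiment::assay(x, "quantity")
  grp <- SummarizedExperiment::colData(x)$group
  df <- data.frame(spot = rownames(q), q, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("spot", grp)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
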