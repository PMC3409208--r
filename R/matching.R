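# Peak-to-peptide matching and the identification report.

emptyMatches <- function() {
  data.frame(peakIndex = integer(), observedMz = numeric(),
             intensity = numeric(), start = integer(), end = integer(),
             sequence = character(), missedCleavages = integer(),
             modState = character(), nVarMods = integer(), mh = numeric(),
             errorDa = numeric(), errorPpm = numeric(), isBest = logical(),
             stringsAsFactors = FALSE)
}

#' Match observed peaks to a theoretical digest
#'
#' Returns every (peak, peptide) pair whose mass difference lies within the
#' tolerance. For each peak, the pair with the smallest absolute ppm error
#' is flagged `isBest`; exact ties fall through fewer missed cleavages,
#' fewer variable modifications, lower mass, then lower start position.
#'
#' @param peaks a \linkS4class{PeakList}.
#' @param peptides theoretical peptide table from [digestProtein()].
#' @param tolerance match tolerance (> 0).
#' @param unit "da" (absolute, the 0.15 Da default) or "ppm" (relative).
#' @return data.frame of matches, columns as in the `matches` slot of
#'   \linkS4class{MatchReport}; zero rows when nothing matches.
#' @export
matchPeaks <- function(peaks, peptides, tolerance = 0.15,
                       unit = c("da", "ppm")) {
  unit <- match.arg(unit)
  stopifnot(is(peaks, "PeakList"), tolerance > 0)
  if (is.null(peptides) || !nrow(peptides))
    stop("the theoretical peptide set is empty")
  if (!length(peaks@mz)) return(emptyMatches())
  o <- order(peptides$mh)
  mhSorted <- peptides$mh[o]
  rows <- vector("list", length(peaks@mz))
  for (p in seq_along(peaks@mz)) {
    obs <- peaks@mz[p]
    if (unit == "da") {
      lo <- obs - tolerance; hi <- obs + tolerance
    } else {
      # |obs - mh| <= tol*1e-6*mh  <=>  obs/(1+t) <= mh <= obs/(1-t)
      t <- tolerance * 1e-6
      lo <- obs / (1 + t); hi <- if (t < 1) obs / (1 - t) else Inf
    }
    i0 <- findInterval(lo, mhSorted, left.open = TRUE) + 1L
    i1 <- findInterval(hi, mhSorted)
    if (i0 > i1) next
    idx <- o[i0:i1]
    rows[[p]] <- data.frame(
      peakIndex = p, observedMz = obs, intensity = peaks@intensity[p],
      start = peptides$start[idx], end = peptides$end[idx],
      sequence = peptides$sequence[idx],
      missedCleavages = peptides$missedCleavages[idx],
      modState = peptides$modState[idx], nVarMods = peptides$nVarMods[idx],
      mh = peptides$mh[idx], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(emptyMatches())
  out$errorDa <- out$observedMz - out$mh
  out$errorPpm <- 1e6 * out$errorDa / out$mh
  pref <- order(out$peakIndex, abs(out$errorPpm), out$missedCleavages,
                out$nVarMods, out$mh, out$start, out$end)
  out <- out[pref, , drop = FALSE]
  out$isBest <- !duplicated(out$peakIndex)
  out <- out[order(out$peakIndex, !out$isBest, out$start, out$end,
                   out$modState), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sequence coverage from matched peptides
#'
#' Coverage is the size of the union (not the sum) of the residue spans of
#' the best-per-peak matches, as a percentage of the protein length.
#'
#' @param matches match table from [matchPeaks()].
#' @param proteinLength protein length in residues (> 0).
#' @return coverage percentage in [0, 100].
#' @export
coveragePercent <- function(matches, proteinLength) {
  stopifnot(proteinLength > 0)
  best <- matches[matches$isBest, , drop = FALSE]
  if (!nrow(best)) return(0)
  ir <- IRanges::reduce(IRanges::IRanges(start = best$start, end = best$end))
  100 * sum(IRanges::width(ir)) / proteinLength
}

#' Signal fractions of a peak list
#'
#' The calibrant fraction is calibrant-assigned intensity over total
#' intensity; the matched fraction is best-matched (non-calibrant)
#' intensity over non-calibrant intensity — the fraction of the remaining
#' reflector signal explained by the candidate protein.
#'
#' @param peaks a \linkS4class{PeakList}.
#' @param matches match table from [matchPeaks()].
#' @param calibrantAssignment calibrant table from [matchCalibrants()]
#'   (or NULL for none).
#' @return named numeric: `matched`, `calibrant`. A zero-intensity peak
#'   list yields c(0, 0) with a warning.
#' @export
signalFractions <- function(peaks, matches, calibrantAssignment = NULL) {
  stopifnot(is(peaks, "PeakList"))
  total <- sum(peaks@intensity)
  if (total <= 0) {
    warning("total reflector intensity is zero; fractions reported as 0")
    return(c(matched = 0, calibrant = 0))
  }
  calIdx <- if (is.null(calibrantAssignment)) integer()
            else calibrantAssignment$peakIndex
  bestIdx <- setdiff(unique(matches$peakIndex[matches$isBest]), calIdx)
  calSum <- sum(peaks@intensity[calIdx])
  nonCal <- total - calSum
  c(matched = if (nonCal > 0) sum(peaks@intensity[bestIdx]) / nonCal else 0,
    calibrant = calSum / total)
}

#' Build the full identification report
#'
#' Orchestrates the whole pipeline for one protein and one spectrum:
#' calibrant assignment, optional affine recalibration, digest, tolerance
#' matching, coverage, signal fractions and the unmatched-peak listing.
#' Every observed peak lands in exactly one of the three report bins
#' (calibrant, best-matched, unmatched).
#'
#' @param accession protein accession used in the report.
#' @param sequence protein sequence string.
#' @param peaks a \linkS4class{PeakList}.
#' @param standards calibrant table ([internalStandards()]) or NULL to
#'   skip calibrant handling entirely.
#' @param tolerance,unit match tolerance and its unit (see [matchPeaks()]).
#' @param rule a \linkS4class{CleavageRule}.
#' @param mods modification list.
#' @param table a \linkS4class{ResidueMassTable}.
#' @param calibrate if TRUE, fit and apply the affine calibration from the
#'   matched calibrants before peptide matching; if no calibrant is found
#'   the spectrum is matched uncalibrated with a warning.
#' @param calibrantWindow calibrant search half-width (Da).
#' @return a \linkS4class{MatchReport}.
#' @export
buildReport <- function(accession, sequence, peaks, standards = NULL,
                        tolerance = 0.15, unit = c("da", "ppm"),
                        rule = cleavageRule(), mods = defaultModifications(),
                        table = defaultMassTable(), calibrate = FALSE,
                        calibrantWindow = 0.5) {
  unit <- match.arg(unit)
  stopifnot(is(peaks, "PeakList"), nzchar(sequence))
  cal <- if (is.null(standards)) emptyCalibrantAssignment()
         else matchCalibrants(peaks, standards, window = calibrantWindow)
  model <- NULL
  if (calibrate) {
    if (nrow(cal)) {
      model <- fitCalibration(cal)
      peaks <- applyCalibration(peaks, model)
      cal$observedMz <- peaks@mz[cal$peakIndex]
      cal$deltaDa <- cal$observedMz - cal$theoreticalMh
      cal$errorPpm <- 1e6 * cal$deltaDa / cal$theoreticalMh
    } else {
      warning("calibration requested but no calibrant peak found; matching uncalibrated")
    }
  }
  peptides <- digestProtein(sequence, rule = rule, mods = mods, table = table)
  matches <- matchPeaks(peaks, peptides, tolerance = tolerance, unit = unit)
  # calibrant peaks are spoken for: drop their peptide matches wholesale
  if (nrow(cal))
    matches <- matches[!matches$peakIndex %in% cal$peakIndex, , drop = FALSE]
  fr <- signalFractions(peaks, matches, cal)
  cov <- coveragePercent(matches, nchar(sequence))
  assigned <- union(cal$peakIndex, unique(matches$peakIndex[matches$isBest]))
  unIdx <- setdiff(seq_along(peaks@mz), assigned)
  unmatched <- data.frame(mz = peaks@mz[unIdx],
                          intensity = peaks@intensity[unIdx])
  unmatched <- unmatched[order(-unmatched$intensity, unmatched$mz), ,
                         drop = FALSE]
  rownames(unmatched) <- NULL
  modLabel <- vapply(mods, function(m)
    sprintf("%s(%s,%+.5f,%s)", m@name, paste(m@targets, collapse = ""),
            m@delta, m@mode), character(1L))
  params <- list(tolerance = tolerance, unit = unit,
                 maxMissed = rule@maxMissed,
                 modifications = unname(modLabel),
                 calibrate = calibrate, calibrantWindow = calibrantWindow,
                 nPeaks = length(peaks@mz))
  new("MatchReport", accession = accession,
      proteinLength = nchar(sequence), matches = matches,
      coveragePercent = cov, matchedSignalFraction = unname(fr["matched"]),
      calibrantSignalFraction = unname(fr["calibrant"]),
      calibrants = cal, unmatched = unmatched, parameters = params,
      calibration = model)
}

#' @rdname MatchReport-class
#' @export
setMethod("accession", "MatchReport", function(object) object@accession)

#' @rdname MatchReport-class
#' @export
setMethod("matchedPeaks", "MatchReport", function(object) object@matches)

#' @rdname MatchReport-class
#' @export
setMethod("unmatchedPeaks", "MatchReport", function(object) object@unmatched)

#' @rdname MatchReport-class
#' @export
setMethod("sequenceCoverage", "MatchReport",
          function(object) object@coveragePercent)

#' @rdname MatchReport-class
#' @export
setMethod("signalFractionsOf", "MatchReport", function(object)
  c(matched = object@matchedSignalFraction,
    calibrant = object@calibrantSignalFraction))

#' @rdname MatchReport-class
#' @export
setMethod("reportParameters", "MatchReport", function(object) object@parameters)

#' @rdname MatchReport-class
#' @export
setMethod("calibrantAssignments", "MatchReport",
          function(object) object@calibrants)

setMethod("show", "MatchReport", function(object) {
  nBest <- sum(object@matches$isBest)
  cat(sprintf("MatchReport for %s (%d residues)\n", object@accession,
              object@proteinLength))
  cat(sprintf("  matched peaks: %d (coverage %.1f%%)\n", nBest,
              object@coveragePercent))
  cat(sprintf("  signal fractions: matched %.3f, calibrant %.3f\n",
              object@matchedSignalFraction, object@calibrantSignalFraction))
  cat(sprintf("  calibrants assigned: %d; unmatched peaks: %d\n",
              nrow(object@calibrants), nrow(object@unmatched)))
  if (!is.null(object@calibration))
    cat(sprintf("  calibration: slope %.8f, intercept %+.5f Da\n",
                object@calibration@slope, object@calibration@intercept))
})
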