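# Truncation-isoform inference from differential matched-peptide evidence:
# a lower molecular-weight spot of the same protein that has lost the
# peptides from one terminus has been truncated there.

peptideKey <- function(df) paste(df$start, df$end, df$modState, sep = "|")

#' Compare the matched peptide sets of two reports
#'
#' `missing` holds the best-matched peptides (identified by residue span
#' and modification state) of the reference that are absent from the
#' query; `retained` those present in both. Both reports must describe the
#' same protein under the same digestion/matching parameters.
#'
#' @param reference \linkS4class{MatchReport} of the full-length form.
#' @param query \linkS4class{MatchReport} of the candidate isoform spot.
#' @return list with data.frames `missing` and `retained` (columns
#'   `start`, `end`, `sequence`, `modState`), each ordered by start.
#' @export
compareMatchedSets <- function(reference, query) {
  stopifnot(is(reference, "MatchReport"), is(query, "MatchReport"))
  if (!identical(reference@accession, query@accession))
    stop("reports describe different proteins: ", reference@accession,
         " vs ", query@accession)
  pr <- reference@parameters; pq <- query@parameters
  for (f in c("tolerance", "unit", "maxMissed", "modifications"))
    if (!identical(pr[[f]], pq[[f]]))
      stop("reports were produced under different parameters (", f, ")")
  bestOf <- function(rep) {
    b <- rep@matches[rep@matches$isBest,
                     c("start", "end", "sequence", "modState"), drop = FALSE]
    b[!duplicated(peptideKey(b)), , drop = FALSE]
  }
  refSet <- bestOf(reference)
  if (!nrow(refSet))
    stop("reference report contains no matched peptides: no evidence base")
  qKeys <- peptideKey(bestOf(query))
  isMissing <- !peptideKey(refSet) %in% qKeys
  orderSpan <- function(d) {
    d <- d[order(d$start, d$end, d$modState), , drop = FALSE]
    rownames(d) <- NULL
    d
  }
  list(missing = orderSpan(refSet[isMissing, , drop = FALSE]),
       retained = orderSpan(refSet[!isMissing, , drop = FALSE]))
}

# Inconsistency profiles over candidate cut positions. For an N-terminal
# truncation starting at residue t, a missing peptide is consistent when it
# lies fully in the removed prefix (end < t) and a retained peptide when it
# lies fully in the kept suffix (start >= t). The C-terminal profile is the
# mirror image, parameterised by u = last kept residue.
inconsistencyProfiles <- function(missing, retained, L) {
  cntGe <- function(v) { # at position t: how many v >= t
    tab <- tabulate(pmin(v, L), nbins = L)
    rev(cumsum(rev(tab)))
  }
  cntLe <- function(v) cumsum(tabulate(pmax(v, 1L), nbins = L))
  # N: In(t) = #\{missing end >= t\} + #\{retained start < t\} = ... start <= t-1
  inN <- cntGe(missing$end) +
    c(0L, cntLe(retained$start)[-L])
  # C: In(u) = #\{missing start <= u\} + #\{retained end > u\} = ... end >= u+1
  inC <- cntLe(missing$start) +
    c(cntGe(retained$end)[-1L], 0L)
  list(N = inN, C = inC)
}

#' Infer a truncation call from missing/retained peptide evidence
#'
#' Scans every candidate cut position and counts the peptides inconsistent
#' with a truncation there (missing peptides not fully removed, retained
#' peptides not fully kept). A terminus is called when the minimal
#' inconsistency count is within an outlier allowance of
#' `floor(outlierFraction * n)` (n = total evidence peptides), is strictly
#' smaller than for the opposite terminus, and at least `minMissing`
#' missing peptides support the call; with allowance 0 this is exactly the
#' strict rule "every missing peptide ends before the first retained
#' residue" (and its C mirror). The boundary interval is the full range of
#' minimising cut positions. Missing peptides strictly inside the retained
#' region give "internal"; conflicting evidence gives "indeterminate".
#'
#' @param missing,retained data.frames from [compareMatchedSets()].
#' @param proteinLength protein length in residues.
#' @param minMissing minimum missing-peptide evidence for an N/C call
#'   (default 2, guarding against single-dropout false positives).
#' @param outlierFraction tolerated fraction of inconsistent peptides
#'   (default 0.15), absorbing detection dropout and cut-straddling
#'   missed-cleavage peptides.
#' @return a \linkS4class{TruncationCall}.
#' @export
inferTruncation <- function(missing, retained, proteinLength,
                            minMissing = 2L, outlierFraction = 0.15) {
  L <- as.integer(proteinLength)
  stopifnot(L >= 1L, outlierFraction >= 0, outlierFraction < 1)
  nMiss <- nrow(missing); nRet <- nrow(retained)
  call <- function(term, bound = integer()) {
    new("TruncationCall", terminus = term, boundary = as.integer(bound),
        missingPeptides = missing, retainedPeptides = retained,
        nMissing = as.integer(nMiss), proteinLength = L)
  }
  if (!nMiss) return(call("none"))
  if (!nRet) return(call("indeterminate"))
  prof <- inconsistencyProfiles(missing, retained, L)
  n <- nMiss + nRet
  allowance <- floor(outlierFraction * n)
  mN <- min(prof$N); mC <- min(prof$C)
  bN <- range(which(prof$N == mN))
  bC <- range(which(prof$C == mC))
  consistentMissingN <- sum(missing$end < bN[2L])
  consistentMissingC <- sum(missing$start > bC[1L])
  candN <- mN <= allowance && consistentMissingN >= minMissing
  candC <- mC <= allowance && consistentMissingC >= minMissing
  if (candN && (!candC || mN < mC)) return(call("N", bN))
  if (candC && (!candN || mC < mN)) return(call("C", bC))
  if (min(missing$start) > min(retained$start) &&
      max(missing$end) < max(retained$end))
    return(call("internal"))
  call("indeterminate")
}

#' @rdname TruncationCall-class
#' @export
setMethod("terminus", "TruncationCall", function(object) object@terminus)

#' @rdname TruncationCall-class
#' @export
setMethod("boundaryInterval", "TruncationCall", function(object) object@boundary)

#' @rdname TruncationCall-class
#' @export
setMethod("missingPeptides", "TruncationCall",
          function(object) object@missingPeptides)

#' @rdname TruncationCall-class
#' @export
setMethod("retainedPeptides", "TruncationCall",
          function(object) object@retainedPeptides)

setMethod("show", "TruncationCall", function(object) {
  cat(sprintf("TruncationCall: terminus %s (%d missing, %d retained peptides)\n",
              object@terminus, object@nMissing, nrow(object@retainedPeptides)))
  if (length(object@boundary) == 2L)
    cat(sprintf("  cut localised to residues %d-%d of %d\n",
                object@boundary[1L], object@boundary[2L], object@proteinLength))
})
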