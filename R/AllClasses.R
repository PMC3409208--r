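#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom stats lm.fit rnorm runif rbinom rlnorm sd t.test p.adjust setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

#' Monoisotopic residue-mass table
#'
#' Holds the monoisotopic masses (Da) of amino-acid residues together with
#' the physical constants every peptide-mass computation needs: the mass of
#' water (added once per peptide, for the terminal H and OH) and of a proton
#' (added on singly protonated MH+ ions). Non-standard residues (for example
#' synthetic amino acids in calibrant peptides) live in \code{extra} so the
#' standard table stays auditable.
#'
#' @slot residues named numeric, one-letter code to monoisotopic residue mass (Da).
#' @slot water numeric, monoisotopic mass of H2O (Da).
#' @slot proton numeric, mass of a proton (Da).
#' @slot extra named numeric, user-supplied masses for non-standard codes.
#'
#' @seealso [defaultMassTable()], [peptideNeutralMass()]
#' @export
setClass("ResidueMassTable",
  slots = c(residues = "numeric", water = "numeric", proton = "numeric",
            extra = "numeric"))

setValidity("ResidueMassTable", function(object) {
  std <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  msgs <- character()
  if (!all(std %in% names(object@residues)))
    msgs <- c(msgs, paste("missing standard residues:",
                          paste(setdiff(std, names(object@residues)), collapse = ", ")))
  if (any(!is.finite(object@residues)) || any(object@residues <= 0))
    msgs <- c(msgs, "all residue masses must be finite and > 0")
  if (length(object@extra) &&
      (any(!is.finite(object@extra)) || any(object@extra <= 0) ||
       is.null(names(object@extra)) || any(!nzchar(names(object@extra)))))
    msgs <- c(msgs, "extra residue masses must be named, finite and > 0")
  if (abs(object@water - 18.0106) > 1e-3)
    msgs <- c(msgs, "water mass implausible (expected ~18.0106 Da)")
  if (abs(object@proton - 1.00728) > 1e-4)
    msgs <- c(msgs, "proton mass implausible (expected ~1.00728 Da)")
  if (length(msgs)) msgs else TRUE
})

#' Residue modification
#'
#' A mass shift applied to specific residues, either \code{fixed} (always
#' applied to every target residue, e.g. carbamidomethyl-Cys from
#' iodoacetamide alkylation) or \code{variable} (applied to 0..n of the
#' target residues, e.g. methionine oxidation).
#'
#' @slot name character, label used in reports (e.g. "Oxidation").
#' @slot targets character, one-letter residue codes the modification hits.
#' @slot delta numeric, monoisotopic mass shift in Da.
#' @slot mode character, "fixed" or "variable".
#'
#' @seealso [modification()], [carbamidomethyl()], [metOxidation()]
#' @export
setClass("Modification",
  slots = c(name = "character", targets = "character", delta = "numeric",
            mode = "character"))

setValidity("Modification", function(object) {
  msgs <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msgs <- c(msgs, "name must be a single non-empty string")
  if (!length(object@targets) || any(nchar(object@targets) != 1L))
    msgs <- c(msgs, "targets must be one-letter residue codes")
  if (length(object@delta) != 1L || !is.finite(object@delta))
    msgs <- c(msgs, "delta must be a single finite mass (Da)")
  if (!identical(object@mode, "fixed") && !identical(object@mode, "variable"))
    msgs <- c(msgs, "mode must be 'fixed' or 'variable'")
  if (length(msgs)) msgs else TRUE
})

#' Tryptic cleavage rule
#'
#' Protease specificity for the in-silico digest. The default is the
#' standard Keil rule for trypsin: cleave C-terminal to K or R unless the
#' next residue is proline, allowing one missed cleavage.
#'
#' @slot cleaveAfter character, residues after which the backbone is cut.
#' @slot blockedByNext character, residues that block a cut when they follow
#'   the cleavage site (may be empty).
#' @slot maxMissed integer, maximum number of missed cleavages per peptide.
#'
#' @seealso [cleavageRule()], [digestProtein()]
#' @export
setClass("CleavageRule",
  slots = c(cleaveAfter = "character", blockedByNext = "character",
            maxMissed = "integer"))

setValidity("CleavageRule", function(object) {
  msgs <- character()
  if (!length(object@cleaveAfter))
    msgs <- c(msgs, "cleaveAfter must name at least one residue")
  if (length(object@maxMissed) != 1L || is.na(object@maxMissed) ||
      object@maxMissed < 0L)
    msgs <- c(msgs, "maxMissed must be a single integer >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Observed MALDI peak list
#'
#' An observed reflector spectrum reduced to centroided (m/z, intensity)
#' pairs, with provenance and a flag recording whether the mass axis has
#' been recalibrated against internal standards. Duplicate m/z values are
#' permitted (adjacent isobaric peptides) and surfaced by [hasDuplicates()].
#'
#' @slot mz numeric, observed m/z values (Da, charge +1 assumed).
#' @slot intensity numeric, peak intensities (arbitrary units, >= 0).
#' @slot sourceId character, provenance label (file name, simulation id).
#' @slot calibrated logical, TRUE once a calibration model has been applied.
#'
#' @seealso [peakList()], [readPeakList()], [applyCalibration()]
#' @export
setClass("PeakList",
  slots = c(mz = "numeric", intensity = "numeric", sourceId = "character",
            calibrated = "logical"))

setValidity("PeakList", function(object) {
  msgs <- character()
  if (length(object@mz) != length(object@intensity))
    msgs <- c(msgs, "mz and intensity must have equal length")
  if (length(object@mz) && (any(!is.finite(object@mz)) || any(object@mz <= 0)))
    msgs <- c(msgs, "all m/z values must be finite and > 0")
  if (length(object@intensity) &&
      (any(!is.finite(object@intensity)) || any(object@intensity < 0)))
    msgs <- c(msgs, "all intensities must be finite and >= 0")
  if (length(object@sourceId) != 1L)
    msgs <- c(msgs, "sourceId must be a single string")
  if (length(object@calibrated) != 1L || is.na(object@calibrated))
    msgs <- c(msgs, "calibrated must be TRUE or FALSE")
  if (length(msgs)) msgs else TRUE
})

#' Affine mass-calibration model
#'
#' Internal-standard recalibration of the observed mass axis:
#' corrected = slope * observed + intercept, applied identically to every
#' peak. Fitted by least squares from matched calibrant pairs; a single
#' calibrant degrades gracefully to a constant offset (slope 1).
#'
#' @slot slope numeric, dimensionless scale factor (close to 1).
#' @slot intercept numeric, additive offset in Da.
#' @slot nCalibrants integer, number of calibrant pairs used in the fit.
#' @slot residualsPpm numeric, signed fit residuals in ppm, one per pair.
#'
#' @seealso [fitCalibration()], [applyCalibration()]
#' @export
setClass("CalibrationModel",
  slots = c(slope = "numeric", intercept = "numeric", nCalibrants = "integer",
            residualsPpm = "numeric"))

setValidity("CalibrationModel", function(object) {
  msgs <- character()
  if (length(object@slope) != 1L || !is.finite(object@slope) ||
      object@slope <= 0.9 || object@slope >= 1.1)
    msgs <- c(msgs, "slope must lie in (0.9, 1.1): larger distortions are not a mass recalibration")
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    msgs <- c(msgs, "intercept must be a single finite offset (Da)")
  if (object@nCalibrants < 1L)
    msgs <- c(msgs, "at least one calibrant pair is required")
  if (length(msgs)) msgs else TRUE
})

#' Peptide-mass-fingerprint match report
#'
#' The per-protein identification report: every observed peak is assigned
#' to exactly one of three bins — internal calibrant, best-matched peptide,
#' or unmatched — and the report carries the matched peptides with their
#' signed ppm accuracy, the sequence coverage from the union of matched
#' spans, and the fraction of total reflector signal in the calibrant and
#' matched bins.
#'
#' @slot accession character, protein accession the digest came from.
#' @slot proteinLength integer, protein length in residues.
#' @slot matches data.frame, all peptide matches within tolerance
#'   (columns: peakIndex, observedMz, intensity, start, end, sequence,
#'   missedCleavages, modState, nVarMods, mh, errorDa, errorPpm, isBest).
#' @slot coveragePercent numeric, 0-100.
#' @slot matchedSignalFraction numeric, matched intensity / non-calibrant intensity.
#' @slot calibrantSignalFraction numeric, calibrant intensity / total intensity.
#' @slot calibrants data.frame, calibrant-to-peak assignments.
#' @slot unmatched data.frame, unassigned peaks sorted by descending intensity.
#' @slot parameters list, echo of the run parameters (tolerance, unit,
#'   maxMissed, modifications, calibration flag).
#' @slot calibration CalibrationModel or NULL when no recalibration was applied.
#'
#' @seealso [buildReport()], [writeReport()], [compareMatchedSets()]
#' @export
setClass("MatchReport",
  slots = c(accession = "character", proteinLength = "integer",
            matches = "data.frame", coveragePercent = "numeric",
            matchedSignalFraction = "numeric",
            calibrantSignalFraction = "numeric",
            calibrants = "data.frame", unmatched = "data.frame",
            parameters = "list", calibration = "ANY"))

setValidity("MatchReport", function(object) {
  msgs <- character()
  frac <- c(object@matchedSignalFraction, object@calibrantSignalFraction)
  if (any(!is.finite(frac)) || any(frac < 0) || any(frac > 1))
    msgs <- c(msgs, "signal fractions must lie in [0, 1]")
  if (object@coveragePercent < 0 || object@coveragePercent > 100)
    msgs <- c(msgs, "coverage must lie in [0, 100]")
  if (!is.null(object@calibration) && !is(object@calibration, "CalibrationModel"))
    msgs <- c(msgs, "calibration must be NULL or a CalibrationModel")
  if (length(msgs)) msgs else TRUE
})

#' Truncation-isoform call
#'
#' Result of comparing the matched peptide set of a candidate (lower
#' molecular weight) spot against the full-length reference spot of the
#' same protein: which terminus (if any) is lost, the residue interval in
#' which the cut must lie, and the missing/retained peptide evidence.
#'
#' @slot terminus character, one of "N", "C", "internal", "none",
#'   "indeterminate".
#' @slot boundary integer, length-2 (first, last) 1-based residue interval
#'   containing the cut for N/C calls, length-0 otherwise.
#' @slot missingPeptides data.frame, reference peptides absent in the query.
#' @slot retainedPeptides data.frame, reference peptides present in both.
#' @slot nMissing integer, count of missing peptides (the evidence count).
#' @slot proteinLength integer.
#'
#' @seealso [inferTruncation()], [compareMatchedSets()]
#' @export
setClass("TruncationCall",
  slots = c(terminus = "character", boundary = "integer",
            missingPeptides = "data.frame", retainedPeptides = "data.frame",
            nMissing = "integer", proteinLength = "integer"))

setValidity("TruncationCall", function(object) {
  msgs <- character()
  if (!object@terminus %in% c("N", "C", "internal", "none", "indeterminate"))
    msgs <- c(msgs, "terminus must be N, C, internal, none or indeterminate")
  if ((object@terminus == "none") != (object@nMissing == 0L))
    msgs <- c(msgs, "terminus 'none' iff there are no missing peptides")
  if (object@terminus %in% c("N", "C")) {
    if (length(object@boundary) != 2L)
      msgs <- c(msgs, "N/C calls must carry a length-2 boundary interval")
    else if (object@boundary[1L] < 1L || object@boundary[2L] > object@proteinLength ||
             object@boundary[1L] > object@boundary[2L])
      msgs <- c(msgs, "boundary interval must lie within the protein")
  } else if (length(object@boundary) != 0L) {
    msgs <- c(msgs, "boundary interval only accompanies N or C calls")
  }
  if (length(msgs)) msgs else TRUE
})

#' Replicate 2D-gel spot-quantity table
#'
#' A SummarizedExperiment holding spot quantities (intensity x area in ppm
#' of total gel signal) for two groups of replicate gels: one assay
#' \code{"quantity"} (spots x samples) and a \code{group} column in
#' colData with exactly two levels and at least two replicates each.
#'
#' @seealso [spotTable()], [screenSpots()]
#' @export
setClass("SpotTable", contains = "SummarizedExperiment")

setValidity("SpotTable", function(object) {
  msgs <- character()
  if (!"quantity" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'quantity' is required")
  cd <- SummarizedExperiment::colData(object)
  if (!"group" %in% colnames(cd)) {
    msgs <- c(msgs, "colData must contain a 'group' column")
  } else {
    tab <- table(cd$group)
    if (length(tab) != 2L)
      msgs <- c(msgs, "exactly two groups are required")
    else if (any(tab < 2L))
      msgs <- c(msgs, "at least two replicates per group are required")
  }
  if ("quantity" %in% SummarizedExperiment::assayNames(object)) {
    q <- SummarizedExperiment::assay(object, "quantity")
    if (any(q < 0, na.rm = TRUE))
      msgs <- c(msgs, "spot quantities must be >= 0")
  }
  if (length(msgs)) msgs else TRUE
})
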