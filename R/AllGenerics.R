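# Accessor generics. Slot access stays internal; users go through these.

#' @rdname PeakList-class
#' @param object,x a \linkS4class{PeakList} (or other pmfkit object).
#' @export
setGeneric("mz", function(object) standardGeneric("mz"))

#' @rdname PeakList-class
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))

#' @rdname PeakList-class
#' @export
setGeneric("sourceId", function(object) standardGeneric("sourceId"))

#' @rdname PeakList-class
#' @export
setGeneric("isCalibrated", function(object) standardGeneric("isCalibrated"))

#' @rdname PeakList-class
#' @export
setGeneric("hasDuplicates", function(object) standardGeneric("hasDuplicates"))

#' @rdname MatchReport-class
#' @export
setGeneric("accession", function(object) standardGeneric("accession"))

#' @rdname MatchReport-class
#' @export
setGeneric("matchedPeaks", function(object) standardGeneric("matchedPeaks"))

#' @rdname MatchReport-class
#' @export
setGeneric("unmatchedPeaks", function(object) standardGeneric("unmatchedPeaks"))

#' @rdname MatchReport-class
#' @export
setGeneric("sequenceCoverage", function(object) standardGeneric("sequenceCoverage"))

#' @rdname MatchReport-class
#' @export
setGeneric("signalFractionsOf", function(object) standardGeneric("signalFractionsOf"))

#' @rdname MatchReport-class
#' @export
setGeneric("reportParameters", function(object) standardGeneric("reportParameters"))

#' @rdname MatchReport-class
#' @export
setGeneric("calibrantAssignments", function(object) standardGeneric("calibrantAssignments"))

#' @rdname CalibrationModel-class
#' @export
setGeneric("calibrationSlope", function(object) standardGeneric("calibrationSlope"))

#' @rdname CalibrationModel-class
#' @export
setGeneric("calibrationIntercept", function(object) standardGeneric("calibrationIntercept"))

#' @rdname CalibrationModel-class
#' @export
setGeneric("calibrationResiduals", function(object) standardGeneric("calibrationResiduals"))

#' @rdname TruncationCall-class
#' @export
setGeneric("terminus", function(object) standardGeneric("terminus"))

#' @rdname TruncationCall-class
#' @export
setGeneric("boundaryInterval", function(object) standardGeneric("boundaryInterval"))

#' @rdname TruncationCall-class
#' @export
setGeneric("missingPeptides", function(object) standardGeneric("missingPeptides"))

#' @rdname TruncationCall-class
#' @export
setGeneric("retainedPeptides", function(object) standardGeneric("retainedPeptides"))
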