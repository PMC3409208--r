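# PeakList construction, accessors and show.

#' Construct a peak list
#'
#' @param mz observed m/z values (Da).
#' @param intensity peak intensities (same length as `mz`); defaults to 1.
#' @param sourceId provenance label.
#' @param calibrated whether the mass axis has already been recalibrated.
#' @return a \linkS4class{PeakList}.
#' @export
peakList <- function(mz, intensity = rep(1, length(mz)), sourceId = "",
                     calibrated = FALSE) {
  new("PeakList", mz = as.numeric(mz), intensity = as.numeric(intensity),
      sourceId = sourceId, calibrated = calibrated)
}

#' @rdname PeakList-class
#' @export
setMethod("mz", "PeakList", function(object) object@mz)

#' @rdname PeakList-class
#' @export
setMethod("intensity", "PeakList", function(object) object@intensity)

#' @rdname PeakList-class
#' @export
setMethod("sourceId", "PeakList", function(object) object@sourceId)

#' @rdname PeakList-class
#' @export
setMethod("isCalibrated", "PeakList", function(object) object@calibrated)

#' @rdname PeakList-class
#' @export
setMethod("hasDuplicates", "PeakList",
          function(object) anyDuplicated(object@mz) > 0L)

#' @rdname PeakList-class
#' @export
setMethod("length", "PeakList", function(x) length(x@mz))

#' @rdname PeakList-class
#' @export
setMethod("as.data.frame", "PeakList", function(x, ...) {
  data.frame(mz = x@mz, intensity = x@intensity)
})

setMethod("show", "PeakList", function(object) {
  cat(sprintf("PeakList with %d peak(s)%s\n", length(object@mz),
              if (nzchar(object@sourceId))
                sprintf(" [%s]", object@sourceId) else ""))
  if (length(object@mz))
    cat(sprintf("  m/z range: %.4f - %.4f\n", min(object@mz), max(object@mz)))
  cat(sprintf("  calibrated: %s%s\n", object@calibrated,
              if (hasDuplicates(object)) "; contains duplicate m/z values" else ""))
})
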