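# Internal-standard mass recalibration: calibrant assignment, affine fit,
# application.

#' Internal calibrant definitions
#'
#' `internalStandards()` builds a calibrant table from vectors;
#' `defaultCalibrants()` reads the editable list shipped with the package
#' (two matrix standards plus trypsin autolysis peptides).
#'
#' @param name calibrant names.
#' @param theoreticalMh theoretical MH+ values (Da).
#' @param kind "matrix_standard" or "autolysis".
#' @return data.frame with columns `name`, `theoreticalMh`, `kind`.
#' @export
internalStandards <- function(name, theoreticalMh,
                              kind = "matrix_standard") {
  stopifnot(length(name) == length(theoreticalMh),
            all(theoreticalMh > 0),
            all(kind %in% c("matrix_standard", "autolysis")))
  data.frame(name = as.character(name),
             theoreticalMh = as.numeric(theoreticalMh),
             kind = rep_len(as.character(kind), length(name)),
             stringsAsFactors = FALSE)
}

#' @rdname internalStandards
#' @export
defaultCalibrants <- function() {
  path <- system.file("extdata", "calibrants.tsv", package = "pmfkit",
                      mustWork = TRUE)
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  internalStandards(tab$name, tab$theoretical_mh, tab$kind)
}

emptyCalibrantAssignment <- function() {
  data.frame(name = character(), theoreticalMh = numeric(),
             kind = character(), peakIndex = integer(),
             observedMz = numeric(), intensity = numeric(),
             deltaDa = numeric(), errorPpm = numeric(),
             stringsAsFactors = FALSE)
}

#' Assign observed peaks to internal calibrants
#'
#' For each standard the nearest observed peak within `window` is selected;
#' each peak serves at most one standard. Conflicts resolve greedily by
#' smallest absolute mass difference; exact distance ties go to the more
#' intense peak.
#'
#' @param peaks a \linkS4class{PeakList}.
#' @param standards calibrant table as from [internalStandards()].
#' @param window search half-width in Da (coarse, pre-calibration).
#' @return data.frame of assignments (possibly zero rows): `name`,
#'   `theoreticalMh`, `kind`, `peakIndex`, `observedMz`, `intensity`,
#'   `deltaDa`, `errorPpm`.
#' @export
matchCalibrants <- function(peaks, standards, window = 0.5) {
  stopifnot(is(peaks, "PeakList"), window > 0)
  if (!length(peaks@mz) || !nrow(standards))
    return(emptyCalibrantAssignment())
  cand <- do.call(rbind, lapply(seq_len(nrow(standards)), function(i) {
    d <- peaks@mz - standards$theoreticalMh[i]
    k <- which(abs(d) <= window)
    if (!length(k)) return(NULL)
    data.frame(std = i, peakIndex = k, delta = d[k],
               intensity = peaks@intensity[k])
  }))
  if (is.null(cand)) return(emptyCalibrantAssignment())
  cand <- cand[order(abs(cand$delta), -cand$intensity, cand$peakIndex), ,
               drop = FALSE]
  usedStd <- logical(nrow(standards))
  usedPeak <- logical(length(peaks@mz))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    s <- cand$std[r]; p <- cand$peakIndex[r]
    if (!usedStd[s] && !usedPeak[p]) {
      usedStd[s] <- TRUE; usedPeak[p] <- TRUE; keep[r] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand$std), , drop = FALSE]
  data.frame(name = standards$name[cand$std],
             theoreticalMh = standards$theoreticalMh[cand$std],
             kind = standards$kind[cand$std],
             peakIndex = cand$peakIndex,
             observedMz = peaks@mz[cand$peakIndex],
             intensity = peaks@intensity[cand$peakIndex],
             deltaDa = cand$delta,
             errorPpm = 1e6 * cand$delta / standards$theoreticalMh[cand$std],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fit an affine mass-calibration model
#'
#' Least-squares fit of theoretical = slope * observed + intercept over the
#' matched calibrant pairs. With a single pair the model degrades to a
#' constant offset (slope fixed at 1).
#'
#' @param pairs data.frame with columns `theoreticalMh` and `observedMz`
#'   (the output of [matchCalibrants()] works directly).
#' @return a \linkS4class{CalibrationModel} with residuals in ppm.
#' @export
fitCalibration <- function(pairs) {
  if (is.null(pairs) || !nrow(pairs))
    stop("at least one calibrant pair is required to fit a calibration")
  theo <- pairs$theoreticalMh
  obs <- pairs$observedMz
  stopifnot(is.numeric(theo), is.numeric(obs), all(is.finite(c(theo, obs))))
  n <- length(theo)
  if (n == 1L) {
    a <- 1; b <- theo - obs
  } else {
    if (isTRUE(all.equal(sd(obs), 0)) || sd(obs) == 0)
      stop("degenerate calibrant set: identical observed masses")
    fit <- lm.fit(cbind(1, obs), theo)
    a <- unname(fit$coefficients[2L]); b <- unname(fit$coefficients[1L])
  }
  resid <- 1e6 * (a * obs + b - theo) / theo
  new("CalibrationModel", slope = a, intercept = b,
      nCalibrants = as.integer(n), residualsPpm = as.numeric(resid))
}

#' @rdname CalibrationModel-class
#' @export
setMethod("calibrationSlope", "CalibrationModel", function(object) object@slope)

#' @rdname CalibrationModel-class
#' @export
setMethod("calibrationIntercept", "CalibrationModel",
          function(object) object@intercept)

#' @rdname CalibrationModel-class
#' @export
setMethod("calibrationResiduals", "CalibrationModel",
          function(object) object@residualsPpm)

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf("CalibrationModel: corrected = %.8f * observed %+.5f Da\n",
              object@slope, object@intercept))
  cat(sprintf("  fitted on %d calibrant(s); max |residual| = %.2f ppm\n",
              object@nCalibrants,
              if (length(object@residualsPpm)) max(abs(object@residualsPpm)) else 0))
})

#' Apply a calibration model to a peak list
#'
#' Maps every m/z through `slope * mz + intercept`; intensities are
#' untouched and the input object is not modified. Re-calibrating an
#' already-calibrated list is an error.
#'
#' @param peaks a \linkS4class{PeakList} (not yet calibrated).
#' @param model a \linkS4class{CalibrationModel}.
#' @return a new calibrated \linkS4class{PeakList}.
#' @export
applyCalibration <- function(peaks, model) {
  stopifnot(is(peaks, "PeakList"), is(model, "CalibrationModel"))
  if (peaks@calibrated)
    stop("peak list is already calibrated; refusing to calibrate twice")
  peakList(model@slope * peaks@mz + model@intercept, peaks@intensity,
           sourceId = peaks@sourceId, calibrated = TRUE)
}
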