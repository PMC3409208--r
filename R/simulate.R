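# Seeded generators: random proteins, MALDI peak lists with calibration
# drift / ppm noise / dropout / contaminants, truncated isoforms, and
# replicate spot tables. Everything is bit-reproducible for a fixed
# config; the three generators re-seed from config$seed with fixed
# offsets so protein, spectrum and spot draws are independent streams.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators with its default.
#' Mass error is applied in the instrument frame — observed =
#' (true - intercept)/slope, then multiplicative Gaussian ppm noise — so
#' that fitting the affine calibration on the calibrant peaks is exactly
#' the inverse problem.
#'
#' @param seed integer seed; identical config + seed gives identical output.
#' @param proteinLength residues per generated protein.
#' @param residueFreqs named numeric of residue sampling weights over the
#'   20 standard codes; NULL = uniform.
#' @param calibrationA,calibrationB true affine distortion (slope,
#'   intercept in Da) of the instrument mass axis.
#' @param noisePpm Gaussian mass-noise SD in ppm (reflector-mode MALDI is
#'   a few ppm after internal calibration; default 5).
#' @param dropout per-peptide detection-failure probability.
#' @param nContaminants number of contaminant peaks, uniform in
#'   `contaminantRange` (Da).
#' @param contaminantRange m/z range of contaminant peaks.
#' @param intensityMeanlog,intensitySdlog log-normal intensity model.
#' @param nSpots,nPerGroup,spotCv,baselineMeanlog,baselineSdlog,plantedFold,nPlanted
#'   spot-table generator: number of spots, replicates per group (4, the
#'   usual replicate design), within-group coefficient of variation,
#'   log-normal spot-abundance baseline, planted fold change and number of
#'   planted differential spots.
#' @return a list of class "SimulationConfig".
#' @export
simConfig <- function(seed = 1L, proteinLength = 300L, residueFreqs = NULL,
                      calibrationA = 1, calibrationB = 0, noisePpm = 5,
                      dropout = 0.1, nContaminants = 5L,
                      contaminantRange = c(800, 3500),
                      intensityMeanlog = log(1000), intensitySdlog = 1,
                      nSpots = 500L, nPerGroup = 4L, spotCv = 0.25,
                      baselineMeanlog = log(500), baselineSdlog = 1,
                      plantedFold = 2, nPlanted = 0L) {
  stopifnot(dropout >= 0, dropout <= 1, noisePpm >= 0, proteinLength >= 1,
            nContaminants >= 0, calibrationA > 0.9, calibrationA < 1.1,
            nPerGroup >= 2, spotCv >= 0, plantedFold > 0, nPlanted >= 0,
            nPlanted <= nSpots)
  cfg <- list(seed = as.integer(seed), proteinLength = as.integer(proteinLength),
              residueFreqs = residueFreqs, calibrationA = calibrationA,
              calibrationB = calibrationB, noisePpm = noisePpm,
              dropout = dropout, nContaminants = as.integer(nContaminants),
              contaminantRange = contaminantRange,
              intensityMeanlog = intensityMeanlog,
              intensitySdlog = intensitySdlog, nSpots = as.integer(nSpots),
              nPerGroup = as.integer(nPerGroup), spotCv = spotCv,
              baselineMeanlog = baselineMeanlog, baselineSdlog = baselineSdlog,
              plantedFold = plantedFold, nPlanted = as.integer(nPlanted))
  class(cfg) <- "SimulationConfig"
  cfg
}

standardResidues <- function() strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

#' Generate a random protein sequence
#'
#' @param config a [simConfig()] object.
#' @return a protein sequence string over the 20 standard residues,
#'   deterministic per seed.
#' @export
genProtein <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  res <- standardResidues()
  p <- config$residueFreqs
  prob <- if (is.null(p)) rep(1 / 20, 20) else {
    stopifnot(all(names(p) %in% res))
    v <- setNames(numeric(20), res); v[names(p)] <- p; v / sum(v)
  }
  paste(sample(res, config$proteinLength, replace = TRUE, prob = prob),
        collapse = "")
}

#' Truncate a protein at a tryptic cleavage boundary
#'
#' Removes whole tryptic fragments from one terminus. Peptide-presence
#' evidence can only localise a cut to peptide resolution, so the
#' generator's truncation model places the cut at the cleavage boundary
#' whose fragment index is closest to `cutFraction` of the fragments,
#' subject to at least `minFragmentsEachSide` fragments on each side.
#'
#' @param sequence full-length protein string.
#' @param terminus "N" (prefix removed) or "C" (suffix removed).
#' @param cutFraction where along the fragment series to cut (0-1).
#' @param rule a \linkS4class{CleavageRule}.
#' @param minFragmentsEachSide minimum fragments kept and removed.
#' @return list: `sequence` (the truncated form), `terminus`, `site`
#'   (for N the new first residue, for C the last kept residue, in
#'   full-length coordinates), `removed` (c(from, to) removed interval).
#' @export
truncateAtCleavageBoundary <- function(sequence, terminus = c("C", "N"),
                                       cutFraction = 0.5,
                                       rule = cleavageRule(),
                                       minFragmentsEachSide = 2L) {
  terminus <- match.arg(terminus)
  sites <- cleavageSites(sequence, rule)
  nf <- length(sites) + 1L
  lo <- minFragmentsEachSide
  hi <- nf - minFragmentsEachSide
  if (lo > hi || !length(sites))
    stop("too few tryptic fragments to truncate with ", minFragmentsEachSide,
         " on each side")
  elig <- sites[seq_along(sites) >= lo & seq_along(sites) <= hi]
  eligIdx <- which(seq_along(sites) >= lo & seq_along(sites) <= hi)
  pick <- which.min(abs(eligIdx / nf - cutFraction))
  cut <- elig[pick]                      # cut after residue `cut`
  L <- nchar(sequence)
  if (terminus == "N") {
    list(sequence = substr(sequence, cut + 1L, L), terminus = "N",
         site = cut + 1L, removed = c(1L, cut))
  } else {
    list(sequence = substr(sequence, 1L, cut), terminus = "C",
         site = cut, removed = c(cut + 1L, L))
  }
}

#' Simulate a MALDI reflector peak list from a protein
#'
#' Digests the sequence, drops each theoretical peptide with probability
#' `dropout`, maps every surviving true mass into the instrument frame
#' through the inverse of the true affine calibration, perturbs it with
#' Gaussian ppm noise, then adds the internal calibrants (never dropped:
#' they are spiked at high abundance) and uniform contaminant peaks, and
#' draws log-normal intensities. The emitted peptide state is the
#' fixed-modification base state: variable modifications are a search-side
#' concern and are off in the instrument model by default.
#'
#' @param sequence protein sequence string.
#' @param config a [simConfig()] object.
#' @param standards calibrant table, or NULL for none.
#' @param rule,mods,table digestion settings (defaults: trypsin with one
#'   missed cleavage, fixed carbamidomethyl-Cys).
#' @return list: `peaks` (a \linkS4class{PeakList}), `truth` (list with
#'   `peptides` — the detected theoretical peptides with true MH+,
#'   `calibration` — c(a, b), `calibrantMz`, `contaminantMz`).
#' @export
simulatePeakList <- function(sequence, config,
                             standards = defaultCalibrants(),
                             rule = cleavageRule(),
                             mods = list(carbamidomethyl()),
                             table = defaultMassTable()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 1000003L)
  a <- config$calibrationA; b <- config$calibrationB
  distort <- function(mTrue) {
    instr <- (mTrue - b) / a
    instr * (1 + rnorm(length(instr), 0, config$noisePpm * 1e-6))
  }
  peptides <- digestProtein(sequence, rule = rule, mods = mods, table = table)
  peptides <- peptides[peptides$nVarMods == 0L, , drop = FALSE]
  keep <- runif(nrow(peptides)) >= config$dropout
  detected <- peptides[keep, , drop = FALSE]
  rownames(detected) <- NULL
  mzPep <- distort(detected$mh)
  mzCal <- if (!is.null(standards) && nrow(standards))
    distort(standards$theoreticalMh) else numeric()
  mzCon <- if (config$nContaminants > 0)
    runif(config$nContaminants, config$contaminantRange[1L],
          config$contaminantRange[2L]) else numeric()
  mzAll <- c(mzPep, mzCal, mzCon)
  int <- rlnorm(length(mzAll), config$intensityMeanlog, config$intensitySdlog)
  list(peaks = peakList(mzAll, int,
                        sourceId = sprintf("sim-seed%d", config$seed)),
       truth = list(peptides = detected, calibration = c(a = a, b = b),
                    calibrantMz = mzCal, contaminantMz = mzCon))
}

#' Generate a replicate 2D-gel spot table
#'
#' Log-normal spot quantities (ppm of total gel signal) for two groups of
#' replicate gels. The first `nPlanted` spots carry a true `plantedFold`
#' increase in group B; the rest are null. Within-group variation is
#' log-normal with coefficient of variation `spotCv`.
#'
#' @param config a [simConfig()] object.
#' @return list: `spots` (a \linkS4class{SpotTable}), `truth` (logical,
#'   TRUE for planted differential spots).
#' @export
genSpotTable <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 2000003L)
  ns <- config$nSpots; npg <- config$nPerGroup
  sdlog <- sqrt(log(1 + config$spotCv^2))
  baseline <- rlnorm(ns, config$baselineMeanlog, config$baselineSdlog)
  truth <- seq_len(ns) <= config$nPlanted
  meanB <- baseline * ifelse(truth, config$plantedFold, 1)
  draw <- function(m) rlnorm(ns * npg, rep(log(m) - sdlog^2 / 2, npg), sdlog)
  q <- cbind(matrix(draw(baseline), ns, npg),
             matrix(draw(meanB), ns, npg))
  spotIds <- sprintf("spot%04d", seq_len(ns))
  groups <- rep(c("A", "B"), each = npg)
  list(spots = spotTable(q, groups, spotIds), truth = truth)
}
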