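# Shared replicate drivers for the simulation-recovery tests.

randomProtein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], n, replace = TRUE),
        collapse = "")
}

# One truncation-recovery replicate: simulate a full-length and a
# truncated spectrum of the same random protein, identify both against
# the full sequence, and compare the inferred call with the truth.
truncationReplicate <- function(seed, dropout = 0, noisePpm = 0) {
  set.seed(seed)
  term <- sample(c("N", "C"), 1L)
  frac <- runif(1L, 0.35, 0.65)
  cfg <- simConfig(seed = seed, proteinLength = 300L, noisePpm = noisePpm,
                   dropout = dropout)
  prot <- genProtein(cfg)
  tr <- truncateAtCleavageBoundary(prot, terminus = term, cutFraction = frac)
  cfgF <- simConfig(seed = seed * 2L + 1L, noisePpm = noisePpm,
                    dropout = dropout)
  cfgT <- simConfig(seed = seed * 2L + 2L, noisePpm = noisePpm,
                    dropout = dropout)
  simF <- simulatePeakList(prot, cfgF)
  simT <- simulatePeakList(tr$sequence, cfgT)
  stds <- defaultCalibrants()
  repF <- buildReport("SIM", prot, simF$peaks, standards = stds)
  repT <- buildReport("SIM", prot, simT$peaks, standards = stds)
  sets <- compareMatchedSets(repF, repT)
  call <- inferTruncation(sets$missing, sets$retained, nchar(prot))
  bi <- boundaryInterval(call)
  list(correct = identical(terminus(call), term),
       contained = length(bi) == 2L && bi[1L] <= tr$site && tr$site <= bi[2L])
}

# One calibration-recovery replicate under a known affine distortion.
calibrationReplicate <- function(seed, a, b, noisePpm = 5) {
  cfg <- simConfig(seed = seed, calibrationA = a, calibrationB = b,
                   noisePpm = noisePpm, dropout = 1, nContaminants = 0L)
  sim <- simulatePeakList(randomProtein(50L, seed), cfg)
  assigned <- matchCalibrants(sim$peaks, defaultCalibrants(), window = 0.5)
  model <- fitCalibration(assigned)
  c(aErr = abs(calibrationSlope(model) - a),
    bErr = abs(calibrationIntercept(model) - b),
    n = nrow(assigned))
}
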