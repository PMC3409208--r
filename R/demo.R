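# Packaged demonstration fixture: a synthetic protein and noise-free
# simulated spectra of its full-length and C-terminally truncated forms.

#' Packaged demonstration fixture (synthetic)
#'
#' A 220-residue synthetic protein together with two simulated noise-free
#' reflector peak lists: the full-length form and a C-terminal truncation
#' ending at residue 103 (whole tryptic fragments removed). The spectra
#' carry the packaged internal calibrants and three contaminant peaks
#' each, and were generated with [simulatePeakList()] under zero mass
#' noise and zero dropout — the limit in which identification recovers
#' 100% sequence coverage and the truncation call localises the cut
#' exactly. Everything is simulated; no instrument data are included.
#'
#' @return `demoProtein()`: list with `accession`, `sequence`, and
#'   `truncationSite` (the last retained residue of the truncated form).
#'   `demoFiles()`: named character vector of the packaged file paths
#'   (`fasta`, `fullPeaks`, `truncatedPeaks`).
#' @examples
#' demo <- demoFiles()
#' peaks <- readPeakList(demo[["fullPeaks"]])
#' prot <- readFastaProteins(demo[["fasta"]])
#' report <- buildReport(prot$accession, prot$sequence, peaks,
#'                       standards = defaultCalibrants())
#' sequenceCoverage(report)
#' @export
demoFiles <- function() {
  dir <- system.file("extdata", "demo", package = "pmfkit", mustWork = TRUE)
  c(fasta = file.path(dir, "demo_protein.fasta"),
    fullPeaks = file.path(dir, "demo_full_peaks.txt"),
    truncatedPeaks = file.path(dir, "demo_truncated_peaks.txt"))
}

#' @rdname demoFiles
#' @export
demoProtein <- function() {
  prot <- readFastaProteins(demoFiles()[["fasta"]])
  list(accession = prot$accession, sequence = prot$sequence,
       truncationSite = 103L)
}
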