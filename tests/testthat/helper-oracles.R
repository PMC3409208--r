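# Independent oracles, deliberately naive: straight double loops over all
# (peak, peptide) pairs, kept free of the package's matching code path.

bruteForceMatch <- function(peaks, peptides, tolerance = 0.15, unit = "da") {
  rows <- list()
  for (p in seq_along(mz(peaks))) {
    obs <- mz(peaks)[p]
    for (j in seq_len(nrow(peptides))) {
      tol <- if (unit == "da") tolerance else tolerance * 1e-6 * peptides$mh[j]
      if (abs(obs - peptides$mh[j]) <= tol) {
        rows[[length(rows) + 1L]] <- data.frame(
          peakIndex = p, start = peptides$start[j], end = peptides$end[j],
          modState = peptides$modState[j],
          missedCleavages = peptides$missedCleavages[j],
          nVarMods = peptides$nVarMods[j], mh = peptides$mh[j],
          errorPpm = 1e6 * (obs - peptides$mh[j]) / peptides$mh[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$isBest <- FALSE
  for (p in unique(out$peakIndex)) {
    k <- which(out$peakIndex == p)
    best <- k[1L]
    for (i in k[-1L]) {      # explicit pairwise tie chain
      cand <- out[i, ]; cur <- out[best, ]
      better <- if (abs(cand$errorPpm) != abs(cur$errorPpm))
        abs(cand$errorPpm) < abs(cur$errorPpm)
      else if (cand$missedCleavages != cur$missedCleavages)
        cand$missedCleavages < cur$missedCleavages
      else if (cand$nVarMods != cur$nVarMods) cand$nVarMods < cur$nVarMods
      else if (cand$mh != cur$mh) cand$mh < cur$mh
      else if (cand$start != cur$start) cand$start < cur$start
      else cand$end < cur$end
      if (better) best <- i
    }
    out$isBest[best] <- TRUE
  }
  out
}

matchKey <- function(df) {
  sort(paste(df$peakIndex, df$start, df$end, df$modState,
             df$missedCleavages, sep = "|"))
}

# union length of 1-based inclusive spans, by residue enumeration
spanUnionLength <- function(starts, ends) {
  if (!length(starts)) return(0L)
  length(unique(unlist(mapply(seq, starts, ends, SIMPLIFY = FALSE))))
}
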