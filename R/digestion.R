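# In-silico proteolysis: cleavage sites, fragments, missed cleavages and
# modification-state expansion.

#' Construct a cleavage rule
#'
#' @param cleaveAfter residues after which the protease cuts (default K, R:
#'   trypsin).
#' @param blockedByNext residues that block a cut when immediately
#'   C-terminal to the site (default P, the standard Keil proline rule);
#'   use `character()` to disable.
#' @param maxMissed maximum missed cleavages per reported peptide.
#' @return a \linkS4class{CleavageRule}.
#' @export
cleavageRule <- function(cleaveAfter = c("K", "R"), blockedByNext = "P",
                         maxMissed = 1L) {
  new("CleavageRule", cleaveAfter = toupper(cleaveAfter),
      blockedByNext = toupper(blockedByNext), maxMissed = as.integer(maxMissed))
}

#' Cleavage positions in a sequence
#'
#' Position i is a cleavage site when residue i is in `cleaveAfter` and the
#' following residue is not in `blockedByNext`. The terminal residue is
#' never a site (a cut there produces no new fragment).
#'
#' @param sequence protein sequence string.
#' @param rule a \linkS4class{CleavageRule}.
#' @return sorted integer vector of 1-based positions after which the
#'   backbone is cut.
#' @examples
#' cleavageSites("AAKGGRCC")  # 3, 6
#' cleavageSites("AKPGR")     # none: K blocked by P, R terminal
#' @export
cleavageSites <- function(sequence, rule = cleavageRule()) {
  validObject(rule)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (!n) stop("empty sequence")
  idx <- which(chars %in% rule@cleaveAfter)
  idx <- idx[idx < n]
  if (length(rule@blockedByNext))
    idx <- idx[!chars[idx + 1L] %in% rule@blockedByNext]
  idx
}

#' Digest a protein in silico
#'
#' Cuts the sequence at every cleavage site and reports every contiguous
#' run of 1..(maxMissed+1) fragments as a theoretical peptide, expanded
#' over all variable-modification states, with neutral mass and MH+
#' populated. Fixed modifications are applied throughout.
#'
#' @param sequence protein sequence string (one-letter codes).
#' @param rule a \linkS4class{CleavageRule}.
#' @param mods list of \linkS4class{Modification} objects
#'   (default: carbamidomethyl-Cys fixed + Met oxidation variable).
#' @param table a \linkS4class{ResidueMassTable}.
#' @param minLength minimum peptide length to report (default 1: no filter).
#' @return data.frame of theoretical peptides ordered by start position,
#'   then missed-cleavage count, then modification state: columns
#'   `sequence`, `start`, `end` (1-based inclusive), `missedCleavages`,
#'   `modState`, `nVarMods`, `neutralMass`, `mh`.
#' @examples
#' digestProtein("AAKGGRCC", cleavageRule(maxMissed = 0), mods = list())
#' @export
digestProtein <- function(sequence, rule = cleavageRule(),
                          mods = defaultModifications(),
                          table = defaultMassTable(), minLength = 1L) {
  validObject(rule)
  validateModifications(mods)
  masses <- residueMassesOf(sequence, table)
  n <- length(masses)
  sites <- cleavageSites(sequence, rule)
  starts <- c(1L, sites + 1L)
  ends <- c(sites, n)
  nf <- length(starts)
  cs <- c(0, cumsum(masses))
  fixedDeltaPer <- function(seq) {
    d <- 0
    for (m in mods) if (m@mode == "fixed")
      d <- d + m@delta * countTargets(seq, m@targets)
    d
  }
  rows <- vector("list", 0L)
  for (j in 0:min(rule@maxMissed, nf - 1L)) {
    for (i in seq_len(nf - j)) {
      s <- starts[i]; e <- ends[i + j]
      if (e - s + 1L < minLength) next
      pep <- substr(sequence, s, e)
      base <- cs[e + 1L] - cs[s] + table@water + fixedDeltaPer(pep)
      states <- enumerateModStates(pep, mods)
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = pep, start = s, end = e, missedCleavages = j,
        modState = states$label, nVarMods = states$nVarMods,
        neutralMass = base + states$varDelta,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$missedCleavages, out$nVarMods,
                   out$modState), , drop = FALSE]
  rownames(out) <- NULL
  out$mh <- mhPlus(out$neutralMass, table)
  out
}
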