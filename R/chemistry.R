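# Residue chemistry: monoisotopic masses, modification deltas, peptide
# neutral mass and MH+.

#' Construct a residue-mass table
#'
#' @param residues named numeric vector of monoisotopic residue masses (Da),
#'   one-letter codes as names; must contain all 20 standard residues.
#' @param water monoisotopic mass of water (Da).
#' @param proton proton mass (Da).
#' @param extra named numeric vector of masses for non-standard residue
#'   codes (e.g. a synthetic amino acid in a calibrant peptide).
#' @return a \linkS4class{ResidueMassTable}.
#' @export
residueMassTable <- function(residues, water = 18.0105646863,
                             proton = 1.0072764666, extra = numeric()) {
  new("ResidueMassTable", residues = residues, water = water,
      proton = proton, extra = extra)
}

#' Default monoisotopic residue-mass table
#'
#' Reads the plain-text table shipped with the package
#' (\code{extdata/monoisotopic_residue_masses.tsv}) so the masses behind
#' every computation are auditable and overridable.
#'
#' @param extra named numeric vector of additional residue masses.
#' @return a \linkS4class{ResidueMassTable}.
#' @examples
#' tab <- defaultMassTable()
#' mhPlus(peptideNeutralMass("RPVKVYPNGAEDESAEAFPLEF", table = tab), tab)
#' @export
defaultMassTable <- function(extra = numeric()) {
  path <- system.file("extdata", "monoisotopic_residue_masses.tsv",
                      package = "pmfkit", mustWork = TRUE)
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  residueMassTable(setNames(tab$mass, tab$code), extra = extra)
}

#' Define a residue modification
#'
#' @param name modification label used in reports.
#' @param targets one-letter codes of the residues modified.
#' @param delta monoisotopic mass shift (Da).
#' @param mode "fixed" (always applied to every target residue) or
#'   "variable" (0..n target residues modified).
#' @return a \linkS4class{Modification}.
#' @export
modification <- function(name, targets, delta,
                         mode = c("fixed", "variable")) {
  mode <- match.arg(mode)
  new("Modification", name = name, targets = toupper(targets),
      delta = delta, mode = mode)
}

#' Standard modifications
#'
#' `carbamidomethyl()` is the fixed Cys carbamidomethylation from
#' iodoacetamide alkylation (+57.02146 Da); `metOxidation()` is variable
#' methionine oxidation (+15.99491 Da). `defaultModifications()` returns
#' both — the usual search configuration for an iodoacetamide-alkylated
#' in-gel digest.
#'
#' @return a \linkS4class{Modification}, or for `defaultModifications()` a
#'   list of them.
#' @export
carbamidomethyl <- function() {
  modification("Carbamidomethyl", "C", 57.02146, "fixed")
}

#' @rdname carbamidomethyl
#' @export
metOxidation <- function() {
  modification("Oxidation", "M", 15.99491, "variable")
}

#' @rdname carbamidomethyl
#' @export
defaultModifications <- function() {
  list(carbamidomethyl(), metOxidation())
}

# One configuration may not aim a fixed and a variable modification at the
# same residue: the mass of such a peptide would be ambiguous.
validateModifications <- function(mods) {
  if (!length(mods)) return(invisible(mods))
  ok <- vapply(mods, is, logical(1L), class2 = "Modification")
  if (!all(ok)) stop("all modifications must be Modification objects")
  lapply(mods, validObject)
  fixed <- unlist(lapply(mods, function(m) if (m@mode == "fixed") m@targets))
  varia <- unlist(lapply(mods, function(m) if (m@mode == "variable") m@targets))
  clash <- intersect(fixed, varia)
  if (length(clash))
    stop("fixed and variable modifications may not target the same residue: ",
         paste(clash, collapse = ", "))
  nm <- vapply(mods, function(m) m@name, character(1L))
  if (anyDuplicated(nm))
    stop("modification names must be unique")
  invisible(mods)
}

# Lookup of per-residue masses with a precise error for unknown codes.
residueMassesOf <- function(sequence, table) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  if (!length(chars)) stop("empty peptide sequence")
  all <- c(table@residues, table@extra)
  m <- all[chars]
  if (anyNA(m)) {
    i <- which(is.na(m))[1L]
    stop(sprintf("unknown residue code '%s' at position %d", chars[i], i))
  }
  unname(m)
}

countTargets <- function(sequence, targets) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  sum(chars %in% targets)
}

#' Peptide neutral monoisotopic mass
#'
#' Sum of residue masses plus one water, plus the deltas of all applied
#' modifications: every fixed modification hits all of its target residues;
#' variable modifications contribute `count * delta` as given in `state`.
#'
#' @param sequence peptide as a string of one-letter residue codes.
#' @param mods list of \linkS4class{Modification} objects in effect.
#' @param state named integer vector of applied variable-modification
#'   counts (names are modification names); NULL means none applied.
#' @param table a \linkS4class{ResidueMassTable}.
#' @return neutral monoisotopic mass in Da.
#' @examples
#' peptideNeutralMass("AAK")                        # 288.17975
#' peptideNeutralMass("M", mods = list(metOxidation()),
#'                    state = c(Oxidation = 1))     # 165.04596
#' @export
peptideNeutralMass <- function(sequence, mods = list(), state = NULL,
                               table = defaultMassTable()) {
  validateModifications(mods)
  mass <- sum(residueMassesOf(sequence, table)) + table@water
  for (m in mods) {
    if (m@mode == "fixed") {
      mass <- mass + m@delta * countTargets(sequence, m@targets)
    } else {
      cnt <- if (is.null(state) || !m@name %in% names(state)) 0L
             else as.integer(state[[m@name]])
      if (cnt < 0L) stop("variable modification counts must be >= 0")
      if (cnt > countTargets(sequence, m@targets))
        stop(sprintf("state applies %d x %s but the peptide has only %d target residue(s)",
                     cnt, m@name, countTargets(sequence, m@targets)))
      mass <- mass + m@delta * cnt
    }
  }
  if (!is.null(state)) {
    known <- vapply(mods, function(m) m@name, character(1L))
    bad <- setdiff(names(state)[state != 0], known)
    if (length(bad))
      stop("state refers to unknown modification(s): ", paste(bad, collapse = ", "))
  }
  mass
}

#' Singly protonated ion mass (MH+)
#'
#' @param neutralMass neutral monoisotopic mass (Da); must correspond to at
#'   least one residue (i.e. exceed the mass of water).
#' @param table a \linkS4class{ResidueMassTable} (supplies the proton mass).
#' @return MH+ in Da. Vectorised and strictly monotone in `neutralMass`.
#' @export
mhPlus <- function(neutralMass, table = defaultMassTable()) {
  if (any(!is.finite(neutralMass)) || any(neutralMass <= table@water + 1e-9))
    stop("neutral mass must exceed the mass of water (empty peptide?)")
  neutralMass + table@proton
}

#' Enumerate modification states of a peptide
#'
#' PMF matching is mass-only, so positional isomers of a variable
#' modification are indistinguishable: states are enumerated by count
#' (0..number of target residues) per variable modification, with the
#' product over independent variable modifications; fixed modifications
#' are always applied and contribute no extra states.
#'
#' @param sequence peptide string.
#' @param mods list of \linkS4class{Modification} objects.
#' @return data.frame with one row per state, ordered by total variable
#'   count ascending: one count column per variable modification, plus
#'   `label` (e.g. `"Oxidation:1"`, empty for the unmodified state),
#'   `nVarMods` (total variable count) and `varDelta` (total variable
#'   mass shift, Da). Fixed deltas are not included in `varDelta`.
#' @export
enumerateModStates <- function(sequence, mods = list()) {
  validateModifications(mods)
  var <- Filter(function(m) m@mode == "variable", mods)
  if (!length(var)) {
    return(data.frame(label = "", nVarMods = 0L, varDelta = 0,
                      stringsAsFactors = FALSE))
  }
  nm <- vapply(var, function(m) m@name, character(1L))
  ntarg <- vapply(var, function(m) countTargets(sequence, m@targets), integer(1L))
  grid <- expand.grid(lapply(ntarg, function(n) 0:n), KEEP.OUT.ATTRS = FALSE)
  names(grid) <- nm
  total <- as.integer(rowSums(grid))
  o <- do.call(order, c(list(total), as.list(grid)))
  grid <- grid[o, , drop = FALSE]
  total <- total[o]
  delta <- as.numeric(as.matrix(grid) %*%
                        vapply(var, function(m) m@delta, numeric(1L)))
  label <- apply(grid, 1L, function(r) {
    on <- r > 0
    if (!any(on)) "" else paste(sprintf("%s:%d", nm[on], r[on]), collapse = ";")
  })
  out <- data.frame(grid, label = label, nVarMods = total, varDelta = delta,
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}
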