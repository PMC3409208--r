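---
title: "Peptide mass fingerprinting with pmfkit: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peptide mass fingerprinting with pmfkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmfkit)
```

# The measurement model

A tryptic in-gel digest analysed on a reflector-mode MALDI-TOF produces a
centroided list of singly protonated peptide masses. `pmfkit` models this
as four layers, each with an explicit inverse used at analysis time:

1. **Chemistry.** A peptide's neutral monoisotopic mass is the sum of its
   residue masses plus one water; the observed ion is MH⁺ = M + 1.00728 Da.
   Reflector mode resolves monoisotopic peaks, so only monoisotopic masses
   are implemented; average-mass (linear-mode) arithmetic is out of scope.
   The residue-mass table is a plain-text file
   (`extdata/monoisotopic_residue_masses.tsv`), auditable and
   overridable, and non-standard residues are supplied as `extra`
   masses rather than hard-coded — deliberately so for synthetic
   calibrant peptides whose published MH⁺ need not be derivable from
   standard residue masses (the shipped pentafluoro-Phe pentapeptide
   calibrant is therefore configured by its MH⁺ value only).
2. **Digestion.** Trypsin cuts after K/R, blocked by a following proline
   (the standard Keil specificity; both sets are configurable), and
   in-gel digests routinely leave missed cleavages, so every run of
   1..(maxMissed+1) consecutive fragments is a theoretical peptide
   (default maxMissed = 1). Fixed modifications
   (carbamidomethyl-Cys, +57.02146 Da, from iodoacetamide alkylation) are
   always applied; variable modifications (Met oxidation, +15.99491 Da)
   are enumerated **by count, not position**: PMF matching is mass-only,
   so positional isomers are indistinguishable and enumerating them would
   only duplicate masses.
3. **The mass axis.** Internal calibrants — matrix-spiked standards and
   trypsin autolysis peptides — have known MH⁺. The instrument's
   distortion is modelled as affine, `observed = (true − b)/a`, and the
   analysis-side correction `corrected = a·observed + b` is fitted by
   ordinary least squares over the matched calibrant pairs. The affine
   form is the package's own choice (two parameters are the most a
   handful of calibrants can support robustly); one calibrant degrades to
   a constant offset, and calibration is optional because merely
   *reporting* calibrant signal is also a legitimate use of the
   standards.
4. **Detection.** Peaks within tolerance of a theoretical mass are
   matches; everything else is either a calibrant or listed unmatched so
   that additional proteins in the spot can be recognised.

# Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| tolerance | 0.15 | Da | the conventional peptide-mass accuracy setting for this instrument class; a ppm mode is provided since relative tolerances suit recalibrated axes better |
| maxMissed | 1 | cleavages | in-gel digests are rarely complete; more than one missed cleavage mostly adds search space |
| fixed mods | Cys +57.02146 | Da | iodoacetamide alkylation is part of the sample preparation, so it is not optional per peptide |
| variable mods | Met +15.99491 | Da | oxidation is a sporadic artifact: each peptide may carry 0..nMet of them |
| calibrant window | 0.5 | Da | coarse pre-calibration search; must exceed the raw axis error but stay below typical peak spacing |
| minMissing | 2 | peptides | a single missing peptide is indistinguishable from one dropout event; two concordant absences are required for an N/C call |
| outlierFraction | 0.15 | — | tolerated fraction of evidence peptides inconsistent with the best cut (see below) |
| fold / p thresholds | 1.5 / 0.05 | — | the conventional spot-of-interest conjunction for silver-stained replicate gels |

# Matching, coverage and signal fractions

All (peak, peptide) pairs within tolerance are reported — ambiguity is
information — but statistics use only the **best match per peak**
(smallest |ppm|, ties resolved by fewer missed cleavages, fewer variable
modifications, lower mass, then lower start position so the result is
deterministic). Coverage is the size of the *union* of best-match spans
over the protein length: overlapping peptides never double-count. One
peptide may be best for several peaks (adjacent spots of the same
peptide); the span union makes this harmless.

Two signal fractions are reported because the natural denominator is
ambiguous: the calibrant fraction uses total intensity, while the matched
fraction uses non-calibrant intensity (the signal actually available to
the analyte). Degenerate inputs are defined, not fatal: an empty or
zero-intensity spectrum reports both fractions as 0 with a warning.

Every observed peak lands in exactly one report bin — calibrant,
best-matched, or unmatched — an invariant the tests enforce on simulated
spectra. Calibrant-assigned peaks are excluded from peptide matching: a
peak cannot be both an internal standard and analyte evidence.

# Truncation inference

A truncated isoform retains the peptides of its kept region and loses the
rest. Given the best-matched peptide sets of a reference (full-length)
and query spot, the package scans every candidate cut position `t` and
counts the evidence inconsistent with it: missing peptides not fully in
the removed region, retained peptides not fully in the kept region. The
terminus with the smaller minimal inconsistency is called when

* that minimum is at most `floor(outlierFraction · n)` of the `n`
  evidence peptides, and
* at least `minMissing` missing peptides are consistent with the cut.

The reported boundary interval is the full range of minimising cut
positions. With `outlierFraction = 0` this reduces exactly to the strict
textbook rule ("every missing peptide ends before the first retained
residue"), which is how the small hand-checked cases behave. The
allowance exists for two structural reasons, not as noise-fudging: a
missed-cleavage peptide that straddles the true cut is *always* missing
yet inconsistent with the strict rule, and detection dropout converts a
random ~10% of retained-region peptides into spurious missing evidence.
Missing evidence flanked by retained peptides on both sides yields
"internal"; anything else conflicting, including an empty retained set,
is "indeterminate". Gel-estimated molecular weight is never used as
evidence — it is not available to the matcher.

The simulator truncates **at tryptic cleavage boundaries** (whole
fragments removed). This is the generator's truncation model, chosen
because peptide-presence evidence cannot localise a cut below peptide
resolution: the boundary interval is a statement about fragment
boundaries, and a mid-fragment cut is representable only as the adjacent
boundary. Real proteolysis need not respect tryptic boundaries, so on
real data the interval should be read as "the cut lies within one
fragment of this range".

# The spot screen

Spot quantities (intensity × area, in ppm of total gel signal) across
two groups of replicate gels (four per group in the usual design) are
screened by the conjunction fold change > 1.5 AND p < 0.05. The test is a
two-sample two-sided t-test, by default equal-variance on log-transformed
quantities — gel spot quantities are closer to log-normal than normal,
and the log scale makes the screen invariant to global rescaling. Welch
and raw-scale variants are options; spots with nonpositive values fall
back to the raw scale with a flag. No multiple-testing correction is
applied by default, matching single-spot screening practice;
Benjamini–Hochberg is available as an option. Zero-signal spots are
excluded with a reason; spots with missing replicates are analysed on
their complete replicates and flagged.

`rankSpots()` is explicitly a *reconstruction* of composite spot
prioritisation — a weighted rank sum over mean intensity, |log fold| and
within-group coefficient of variation with configurable weights — not a
reproduction of any particular scoring system, whose weights are not
recoverable.

# The synthetic generators, and what passing tests show

`simulatePeakList()` emulates: digestion → per-peptide detection dropout
→ affine axis distortion applied in the *instrument frame* (so that
calibration fitting is exactly the inverse problem, well-posed by
construction) → multiplicative Gaussian ppm noise → calibrant peaks
(never dropped: standards are spiked in excess) → uniform contaminants →
log-normal intensities. Defaults: 5 ppm noise, 10% dropout, 5
contaminants in 800–3500 Da, log-normal intensities with meanlog
log(1000) and sdlog 1 — values a practitioner would call typical for
silver-stain-level loads; the emitted peptide state is the
fixed-modification base state, since oxidation is a search-side concern.

What the generators do **not** emulate: isotope envelopes and centroiding
error, chemical-noise baselines, intensity suppression between
co-desorbing peptides, correlated (non-affine) axis distortion, and
non-tryptic in-vivo truncation sites. Passing tests therefore demonstrate
the correctness of the algorithms under the stated measurement model, not
instrument-grade performance on real spectra.

Validation problem sizes (the package's own choices): matching equals a
brute-force oracle on 100 random instances; digestion laws on 1000 random
sequences; calibration recovery on 200 seeded replicates (5 ppm noise, 6
calibrants), asserting ≥95% of replicates within 5×10⁻⁵ on the slope and
0.02 Da on the intercept — with 6 calibrants the intercept's sampling SD
is ≈0.009 Da, so requiring *every* replicate inside 0.02 Da would fail by
chance alone; truncation recovery on 200 replicates each dropout-free
(≥95% exact) and at 10% dropout (≥90% terminus accuracy); spot-screen
type-I error on 200 null tables of 500 spots.

# Numerical and degenerate-input choices

* Residue coordinates are 1-based inclusive everywhere — files, reports,
  boundary intervals.
* `fitCalibration()` refuses zero pairs and identical observed masses
  (rank-deficient); the slope is constrained by a validity check to
  (0.9, 1.1), since anything larger is not a mass recalibration.
* Re-applying calibration to an already-calibrated list is an error, not
  a silent second transform.
* Tie-breaks (matching, calibrant assignment, ranking) are fully
  specified so identical inputs give identical outputs on any platform.
* The demonstration fixture is constructed (and verified in code) to have
  pairwise-distinct theoretical peptide masses, so "100% coverage in the
  noise-free limit" is a property of the algorithm, not luck: proteins
  with repeated short tryptic fragments can never reach 100% best-match
  coverage because isobaric spans cannot both be best for one peak.

# Known limitations

* No probabilistic identification score (Mowse-style), no decoy FDR:
  the report quantifies fit, it does not test significance.
* Charge +1 only; multiply charged species and isotope clusters are not
  modelled.
* The affine calibration cannot capture higher-order TOF distortions.
* Internal-deletion isoforms and PTM-driven spot shifts are outside the
  truncation model.
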