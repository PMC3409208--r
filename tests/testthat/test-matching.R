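test_that("a peak matches its peptide with ppm-scale accuracy reporting", {
  d <- digestProtein("AAKGGRCC", cleavageRule(maxMissed = 1), mods = list())
  m <- matchPeaks(peakList(289.187, 100), d, tolerance = 0.15, unit = "da")
  best <- m[m$isBest, ]
  expect_equal(best$sequence, "AAK")
  expect_equal(best$errorPpm, -0.073, tolerance = 0.05)
  expect_equal(best$errorDa, 289.187 - best$mh, tolerance = 1e-9)

  far <- matchPeaks(peakList(5000, 1), d)
  expect_equal(nrow(far), 0L)
})

test_that("ambiguous peaks list all candidates and flag one best", {
  # AAK (289.18702) and GGR (289.16190) are 0.025 Da apart: both in tolerance
  d <- digestProtein("AAKGGRCC", cleavageRule(maxMissed = 1), mods = list())
  m <- matchPeaks(peakList(289.175, 10), d, tolerance = 0.15)
  expect_equal(sort(m$sequence), c("AAK", "GGR"))
  expect_equal(sum(m$isBest), 1L)
  expect_equal(m$sequence[m$isBest],
               m$sequence[which.min(abs(m$errorPpm))])
})

test_that("exact mass ties fall through the missed-cleavage tie chain", {
  peptides <- data.frame(
    sequence = c("AGGK", "GAGK"), start = c(1L, 5L), end = c(4L, 8L),
    missedCleavages = c(1L, 0L), modState = "", nVarMods = 0L,
    neutralMass = peptideNeutralMass("AGGK"), stringsAsFactors = FALSE)
  peptides$mh <- peptides$neutralMass + 1.0072764666
  m <- matchPeaks(peakList(peptides$mh[1], 5), peptides, tolerance = 0.15)
  expect_equal(nrow(m), 2L)
  expect_equal(m$sequence[m$isBest], "GAGK")   # fewer missed cleavages
})

test_that("matching agrees with the brute-force oracle on random instances", {
  set.seed(202)
  for (i in 1:30) {
    prot <- randomProtein(sample(40:120, 1))
    d <- digestProtein(prot, cleavageRule(maxMissed = sample(0:1, 1)),
                       mods = if (i %% 2) defaultModifications() else list())
    nearby <- sample(d$mh, min(8, nrow(d))) +
      runif(min(8, nrow(d)), -0.3, 0.3)
    pk <- peakList(c(nearby, runif(5, 300, 3500)),
                   runif(length(nearby) + 5, 1, 100))
    unit <- if (i %% 3) "da" else "ppm"
    tol <- if (unit == "da") 0.15 else 100
    mine <- matchPeaks(pk, d, tolerance = tol, unit = unit)
    oracle <- bruteForceMatch(pk, d, tolerance = tol, unit = unit)
    if (is.null(oracle)) {
      expect_equal(nrow(mine), 0L)
    } else {
      expect_identical(matchKey(mine), matchKey(oracle))
      expect_identical(matchKey(mine[mine$isBest, ]),
                       matchKey(oracle[oracle$isBest, ]))
    }
  }
})

test_that("enlarging the tolerance never shrinks the matched set", {
  set.seed(31)
  prot <- randomProtein(100)
  d <- digestProtein(prot, mods = list())
  pk <- peakList(runif(40, 300, 3000), runif(40, 1, 10))
  prev <- -1
  for (tol in c(0.05, 0.15, 0.5, 1.0)) {
    m <- matchPeaks(pk, d, tolerance = tol)
    expect_gte(nrow(m), prev)
    prev <- nrow(m)
  }
})

test_that("coverage is the union, not the sum, of matched spans", {
  mk <- function(starts, ends) data.frame(
    peakIndex = seq_along(starts), start = starts, end = ends,
    isBest = rep(TRUE, length(starts)))
  expect_equal(coveragePercent(mk(integer(), integer()), 8), 0)
  expect_equal(coveragePercent(mk(c(1, 4), c(3, 6)), 8), 75)
  expect_equal(coveragePercent(mk(c(1, 4), c(6, 8)), 8), 100)
  # agrees with residue-enumeration oracle on random span sets
  set.seed(17)
  for (i in 1:20) {
    s <- sample(1:50, 6); e <- pmin(s + sample(0:20, 6, TRUE), 60)
    expect_equal(coveragePercent(mk(s, e), 60),
                 100 * spanUnionLength(s, e) / 60)
  }
})

test_that("signal fractions partition calibrant and matched intensity", {
  pk <- peakList(c(1000, 1500, 2000), c(200, 300, 500))
  matches <- data.frame(peakIndex = 2L, isBest = TRUE)
  cal <- data.frame(peakIndex = 1L)
  fr <- signalFractions(pk, matches, cal)
  expect_equal(fr[["calibrant"]], 0.2)
  expect_equal(fr[["matched"]], 0.375)

  all <- signalFractions(pk, data.frame(peakIndex = 1:3, isBest = TRUE), NULL)
  expect_equal(unname(all), c(1, 0))

  expect_warning(fr0 <- signalFractions(peakList(numeric()),
                                        matches[0, ], NULL), "zero")
  expect_equal(unname(fr0), c(0, 0))
})

test_that("reports partition every peak exactly once", {
  set.seed(77)
  for (i in 1:10) {
    cfg <- simConfig(seed = 1000 + i, proteinLength = 150)
    prot <- genProtein(cfg)
    sim <- simulatePeakList(prot, cfg)
    rep <- buildReport("P", prot, sim$peaks,
                       standards = defaultCalibrants())
    calIdx <- calibrantAssignments(rep)$peakIndex
    bestIdx <- unique(matchedPeaks(rep)$peakIndex[matchedPeaks(rep)$isBest])
    unIdx <- which(mz(sim$peaks) %in% unmatchedPeaks(rep)$mz)
    expect_equal(length(calIdx) + length(bestIdx) + nrow(unmatchedPeaks(rep)),
                 length(sim$peaks))
    expect_length(intersect(calIdx, bestIdx), 0L)
  }
})

test_that("a calibrants-only spectrum yields zero coverage, full calibrant signal", {
  stds <- defaultCalibrants()
  pk <- peakList(stds$theoreticalMh, rep(100, nrow(stds)))
  rep <- buildReport("P", "AAKGGRCC", pk, standards = stds)
  expect_equal(sequenceCoverage(rep), 0)
  expect_equal(signalFractionsOf(rep)[["calibrant"]], 1)
  expect_equal(nrow(unmatchedPeaks(rep)), 0L)
})

test_that("report defaults echo the standard search parameters", {
  rep <- buildReport("P", "AAKGGRCC", peakList(289.187, 5))
  p <- reportParameters(rep)
  expect_equal(p$tolerance, 0.15)
  expect_equal(p$unit, "da")
  expect_equal(p$maxMissed, 1L)
  expect_match(p$modifications[1], "Carbamidomethyl")
})

test_that("unmatched peaks are listed by descending intensity", {
  pk <- peakList(c(4000, 4100, 4200), c(5, 50, 20))
  rep <- buildReport("P", "AAKGGRCC", pk)
  expect_equal(unmatchedPeaks(rep)$intensity, c(50, 20, 5))
})
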