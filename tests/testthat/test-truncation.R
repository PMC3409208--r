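makeReport <- function(sequence, peaks, acc = "P1") {
  buildReport(acc, sequence, peaks, standards = NULL, mods = list())
}

test_that("identical reports give no missing peptides and a 'none' call", {
  d <- digestProtein("AAKGGRCCWWWKTTTR", mods = list())
  pk <- peakList(d$mh[d$missedCleavages == 0], rep(10, 4))
  r1 <- makeReport("AAKGGRCCWWWKTTTR", pk)
  r2 <- makeReport("AAKGGRCCWWWKTTTR", pk)
  sets <- compareMatchedSets(r1, r2)
  expect_equal(nrow(sets$missing), 0L)
  expect_equal(nrow(sets$retained), sum(r1@matches$isBest))
  call <- inferTruncation(sets$missing, sets$retained, 16)
  expect_equal(terminus(call), "none")
  expect_length(boundaryInterval(call), 0L)
})

test_that("peptides absent from the query are reported as missing, by span", {
  seqn <- "AAKGGRCCWWWKTTTR"
  d0 <- digestProtein(seqn, cleavageRule(maxMissed = 0), mods = list())
  full <- peakList(d0$mh, rep(10, nrow(d0)))
  partial <- peakList(d0$mh[-1], rep(10, nrow(d0) - 1L))
  sets <- compareMatchedSets(makeReport(seqn, full), makeReport(seqn, partial))
  expect_equal(sets$missing$start, 1L)
  expect_equal(sets$missing$end, 3L)
  expect_equal(nrow(sets$retained), nrow(d0) - 1L)
})

test_that("comparisons demand the same protein, parameters and evidence base", {
  seqn <- "AAKGGRCCWWWKTTTR"
  d <- digestProtein(seqn, mods = list())
  pk <- peakList(d$mh[1], 10)
  r1 <- makeReport(seqn, pk)
  expect_error(compareMatchedSets(r1, makeReport(seqn, pk, acc = "P2")),
               "different proteins")
  rTol <- buildReport("P1", seqn, pk, mods = list(), tolerance = 0.2)
  expect_error(compareMatchedSets(r1, rTol), "parameters")
  empty <- makeReport(seqn, peakList(9999, 1))
  expect_error(compareMatchedSets(empty, r1), "no matched peptides")
})

test_that("hand-built evidence reproduces the N-terminal boundary rule", {
  missing <- data.frame(start = c(1L, 10L), end = c(15L, 30L),
                        sequence = "", modState = "")
  retained <- data.frame(start = 48L, end = 60L, sequence = "", modState = "")
  call <- inferTruncation(missing, retained, 80)
  expect_equal(terminus(call), "N")
  expect_equal(boundaryInterval(call), c(31L, 48L))
})

test_that("missing peptides flanked by retained ones give an internal call", {
  missing <- data.frame(start = 60L, end = 75L, sequence = "", modState = "")
  retained <- data.frame(start = c(1L, 80L), end = c(50L, 100L),
                         sequence = "", modState = "")
  call <- inferTruncation(missing, retained, 100)
  expect_equal(terminus(call), "internal")
})

test_that("too little missing evidence is indeterminate, not a terminus call", {
  missing <- data.frame(start = 1L, end = 15L, sequence = "", modState = "")
  retained <- data.frame(start = c(48L, 70L), end = c(60L, 90L),
                         sequence = "", modState = "")
  expect_equal(terminus(inferTruncation(missing, retained, 100,
                                        minMissing = 2L)), "indeterminate")
  expect_equal(terminus(inferTruncation(missing, retained, 100,
                                        minMissing = 1L)), "N")
})

test_that("reversing the protein maps N-calls to C-calls exactly", {
  set.seed(55)
  for (i in 1:25) {
    L <- sample(80:200, 1)
    ns <- sample(2:6, 1); nr <- sample(2:6, 1)
    s <- sort(sample(seq_len(L - 10), ns + nr))
    e <- pmin(s + sample(5:15, ns + nr, TRUE), L)
    pick <- sample(ns + nr, ns)
    missing <- data.frame(start = s[pick], end = e[pick],
                          sequence = "", modState = "")
    retained <- data.frame(start = s[-pick], end = e[-pick],
                           sequence = "", modState = "")
    fwd <- inferTruncation(missing, retained, L)
    rev1 <- function(d) data.frame(start = L - d$end + 1L,
                                   end = L - d$start + 1L,
                                   sequence = "", modState = "")
    bwd <- inferTruncation(rev1(missing), rev1(retained), L)
    map <- c(N = "C", C = "N", internal = "internal", none = "none",
             indeterminate = "indeterminate")
    expect_equal(terminus(bwd), unname(map[terminus(fwd)]))
    if (terminus(fwd) %in% c("N", "C"))
      expect_equal(boundaryInterval(bwd),
                   rev(L - boundaryInterval(fwd) + 1L))
  }
})

test_that("simulated truncations are recovered dropout-free", {
  res <- lapply(1:30, truncationReplicate, dropout = 0, noisePpm = 0)
  correct <- vapply(res, `[[`, logical(1), "correct")
  contained <- vapply(res, `[[`, logical(1), "contained")
  expect_gte(mean(correct & contained), 28 / 30)
})
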