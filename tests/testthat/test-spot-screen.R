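quadTable <- function(a, b) {
  spotTable(rbind(c(a, b)), rep(c("A", "B"), each = length(a)), "s1")
}

test_that("clear two-fold differences are selected", {
  st <- quadTable(c(950, 1000, 1050, 1000), c(1950, 2000, 2050, 2000))
  res <- screenSpots(st)
  expect_equal(res$foldChange, 2, tolerance = 1e-9)
  expect_equal(res$direction, "B")
  expect_lt(res$pValue, 0.05)
  expect_true(res$selected)
})

test_that("identical replicate vectors yield fold 1 and no selection", {
  st <- quadTable(c(10, 11, 12, 13), c(10, 11, 12, 13))
  res <- screenSpots(st)
  expect_equal(res$foldChange, 1)
  expect_false(res$selected)
})

test_that("the fold gate blocks significant sub-threshold changes", {
  a <- c(99, 100, 101, 100)
  st <- quadTable(a, 1.4 * a)
  res <- screenSpots(st)
  expect_lt(res$pValue, 1e-4)
  expect_lt(res$foldChange, 1.5)
  expect_false(res$selected)
})

test_that("selection is exactly the fold AND p conjunction", {
  set.seed(88)
  sim <- genSpotTable(simConfig(seed = 88, nSpots = 200, nPlanted = 40,
                                spotCv = 0.3))
  res <- screenSpots(sim$spots)
  th <- attr(res, "thresholds")
  ok <- !res$excluded
  expect_identical(res$selected[ok],
                   res$foldChange[ok] > th$foldThreshold &
                     res$pUsed[ok] < th$pThreshold)
})

test_that("degenerate and incomplete spots are excluded or flagged", {
  q <- rbind(c(0, 0, 0, 0, 0, 0, 0, 0),
             c(10, 11, NA, 12, 30, 31, 29, NA),
             c(10, 11, 12, 13, 30, 31, 29, 28))
  st <- spotTable(q, rep(c("A", "B"), each = 4), c("zero", "gappy", "clean"))
  res <- screenSpots(st)
  expect_true(res$excluded[1])
  expect_match(res$reason[1], "zero signal")
  expect_false(res$excluded[2])
  expect_match(res$flags[2], "incomplete")
  expect_true(res$selected[3])
})

test_that("the screen is invariant to global rescaling", {
  set.seed(12)
  sim <- genSpotTable(simConfig(seed = 12, nSpots = 100, nPlanted = 10,
                                spotCv = 0.2))
  q <- SummarizedExperiment::assay(sim$spots, "quantity")
  grp <- SummarizedExperiment::colData(sim$spots)$group
  r1 <- screenSpots(sim$spots)
  r2 <- screenSpots(spotTable(q * 37.5, grp, rownames(q)))
  expect_equal(r1$foldChange, r2$foldChange, tolerance = 1e-9)
  expect_equal(r1$pValue, r2$pValue, tolerance = 1e-9)
  expect_identical(r1$selected, r2$selected)
})

test_that("null tables show the nominal false-positive rate", {
  ps <- unlist(lapply(1:20, function(s) {
    sim <- genSpotTable(simConfig(seed = 3000 + s, nSpots = 200,
                                  spotCv = 0.25))
    screenSpots(sim$spots)$pValue
  }))
  frac <- mean(ps < 0.05)
  expect_gte(frac, 0.03); expect_lte(frac, 0.07)
})

test_that("planted two-fold spots at CV 0.1 are nearly always selected", {
  hits <- unlist(lapply(1:10, function(s) {
    sim <- genSpotTable(simConfig(seed = 4000 + s, nSpots = 50,
                                  nPlanted = 50, spotCv = 0.1,
                                  plantedFold = 2))
    screenSpots(sim$spots)$selected
  }))
  expect_gte(mean(hits), 0.95)
})

test_that("ranking follows the configured composite", {
  res <- data.frame(spot = c("a", "b", "c"),
                    meanIntensity = c(100, 100, 5),
                    foldChange = c(2, 2, 4),
                    cvWithin = c(0.05, 0.20, 0.10),
                    selected = c(TRUE, TRUE, TRUE),
                    stringsAsFactors = FALSE)
  # identical except CV: lower CV ranks first under default weights
  r <- rankSpots(res[1:2, ])
  expect_equal(r$spot, c("a", "b"))
  # fold-only weights reproduce the fold ordering
  r2 <- rankSpots(res, weights = c(fold = 1))
  expect_equal(r2$spot[1], "c")
  # single selected spot is rank 1 under any weights
  r3 <- rankSpots(res[3, ], weights = c(intensity = 5))
  expect_equal(r3$rank, 1L)
})

test_that("spot tables validate their group design", {
  expect_error(spotTable(matrix(1:8, 2), rep("A", 4)), "two groups")
  expect_error(spotTable(matrix(1:6, 2), c("A", "A", "B")),
               "two replicates")
  expect_error(spotTable(matrix(c(-1, 1, 1, 1, 1, 1, 1, 1), 2),
                         rep(c("A", "B"), each = 2)), ">= 0")
})
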