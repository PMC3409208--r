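# Differential 2D-gel spot screen: fold-change + two-group test on
# replicate spot quantities, and the composite reconstruction ranking.

#' Construct a spot-quantity table
#'
#' @param quantities numeric matrix, spots x samples, in ppm of total gel
#'   intensity (intensity x area normalised).
#' @param groups group label per sample column (exactly two levels, at
#'   least two replicates each).
#' @param spotIds spot identifiers (default: rownames or spot0001...).
#' @return a \linkS4class{SpotTable}.
#' @export
spotTable <- function(quantities, groups, spotIds = NULL) {
  quantities <- as.matrix(quantities)
  if (is.null(spotIds))
    spotIds <- if (!is.null(rownames(quantities))) rownames(quantities)
               else sprintf("spot%04d", seq_len(nrow(quantities)))
  stopifnot(length(groups) == ncol(quantities),
            length(spotIds) == nrow(quantities))
  rownames(quantities) <- spotIds
  colnames(quantities) <- sprintf("%s_%d", groups,
                                  stats::ave(seq_along(groups), groups,
                                             FUN = seq_along))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(quantity = quantities),
    colData = S4Vectors::DataFrame(group = as.character(groups),
                                   row.names = colnames(quantities)))
  new("SpotTable", se)
}

#' Screen spots for differential intensity
#'
#' Per spot: fold change on group means (larger mean over smaller, with
#' the direction recorded) and a two-sample two-sided t-test, by default
#' equal-variance on log-transformed quantities. A spot is selected when
#' fold change exceeds `foldThreshold` AND the (optionally BH-adjusted)
#' p-value is below `pThreshold` — the conjunction used to pick spots of
#' interest at fold > 1.5, p < 0.05. No multiple-testing correction is
#' applied by default.
#'
#' Spots with zero mean in both groups are excluded with a reason; spots
#' with missing values are analysed on their complete replicates and
#' flagged; spots with nonpositive values fall back to a raw-scale test
#' when log transformation is requested.
#'
#' @param x a \linkS4class{SpotTable}.
#' @param foldThreshold fold-change gate (default 1.5).
#' @param pThreshold p-value gate (default 0.05).
#' @param logScale test on log quantities (default TRUE).
#' @param welch use the Welch unequal-variance test (default FALSE).
#' @param adjust "none" (default, mirroring single-spot screening) or
#'   "BH" for Benjamini-Hochberg; selection uses the adjusted value when
#'   adjustment is on.
#' @return data.frame, one row per spot: `spot`, `meanA`, `meanB`,
#'   `foldChange`, `direction`, `pValue`, `pUsed`, `selected`,
#'   `meanIntensity`, `cvWithin`, `excluded`, `reason`, `flags`; the
#'   thresholds are echoed in `attr(,"thresholds")`.
#' @export
screenSpots <- function(x, foldThreshold = 1.5, pThreshold = 0.05,
                        logScale = TRUE, welch = FALSE,
                        adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(is(x, "SpotTable"), foldThreshold > 0, pThreshold > 0)
  validObject(x)
  q <- SummarizedExperiment::assay(x, "quantity")
  grp <- SummarizedExperiment::colData(x)$group
  lv <- unique(grp)
  ia <- which(grp == lv[1L]); ib <- which(grp == lv[2L])
  n <- nrow(q)
  out <- data.frame(spot = rownames(q), meanA = NA_real_, meanB = NA_real_,
                    foldChange = NA_real_, direction = NA_character_,
                    pValue = NA_real_, pUsed = NA_real_, selected = FALSE,
                    meanIntensity = NA_real_, cvWithin = NA_real_,
                    excluded = FALSE, reason = "", flags = "",
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    va <- q[i, ia]; vb <- q[i, ib]
    flags <- character()
    if (anyNA(c(va, vb))) {
      va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
      flags <- c(flags, "incomplete-replicates")
    }
    if (length(va) < 2L || length(vb) < 2L) {
      out$excluded[i] <- TRUE; out$reason[i] <- "fewer than 2 replicates"
      next
    }
    ma <- mean(va); mb <- mean(vb)
    if (ma == 0 && mb == 0) {
      out$excluded[i] <- TRUE; out$reason[i] <- "zero signal in both groups"
      next
    }
    useLog <- logScale && all(c(va, vb) > 0)
    if (logScale && !useLog) flags <- c(flags, "raw-scale-test")
    ta <- if (useLog) log(va) else va
    tb <- if (useLog) log(vb) else vb
    p <- tryCatch(
      t.test(ta, tb, var.equal = !welch)$p.value,
      error = function(e) if (isTRUE(all.equal(mean(ta), mean(tb)))) 1 else 0)
    out$meanA[i] <- ma; out$meanB[i] <- mb
    out$foldChange[i] <- max(ma, mb) / min(ma, mb)
    out$direction[i] <- if (mb >= ma) lv[2L] else lv[1L]
    out$pValue[i] <- p
    out$meanIntensity[i] <- mean(c(va, vb))
    cv <- function(v) if (mean(v) > 0) sd(v) / mean(v) else NA_real_
    out$cvWithin[i] <- mean(c(cv(va), cv(vb)), na.rm = TRUE)
    out$flags[i] <- paste(flags, collapse = ";")
  }
  ok <- !out$excluded
  out$pUsed[ok] <- if (adjust == "BH") p.adjust(out$pValue[ok], "BH")
                   else out$pValue[ok]
  out$selected <- ok & !is.na(out$pUsed) &
    out$foldChange > foldThreshold & out$pUsed < pThreshold
  attr(out, "thresholds") <- list(foldThreshold = foldThreshold,
                                  pThreshold = pThreshold,
                                  logScale = logScale, welch = welch,
                                  adjust = adjust)
  out
}

#' Rank selected spots by a composite score
#'
#' A reconstruction of spot prioritisation by intensity, between-group
#' ratio and within-replicate consistency: the weighted sum of the ranks
#' of mean intensity (high is good), |log fold change| (large is good)
#' and within-group coefficient of variation (small is good). The weights
#' are configurable and the composite is explicitly a reconstruction, not
#' a reproduction of any published scoring. Ties break by spot id.
#'
#' @param result output of [screenSpots()].
#' @param weights named numeric: `intensity`, `fold`, `consistency`.
#' @return the selected rows of `result`, ordered, with a `rank` column.
#' @export
rankSpots <- function(result,
                      weights = c(intensity = 1, fold = 1, consistency = 1)) {
  w <- c(intensity = 0, fold = 0, consistency = 0)
  w[names(weights)] <- weights
  sel <- result[result$selected, , drop = FALSE]
  if (!nrow(sel)) return(cbind(sel, rank = integer()))
  score <- w[["intensity"]] * rank(-sel$meanIntensity, ties.method = "average") +
    w[["fold"]] * rank(-abs(log(sel$foldChange)), ties.method = "average") +
    w[["consistency"]] * rank(sel$cvWithin, ties.method = "average")
  o <- order(score, sel$spot)
  sel <- sel[o, , drop = FALSE]
  sel$rank <- seq_len(nrow(sel))
  rownames(sel) <- NULL
  sel
}

setMethod("show", "SpotTable", function(object) {
  cd <- SummarizedExperiment::colData(object)
  tab <- table(cd$group)
  cat(sprintf("SpotTable: %d spots x %d samples (%s)\n", nrow(object),
              ncol(object),
              paste(sprintf("%s n=%d", names(tab), tab), collapse = ", ")))
})
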