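# Nucleotide-level evaluation of island predictions and table-style
# summaries of an island set.

#' Nucleotide-level confusion counts
#'
#' Labels every base of the sequence as island/non-island under the
#' predicted and reference sets and counts TP (in both), FP (predicted
#' only), FN (reference only) and TN (neither). Interval arithmetic is done
#' with `IRanges`.
#'
#' @param predicted,reference [IslandSet-class] objects on the same
#'   sequence.
#' @param seqLength evaluated sequence length in bp.
#' @return Named numeric vector `c(TP, FP, TN, FN)` summing to `seqLength`.
#' @examples
#' p <- IslandSet("s", 150, 350); r <- IslandSet("s", 100, 300)
#' confusionCounts(p, r, 1000)
#' @export
confusionCounts <- function(predicted, reference, seqLength) {
  if (length(predicted) > 0L && length(reference) > 0L &&
      predicted@seqId != reference@seqId)
    stop(sprintf("sequence id mismatch: '%s' vs '%s'",
                 predicted@seqId, reference@seqId))
  toRanges <- function(x) {
    if (length(x) > 0L && (min(x@start) < 0L || max(x@end) > seqLength))
      stop("islands extend beyond [0, seqLength)")
    IRanges::reduce(IRanges::IRanges(start = x@start + 1L, end = x@end))
  }
  p <- toRanges(predicted); r <- toRanges(reference)
  tp <- sum(IRanges::width(IRanges::intersect(p, r)))
  fp <- sum(IRanges::width(IRanges::setdiff(p, r)))
  fn <- sum(IRanges::width(IRanges::setdiff(r, p)))
  c(TP = tp, FP = fp, TN = seqLength - tp - fp - fn, FN = fn)
}

#' Prediction metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity (true-negative rate)
#' `TN/(TN+FP)`, positive predictive value `TP/(TP+FP)`, accuracy
#' `(TP+TN)/total`, and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. Specificity is
#' reported as the true-negative rate (the dominant usage in island
#' comparisons) with PPV alongside, so either reading of "SP" is available.
#' A metric whose denominator is zero is undefined and reported as `NA`.
#'
#' @param counts named vector with elements `TP`, `FP`, `TN`, `FN` (as
#'   returned by [confusionCounts()]).
#' @return Named numeric vector `c(SN, SP, PPV, ACC, CC)`.
#' @export
predictionMetrics <- function(counts) {
  tp <- as.numeric(counts[["TP"]]); fp <- as.numeric(counts[["FP"]])
  tn <- as.numeric(counts[["TN"]]); fn <- as.numeric(counts[["FN"]])
  total <- tp + fp + tn + fn
  if (total <= 0) stop("confusion counts sum to zero")
  safeDiv <- function(num, den) if (den > 0) num / den else NA_real_
  ccDen <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  c(SN = safeDiv(tp, tp + fn),
    SP = safeDiv(tn, tn + fp),
    PPV = safeDiv(tp, tp + fp),
    ACC = (tp + tn) / total,
    CC = if (ccDen > 0) (tp * tn - fp * fn) / ccDen else NA_real_)
}

#' Coverage percentage from a total island length
#'
#' `100 * totalLength / seqLength`, the "island coverage" figure of
#' chromosome-scale benchmark tables.
#'
#' @param totalLength summed island length in bp.
#' @param seqLength sequence (chromosome) length in bp.
#' @return Coverage in percent (unrounded).
#' @export
coveragePercent <- function(totalLength, seqLength) {
  100 * totalLength / seqLength
}

#' Mean island length from a total and a count
#'
#' @param totalLength summed island length in bp.
#' @param nIslands number of islands.
#' @return Mean length in bp (unrounded).
#' @export
meanIslandLength <- function(totalLength, nIslands) {
  totalLength / nIslands
}

#' Round half away from zero
#'
#' Benchmark tables round half-up (357.5 prints as 358), unlike R's
#' banker's rounding; used when comparing computed summaries against
#' printed tables.
#'
#' @param x numeric vector.
#' @param digits decimal places, default 0.
#' @return Rounded vector.
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summarize an island set
#'
#' The summary block used in chromosome-scale comparisons: island count,
#' total length, coverage of the sequence, length mean/min/max, and the
#' mean and population standard deviation (divisor `n`) of the per-island
#' GC% and O/E ratio, recomputed from the index.
#'
#' @param islands an [IslandSet-class].
#' @param index the [CompositionIndex-class] of the underlying sequence.
#' @return A one-row data.frame with columns `n_islands`, `total_length`,
#'   `coverage_percent`, `length_mean`, `length_min`, `length_max`,
#'   `gc_mean`, `gc_sd`, `oe_mean`, `oe_sd`.
#' @export
summarizeIslands <- function(islands, index) {
  k <- length(islands)
  if (k == 0L)
    return(data.frame(n_islands = 0L, total_length = 0,
                      coverage_percent = 0, length_mean = NA_real_,
                      length_min = NA_real_, length_max = NA_real_,
                      gc_mean = NA_real_, gc_sd = NA_real_,
                      oe_mean = NA_real_, oe_sd = NA_real_))
  len <- islands@end - islands@start
  gc <- gcContent(index, islands@start, islands@end)
  oe <- oeRatio(index, islands@start, islands@end)
  popSd <- function(v) sqrt(mean((v - mean(v))^2))
  data.frame(n_islands = k, total_length = sum(len),
             coverage_percent = coveragePercent(sum(len), index@n),
             length_mean = mean(len), length_min = min(len),
             length_max = max(len),
             gc_mean = mean(gc), gc_sd = popSd(gc),
             oe_mean = mean(oe), oe_sd = popSd(oe))
}
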