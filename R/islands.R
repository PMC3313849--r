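# Deterministic island machinery: criteria test, sliding-window
# find/extend/trim extraction, gap merging, assembly-gap splitting, and the
# exhaustive oracle used to validate the extractor on short sequences.

#' Test an interval against island criteria
#'
#' TRUE iff the interval length, GC content and O/E ratio are all at least
#' the corresponding thresholds (inclusive comparisons).
#'
#' @param index a [CompositionIndex-class].
#' @param start,end 0-based half-open interval bounds (vectors allowed).
#' @param criteria an [IslandCriteria-class].
#' @return Logical vector.
#' @export
meetsCriteria <- function(index, start, end, criteria) {
  (end - start) >= criteria@minLength &
    gcContent(index, start, end) >= criteria@minGC &
    oeRatio(index, start, end) >= criteria@minOE
}

# GC and O/E thresholds only (length is checked by the callers after
# trimming, as the extractor may legitimately hold sub-threshold intervals
# mid-flight).
.meetsThresholds <- function(index, start, end, criteria) {
  gcContent(index, start, end) >= criteria@minGC &
    oeRatio(index, start, end) >= criteria@minOE
}

#' Trim an interval to the composition thresholds
#'
#' Removes one base at a time from whichever end most increases the
#' limiting criterion margin `min(gc / minGC, oe / minOE)` (ties trim the
#' left end), until the whole interval meets the GC and O/E thresholds or
#' shrinks below `minLength`.
#'
#' @inheritParams meetsCriteria
#' @param start,end interval to trim, 0-based half-open.
#' @return Integer `c(start, end)` of the trimmed interval, or `NULL` when
#'   no qualifying interval of at least `minLength` bp remains.
#' @export
trimIsland <- function(index, start, end, criteria) {
  stopifnot(start < end)
  margin <- function(s, e) {
    min(gcContent(index, s, e) / criteria@minGC,
        oeRatio(index, s, e) / criteria@minOE)
  }
  repeat {
    if (.meetsThresholds(index, start, end, criteria))
      return(c(as.integer(start), as.integer(end)))
    if (end - start <= criteria@minLength) return(NULL)
    if (margin(start + 1L, end) >= margin(start, end - 1L))
      start <- start + 1L
    else
      end <- end - 1L
  }
}

# Maximal runs of >= minRun consecutive invalid (N-like) bases, as a
# two-column matrix of 0-based half-open intervals.
.nRuns <- function(index, minRun = 50L) {
  validPerBase <- diff(index@prefValid)
  r <- rle(validPerBase == 0)
  ends <- cumsum(r$lengths)
  keep <- r$values & r$lengths >= minRun
  cbind(start = (ends - r$lengths)[keep], end = ends[keep])
}

# TRUE when [start, end) contains an assembly-gap run of >= minRun Ns.
.containsNRun <- function(index, start, end, minRun = 50L) {
  runs <- .nRuns(index, minRun)
  if (nrow(runs) == 0L) return(FALSE)
  any(runs[, 1] < end & runs[, 2] > start &
        pmin(runs[, 2], end) - pmax(runs[, 1], start) >= minRun)
}

# Split islands at runs of >= minRun consecutive ambiguous bases and keep
# the fragments that still satisfy all criteria.
.splitAtNRuns <- function(starts, ends, index, criteria, minRun = 50L) {
  runs <- .nRuns(index, minRun)
  if (nrow(runs) == 0L || length(starts) == 0L)
    return(list(start = starts, end = ends))
  outS <- integer(0); outE <- integer(0)
  for (i in seq_along(starts)) {
    pieces <- cbind(starts[i], ends[i])
    for (j in seq_len(nrow(runs))) {
      nxt <- NULL
      for (k in seq_len(nrow(pieces))) {
        s <- pieces[k, 1]; e <- pieces[k, 2]
        if (runs[j, 1] < e && runs[j, 2] > s) {
          if (runs[j, 1] > s) nxt <- rbind(nxt, c(s, runs[j, 1]))
          if (runs[j, 2] < e) nxt <- rbind(nxt, c(runs[j, 2], e))
        } else nxt <- rbind(nxt, c(s, e))
      }
      pieces <- if (is.null(nxt)) matrix(integer(0), 0, 2) else nxt
      if (nrow(pieces) == 0L) break
    }
    for (k in seq_len(nrow(pieces))) {
      s <- pieces[k, 1]; e <- pieces[k, 2]
      if (e - s >= criteria@minLength && meetsCriteria(index, s, e, criteria)) {
        outS <- c(outS, s); outE <- c(outE, e)
      }
    }
  }
  o <- order(outS)
  list(start = as.integer(outS[o]), end = as.integer(outE[o]))
}

#' Merge nearby islands
#'
#' Fuses adjacent islands separated by fewer than `mergeGap` bp whenever the
#' spanning interval still meets all criteria; a merged island is
#' immediately eligible for further merging, and passes are repeated until
#' nothing changes (so the operation is idempotent). A merge is refused when
#' the gap contains an assembly-gap run of 50 or more ambiguous bases, which
#' keeps islands split at such runs from being silently re-bridged.
#'
#' @param islands an [IslandSet-class], sorted and non-overlapping.
#' @param index the [CompositionIndex-class] of the underlying sequence.
#' @param criteria an [IslandCriteria-class].
#' @return An [IslandSet-class] with statistics recomputed from `index`.
#' @export
mergeIslands <- function(islands, index, criteria) {
  starts <- islands@start; ends <- islands@end
  repeat {
    if (length(starts) < 2L) break
    newS <- starts[1]; newE <- ends[1]
    outS <- integer(0); outE <- integer(0)
    for (i in 2:length(starts)) {
      gap <- starts[i] - newE
      if (gap < criteria@mergeGap &&
          !.containsNRun(index, newE, max(starts[i], newE + 1L)) &&
          meetsCriteria(index, newS, ends[i], criteria)) {
        newE <- ends[i]
      } else {
        outS <- c(outS, newS); outE <- c(outE, newE)
        newS <- starts[i]; newE <- ends[i]
      }
    }
    outS <- c(outS, newS); outE <- c(outE, newE)
    changed <- length(outS) != length(starts)
    starts <- outS; ends <- outE
    if (!changed) break
  }
  IslandSet(islands@seqId, starts, ends, index = index,
            provenance = islands@provenance)
}

#' Sliding-window island extraction
#'
#' Scans a `window`-bp window in steps of `step` bp. When a window meets the
#' GC and O/E thresholds the candidate is extended rightward one whole
#' window at a time while each added window still meets them; the extended
#' interval is then trimmed base-by-base (see [trimIsland()]) until the
#' whole interval meets the thresholds, kept if its final length reaches
#' `minLength`, and scanning resumes after it. Islands containing a run of
#' 50 or more ambiguous bases are split at the run, and the surviving
#' islands are gap-merged with [mergeIslands()].
#'
#' @param index a [CompositionIndex-class].
#' @param criteria an [IslandCriteria-class].
#' @param window scan window in bp, default 200.
#' @param step scan step in bp, default 1.
#' @return An [IslandSet-class]; empty (with a warning) when the sequence is
#'   shorter than `window`.
#' @export
slidingWindowSearch <- function(index, criteria, window = 200, step = 1) {
  window <- as.integer(window); step <- as.integer(step)
  n <- index@n
  prov <- sprintf("sliding window=%d step=%d criteria=%g/%g/%g/%g",
                  window, step, criteria@minLength, criteria@minGC,
                  criteria@minOE, criteria@mergeGap)
  if (window > n) {
    warning("sequence shorter than the scan window; no islands")
    return(IslandSet(index@seqId, provenance = prov))
  }
  wStarts <- 0:(n - window)
  wMeets <- .meetsThresholds(index, wStarts, wStarts + window, criteria)
  starts <- integer(0); ends <- integer(0)
  s <- 0L
  while (s <= n - window) {
    if (!wMeets[s + 1L]) { s <- s + step; next }
    e <- s + window
    while (e + window <= n && wMeets[e + 1L]) e <- e + window
    tr <- trimIsland(index, s, e, criteria)
    if (!is.null(tr) && tr[2] - tr[1] >= criteria@minLength) {
      starts <- c(starts, tr[1]); ends <- c(ends, tr[2])
      s <- tr[2]
    } else {
      # no qualifying interval of sufficient length in the scanned extent
      s <- e
    }
  }
  sp <- .splitAtNRuns(starts, ends, index, criteria)
  mergeIslands(IslandSet(index@seqId, sp$start, sp$end, index = index,
                         provenance = prov),
               index, criteria)
}

#' Exhaustive interval oracle
#'
#' Considers every interval of the sequence and greedily reports, left to
#' right, the longest qualifying interval at each leftmost qualifying start,
#' continuing after it — an O(n^2) reference against which the windowed
#' extractor is validated. Refuses sequences longer than 10 kb.
#'
#' @inheritParams slidingWindowSearch
#' @return An [IslandSet-class] of non-overlapping qualifying intervals.
#' @export
bruteForceOracle <- function(index, criteria) {
  if (index@n > 10000L)
    stop("bruteForceOracle is O(n^2) and limited to sequences <= 10 kb")
  m <- .cpp_oracle_scan(index@prefC, index@prefG, index@prefCpG,
                        index@prefValid, index@n,
                        as.integer(criteria@minLength),
                        criteria@minGC, criteria@minOE)
  IslandSet(index@seqId, m[, 1], m[, 2], index = index,
            provenance = "brute-force oracle")
}
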