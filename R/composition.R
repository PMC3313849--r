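# Interval composition statistics on prefix sums. All coordinates are
# 0-based half-open; counts exclude ambiguous bases (anything outside
# A/C/G/T counts as N and breaks CpG dinucleotides).

#' Build the prefix-count composition index
#'
#' One linear pass over the sequence yields prefix counts of C, G, valid
#' (A/C/G/T) bases and CpG dinucleotides, after which any interval's GC
#' content and observed/expected CpG ratio are O(1) queries.
#'
#' @param seq a [GenomeSequence-class] (or a plain character string, in
#'   which case `seqId` names it).
#' @param seqId identifier used when `seq` is a bare string.
#' @return A [CompositionIndex-class].
#' @examples
#' idx <- buildIndex(GenomeSequence("s", "ACGT"))
#' gcContent(idx, 0, 4)
#' @export
buildIndex <- function(seq, seqId = "seq") {
  if (is(seq, "GenomeSequence")) {
    residues <- seq@residues
    seqId <- seq@id
  } else {
    residues <- toupper(as.character(seq))
  }
  n <- nchar(residues)
  ch <- charToRaw(residues)
  isC <- ch == charToRaw("C")
  isG <- ch == charToRaw("G")
  isValid <- isC | isG | ch == charToRaw("A") | ch == charToRaw("T")
  # cpg[p] : a CpG dinucleotide starts at 0-based position p (p = 0..n-2)
  cpg <- if (n >= 2L) isC[-n] & isG[-1L] else logical(0)
  # prefCpG[k] = number of CpG starts at positions < k - 1 (see class docs)
  prefCpG <- if (n >= 2L) c(0, cumsum(cpg), sum(cpg)) else numeric(n + 1L)
  new("CompositionIndex", seqId = seqId, n = as.integer(n),
      prefC = c(0, cumsum(isC)), prefG = c(0, cumsum(isG)),
      prefCpG = prefCpG, prefValid = c(0, cumsum(isValid)))
}

.checkInterval <- function(index, start, end) {
  if (length(start) != length(end))
    stop("'start' and 'end' must have equal lengths")
  if (any(start < 0) || any(end > index@n) || any(start >= end))
    stop("intervals must satisfy 0 <= start < end <= n")
}

#' Raw interval composition counts
#'
#' @param index a [CompositionIndex-class].
#' @param start,end interval bounds (vectors allowed), 0-based half-open.
#' @return A data.frame with columns `c`, `g`, `cpg`, `valid`, `len`; `cpg`
#'   counts only dinucleotides fully inside the interval.
#' @export
intervalCounts <- function(index, start, end) {
  .checkInterval(index, start, end)
  nC <- index@prefC[end + 1L] - index@prefC[start + 1L]
  nG <- index@prefG[end + 1L] - index@prefG[start + 1L]
  nValid <- index@prefValid[end + 1L] - index@prefValid[start + 1L]
  nCpG <- ifelse(end - start >= 2L,
                 index@prefCpG[pmax(end, start + 1L)] -
                   index@prefCpG[start + 1L],
                 0)
  data.frame(c = nC, g = nG, cpg = nCpG, valid = nValid, len = end - start)
}

#' GC content of an interval
#'
#' `100 * (N_C + N_G) / L_valid`, where `L_valid` is the number of
#' unambiguous bases in the interval. Returns 0 when the interval contains
#' no valid bases.
#'
#' @inheritParams intervalCounts
#' @return GC percentage(s) in `[0, 100]`.
#' @examples
#' gcContent(buildIndex("ATGC"), 0, 4)  # 50
#' @export
gcContent <- function(index, start, end) {
  cnt <- intervalCounts(index, start, end)
  ifelse(cnt$valid > 0, 100 * (cnt$c + cnt$g) / cnt$valid, 0)
}

#' Observed/expected CpG ratio of an interval
#'
#' The classical composition statistic `(N_CpG * L_valid) / (N_C * N_G)`.
#' Intervals with no C or no G return 0 rather than failing, so search code
#' can score arbitrary candidates: such regions can never satisfy an O/E
#' threshold anyway.
#'
#' @inheritParams intervalCounts
#' @return O/E ratio(s), `>= 0`.
#' @examples
#' oeRatio(buildIndex("CGCGCGCG"), 0, 8)  # 2
#' @export
oeRatio <- function(index, start, end) {
  cnt <- intervalCounts(index, start, end)
  ifelse(cnt$c > 0 & cnt$g > 0, cnt$cpg * cnt$valid / (cnt$c * cnt$g), 0)
}

#' Windowed statistic track
#'
#' Cuts the sequence into fixed, non-overlapping bins (`[0, w)`,
#' `[w, 2w)`, ..., last bin truncated at the sequence end) and evaluates the
#' statistic in each bin — the binning used by GC%/O-E chart displays.
#'
#' @param index a [CompositionIndex-class].
#' @param statistic `"gc_percent"` or `"oe_ratio"`.
#' @param window bin width in bp, default 50.
#' @return A [Track-class].
#' @export
windowedTrack <- function(index, statistic = c("gc_percent", "oe_ratio"),
                          window = 50) {
  statistic <- match.arg(statistic)
  if (window < 2) stop("'window' must be >= 2")
  n <- index@n
  if (n == 0L)
    return(new("Track", seqId = index@seqId, start = integer(0),
               end = integer(0), value = numeric(0), statistic = statistic))
  starts <- as.integer(seq.int(0L, n - 1L, by = window))
  ends <- pmin(starts + as.integer(window), n)
  value <- if (statistic == "gc_percent") gcContent(index, starts, ends)
           else oeRatio(index, starts, ends)
  new("Track", seqId = index@seqId, start = starts, end = ends,
      value = as.numeric(value), statistic = statistic)
}

#' Positions of CpG dinucleotides
#'
#' @param seq a [GenomeSequence-class] or character string.
#' @return Sorted 0-based start positions `p` with a literal `C` at `p` and
#'   `G` at `p + 1`.
#' @examples
#' cpgPositions("ACGCGT")  # 1 3
#' @export
cpgPositions <- function(seq) {
  residues <- if (is(seq, "GenomeSequence")) seq@residues
              else toupper(as.character(seq))
  hits <- gregexpr("CG", residues, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L
}
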