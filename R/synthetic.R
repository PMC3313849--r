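# Seeded synthetic genomes: CpG-depleted background with planted CpG-rich
# islands and exact ground-truth coordinates.

# Transition matrix of a first-order chain over (A, C, G, T) whose
# stationary distribution is exactly the target base composition and whose
# C->G probability realizes the target O/E ratio. Row C is
# P(G|C) = oe * pG with the remainder spread over A/C/T proportionally to
# their stationary probabilities; rows A/G/T are the unique shared row that
# restores the stationary composition (plain i.i.d. rows would drag the
# realized GC% below target).
.markovTransition <- function(gc, oeTarget) {
  pC <- gc / 200; pG <- pC
  pA <- (1 - gc / 100) / 2; pT <- pA
  p <- c(A = pA, C = pC, G = pG, T = pT)
  q <- oeTarget * pG
  if (q > 1) stop("infeasible targets: oe * gc/200 must be <= 1")
  rowC <- c(A = (1 - q) * pA / (1 - pG), C = (1 - q) * pC / (1 - pG),
            G = q, T = (1 - q) * pT / (1 - pG))
  rowOther <- (p - pC * rowC) / (1 - pC)
  if (any(rowOther < 0) || any(rowC < 0))
    stop("infeasible targets: transition probabilities would be negative")
  trans <- rbind(A = rowOther, C = rowC, G = rowOther, T = rowOther)
  list(trans = trans, init = p)
}

#' Sample a DNA string from a first-order Markov chain
#'
#' Generates a sequence whose stationary base composition is exactly
#' `pC = pG = gc/200`, `pA = pT = (1 - gc/100)/2` and whose CpG
#' observed/expected ratio converges to `oeTarget` (under this model
#' `O/E = P(G|C)/pG`). `oeTarget = 1` reduces to the i.i.d. model and
#' `oeTarget = 0` forbids CpG dinucleotides entirely. Uses R's RNG, so wrap
#' in `set.seed()` for reproducibility.
#'
#' @param length sequence length in bp.
#' @param gc target GC content in percent, in (0, 100).
#' @param oeTarget target O/E ratio; must satisfy `oeTarget * gc/200 <= 1`.
#' @return A character string over A/C/G/T.
#' @examples
#' set.seed(1)
#' cpgPositions(markovSequence(100, 50, 0))  # none
#' @export
markovSequence <- function(length, gc, oeTarget) {
  if (gc <= 0 || gc >= 100) stop("'gc' must be in (0, 100)")
  if (oeTarget < 0) stop("'oeTarget' must be >= 0")
  m <- .markovTransition(gc, oeTarget)
  codes <- .cpp_markov_chain(as.integer(length), m$trans, m$init)
  paste(c("A", "C", "G", "T")[codes], collapse = "")
}

#' Generate a synthetic genome with planted islands
#'
#' Draws island lengths uniformly from the configured range, places the
#' islands uniformly at random subject to the minimum gap (rejection
#' sampling, up to 1000 attempts), and fills island and background segments
#' from their respective Markov models. The chain restarts at every
#' boundary, so the truth coordinates are exact by construction; only the
#' junction dinucleotide is left to chance.
#'
#' @param spec a [SyntheticGenomeSpec-class]; `spec@seed` must be set.
#' @return A list with `sequence` (a [GenomeSequence-class]) and `truth`
#'   (an [IslandSet-class] of the planted intervals, statistics measured on
#'   the realized sequence).
#' @export
generateGenome <- function(spec) {
  validObject(spec)
  if (is.na(spec@seed))
    stop("the generator requires an explicit seed in the spec")
  set.seed(as.integer(spec@seed))
  n <- spec@length
  k <- spec@nIslands
  if (k == 0L) {
    res <- markovSequence(n, spec@backgroundGc, spec@backgroundOe)
    gs <- GenomeSequence(sprintf("synthetic_seed%d", as.integer(spec@seed)),
                         res)
    return(list(sequence = gs,
                truth = IslandSet(gs@id, provenance = "planted truth")))
  }
  lens <- sample.int(spec@islandLengthRange[2] - spec@islandLengthRange[1] + 1L,
                     k, replace = TRUE) + spec@islandLengthRange[1] - 1L
  starts <- NULL
  for (attempt in seq_len(1000L)) {
    cand <- floor(stats::runif(k, 0, n - lens + 1))
    ord <- order(cand)
    s <- cand[ord]; l <- lens[ord]
    if (k == 1L || all(s[-1L] - (s[-k] + l[-k]) >= spec@minIslandGap)) {
      starts <- as.integer(s); lens <- as.integer(l)
      break
    }
  }
  if (is.null(starts))
    stop("could not place islands after 1000 attempts; ",
         "reduce 'nIslands' or the island lengths")
  ends <- starts + lens
  pieces <- character(2L * k + 1L)
  prev <- 0L
  for (i in seq_len(k)) {
    if (starts[i] > prev)
      pieces[2L * i - 1L] <- markovSequence(starts[i] - prev,
                                            spec@backgroundGc,
                                            spec@backgroundOe)
    pieces[2L * i] <- markovSequence(lens[i], spec@islandGc, spec@islandOe)
    prev <- ends[i]
  }
  if (prev < n)
    pieces[2L * k + 1L] <- markovSequence(n - prev, spec@backgroundGc,
                                          spec@backgroundOe)
  gs <- GenomeSequence(sprintf("synthetic_seed%d", as.integer(spec@seed)),
                       paste(pieces, collapse = ""))
  idx <- buildIndex(gs)
  list(sequence = gs,
       truth = IslandSet(gs@id, starts, ends, index = idx,
                         provenance = sprintf("planted truth seed=%d",
                                              as.integer(spec@seed))))
}
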