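#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib CpGscout, .registration = TRUE
NULL

# IUPAC nucleotide codes accepted on input; everything outside ACGT is
# treated as N by the composition layer.
.IUPAC_CODES <- c("A", "C", "G", "T", "N",
                  "M", "R", "W", "S", "Y", "K", "V", "H", "D", "B")

#' DNA sequence with a validated alphabet
#'
#' A named DNA string over the IUPAC alphabet. Residues are uppercased on
#' construction; soft-masked (lowercase) input is recorded in the
#' `softMasked` flag. All coordinates used by the package are 0-based
#' half-open.
#'
#' @slot id record identifier.
#' @slot residues uppercase residue string.
#' @slot softMasked `TRUE` if the original input contained lowercase
#'   (soft-masked) residues.
#'
#' @exportClass GenomeSequence
setClass("GenomeSequence",
         representation(id = "character",
                        residues = "character",
                        softMasked = "logical"),
         prototype(softMasked = FALSE))

setValidity("GenomeSequence", function(object) {
  if (length(object@id) != 1L || !nzchar(object@id))
    return("'id' must be a single non-empty string")
  if (length(object@residues) != 1L)
    return("'residues' must be a single string")
  bad <- regexpr(sprintf("[^%s]", paste(.IUPAC_CODES, collapse = "")),
                 object@residues)
  if (bad > 0L)
    return(sprintf("invalid character '%s' at offset %d",
                   substr(object@residues, bad, bad), bad - 1L))
  TRUE
})

#' Construct a GenomeSequence
#'
#' @param id record identifier.
#' @param residues DNA string; lowercase is uppercased and flagged as
#'   soft-masked.
#' @param softMasked override for the soft-mask flag; by default it is set
#'   when `residues` contains lowercase letters.
#' @return A [GenomeSequence-class] object.
#' @examples
#' gs <- GenomeSequence("s", "acgtACGT")
#' length(gs)
#' @export
GenomeSequence <- function(id, residues, softMasked = NA) {
  if (is.na(softMasked))
    softMasked <- grepl("[a-z]", residues)
  new("GenomeSequence", id = as.character(id),
      residues = toupper(residues), softMasked = softMasked)
}

#' @describeIn GenomeSequence sequence length in bp.
#' @param x a `GenomeSequence`.
#' @export
setMethod("length", "GenomeSequence", function(x) nchar(x@residues))

setMethod("show", "GenomeSequence", function(object) {
  n <- length(object)
  cat(sprintf("GenomeSequence '%s': %d bp%s\n  %s%s\n",
              object@id, n,
              if (object@softMasked) " (soft-masked input)" else "",
              substr(object@residues, 1, min(n, 60)),
              if (n > 60) "..." else ""))
})

#' Prefix-count composition index
#'
#' Prefix sums of C, G, CpG-dinucleotide and valid (unambiguous A/C/G/T)
#' base counts, giving O(1) composition statistics for any interval.
#' `prefC[i + 1]` is the number of C in the first `i` bases; `prefCpG[i + 1]`
#' counts CpG dinucleotides starting strictly before position `i`
#' (0-based). A CpG is counted only when a literal C is immediately
#' followed by a literal G, so any ambiguity code breaks the dinucleotide.
#'
#' @slot seqId identifier of the indexed sequence.
#' @slot n sequence length in bp.
#' @slot prefC,prefG,prefCpG,prefValid numeric prefix-count vectors of
#'   length `n + 1`.
#'
#' @exportClass CompositionIndex
setClass("CompositionIndex",
         representation(seqId = "character", n = "integer",
                        prefC = "numeric", prefG = "numeric",
                        prefCpG = "numeric", prefValid = "numeric"))

setValidity("CompositionIndex", function(object) {
  n <- object@n
  for (nm in c("prefC", "prefG", "prefCpG", "prefValid")) {
    v <- slot(object, nm)
    if (length(v) != n + 1L) return(sprintf("'%s' must have length n + 1", nm))
    if (v[1] != 0) return(sprintf("'%s[1]' must be 0", nm))
    if (any(diff(v) < 0)) return(sprintf("'%s' must be non-decreasing", nm))
  }
  if (object@prefC[n + 1L] + object@prefG[n + 1L] > object@prefValid[n + 1L])
    return("C + G counts exceed valid-base count")
  if (object@prefCpG[n + 1L] > min(object@prefC[n + 1L], object@prefG[n + 1L]))
    return("CpG count exceeds min(C, G)")
  TRUE
})

setMethod("show", "CompositionIndex", function(object) {
  cat(sprintf(
    "CompositionIndex '%s': %d bp, %d C, %d G, %d CpG, %d valid bases\n",
    object@seqId, object@n, object@prefC[object@n + 1L],
    object@prefG[object@n + 1L], object@prefCpG[object@n + 1L],
    object@prefValid[object@n + 1L]))
})

#' Island qualification criteria
#'
#' The three thresholds of the classical composition-based island
#' definition (minimum length, minimum GC%, minimum observed/expected CpG
#' ratio) plus the merge gap below which neighbouring islands are fused.
#' All three thresholds are applied inclusively (`>=`).
#'
#' @slot minLength minimum island length, bp.
#' @slot minGC minimum GC content, percent.
#' @slot minOE minimum CpG observed/expected ratio.
#' @slot mergeGap islands closer than this many bp are merge candidates
#'   (strictly less than).
#'
#' @exportClass IslandCriteria
setClass("IslandCriteria",
         representation(minLength = "numeric", minGC = "numeric",
                        minOE = "numeric", mergeGap = "numeric"))

setValidity("IslandCriteria", function(object) {
  if (object@minLength < 2) return("'minLength' must be >= 2")
  if (object@minGC <= 0 || object@minGC > 100)
    return("'minGC' must be in (0, 100]")
  if (object@minOE <= 0) return("'minOE' must be > 0")
  if (object@mergeGap < 0) return("'mergeGap' must be >= 0")
  TRUE
})

#' Construct island criteria
#'
#' @param minLength minimum island length (bp), default 200.
#' @param minGC minimum GC content (percent), default 50.
#' @param minOE minimum CpG observed/expected ratio, default 0.6.
#' @param mergeGap merge islands separated by fewer than this many bp,
#'   default 100.
#' @return An [IslandCriteria-class] object.
#' @seealso [criteriaPreset()] for the standard parameterizations.
#' @export
islandCriteria <- function(minLength = 200, minGC = 50, minOE = 0.6,
                           mergeGap = 100) {
  new("IslandCriteria", minLength = as.numeric(minLength),
      minGC = as.numeric(minGC), minOE = as.numeric(minOE),
      mergeGap = as.numeric(mergeGap))
}

#' Standard criteria presets
#'
#' `"ggf"` is the classical composition definition (length >= 200 bp,
#' GC >= 50%, O/E >= 0.6); `"tj"` is the stricter re-evaluation
#' (500 bp / 55% / 0.65) designed to exclude short repeats such as Alu.
#' Both use the conventional 100 bp merge gap.
#'
#' @param name `"ggf"` or `"tj"`.
#' @return An [IslandCriteria-class] object.
#' @examples
#' criteriaPreset("tj")
#' @export
criteriaPreset <- function(name = c("ggf", "tj")) {
  switch(match.arg(name),
         ggf = islandCriteria(200, 50, 0.6, 100),
         tj  = islandCriteria(500, 55, 0.65, 100))
}

setMethod("show", "IslandCriteria", function(object) {
  cat(sprintf(
    "IslandCriteria: length >= %g bp, GC >= %g%%, O/E >= %g, merge gap < %g bp\n",
    object@minLength, object@minGC, object@minOE, object@mergeGap))
})

#' A set of predicted CpG islands on one sequence
#'
#' Sorted, non-overlapping intervals in 0-based half-open coordinates with
#' their GC content and observed/expected CpG ratio. The central result
#' container of the package: every predictor returns one, and all writers
#' consume one.
#'
#' @slot seqId sequence identifier.
#' @slot start,end integer interval bounds, 0-based half-open.
#' @slot gc GC content of each island, percent.
#' @slot oe observed/expected CpG ratio of each island.
#' @slot provenance free-text record of the generating algorithm and its
#'   parameters; emitted as a `#` header by the writers.
#'
#' @exportClass IslandSet
setClass("IslandSet",
         representation(seqId = "character", start = "integer",
                        end = "integer", gc = "numeric", oe = "numeric",
                        provenance = "character"),
         prototype(provenance = ""))

setValidity("IslandSet", function(object) {
  k <- length(object@start)
  if (length(object@end) != k || length(object@gc) != k ||
      length(object@oe) != k)
    return("start/end/gc/oe must have equal lengths")
  if (length(object@seqId) != 1L) return("'seqId' must be a single string")
  if (k == 0L) return(TRUE)
  if (any(object@start < 0L)) return("negative start coordinate")
  if (any(object@end <= object@start)) return("empty or inverted interval")
  if (k > 1L) {
    if (is.unsorted(object@start)) return("islands must be sorted by start")
    if (any(object@start[-1L] < object@end[-k]))
      return("islands must not overlap")
  }
  TRUE
})

#' Construct an IslandSet
#'
#' GC% and O/E are recomputed from `index` when it is supplied, which keeps
#' the stored statistics consistent with the sequence by construction.
#'
#' @param seqId sequence identifier.
#' @param start,end 0-based half-open interval bounds.
#' @param index optional [CompositionIndex-class] used to compute per-island
#'   GC% and O/E.
#' @param gc,oe per-island statistics, used only when `index` is missing.
#' @param provenance free-text provenance string.
#' @return An [IslandSet-class].
#' @export
IslandSet <- function(seqId, start = integer(0), end = integer(0),
                      index = NULL, gc = NULL, oe = NULL, provenance = "") {
  start <- as.integer(start); end <- as.integer(end)
  o <- order(start)
  start <- start[o]; end <- end[o]
  if (!is.null(index)) {
    gc <- gcContent(index, start, end)
    oe <- oeRatio(index, start, end)
  } else {
    if (is.null(gc)) gc <- rep(NA_real_, length(start))
    if (is.null(oe)) oe <- rep(NA_real_, length(start))
    gc <- gc[o]; oe <- oe[o]
  }
  new("IslandSet", seqId = as.character(seqId), start = start, end = end,
      gc = as.numeric(gc), oe = as.numeric(oe),
      provenance = as.character(provenance))
}

#' @describeIn IslandSet number of islands.
#' @param x an `IslandSet`.
#' @export
setMethod("length", "IslandSet", function(x) length(x@start))

#' @describeIn IslandSet one row per island: `seq_id`, `start`, `end`,
#'   `length`, `gc_percent`, `oe_ratio`.
#' @param row.names,optional,... passed through (unused).
#' @export
setMethod("as.data.frame", "IslandSet",
          function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(seq_id = rep(x@seqId, length(x@start)),
             start = x@start, end = x@end, length = x@end - x@start,
             gc_percent = x@gc, oe_ratio = x@oe,
             stringsAsFactors = FALSE)
})

setMethod("show", "IslandSet", function(object) {
  k <- length(object)
  cat(sprintf("IslandSet on '%s': %d island%s%s\n", object@seqId, k,
              if (k == 1L) "" else "s",
              if (nzchar(object@provenance))
                paste0(" [", object@provenance, "]") else ""))
  if (k > 0L) {
    df <- as.data.frame(object)
    print(utils::head(df, 8))
    if (k > 8L) cat(sprintf("  ... and %d more\n", k - 8L))
  }
})

#' Convert an IslandSet to GRanges
#'
#' Coordinates shift from the package's 0-based half-open convention to the
#' 1-based closed convention of [GenomicRanges::GRanges].
#'
#' @param x an [IslandSet-class].
#' @return A `GRanges` with metadata columns `gc_percent` and `oe_ratio`.
#' @export
islandsAsGRanges <- function(x) {
  stopifnot(is(x, "IslandSet"))
  gr <- GenomicRanges::GRanges(
    seqnames = x@seqId,
    ranges = IRanges::IRanges(start = x@start + 1L, end = x@end))
  S4Vectors::mcols(gr)$gc_percent <- x@gc
  S4Vectors::mcols(gr)$oe_ratio <- x@oe
  gr
}

#' Windowed statistic track
#'
#' Non-overlapping, sorted bins carrying a per-bin statistic (GC% or O/E
#' ratio), suitable for bedGraph export.
#'
#' @slot seqId sequence identifier.
#' @slot start,end 0-based half-open bin bounds.
#' @slot value per-bin statistic values.
#' @slot statistic `"gc_percent"` or `"oe_ratio"`.
#'
#' @exportClass Track
setClass("Track",
         representation(seqId = "character", start = "integer",
                        end = "integer", value = "numeric",
                        statistic = "character"))

setValidity("Track", function(object) {
  k <- length(object@start)
  if (length(object@end) != k || length(object@value) != k)
    return("start/end/value must have equal lengths")
  if (!object@statistic %in% c("gc_percent", "oe_ratio"))
    return("statistic must be 'gc_percent' or 'oe_ratio'")
  if (k > 1L && any(object@start[-1L] < object@end[-k]))
    return("bins must be sorted and non-overlapping")
  TRUE
})

setMethod("show", "Track", function(object) {
  cat(sprintf("Track '%s' (%s): %d bins\n", object@seqId, object@statistic,
              length(object@start)))
})

#' Metaheuristic search configuration
#'
#' Parameters of the particle-swarm and genetic-algorithm island searches
#' and of the segment driver that applies them along a sequence. The
#' complementary variants (`"cpso"`, `"cga"`) trigger a complementary
#' restart after `stagnationLimit` consecutive generations without
#' improvement of the best solution.
#'
#' @slot algorithm one of `"pso"`, `"cpso"`, `"ga"`, `"cga"`.
#' @slot population swarm/population size.
#' @slot maxIter generations per segment round.
#' @slot inertia length-2 vector: initial and final PSO inertia weight
#'   (linear schedule).
#' @slot c1,c2 PSO cognitive and social acceleration coefficients.
#' @slot vMax PSO velocity clamp in bp (`NA` means segment length / 10).
#' @slot crossoverRate,mutationRate GA single-point crossover and per-bit
#'   mutation probabilities.
#' @slot eliteCount GA individuals copied unchanged each generation.
#' @slot stagnationLimit generations without best-fitness improvement that
#'   trigger the complementary restart (default 5).
#' @slot segmentLength,segmentOverlap segment tiling of the sequence, bp.
#' @slot maskRounds maximum islands recovered per segment before moving on.
#' @slot seed RNG seed; required, no silent default.
#'
#' @exportClass SearchConfig
setClass("SearchConfig",
         representation(algorithm = "character", population = "integer",
                        maxIter = "integer", inertia = "numeric",
                        c1 = "numeric", c2 = "numeric", vMax = "numeric",
                        crossoverRate = "numeric", mutationRate = "numeric",
                        eliteCount = "integer", stagnationLimit = "integer",
                        segmentLength = "integer", segmentOverlap = "integer",
                        maskRounds = "integer", seed = "numeric"))

setValidity("SearchConfig", function(object) {
  if (!object@algorithm %in% c("pso", "cpso", "ga", "cga"))
    return("algorithm must be one of pso, cpso, ga, cga")
  if (object@population < 2L) return("'population' must be >= 2")
  if (object@maxIter < 1L) return("'maxIter' must be >= 1")
  if (length(object@inertia) != 2L) return("'inertia' must have length 2")
  for (nm in c("crossoverRate", "mutationRate")) {
    v <- slot(object, nm)
    if (v < 0 || v > 1) return(sprintf("'%s' must be in [0, 1]", nm))
  }
  if (object@eliteCount < 0L || object@eliteCount > object@population)
    return("'eliteCount' must be in [0, population]")
  if (object@stagnationLimit < 1L) return("'stagnationLimit' must be >= 1")
  if (object@segmentOverlap >= object@segmentLength)
    return("'segmentOverlap' must be smaller than 'segmentLength'")
  if (object@maskRounds < 1L) return("'maskRounds' must be >= 1")
  TRUE
})

#' Construct a search configuration
#'
#' Defaults: population 40, 200 generations, inertia 0.9 to 0.4, c1 = c2 = 2,
#' velocity clamp = segment length / 10, crossover 0.8, mutation 0.01,
#' 2 elites, stagnation limit 5, 10 kb segments with 1 kb overlap, at most
#' 10 mask rounds per segment. The seed has no default: stochastic searches
#' refuse to run without one.
#'
#' @param algorithm `"pso"`, `"cpso"`, `"ga"` or `"cga"`.
#' @param population,maxIter,inertia,c1,c2,vMax,crossoverRate,mutationRate
#'   see slot documentation in [SearchConfig-class].
#' @param eliteCount,stagnationLimit,segmentLength,segmentOverlap,maskRounds
#'   see slot documentation in [SearchConfig-class].
#' @param seed integer RNG seed.
#' @return A [SearchConfig-class].
#' @export
searchConfig <- function(algorithm = c("cpso", "pso", "cga", "ga"),
                         population = 40, maxIter = 200,
                         inertia = c(0.9, 0.4), c1 = 2, c2 = 2, vMax = NA,
                         crossoverRate = 0.8, mutationRate = 0.01,
                         eliteCount = 2, stagnationLimit = 5,
                         segmentLength = 10000, segmentOverlap = 1000,
                         maskRounds = 10, seed = NA) {
  new("SearchConfig", algorithm = match.arg(algorithm),
      population = as.integer(population), maxIter = as.integer(maxIter),
      inertia = as.numeric(inertia), c1 = as.numeric(c1),
      c2 = as.numeric(c2), vMax = as.numeric(vMax),
      crossoverRate = as.numeric(crossoverRate),
      mutationRate = as.numeric(mutationRate),
      eliteCount = as.integer(eliteCount),
      stagnationLimit = as.integer(stagnationLimit),
      segmentLength = as.integer(segmentLength),
      segmentOverlap = as.integer(segmentOverlap),
      maskRounds = as.integer(maskRounds), seed = as.numeric(seed))
}

setMethod("show", "SearchConfig", function(object) {
  cat(sprintf(
    "SearchConfig: %s, population %d, %d generations, seed %s\n",
    object@algorithm, object@population, object@maxIter,
    if (is.na(object@seed)) "<unset>" else format(object@seed)))
})

#' Metaheuristic population state
#'
#' Shared state container for the PSO swarm and the GA population. Candidate
#' positions are `(start, length)` pairs; the GA additionally carries the
#' binary genomes its operators act on. `stagnation` counts consecutive
#' generations without improvement of `gbestFit` and resets to zero whenever
#' the best solution improves.
#'
#' @slot algorithm `"pso"` or `"ga"` (the complementary variants share the
#'   same state).
#' @slot positions population-by-2 matrix of `(start, length)` candidates.
#' @slot velocities PSO velocities (zero-row matrix for the GA).
#' @slot genomes GA logical genome matrix (zero-column for PSO).
#' @slot fitness fitness of the current positions.
#' @slot pbest,pbestFit PSO per-particle best positions and fitness.
#' @slot gbest,gbestFit best position and fitness found so far.
#' @slot stagnation consecutive stagnant generations.
#' @slot generation generations elapsed.
#' @slot bounds numeric `(startLo, startHi, lenLo, lenHi)` box bounds.
#' @slot nBitsStart,nBitsLen GA encoding widths.
#'
#' @exportClass SwarmState
setClass("SwarmState",
         representation(algorithm = "character", positions = "matrix",
                        velocities = "matrix", genomes = "matrix",
                        fitness = "numeric", pbest = "matrix",
                        pbestFit = "numeric", gbest = "numeric",
                        gbestFit = "numeric", stagnation = "integer",
                        generation = "integer", bounds = "numeric",
                        nBitsStart = "integer", nBitsLen = "integer"))

setValidity("SwarmState", function(object) {
  if (!object@algorithm %in% c("pso", "ga"))
    return("algorithm must be 'pso' or 'ga'")
  if (ncol(object@positions) != 2L)
    return("'positions' must have two columns (start, length)")
  if (length(object@bounds) != 4L)
    return("'bounds' must be (startLo, startHi, lenLo, lenHi)")
  if (object@stagnation < 0L) return("'stagnation' must be >= 0")
  TRUE
})

setMethod("show", "SwarmState", function(object) {
  cat(sprintf(
    "SwarmState (%s): %d members, generation %d, best fitness %.1f at (%d, %d), stagnation %d\n",
    object@algorithm, nrow(object@positions), object@generation,
    object@gbestFit, round(object@gbest[1]), round(object@gbest[2]),
    object@stagnation))
})

#' Synthetic genome specification
#'
#' Parameters of the seeded generator: a CpG-depleted background (default
#' GC 40%, O/E 0.2) with planted CpG-rich islands (default GC 60%, O/E 0.8,
#' lengths 300-1500 bp) separated by at least `minIslandGap` bp. These
#' defaults emulate the contrast that composition-based island criteria are
#' designed to detect.
#'
#' @slot length genome length, bp.
#' @slot backgroundGc,backgroundOe background composition targets.
#' @slot nIslands number of planted islands.
#' @slot islandLengthRange length-2 integer range of island lengths, bp.
#' @slot islandGc,islandOe island composition targets.
#' @slot minIslandGap minimum gap between islands, bp.
#' @slot seed RNG seed.
#'
#' @exportClass SyntheticGenomeSpec
setClass("SyntheticGenomeSpec",
         representation(length = "integer", backgroundGc = "numeric",
                        backgroundOe = "numeric", nIslands = "integer",
                        islandLengthRange = "integer", islandGc = "numeric",
                        islandOe = "numeric", minIslandGap = "integer",
                        seed = "numeric"))

setValidity("SyntheticGenomeSpec", function(object) {
  if (object@length < 1L) return("'length' must be positive")
  for (nm in c("backgroundGc", "islandGc")) {
    v <- slot(object, nm)
    if (v <= 0 || v >= 100) return(sprintf("'%s' must be in (0, 100)", nm))
  }
  for (nm in c("backgroundOe", "islandOe")) {
    v <- slot(object, nm)
    if (v < 0 || v >= 4) return(sprintf("'%s' must be in [0, 4)", nm))
  }
  if (object@nIslands < 0L) return("'nIslands' must be >= 0")
  if (length(object@islandLengthRange) != 2L ||
      object@islandLengthRange[1] > object@islandLengthRange[2])
    return("'islandLengthRange' must be an increasing length-2 range")
  if (object@nIslands > 0L) {
    need <- object@nIslands * object@islandLengthRange[2] +
      (object@nIslands - 1L) * object@minIslandGap
    if (need > object@length)
      return("islands and gaps cannot fit within 'length'")
  }
  TRUE
})

#' Construct a synthetic genome specification
#'
#' @param length genome length in bp.
#' @param nIslands number of planted islands.
#' @param seed integer RNG seed.
#' @param backgroundGc,backgroundOe background GC% and O/E targets
#'   (defaults 40 and 0.2).
#' @param islandLengthRange island length range in bp (default 300-1500).
#' @param islandGc,islandOe island GC% and O/E targets (defaults 60 and 0.8).
#' @param minIslandGap minimum distance between planted islands in bp
#'   (default 500).
#' @return A [SyntheticGenomeSpec-class].
#' @export
syntheticGenomeSpec <- function(length = 50000, nIslands = 10, seed = NA,
                                backgroundGc = 40, backgroundOe = 0.2,
                                islandLengthRange = c(300, 1500),
                                islandGc = 60, islandOe = 0.8,
                                minIslandGap = 500) {
  new("SyntheticGenomeSpec", length = as.integer(length),
      backgroundGc = as.numeric(backgroundGc),
      backgroundOe = as.numeric(backgroundOe),
      nIslands = as.integer(nIslands),
      islandLengthRange = as.integer(islandLengthRange),
      islandGc = as.numeric(islandGc), islandOe = as.numeric(islandOe),
      minIslandGap = as.integer(minIslandGap), seed = as.numeric(seed))
}

setMethod("show", "SyntheticGenomeSpec", function(object) {
  cat(sprintf(
    "SyntheticGenomeSpec: %d bp, background GC %g%% / O-E %g, %d islands (GC %g%% / O-E %g, %d-%d bp)\n",
    object@length, object@backgroundGc, object@backgroundOe,
    object@nIslands, object@islandGc, object@islandOe,
    object@islandLengthRange[1], object@islandLengthRange[2]))
})
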