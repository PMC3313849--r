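# Stochastic island discovery. Candidates are (start, length) pairs inside
# a segment; PSO moves them continuously, the GA evolves a binary encoding.
# The complementary variants reflect the stagnant worse half of the
# population across the box bounds after `stagnationLimit` flat
# generations.

#' Fitness of island candidates
#'
#' A feasible candidate (one satisfying all criteria) scores its length, so
#' the search prefers the longest valid island reachable in the segment.
#' Infeasible candidates score
#' `min(length, minLength) * min(gc/minGC, 1)^2 * min(oe/minOE, 1)^2`, a
#' smooth ramp toward feasibility that rewards overlap with CpG-rich ground
#' while staying strictly below the score of every feasible candidate:
#' without the cap on the length factor, a segment-long interval of diluted
#' composition would outscore every true island and the search would
#' converge to an infeasible candidate.
#'
#' @param index a [CompositionIndex-class] (segment-local when masking is in
#'   effect; masked bases are rewritten to `A` before indexing).
#' @param start,length candidate interval(s): 0-based start and length in
#'   bp. Vectors are scored element-wise.
#' @param criteria an [IslandCriteria-class].
#' @return Numeric score(s) `>= 0`.
#' @export
candidateFitness <- function(index, start, length, criteria) {
  end <- start + length
  feasible <- meetsCriteria(index, start, end, criteria)
  gcTerm <- pmin(gcContent(index, start, end) / criteria@minGC, 1)
  oeTerm <- pmin(oeRatio(index, start, end) / criteria@minOE, 1)
  ifelse(feasible, length,
         pmin(length, criteria@minLength) * gcTerm^2 * oeTerm^2)
}

# Pure box clamp: keeping the bounds a plain box means the complementary
# reflection maps the box onto itself, so the complement stays an exact
# involution. Candidates overhanging the segment end are clipped at
# evaluation time instead.
.clampPositions <- function(pos, bounds) {
  pos[, 1] <- pmin(pmax(pos[, 1], bounds[1]), bounds[2])
  pos[, 2] <- pmin(pmax(pos[, 2], bounds[3]), bounds[4])
  pos
}

.evalPositions <- function(index, pos, criteria) {
  s <- as.integer(round(pos[, 1]))
  l <- pmin(as.integer(round(pos[, 2])), index@n - s)
  candidateFitness(index, s, l, criteria)
}

.bitsNeeded <- function(range) {
  max(1L, as.integer(ceiling(log2(range + 1))))
}

.encodeGA <- function(values, nBits) {
  t(vapply(values, function(v)
    as.integer(intToBits(as.integer(v)))[seq_len(nBits)],
    integer(nBits)))
}

.decodeGA <- function(genomes, nBitsStart, nBitsLen, bounds) {
  powS <- 2^(seq_len(nBitsStart) - 1)
  powL <- 2^(seq_len(nBitsLen) - 1)
  start <- bounds[1] + genomes[, seq_len(nBitsStart), drop = FALSE] %*% powS
  len <- bounds[3] +
    genomes[, nBitsStart + seq_len(nBitsLen), drop = FALSE] %*% powL
  .clampPositions(cbind(as.numeric(start), as.numeric(len)), bounds)
}

#' Initialize a swarm or GA population
#'
#' Candidates are drawn uniformly inside the box bounds
#' `start in [lo, hi - minLength]`, `length in [minLength, hi - lo]`, their
#' fitness is evaluated and the personal/global bests are seeded.
#'
#' @param index segment [CompositionIndex-class].
#' @param criteria an [IslandCriteria-class].
#' @param config a [SearchConfig-class].
#' @param lo,hi segment bounds (0-based half-open), defaults to the whole
#'   indexed sequence.
#' @param positions optional population-by-2 matrix of initial
#'   `(start, length)` candidates overriding the uniform draw.
#' @return A [SwarmState-class].
#' @export
initSwarm <- function(index, criteria, config, lo = 0L, hi = index@n,
                      positions = NULL) {
  minLen <- criteria@minLength
  if (hi - lo < minLen)
    stop("segment shorter than the minimum island length")
  bounds <- c(lo, hi - minLen, minLen, hi - lo)
  pop <- config@population
  if (is.null(positions)) {
    positions <- cbind(stats::runif(pop, bounds[1], bounds[2]),
                       stats::runif(pop, bounds[3], bounds[4]))
  }
  positions <- .clampPositions(positions, bounds)
  kind <- if (config@algorithm %in% c("pso", "cpso")) "pso" else "ga"
  if (kind == "ga") {
    nBitsStart <- .bitsNeeded(bounds[2] - bounds[1])
    nBitsLen <- .bitsNeeded(bounds[4] - bounds[3])
    genomes <- cbind(
      .encodeGA(round(positions[, 1]) - bounds[1], nBitsStart),
      .encodeGA(round(positions[, 2]) - bounds[3], nBitsLen))
    positions <- .decodeGA(genomes, nBitsStart, nBitsLen, bounds)
    velocities <- matrix(0, 0, 2)
  } else {
    nBitsStart <- nBitsLen <- 0L
    genomes <- matrix(0L, pop, 0)
    velocities <- matrix(0, pop, 2)
  }
  fitness <- .evalPositions(index, positions, criteria)
  best <- which.max(fitness)
  new("SwarmState", algorithm = kind, positions = positions,
      velocities = velocities, genomes = genomes, fitness = fitness,
      pbest = positions, pbestFit = fitness,
      gbest = positions[best, ], gbestFit = fitness[best],
      stagnation = 0L, generation = 0L, bounds = as.numeric(bounds),
      nBitsStart = as.integer(nBitsStart), nBitsLen = as.integer(nBitsLen))
}

# Track gbest and the stagnation counter after a generation's fitness is in.
.updateBest <- function(state) {
  best <- which.max(if (state@algorithm == "pso") state@pbestFit
                    else state@fitness)
  bestFit <- if (state@algorithm == "pso") state@pbestFit[best]
             else state@fitness[best]
  if (bestFit > state@gbestFit) {
    state@gbestFit <- bestFit
    state@gbest <- if (state@algorithm == "pso") state@pbest[best, ]
                   else state@positions[best, ]
    state@stagnation <- 0L
  } else {
    state@stagnation <- state@stagnation + 1L
  }
  state
}

#' One particle-swarm generation
#'
#' Standard velocity/position update
#' `v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)`, `x <- x + v`, with
#' velocities clamped to `+/- vMax` and positions to the box bounds,
#' followed by fitness evaluation and pbest/gbest bookkeeping. The inertia
#' weight follows the linear schedule in `config@inertia` across
#' `config@maxIter` generations.
#'
#' @param state a [SwarmState-class] from [initSwarm()].
#' @param index segment [CompositionIndex-class].
#' @param criteria an [IslandCriteria-class].
#' @param config a [SearchConfig-class].
#' @return The advanced [SwarmState-class].
#' @export
psoStep <- function(state, index, criteria, config) {
  stopifnot(state@algorithm == "pso")
  pop <- nrow(state@positions)
  gen <- state@generation + 1L
  frac <- if (config@maxIter > 1L) min((gen - 1) / (config@maxIter - 1), 1)
          else 0
  w <- config@inertia[1] + (config@inertia[2] - config@inertia[1]) * frac
  vMax <- if (is.na(config@vMax))
    (state@bounds[2] + state@bounds[3] - state@bounds[1]) / 10
  else config@vMax
  r1 <- matrix(stats::runif(pop * 2), pop, 2)
  r2 <- matrix(stats::runif(pop * 2), pop, 2)
  gbestMat <- matrix(state@gbest, pop, 2, byrow = TRUE)
  v <- w * state@velocities +
    config@c1 * r1 * (state@pbest - state@positions) +
    config@c2 * r2 * (gbestMat - state@positions)
  v <- pmin(pmax(v, -vMax), vMax)
  pos <- .clampPositions(state@positions + v, state@bounds)
  fit <- .evalPositions(index, pos, criteria)
  improved <- fit > state@pbestFit
  state@pbest[improved, ] <- pos[improved, ]
  state@pbestFit[improved] <- fit[improved]
  state@velocities <- v
  state@positions <- pos
  state@fitness <- fit
  state@generation <- gen
  .updateBest(state)
}

#' One genetic-algorithm generation
#'
#' Binary tournament selection (k = 2), single-point crossover on the
#' concatenated `(start, length)` bit encoding at `crossoverRate`, per-bit
#' mutation at `mutationRate`, and elitism copying the `eliteCount` best
#' previous individuals over the worst offspring. Decoded positions are
#' re-clamped to the box bounds.
#'
#' @inheritParams psoStep
#' @return The advanced [SwarmState-class].
#' @export
gaStep <- function(state, index, criteria, config) {
  stopifnot(state@algorithm == "ga")
  pop <- nrow(state@genomes)
  nBits <- ncol(state@genomes)
  # tournament selection, k = 2
  a <- sample.int(pop, pop, replace = TRUE)
  b <- sample.int(pop, pop, replace = TRUE)
  sel <- ifelse(state@fitness[a] >= state@fitness[b], a, b)
  genomes <- state@genomes[sel, , drop = FALSE]
  # single-point crossover on consecutive pairs
  for (i in seq_len(floor(pop / 2))) {
    if (stats::runif(1) < config@crossoverRate) {
      cut <- sample.int(nBits - 1L, 1L)
      i1 <- 2L * i - 1L; i2 <- 2L * i
      tail1 <- genomes[i1, (cut + 1L):nBits]
      genomes[i1, (cut + 1L):nBits] <- genomes[i2, (cut + 1L):nBits]
      genomes[i2, (cut + 1L):nBits] <- tail1
    }
  }
  # per-bit mutation
  if (config@mutationRate > 0) {
    flips <- matrix(stats::runif(pop * nBits) < config@mutationRate,
                    pop, nBits)
    genomes[flips] <- 1L - genomes[flips]
  }
  pos <- .decodeGA(genomes, state@nBitsStart, state@nBitsLen, state@bounds)
  fit <- .evalPositions(index, pos, criteria)
  # elitism: best previous individuals replace the worst offspring
  if (config@eliteCount > 0L) {
    eliteIdx <- order(state@fitness, decreasing = TRUE)[
      seq_len(config@eliteCount)]
    worstIdx <- order(fit)[seq_len(config@eliteCount)]
    genomes[worstIdx, ] <- state@genomes[eliteIdx, , drop = FALSE]
    pos[worstIdx, ] <- state@positions[eliteIdx, , drop = FALSE]
    fit[worstIdx] <- state@fitness[eliteIdx]
  }
  state@genomes <- genomes
  state@positions <- pos
  state@fitness <- fit
  state@generation <- state@generation + 1L
  .updateBest(state)
}

#' Complementary restart
#'
#' Replaces the worse half of the population (never the current best
#' members) by the complement of each member's position across the box
#' bounds, `x' = lo + hi - x` per coordinate — an involution that throws
#' stagnant candidates to the unexplored side of the segment. Velocities of
#' replaced particles are zeroed and their personal bests reset to the new
#' position; the global best is retained and the stagnation counter reset.
#' Calling it before the stagnation limit is reached is a warning no-op.
#'
#' @param state a [SwarmState-class].
#' @param config a [SearchConfig-class].
#' @param index,criteria optional; when supplied, the fitness of replaced
#'   members is re-evaluated immediately (the search driver does this).
#' @return The restarted [SwarmState-class].
#' @export
complementaryRestart <- function(state, config, index = NULL,
                                 criteria = NULL) {
  if (state@stagnation < config@stagnationLimit) {
    warning("stagnation limit not reached; restart is a no-op")
    return(state)
  }
  pop <- nrow(state@positions)
  nKeep <- if (state@algorithm == "ga") max(1L, config@eliteCount) else 1L
  protected <- order(state@fitness, decreasing = TRUE)[seq_len(nKeep)]
  candidates <- setdiff(order(state@fitness), protected)
  replace <- candidates[seq_len(min(floor(pop / 2), length(candidates)))]
  b <- state@bounds
  newPos <- state@positions[replace, , drop = FALSE]
  newPos[, 1] <- b[1] + b[2] - newPos[, 1]
  newPos[, 2] <- b[3] + b[4] - newPos[, 2]
  newPos <- .clampPositions(newPos, b)
  state@positions[replace, ] <- newPos
  if (state@algorithm == "pso") {
    state@velocities[replace, ] <- 0
    state@pbest[replace, ] <- newPos
    state@pbestFit[replace] <- -Inf
  } else {
    state@genomes[replace, ] <- cbind(
      .encodeGA(round(newPos[, 1]) - b[1], state@nBitsStart),
      .encodeGA(round(newPos[, 2]) - b[3], state@nBitsLen))
  }
  if (!is.null(index) && !is.null(criteria)) {
    fit <- .evalPositions(index, newPos, criteria)
    state@fitness[replace] <- fit
    if (state@algorithm == "pso") state@pbestFit[replace] <- fit
  } else {
    state@fitness[replace] <- -Inf
  }
  state@stagnation <- 0L
  state
}

#' Run one metaheuristic search over a segment
#'
#' Initializes the population (unless `state` is given) and advances it for
#' `config@maxIter` generations, firing the complementary restart whenever
#' the configured variant is complementary and the stagnation counter
#' reaches `config@stagnationLimit`.
#'
#' @inheritParams initSwarm
#' @param state optional pre-built [SwarmState-class] (e.g. from
#'   [initSwarm()] with custom positions).
#' @return A list with elements `state` (final [SwarmState-class]),
#'   `restarts` (generations at which a complementary restart fired) and
#'   `gbestTrace` (best fitness after each generation).
#' @export
runSearch <- function(index, criteria, config, lo = 0L, hi = index@n,
                      state = NULL) {
  if (is.null(state))
    state <- initSwarm(index, criteria, config, lo, hi)
  complementary <- config@algorithm %in% c("cpso", "cga")
  stepFun <- if (state@algorithm == "pso") psoStep else gaStep
  restarts <- integer(0)
  trace <- numeric(config@maxIter)
  for (gen in seq_len(config@maxIter)) {
    state <- stepFun(state, index, criteria, config)
    if (complementary && state@stagnation >= config@stagnationLimit) {
      state <- complementaryRestart(state, config, index, criteria)
      restarts <- c(restarts, gen)
    }
    trace[gen] <- state@gbestFit
  }
  list(state = state, restarts = restarts, gbestTrace = trace)
}

#' Segment-driven stochastic island discovery
#'
#' Tiles the sequence into overlapping segments, repeatedly runs the
#' configured metaheuristic in each segment, records the best candidate
#' whenever it is feasible, masks its bases (rewritten to `A`, so they score
#' as CpG-free ground in later rounds) and searches again, up to
#' `maskRounds` islands per segment. Pooled islands from all segments are
#' de-duplicated across segment overlaps (keeping the longer island;
#' leftmost on ties), split at assembly-gap runs, and gap-merged. Every
#' emitted island satisfies the criteria on the unmasked sequence.
#'
#' @param seq a [GenomeSequence-class].
#' @param criteria an [IslandCriteria-class].
#' @param config a [SearchConfig-class]; `config@seed` must be set.
#' @param verbose emit per-segment progress messages.
#' @return An [IslandSet-class].
#' @export
searchIslands <- function(seq, criteria, config, verbose = FALSE) {
  stopifnot(is(seq, "GenomeSequence"))
  if (is.na(config@seed))
    stop("stochastic search requires an explicit seed in the configuration")
  if (config@segmentLength < criteria@minLength)
    stop("'segmentLength' must be at least the minimum island length")
  set.seed(as.integer(config@seed))
  n <- length(seq)
  globalIndex <- buildIndex(seq)
  segLen <- min(config@segmentLength, n)
  stride <- max(segLen - config@segmentOverlap, 1L)
  segStarts <- seq.int(0L, max(n - segLen, 0L), by = stride)
  if (segStarts[length(segStarts)] + segLen < n)
    segStarts <- c(segStarts, n - segLen)
  found <- matrix(integer(0), 0, 2)
  for (lo in segStarts) {
    hi <- min(lo + segLen, n)
    segRes <- substr(seq@residues, lo + 1L, hi)
    for (maskRound in seq_len(config@maskRounds)) {
      segIndex <- buildIndex(segRes, seqId = seq@id)
      res <- runSearch(segIndex, criteria, config, 0L, hi - lo)
      st <- res$state
      s <- as.integer(round(st@gbest[1]))
      l <- as.integer(round(st@gbest[2]))
      s <- max(0L, min(s, (hi - lo) - as.integer(criteria@minLength)))
      l <- max(as.integer(criteria@minLength), min(l, (hi - lo) - s))
      if (!meetsCriteria(segIndex, s, s + l, criteria)) break
      found <- rbind(found, c(lo + s, lo + s + l))
      if (verbose)
        message(sprintf(
          "segment [%d,%d): island [%d,%d) fitness %.0f, %d restart(s)",
          lo, hi, lo + s, lo + s + l, st@gbestFit, length(res$restarts)))
      # mask the recovered island so the next round finds something new
      substr(segRes, s + 1L, s + l) <- strrep("A", l)
    }
  }
  # resolve duplicates introduced by the segment overlap: longer wins,
  # leftmost on ties
  if (nrow(found) > 1L) {
    o <- order(found[, 1] - found[, 2], found[, 1])
    keepS <- integer(0); keepE <- integer(0)
    for (i in o) {
      s <- found[i, 1]; e <- found[i, 2]
      if (!any(s < keepE & e > keepS)) {
        keepS <- c(keepS, s); keepE <- c(keepE, e)
      }
    }
    found <- cbind(keepS, keepE)
  }
  o <- order(found[, 1])
  starts <- found[o, 1]; ends <- found[o, 2]
  # masked-round candidates never span a mask, so their composition on the
  # true sequence equals what the search scored; re-filter defensively
  keep <- meetsCriteria(globalIndex, starts, ends, criteria)
  sp <- .splitAtNRuns(starts[keep], ends[keep], globalIndex, criteria)
  prov <- sprintf(
    "%s population=%d maxIter=%d segment=%d/%d maskRounds=%d seed=%d criteria=%g/%g/%g/%g",
    config@algorithm, config@population, config@maxIter,
    config@segmentLength, config@segmentOverlap, config@maskRounds,
    as.integer(config@seed), criteria@minLength, criteria@minGC,
    criteria@minOE, criteria@mergeGap)
  mergeIslands(IslandSet(seq@id, sp$start, sp$end, index = globalIndex,
                         provenance = prov),
               globalIndex, criteria)
}

#' Predict CpG islands in a sequence
#'
#' Front door dispatching to the deterministic sliding-window extractor or
#' to the stochastic segment search.
#'
#' @param seq a [GenomeSequence-class].
#' @param criteria an [IslandCriteria-class] (default: the classical
#'   200 bp / 50% / 0.6 preset).
#' @param method `"sliding"`, `"cpso"`, `"cga"`, `"pso"` or `"ga"`.
#' @param config a [SearchConfig-class] for the stochastic methods; its
#'   `algorithm` field is overridden by `method`. Required (with a seed) for
#'   stochastic methods.
#' @param window,step sliding-window parameters.
#' @param verbose progress messages for the stochastic methods.
#' @return An [IslandSet-class].
#' @examples
#' seq <- GenomeSequence("demo", strrep("AT", 300))
#' length(predictIslands(seq))  # 0
#' @export
predictIslands <- function(seq, criteria = criteriaPreset("ggf"),
                           method = c("sliding", "cpso", "cga", "pso", "ga"),
                           config = NULL, window = 200, step = 1,
                           verbose = FALSE) {
  method <- match.arg(method)
  if (method == "sliding")
    return(slidingWindowSearch(buildIndex(seq), criteria, window, step))
  if (is.null(config))
    stop("stochastic methods require a 'config' (see searchConfig())")
  config@algorithm <- method
  validObject(config)
  searchIslands(seq, criteria, config, verbose = verbose)
}
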