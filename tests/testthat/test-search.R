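# Fitness shape, PSO/GA generation mechanics, the complementary restart and
# the segment driver.

ggf <- criteriaPreset("ggf")

test_that("fitness scores feasible candidates by length and caps the rest", {
  idx <- buildIndex(paste0(strrep("AT", 200), strrep("CG", 300),
                           strrep("AT", 200)))
  # feasible 600 bp island scores exactly its length
  expect_equal(candidateFitness(idx, 400, 600, ggf), 600)
  # all-AT candidate: GC term zero
  expect_equal(candidateFitness(idx, 0, 300, ggf), 0)
  # monotone in length across nested feasible candidates
  lens <- c(200, 300, 450, 600)
  fits <- candidateFitness(idx, rep(400, 4), lens, ggf)
  expect_true(all(diff(fits) > 0))
  expect_equal(fits, lens)
  # an infeasible candidate never outscores a feasible one
  infeasible <- candidateFitness(idx, 0, idx@n, ggf)  # diluted whole seq
  expect_lt(infeasible, ggf@minLength)
})

test_that("PSO fixed points behave: zero coefficients freeze the swarm", {
  set.seed(301)
  idx <- buildIndex(markovSequence(3000, 45, 0.4))
  cfg <- searchConfig("pso", population = 10, maxIter = 50,
                      inertia = c(0, 0), c1 = 0, c2 = 0, seed = 1)
  st <- initSwarm(idx, ggf, cfg)
  st2 <- psoStep(st, idx, ggf, cfg)
  expect_equal(st2@positions, st@positions)
  expect_equal(st2@velocities, st@velocities)
  expect_equal(st2@generation, 1L)

  # identical particles sitting on the optimum with zero velocity stay put
  cfg2 <- searchConfig("pso", population = 6, maxIter = 50, seed = 1)
  pos <- matrix(rep(c(500, 400), each = 6), ncol = 2)
  stOpt <- initSwarm(idx, ggf, cfg2, positions = pos)
  stepped <- psoStep(stOpt, idx, ggf, cfg2)
  expect_equal(stepped@positions, stOpt@positions)
  expect_equal(stepped@gbestFit, stOpt@gbestFit)
  expect_equal(stepped@stagnation, 1L)
})

test_that("gbest fitness is non-decreasing across PSO generations", {
  set.seed(302)
  pb <- plantedBlockSeq(n = 4000, blockStart = 1500, blockLen = 700,
                        seed = 51)
  idx <- buildIndex(pb$residues)
  cfg <- searchConfig("pso", population = 20, maxIter = 100, seed = 1)
  set.seed(1)
  st <- initSwarm(idx, ggf, cfg)
  trace <- numeric(100)
  for (i in 1:100) {
    st <- psoStep(st, idx, ggf, cfg)
    trace[i] <- st@gbestFit
  }
  expect_true(all(diff(trace) >= 0))
  expect_gte(st@gbestFit, 600)  # found the block
})

test_that("GA with no operators and full elitism is the identity", {
  set.seed(303)
  idx <- buildIndex(markovSequence(3000, 45, 0.4))
  cfg <- searchConfig("ga", population = 12, maxIter = 10,
                      crossoverRate = 0, mutationRate = 0,
                      eliteCount = 12, seed = 1)
  st <- initSwarm(idx, ggf, cfg)
  st2 <- gaStep(st, idx, ggf, cfg)
  # same multiset of candidates (order may differ)
  sortPos <- function(m) m[order(m[, 1], m[, 2]), ]
  expect_equal(sortPos(st2@positions), sortPos(st@positions))
  expect_equal(sort(st2@fitness), sort(st@fitness))
})

test_that("GA best fitness is non-decreasing with elitism and stays in bounds", {
  set.seed(304)
  pb <- plantedBlockSeq(n = 4000, blockStart = 800, blockLen = 700,
                        seed = 52)
  idx <- buildIndex(pb$residues)
  cfg <- searchConfig("ga", population = 20, maxIter = 100, seed = 1)
  set.seed(2)
  st <- initSwarm(idx, ggf, cfg)
  best <- numeric(100)
  for (i in 1:100) {
    st <- gaStep(st, idx, ggf, cfg)
    best[i] <- max(st@fitness)
    b <- st@bounds
    expect_true(all(st@positions[, 1] >= b[1] & st@positions[, 1] <= b[2]))
    expect_true(all(st@positions[, 2] >= b[3] & st@positions[, 2] <= b[4]))
  }
  expect_true(all(diff(best) >= 0))
})

test_that("the complementary restart reflects, involutes and respects rank", {
  set.seed(305)
  idx <- buildIndex(markovSequence(2000, 45, 0.4))
  cfg <- searchConfig("cpso", population = 8, maxIter = 10, seed = 1)
  st <- initSwarm(idx, ggf, cfg)

  # below the stagnation limit: warning no-op
  expect_warning(same <- complementaryRestart(st, cfg), "no-op")
  expect_equal(same@positions, st@positions)

  st@stagnation <- 5L
  b <- st@bounds
  # park the worst particle at the lower corner: it must map to the upper
  worst <- which.min(st@fitness)
  st@positions[worst, ] <- c(b[1], b[3])
  st@fitness[worst] <- -1
  r1 <- complementaryRestart(st, cfg, idx, ggf)
  expect_equal(unname(r1@positions[worst, 1]), b[2])
  expect_equal(r1@stagnation, 0L)
  expect_equal(r1@gbest, st@gbest)  # gbest retained
  # velocities of replaced members rezeroed, pbest reset to new position
  expect_true(all(r1@velocities[worst, ] == 0))
  expect_equal(r1@pbest[worst, ], r1@positions[worst, ])

  # involution: reflecting the same members again restores the swarm
  r1@stagnation <- 5L
  r1@fitness[] <- st@fitness  # same ranking, same replaced set
  r2 <- complementaryRestart(r1, cfg, idx, ggf)
  expect_equal(r2@positions, st@positions, tolerance = 1e-9)

  # the best member is never replaced
  bestIdx <- which.max(st@fitness)
  expect_equal(r1@positions[bestIdx, ], st@positions[bestIdx, ])
})

test_that("the restart fires only after the stagnation limit is reached", {
  # perfectly flat landscape: nothing ever improves, so restarts must fire
  # at exactly generations 5, 10, 15, ...
  idx <- buildIndex(strrep("AT", 1500))
  cfg <- searchConfig("cpso", population = 10, maxIter = 12, seed = 9)
  set.seed(9)
  res <- runSearch(idx, ggf, cfg)
  expect_equal(res$restarts, c(5L, 10L))
  cfgGa <- searchConfig("cga", population = 10, maxIter = 12,
                        crossoverRate = 0, mutationRate = 0,
                        eliteCount = 10, seed = 9)
  set.seed(9)
  resGa <- runSearch(idx, ggf, cfgGa)
  expect_equal(resGa$restarts, c(5L, 10L))
})

test_that("the complementary restart escapes a deceptive two-peak landscape", {
  idx <- buildIndex(twoPeakSeq())
  n <- idx@n
  success <- function(alg, seeds = 1:8) {
    wins <- 0L
    for (seed in seeds) {
      set.seed(seed)
      cfg <- searchConfig(alg, maxIter = 100, seed = seed)
      init <- cbind(runif(40, 0, 1200), runif(40, 200, 400))
      st0 <- initSwarm(idx, ggf, cfg, positions = init)
      res <- runSearch(idx, ggf, cfg, state = st0)
      if (res$state@gbestFit >= 1200) wins <- wins + 1L
    }
    wins
  }
  expect_gte(success("cpso"), success("pso"))
  expect_gte(success("cpso"), 6L)  # reliably reaches the larger block
})

test_that("segment search recovers planted islands and is deterministic", {
  g <- generateGenome(syntheticGenomeSpec(length = 20000, nIslands = 4,
                                          seed = 13))
  cfg <- searchConfig("cpso", maxIter = 120, seed = 5)
  isl <- searchIslands(g$sequence, ggf, cfg)
  idx <- buildIndex(g$sequence)
  expect_true(all(meetsCriteria(idx, isl@start, isl@end, ggf)))
  expect_gte(nucleotideRecall(isl, g$truth, 20000), 0.9)
  # byte-identical rerun under the same seed
  isl2 <- searchIslands(g$sequence, ggf, cfg)
  expect_identical(as.data.frame(isl), as.data.frame(isl2))
  # a genome without qualifying ground yields an empty set
  flat <- GenomeSequence("flat", strrep("AT", 6000))
  expect_equal(length(searchIslands(flat, ggf, cfg)), 0L)
})

test_that("stochastic searches refuse to run without a seed", {
  g <- GenomeSequence("s", strrep("AT", 3000))
  expect_error(searchIslands(g, ggf, searchConfig("cpso")), "seed")
  expect_error(predictIslands(g, ggf, method = "cga"), "config")
})
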