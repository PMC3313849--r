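# Criteria, trimming, merging, the sliding-window extractor and the
# exhaustive oracle.

test_that("criteria thresholds are inclusive and preset values apply", {
  # 250 bp at GC 55 / O-E ~0.7 passes the classical preset
  set.seed(201)
  res <- markovSequence(5000, 55, 0.7)
  idx <- buildIndex(res)
  ggf <- criteriaPreset("ggf")
  expect_true(meetsCriteria(idx, 0, 2500, ggf))
  # too short fails regardless of composition
  expect_false(meetsCriteria(buildIndex(strrep("CG", 75)), 0, 150, ggf))
  # the stricter preset rejects on length below 500
  tj <- criteriaPreset("tj")
  expect_false(meetsCriteria(buildIndex(strrep("CG", 125)), 0, 250, tj))
  expect_equal(c(tj@minLength, tj@minGC, tj@minOE), c(500, 55, 0.65))

  # inclusivity: an interval exactly at every threshold qualifies
  # GGCA repeated: GC = 50 exactly; check boundary behaviour on GC
  at50 <- buildIndex(strrep("GGCATTAC", 50))  # GC exactly 50, 400 bp
  expect_equal(gcContent(at50, 0, 400), 50)
  crit <- islandCriteria(200, 50, oeRatio(at50, 0, 400), 100)
  expect_true(meetsCriteria(at50, 0, 400, crit))
})

test_that("trimming keeps qualifying intervals and pares marginal flanks", {
  ggf <- criteriaPreset("ggf")
  # already qualifying -> identity
  cg <- buildIndex(strrep("CG", 200))
  expect_equal(trimIsland(cg, 0, 400, ggf), c(0L, 400L))

  # GC-marginal 400 bp core (GC 50, O/E 4) with 100 bp AT flanks: any
  # residual flank drags GC below 50, so trimming recovers the core +/-2 bp
  res <- paste0(strrep("AT", 50), strrep("CGAT", 100), strrep("AT", 50))
  idx <- buildIndex(res)
  tr <- trimIsland(idx, 0, 600, ggf)
  expect_false(is.null(tr))
  expect_lte(abs(tr[1] - 100), 2)
  expect_lte(abs(tr[2] - 500), 2)
  expect_true(meetsCriteria(idx, tr[1], tr[2], ggf))

  # hopeless interval -> NULL
  at <- buildIndex(strrep("AT", 300))
  expect_null(trimIsland(at, 0, 600, ggf))
})

test_that("islands closer than the merge gap fuse iff the span qualifies", {
  ggf <- criteriaPreset("ggf")
  mkSeq <- function(gap, island = strrep("CG", 150)) {
    res <- paste0(island, strrep("A", gap), island)
    idx <- buildIndex(res)
    k <- nchar(island)
    list(idx = idx,
         set = IslandSet("s", c(0L, k + gap), c(k, 2L * k + gap),
                         index = idx))
  }
  # 99 bp apart, span still qualifies -> one island
  x <- mkSeq(99)
  merged <- mergeIslands(x$set, x$idx, ggf)
  expect_equal(length(merged), 1L)
  expect_equal(c(merged@start, merged@end), c(0L, 699L))
  # exactly 100 bp apart -> not merged (strictly less than the gap)
  x <- mkSeq(100)
  expect_equal(length(mergeIslands(x$set, x$idx, ggf)), 2L)
  # near islands whose span fails GC -> not merged
  x <- mkSeq(50, island = strrep("CGAT", 75))  # GC exactly 50 per island
  expect_equal(length(mergeIslands(x$set, x$idx, ggf)), 2L)
  expect_lt(gcContent(x$idx, 0, 650), 50)
})

test_that("merging is idempotent", {
  set.seed(202)
  g <- generateGenome(syntheticGenomeSpec(length = 8000, nIslands = 3,
                                          seed = 77,
                                          islandLengthRange = c(300, 600),
                                          minIslandGap = 120))
  idx <- buildIndex(g$sequence)
  ggf <- criteriaPreset("ggf")
  once <- mergeIslands(g$truth, idx, ggf)
  twice <- mergeIslands(once, idx, ggf)
  expect_identical(as.data.frame(once), as.data.frame(twice))
})

test_that("sliding window finds a planted block and nothing in AT ground", {
  ggf <- criteriaPreset("ggf")
  pb <- plantedBlockSeq(n = 2000, blockStart = 700, blockLen = 600,
                        seed = 11)
  idx <- buildIndex(pb$residues)
  found <- slidingWindowSearch(idx, ggf)
  expect_equal(length(found), 1L)
  overlap <- min(found@end, pb$end) - max(found@start, pb$start)
  expect_gte(overlap, 0.9 * (pb$end - pb$start))
  expect_true(all(meetsCriteria(idx, found@start, found@end, ggf)))

  empty <- slidingWindowSearch(buildIndex(strrep("AT", 500)), ggf)
  expect_equal(length(empty), 0L)

  # sequence shorter than the scan window: empty set with a warning
  expect_warning(short <- slidingWindowSearch(buildIndex("ACGT"), ggf),
                 "shorter")
  expect_equal(length(short), 0L)
})

test_that("every extractor island satisfies the criteria postcondition", {
  ggf <- criteriaPreset("ggf")
  for (seed in c(31, 32, 33)) {
    g <- generateGenome(syntheticGenomeSpec(length = 5000, nIslands = 2,
                                            seed = seed,
                                            islandLengthRange = c(300, 900)))
    idx <- buildIndex(g$sequence)
    for (isl in list(slidingWindowSearch(idx, ggf),
                     bruteForceOracle(idx, ggf))) {
      if (length(isl) == 0L) next
      expect_true(all(meetsCriteria(idx, isl@start, isl@end, ggf)))
      expect_true(validObject(isl))
    }
  }
})

test_that("the exhaustive oracle is greedy-leftmost and criteria-clean", {
  ggf <- criteriaPreset("ggf")
  expect_equal(length(bruteForceOracle(buildIndex(strrep("AT", 400)), ggf)),
               0L)
  pb <- plantedBlockSeq(n = 2000, blockStart = 600, blockLen = 500,
                        seed = 21)
  idx <- buildIndex(pb$residues)
  orc <- bruteForceOracle(idx, ggf)
  expect_equal(length(orc), 1L)
  # the oracle interval contains most of the planted block (flanks are
  # allowed to extend it outward, never to push it off the block)
  overlap <- min(orc@end, pb$end) - max(orc@start, pb$start)
  expect_gte(overlap, 0.9 * (pb$end - pb$start))
  expect_error(bruteForceOracle(buildIndex(strrep("A", 10001)), ggf),
               "10 kb")
})

test_that("islands split at long ambiguity runs and do not re-bridge", {
  ggf <- criteriaPreset("ggf")
  # two 300 bp CpG blocks bridged by 60 Ns: N run must split the island
  res <- paste0(strrep("CG", 150), strrep("N", 60), strrep("CG", 150))
  idx <- buildIndex(res)
  found <- slidingWindowSearch(idx, ggf)
  expect_equal(length(found), 2L)
  # no island may span the N run [300, 360)
  expect_true(all(found@end <= 300L | found@start >= 360L))
  expect_equal(found@start[1], 0L)
  expect_equal(found@end[1], 300L)
  # the N gap is < mergeGap bp wide, yet merging must not re-bridge it
  merged <- mergeIslands(found, idx, ggf)
  expect_equal(length(merged), 2L)
})

test_that("island extraction is invariant to FASTA line wrapping", {
  pb <- plantedBlockSeq(n = 1500, blockStart = 400, blockLen = 500,
                        seed = 41)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  writeLines(c(">s", pb$residues), f1)
  writeLines(c(">s", substring(pb$residues,
                               seq(1, nchar(pb$residues), 60),
                               pmin(seq(60, nchar(pb$residues) + 59, 60),
                                    nchar(pb$residues)))), f2)
  ggf <- criteriaPreset("ggf")
  isl1 <- slidingWindowSearch(buildIndex(readFasta(f1)[[1]]), ggf)
  isl2 <- slidingWindowSearch(buildIndex(readFasta(f2)[[1]]), ggf)
  expect_identical(as.data.frame(isl1), as.data.frame(isl2))
})
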