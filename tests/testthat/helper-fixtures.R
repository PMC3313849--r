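# Shared fixtures and independent (string-level) oracles for the tests.
# Everything here recounts composition naively, character by character, so
# it stays independent of the prefix-sum implementation it checks.

# naive per-interval recount of C, G, CpG, valid bases over [start, end)
naiveCounts <- function(residues, start, end) {
  chars <- strsplit(substr(residues, start + 1L, end), "")[[1]]
  nC <- sum(chars == "C")
  nG <- sum(chars == "G")
  nValid <- sum(chars %in% c("A", "C", "G", "T"))
  nCpG <- if (length(chars) >= 2L)
    sum(chars[-length(chars)] == "C" & chars[-1L] == "G")
  else 0L
  list(c = nC, g = nG, cpg = nCpG, valid = nValid)
}

naiveGc <- function(residues, start, end) {
  k <- naiveCounts(residues, start, end)
  if (k$valid == 0) 0 else 100 * (k$c + k$g) / k$valid
}

naiveOe <- function(residues, start, end) {
  k <- naiveCounts(residues, start, end)
  if (k$c == 0 || k$g == 0) 0 else k$cpg * k$valid / (k$c * k$g)
}

reverseComplement <- function(residues) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(residues, "")[[1]]),
                                 collapse = ""))
}

# random A/C/G/T string from R's RNG (seed set by the caller)
randomDna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# per-nucleotide confusion recount from logical coverage vectors
naiveConfusion <- function(predStart, predEnd, refStart, refEnd, n) {
  p <- logical(n); r <- logical(n)
  for (i in seq_along(predStart)) p[(predStart[i] + 1L):predEnd[i]] <- TRUE
  for (i in seq_along(refStart)) r[(refStart[i] + 1L):refEnd[i]] <- TRUE
  c(TP = sum(p & r), FP = sum(p & !r), TN = sum(!p & !r), FN = sum(!p & r))
}

# sequence with a planted high-CpG block (sharp contrast, GC 70 / O-E 1.2
# by default) inside a CpG-depleted background
plantedBlockSeq <- function(n = 2000, blockStart = 700, blockLen = 600,
                            seed = 1, blockGc = 70, blockOe = 1.2) {
  spec <- syntheticGenomeSpec(length = n, nIslands = 0, seed = seed)
  g <- generateGenome(spec)
  res <- g$sequence@residues
  set.seed(seed + 1)
  block <- markovSequence(blockLen, blockGc, blockOe)
  substr(res, blockStart + 1L, blockStart + blockLen) <- block
  list(residues = res, start = blockStart, end = blockStart + blockLen)
}

# deterministic two-peak landscape: a small and a large qualifying CpG
# block separated by wide AT-only ground
twoPeakSeq <- function() {
  paste0(strrep("AT", 250), strrep("CG", 150), strrep("AT", 1500),
         strrep("CG", 600), strrep("AT", 250))
}

nucleotideRecall <- function(predicted, reference, n) {
  cc <- confusionCounts(predicted, reference, n)
  if (cc[["TP"]] + cc[["FN"]] == 0) return(NA_real_)
  cc[["TP"]] / (cc[["TP"]] + cc[["FN"]])
}
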