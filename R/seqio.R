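# FASTA input and BED6 / GFF3 / bedGraph output. Internal coordinates are
# 0-based half-open throughout; BED and bedGraph emit them unchanged, GFF3
# converts to 1-based closed on write. Every writer emits a '#' provenance
# header.

#' Read a FASTA file
#'
#' Records are read with `Biostrings`, validated against the IUPAC DNA
#' alphabet (a violation reports the record and 0-based offset), uppercased,
#' and returned as [GenomeSequence-class] objects; soft-masked (lowercase)
#' records keep a per-record flag. Record ids are the first whitespace
#' token of the header.
#'
#' @param path FASTA file (one or more records, optionally line-wrapped).
#' @return A named list of [GenomeSequence-class] objects, in file order.
#' @export
readFasta <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L)
    stop(sprintf("no records in FASTA file '%s'", path))
  out <- lapply(seq_along(raw), function(i) {
    id <- strsplit(names(raw)[i], "[ \t]")[[1]][1]
    residues <- as.character(raw[[i]])
    bad <- regexpr(sprintf("[^%s%s]",
                           paste(.IUPAC_CODES, collapse = ""),
                           tolower(paste(.IUPAC_CODES, collapse = ""))),
                   residues)
    if (bad > 0L)
      stop(sprintf(
        "record '%s': invalid character '%s' at offset %d", id,
        substr(residues, bad, bad), bad - 1L))
    GenomeSequence(id, residues)
  })
  names(out) <- vapply(out, function(x) x@id, character(1))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs a [GenomeSequence-class] or list of them.
#' @param path output file.
#' @param width line-wrap width, default 70.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path, width = 70) {
  if (is(seqs, "GenomeSequence")) seqs <- list(seqs)
  set <- Biostrings::DNAStringSet(
    vapply(seqs, function(x) x@residues, character(1)))
  names(set) <- vapply(seqs, function(x) x@id, character(1))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

.provHeader <- function(what, provenance) {
  prov <- provenance[nzchar(provenance)]
  sprintf("# CpGscout %s %s%s",
          as.character(utils::packageVersion("CpGscout")), what,
          if (length(prov)) paste0("; ", paste(unique(prov), collapse = "; "))
          else "")
}

.atomicWrite <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path))
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

.asIslandList <- function(islands) {
  if (is(islands, "IslandSet")) islands <- list(islands)
  for (x in islands) validObject(x)
  islands[order(vapply(islands, function(x) x@seqId, character(1)))]
}

#' Write islands as BED6
#'
#' One line per island: chrom, 0-based half-open start/end, name
#' `CpG_island_<k>`, score `round(1000 * min(O/E, 1))`, strand `.`; lines
#' sorted by (chrom, start) under a `#` provenance header.
#'
#' @param islands an [IslandSet-class] or a list of them (one per
#'   sequence).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeIslandsBed <- function(islands, path) {
  islands <- .asIslandList(islands)
  lines <- .provHeader(
    "islands BED6",
    vapply(islands, function(x) x@provenance, character(1)))
  k <- 0L
  for (x in islands) {
    if (length(x) == 0L) next
    score <- round(1000 * pmin(x@oe, 1))
    lines <- c(lines, sprintf("%s\t%d\t%d\tCpG_island_%d\t%d\t.",
                              x@seqId, x@start, x@end,
                              k + seq_along(x@start), score))
    k <- k + length(x)
  }
  .atomicWrite(lines, path)
}

#' Read islands from a BED file
#'
#' Parses with `rtracklayer` (comment and header lines are dropped first)
#' and converts back to the package's 0-based half-open convention.
#'
#' @param path BED file.
#' @param index optional [CompositionIndex-class]; when given, GC% and O/E
#'   are recomputed, otherwise they are `NA`.
#' @return A single [IslandSet-class] (the file's only chromosome) or a
#'   named list of them when the file covers several.
#' @export
readIslandsBed <- function(path, index = NULL) {
  lines <- readLines(path)
  body <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(body) == 0L) {
    if (is.null(index)) stop("empty BED file and no index to name it")
    return(IslandSet(index@seqId))
  }
  con <- textConnection(body)
  on.exit(close(con))
  gr <- rtracklayer::import(con, format = "bed")
  perChrom <- lapply(split(gr, GenomicRanges::seqnames(gr)), function(g) {
    if (length(g) == 0L) return(NULL)
    IslandSet(as.character(GenomicRanges::seqnames(g))[1],
              GenomicRanges::start(g) - 1L, GenomicRanges::end(g),
              index = index)
  })
  perChrom <- Filter(Negate(is.null), perChrom)
  if (length(perChrom) == 1L) perChrom[[1]] else perChrom
}

#' Write islands as GFF3
#'
#' Feature type `CpG_island` in 1-based closed coordinates; attributes
#' carry `length`, `gc_percent` and `oe_ratio`.
#'
#' @inheritParams writeIslandsBed
#' @return `path`, invisibly.
#' @export
writeIslandsGff <- function(islands, path) {
  islands <- .asIslandList(islands)
  lines <- c("##gff-version 3",
             .provHeader("islands GFF3",
                         vapply(islands, function(x) x@provenance,
                                character(1))))
  k <- 0L
  for (x in islands) {
    if (length(x) == 0L) next
    lines <- c(lines, sprintf(
      "%s\tCpGscout\tCpG_island\t%d\t%d\t.\t.\t.\tID=CpG_island_%d;length=%d;gc_percent=%.4f;oe_ratio=%.6f",
      x@seqId, x@start + 1L, x@end, k + seq_along(x@start),
      x@end - x@start, x@gc, x@oe))
    k <- k + length(x)
  }
  .atomicWrite(lines, path)
}

#' Write a track as bedGraph
#'
#' Lines `chrom start end value` in 0-based half-open coordinates under a
#' `#` provenance header.
#'
#' @param track a [Track-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTrackBedgraph <- function(track, path) {
  validObject(track)
  lines <- .provHeader(sprintf("track %s", track@statistic), "")
  if (length(track@start) > 0L)
    lines <- c(lines, sprintf("%s\t%d\t%d\t%.6g", track@seqId, track@start,
                              track@end, track@value))
  .atomicWrite(lines, path)
}
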