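# fixtures built in code: hand-made reads/pileups and small oracles

# an AlignedRead from explicit alleles; sequence derived from emissions
makeRead <- function(id, start, alleles, contig = "ctg", mapq = 60L,
                     hp = NA_integer_) {
  new("AlignedRead", readId = id, contig = contig,
      start = as.integer(start), mapq = as.integer(mapq), strand = "+",
      alleles = alleles,
      sequence = paste(alleles[alleles != "-"], collapse = ""),
      hp = as.integer(hp))
}

# n identical reads covering the whole reference
unanimousReads <- function(refSeq, n, prefix = "r") {
  al <- strsplit(refSeq, "", fixed = TRUE)[[1]]
  lapply(seq_len(n), function(i)
    makeRead(sprintf("%s%02d", prefix, i), 1L, al))
}

# random pileup with unlinked per-column substitution errors: each column
# independently corrupts a subset of <= maxFrac reads to one wrong base
randomErrorPileup <- function(L, nReads, maxFrac = 0.2) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, L, replace = TRUE)
  mat <- matrix(rep(ref, nReads), nrow = nReads, byrow = TRUE)
  for (p in seq_len(L)) {
    nerr <- sample(0:floor(maxFrac * nReads), 1L)
    if (nerr == 0L) next
    rows <- sample.int(nReads, nerr)
    mat[rows, p] <- sample(setdiff(bases, ref[p]), 1L)
  }
  reads <- lapply(seq_len(nReads), function(i)
    makeRead(sprintf("r%02d", i), 1L, mat[i, ]))
  buildPileup(paste(ref, collapse = ""), reads, "ctg")
}

# column-wise majority oracle with the same tie-break as the consensus
# (reference base preferred, then lexicographic)
majorityConsensus <- function(pileup) {
  L <- length(pileup)
  refc <- strsplit(pileup@refSeq, "", fixed = TRUE)[[1]]
  out <- character(L)
  for (p in seq_len(L)) {
    col <- pileupColumn(pileup, p)
    if (!length(col)) { out[p] <- refc[p]; next }
    n <- lengths(col)
    top <- names(col)[n == max(n)]
    out[p] <- if (refc[p] %in% top) refc[p] else sort(top)[1]
  }
  paste(out[out != "-"], collapse = "")
}

# plain Rand index by pair counting
randIndex <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2L) return(1)
  agree <- 0L; total <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    total <- total + 1L
    if ((a[i] == a[j]) == (b[i] == b[j])) agree <- agree + 1L
  }
  agree / total
}

# haplotype label encoded in simulated read names ("..._h1" / "..._h2")
readHap <- function(ids) as.integer(sub("^.*_h", "", ids))

# write SAM lines and load them back as AlignedReads
loadSamLines <- function(lines, ...) {
  p <- tempfile(fileext = ".sam")
  writeSam(lines, p)
  on.exit(unlink(p))
  loadAlignments(p, ...)
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# a diploid toy locus: ref carries the hap1 allele, half the reads carry
# the hap2 allele at `altPos`; the short-read DB holds both haplotypes
toyHetLocus <- function(L = 160L, altPos = 80L, nPerHap = 6L, k = 11L) {
  set.seed(99)
  ref <- randomDna(L)
  refc <- strsplit(ref, "", fixed = TRUE)[[1]]
  altc <- refc
  altc[altPos] <- setdiff(c("A", "C", "G", "T"), refc[altPos])[1]
  alt <- paste(altc, collapse = "")
  reads <- c(
    lapply(seq_len(nPerHap), function(i)
      makeRead(sprintf("a%02d_h1", i), 1L, refc)),
    lapply(seq_len(nPerHap), function(i)
      makeRead(sprintf("b%02d_h2", i), 1L, altc)))
  db <- buildKmerDB(c(ref, ref, alt, alt), k = k, minCount = 2)
  list(ref = ref, alt = alt, reads = reads, db = db,
       pileup = buildPileup(ref, reads, "ctg"), altPos = altPos, k = k)
}

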