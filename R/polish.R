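#' @include phasing.R
NULL

#' Resolve one residual low-quality region
#'
#' After phasing and the final consensus pass, a few LQRs may remain. They
#' are resolved conservatively from the spanning-read window subsequences
#' collected in the region's [LqrKmerSet-class], validated K-mer by K-mer
#' against the short-read database:
#' \itemize{
#'   \item no fully validated candidate: the reference window is kept
#'     verbatim (rule \code{reference_kmer}) -- the way to avoid
#'     overcorrection when short reads cannot vouch for any alternative;
#'   \item exactly one validated candidate: it is chosen (rule
#'     \code{majority});
#'   \item several validated candidates: the best-supported one wins --
#'     ranked by number of supporting reads, then by the database count of
#'     the weakest constituent K-mer, then reference match, then
#'     lexicographic order (rule \code{best_count_kmer}). Read support
#'     ranks first because a sequencing error touching a homopolymer run
#'     at the window edge produces a candidate that is a genuine genome
#'     substring and therefore passes K-mer validation; among
#'     equally-supported (genuinely ambiguous) candidates the database
#'     count decides.
#' }
#'
#' @param lqr the residual region (GRanges of length 1)
#' @param kmerSet its [LqrKmerSet-class] from [extractLqrKmers()]
#' @param refSeq the contig sequence
#' @param dbs a [KmerDB-class] or list of them
#' @return list with \code{seq} (the chosen window sequence), \code{rule},
#'   and \code{window} (1-based closed bounds the sequence replaces)
#' @export
resolveResidualLqr <- function(lqr, kmerSet, refSeq, dbs) {
  if (is(dbs, "KmerDB")) dbs <- list(dbs)
  k <- if (length(kmerSet@allValid)) nchar(kmerSet@allValid[1])
       else kmerLength(dbs[[1]])
  ws <- kmerSet@window[1]; we <- kmerSet@window[2]
  refWindow <- substr(refSeq, ws, we)
  support <- table(unname(kmerSet@perReadSeq))
  cand <- names(support)
  validCand <- character(0); candCount <- integer(0); candSupp <- integer(0)
  db <- dbs[[match(k, vapply(dbs, kmerLength, integer(1)))]]
  for (sq in cand) {
    if (nchar(sq) < k) next
    kms <- .kmer_windows_cpp(sq, as.integer(k), TRUE)
    if (anyNA(kms)) next
    if (!all(isValidKmer(dbs, kms))) next
    validCand <- c(validCand, sq)
    candCount <- c(candCount, min(queryCount(db, kms)))
    candSupp <- c(candSupp, as.integer(support[[sq]]))
  }
  if (length(validCand) == 0L)
    return(list(seq = refWindow, rule = "reference_kmer",
                window = c(ws, we)))
  if (length(validCand) == 1L)
    return(list(seq = validCand, rule = "majority", window = c(ws, we)))
  # rank: read support (a sequencing error touching a homopolymer run at
  # the window edge yields a fully valid artefact, so K-mer validity alone
  # cannot reject it), then weakest-link database count, then reference
  # match, then lexicographic
  ord <- order(-candSupp, -candCount, validCand != refWindow, validCand)
  list(seq = validCand[ord[1]], rule = "best_count_kmer",
       window = c(ws, we))
}

# transitively merge LQRs closer than `gap` so their padded extraction
# windows never overlap during splicing
.mergeWindowOverlaps <- function(lqrs, gap) {
  if (length(lqrs) < 2L) return(lqrs)
  st <- start(lqrs); en <- end(lqrs)
  lq <- mcols(lqrs)$lqps
  grp <- cumsum(c(1L, as.integer(st[-1] - en[-length(en)] > gap)))
  if (all(grp == seq_along(grp))) return(lqrs)
  newSt <- tapply(st, grp, min)
  newEn <- tapply(en, grp, max)
  out <- GRanges(seqnames = as.character(seqnames(lqrs))[1],
                 ranges = IRanges(as.integer(newSt), as.integer(newEn)))
  mcols(out)$lqps <- IntegerList(lapply(split(seq_along(lqrs), grp),
    function(ix) sort(unique(unlist(lq[ix])))))
  out
}

#' Polish one contig
#'
#' Full per-contig pipeline: iterative phasing ([iteratePhasing()]) to
#' discard reads from conflicting haplotype/repeat communities, a final KSC
#' consensus from the surviving reads, and residual-LQR resolution
#' ([resolveResidualLqr()]) spliced into the consensus by reference
#' coordinates. A contig with no usable reads is returned unchanged with a
#' warning.
#'
#' @param contigSeq the draft contig sequence (character or DNAString)
#' @param reads list of [AlignedRead-class] mapped to this contig
#' @param dbs a [KmerDB-class] or list of them
#' @param contig contig name
#' @inheritParams iteratePhasing
#' @return list with \code{sequence} (polished contig), \code{report}
#'   (a [PolishReport-class]), and \code{phasing} (the [iteratePhasing()]
#'   result, including its per-iteration history)
#' @export
polishContig <- function(contigSeq, reads, dbs, contig = NULL,
                         chainK = 3L, lqpThreshold = 0.95,
                         mergeGap = NULL, pad = NULL,
                         mode = c("reference", "largest"),
                         maxIters = 5L, seed = 1L) {
  mode <- match.arg(mode)
  contigSeq <- toupper(as.character(contigSeq))
  L <- nchar(contigSeq)
  if (is(dbs, "KmerDB")) dbs <- list(dbs)
  k <- kmerLength(dbs[[1]])
  if (is.null(mergeGap)) mergeGap <- k
  if (is.null(pad)) pad <- 0L
  emptyReport <- function(ctg) new("PolishReport", contig = ctg,
    nLqrsInitial = 0L, nIterations = 0L, nReadsDiscarded = 0L,
    converged = TRUE,
    residualResolutions = data.frame(lqrStart = integer(0),
      lqrEnd = integer(0), windowStart = integer(0), windowEnd = integer(0),
      rule = character(0), seq = character(0)),
    edits = data.frame(position = integer(0), ref = character(0),
                       alt = character(0)),
    iterationLog = data.frame())
  if (!length(reads)) {
    warning("contig has zero coverage; returned unchanged")
    return(list(sequence = contigSeq,
                report = emptyReport(if (is.null(contig)) "contig"
                                     else contig)))
  }
  ph <- iteratePhasing(reads, contigSeq, dbs, contig = contig,
                       chainK = chainK, lqpThreshold = lqpThreshold,
                       mergeGap = mergeGap, pad = pad, mode = mode,
                       maxIters = maxIters, seed = seed)
  if (!length(ph$reads)) {
    warning("all reads discarded during phasing; contig returned unchanged")
    return(list(sequence = contigSeq,
                report = emptyReport(if (is.null(contig)) "contig"
                                     else contig)))
  }
  pileup <- buildPileup(contigSeq, ph$reads, contig)
  cons <- kscConsensus(pileup, chainK)
  em <- cons$trace$allele
  em[em == "-"] <- ""
  refc <- strsplit(contigSeq, "", fixed = TRUE)[[1]]
  # residual regions left after phasing
  lqps <- detectLqps(cons$trace, lqpThreshold)
  rrRows <- list(); windowEdits <- list()
  inWindow <- rep(FALSE, L)
  if (length(lqps)) {
    lqrs <- mergeLqrs(lqps, L, mergeGap, pad, pileup@contig)
    # LQRs whose K-mer-padded windows would overlap are spliced as one
    lqrs <- .mergeWindowOverlaps(lqrs, 2L * (k - 1L))
    for (i in seq_along(lqrs)) {
      ks <- extractLqrKmers(pileup, lqrs[i], dbs, k)
      res <- resolveResidualLqr(lqrs[i], ks, contigSeq, dbs)
      ws <- res$window[1]; we <- res$window[2]
      refWindow <- substr(contigSeq, ws, we)
      inWindow[ws:we] <- TRUE
      if (res$rule == "reference_kmer" || res$seq == refWindow) {
        em[ws:we] <- refc[ws:we]
      } else {
        em[ws] <- res$seq
        if (we > ws) em[(ws + 1L):we] <- ""
        windowEdits[[length(windowEdits) + 1L]] <- data.frame(
          position = ws, ref = refWindow, alt = res$seq,
          stringsAsFactors = FALSE)
      }
      rrRows[[length(rrRows) + 1L]] <- data.frame(
        lqrStart = start(lqrs[i]), lqrEnd = end(lqrs[i]),
        windowStart = ws, windowEnd = we, rule = res$rule, seq = res$seq,
        stringsAsFactors = FALSE)
    }
  }
  finalSeq <- paste(em, collapse = "")
  changed <- which(em != refc & !inWindow)
  editsDf <- rbind(
    data.frame(position = changed, ref = refc[changed], alt = em[changed],
               stringsAsFactors = FALSE),
    if (length(windowEdits)) do.call(rbind, windowEdits))
  editsDf <- editsDf[order(editsDf$position), , drop = FALSE]
  rownames(editsDf) <- NULL
  nLqrsInitial <- if (!is.null(ph$log) && nrow(ph$log)) ph$log$nLqrs[1]
                  else 0L
  report <- new("PolishReport", contig = pileup@contig,
    nLqrsInitial = as.integer(nLqrsInitial),
    nIterations = ph$iterations,
    nReadsDiscarded = length(ph$discarded), converged = ph$converged,
    residualResolutions = if (length(rrRows)) do.call(rbind, rrRows)
      else data.frame(lqrStart = integer(0), lqrEnd = integer(0),
                      windowStart = integer(0), windowEnd = integer(0),
                      rule = character(0), seq = character(0)),
    edits = editsDf,
    iterationLog = if (is.null(ph$log)) data.frame() else ph$log)
  list(sequence = finalSeq, report = report, phasing = ph)
}

#' Polish a whole assembly
#'
#' Convenience wrapper running [polishContig()] per contig of an assembly,
#' loading reads per contig from one alignment file.
#'
#' @param assembly path to a FASTA file or a named [Biostrings::DNAStringSet]
#'   / named character vector of contigs
#' @param alignments path to a SAM/BAM of long reads mapped to the assembly
#' @param dbs a [KmerDB-class] or list of them
#' @param minMapq mapping-quality filter for [loadAlignments()]
#' @param ... forwarded to [polishContig()]
#' @return list with \code{sequences} (named character vector of polished
#'   contigs) and \code{reports} (named list of [PolishReport-class])
#' @export
polishAssembly <- function(assembly, alignments, dbs, minMapq = 1L, ...) {
  contigs <- if (is.character(assembly) && length(assembly) == 1L &&
                 file.exists(assembly)) {
    as.character(readDNAStringSet(assembly))
  } else as.character(assembly)
  if (is.null(names(contigs)))
    stop("assembly contigs must be named")
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  reads <- loadAlignments(alignments, minMapq = minMapq)
  byCtg <- split(reads, vapply(reads, function(r) r@contig, character(1)))
  out <- character(0); reports <- list()
  for (ctg in names(contigs)) {
    rd <- byCtg[[ctg]]
    if (is.null(rd)) rd <- list()
    res <- polishContig(contigs[[ctg]], rd, dbs, contig = ctg, ...)
    out[[ctg]] <- res$sequence
    reports[[ctg]] <- res$report
  }
  list(sequences = out, reports = reports)
}

#' Write polished contigs as FASTA (80-column wrapped)
#'
#' @param sequences named character vector of contigs
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeFasta <- function(sequences, path) {
  writeXStringSet(DNAStringSet(sequences), path, width = 80L)
  invisible(path)
}

#' Write the edits of a polishing report as a VCF-like TSV
#'
#' Columns contig, pos (1-based), ref, alt; deletions have alt "" and
#' insertions a multi-base alt anchored at pos.
#'
#' @param report a [PolishReport-class]
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeEdits <- function(report, path) {
  ed <- edits(report)
  df <- data.frame(contig = rep(report@contig, nrow(ed)),
                   pos = ed$position, ref = ed$ref, alt = ed$alt)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
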