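#' @include alignment_io.R
NULL

#' K-mer score chain consensus with traceback
#'
#' Runs the KSC dynamic program over a pileup. Each (position, allele) node
#' scores as the best predecessor score plus the read count of the chain-mer
#' formed by the last \code{chainK} alleles on the predecessor's best path
#' ending in this allele, minus the column's valid depth; the score of a
#' node with no predecessor is its supporter count at the first column
#' minus that column's depth. Traceback from the best final node yields the
#' consensus: deletion alleles contribute no base, insertion alleles
#' contribute their full string. Zero-coverage columns emit the reference
#' base and carry support 0 (they are always flagged low-quality
#' downstream).
#'
#' Score ties prefer the allele matching the reference base, then the
#' lexicographically smaller allele, keeping the result deterministic and
#' conservative toward the input assembly.
#'
#' @param pileup a [ReadPileup-class] with at least one read
#' @param chainK chain-mer length; default 3
#' @return list with elements \code{consensus} (character), \code{trace}
#'   (data.frame with 1-based \code{position}, chosen \code{allele},
#'   \code{support} fraction of the column's valid depth, and \code{depth}),
#'   and \code{finalScore}
#' @export
kscConsensus <- function(pileup, chainK = 3L) {
  if (length(pileup@readIds) == 0L)
    stop("pileup contains no reads")
  chainK <- as.integer(chainK)
  if (chainK < 2L) stop("chainK must be >= 2")
  res <- .ksc_core_cpp(pileup@refSeq, pileup@alleleList,
                       pileup@starts - 1L, chainK)
  list(consensus = res$consensus,
       trace = data.frame(position = seq_len(nchar(pileup@refSeq)),
                          allele = res$allele, support = res$support,
                          depth = res$depth, stringsAsFactors = FALSE),
       finalScore = res$final_score)
}

#' Detect low-quality positions on a consensus traceback
#'
#' A position is low quality (LQP) when the chosen allele accounts for at
#' most \code{threshold} of the column's valid depth -- the boundary is
#' inclusive, so support exactly at the threshold is flagged. Zero-depth
#' positions are always LQPs.
#'
#' @param trace traceback data.frame from [kscConsensus()]
#' @param threshold support fraction cutoff in (0, 1]; default 0.95
#' @return integer vector of 1-based LQP positions
#' @export
detectLqps <- function(trace, threshold = 0.95) {
  stopifnot(threshold > 0, threshold <= 1)
  trace$position[trace$support <= threshold | trace$depth == 0L]
}

#' Merge adjacent low-quality positions into regions
#'
#' Consecutive LQPs closer than \code{mergeGap} bases join one low-quality
#' region (LQR); each region is then padded by \code{pad} bases on both
#' sides and clipped to the contig. The default gap is the validation K,
#' and the default pad is 0: K-mer extraction
#' ([extractLqrKmers()]) adds its own K - 1 window on each side, which
#' already guarantees that every extracted K-mer overlaps a member LQP --
#' padding here as well would dilute the region's K-mer set with flanking
#' K-mers shared between haplotypes.
#'
#' @param positions sorted integer vector of 1-based LQP positions
#' @param contigLen contig length in bases
#' @param mergeGap merge distance; default 21
#' @param pad extra padding in bases; default 0
#' @param contig contig name for the returned ranges
#' @return [GenomicRanges::GRanges] with metadata column \code{lqps}
#'   (IntegerList of member positions)
#' @export
mergeLqrs <- function(positions, contigLen, mergeGap = 21L, pad = 0L,
                      contig = "contig") {
  stopifnot(mergeGap >= 0L, pad >= 0L)
  if (!length(positions))
    return(GRanges(seqnames = character(0),
                   ranges = IRanges(integer(0), integer(0)),
                   lqps = IntegerList()))
  positions <- sort(as.integer(positions))
  grp <- cumsum(c(1L, as.integer(diff(positions) >= mergeGap)))
  members <- split(positions, grp)
  lo <- vapply(members, min, integer(1))
  hi <- vapply(members, max, integer(1))
  gr <- GRanges(seqnames = contig,
                ranges = IRanges(start = pmax(1L, lo - pad),
                                 end = pmin(as.integer(contigLen), hi + pad)))
  mcols(gr)$lqps <- IntegerList(unname(members))
  gr
}

#' Export low-quality regions as BED
#'
#' Writes LQRs in 0-based half-open BED3 coordinates.
#'
#' @param lqrs [GenomicRanges::GRanges] from [mergeLqrs()]
#' @param path output path
#' @return \code{path}, invisibly
#' @export
lqrsToBed <- function(lqrs, path) {
  df <- data.frame(chrom = as.character(seqnames(lqrs)),
                   start = start(lqrs) - 1L, end = end(lqrs))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
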