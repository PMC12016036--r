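#' @include AllClasses.R
NULL

#' K-mer length of a database
#' @param x a [KmerDB-class]
#' @return integer K length
#' @export
setGeneric("kmerLength", function(x) standardGeneric("kmerLength"))

#' @rdname kmerLength
#' @export
setMethod("kmerLength", "KmerDB", function(x) x@k)

#' Validity threshold of a database
#' @param x a [KmerDB-class]
#' @return integer minimum count
#' @export
setGeneric("minCount", function(x) standardGeneric("minCount"))

#' @rdname minCount
#' @export
setMethod("minCount", "KmerDB", function(x) x@minCount)

#' Number of stored K-mers
#' @param x a [KmerDB-class]
#' @export
setMethod("length", "KmerDB", function(x) length(ls(x@counts)))

setMethod("show", "KmerDB", function(object) {
  cat(sprintf("KmerDB: %d canonical %d-mers (min count %d)\n",
              length(object), object@k, object@minCount))
})

#' Read id accessor
#' @param x an [AlignedRead-class] or [ReadPileup-class]
#' @export
setGeneric("readIds", function(x) standardGeneric("readIds"))

#' @rdname readIds
#' @export
setMethod("readIds", "AlignedRead", function(x) x@readId)

#' @rdname readIds
#' @export
setMethod("readIds", "ReadPileup", function(x) x@readIds)

#' Alignment start / end (1-based, closed)
#' @param x an [AlignedRead-class]
#' @export
setGeneric("alignStart", function(x) standardGeneric("alignStart"))

#' @rdname alignStart
#' @export
setMethod("alignStart", "AlignedRead", function(x) x@start)

#' @rdname alignStart
#' @export
setGeneric("alignEnd", function(x) standardGeneric("alignEnd"))

#' @rdname alignStart
#' @export
setMethod("alignEnd", "AlignedRead",
          function(x) x@start + length(x@alleles) - 1L)

setMethod("show", "AlignedRead", function(object) {
  cat(sprintf("AlignedRead %s: %s:%d-%d mapq %d (%s)\n", object@readId,
              object@contig, object@start, alignEnd(object), object@mapq,
              object@strand))
})

#' Contig length covered by a pileup
#' @param x a [ReadPileup-class]
#' @export
setMethod("length", "ReadPileup", function(x) nchar(x@refSeq))

#' Per-position valid depth
#'
#' Number of reads contributing an allele at each reference position after
#' alignment filters (the "valid depth" entering the consensus score).
#'
#' @param x a [ReadPileup-class]
#' @return integer vector, one entry per reference position
#' @export
setGeneric("validDepth", function(x) standardGeneric("validDepth"))

#' @rdname validDepth
#' @export
setMethod("validDepth", "ReadPileup", function(x) {
  L <- nchar(x@refSeq)
  d <- integer(L + 1L)
  if (length(x@starts)) {
    ends <- x@starts + lengths(x@alleleList)
    for (i in seq_along(x@starts)) {
      d[x@starts[i]] <- d[x@starts[i]] + 1L
      d[ends[i]] <- d[ends[i]] - 1L
    }
  }
  cumsum(d)[seq_len(L)]
})

setMethod("show", "ReadPileup", function(object) {
  d <- validDepth(object)
  cat(sprintf("ReadPileup on %s: %d bp, %d reads, mean depth %.1f\n",
              object@contig, nchar(object@refSeq), length(object@readIds),
              mean(d)))
})

#' Community labels of a read graph
#' @param x a [ReadGraph-class]
#' @return named integer vector (NA before Louvain has run)
#' @export
setGeneric("communities", function(x) standardGeneric("communities"))

#' @rdname communities
#' @export
setMethod("communities", "ReadGraph", function(x) x@communities)

#' Conflicting community pairs
#'
#' Pairs of communities whose summed signed inter-community edge weight is
#' negative: reads covering the same region but carrying different
#' haplotype or repeat-copy K-mers.
#'
#' @param x a [ReadGraph-class]
#' @return data.frame with columns c1, c2, weight (weight < 0 rows only)
#' @export
setGeneric("conflictPairs", function(x) standardGeneric("conflictPairs"))

#' @rdname conflictPairs
#' @export
setMethod("conflictPairs", "ReadGraph", function(x) {
  cp <- x@communityPairs
  cp[cp$weight < 0, , drop = FALSE]
})

setMethod("show", "ReadGraph", function(object) {
  ncom <- length(unique(object@communities[!is.na(object@communities)]))
  cat(sprintf(
    "ReadGraph: %d reads, %d edges, %d communities, %d conflict pairs\n",
    length(object@nodes), nrow(object@edges), ncom,
    nrow(conflictPairs(object))))
})

#' Edits applied by a polishing run
#' @param x a [PolishReport-class]
#' @return data.frame with columns position, ref, alt
#' @export
setGeneric("edits", function(x) standardGeneric("edits"))

#' @rdname edits
#' @export
setMethod("edits", "PolishReport", function(x) x@edits)

setMethod("show", "PolishReport", function(object) {
  cat(sprintf(paste0(
    "PolishReport for %s: %d initial LQRs, %d iterations (%s), ",
    "%d reads discarded, %d edits, %d residual resolutions\n"),
    object@contig, object@nLqrsInitial, object@nIterations,
    if (object@converged) "converged" else "iteration budget hit",
    object@nReadsDiscarded, nrow(object@edits),
    nrow(object@residualResolutions)))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0(
    "SimConfig: %d bp, het %.3g, %d repeat copies, %gx HiFi ",
    "(err %.2g, hp x%g), %gx short reads, seed %d\n"),
    object@genomeLength, object@hetRate, object@nRepeatCopies,
    object@hifiCoverage, object@hifiErrorRate,
    object@homopolymerErrorMultiplier, object@srCoverage, object@seed))
})
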