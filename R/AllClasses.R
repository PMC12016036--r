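#' @include hifipolish-package.R
NULL

#' KmerDB: canonical K-mer count database
#'
#' Holds canonical K-mer counts for one K length, built from high-accuracy
#' short reads, together with the validity threshold \code{minCount}. K-mers
#' are stored in canonical form (the lexicographic minimum of a K-mer and its
#' reverse complement), so querying a K-mer and its reverse complement
#' returns the same count. K-mers whose total count fell below
#' \code{minCount} at build time are dropped.
#'
#' @slot k integer, K-mer length in bases (2--32).
#' @slot minCount integer, minimum count for a K-mer to be considered valid.
#' @slot counts environment mapping canonical K-mer to its positive count.
#'
#' @seealso [buildKmerDB()], [queryCount()], [isValidKmer()]
#' @export
setClass("KmerDB",
  representation(k = "integer", minCount = "integer", counts = "environment"))

setValidity("KmerDB", function(object) {
  msg <- character()
  if (length(object@k) != 1L || is.na(object@k) || object@k < 2L)
    msg <- c(msg, "k must be a single integer >= 2")
  if (length(object@minCount) != 1L || is.na(object@minCount) ||
      object@minCount < 1L)
    msg <- c(msg, "minCount must be a single integer >= 1")
  if (length(msg)) msg else TRUE
})

#' AlignedRead: one long read aligned to a contig
#'
#' A parsed alignment record reduced to the per-reference-column allele
#' representation the consensus algorithm consumes: one allele per covered
#' reference position -- a base, \code{"-"} for a deletion, or the anchor
#' base concatenated with inserted bases for an insertion (insertions are
#' attached to the reference column of their left anchor base).
#'
#' Coordinates are 1-based and closed; \code{start} is the first covered
#' reference position and the covered span is
#' \code{start:(start + length(alleles) - 1)}.
#'
#' @slot readId character, read name.
#' @slot contig character, reference contig name.
#' @slot start integer, 1-based first covered reference position.
#' @slot mapq integer mapping quality.
#' @slot strand character, "+" or "-".
#' @slot alleles character vector, one allele per covered reference column.
#' @slot sequence character, the read sequence (soft clips removed,
#'   reference orientation).
#' @slot hp integer, haplotype tag (HP) when present, else NA.
#' @export
setClass("AlignedRead",
  representation(readId = "character", contig = "character",
    start = "integer", mapq = "integer", strand = "character",
    alleles = "character", sequence = "character", hp = "integer"))

setValidity("AlignedRead", function(object) {
  msg <- character()
  if (length(object@alleles) < 1L)
    msg <- c(msg, "alleles must be non-empty")
  if (length(object@start) != 1L || is.na(object@start) || object@start < 1L)
    msg <- c(msg, "start must be a positive position")
  if (length(msg)) msg else TRUE
})

#' ReadPileup: per-contig pileup of read alleles
#'
#' Column-indexable view of a set of [AlignedRead] objects on one contig.
#' Reads are stored densely (per-read allele vectors plus start offsets);
#' per-column allele maps are materialised on demand with [pileupColumn()],
#' and the per-position valid depth (number of reads contributing an allele
#' after filters) with [validDepth()].
#'
#' @slot contig character contig name.
#' @slot refSeq character, the contig sequence.
#' @slot readIds character vector of read names.
#' @slot starts integer vector of 1-based read start positions.
#' @slot alleleList list of per-read allele character vectors.
#' @slot hp integer vector of haplotype tags (NA when absent).
#' @export
setClass("ReadPileup",
  representation(contig = "character", refSeq = "character",
    readIds = "character", starts = "integer", alleleList = "list",
    hp = "integer"))

setValidity("ReadPileup", function(object) {
  n <- length(object@readIds)
  if (length(object@starts) != n || length(object@alleleList) != n)
    return("readIds, starts and alleleList must have equal length")
  L <- nchar(object@refSeq)
  ends <- object@starts + lengths(object@alleleList) - 1L
  if (n > 0L && any(ends > L))
    return("read coordinates exceed contig length")
  TRUE
})

#' LqrKmerSet: validated K-mers of reads spanning one low-quality region
#'
#' For one LQR, the K-mers extracted from each long read that maps across
#' the K-mer-padded LQR window, after removal of K-mers not validated by the
#' short-read database. A set with >= 2 distinct valid K-mers is classified
#' heterozygous (two haplotypes or repeat copies are present).
#'
#' @slot lqr GRanges of length 1, the low-quality region.
#' @slot window integer of length 2, 1-based closed bounds of the padded
#'   extraction window.
#' @slot perRead named list; per spanning read, its ordered valid K-mers
#'   (canonical form) over the window.
#' @slot perReadSeq named character; per spanning read, its window
#'   subsequence (used for residual-region resolution).
#' @slot validSeqs character; the distinct window subsequences whose
#'   constituent K-mers are all valid -- the surviving "versions" of the
#'   region.
#' @slot allValid character, union of valid K-mers.
#' @slot counts named integer, short-read database counts of allValid.
#' @slot isHet logical, >= 2 distinct fully validated versions.
#' @export
setClass("LqrKmerSet",
  representation(lqr = "GRanges", window = "integer", perRead = "list",
    perReadSeq = "character", validSeqs = "character",
    allValid = "character", counts = "integer", isHet = "logical"))

setValidity("LqrKmerSet", function(object) {
  if (length(object@window) != 2L)
    return("window must be (start, end)")
  if (!identical(object@isHet, length(object@validSeqs) >= 2L))
    return("isHet must equal |validSeqs| >= 2")
  TRUE
})

#' ReadGraph: signed read graph with community labels
#'
#' Reads are nodes; edge weights accumulate +1 per valid K-mer shared at a
#' heterozygous LQR and -1 per position-equivalent valid K-mer on which two
#' reads differ. Louvain community detection runs on the positive-weight
#' subgraph; the full signed weights define conflict community pairs
#' (inter-community weight < 0: same locus, different haplotype or repeat
#' copy).
#'
#' @slot nodes character, read ids.
#' @slot edges data.frame with columns r1, r2, weight (symmetric, stored
#'   once with r1 < r2).
#' @slot communities named integer, community label per read (NA before
#'   [louvainCommunities()] has run).
#' @slot communityPairs data.frame with columns c1, c2, weight: summed
#'   signed edge weight between communities.
#' @slot readKmers named list, per read the union of its valid K-mers over
#'   heterozygous LQRs.
#' @export
setClass("ReadGraph",
  representation(nodes = "character", edges = "data.frame",
    communities = "integer", communityPairs = "data.frame",
    readKmers = "list"))

setValidity("ReadGraph", function(object) {
  e <- object@edges
  if (nrow(e) > 0L) {
    if (!all(c("r1", "r2", "weight") %in% names(e)))
      return("edges must have columns r1, r2, weight")
    if (any(!c(e$r1, e$r2) %in% object@nodes))
      return("edge endpoints must be graph nodes")
  }
  TRUE
})

#' PolishReport: bookkeeping of one contig's polishing run
#'
#' @slot contig character contig name.
#' @slot nLqrsInitial integer, LQRs found in the first consensus pass.
#' @slot nIterations integer, phasing iterations run.
#' @slot nReadsDiscarded integer, reads removed as conflicting.
#' @slot converged logical, whether all conflict communities were resolved
#'   within the iteration budget.
#' @slot residualResolutions data.frame: one row per residual LQR with
#'   columns lqrStart, lqrEnd, windowStart, windowEnd, rule (one of
#'   "reference_kmer", "best_count_kmer", "majority") and chosen sequence.
#' @slot edits data.frame with columns position, ref, alt (1-based
#'   reference position; alt "" means the reference base was dropped,
#'   multi-base alt means inserted sequence).
#' @slot iterationLog data.frame, one row per phasing iteration.
#' @export
setClass("PolishReport",
  representation(contig = "character", nLqrsInitial = "integer",
    nIterations = "integer", nReadsDiscarded = "integer",
    converged = "logical", residualResolutions = "data.frame",
    edits = "data.frame", iterationLog = "data.frame"))

setValidity("PolishReport", function(object) {
  rr <- object@residualResolutions
  if (nrow(rr) > 0L &&
      !all(rr$rule %in% c("reference_kmer", "best_count_kmer", "majority")))
    return("unknown residual resolution rule")
  TRUE
})

#' SimConfig: synthetic dataset configuration
#'
#' Parameters of the desk-scale diploid/repeat genome and read simulator.
#' Defaults describe a 100-kb diploid genome at 1\% heterozygosity with
#' 30x HiFi-like long reads (99.9\% accurate, homopolymer-biased indels)
#' and 50x accurate short reads; see the methods vignette for rationale.
#'
#' @slot genomeLength integer, haploid genome length in bases.
#' @slot hetRate numeric, per-base heterozygosity of the simulated diploid.
#' @slot nRepeatCopies integer, number of planted near-identical repeat
#'   copies (0 disables repeats).
#' @slot repeatLength integer, repeat copy length in bases.
#' @slot repeatDivergence numeric, per-base divergence between copies.
#' @slot repeatMismapRate numeric, fraction of reads fully inside a repeat
#'   copy that are relocated to the homologous position of another copy
#'   (emulates mapper confusion between near-identical copies).
#' @slot hifiCoverage numeric, HiFi fold coverage.
#' @slot hifiErrorRate numeric, HiFi per-base error rate outside
#'   homopolymers.
#' @slot homopolymerErrorMultiplier numeric >= 1, error-rate multiplier
#'   inside homopolymer runs (length >= 3), where errors become 1-bp indels.
#' @slot hifiReadLength integer, HiFi read length in bases.
#' @slot srCoverage numeric, short-read fold coverage.
#' @slot srErrorRate numeric, short-read substitution error rate.
#' @slot srReadLength integer, short-read length in bases.
#' @slot seed integer, fixes all randomness of the simulator.
#' @seealso [simConfig()], [simulateDiploid()], [simulateReads()]
#' @export
setClass("SimConfig",
  representation(genomeLength = "integer", hetRate = "numeric",
    nRepeatCopies = "integer", repeatLength = "integer",
    repeatDivergence = "numeric", repeatMismapRate = "numeric",
    hifiCoverage = "numeric", hifiErrorRate = "numeric",
    homopolymerErrorMultiplier = "numeric", hifiReadLength = "integer",
    srCoverage = "numeric", srErrorRate = "numeric",
    srReadLength = "integer", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  rates <- c(het = object@hetRate, div = object@repeatDivergence,
             mismap = object@repeatMismapRate, hifiErr = object@hifiErrorRate,
             srErr = object@srErrorRate)
  if (any(rates < 0 | rates > 1))
    msg <- c(msg, "rates must lie in [0, 1]")
  lens <- c(object@genomeLength, object@repeatLength,
            object@hifiReadLength, object@srReadLength)
  if (any(lens < 1L)) msg <- c(msg, "lengths must be positive")
  if (object@homopolymerErrorMultiplier < 1)
    msg <- c(msg, "homopolymerErrorMultiplier must be >= 1")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (length(msg)) msg else TRUE
})
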