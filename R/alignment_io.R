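#' @include kmer_db.R
NULL

#' Load long-read-to-assembly alignments
#'
#' Parses a SAM (or BAM) file into [AlignedRead-class] objects. Secondary
#' (0x100) and supplementary (0x800) records, unmapped records, and records
#' below \code{minMapq} are dropped. The CIGAR of each surviving record is
#' walked into the per-reference-column allele representation: match
#' columns (\code{M}, \code{=}, \code{X}) carry the read base, deleted
#' reference columns carry \code{"-"}, and inserted bases are appended to
#' the allele of their left anchor column. Soft clips are skipped; hard
#' clips ignored.
#'
#' @param samPath path to a SAM or BAM file with a valid header
#' @param region optional \code{"contig"} or \code{"contig:start-end"}
#'   (1-based, closed); only overlapping reads are returned
#' @param minMapq minimum mapping quality; default 1 excludes multimappers
#'   reported at MAPQ 0
#' @return list of [AlignedRead-class]
#' @export
loadAlignments <- function(samPath, region = NULL, minMapq = 1L) {
  if (!file.exists(samPath)) stop("alignment file not found: ", samPath)
  bam <- if (grepl("\\.bam$", samPath, ignore.case = TRUE)) samPath else {
    first <- readLines(samPath, n = 1L)
    if (!length(first) || !startsWith(first, "@"))
      stop("malformed SAM (missing header) in ", samPath)
    dest <- tempfile(fileext = "")
    tryCatch(
      Rsamtools::asBam(samPath, dest, overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) stop("malformed SAM (missing header or invalid ",
                               "record) in ", samPath, ": ",
                               conditionMessage(e)))
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"),
    tag = "HP")
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(rec$qname)
  if (n == 0L) return(list())
  keep <- bitwAnd(rec$flag, 0x4L) == 0L &      # mapped
    bitwAnd(rec$flag, 0x100L) == 0L &          # not secondary
    bitwAnd(rec$flag, 0x800L) == 0L &          # not supplementary
    rec$mapq >= minMapq & !is.na(rec$pos)
  hp <- rec$tag$HP
  if (is.null(hp)) hp <- rep(NA_integer_, n)
  out <- vector("list", sum(keep))
  j <- 0L
  for (i in which(keep)) {
    walked <- .cigarWalk(rec$cigar[i], as.character(rec$seq[i]),
                         rec$qname[i])
    j <- j + 1L
    out[[j]] <- new("AlignedRead", readId = rec$qname[i],
      contig = as.character(rec$rname[i]), start = rec$pos[i],
      mapq = rec$mapq[i],
      strand = if (bitwAnd(rec$flag[i], 0x10L)) "-" else "+",
      alleles = walked$alleles, sequence = walked$sequence,
      hp = as.integer(hp[i]))
  }
  if (!is.null(region)) {
    m <- regmatches(region,
      regexec("^([^:]+)(?::(\\d+)-(\\d+))?$", region))[[1]]
    if (length(m) == 0L) stop("cannot parse region: ", region)
    ctg <- m[2]
    rs <- if (nzchar(m[3])) as.integer(m[3]) else 1L
    re <- if (nzchar(m[4])) as.integer(m[4]) else .Machine$integer.max
    out <- Filter(function(r)
      r@contig == ctg && alignEnd(r) >= rs && r@start <= re, out)
  }
  out
}

# expand one CIGAR/SEQ pair into per-reference-column alleles
.cigarWalk <- function(cigar, seq, qname = "?") {
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cigar)[[1]]
  if (m[1] == -1L) stop("unparseable CIGAR '", cigar, "' in record ", qname)
  toks <- regmatches(cigar, gregexpr("\\d+|[A-Z=]", cigar))[[1]]
  lens <- as.integer(toks[c(TRUE, FALSE)])
  ops <- toks[c(FALSE, TRUE)]
  if (any(!ops %in% c("M", "I", "D", "S", "H", "=", "X", "P")))
    stop("unsupported CIGAR op '",
         ops[which(!ops %in% c("M", "I", "D", "S", "H", "=", "X", "P"))[1]],
         "' in record ", qname)
  seqc <- strsplit(seq, "", fixed = TRUE)[[1]]
  refLen <- sum(lens[ops %in% c("M", "D", "=", "X")])
  alleles <- character(refLen)
  qpos <- 0L; rpos <- 0L
  for (i in seq_along(ops)) {
    len <- lens[i]
    switch(ops[i],
      "M" = , "=" = , "X" = {
        alleles[rpos + seq_len(len)] <- seqc[qpos + seq_len(len)]
        qpos <- qpos + len; rpos <- rpos + len
      },
      "I" = {
        ins <- paste(seqc[qpos + seq_len(len)], collapse = "")
        if (rpos > 0L)  # leading insertion has no anchor column; drop
          alleles[rpos] <- paste0(alleles[rpos], ins)
        qpos <- qpos + len
      },
      "D" = {
        alleles[rpos + seq_len(len)] <- "-"
        rpos <- rpos + len
      },
      "S" = {
        qpos <- qpos + len
      },
      "H" = NULL, "P" = NULL)
  }
  # sequence slot keeps the aligned portion (soft clips removed)
  softmask <- rep(TRUE, length(seqc))
  qp <- 0L
  for (i in seq_along(ops)) {
    if (ops[i] %in% c("M", "=", "X", "I")) qp <- qp + lens[i]
    else if (ops[i] == "S") {
      softmask[qp + seq_len(lens[i])] <- FALSE
      qp <- qp + lens[i]
    }
  }
  list(alleles = alleles,
       sequence = paste(seqc[softmask], collapse = ""))
}

#' Build a per-contig pileup of read alleles
#'
#' Collects [AlignedRead-class] objects from one contig into a
#' [ReadPileup-class]. Reads on other contigs raise an error, as do reads
#' whose alignment extends beyond the contig sequence.
#'
#' @param contigSeq contig sequence (character or DNAString)
#' @param reads list of [AlignedRead-class]
#' @param contig contig name; default taken from the reads (or "contig"
#'   when no reads are given)
#' @return a [ReadPileup-class]
#' @export
buildPileup <- function(contigSeq, reads, contig = NULL) {
  contigSeq <- toupper(as.character(contigSeq))
  if (length(reads)) {
    ctgs <- unique(vapply(reads, function(r) r@contig, character(1)))
    if (length(ctgs) > 1L)
      stop("reads span multiple contigs: ", paste(ctgs, collapse = ", "))
    if (is.null(contig)) contig <- ctgs
    ends <- vapply(reads, alignEnd, integer(1))
    if (any(ends > nchar(contigSeq)))
      stop("read coordinates exceed contig length")
  }
  if (is.null(contig)) contig <- "contig"
  new("ReadPileup", contig = contig, refSeq = contigSeq,
      readIds = vapply(reads, function(r) r@readId, character(1)),
      starts = vapply(reads, function(r) r@start, integer(1)),
      alleleList = lapply(reads, function(r) r@alleles),
      hp = vapply(reads, function(r) r@hp, integer(1)))
}

#' Alleles at one pileup column
#'
#' @param pileup a [ReadPileup-class]
#' @param pos 1-based reference position
#' @return named list: allele string -> character vector of supporting read
#'   ids. Empty list at zero-coverage positions.
#' @export
pileupColumn <- function(pileup, pos) {
  stopifnot(pos >= 1L, pos <= nchar(pileup@refSeq))
  ends <- pileup@starts + lengths(pileup@alleleList) - 1L
  idx <- which(pileup@starts <= pos & ends >= pos)
  if (!length(idx)) return(list())
  al <- vapply(idx, function(i)
    pileup@alleleList[[i]][pos - pileup@starts[i] + 1L], character(1))
  split(pileup@readIds[idx], al)
}

#' Subset a pileup to a set of reads
#'
#' @param pileup a [ReadPileup-class]
#' @param ids read ids to keep
#' @return a [ReadPileup-class]
#' @export
subsetPileup <- function(pileup, ids) {
  keep <- pileup@readIds %in% ids
  new("ReadPileup", contig = pileup@contig, refSeq = pileup@refSeq,
      readIds = pileup@readIds[keep], starts = pileup@starts[keep],
      alleleList = pileup@alleleList[keep], hp = pileup@hp[keep])
}
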