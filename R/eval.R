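#' @include polish.R
NULL

# distinct canonical K-mers of one or more sequences
.kmerSet <- function(seqs, k) {
  res <- .kmer_count_cpp(as.character(seqs), as.integer(k))
  res$kmer
}

#' Count changed K-mers between two assemblies
#'
#' Number of distinct canonical K-mers present in the polished assembly but
#' absent from the original. A single new K-mer of length K can drag in up
#' to 2K - 1 overlapping changed K-mers, so this count scales with, but
#' exceeds, the number of edited sites. Haplotype switch errors inflate
#' this count without inflating [overcorrectionKmers()], because switched
#' K-mers still exist in the sample's short reads.
#'
#' @param polished,original character vectors, DNAStringSets, or FASTA
#'   paths
#' @param k K-mer length (same for both sets); default 21
#' @return integer count
#' @export
changedKmers <- function(polished, original, k = 21L) {
  kp <- .kmerSet(.asSequenceCharacters(polished), k)
  ko <- .kmerSet(.asSequenceCharacters(original), k)
  length(setdiff(kp, ko))
}

#' Count potential overcorrection K-mers
#'
#' Number of distinct canonical K-mers present in the polished assembly but
#' absent from both the original assembly and the short-read K-mer
#' database: sequence the polisher invented. A correct polisher should
#' leave this at (or very near) zero.
#'
#' @param polished,original character vectors, DNAStringSets, or FASTA
#'   paths
#' @param db a [KmerDB-class] built from the same sample's short reads;
#'   its K is used for both assemblies
#' @return integer count
#' @export
overcorrectionKmers <- function(polished, original, db) {
  k <- kmerLength(db)
  kp <- .kmerSet(.asSequenceCharacters(polished), k)
  ko <- .kmerSet(.asSequenceCharacters(original), k)
  new <- setdiff(kp, ko)
  if (!length(new)) return(0L)
  sum(queryCount(db, new) == 0L)
}

#' Read a PAF alignment file
#'
#' Minimal reader for the 12 mandatory PAF columns (minimap2 dialect);
#' extra tag columns are ignored. Malformed lines raise an error naming
#' the line number.
#'
#' @param path PAF path (optionally gzipped)
#' @return data.frame with columns qname, qlen, qstart, qend, strand,
#'   tname, tlen, tstart, tend, nmatch, blocklen, mapq
#' @export
readPaf <- function(path) {
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 12L))
    stop("malformed PAF line ", which(nf < 12L)[1], ": fewer than 12 fields")
  grab <- function(i) vapply(parts, `[`, character(1), i)
  num <- function(i, line.what) {
    v <- suppressWarnings(as.numeric(grab(i)))
    if (anyNA(v))
      stop("malformed PAF line ", which(is.na(v))[1],
           ": non-numeric ", line.what)
    v
  }
  data.frame(qname = grab(1), qlen = num(2, "query length"),
             qstart = num(3, "query start"), qend = num(4, "query end"),
             strand = grab(5), tname = grab(6),
             tlen = num(7, "target length"), tstart = num(8, "target start"),
             tend = num(9, "target end"), nmatch = num(10, "match count"),
             blocklen = num(11, "block length"), mapq = num(12, "mapq"),
             stringsAsFactors = FALSE)
}

#' Alignment-identity quality value
#'
#' Filters PAF records, then computes
#' \deqn{QV = -10 \log_{10}(1 - \mathrm{match}/\mathrm{block})}
#' from the pooled match and block lengths of the survivors. A record is
#' removed when its coverage (block length / query length) or identity
#' (matches / block length) is at or below the respective cutoff --
#' removal is inclusive. Perfect pooled identity is reported at the
#' documented ceiling.
#'
#' @param paf data.frame from [readPaf()] or a PAF path
#' @param minCoverage coverage cutoff; default 0.90
#' @param minIdentity identity cutoff; default 0.98
#' @param qvCap ceiling for zero-error input; default 99
#' @return list with \code{qv} and \code{kept} (number of surviving
#'   records); \code{qv} is NA when nothing survives
#' @export
alignmentQv <- function(paf, minCoverage = 0.90, minIdentity = 0.98,
                        qvCap = 99) {
  if (is.character(paf)) paf <- readPaf(paf)
  coverage <- paf$blocklen / paf$qlen
  identity <- paf$nmatch / paf$blocklen
  keep <- coverage > minCoverage & identity > minIdentity
  paf <- paf[keep, , drop = FALSE]
  if (!nrow(paf)) {
    warning("no alignments survive the coverage/identity filters")
    return(list(qv = NA_real_, kept = 0L))
  }
  err <- 1 - sum(paf$nmatch) / sum(paf$blocklen)
  qv <- if (err <= 0) qvCap else min(qvCap, -10 * log10(err))
  list(qv = qv, kept = nrow(paf))
}

#' K-mer quality value of an assembly
#'
#' Shared-K-mer QV: over all K-length windows of the assembly, the fraction
#' shared with the short-read database estimates the probability that a
#' window is error free; the per-base error rate is
#' \eqn{E = 1 - (\mathrm{shared}/\mathrm{total})^{1/k}} and
#' \eqn{QV = -10\log_{10} E}. All windows shared gives the documented
#' ceiling. A compatible re-statement of the standard reference-free QV,
#' not a bit-exact clone of any particular tool.
#'
#' @param assembly character vector, DNAStringSet, or FASTA path
#' @param db a [KmerDB-class] from the same sample's short reads
#' @param qvCap ceiling; default 99
#' @return numeric QV (dB)
#' @export
kmerQv <- function(assembly, db, qvCap = 99) {
  k <- kmerLength(db)
  seqs <- .asSequenceCharacters(assembly)
  if (!length(seqs) || all(nchar(seqs) < k))
    stop("empty assembly (no K-length windows)")
  total <- 0L; shared <- 0L
  for (s in seqs) {
    w <- .kmer_windows_cpp(s, as.integer(k), TRUE)
    w <- w[!is.na(w)]
    if (!length(w)) next
    total <- total + length(w)
    shared <- shared + sum(queryCount(db, w) > 0L)
  }
  if (total == 0L) stop("empty assembly (no K-length windows)")
  if (shared == total) return(qvCap)
  err <- 1 - (shared / total)^(1 / k)
  min(qvCap, -10 * log10(err))
}

#' Haplotype switch error against known truth haplotypes
#'
#' Assigns each heterozygous site of the polished sequence to one truth
#' haplotype via its distinguishing K-mer (the K-window centred on the site
#' in each haplotype, canonical form, looked up in the polished K-mer set);
#' a switch is counted at each adjacent pair of assigned sites with
#' different assignments. Sites whose two haplotype K-mers are both present
#' or both absent are unassignable and excluded from pairs. A single
#' (or no) assignable site yields rate 0 with \code{defined = FALSE}.
#'
#' @param polished character vector, DNAStringSet, or FASTA path
#' @param hap1,hap2 the two truth haplotype sequences
#' @param variants data.frame of truth heterozygous variants with columns
#'   \code{pos1} and \code{pos2} (1-based site position in hap1 / hap2), as
#'   produced by [simulateDiploid()]
#' @param k distinguishing K-mer length; default 21
#' @return list with \code{switches}, \code{hetSites} (assigned sites),
#'   \code{rate} (switches per adjacent assigned pair), \code{unassigned},
#'   and \code{defined}
#' @export
switchError <- function(polished, hap1, hap2, variants, k = 21L) {
  hap1 <- as.character(hap1); hap2 <- as.character(hap2)
  polKmers <- .kmerSet(.asSequenceCharacters(polished), k)
  half <- k %/% 2L
  centered <- function(seqchr, pos) {
    L <- nchar(seqchr)
    s <- pmin(pmax(pos - half, 1L), pmax(L - k + 1L, 1L))
    substr(rep(seqchr, length(s)), s, s + k - 1L)
  }
  v <- variants[order(variants$pos1), , drop = FALSE]
  if (!nrow(v))
    return(list(switches = 0L, hetSites = 0L, rate = 0,
                unassigned = 0L, defined = FALSE))
  k1 <- canonicalKmers(centered(hap1, v$pos1))
  k2 <- canonicalKmers(centered(hap2, v$pos2))
  in1 <- k1 %in% polKmers
  in2 <- k2 %in% polKmers
  assign <- ifelse(in1 & !in2, 1L, ifelse(in2 & !in1, 2L, NA_integer_))
  assign[k1 == k2] <- NA_integer_  # non-distinguishing window
  a <- assign[!is.na(assign)]
  unas <- sum(is.na(assign))
  if (length(a) < 2L)
    return(list(switches = 0L, hetSites = length(a), rate = 0,
                unassigned = unas, defined = FALSE))
  sw <- sum(diff(a) != 0L)
  list(switches = sw, hetSites = length(a),
       rate = sw / (length(a) - 1L), unassigned = unas, defined = TRUE)
}

#' Summarise polishing quality in one report
#'
#' @param polished,original assemblies (character/DNAStringSet/FASTA path)
#' @param db a [KmerDB-class]
#' @return list with changedKmers, overcorrectionKmers, kmerQv of both
#'   assemblies
#' @export
evalReport <- function(polished, original, db) {
  list(changedKmers = changedKmers(polished, original, kmerLength(db)),
       overcorrectionKmers = overcorrectionKmers(polished, original, db),
       kmerQvPolished = kmerQv(polished, db),
       kmerQvOriginal = kmerQv(original, db))
}
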