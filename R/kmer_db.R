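#' @include AllGenerics.R
NULL

#' Canonical form of K-mers
#'
#' Returns the lexicographic minimum of each K-mer and its reverse
#' complement. This is the form under which all databases store and query
#' counts: short reads are unstranded, so a K-mer and its reverse complement
#' are the same observation.
#'
#' @param kmers character vector of DNA strings (any common length)
#' @return character vector of canonical K-mers
#' @examples
#' canonicalKmers(c("AAA", "TTT"))  # both "AAA"
#' @export
canonicalKmers <- function(kmers) {
  .canonical_kmers_cpp(as.character(kmers))
}

#' Build a canonical K-mer count database
#'
#' Counts canonical K-mers across a set of DNA sequences (typically
#' high-accuracy short reads) and drops K-mers seen fewer than
#' \code{minCount} times, which removes most isolated sequencing errors.
#' Windows containing \code{N} are skipped; records containing characters
#' outside \code{A,C,G,T,N} are skipped with a warning.
#'
#' @param sequences character vector, [Biostrings::DNAStringSet], or path(s)
#'   to FASTA/FASTQ files (optionally gzipped).
#' @param k integer K-mer length, 2--32. Default 21, the conventional length
#'   for assembly validation.
#' @param minCount integer validity threshold; default 2 drops singletons.
#' @return a [KmerDB-class]
#' @examples
#' db <- buildKmerDB(c("AAAT"), k = 3, minCount = 1)
#' queryCount(db, c("AAA", "AAT"))
#' @export
buildKmerDB <- function(sequences, k = 21L, minCount = 2L) {
  k <- as.integer(k); minCount <- as.integer(minCount)
  if (is.na(k) || k < 2L) stop("k must be an integer >= 2")
  if (is.na(minCount) || minCount < 1L) stop("minCount must be >= 1")
  seqs <- .asSequenceCharacters(sequences)
  bad <- grepl("[^ACGTNacgtn]", seqs)
  if (any(bad)) {
    warning(sprintf("skipping %d record(s) with non-ACGTN characters",
                    sum(bad)))
    seqs <- seqs[!bad]
  }
  res <- .kmer_count_cpp(seqs, k)
  keep <- res$count >= minCount
  env <- new.env(hash = TRUE, parent = emptyenv(),
                 size = max(29L, sum(keep)))
  if (any(keep))
    list2env(as.list(setNames(res$count[keep], res$kmer[keep])), envir = env)
  new("KmerDB", k = k, minCount = minCount, counts = env)
}

# accept character, XStringSet, or file paths
.asSequenceCharacters <- function(sequences) {
  if (is(sequences, "XStringSet")) return(as.character(sequences))
  if (is.character(sequences) && length(sequences) &&
      all(file.exists(sequences))) {
    out <- lapply(sequences, function(p) {
      fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", p, ignore.case = TRUE))
        "fastq" else "fasta"
      as.character(readDNAStringSet(p, format = fmt))
    })
    return(unlist(out, use.names = FALSE))
  }
  as.character(sequences)
}

#' Query K-mer counts
#'
#' Looks up the stored count of the canonical form of each K-mer; absent
#' K-mers return 0. All queried K-mers must have the database's K length.
#'
#' @param db a [KmerDB-class]
#' @param kmers character vector of K-mers
#' @return integer vector of counts
#' @export
setGeneric("queryCount", function(db, kmers) standardGeneric("queryCount"))

#' @rdname queryCount
#' @export
setMethod("queryCount", "KmerDB", function(db, kmers) {
  kmers <- as.character(kmers)
  if (!length(kmers)) return(integer(0))
  if (any(nchar(kmers) != db@k))
    stop(sprintf("all queried K-mers must have length k = %d", db@k))
  canon <- .canonical_kmers_cpp(kmers)
  vapply(mget(canon, envir = db@counts, ifnotfound = 0L),
         as.integer, integer(1), USE.NAMES = FALSE)
})

#' Decide K-mer validity against short-read databases
#'
#' A K-mer is valid when its count in the database matching its length
#' reaches that database's \code{minCount}. K-mers failing validation are
#' excluded from all downstream phasing and resolution steps. Several
#' databases of different K may be supplied; the one whose K equals the
#' query length is used.
#'
#' @param dbs a [KmerDB-class] or list of them (distinct K lengths)
#' @param kmers character vector of K-mers, all of one length
#' @return logical vector
#' @export
isValidKmer <- function(dbs, kmers) {
  if (is(dbs, "KmerDB")) dbs <- list(dbs)
  kmers <- as.character(kmers)
  if (!length(kmers)) return(logical(0))
  len <- unique(nchar(kmers))
  if (length(len) != 1L)
    stop("all queried K-mers must share one length")
  ks <- vapply(dbs, kmerLength, integer(1))
  i <- match(len, ks)
  if (is.na(i))
    stop(sprintf("no K-mer database with k = %d available", len))
  queryCount(dbs[[i]], kmers) >= minCount(dbs[[i]])
}

#' Write / read a K-mer database as sorted TSV
#'
#' Plain two-column text serialisation (kmer TAB count, gzip-compressed when
#' the path ends in .gz), preceded by one header line carrying k and
#' min_count. Readable by eye and by any scripting language; deliberately
#' independent of binary counter formats.
#'
#' @param db a [KmerDB-class]
#' @param path output path, conventionally \code{*.kc.tsv.gz}
#' @return \code{path}, invisibly
#' @export
writeKmerDB <- function(db, path) {
  ks <- sort(ls(db@counts))
  cnt <- vapply(mget(ks, envir = db@counts), as.integer, integer(1),
                USE.NAMES = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("#hifipolish-kmerdb\tk=%d\tmin_count=%d",
                     db@k, db@minCount), con)
  if (length(ks)) writeLines(paste(ks, cnt, sep = "\t"), con)
  invisible(path)
}

#' @rdname writeKmerDB
#' @export
readKmerDB <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  header <- readLines(con, n = 1L)
  if (!grepl("^#hifipolish-kmerdb\t", header))
    stop("not a hifipolish K-mer database: ", path)
  fields <- strsplit(header, "\t", fixed = TRUE)[[1]]
  k <- as.integer(sub("^k=", "", fields[2]))
  mc <- as.integer(sub("^min_count=", "", fields[3]))
  body <- readLines(con)
  env <- new.env(hash = TRUE, parent = emptyenv(),
                 size = max(29L, length(body)))
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    kmers <- vapply(parts, `[`, character(1), 1L)
    cnt <- as.integer(vapply(parts, `[`, character(1), 2L))
    list2env(as.list(setNames(cnt, kmers)), envir = env)
  }
  new("KmerDB", k = k, minCount = mc, counts = env)
}
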