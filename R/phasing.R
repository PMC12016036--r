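#' @include ksc.R
NULL

# read i's emitted sequence over reference columns ws..we (1-based closed):
# deletion alleles emit nothing, insertion alleles their full string
.readWindowSeq <- function(pileup, i, ws, we) {
  s <- pileup@starts[i]
  al <- pileup@alleleList[[i]][(ws - s + 1L):(we - s + 1L)]
  paste(al[al != "-"], collapse = "")
}

#' Extract and validate K-mers of reads spanning a low-quality region
#'
#' Pads the LQR by K - 1 bases on both sides (so every extracted K-mer
#' overlaps a low-quality column), collects the reads whose alignments
#' fully span the padded window, takes all K-length windows of each read's
#' emitted sequence over that window, and keeps only K-mers validated by
#' the short-read database (count >= its minCount). Reads whose window
#' K-mers are all valid contribute a validated "version" of the region;
#' a set with >= 2 distinct validated versions is classified heterozygous:
#' two haplotypes or repeat copies meet at this region. K-mers (and
#' versions) failing validation are sequencing or assembly errors and are
#' excluded downstream.
#'
#' An LQR spanned by no read yields an empty (unresolved) set.
#'
#' @param pileup a [ReadPileup-class]
#' @param lqr one range from [mergeLqrs()] (GRanges of length 1)
#' @param dbs a [KmerDB-class] or list of them
#' @param k K-mer length; default the first database's K
#' @return an [LqrKmerSet-class]
#' @export
extractLqrKmers <- function(pileup, lqr, dbs, k = NULL) {
  if (is(dbs, "KmerDB")) dbs <- list(dbs)
  if (is.null(k)) k <- kmerLength(dbs[[1]])
  stopifnot(length(lqr) == 1L)
  L <- nchar(pileup@refSeq)
  ws <- max(1L, start(lqr) - (k - 1L))
  we <- min(L, end(lqr) + (k - 1L))
  ends <- pileup@starts + lengths(pileup@alleleList) - 1L
  span <- which(pileup@starts <= ws & ends >= we)
  perRead <- list(); perReadSeq <- character(0)
  validSeqs <- character(0)
  for (i in span) {
    sq <- .readWindowSeq(pileup, i, ws, we)
    kms <- character(0); fullValid <- FALSE
    if (nchar(sq) >= k) {
      kms <- .kmer_windows_cpp(sq, as.integer(k), TRUE)
      kms <- kms[!is.na(kms)]
      if (length(kms)) {
        ok <- isValidKmer(dbs, kms)
        fullValid <- all(ok)
        kms <- kms[ok]
      }
    }
    perRead[[pileup@readIds[i]]] <- kms
    perReadSeq[[pileup@readIds[i]]] <- sq
    if (fullValid && !(sq %in% validSeqs)) validSeqs <- c(validSeqs, sq)
  }
  allValid <- unique(unlist(perRead, use.names = FALSE))
  if (is.null(allValid)) allValid <- character(0)
  counts <- if (length(allValid))
    setNames(queryCount(dbs[[match(k, vapply(dbs, kmerLength, integer(1)))]],
                        allValid), allValid) else
    setNames(integer(0), character(0))
  new("LqrKmerSet", lqr = lqr, window = c(ws, we), perRead = perRead,
      perReadSeq = perReadSeq, validSeqs = validSeqs, allValid = allValid,
      counts = counts, isHet = length(validSeqs) >= 2L)
}

# signed weight between two ordered valid-K-mer vectors:
# +1 per distinct shared K-mer, -1 per position-equivalent (rank-paired)
# K-mer on which the reads differ
.pairWeight <- function(a, b) {
  ua <- unique(a); ub <- unique(b)
  shared <- length(intersect(ua, ub))
  m <- min(length(a), length(b))
  diffs <- if (m > 0L) sum(a[seq_len(m)] != b[seq_len(m)]) else 0L
  shared - diffs
}

#' Compute signed read-pair weights over heterozygous K-mer sets
#'
#' For every heterozygous [LqrKmerSet-class] and every pair of reads
#' spanning it, the pair's weight gains +1 per valid K-mer the reads share
#' and loses 1 per position-equivalent valid K-mer on which they differ;
#' weights accumulate across LQRs. Non-heterozygous sets contribute
#' nothing. Reads from the same haplotype or repeat copy therefore end up
#' positively connected, reads from different ones negatively.
#'
#' @param kmerSets list of [LqrKmerSet-class] (non-heterozygous entries are
#'   ignored)
#' @return a [ReadGraph-class] without community labels
#' @export
computeReadWeights <- function(kmerSets) {
  hets <- Filter(function(s) s@isHet, kmerSets)
  chunks <- list(); ci <- 0L
  nodes <- character(0)
  readKmers <- list()
  for (s in hets) {
    rd <- names(s@perRead)
    nodes <- union(nodes, rd)
    for (r in rd) {
      kms <- s@perRead[[r]]
      if (length(kms))
        readKmers[[r]] <- c(readKmers[[r]], kms)
    }
    if (length(rd) < 2L) next
    sig <- vapply(s@perRead, paste, character(1), collapse = ",")
    grp <- match(sig, unique(sig))
    reps <- s@perRead[!duplicated(grp)]      # one K-mer vector per group
    ng <- length(reps)
    for (gi in seq_len(ng)) for (gj in gi:ng) {
      w <- .pairWeight(reps[[gi]], reps[[gj]])
      if (w == 0L) next
      ri <- rd[grp == gi]; rj <- rd[grp == gj]
      pairs <- if (gi == gj) {
        if (length(ri) < 2L) next
        t(utils::combn(ri, 2L))
      } else as.matrix(expand.grid(ri, rj, stringsAsFactors = FALSE))
      ci <- ci + 1L
      chunks[[ci]] <- data.table(
        r1 = pmin(pairs[, 1], pairs[, 2]),
        r2 = pmax(pairs[, 1], pairs[, 2]), weight = as.numeric(w))
    }
  }
  edges <- if (ci) {
    dt <- rbindlist(chunks)[, list(weight = sum(weight)), by = c("r1", "r2")]
    as.data.frame(dt)
  } else data.frame(r1 = character(0), r2 = character(0),
                    weight = numeric(0))
  readKmers <- lapply(readKmers, unique)
  new("ReadGraph", nodes = sort(nodes), edges = edges,
      communities = setNames(rep(NA_integer_, length(nodes)), sort(nodes)),
      communityPairs = data.frame(c1 = integer(0), c2 = integer(0),
                                  weight = numeric(0)),
      readKmers = readKmers)
}

#' Group reads by Louvain community detection
#'
#' Runs Louvain modularity optimisation (resolution 1) on the
#' positive-weight subgraph -- standard modularity is undefined for negative
#' weights, which here only define conflicts. Reads without positive edges
#' form singleton communities. Inter-community weights are then summed over
#' the full signed graph; pairs with negative total weight are the conflict
#' communities: same region, different haplotype or repeat copy.
#'
#' @param graph a [ReadGraph-class]
#' @param seed integer seed making the community assignment reproducible
#' @return the graph with \code{communities} and \code{communityPairs}
#'   filled in
#' @export
louvainCommunities <- function(graph, seed = 1L) {
  if (!length(graph@nodes)) return(graph)
  pos <- graph@edges[graph@edges$weight > 0, , drop = FALSE]
  g <- igraph::graph_from_data_frame(pos, directed = FALSE,
                                     vertices = graph@nodes)
  set.seed(as.integer(seed))
  memb <- if (nrow(pos)) {
    as.integer(igraph::membership(igraph::cluster_louvain(g)))
  } else seq_along(graph@nodes)
  names(memb) <- igraph::V(g)$name
  memb <- memb[graph@nodes]
  graph@communities <- memb
  e <- graph@edges
  if (nrow(e)) {
    dt <- data.table(c1 = pmin(memb[e$r1], memb[e$r2]),
                     c2 = pmax(memb[e$r1], memb[e$r2]),
                     weight = e$weight)
    dt <- dt[dt$c1 != dt$c2, ]
    cp <- as.data.frame(dt[, list(weight = sum(weight)), by = c("c1", "c2")])
  } else {
    cp <- data.frame(c1 = integer(0), c2 = integer(0), weight = numeric(0))
  }
  graph@communityPairs <- cp[order(cp$c1, cp$c2), , drop = FALSE]
  graph
}

#' Resolve conflict communities
#'
#' Processes conflicting community pairs from the most negative weight up.
#' In mode \code{"reference"} the community whose reads share the most
#' K-mers with the reference sequence is kept (each shared K-mer counted
#' once per read, so deeper communities are not penalised); in mode
#' \code{"largest"} the community with more reads is kept. All reads of the
#' losing community are marked for discarding. Exact ties keep the
#' community containing the lexicographically smallest read id.
#'
#' @param graph a [ReadGraph-class] after [louvainCommunities()]
#' @param refKmers character vector of canonical reference K-mers over the
#'   heterozygous LQR windows
#' @param mode "reference" (default) or "largest"
#' @return character vector of read ids to discard
#' @export
resolveConflicts <- function(graph, refKmers,
                             mode = c("reference", "largest")) {
  mode <- match.arg(mode)
  cp <- conflictPairs(graph)
  if (!nrow(cp)) return(character(0))
  cp <- cp[order(cp$weight, cp$c1, cp$c2), , drop = FALSE]
  memb <- graph@communities
  gone <- integer(0)
  discard <- character(0)
  score <- function(comm) {
    rds <- names(memb)[memb == comm]
    if (mode == "largest") return(length(rds))
    sum(vapply(rds, function(r) {
      kms <- graph@readKmers[[r]]
      if (is.null(kms)) 0L else length(intersect(kms, refKmers))
    }, integer(1)))
  }
  for (i in seq_len(nrow(cp))) {
    c1 <- cp$c1[i]; c2 <- cp$c2[i]
    if (c1 %in% gone || c2 %in% gone) next
    s1 <- score(c1); s2 <- score(c2)
    loser <- if (s1 > s2) c2 else if (s2 > s1) c1 else {
      # tie: keep the community with the lexicographically smallest read id
      m1 <- min(names(memb)[memb == c1])
      m2 <- min(names(memb)[memb == c2])
      if (m1 <= m2) c2 else c1
    }
    gone <- c(gone, loser)
    discard <- c(discard, names(memb)[memb == loser])
  }
  sort(unique(discard))
}

#' Iterative read phasing over low-quality regions
#'
#' Repeats \{KSC consensus, LQP detection, LQR merging, K-mer extraction
#' and validation, read-graph construction, Louvain grouping, conflict
#' resolution\} until no conflict community pair remains or the iteration
#' budget is exhausted (in which case a warning is raised and the last
#' state returned). Reads discarded in each iteration are logged.
#'
#' @param reads list of [AlignedRead-class] on one contig
#' @param contigSeq the contig sequence
#' @param dbs a [KmerDB-class] or list of them
#' @param contig contig name (default from the reads)
#' @param chainK chain-mer length for [kscConsensus()]
#' @param lqpThreshold support cutoff for [detectLqps()]
#' @param mergeGap,pad LQR merging parameters; default K and 0
#' @param mode conflict resolution mode, see [resolveConflicts()]
#' @param maxIters maximum number of iterations (>= 1); default 5
#' @param seed integer seed (Louvain reproducibility)
#' @return list with elements \code{reads} (surviving reads),
#'   \code{discarded}, \code{log} (one data.frame row per iteration),
#'   \code{iterations}, \code{converged}, and \code{history} (per
#'   iteration: LQRs, heterozygous K-mer sets, graph, discarded ids)
#' @export
iteratePhasing <- function(reads, contigSeq, dbs, contig = NULL,
                           chainK = 3L, lqpThreshold = 0.95,
                           mergeGap = NULL, pad = NULL,
                           mode = c("reference", "largest"),
                           maxIters = 5L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(maxIters >= 1L)
  if (is(dbs, "KmerDB")) dbs <- list(dbs)
  k <- kmerLength(dbs[[1]])
  if (is.null(mergeGap)) mergeGap <- k
  if (is.null(pad)) pad <- 0L
  contigSeq <- toupper(as.character(contigSeq))
  L <- nchar(contigSeq)
  logRows <- list(); history <- list()
  discardedAll <- character(0)
  converged <- FALSE
  it <- 0L
  while (it < maxIters) {
    it <- it + 1L
    pileup <- buildPileup(contigSeq, reads, contig)
    cons <- kscConsensus(pileup, chainK)
    lqps <- detectLqps(cons$trace, lqpThreshold)
    row <- data.frame(iteration = it, nLqps = length(lqps), nLqrs = 0L,
                      nHetSets = 0L, nCommunities = 0L, nConflicts = 0L,
                      nDiscarded = 0L)
    if (!length(lqps)) { logRows[[it]] <- row; converged <- TRUE; break }
    lqrs <- mergeLqrs(lqps, L, mergeGap, pad, pileup@contig)
    row$nLqrs <- length(lqrs)
    sets <- lapply(seq_along(lqrs), function(i)
      extractLqrKmers(pileup, lqrs[i], dbs, k))
    hets <- Filter(function(s) s@isHet, sets)
    row$nHetSets <- length(hets)
    if (!length(hets)) { logRows[[it]] <- row; converged <- TRUE; break }
    graph <- computeReadWeights(hets)
    graph <- louvainCommunities(graph, seed = seed + it)
    row$nCommunities <-
      length(unique(graph@communities[!is.na(graph@communities)]))
    cps <- conflictPairs(graph)
    row$nConflicts <- nrow(cps)
    history[[it]] <- list(lqrs = lqrs, hetSets = hets, graph = graph,
                          discarded = character(0))
    if (!nrow(cps)) { logRows[[it]] <- row; converged <- TRUE; break }
    refKmers <- unique(unlist(lapply(hets, function(s) {
      w <- .kmer_windows_cpp(substr(contigSeq, s@window[1], s@window[2]),
                             as.integer(k), TRUE)
      w[!is.na(w)]
    })))
    disc <- resolveConflicts(graph, refKmers, mode)
    row$nDiscarded <- length(disc)
    logRows[[it]] <- row
    history[[it]]$discarded <- disc
    if (!length(disc)) break
    discardedAll <- c(discardedAll, disc)
    reads <- Filter(function(r) !(r@readId %in% disc), reads)
  }
  if (!converged)
    warning(sprintf(
      "phasing stopped after %d iteration(s) with conflicts unresolved", it))
  list(reads = reads, discarded = discardedAll,
       log = do.call(rbind, logRows), iterations = it,
       converged = converged, history = history)
}
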