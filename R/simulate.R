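#' @include eval.R
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

.BASES <- c("A", "C", "G", "T")

.randSeq <- function(n) sample(.BASES, n, replace = TRUE)

.otherBase <- function(base) {
  vapply(base, function(b) sample(setdiff(.BASES, b), 1L), character(1),
         USE.NAMES = FALSE)
}

# TRUE at positions inside a homopolymer run of >= minRun identical bases
.homopolymerMask <- function(seq, minRun = 3L) {
  chars <- if (length(seq) == 1L && nchar(seq[1]) > 1L)
    strsplit(seq, "", fixed = TRUE)[[1]] else seq
  r <- rle(chars)
  rep(r$lengths >= minRun, r$lengths)
}

#' Build a simulation configuration
#'
#' Desk-scale defaults: a 100-kb diploid at 1\% heterozygosity, 30x
#' HiFi-like reads of 10 kb at a 0.1\% error rate whose errors become 1-bp
#' indels at 10x that rate inside homopolymer runs, and 50x accurate 150-bp
#' short reads at 0.1\% substitution error. Repeats are off by default;
#' when planted, 20\% of reads lying fully inside a copy are relocated to
#' the homologous position of another copy, emulating mapper confusion
#' between near-identical copies.
#'
#' @param genomeLength,hetRate,nRepeatCopies,repeatLength,repeatDivergence
#'   see [SimConfig-class]
#' @param repeatMismapRate,hifiCoverage,hifiErrorRate see [SimConfig-class]
#' @param homopolymerErrorMultiplier,hifiReadLength see [SimConfig-class]
#' @param srCoverage,srErrorRate,srReadLength,seed see [SimConfig-class]
#' @return a [SimConfig-class]
#' @export
simConfig <- function(genomeLength = 100000L, hetRate = 0.01,
                      nRepeatCopies = 0L, repeatLength = 5000L,
                      repeatDivergence = 0.005, repeatMismapRate = 0.2,
                      hifiCoverage = 30, hifiErrorRate = 0.001,
                      homopolymerErrorMultiplier = 10,
                      hifiReadLength = 10000L, srCoverage = 50,
                      srErrorRate = 0.001, srReadLength = 150L, seed = 1L) {
  new("SimConfig", genomeLength = as.integer(genomeLength),
      hetRate = hetRate, nRepeatCopies = as.integer(nRepeatCopies),
      repeatLength = as.integer(repeatLength),
      repeatDivergence = repeatDivergence,
      repeatMismapRate = repeatMismapRate, hifiCoverage = hifiCoverage,
      hifiErrorRate = hifiErrorRate,
      homopolymerErrorMultiplier = homopolymerErrorMultiplier,
      hifiReadLength = as.integer(hifiReadLength), srCoverage = srCoverage,
      srErrorRate = srErrorRate, srReadLength = as.integer(srReadLength),
      seed = as.integer(seed))
}

#' Simulate a diploid genome with planted repeat copies
#'
#' Draws a random haploid sequence, optionally plants \code{nRepeatCopies}
#' copies of one repeat template (each copy receiving its own recorded
#' diagnostic substitutions at the configured divergence), then derives the
#' second haplotype by applying heterozygous variants at \code{hetRate}
#' (90\% substitutions, 10\% indels of 1--3 bp). Variants keep a minimum
#' spacing of 4 bp (indel events never overlap) and avoid repeat copies
#' and contig ends; repeat copies differ between themselves only at their
#' diagnostic positions.
#'
#' All randomness is fixed by \code{config@seed}.
#'
#' @param config a [SimConfig-class]
#' @return list with \code{hap1}, \code{hap2} (character sequences),
#'   \code{variants} (data.frame pos1, pos2, type, ref, alt, len),
#'   \code{repeats} (list of \code{annotation} and \code{diagnostics}
#'   data.frames), and \code{config}
#' @export
simulateDiploid <- function(config) {
  stopifnot(is(config, "SimConfig"))
  set.seed(config@seed)
  L <- config@genomeLength
  hap1c <- .randSeq(L)

  repAnn <- data.frame(copy = integer(0), start = integer(0),
                       end = integer(0))
  repDiag <- data.frame(copy = integer(0), posTemplate = integer(0),
                        posGenome = integer(0), base = character(0),
                        templateBase = character(0))
  nrep <- config@nRepeatCopies
  if (nrep >= 1L) {
    repLen <- config@repeatLength
    if (nrep * (repLen + 2000L) > L)
      stop("genome too short for the requested repeat copies")
    template <- .randSeq(repLen)
    startsR <- round((L - repLen) * seq_len(nrep) / (nrep + 1L))
    diagRows <- list()
    for (i in seq_len(nrep)) {
      nd <- max(1L, rbinom(1L, repLen, config@repeatDivergence))
      dpos <- sort(sample.int(repLen, nd))
      dbase <- .otherBase(template[dpos])
      copySeq <- template
      copySeq[dpos] <- dbase
      hap1c[startsR[i] + seq_len(repLen) - 1L] <- copySeq
      diagRows[[i]] <- data.frame(copy = i, posTemplate = dpos,
        posGenome = startsR[i] + dpos - 1L, base = dbase,
        templateBase = template[dpos], stringsAsFactors = FALSE)
    }
    repAnn <- data.frame(copy = seq_len(nrep), start = startsR,
                         end = startsR + repLen - 1L)
    repDiag <- do.call(rbind, diagRows)
  }

  # heterozygous variants on hap2
  cand <- which(runif(L) < config@hetRate)
  cand <- cand[cand > 30L & cand < L - 30L]
  if (nrow(repAnn)) {
    inRep <- rep(FALSE, L)
    for (i in seq_len(nrow(repAnn)))
      inRep[max(1L, repAnn$start[i] - 30L):min(L, repAnn$end[i] + 30L)] <-
        TRUE
    cand <- cand[!inRep[cand]]
  }
  if (length(cand) > 1L)  # spacing >= 4 bp keeps indel events disjoint
    cand <- cand[c(TRUE, diff(cand) >= 4L)]
  nv <- length(cand)
  variants <- if (nv) {
    type <- ifelse(runif(nv) < 0.9, "sub",
                   ifelse(runif(nv) < 0.5, "ins", "del"))
    len <- ifelse(type == "sub", 1L, sample(1:3, nv, replace = TRUE))
    ref <- character(nv); alt <- character(nv)
    for (i in seq_len(nv)) {
      p <- cand[i]
      if (type[i] == "sub") {
        ref[i] <- hap1c[p]; alt[i] <- .otherBase(hap1c[p])
      } else if (type[i] == "ins") {
        ref[i] <- ""; alt[i] <- paste(.randSeq(len[i]), collapse = "")
      } else {
        ref[i] <- paste(hap1c[p:(p + len[i] - 1L)], collapse = "")
        alt[i] <- ""
      }
    }
    data.frame(pos1 = cand, pos2 = NA_integer_, type = type, ref = ref,
               alt = alt, len = len, stringsAsFactors = FALSE)
  } else data.frame(pos1 = integer(0), pos2 = integer(0),
                    type = character(0), ref = character(0),
                    alt = character(0), len = integer(0))

  # build hap2 and fill pos2 (hap2 coordinate of each site)
  hap2c <- hap1c
  subs <- variants$type == "sub"
  hap2c[variants$pos1[subs]] <- variants$alt[subs]
  indels <- which(!subs)
  if (length(indels)) {
    pieces <- character(0); cur <- 1L; off <- 0L
    for (i in seq_len(nrow(variants))) {
      if (variants$type[i] == "sub") {
        variants$pos2[i] <- variants$pos1[i] + off
        next
      }
      p <- variants$pos1[i]
      if (variants$type[i] == "ins") {
        pieces <- c(pieces, paste(hap2c[cur:p], collapse = ""),
                    variants$alt[i])
        cur <- p + 1L
        variants$pos2[i] <- p + off
        off <- off + variants$len[i]
      } else { # del
        pieces <- c(pieces, paste(hap2c[cur:(p - 1L)], collapse = ""))
        cur <- p + variants$len[i]
        variants$pos2[i] <- max(1L, p - 1L + off)
        off <- off - variants$len[i]
      }
    }
    pieces <- c(pieces, paste(hap2c[cur:L], collapse = ""))
    hap2 <- paste(pieces, collapse = "")
  } else {
    variants$pos2 <- variants$pos1
    hap2 <- paste(hap2c, collapse = "")
  }

  list(hap1 = paste(hap1c, collapse = ""), hap2 = hap2,
       variants = variants,
       repeats = list(annotation = repAnn, diagnostics = repDiag),
       config = config)
}

#' Inject base errors into an assembly
#'
#' Creates the "draft assembly with residual errors" a polisher must fix:
#' \code{nSubs} substitutions and \code{nIndels} indels of 1--2 bp, with
#' \code{homopolymerFrac} of all sites placed inside homopolymer runs
#' (length >= 3) -- where HiFi-based assemblies actually err. Sites keep a
#' pairwise distance of >= 50 bp, stay >= 60 bp from the contig ends, and
#' avoid \code{avoid} positions by >= 10 bp (pass heterozygous-variant
#' positions there so injected errors never sit on top of het sites).
#'
#' @param hap1 the true sequence (character)
#' @param nSubs,nIndels number of substitutions / indels to inject
#' @param seed integer seed
#' @param homopolymerFrac fraction of sites in homopolymer tracts;
#'   default 0.7
#' @param avoid integer positions to stay away from
#' @return list with \code{draft} (the perturbed sequence) and
#'   \code{ledger} (data.frame type, pos, posDraft, ref, alt, len,
#'   inHomopolymer), where \code{pos} is the 1-based position in
#'   \code{hap1} and \code{posDraft} its image in the draft
#' @export
perturbAssembly <- function(hap1, nSubs = 20L, nIndels = 10L, seed = 1L,
                            homopolymerFrac = 0.7, avoid = integer(0)) {
  set.seed(as.integer(seed))
  hap1 <- toupper(as.character(hap1))
  hapc <- strsplit(hap1, "", fixed = TRUE)[[1]]
  L <- length(hapc)
  n <- nSubs + nIndels
  if (n == 0L)
    return(list(draft = hap1,
                ledger = data.frame(type = character(0), pos = integer(0),
                  posDraft = integer(0), ref = character(0),
                  alt = character(0), len = integer(0),
                  inHomopolymer = logical(0))))
  if (n > L / 1000)
    stop("error counts exceed genome length / 1000")
  homo <- .homopolymerMask(hapc)
  ok <- rep(TRUE, L)
  ok[seq_len(min(60L, L))] <- FALSE
  ok[max(1L, L - 60L):L] <- FALSE
  for (a in avoid) ok[max(1L, a - 10L):min(L, a + 10L)] <- FALSE
  pickFrom <- function(pool, want, chosen) {
    pool <- sample(pool)
    out <- integer(0)
    for (p in pool) {
      if (length(out) >= want) break
      if (all(abs(p - c(chosen, out)) >= 50L)) out <- c(out, p)
    }
    out
  }
  nHomo <- round(homopolymerFrac * n)
  sites <- pickFrom(which(ok & homo), nHomo, integer(0))
  sites <- c(sites, pickFrom(which(ok & !homo), n - length(sites), sites))
  if (length(sites) < n)
    stop("could not place all error sites with the required spacing")
  sites <- sample(sites)  # shuffle before assigning types
  type <- c(rep("sub", nSubs),
            sample(c("ins", "del"), nIndels, replace = TRUE))
  len <- ifelse(type == "sub", 1L, sample(1:2, n, replace = TRUE))
  ord <- order(sites)
  sites <- sites[ord]; type <- type[ord]; len <- len[ord]
  ref <- character(n); alt <- character(n); posDraft <- integer(n)
  pieces <- character(0); cur <- 1L; off <- 0L
  for (i in seq_len(n)) {
    p <- sites[i]
    if (type[i] == "sub") {
      ref[i] <- hapc[p]
      alt[i] <- .otherBase(hapc[p])
      posDraft[i] <- p + off
      pieces <- c(pieces, paste(hapc[cur:(p - 1L)], collapse = ""), alt[i])
      cur <- p + 1L
    } else if (type[i] == "ins") {     # draft gains spurious bases after p
      ref[i] <- ""
      alt[i] <- paste(.randSeq(len[i]), collapse = "")
      posDraft[i] <- p + off
      pieces <- c(pieces, paste(hapc[cur:p], collapse = ""), alt[i])
      cur <- p + 1L
      off <- off + len[i]
    } else {                           # draft loses true bases p..p+len-1
      ref[i] <- paste(hapc[p:(p + len[i] - 1L)], collapse = "")
      alt[i] <- ""
      posDraft[i] <- p + off
      pieces <- c(pieces, paste(hapc[cur:(p - 1L)], collapse = ""))
      cur <- p + len[i]
      off <- off - len[i]
    }
  }
  pieces <- c(pieces, paste(hapc[cur:L], collapse = ""))
  list(draft = paste(pieces, collapse = ""),
       ledger = data.frame(type = type, pos = sites, posDraft = posDraft,
                           ref = ref, alt = alt, len = len,
                           inHomopolymer = homo[sites],
                           stringsAsFactors = FALSE))
}

#' Simulate HiFi-like long reads, short reads, and a truth SAM
#'
#' Draws reads uniformly from both haplotypes of a [simulateDiploid()]
#' genome and emits, for the long reads, a truth SAM against the polishing
#' reference -- the perturbed draft when \code{draft}/\code{perturbLedger}
#' are given, otherwise hap1 -- with exact CIGARs composed from the known
#' haplotype variants, the inverse of the injected draft errors, and the
#' simulated sequencing errors. No external aligner is needed; a real SAM
#' from any mapper can be substituted downstream.
#'
#' Long-read errors follow the HiFi profile: substitutions at
#' \code{hifiErrorRate} outside homopolymers; inside homopolymer runs
#' (>= 3 bases) the rate is multiplied by
#' \code{homopolymerErrorMultiplier} and errors become 1-bp
#' insertions/deletions of the run base. Short reads receive substitution
#' errors at \code{srErrorRate} and are drawn from the true haplotype
#' sequences. Raw read starts are uniform over
#' \code{[-(readLen-1), L-1]} and clipped to the contig (minimum emitted
#' length 100 bp), giving near-uniform coverage including the contig ends.
#'
#' When repeats are planted and \code{repeatMismapRate > 0}, that fraction
#' of long reads lying fully inside one repeat copy is relocated to the
#' homologous position of another copy, emulating mapper confusion between
#' near-identical copies (disabled with a warning if draft errors fall
#' inside a repeat copy).
#'
#' All randomness derives from \code{config@seed}; two identical calls
#' produce byte-identical output.
#'
#' @param sim result of [simulateDiploid()]
#' @param draft optional perturbed draft from [perturbAssembly()]
#' @param perturbLedger its ledger (required with \code{draft})
#' @param contig contig name used in the SAM; default "sim_contig"
#' @param what which read sets to simulate; default both
#' @param dir optional directory; when given, writes
#'   \code{reads.sam}, \code{hifi.fastq.gz} and \code{short.fastq.gz}
#' @return list with \code{sam} (character lines), \code{truth}
#'   (data.frame read, hap, start, end, mismapped, originCopy,
#'   targetCopy), \code{errorLog} (data.frame read, pos, type,
#'   inHomopolymer), \code{shortReads} (DNAStringSet), and \code{paths}
#'   when \code{dir} was given
#' @export
simulateReads <- function(sim, draft = NULL, perturbLedger = NULL,
                          contig = "sim_contig",
                          what = c("hifi", "short"), dir = NULL) {
  config <- sim$config
  ref <- toupper(as.character(draft %||% sim$hap1))
  refc <- strsplit(ref, "", fixed = TRUE)[[1]]
  Ld <- length(refc)
  hap1c <- strsplit(sim$hap1, "", fixed = TRUE)[[1]]
  homo <- .homopolymerMask(refc)

  # --- perturbation maps (inverse of draft errors, in draft coords) -------
  led <- perturbLedger
  if (!is.null(draft) && is.null(led))
    stop("perturbLedger is required when draft is given")
  pertSubPos <- integer(0); pertSubBase <- character(0)
  spurious <- integer(0)
  insBeforePos <- integer(0); insBeforeStr <- character(0)
  evPos <- integer(0); evCum <- integer(0)
  if (!is.null(led) && nrow(led)) {
    s <- led$type == "sub"
    pertSubPos <- led$posDraft[s]; pertSubBase <- led$ref[s]
    for (i in which(led$type == "ins"))
      spurious <- c(spurious, led$posDraft[i] + seq_len(led$len[i]))
    d <- led$type == "del"
    insBeforePos <- led$posDraft[d]; insBeforeStr <- led$ref[d]
    ind <- led$type != "sub"
    if (any(ind)) {
      evPos <- led$pos[ind]
      evCum <- cumsum(ifelse(led$type[ind] == "ins", led$len[ind],
                             -led$len[ind]))
    }
  }
  pertOffAt <- function(x) {
    if (!length(evPos)) return(rep(0L, length(x)))
    i <- findInterval(x - 0.5, evPos)
    ifelse(i == 0L, 0L, evCum[pmax(i, 1L)])
  }

  # --- heterozygous variant maps in draft coords --------------------------
  v <- sim$variants
  hetSubPos <- integer(0); hetSubAlt <- character(0)
  hetInsPos <- integer(0); hetInsStr <- character(0)
  hetDelPos <- integer(0)
  if (nrow(v)) {
    posD <- v$pos1 + pertOffAt(v$pos1)
    touched <- c(pertSubPos, spurious, insBeforePos)
    bad <- vapply(seq_len(nrow(v)), function(i)
      any((posD[i] + 0:(v$len[i] - 1L)) %in% touched), logical(1))
    if (any(bad)) {
      warning(sprintf("dropping %d het variant(s) colliding with draft %s",
                      sum(bad), "errors"))
      v <- v[!bad, , drop = FALSE]; posD <- posD[!bad]
    }
    s <- v$type == "sub"
    hetSubPos <- posD[s]; hetSubAlt <- v$alt[s]
    ii <- v$type == "ins"
    hetInsPos <- posD[ii]; hetInsStr <- v$alt[ii]
    for (i in which(v$type == "del"))
      hetDelPos <- c(hetDelPos, posD[i] + 0:(v$len[i] - 1L))
  }

  # --- repeat copies in draft coords --------------------------------------
  repAnn <- sim$repeats$annotation
  mismapOk <- nrow(repAnn) >= 2L && config@repeatMismapRate > 0
  if (mismapOk && !is.null(led) && nrow(led)) {
    inRep <- any(vapply(seq_len(nrow(repAnn)), function(i)
      any(led$pos >= repAnn$start[i] & led$pos <= repAnn$end[i]),
      logical(1)))
    if (inRep) {
      warning("draft errors inside repeat copies; mismapping disabled")
      mismapOk <- FALSE
    }
  }
  repStartD <- repEndD <- integer(0)
  if (nrow(repAnn)) {
    repStartD <- repAnn$start + pertOffAt(repAnn$start)
    repEndD <- repAnn$end + pertOffAt(repAnn$start)
  }

  out <- list()
  doHifi <- "hifi" %in% what
  doShort <- "short" %in% what

  if (doHifi) {
    set.seed(config@seed + 1000L)
    rl <- config@hifiReadLength
    span <- Ld + rl - 1L
    nReads <- max(1L, round(config@hifiCoverage * span / rl))
    rawStart <- sample.int(span, nReads, replace = TRUE) - (rl - 1L)
    ss <- pmax(1L, rawStart)
    ee <- pmin(Ld, rawStart + rl - 1L)
    keep <- ee - ss + 1L >= 100L
    ss <- ss[keep]; ee <- ee[keep]
    nReads <- length(ss)
    haps <- if (config@hetRate > 0 || nrow(v))
      sample(1:2, nReads, replace = TRUE) else rep(1L, nReads)
    strands <- sample(c("+", "-"), nReads, replace = TRUE)

    samLines <- character(nReads)
    truthRows <- vector("list", nReads)
    errRows <- list()
    for (i in seq_len(nReads)) {
      s0 <- ss[i]; e0 <- ee[i]; hap <- haps[i]
      rid <- sprintf("hifi%05d_h%d", i, hap)
      mis <- FALSE; originCopy <- NA_integer_; targetCopy <- NA_integer_
      shift <- 0L
      if (mismapOk) {
        inside <- which(s0 >= repStartD & e0 <= repEndD)
        if (length(inside) == 1L &&
            runif(1) < config@repeatMismapRate) {
          originCopy <- inside
          targetCopy <- sample(setdiff(seq_len(nrow(repAnn)), inside), 1L)
          # relocate to the homologous position of the target copy: the
          # read keeps its origin-copy bases, mapped at the target locus
          shift <- repStartD[targetCopy] - repStartD[originCopy]
          s0 <- s0 + shift; e0 <- e0 + shift
          mis <- TRUE
        }
      }
      p <- s0:e0
      np <- length(p)
      em <- refc[p]
      baseOp <- rep("=", np)
      insAfter <- rep("", np)
      if (mis) {
        # true bases come from the origin copy (hap1 coords; repeats carry
        # no het variants or draft errors)
        offOrigin <- pertOffAt(repAnn$start[originCopy])[1]
        em <- hap1c[p - shift - offOrigin]
        baseOp[em != refc[p]] <- "X"
      } else {
        m <- match(p, pertSubPos)
        hit <- which(!is.na(m))
        if (length(hit)) {
          em[hit] <- pertSubBase[m[hit]]
          baseOp[hit] <- "X"
        }
        sp <- which(p %in% spurious)
        if (length(sp)) { baseOp[sp] <- "D"; em[sp] <- "" }
        m <- match(insBeforePos, p)
        for (j in which(!is.na(m) & m > 1L))
          insAfter[m[j] - 1L] <- paste0(insAfter[m[j] - 1L],
                                        insBeforeStr[j])
        if (hap == 2L) {
          m <- match(p, hetSubPos)
          hit <- which(!is.na(m))
          if (length(hit)) {
            em[hit] <- hetSubAlt[m[hit]]
            baseOp[hit] <- "X"
          }
          dl <- which(p %in% hetDelPos)
          if (length(dl)) { baseOp[dl] <- "D"; em[dl] <- "" }
          m <- match(hetInsPos, p)
          for (j in which(!is.na(m)))
            insAfter[m[j]] <- paste0(insAfter[m[j]], hetInsStr[j])
        }
      }
      # sequencing errors on unmodified match positions
      plain <- which(baseOp == "=" & insAfter == "" & em == refc[p])
      if (length(plain) && config@hifiErrorRate > 0) {
        pe <- config@hifiErrorRate *
          ifelse(homo[p[plain]], config@homopolymerErrorMultiplier, 1)
        hitE <- plain[runif(length(plain)) < pmin(pe, 0.5)]
        for (j in hitE) {
          if (homo[p[j]]) {
            if (runif(1) < 0.5) {
              insAfter[j] <- paste0(em[j], insAfter[j])  # extra run base
              errRows[[length(errRows) + 1L]] <- data.frame(read = rid,
                pos = p[j], type = "ins", inHomopolymer = TRUE)
            } else {
              baseOp[j] <- "D"; em[j] <- ""
              errRows[[length(errRows) + 1L]] <- data.frame(read = rid,
                pos = p[j], type = "del", inHomopolymer = TRUE)
            }
          } else {
            em[j] <- .otherBase(em[j])
            baseOp[j] <- "X"
            errRows[[length(errRows) + 1L]] <- data.frame(read = rid,
              pos = p[j], type = "sub", inHomopolymer = FALSE)
          }
        }
      }
      # trim leading/trailing deleted columns
      a <- 1L; b <- np
      while (a <= b && baseOp[a] == "D") a <- a + 1L
      while (b >= a && baseOp[b] == "D") b <- b - 1L
      if (b - a + 1L < 50L) { samLines[i] <- NA_character_; next }
      em <- em[a:b]; baseOp <- baseOp[a:b]; insAfter <- insAfter[a:b]
      pos1 <- p[a]
      # CIGAR with insertion breakpoints
      idxIns <- which(nzchar(insAfter))
      cuts <- sort(unique(c(idxIns, length(baseOp))))
      toks <- character(0); aa <- 1L
      for (bcut in cuts) {
        r <- rle(baseOp[aa:bcut])
        toks <- c(toks, paste0(r$lengths, r$values))
        if (nzchar(insAfter[bcut]))
          toks <- c(toks, paste0(nchar(insAfter[bcut]), "I"))
        aa <- bcut + 1L
      }
      cigar <- paste(toks, collapse = "")
      seqStr <- paste(paste0(em, insAfter), collapse = "")
      flag <- if (strands[i] == "-") 16L else 0L
      samLines[i] <- paste(rid, flag, contig, pos1, 60L, cigar, "*", 0L,
                           0L, seqStr, "*", sprintf("HP:i:%d", hap),
                           sep = "\t")
      truthRows[[i]] <- data.frame(read = rid, hap = hap, start = pos1,
        end = pos1 + length(baseOp) - 1L, mismapped = mis,
        originCopy = originCopy, targetCopy = targetCopy,
        stringsAsFactors = FALSE)
    }
    keepL <- !is.na(samLines)
    header <- c("@HD\tVN:1.6\tSO:unknown",
                sprintf("@SQ\tSN:%s\tLN:%d", contig, Ld))
    out$sam <- c(header, samLines[keepL])
    out$truth <- do.call(rbind, truthRows[keepL])
    out$errorLog <- if (length(errRows)) do.call(rbind, errRows) else
      data.frame(read = character(0), pos = integer(0),
                 type = character(0), inHomopolymer = logical(0))
  }

  if (doShort) {
    set.seed(config@seed + 2000L)
    srl <- config@srReadLength
    seqsByHap <- c(sim$hap1, sim$hap2)
    reads <- character(0)
    for (h in 1:2) {
      hs <- seqsByHap[h]
      Lh <- nchar(hs)
      span <- Lh + srl - 1L
      nR <- max(1L, round(config@srCoverage / 2 * span / srl))
      rawStart <- sample.int(span, nR, replace = TRUE) - (srl - 1L)
      s1 <- pmax(1L, rawStart)
      e1 <- pmin(Lh, rawStart + srl - 1L)
      keep <- e1 - s1 + 1L >= 50L
      rd <- substring(hs, s1[keep], e1[keep])
      # substitution errors
      nerr <- rbinom(length(rd), nchar(rd), config@srErrorRate)
      for (i in which(nerr > 0L)) {
        ch <- strsplit(rd[i], "", fixed = TRUE)[[1]]
        at <- sample.int(length(ch), nerr[i])
        ch[at] <- .otherBase(ch[at])
        rd[i] <- paste(ch, collapse = "")
      }
      reads <- c(reads, rd)
    }
    sr <- DNAStringSet(reads)
    names(sr) <- sprintf("sr%06d", seq_along(sr))
    flip <- sample(c(TRUE, FALSE), length(sr), replace = TRUE)
    sr[flip] <- reverseComplement(sr[flip])
    out$shortReads <- sr
  }

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list()
    if (doHifi) {
      paths$sam <- file.path(dir, "reads.sam")
      writeLines(out$sam, paths$sam)
    }
    if (doShort) {
      paths$short <- file.path(dir, "short.fasta.gz")
      writeXStringSet(out$shortReads, paths$short, compress = TRUE)
    }
    out$paths <- paths
  }
  out
}

#' Write SAM lines to a file
#' @param lines character vector of SAM lines (header included)
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeSam <- function(lines, path) {
  writeLines(lines, path)
  invisible(path)
}
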