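kmerSetOf <- function(perRead, validSeqs = character(0)) {
  new("LqrKmerSet",
      lqr = GenomicRanges::GRanges("ctg", IRanges::IRanges(10, 10)),
      window = c(5L, 15L), perRead = perRead,
      perReadSeq = setNames(rep("", length(perRead)), names(perRead)),
      validSeqs = validSeqs, allValid = unique(unlist(perRead)),
      counts = setNames(integer(0), character(0)),
      isHet = length(validSeqs) >= 2L)
}

test_that("K-mers are extracted from reads spanning the padded window", {
  toy <- toyHetLocus()
  lqr <- GenomicRanges::GRanges("ctg",
                                IRanges::IRanges(toy$altPos, toy$altPos))
  ks <- extractLqrKmers(toy$pileup, lqr, toy$db)
  # all 12 reads span; k K-mers per read, every one overlapping the site
  expect_length(ks@perRead, 12)
  expect_true(all(lengths(ks@perRead) == toy$k))
  # both haplotype versions are valid: heterozygous
  expect_length(ks@validSeqs, 2)
  expect_true(ks@isHet)
  # hap1 and hap2 reads hold disjoint K-mer sets (every K-mer covers the
  # variant)
  expect_length(intersect(ks@perRead$a01_h1, ks@perRead$b01_h2), 0)

  # a read ending inside the window does not contribute
  short <- makeRead("s01_h1", 1L,
                    strsplit(toy$ref, "")[[1]][seq_len(toy$altPos)])
  pile2 <- buildPileup(toy$ref, c(toy$reads, list(short)), "ctg")
  ks2 <- extractLqrKmers(pile2, lqr, toy$db)
  expect_false("s01_h1" %in% names(ks2@perRead))

  # an LQR spanned by no read yields an empty, unresolved set
  pile3 <- buildPileup(toy$ref, list(short), "ctg")
  ks3 <- extractLqrKmers(pile3,
    GenomicRanges::GRanges("ctg", IRanges::IRanges(150, 150)), toy$db)
  expect_length(ks3@perRead, 0)
  expect_false(ks3@isHet)
})

test_that("homozygous window with one validated version is not het", {
  toy <- toyHetLocus()
  # far from the variant every read agrees
  lqr <- GenomicRanges::GRanges("ctg", IRanges::IRanges(30, 30))
  ks <- extractLqrKmers(toy$pileup, lqr, toy$db)
  expect_length(ks@validSeqs, 1)
  expect_false(ks@isHet)
})

test_that("pair weights count shared and rank-paired differing K-mers", {
  same <- kmerSetOf(list(r1 = c("AAAAA", "CCCCC", "GGGGG"),
                         r2 = c("AAAAA", "CCCCC", "GGGGG")),
                    validSeqs = c("x", "y"))
  g <- computeReadWeights(list(same))
  expect_equal(g@edges$weight, 3)

  disj <- kmerSetOf(list(r1 = c("AAAAA", "CCCCC", "GGGGG"),
                         r2 = c("AATAA", "CCTCC", "GGTGG")),
                    validSeqs = c("x", "y"))
  g2 <- computeReadWeights(list(disj))
  expect_equal(g2@edges$weight, -3)

  # reads sharing no LQR get no edge; non-het sets contribute nothing
  twoLqrs <- list(
    kmerSetOf(list(r1 = "AAAAA", r2 = "AAAAA"), validSeqs = c("x", "y")),
    kmerSetOf(list(r3 = "CCCCC", r4 = "CCCCC"), validSeqs = c("x", "y")),
    kmerSetOf(list(r1 = "GGGGG", r3 = "GGGGG")))  # not het
  g3 <- computeReadWeights(twoLqrs)
  pairs <- paste(g3@edges$r1, g3@edges$r2)
  expect_setequal(pairs, c("r1 r2", "r3 r4"))
  # symmetry by construction: each unordered pair stored once with r1 < r2
  expect_true(all(g3@edges$r1 < g3@edges$r2))
})

plantedGraph <- function() {
  a <- sprintf("a%02d", 1:5); b <- sprintf("b%02d", 1:5)
  within <- rbind(t(combn(a, 2)), t(combn(b, 2)))
  across <- as.matrix(expand.grid(a, b, stringsAsFactors = FALSE))
  edges <- data.frame(
    r1 = c(within[, 1], pmin(across[, 1], across[, 2])),
    r2 = c(within[, 2], pmax(across[, 1], across[, 2])),
    weight = c(rep(3, nrow(within)), rep(-2, nrow(across))),
    stringsAsFactors = FALSE)
  new("ReadGraph", nodes = sort(c(a, b)), edges = edges,
      communities = setNames(rep(NA_integer_, 10), sort(c(a, b))),
      communityPairs = data.frame(c1 = integer(0), c2 = integer(0),
                                  weight = numeric(0)),
      readKmers = c(setNames(rep(list(c("AAAAA", "CCCCC")), 5), a),
                    setNames(rep(list(c("GGGGG")), 5), b)))
}

test_that("Louvain separates planted groups and flags the conflict", {
  g <- louvainCommunities(plantedGraph(), seed = 11)
  memb <- communities(g)
  expect_equal(length(unique(memb)), 2)
  expect_equal(length(unique(memb[startsWith(names(memb), "a")])), 1)
  expect_equal(length(unique(memb[startsWith(names(memb), "b")])), 1)
  cp <- conflictPairs(g)
  expect_equal(nrow(cp), 1)
  expect_equal(cp$weight, -2 * 25)
  # inter-community weight equals the sum of member edge weights
  e <- g@edges
  inter <- sum(e$weight[memb[e$r1] != memb[e$r2]])
  expect_equal(cp$weight, inter)
})

test_that("a fully consistent graph forms one conflict-free community", {
  a <- sprintf("r%02d", 1:6)
  within <- t(combn(a, 2))
  g <- new("ReadGraph", nodes = a,
           edges = data.frame(r1 = within[, 1], r2 = within[, 2],
                              weight = 2, stringsAsFactors = FALSE),
           communities = setNames(rep(NA_integer_, 6), a),
           communityPairs = data.frame(c1 = integer(0), c2 = integer(0),
                                       weight = numeric(0)),
           readKmers = list())
  g <- louvainCommunities(g, seed = 3)
  expect_equal(length(unique(communities(g))), 1)
  expect_equal(nrow(conflictPairs(g)), 0)
})

test_that("conflict resolution keeps the reference-sharing or largest side", {
  g <- louvainCommunities(plantedGraph(), seed = 11)
  # group a shares 2 reference K-mers per read, group b none
  disc <- resolveConflicts(g, refKmers = c("AAAAA", "CCCCC"),
                           mode = "reference")
  expect_setequal(disc, sprintf("b%02d", 1:5))
  # with the reference on b's side, a is discarded
  disc2 <- resolveConflicts(g, refKmers = "GGGGG", mode = "reference")
  expect_setequal(disc2, sprintf("a%02d", 1:5))
  # largest mode: equal sizes tie -> keep the community holding the
  # lexicographically smallest read id (a01)
  disc3 <- resolveConflicts(g, refKmers = character(0), mode = "largest")
  expect_setequal(disc3, sprintf("b%02d", 1:5))
})

test_that("iteration terminates immediately on homozygous clean input", {
  ref <- randomDna(400)
  reads <- unanimousReads(ref, 8)
  db <- buildKmerDB(c(ref, ref), k = 11, minCount = 2)
  out <- iteratePhasing(reads, ref, db, contig = "ctg", seed = 1)
  expect_equal(out$iterations, 1L)
  expect_true(out$converged)
  expect_length(out$discarded, 0)
})

test_that("reference mode discards exactly the non-reference haplotype", {
  toy <- toyHetLocus()
  out <- iteratePhasing(toy$reads, toy$ref, toy$db, contig = "ctg",
                        mode = "reference", seed = 4)
  expect_true(out$converged)
  expect_true(length(out$discarded) > 0)
  expect_true(all(readHap(out$discarded) == 2L))
  # monotone safety: discarding reads cannot add alleles to a column
  pileAfter <- buildPileup(toy$ref, out$reads, "ctg")
  colBefore <- pileupColumn(toy$pileup, toy$altPos)
  colAfter <- pileupColumn(pileAfter, toy$altPos)
  expect_true(all(names(colAfter) %in% names(colBefore)))

  # an exhausted iteration budget with conflicts leaves a warning
  expect_warning(
    iteratePhasing(toy$reads, toy$ref, toy$db, contig = "ctg",
                   maxIters = 1L, seed = 4),
    "conflicts unresolved")
})
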