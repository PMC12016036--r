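test_that("changed K-mers obey the overlap bound of a single edit", {
  set.seed(13)
  s <- randomDna(2000)
  expect_equal(changedKmers(s, s), 0L)
  # one substitution in unique interior sequence: <= 2k - 1 new K-mers
  chars <- strsplit(s, "")[[1]]
  chars[1000] <- setdiff(c("A", "C", "G", "T"), chars[1000])[1]
  edited <- paste(chars, collapse = "")
  ck <- changedKmers(edited, s, k = 21)
  expect_gt(ck, 0)
  expect_lte(ck, 41)
  # at the first position only k windows can change
  chars2 <- strsplit(s, "")[[1]]
  chars2[1] <- setdiff(c("A", "C", "G", "T"), chars2[1])[1]
  expect_lte(changedKmers(paste(chars2, collapse = ""), s, k = 21), 21)
})

test_that("overcorrection K-mers need absence from reads and original", {
  set.seed(14)
  truth <- randomDna(2000)
  db <- buildKmerDB(c(truth, truth), k = 21, minCount = 2)
  chars <- strsplit(truth, "")[[1]]
  chars[700] <- setdiff(c("A", "C", "G", "T"), chars[700])[1]
  draft <- paste(chars, collapse = "")
  # correcting the draft back to truth: new K-mers exist in the reads
  expect_gt(changedKmers(truth, draft), 0)
  expect_equal(overcorrectionKmers(truth, draft, db), 0L)
  # an invented edit is pure overcorrection
  chars2 <- strsplit(draft, "")[[1]]
  chars2[1200] <- setdiff(c("A", "C", "G", "T"), chars2[1200])[1]
  invented <- paste(chars2, collapse = "")
  expect_gt(overcorrectionKmers(invented, draft, db), 0)
  expect_equal(overcorrectionKmers(draft, draft, db), 0L)
})

test_that("overcorrection never exceeds changed K-mers", {
  set.seed(15)
  db <- buildKmerDB(randomDna(3000), k = 21, minCount = 1)
  for (i in 1:10) {
    a <- randomDna(500)
    b <- randomDna(500)
    expect_lte(overcorrectionKmers(a, b, db), changedKmers(a, b, 21))
  }
})

test_that("changed K-mers are zero iff the K-mer sets are equal", {
  s <- randomDna(400)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  # reverse complement has the identical canonical K-mer set
  expect_equal(changedKmers(rc, s), 0L)
  expect_gt(changedKmers(paste0(s, "ACGTACGTACGTACGTACGTAGG"), s), 0L)
})

pafLine <- function(qname, qlen, nmatch, blocklen) {
  paste(qname, qlen, 0, qlen, "+", "t", 10000, 0, blocklen, nmatch,
        blocklen, 60, sep = "\t")
}

test_that("alignment QV follows the closed form with inclusive filters", {
  p <- tempfile(fileext = ".paf")
  writeLines(c(pafLine("a", 10000, 9900, 10000),
               pafLine("b", 10000, 9990, 10000)), p)
  # identity 0.99 -> QV 20; 0.999 -> QV 30
  expect_equal(alignmentQv(readPaf(p)[1, ])$qv, 20, tolerance = 1e-12)
  expect_equal(alignmentQv(readPaf(p)[2, ])$qv, 30, tolerance = 1e-12)

  # inclusive removal at both boundaries
  rec <- readPaf(p)[1, ]
  covBoundary <- rec; covBoundary$blocklen <- 9000; covBoundary$nmatch <- 8999
  expect_warning(out <- alignmentQv(covBoundary), "no alignments")
  expect_equal(out$kept, 0L)
  idBoundary <- rec; idBoundary$nmatch <- 9800
  expect_warning(alignmentQv(idBoundary), "no alignments")
  justAbove <- rec; justAbove$nmatch <- 9801
  expect_equal(alignmentQv(justAbove)$kept, 1L)

  # perfect identity hits the documented ceiling
  perfect <- rec; perfect$nmatch <- 10000
  expect_equal(alignmentQv(perfect)$qv, 99)

  # monotone decreasing in mismatch fraction
  worse <- rec; worse$nmatch <- 9850
  expect_lt(alignmentQv(worse)$qv, alignmentQv(rec)$qv)

  bad <- tempfile(fileext = ".paf")
  writeLines(c(pafLine("a", 100, 99, 100), "only\tthree\tfields"), bad)
  expect_error(readPaf(bad), "line 2")
})

test_that("K-mer QV matches its closed form and is monotone", {
  # db from "AC": canonical 2-mer set {AC}; assembly ACAC has windows
  # AC, CA, AC -> 2 of 3 shared; E = 1 - (2/3)^(1/2)
  db <- buildKmerDB("AC", k = 2, minCount = 1)
  expect_equal(kmerQv("ACAC", db), -10 * log10(1 - sqrt(2 / 3)),
               tolerance = 1e-12)
  # all windows shared: ceiling
  dbFull <- buildKmerDB("ACAC", k = 2, minCount = 1)
  expect_equal(kmerQv("ACAC", dbFull), 99)
  # fewer shared K-mers give a lower QV
  s <- randomDna(1000)
  db2 <- buildKmerDB(s, k = 21, minCount = 1)
  good <- s
  chars <- strsplit(s, "")[[1]]
  chars[c(200, 600)] <- vapply(chars[c(200, 600)], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], "")
  worse <- paste(chars, collapse = "")
  expect_lt(kmerQv(worse, db2), kmerQv(good, db2))
  expect_error(kmerQv("ACG", db2), "empty assembly")
})

test_that("switch errors count alternations of haplotype assignment", {
  cfg <- simConfig(genomeLength = 20000L, hetRate = 0.01, seed = 61L)
  sim <- simulateDiploid(cfg)
  # hap1 itself: all sites assigned to hap1, no switches
  sw1 <- switchError(sim$hap1, sim$hap1, sim$hap2, sim$variants)
  expect_equal(sw1$switches, 0L)
  expect_gt(sw1$hetSites, 50)
  expect_equal(sw1$rate, 0)
  # hap2: no switches either
  sw2 <- switchError(sim$hap2, sim$hap1, sim$hap2, sim$variants)
  expect_equal(sw2$switches, 0L)

  # a mosaic switching haplotype mid-contig: exactly one switch.
  # substitution sites only, spaced beyond K so the distinguishing
  # windows never overlap and every site stays assignable
  cut <- 10000L
  v <- sim$variants[sim$variants$type == "sub", ]
  v <- v[c(TRUE, diff(v$pos1) > 25), ]
  chars <- strsplit(sim$hap1, "")[[1]]
  sel <- v$pos1 > cut
  chars[v$pos1[sel]] <- v$alt[sel]
  mosaic <- paste(chars, collapse = "")
  swm <- switchError(mosaic, sim$hap1, sim$hap2, v)
  expect_equal(swm$switches, 1L)

  # alternating assignment at every site: rate 1
  vAlt <- v[seq_len(6), ]
  chars2 <- strsplit(sim$hap1, "")[[1]]
  flip <- vAlt$pos1[c(FALSE, TRUE)]
  chars2[flip] <- vAlt$alt[match(flip, vAlt$pos1)]
  alternating <- paste(chars2, collapse = "")
  swa <- switchError(alternating, sim$hap1, sim$hap2, vAlt)
  expect_equal(swa$hetSites, 6L)
  expect_equal(swa$rate, 1)

  # single (or no) assignable site: rate reported 0 and flagged undefined
  sw0 <- switchError(sim$hap1, sim$hap1, sim$hap2, v[1, ])
  expect_equal(sw0$rate, 0)
  expect_false(sw0$defined)
})

test_that("switch counting agrees with a brute-force assignment vector", {
  set.seed(71)
  cfg <- simConfig(genomeLength = 15000L, hetRate = 0.008, seed = 72L)
  sim <- simulateDiploid(cfg)
  # substitution sites isolated from every other variant (any type), so
  # each distinguishing window holds exactly one variant
  allPos <- sim$variants$pos1
  v <- sim$variants[sim$variants$type == "sub", ]
  iso <- vapply(v$pos1, function(p)
    sum(abs(allPos - p) <= 25) == 1L, logical(1))
  v <- v[iso, ]
  # random known mosaic
  takeHap2 <- runif(nrow(v)) < 0.5
  chars <- strsplit(sim$hap1, "")[[1]]
  chars[v$pos1[takeHap2]] <- v$alt[takeHap2]
  mosaic <- paste(chars, collapse = "")
  sw <- switchError(mosaic, sim$hap1, sim$hap2, v)
  truthAssign <- ifelse(takeHap2[order(v$pos1)], 2L, 1L)
  expect_equal(sw$switches, sum(diff(truthAssign) != 0L))
  expect_equal(sw$hetSites, length(truthAssign))
})
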