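# a residual-region fixture: ref window plus alternative versions with
# controllable read support and database content
residualFixture <- function(versions, support, dbSeqs, k = 7L,
                            minCount = 1L) {
  lqr <- GenomicRanges::GRanges("ctg", IRanges::IRanges(30, 32))
  perReadSeq <- rep(versions, support)
  names(perReadSeq) <- sprintf("r%02d", seq_along(perReadSeq))
  ks <- new("LqrKmerSet", lqr = lqr, window = c(24L, 38L),
            perRead = setNames(vector("list", length(perReadSeq)),
                               names(perReadSeq)),
            perReadSeq = perReadSeq, validSeqs = character(0),
            allValid = character(0),
            counts = setNames(integer(0), character(0)), isHet = FALSE)
  db <- buildKmerDB(dbSeqs, k = k, minCount = minCount)
  list(lqr = lqr, ks = ks, db = db)
}

test_that("residual regions fall back to the reference without evidence", {
  ref <- randomDna(60)
  refWindow <- substr(ref, 24, 38)
  # database knows nothing about any candidate
  fx <- residualFixture(versions = c("ACGTACGTACGTACG"), support = 3L,
                        dbSeqs = "TTTTTTTTTTTTTTTTTTTT")
  res <- resolveResidualLqr(fx$lqr, fx$ks, ref, fx$db)
  expect_equal(res$rule, "reference_kmer")
  expect_equal(res$seq, refWindow)
})

test_that("a single validated version is adopted", {
  ref <- randomDna(60)
  v <- randomDna(15)
  fx <- residualFixture(versions = v, support = 4L, dbSeqs = v)
  res <- resolveResidualLqr(fx$lqr, fx$ks, ref, fx$db)
  expect_equal(res$rule, "majority")
  expect_equal(res$seq, v)
})

test_that("equally supported candidates are ranked by database count", {
  ref <- randomDna(60)
  # two validated versions, equal read support; X is far more abundant in
  # the short reads than Y
  x <- "ACGGTCAGGTTCAAG"; y <- "ACGGTCACGTTCAAG"
  fx <- residualFixture(versions = c(x, y), support = c(3L, 3L),
                        dbSeqs = c(rep(x, 40), rep(y, 12)))
  res <- resolveResidualLqr(fx$lqr, fx$ks, ref, fx$db)
  expect_equal(res$rule, "best_count_kmer")
  expect_equal(res$seq, x)
  # read support outranks the count when the split is uneven
  fx2 <- residualFixture(versions = c(x, y), support = c(2L, 7L),
                         dbSeqs = c(rep(x, 40), rep(y, 12)))
  expect_equal(resolveResidualLqr(fx2$lqr, fx2$ks, ref, fx2$db)$seq, y)
})

test_that("count and support ties prefer the reference window", {
  ref <- paste0(randomDna(23), "ACGGTCAGGTTCAAG", randomDna(22))
  x <- substr(ref, 24, 38)            # the reference window itself
  y <- sub("GG", "CC", x, fixed = TRUE)
  fx <- residualFixture(versions = c(x, y), support = c(3L, 3L),
                        dbSeqs = c(rep(x, 10), rep(y, 10)))
  res <- resolveResidualLqr(fx$lqr, fx$ks, ref, fx$db)
  expect_equal(res$seq, x)
})

test_that("zero-coverage contigs are returned unchanged with a warning", {
  ref <- randomDna(500)
  db <- buildKmerDB(ref, k = 11, minCount = 1)
  expect_warning(res <- polishContig(ref, list(), db, contig = "c"),
                 "zero coverage")
  expect_identical(res$sequence, ref)
  expect_equal(nrow(edits(res$report)), 0)
})

test_that("polishing clean data is the identity", {
  cfg <- simConfig(genomeLength = 8000L, hetRate = 0, hifiErrorRate = 0,
                   srErrorRate = 0, hifiReadLength = 1500L,
                   hifiCoverage = 20, seed = 41L)
  sim <- simulateDiploid(cfg)
  rr <- simulateReads(sim)
  reads <- loadSamLines(rr$sam)
  db <- buildKmerDB(rr$shortReads, k = 21, minCount = 2)
  res <- polishContig(sim$hap1, reads, db, contig = "sim_contig", seed = 2)
  expect_identical(res$sequence, sim$hap1)
  expect_equal(nrow(edits(res$report)), 0)
  expect_equal(changedKmers(res$sequence, sim$hap1), 0)
})

test_that("injected draft errors are corrected without overcorrection", {
  cfg <- simConfig(genomeLength = 12000L, hetRate = 0,
                   hifiReadLength = 2000L, seed = 43L)
  sim <- simulateDiploid(cfg)
  pert <- perturbAssembly(sim$hap1, nSubs = 6L, nIndels = 3L, seed = 44L)
  rr <- simulateReads(sim, draft = pert$draft, perturbLedger = pert$ledger)
  reads <- loadSamLines(rr$sam)
  db <- buildKmerDB(rr$shortReads, k = 21, minCount = 2)
  res <- polishContig(pert$draft, reads, db, contig = "sim_contig",
                      seed = 2)
  expect_identical(res$sequence, sim$hap1)
  expect_equal(overcorrectionKmers(res$sequence, pert$draft, db), 0)
  # every edited window's K-mers exist in the short-read database
  expect_true(nrow(edits(res$report)) >= 9)
})

test_that("re-polishing a substitution-polished contig is a fixed point", {
  cfg <- simConfig(genomeLength = 10000L, hetRate = 0,
                   hifiReadLength = 2000L, seed = 47L)
  sim <- simulateDiploid(cfg)
  pert <- perturbAssembly(sim$hap1, nSubs = 8L, nIndels = 0L, seed = 48L)
  rr <- simulateReads(sim, draft = pert$draft, perturbLedger = pert$ledger)
  reads <- loadSamLines(rr$sam)
  db <- buildKmerDB(rr$shortReads, k = 21, minCount = 2)
  res1 <- polishContig(pert$draft, reads, db, contig = "sim_contig",
                       seed = 2)
  # substitution-only edits keep coordinates, so the same alignments apply
  res2 <- polishContig(res1$sequence, reads, db, contig = "sim_contig",
                       seed = 2)
  expect_lte(nrow(edits(res2$report)), 1)
  expect_identical(res2$sequence, res1$sequence)
})

test_that("polishAssembly runs per contig and writes FASTA", {
  cfg <- simConfig(genomeLength = 6000L, hetRate = 0, hifiErrorRate = 0,
                   srErrorRate = 0, hifiReadLength = 1200L,
                   hifiCoverage = 15, seed = 51L)
  sim <- simulateDiploid(cfg)
  rr <- simulateReads(sim, dir = tempfile("simdir"))
  db <- buildKmerDB(rr$shortReads, k = 21, minCount = 2)
  fa <- tempfile(fileext = ".fa")
  writeFasta(c(sim_contig = sim$hap1), fa)
  out <- polishAssembly(fa, rr$paths$sam, db, seed = 2)
  expect_named(out$sequences, "sim_contig")
  expect_identical(unname(out$sequences["sim_contig"]), sim$hap1)
  pol <- tempfile(fileext = ".fa")
  writeFasta(out$sequences, pol)
  back <- Biostrings::readDNAStringSet(pol)
  expect_identical(as.character(back[["sim_contig"]]), sim$hap1)
})
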