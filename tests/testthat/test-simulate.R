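test_that("zero heterozygosity collapses the diploid to one haplotype", {
  cfg <- simConfig(genomeLength = 5000L, hetRate = 0, seed = 2L)
  sim <- simulateDiploid(cfg)
  expect_identical(sim$hap1, sim$hap2)
  expect_equal(nrow(sim$variants), 0L)
})

test_that("heterozygous site count sits in the binomial band", {
  cfg <- simConfig(genomeLength = 100000L, hetRate = 0.01, seed = 8L)
  sim <- simulateDiploid(cfg)
  n <- nrow(sim$variants)
  mu <- 1e5 * 0.01
  sigma <- sqrt(1e5 * 0.01 * 0.99)
  expect_gt(n, mu - 3 * sigma)
  expect_lt(n, mu + 3 * sigma)
  # hap2 reproduces every substitution at its recorded coordinate
  v <- sim$variants[sim$variants$type == "sub", ]
  expect_true(all(substr(rep(sim$hap2, nrow(v)), v$pos2, v$pos2) == v$alt))
  expect_true(all(substr(rep(sim$hap1, nrow(v)), v$pos1, v$pos1) == v$ref))
})

test_that("repeat copies differ only at their recorded diagnostics", {
  cfg <- simConfig(genomeLength = 30000L, hetRate = 0, nRepeatCopies = 2L,
                   repeatLength = 5000L, repeatDivergence = 0.005,
                   seed = 9L)
  sim <- simulateDiploid(cfg)
  ann <- sim$repeats$annotation
  d <- sim$repeats$diagnostics
  expect_equal(nrow(ann), 2L)
  c1 <- strsplit(substr(sim$hap1, ann$start[1], ann$end[1]), "")[[1]]
  c2 <- strsplit(substr(sim$hap1, ann$start[2], ann$end[2]), "")[[1]]
  diffs <- which(c1 != c2)
  expect_true(all(diffs %in% d$posTemplate))
  expect_gt(length(diffs), 0)
  # each diagnostic allele is present at its genome position
  hap <- strsplit(sim$hap1, "")[[1]]
  expect_true(all(hap[d$posGenome] == d$base))
})

test_that("error-free reads are exact substrings at stated coverage", {
  cfg <- simConfig(genomeLength = 20000L, hetRate = 0, hifiErrorRate = 0,
                   srErrorRate = 0, hifiReadLength = 2000L,
                   hifiCoverage = 12, seed = 10L)
  sim <- simulateDiploid(cfg)
  rr <- simulateReads(sim)
  seqs <- vapply(strsplit(rr$sam[-(1:2)], "\t"), `[`, "", 10L)
  for (s in seqs[seq(1, length(seqs), by = 10)])
    expect_true(grepl(s, sim$hap1, fixed = TRUE))
  total <- sum(nchar(seqs))
  expect_lt(abs(total - 12 * 20000) / (12 * 20000), 0.1)
  expect_equal(nrow(rr$errorLog), 0L)
})

test_that("homopolymer bias concentrates errors in runs", {
  cfg <- simConfig(genomeLength = 60000L, hetRate = 0,
                   homopolymerErrorMultiplier = 10, seed = 12L)
  sim <- simulateDiploid(cfg)
  # a random genome holds >= 15% of its bases in runs of >= 3
  mask <- hifipolish:::.homopolymerMask(sim$hap1)
  expect_gt(mean(mask), 0.15)
  rr <- simulateReads(sim, what = "hifi")
  expect_gt(nrow(rr$errorLog), 100)
  expect_gte(mean(rr$errorLog$inHomopolymer), 0.6)
  # homopolymer errors are indels, others substitutions
  expect_true(all(rr$errorLog$type[rr$errorLog$inHomopolymer] %in%
                    c("ins", "del")))
  expect_true(all(rr$errorLog$type[!rr$errorLog$inHomopolymer] == "sub"))
})

test_that("assembly perturbation is fully ledgered", {
  set.seed(1)
  hap <- randomDna(30000)
  p0 <- perturbAssembly(hap, nSubs = 0L, nIndels = 0L, seed = 3L)
  expect_identical(p0$draft, hap)
  expect_equal(nrow(p0$ledger), 0L)

  p <- perturbAssembly(hap, nSubs = 20L, nIndels = 10L, seed = 3L)
  expect_equal(sum(p$ledger$type == "sub"), 20L)
  expect_equal(sum(p$ledger$type != "sub"), 10L)
  expect_equal(round(mean(p$ledger$inHomopolymer) * 30) , 21)  # 70%
  # substitutions land where the ledger says, in draft coordinates
  subs <- p$ledger[p$ledger$type == "sub", ]
  expect_true(all(substr(rep(p$draft, nrow(subs)), subs$posDraft,
                         subs$posDraft) == subs$alt))
  expect_true(all(substr(rep(hap, nrow(subs)), subs$pos, subs$pos)
                  == subs$ref))
  expect_error(perturbAssembly(hap, nSubs = 100L, nIndels = 0L, seed = 1),
               "exceed")
})

test_that("the simulator is byte-deterministic under a fixed seed", {
  cfg <- simConfig(genomeLength = 8000L, hetRate = 0.01, seed = 33L)
  one <- simulateReads(simulateDiploid(cfg))
  two <- simulateReads(simulateDiploid(cfg))
  expect_identical(one$sam, two$sam)
  expect_identical(as.character(one$shortReads),
                   as.character(two$shortReads))
})

test_that("mismapped repeat reads relocate to homologous coordinates", {
  cfg <- simConfig(genomeLength = 30000L, hetRate = 0, nRepeatCopies = 2L,
                   repeatLength = 5000L, repeatMismapRate = 0.5,
                   hifiReadLength = 2000L, seed = 13L)
  sim <- simulateDiploid(cfg)
  rr <- simulateReads(sim, what = "hifi")
  tr <- rr$truth
  expect_gt(sum(tr$mismapped), 0)
  ann <- sim$repeats$annotation
  mis <- tr[tr$mismapped, ]
  # every mismapped read lies fully inside its target copy
  expect_true(all(mis$start >= ann$start[mis$targetCopy] &
                  mis$end <= ann$end[mis$targetCopy]))
})
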