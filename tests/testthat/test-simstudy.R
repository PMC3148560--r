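# Small simulation scales keep these fast; the heavier Monte-Carlo checks
# live in test-acceptance.R and share cached study data.

tinySpec <- function(sequenceLength = 5e4, sampleSize = 20L,
                     nSampledSnps = 50L, ...) {
  scenarioSpec(sequenceLength = sequenceLength, sampleSize = sampleSize,
               nSampledSnps = nSampledSnps, ...)
}

test_that("scenario specs validate and round-trip through JSON", {
  expect_error(scenarioSpec(theta = -1), "positive")
  expect_error(scenarioSpec(targetFreqRange = c(0.8, 0.6)), "increasing")
  spec <- scenarioSpec("island", migration4Nm = 400, selection2Ns = 0)
  f <- withr::local_tempfile()
  writeScenario(spec, f)
  back <- readScenario(f)
  expect_equal(haploSweep:::scenarioToList(back),
               haploSweep:::scenarioToList(spec))
  writeLines('{"model": "panmictic", "bogus_key": 1}', f)
  expect_error(readScenario(f), "unknown scenario key")
})

test_that("replicates are bit-reproducible from (spec, seed)", {
  spec <- asNeutral(tinySpec())
  r1 <- simulateReplicate(spec, seed = 5)
  r2 <- simulateReplicate(spec, seed = 5)
  expect_identical(alleles(r1@dataset), alleles(r2@dataset))
  expect_identical(physicalPositions(r1@dataset), physicalPositions(r2@dataset))
  r3 <- simulateReplicate(spec, seed = 6)
  expect_false(identical(alleles(r1@dataset), alleles(r3@dataset)))
})

test_that("sweep replicates respect the target frequency window", {
  reps <- simulateReplicates(tinySpec(), 5, seed = 9)
  for (r in reps) {
    expect_false(is.na(r@causalIndex))
    expect_gte(r@causalFreq, 0.6)
    expect_lte(r@causalFreq, 0.8)
    expect_equal(derivedFreq(r@dataset)[r@causalIndex], r@causalFreq)
    expect_gte(r@attempts, 1L)
  }
})

test_that("neutral panmictic diversity matches the coalescent expectation", {
  # E[pairwise diversity per site] = theta = 6e-3 under the neutral
  # coalescent; check the Monte-Carlo mean over replicates within 4 SE
  spec <- asNeutral(scenarioSpec(sequenceLength = 5e4, sampleSize = 20L))
  reps <- simulateReplicates(spec, 60, seed = 33)
  pis <- vapply(reps, function(r) {
    a <- alleles(r@dataset)
    f <- colMeans(a)
    n <- nrow(a)
    sum(2 * f * (1 - f) * n / (n - 1)) / spec@sequenceLength
  }, 1)
  se <- sd(pis) / sqrt(length(pis))
  expect_lt(abs(mean(pis) - 6e-3), 4 * se + 1e-4)
})

test_that("island neutral replicates run and island sweeps are refused", {
  spec <- asNeutral(tinySpec(model = "island", migration4Nm = 40))
  r <- simulateReplicate(spec, seed = 2)
  expect_equal(nHaplotypes(r@dataset), 20L)
  expect_error(simulateReplicate(tinySpec(model = "island"), seed = 2),
               "island")
})

test_that("growth and bottleneck demographies simulate with a sweep", {
  for (m in c("growth", "bottleneck")) {
    r <- simulateReplicate(tinySpec(model = m), seed = 4)
    expect_false(is.na(r@causalIndex))
    expect_gte(r@causalFreq, 0.6)
  }
})

test_that("SNP downsampling keeps the causal site and the MAF floor", {
  rep <- simulateReplicate(tinySpec(sequenceLength = 2e5, sampleSize = 40L,
                                    nSampledSnps = 200L), seed = 77)
  d1 <- downsampleSnps(rep, seed = 1)
  expect_equal(nSites(d1@dataset), 200L)
  expect_false(is.na(d1@causalIndex))
  f <- derivedFreq(d1@dataset)
  expect_true(all(pmin(f, 1 - f) >= 0.05))
  expect_equal(f[d1@causalIndex], rep@causalFreq)

  d2 <- downsampleSnps(rep, seed = 2)
  expect_false(identical(physicalPositions(d1@dataset),
                         physicalPositions(d2@dataset)))
  expect_equal(derivedFreq(d2@dataset)[d2@causalIndex], rep@causalFreq)

  # exactly as many qualifying SNPs as requested: identity up to bookkeeping
  f0 <- derivedFreq(rep@dataset)
  nQual <- sum(pmin(f0, 1 - f0) >= 0.05)
  d3 <- downsampleSnps(rep, nSnps = nQual, seed = 3)
  expect_equal(nSites(d3@dataset), nQual)
  expect_error(downsampleSnps(rep, nSnps = nQual + 1, seed = 3), "available")
})

test_that("causal ranking agrees with a sort-based oracle and tie conventions", {
  sc <- data.frame(snp_index = 1:7,
                   standardized = c(0.5, -2, 1, NA, -1, 1, 0.1))
  # |scores| desc: 2, then a three-way tie at 1 (snps 3, 5, 6) -> rank 3
  expect_equal(causalRank(sc, 2), 1)
  expect_equal(causalRank(sc, 3), 3)
  expect_equal(causalRank(sc, 6), 3)
  r <- causalRank(sc, 4)
  expect_equal(as.numeric(r), (7 + 1) / 2)
  expect_true(attr(r, "undefined"))
  expect_error(causalRank(sc, 99), "not in the scan")

  set.seed(8)
  sc2 <- data.frame(snp_index = 1:50, standardized = rnorm(50))
  ix <- 17
  brute <- which(order(-abs(sc2$standardized)) == ix)
  expect_equal(causalRank(sc2, ix), brute)

  sc3 <- data.frame(snp_index = 1:9, standardized = rep(0.3, 9))
  expect_equal(causalRank(sc3, 5), 5)   # (S+1)/2 under full ties
})

test_that("fixtures are deterministic and leave the caller's RNG alone", {
  set.seed(123); before <- runif(1)
  set.seed(123)
  h1 <- makeFixture("random", list(n = 6, S = 12), seed = 99)
  after <- runif(1)
  expect_equal(before, after)   # RNG state restored around fixture building
  h2 <- makeFixture("random", list(n = 6, S = 12), seed = 99)
  expect_identical(alleles(h1), alleles(h2))
  expect_error(makeFixture("nope", seed = 1), "unknown fixture")
})

test_that("the identical-block fixture keeps carrier EHH at 1 across the block", {
  hd <- makeFixture("identical-block", list(n = 12, S = 41, k = 6,
                                            blockHalfWidth = 10), seed = 6)
  d <- ehhDecay(hd, attr(hd, "coreIndex"), 1)
  blk <- attr(hd, "blockRange")
  inBlock <- d@right$index <= blk[2]
  expect_true(all(d@right$ehh[inBlock] == 1))
  inBlockL <- d@left$index >= blk[1]
  expect_true(all(d@left$ehh[inBlockL] == 1))
})

test_that("a small power/FDR study is reproducible and internally consistent", {
  spec <- tinySpec(sequenceLength = 1e5, sampleSize = 30L, nSampledSnps = 100L)
  rep1 <- powerFdrStudy(spec, nSweepReps = 3L, nNeutralReps = 2L,
                        nNullReps = 8L, alpha = 0.1,
                        statistics = c("ihs", "wihs"), seed = 404,
                        halfWidth = 10L)
  expect_s3_class(rep1, "powerFdrReport")
  expect_equal(dim(rep1$nullStats), c(8L, 2L))
  inUnit <- function(v) all(is.na(v) | (v >= 0 & v <= 1))
  expect_true(inUnit(rep1$power))   # NA allowed: tiny replicates can leave
  expect_true(inUnit(rep1$fdr))     # every window score undefined

  expect_equal(colnames(rep1$causalRanks), c("ihs", "wihs"))

  rep2 <- powerFdrStudy(spec, nSweepReps = 3L, nNeutralReps = 2L,
                        nNullReps = 8L, alpha = 0.1,
                        statistics = c("ihs", "wihs"), seed = 404,
                        halfWidth = 10L)
  expect_identical(rep1$nullStats, rep2$nullStats)
  expect_identical(rep1$causalStats, rep2$causalStats)
})
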