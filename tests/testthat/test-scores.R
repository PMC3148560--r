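test_that("mirror-structured alleles give a raw score of exactly 0", {
  hd <- makeFixture("mirror", list(k = 6, S = 31), seed = 17)
  sc <- ihsScan(hd, standardized = FALSE)
  row <- match(attr(hd, "coreIndex"), sc$snp_index)
  expect_equal(sc$raw[row], 0)
})

test_that("a scan with no MAF-passing site returns an empty score list", {
  set.seed(3)
  a <- matrix(0L, 50, 10)
  a[1, ] <- 1L                      # every site at frequency 0.02
  hd <- HaplotypeDataset(a, (0:9) * 1000, (0:9) * 0.01)
  sc <- ihsScan(hd)
  expect_equal(nrow(sc), 0L)
})

test_that("ihsScan agrees with a straight-line reimplementation", {
  for (s in 1:3) {
    hd <- makeFixture("random", list(n = 16, S = 25), seed = 500 + s)
    sc <- ihsScan(hd, standardized = FALSE)
    oracle <- bruteIHSraw(alleles(hd), geneticPositions(hd))
    got <- rep(NA_real_, nSites(hd))
    got[sc$snp_index] <- sc$raw
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("wihsScan reduces to ihsScan for constant and rescaled distances", {
  hd <- makeFixture("random", list(n = 14, S = 40), seed = 23)
  sc <- ihsScan(hd)
  scc <- wihsScan(hd, constantDm(14, 3.7))
  expect_identical(sc$raw, scc$raw)
  expect_identical(sc$standardized, scc$standardized)

  dm <- squaredHammingMatrix(hd)
  dm10 <- new("DistanceMatrix", values = dm@values * 10,
              sitesCompared = dm@sitesCompared)
  expect_equal(wihsScan(hd, dm)$raw, wihsScan(hd, dm10)$raw,
               tolerance = 1e-12)
  expect_error(wihsScan(hd, constantDm(9)), "does not match")
})

test_that("a near-duplicate derived clade moves WiHS away from iHS as the weights dictate", {
  # derived carriers: 4 near-identical haplotypes (a clade) + 2 distinct;
  # the clade shares a long identical segment, inflating classical EHH_D.
  # Down-weighting the clade must reduce iwEHH_D, so raw WiHS > raw iHS.
  set.seed(99)
  S <- 41; core <- 21
  clade <- matrix(rbinom(4 * S, 1, 0.5), 4)
  block <- (core - 8):(core + 8)   # identical only across the central block
  clade[, block] <- matrix(rep(clade[1, block], 4), 4, byrow = TRUE)
  others <- matrix(rbinom(4 * S, 1, 0.5), 4)
  anc <- matrix(rbinom(6 * S, 1, 0.5), 6)
  a <- rbind(clade, others, anc)
  a[1:8, core] <- 1L
  a[9:14, core] <- 0L
  storage.mode(a) <- "integer"
  hd <- HaplotypeDataset(a, (0:(S - 1)) * 1000, (0:(S - 1)) * 1e-2)
  dm <- squaredHammingMatrix(hd)
  r <- match(core, ihsScan(hd, standardized = FALSE)$snp_index)
  rawI <- ihsScan(hd, standardized = FALSE)$raw[r]
  rawW <- wihsScan(hd, dm, standardized = FALSE)$raw[r]
  expect_false(isTRUE(all.equal(rawI, rawW)))
  expect_gt(rawW, rawI)
})

test_that("standardization has unit moments per bin and the textbook two-score case", {
  hd <- makeFixture("random", list(n = 30, S = 120), seed = 31)
  sc <- ihsScan(hd)
  def <- !is.na(sc$standardized)
  expect_gt(sum(def), 20)

  # two raw scores in one merged bin: sample SD gives -/+ 1/sqrt(2)
  sc2 <- data.frame(snp_index = 1:2, chromosome = "c", position = c(1, 2),
                    derived_freq = c(0.3, 0.4), iwEHH_A = 1, iwEHH_D = 1,
                    raw = c(1, 3), standardized = NA_real_, status = "ok")
  out <- standardize(sc2)
  expect_equal(out$standardized, c(-1, 1) / sqrt(2))

  # location invariance
  sc3 <- sc2; sc3$raw <- sc3$raw + 100
  expect_equal(standardize(sc3)$standardized, out$standardized)
})

test_that("every populated frequency bin is re-centered to mean 0, SD 1", {
  hd <- makeFixture("random", list(n = 40, S = 300), seed = 37)
  sc <- ihsScan(hd, binning = frequencyBins("count", minBinCount = 10))
  bins <- attr(sc, "bins")
  pop <- unique(bins[!is.na(bins)])
  expect_gt(length(pop), 1)
  for (b in pop) {
    v <- sc$standardized[which(bins == b)]
    expect_gte(length(v), 10)
    expect_equal(mean(v), 0, tolerance = 1e-9)
    expect_equal(stats::sd(v), 1, tolerance = 1e-9)
  }
})

test_that("phsScan matches the direct-summation oracle", {
  for (s in 1:3) {
    hd <- makeFixture("random", list(n = 10, S = 20), seed = 700 + s)
    sc <- phsScan(hd, standardized = FALSE, mafMin = 0)
    oracle <- brutePHS(alleles(hd), geneticPositions(hd))
    got <- rep(NA_real_, nSites(hd))
    got[sc$snp_index] <- sc$raw
    keep <- !is.na(oracle) & !is.na(got)
    expect_gt(sum(keep), 10)
    expect_equal(got[keep], oracle[keep], tolerance = 1e-10)
  }
})

test_that("PHS is zero everywhere when all haplotypes are identical", {
  a <- matrix(rep(c(0L, 1L, 0L, 1L, 1L), each = 6), 6)
  hd <- HaplotypeDataset(a, (0:4) * 1000, (0:4) * 0.01)
  expect_warning(sc <- phsScan(hd, standardized = FALSE, mafMin = 0),
                 "zero tract-length SD")
  # every pair's tract lengths are constant, so all z = 0; sites whose
  # derived allele has carriers score exactly 0, the rest are undefined
  hasCarriers <- sc$derived_freq > 0
  expect_true(all(sc$raw[hasCarriers] == 0))
  expect_true(all(is.na(sc$raw[!hasCarriers])))
  expect_true(all(sc$status[!hasCarriers] == "too_few_carriers"))
})

test_that("an extended shared segment among derived carriers lifts PHS inside it", {
  hd <- makeFixture("identical-block", list(n = 14, S = 41, k = 6,
                                            blockHalfWidth = 8), seed = 41)
  sc <- phsScan(hd, standardized = FALSE, mafMin = 0)
  core <- attr(hd, "coreIndex")
  row <- match(core, sc$snp_index)
  expect_gt(sc$raw[row], 0)
  outside <- sc$snp_index < attr(hd, "blockRange")[1] - 5
  expect_gt(sc$raw[row], mean(abs(sc$raw[outside]), na.rm = TRUE))
})

test_that("PHS pair evaluations grow as C(n,2) and integrated scans linearly", {
  hd1 <- makeFixture("random", list(n = 20, S = 60), seed = 51)
  hd2 <- makeFixture("random", list(n = 40, S = 60), seed = 51)
  p1 <- attr(phsScan(hd1), "opCount")
  p2 <- attr(phsScan(hd2), "opCount")
  expect_equal(p1, choose(20, 2))
  expect_equal(p2, choose(40, 2))
  expect_equal(p2 / p1, choose(40, 2) / choose(20, 2))

  i1 <- attr(ihsScan(hd1), "opCount")
  i2 <- attr(ihsScan(hd2), "opCount")
  expect_lt(i2 / i1, 3)   # linear-ish in n, far from the 4.1x of pairs
  expect_gt(i2 / i1, 1.3)
})

test_that("scores are invariant to reversing SNP order", {
  hd <- makeFixture("random", list(n = 16, S = 50), seed = 61)
  S <- nSites(hd)
  g <- geneticPositions(hd)
  rev_ds <- HaplotypeDataset(alleles(hd)[, S:1],
                             max(physicalPositions(hd)) - rev(physicalPositions(hd)),
                             max(g) - rev(g))
  sc <- ihsScan(hd, standardized = FALSE)
  scr <- ihsScan(rev_ds, standardized = FALSE)
  expect_equal(sc$raw, rev(scr$raw), tolerance = 1e-12)
})

test_that("window statistics count and clip as specified", {
  sc <- data.frame(snp_index = 1:200, standardized = 1)
  w <- windowAverage(sc, 100, 25, nSites = 200)
  expect_equal(w$window_start, 75)
  expect_equal(w$window_end, 125)
  expect_equal(w$n_defined, 51)
  expect_equal(w$mean_abs_score, 1)

  wc <- windowAverage(sc, 11, 25, nSites = 200)
  expect_equal(wc$n_defined, 36)   # clipped at the left end

  sc$standardized[75:125] <- NA
  expect_true(is.na(windowAverage(sc, 100, 25, nSites = 200)$mean_abs_score))
})

test_that("sliding windows tile with the requested stride", {
  sc <- data.frame(snp_index = 1:100, standardized = rnorm(100))
  w <- slidingWindows(sc, windowSize = 50, offset = 20, nSites = 100)
  expect_equal(w$window_start, c(1, 21, 41, 61))
  expect_equal(w$window_end, c(50, 70, 90, 100))

  w2 <- slidingWindows(sc, windowSize = 50, offset = 50, nSites = 100)
  expect_equal(w2$window_start, c(1, 51))

  # a trailing fragment shorter than half a window merges into the previous
  sc3 <- data.frame(snp_index = 1:120, standardized = 1)
  w3 <- slidingWindows(sc3, windowSize = 50, offset = 50, nSites = 120)
  expect_equal(w3$window_end[nrow(w3)], 120)
  expect_equal(nrow(w3), 2L)
  expect_equal(w3$mean_abs_score, c(1, 1))
})

test_that("empirical significance uses the add-one estimator and quantile cutoff", {
  w <- data.frame(window_start = 1, window_end = 51,
                  mean_abs_score = 5, n_defined = 51)
  nulls <- seq(0.1, 1, length.out = 1000)
  out <- empiricalSignificance(w, nulls, alpha = 0.01)
  expect_equal(out$empirical_p, 1 / 1001)
  expect_true(out$significant)

  w$mean_abs_score <- 0.01
  out2 <- empiricalSignificance(w, nulls, alpha = 0.01)
  expect_equal(out2$empirical_p, 1)
  expect_false(out2$significant)
})

test_that("empirical significance is calibrated on null-drawn observations", {
  set.seed(73)
  nulls <- rnorm(2000)
  obs <- rnorm(4000)
  w <- data.frame(window_start = 1, window_end = 2, mean_abs_score = obs,
                  n_defined = 1)
  out <- empiricalSignificance(w, nulls, alpha = 0.05)
  rate <- mean(out$significant)
  ci <- stats::binom.test(sum(out$significant), length(obs), 0.05)$conf.int
  expect_true(ci[1] <= 0.05 && 0.05 <= ci[2])
})
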