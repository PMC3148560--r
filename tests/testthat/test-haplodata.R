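test_that("tsv dialect parses and round-trips", {
  f <- withr::local_tempfile()
  writeLines(c("100\t200\t300",
               "0\t0\t1", "1\t0\t1", "0\t1\t0", "1\t1\t0"), f)
  hd <- readHaplotypes(f, "tsv")
  expect_equal(nHaplotypes(hd), 4L)
  expect_equal(nSites(hd), 3L)
  expect_equal(physicalPositions(hd), c(100, 200, 300))
  expect_equal(alleles(hd)[2, ], c(1L, 0L, 1L))

  f2 <- withr::local_tempfile()
  hd2 <- makeFixture("random", list(n = 7, S = 25), seed = 3)
  a <- alleles(hd2); a[2, 5] <- NA; a[4, 1] <- NA
  hd2 <- HaplotypeDataset(a, physicalPositions(hd2))
  writeHaplotypes(hd2, f2)
  back <- readHaplotypes(f2, "tsv")
  expect_identical(alleles(back), alleles(hd2))
  expect_equal(physicalPositions(back), physicalPositions(hd2))
})

test_that("ms positions scale to bp and duplicate positions are jittered", {
  f <- withr::local_tempfile()
  writeLines(c("msbridge 3 1", "123", "", "//", "segsites: 2",
               "positions: 0.25 0.75", "01", "10", "11"), f)
  hd <- readHaplotypes(f, "ms", sequenceLength = 2e6)
  expect_equal(physicalPositions(hd), c(5e5, 1.5e6))
  expect_equal(nHaplotypes(hd), 3L)

  f2 <- withr::local_tempfile()
  writeLines(c("//", "segsites: 3", "positions: 0.2 0.20000004 0.9",
               "010", "101", "110"), f2)
  expect_warning(hd2 <- readHaplotypes(f2, "ms", sequenceLength = 1e6),
                 "jittered")
  expect_equal(physicalPositions(hd2), c(2e5, 2e5 + 1, 9e5))
})

vcfLines <- function(gts, aa = c("A", "A", "A"), alt = c("G", "T", "C")) {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2"), collapse = "\t"),
    vapply(1:3, function(k) {
      info <- if (is.na(aa[k])) "." else paste0("AA=", aa[k])
      paste(c("chr7", 1000 * k, ".", "A", alt[k], ".", "PASS", info, "GT",
              gts[[k]]), collapse = "\t")
    }, ""))
}

test_that("vcf reading polarizes by the AA annotation", {
  f <- withr::local_tempfile()
  # site 2: AA == ALT, so REF carriers are derived (recode REF -> 1)
  writeLines(vcfLines(list(c("0|1", "1|1"), c("0|1", "0|0"), c("1|0", "0|1")),
                      aa = c("A", "T", "A"), alt = c("G", "T", "C")), f)
  hd <- readHaplotypes(f, "vcf")
  expect_equal(nHaplotypes(hd), 4L)
  expect_equal(nSites(hd), 3L)
  # site 1: AA = REF, coding unchanged: haplotypes s1a,s1b,s2a,s2b = 0,1,1,1
  expect_equal(alleles(hd)[, 1], c(0L, 1L, 1L, 1L))
  # site 2: AA = ALT, flipped: GT 0|1 0|0 -> 1,0,1,1
  expect_equal(alleles(hd)[, 2], c(1L, 0L, 1L, 1L))
  # POS converts 1-based -> 0-based
  expect_equal(physicalPositions(hd), c(999, 1999, 2999))
})

test_that("vcf sites without a usable ancestral state are dropped and counted", {
  f <- withr::local_tempfile()
  # site 2 has no AA tag; sites 1 and 3 stay usable
  writeLines(vcfLines(list(c("0|1", "1|1"), c("0|1", "0|0"), c("1|0", "0|1")),
                      aa = c("A", NA, "C"), alt = c("G", "T", "C")), f)
  hd <- readHaplotypes(f, "vcf")
  expect_equal(nSites(hd), 2L)
  expect_equal(unname(attr(hd, "droppedSites")["no_ancestral"]), 1L)

  # AA matching neither allele counts as unusable too; with only one site
  # left the dataset is rejected
  writeLines(vcfLines(list(c("0|1", "1|1"), c("0|1", "0|0"), c("1|0", "0|1")),
                      aa = c("A", NA, "G"), alt = c("G", "T", "C")), f)
  expect_error(readHaplotypes(f, "vcf"), "fewer than 2")
})

test_that("unphased genotypes are a hard error naming the record", {
  f <- withr::local_tempfile()
  writeLines(vcfLines(list(c("0|1", "1|1"), c("0/1", "0|0"), c("1|0", "0|1"))), f)
  expect_error(readHaplotypes(f, "vcf"), "unphased.*chr7:2000")
})

test_that("multiallelic sites are skipped with a warning", {
  f <- withr::local_tempfile()
  writeLines(vcfLines(list(c("0|1", "1|1"), c("0|1", "0|0"), c("1|0", "0|1")),
                      alt = c("G", "T,C", "C")), f)
  expect_warning(hd <- readHaplotypes(f, "vcf"), "multiallelic")
  expect_equal(nSites(hd), 2L)
})

test_that("linear and polynomial genetic maps are recovered exactly", {
  gm <- fitGeneticMap(data.frame(bp = c(0, 1e6, 2e6), cM = c(0, 1, 2)),
                      degree = 1)
  expect_equal(mapPosition(gm, 5e5), 0.5)
  expect_false(gm@piecewise)

  bp <- seq(0, 2e6, length.out = 9)
  cm <- (bp / 1e6)^2
  gm2 <- fitGeneticMap(data.frame(bp = bp, cM = cm), degree = 2)
  expect_equal(mapPosition(gm2, bp), cm, tolerance = 1e-8)
})

test_that("a non-monotone polynomial fit falls back to piecewise-linear", {
  # plateau then rise: an unconstrained cubic undershoots on the plateau
  anchors <- data.frame(bp = c(0, 1, 2, 3, 4, 5, 6) * 1e5,
                        cM = c(0, 0.01, 0.02, 0.03, 2, 6, 6.1))
  gm3 <- fitGeneticMap(anchors, degree = 3)
  # independent check that the unconstrained cubic really is non-monotone
  co <- stats::lm(cM ~ poly(bp, 3, raw = TRUE), data = anchors)$coefficients
  grid <- seq(0, 6e5, length.out = 200)
  vals <- cbind(1, grid, grid^2, grid^3) %*% co
  expect_true(is.unsorted(vals))
  expect_true(gm3@piecewise)
  g <- mapPosition(gm3, seq(0, 6e5, length.out = 500))
  expect_false(is.unsorted(g))
})

test_that("fitted maps are monotone over the anchor range for random anchors", {
  for (s in 1:20) {
    set.seed(s)
    k <- sample(5:12, 1)
    bp <- sort(sample.int(1e6, k))
    cm <- cumsum(runif(k, 0, 2))
    gm <- fitGeneticMap(data.frame(bp = bp, cM = cm),
                        degree = sample(1:4, 1))
    g <- mapPosition(gm, seq(min(bp), max(bp), length.out = 400))
    expect_false(is.unsorted(g), info = paste("seed", s))
  }
})

test_that("map fitting validates its inputs", {
  expect_error(fitGeneticMap(data.frame(bp = c(0, 1e6), cM = c(0, 1)),
                             degree = 3), "at least degree")
  expect_error(fitGeneticMap(data.frame(bp = c(0, 1e6, 2e6),
                                        cM = c(0, 2, 1)), degree = 1),
               "non-decreasing")
})

test_that("assignGeneticPositions composes with the fitted map", {
  hd <- makeFixture("random", list(n = 4, S = 3), seed = 1)
  hd@physicalPositions <- c(0, 1e6, 2e6)
  gm <- fitGeneticMap(data.frame(bp = c(0, 1e6, 2e6), cM = c(0, 1, 2)),
                      degree = 1)
  out <- assignGeneticPositions(hd, gm)
  expect_equal(geneticPositions(out), c(0, 1, 2))
  expect_equal(nSites(out), nSites(hd))

  # constant (degree-0) map: zero-width trapezoids everywhere
  gm0 <- fitGeneticMap(data.frame(bp = c(0, 1e6, 2e6), cM = c(1, 1, 1)),
                       degree = 0)
  out0 <- assignGeneticPositions(hd, gm0)
  expect_true(all(geneticPositions(out0) == 1))
  hd2 <- makeFixture("random", list(n = 12, S = 21), seed = 5)
  hd2@geneticPositions <- rep(1, 21)
  dec <- ehhDecay(hd2, 11, 1)
  expect_equal(as.numeric(integrateEHH(dec)), 0)
})

test_that("score tables round-trip through TSV", {
  empty <- data.frame(chromosome = character(0), position = numeric(0),
                      derived_freq = numeric(0), iwEHH_A = numeric(0),
                      iwEHH_D = numeric(0), raw = numeric(0),
                      standardized = numeric(0))
  f <- withr::local_tempfile()
  writeScores(empty, f)
  expect_equal(nrow(readScores(f)), 0L)

  set.seed(42)
  sc <- data.frame(chromosome = "chr2", position = sort(sample.int(1e6, 100)),
                   derived_freq = round(runif(100), 6),
                   iwEHH_A = round(runif(100, 0, 5), 9),
                   iwEHH_D = round(runif(100, 0, 5), 9),
                   raw = round(rnorm(100), 9),
                   standardized = round(rnorm(100), 9))
  writeScores(sc, f)
  back <- readScores(f)
  expect_equal(back, sc)

  w <- data.frame(window_start = c(1, 21), window_end = c(50, 70),
                  mean_abs_score = c(0.5, 1.25), rank = c(2, 1),
                  empirical_p = c(0.5, 0.001))
  writeScores(w, f)
  expect_equal(readScores(f), w)
})

test_that("HaplotypeDataset validity catches malformed input", {
  expect_error(HaplotypeDataset(matrix(0:1, 1), c(1)), "at least 2")
  expect_error(HaplotypeDataset(matrix(c(0L, 2L, 1L, 0L), 2), c(1, 2)),
               "0, 1 or NA")
  expect_error(HaplotypeDataset(matrix(0L, 2, 2), c(2, 1)),
               "strictly increasing")
})
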