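# Shared Monte-Carlo study data for the acceptance-level tests.
#
# Study conditions are the design's parameters (theta = 6e-3, rho = 8e-4,
# Ne = 1000, n = 100 chromosomes, sweep 2Ns = 200 conditioned on final
# derived frequency 0.6-0.8). The main arms run at a reduced sequence
# length of 500 kb with a proportionally reduced panel of 1000 sampled
# SNPs (the full design is 2 Mbp / 4000 SNPs); the selection-strength arm
# needs 1 Mbp (see studySelectionCurve). Everything is simulated once per
# test run from fixed seeds and cached across test files; replicates are
# simulated and scored in small chunks to bound memory.

.studyEnv <- new.env(parent = emptyenv())

studySpec <- function(model = "panmictic", ...) {
  scenarioSpec(model, sequenceLength = 5e5, sampleSize = 100L,
               nSampledSnps = 1000L, ...)
}

# simulate n replicates in chunks, apply fun(rep, globalIndex), discard
simChunks <- function(spec, n, baseSeed, fun, chunk = 10L) {
  out <- vector("list", n)
  idx <- 0L
  for (ck in seq_len(ceiling(n / chunk))) {
    k <- min(chunk, n - (ck - 1L) * chunk)
    reps <- suppressWarnings(
      simulateReplicates(spec, k, seed = baseSeed + 7919L * (ck - 1L)))
    for (j in seq_len(k)) {
      idx <- idx + 1L
      out[[idx]] <- fun(reps[[j]], idx)
    }
    rm(reps)
    gc(FALSE)
  }
  out
}

studyScan <- function(ds, st) {
  suppressWarnings(switch(st,
    ihs = ihsScan(ds),
    wihs = wihsScan(ds, squaredHammingMatrix(ds)),
    phs = phsScan(ds)))
}

studyNull <- function() {
  if (!is.null(.studyEnv$null)) return(.studyEnv$null)
  stats <- c("ihs", "wihs", "phs")
  rows <- simChunks(asNeutral(studySpec()), 200L, 482001L, function(rep, i) {
    d <- downsampleSnps(rep, seed = 9000L + i)
    ds <- d@dataset
    ctr <- ((9973L * i) %% nSites(ds)) + 1L   # deterministic uniform center
    vapply(stats, function(st)
      windowAverage(studyScan(ds, st), ctr, 25L,
                    nSites(ds))$mean_abs_score, 1)
  })
  m <- do.call(rbind, rows)
  .studyEnv$null <- list(
    stats = m,
    cutoff = apply(m, 2, quantile, probs = 0.99, names = FALSE, na.rm = TRUE))
  .studyEnv$null
}

studyPanmicticSweeps <- function() {
  if (!is.null(.studyEnv$pan)) return(.studyEnv$pan)
  stats <- c("ihs", "wihs", "phs")
  rows <- simChunks(studySpec(), 50L, 771002L, function(rep, i) {
    d <- downsampleSnps(rep, seed = 31000L + i)
    ds <- d@dataset
    sapply(stats, function(st) {
      sc <- studyScan(ds, st)
      c(window = windowAverage(sc, d@causalIndex, 25L,
                               nSites(ds))$mean_abs_score,
        rank = causalRank(sc, d@causalIndex))
    })
  })
  .studyEnv$pan <- list(
    window = t(vapply(rows, function(m) m["window", ], numeric(3))),
    rank = t(vapply(rows, function(m) m["rank", ], numeric(3))))
  .studyEnv$pan
}

studyGrowthSweeps <- function() {
  if (!is.null(.studyEnv$growth)) return(.studyEnv$growth)
  rows <- simChunks(studySpec("growth"), 40L, 113003L, function(rep, i) {
    d <- downsampleSnps(rep, seed = 52000L + i)
    ds <- d@dataset
    vapply(c("ihs", "wihs"), function(st)
      windowAverage(studyScan(ds, st), d@causalIndex, 25L,
                    nSites(ds))$mean_abs_score, 1)
  })
  .studyEnv$growth <- list(window = do.call(rbind, rows))
  .studyEnv$growth
}

# Selection-strength curve. This arm runs at 1 Mbp / 2000 SNPs: at 500 kb
# the sweep footprint spans so much of the region that within-replicate
# standardization absorbs the signal and the power gradient over 2Ns is
# unmeasurable; at 1 Mbp it resolves.
studySelectionCurve <- function() {
  if (!is.null(.studyEnv$curve)) return(.studyEnv$curve)
  bigSpec <- function(...)
    scenarioSpec(sequenceLength = 1e6, sampleSize = 100L,
                 nSampledSnps = 2000L, ...)
  wihsWindow <- function(rep, dsSeed, center = NULL) {
    d <- downsampleSnps(rep, seed = dsSeed)
    ds <- d@dataset
    ctr <- if (!is.na(d@causalIndex)) d@causalIndex else center
    sc <- studyScan(ds, "wihs")
    windowAverage(sc, ctr, 25L, nSites(ds))$mean_abs_score
  }
  nv <- unlist(simChunks(asNeutral(bigSpec()), 60L, 355007L,
                         function(rep, i)
    wihsWindow(rep, dsSeed = 81000L + i,
               center = ((7919L * i) %% 2000L) + 1L)))
  cutoff <- quantile(nv, 0.99, names = FALSE, na.rm = TRUE)
  stats <- list()
  for (s2 in c(50, 100, 150, 200)) {
    stats[[as.character(s2)]] <- unlist(simChunks(
      bigSpec(selection2Ns = s2), 20L, 410008L + s2,
      function(rep, i) wihsWindow(rep, dsSeed = 92000L + 101L * s2 + i)))
  }
  .studyEnv$curve <- list(cutoff = cutoff, nullStats = nv, stats = stats)
  .studyEnv$curve
}

# FDR arm: all tiling 51-SNP windows of neutral replicates of a scenario,
# scored against the panmictic cutoff
studyFdr <- function(model, migration4Nm = 40) {
  key <- paste0("fdr_", model)
  if (!is.null(.studyEnv[[key]])) return(.studyEnv[[key]])
  cutoff <- studyNull()$cutoff
  stats <- c("ihs", "wihs")
  rows <- simChunks(asNeutral(studySpec(model, migration4Nm = migration4Nm)),
                    60L, if (model == "island") 821004L else 935005L,
                    function(rep, i) {
    d <- downsampleSnps(rep, seed = 64000L + i)
    ds <- d@dataset
    sapply(stats, function(st) {
      sc <- studyScan(ds, st)
      w <- slidingWindows(sc, windowSize = 51L, offset = 51L,
                          nSites = nSites(ds))
      c(hits = sum(w$mean_abs_score > cutoff[st], na.rm = TRUE),
        total = sum(!is.na(w$mean_abs_score)))
    })
  })
  hits <- colSums(t(vapply(rows, function(m) m["hits", ], numeric(2))))
  tot <- colSums(t(vapply(rows, function(m) m["total", ], numeric(2))))
  .studyEnv[[key]] <- list(hits = hits, total = tot, fdr = hits / tot)
  .studyEnv[[key]]
}
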