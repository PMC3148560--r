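#' Build a simulation scenario
#'
#' Defaults are the study conditions of the simulation design: 2-Mbp
#' sequences, 100 sampled chromosomes, population-scaled mutation rate
#' theta = 6e-3 and recombination rate rho = 8e-4 per site, Ne = 1000,
#' a sweep with 2Ns = 200 conditioned on a present-day derived frequency
#' between 0.6 and 0.8, and 4000 sampled SNPs with MAF >= 0.05. Set
#' \code{selection2Ns = 0} (or use [asNeutral()]) for neutral replicates.
#'
#' Growth- and bottleneck-epoch timings are not pinned down by the study
#' design beyond their shape (exponential growth to the present size;
#' a temporary reduction to one fifth of Ne with later recovery); the
#' defaults below are configurable approximations.
#'
#' @param model \code{"panmictic"}, \code{"island"}, \code{"growth"} or
#'   \code{"bottleneck"}.
#' @param sequenceLength,sampleSize,theta,rho,Ne core parameters (see
#'   [ScenarioSpec-class]).
#' @param selection2Ns scaled selection coefficient 2Ns (0 = neutral).
#' @param migration4Nm island migration rate 4Nm (one of 4, 40, 400 in the
#'   study design).
#' @param bottleneckDepth,bottleneckStart,bottleneckEnd bottleneck size
#'   fraction and epoch edges (units of 2Ne generations). Epochs default to
#'   times older than the typical sweep origination, since the backend
#'   cannot change population size while the sweep phase is running.
#' @param growthStart,ancestralSizeFraction growth-model onset and
#'   ancestral size fraction.
#' @param sweepStartTime requested sweep start (NA = duration set by the
#'   selection coefficient; the built-in backend does not take a start
#'   time).
#' @param targetFreqRange accepted present-day derived-frequency window of
#'   the sweep site.
#' @param nSampledSnps,mafMin SNP downsampling parameters.
#' @return a [ScenarioSpec-class]
#' @examples
#' scenarioSpec("panmictic")
#' asNeutral(scenarioSpec("island", migration4Nm = 40))
#' @export
scenarioSpec <- function(model = c("panmictic", "island", "growth", "bottleneck"),
                         sequenceLength = 2e6, sampleSize = 100L,
                         theta = 6e-3, rho = 8e-4, Ne = 1000,
                         selection2Ns = 200, migration4Nm = 40,
                         bottleneckDepth = 0.2, bottleneckStart = 0.15,
                         bottleneckEnd = 0.25, growthStart = 0.15,
                         ancestralSizeFraction = 0.1, sweepStartTime = NA_real_,
                         targetFreqRange = c(0.6, 0.8),
                         nSampledSnps = 4000L, mafMin = 0.05) {
  new("ScenarioSpec", model = match.arg(model),
      sequenceLength = sequenceLength, sampleSize = as.integer(sampleSize),
      theta = theta, rho = rho, Ne = Ne, selection2Ns = selection2Ns,
      migration4Nm = migration4Nm, bottleneckDepth = bottleneckDepth,
      bottleneckStart = bottleneckStart, bottleneckEnd = bottleneckEnd,
      growthStart = growthStart, ancestralSizeFraction = ancestralSizeFraction,
      sweepStartTime = sweepStartTime, targetFreqRange = targetFreqRange,
      nSampledSnps = as.integer(nSampledSnps), mafMin = mafMin)
}

#' @describeIn scenarioSpec the same scenario without selection
#' @param spec a [ScenarioSpec-class]
#' @export
asNeutral <- function(spec) {
  spec@selection2Ns <- 0
  spec
}

scenarioToList <- function(spec) {
  list(model = spec@model, sequenceLength = spec@sequenceLength,
       sampleSize = spec@sampleSize, theta = spec@theta, rho = spec@rho,
       Ne = spec@Ne, selection2Ns = spec@selection2Ns,
       migration4Nm = spec@migration4Nm,
       bottleneckDepth = spec@bottleneckDepth,
       bottleneckStart = spec@bottleneckStart,
       bottleneckEnd = spec@bottleneckEnd,
       growthStart = spec@growthStart,
       ancestralSizeFraction = spec@ancestralSizeFraction,
       sweepStartTime = spec@sweepStartTime,
       targetFreqRange = spec@targetFreqRange,
       nSampledSnps = spec@nSampledSnps, mafMin = spec@mafMin)
}

#' Read / write a scenario configuration file (JSON)
#'
#' The schema is the argument list of [scenarioSpec()]; unknown keys are an
#' error, missing keys take the defaults.
#'
#' @param path file path
#' @param spec a [ScenarioSpec-class]
#' @return \code{readScenario}: a [ScenarioSpec-class]
#' @export
readScenario <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  l <- l[!vapply(l, is.null, TRUE)]   # JSON null = take the default
  known <- names(formals(scenarioSpec))
  bad <- setdiff(names(l), known)
  if (length(bad)) stop("unknown scenario key(s): ", paste(bad, collapse = ", "))
  do.call(scenarioSpec, l)
}

#' @rdname readScenario
#' @export
writeScenario <- function(spec, path) {
  jsonlite::write_json(scenarioToList(spec), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

# uniform genetic-map density implied by the scenario: per-generation
# per-bp crossover rate rho/(4 Ne), times 100 for cM
scenarioCMperBp <- function(spec) 100 * spec@rho / (4 * spec@Ne)

pythonBinary <- function() {
  p <- getOption("haploSweep.python", Sys.which("python"))
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p))
    stop("coalescent backend unavailable: no 'python' with msprime on PATH ",
         "(set options(haploSweep.python = ...))")
  p
}

#' Simulate replicates under a scenario
#'
#' Runs the coalescent backend (msprime, bridged through ms-format) for
#' \code{n} replicates. Sweep replicates are conditioned by rejection
#' sampling on the causal site's sampled derived frequency lying in
#' \code{targetFreqRange(spec)}; the accepted seed and the number of
#' attempts are recorded in each [SimReplicate-class]. A uniform genetic
#' map at the scenario's cM/bp density is attached. Everything is
#' reproducible from (spec, seed).
#'
#' The built-in backend simulates sweeps in single-deme models
#' (panmictic, growth, bottleneck); island-model replicates are neutral
#' only, and requesting island + selection is an error pointing at
#' ms-format import of external simulator output.
#'
#' @param spec a [ScenarioSpec-class]
#' @param n number of replicates
#' @param seed integer base seed (< 2^31)
#' @param maxRejects per-replicate cap on frequency rejections
#' @return list of [SimReplicate-class]
#' @export
simulateReplicates <- function(spec, n = 1L, seed, maxRejects = 100L) {
  validObject(spec)
  if (spec@model == "island" && spec@selection2Ns > 0)
    stop("the built-in msprime backend cannot simulate a sweep in the ",
         "two-deme island model; simulate externally (e.g. msms) and load ",
         "the ms output with readHaplotypes(format = 'ms')")
  script <- system.file("python", "simulate_backend.py", package = "haploSweep")
  if (!nzchar(script)) stop("backend script not found in installed package")

  sl <- scenarioToList(spec)
  sl$maxRejects <- maxRejects
  specFile <- tempfile(fileext = ".json")
  msFile <- tempfile(fileext = ".ms")
  metaFile <- tempfile(fileext = ".json")
  on.exit(unlink(c(specFile, msFile, metaFile)))
  jsonlite::write_json(sl, specFile, auto_unbox = TRUE, digits = NA,
                       null = "null")

  out <- suppressWarnings(system2(
    pythonBinary(), c(script, "--spec", specFile, "--n", n,
                      "--seed", format(as.integer(seed), scientific = FALSE),
                      "--ms-out", msFile, "--meta-out", metaFile),
    stdout = TRUE, stderr = TRUE))
  code <- attr(out, "status")
  if (!is.null(code) && code != 0)
    stop("coalescent backend (msprime) failed [exit ", code, "]:\n",
         paste(out, collapse = "\n"))

  blocks <- parseMsBlocks(readLines(msFile))
  meta <- jsonlite::read_json(metaFile, simplifyVector = FALSE)
  if (length(blocks) != n || length(meta) != n)
    stop("backend returned ", length(blocks), " blocks for ", n, " replicates")

  lapply(seq_len(n), function(i) {
    ds <- msBlockToDataset(blocks[[i]], spec@sequenceLength,
                           chromosomeId = sprintf("sim%d", i))
    ds <- assignUniformMap(ds, scenarioCMperBp(spec))
    m <- meta[[i]]
    ci <- if (m$causal_index >= 0) m$causal_index + 1L else NA_integer_
    new("SimReplicate", dataset = ds, causalIndex = ci,
        causalFreq = if (is.null(m$causal_freq)) NA_real_ else m$causal_freq,
        seed = as.integer(m$seed), scenario = spec,
        attempts = as.integer(m$attempts))
  })
}

#' @rdname simulateReplicates
#' @export
simulateReplicate <- function(spec, seed, maxRejects = 100L)
  simulateReplicates(spec, 1L, seed, maxRejects)[[1]]

# run expr with a local RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Randomly downsample SNPs to a fixed panel
#'
#' Draws \code{nSnps} SNPs with minor allele frequency at least
#' \code{mafMin} uniformly without replacement (order preserved),
#' emulating array-style SNP ascertainment. The causal SNP, when present,
#' is force-included and its index in the new grid recorded.
#'
#' @param rep a [SimReplicate-class]
#' @param nSnps panel size; defaults to the scenario's
#'   \code{nSampledSnps}.
#' @param mafMin frequency floor; defaults to the scenario's.
#' @param seed integer seed for the draw
#' @return a [SimReplicate-class] with the reduced dataset
#' @export
downsampleSnps <- function(rep, nSnps = NULL, mafMin = NULL, seed) {
  spec <- rep@scenario
  if (is.null(nSnps)) nSnps <- spec@nSampledSnps
  if (is.null(mafMin)) mafMin <- spec@mafMin
  ds <- rep@dataset
  f <- derivedFreq(ds)
  qual <- which(pmin(f, 1 - f) >= mafMin)
  if (length(qual) < nSnps)
    stop("only ", length(qual), " SNPs with MAF >= ", mafMin,
         " available, need ", nSnps)
  causal <- rep@causalIndex
  pick <- withSeed(seed, {
    if (!is.na(causal)) {
      pool <- setdiff(qual, causal)
      sort(c(causal, sample(pool, nSnps - 1L)))
    } else sort(sample(qual, nSnps))
  })
  a <- alleles(ds)[, pick, drop = FALSE]
  sub <- HaplotypeDataset(a, physicalPositions(ds)[pick],
                          geneticPositions(ds)[pick],
                          sequenceIds(ds), chromosomeId(ds))
  newCausal <- if (!is.na(causal)) match(causal, pick) else NA_integer_
  initialize(rep, dataset = sub, causalIndex = as.integer(newCausal))
}

#' Rank of the causal SNP by absolute standardized score
#'
#' SNPs are sorted by \code{|standardized|} descending; ties get the
#' average rank. When the causal SNP's score is undefined it gets the
#' midpoint convention \code{(n_defined + n_undefined + 1)/2} and the
#' result carries \code{attr(, "undefined") = TRUE}.
#'
#' @param scores a scan result (see [ihsScan()])
#' @param causalIndex SNP index (in the scanned dataset's grid) of the
#'   selected site
#' @return numeric rank (1 = highest absolute score)
#' @export
causalRank <- function(scores, causalIndex) {
  row <- match(causalIndex, scores$snp_index)
  if (is.na(row)) stop("causal SNP index ", causalIndex, " not in the scan")
  s <- abs(scores$standardized)
  if (is.na(s[row])) {
    out <- (length(s) + 1) / 2
    attr(out, "undefined") <- TRUE
    return(out)
  }
  # NAs keep no rank: defined scores are ranked among themselves, which
  # equals their rank with undefined scores sorted to the bottom
  r <- rank(-s, ties.method = "average", na.last = "keep")
  unname(r[row])
}

scanByName <- function(ds, statistic, mafMin = 0.05) {
  switch(statistic,
         ihs = ihsScan(ds, mafMin = mafMin),
         wihs = wihsScan(ds, squaredHammingMatrix(ds), mafMin = mafMin),
         phs = phsScan(ds, mafMin = mafMin),
         stop("unknown statistic: ", statistic))
}

#' Power and false-discovery-rate study
#'
#' Reproduces the simulation-study evaluation for one scenario:
#' \enumerate{
#'   \item \strong{Null distribution}: \code{nNullReps} neutral replicates
#'     of \code{nullSpec} (panmictic by default) are scanned and the
#'     windowed statistic (mean absolute standardized score in a
#'     \code{halfWidth}-SNP window) evaluated at one uniformly random SNP
#'     per replicate; the cutoff is its \code{1 - alpha} quantile.
#'   \item \strong{Power}: the fraction of \code{nSweepReps} sweep
#'     replicates of \code{scenario} whose window statistic at the causal
#'     SNP exceeds the cutoff.
#'   \item \strong{FDR}: the fraction of all tiling
#'     \code{2*halfWidth+1}-SNP windows exceeding the cutoff in
#'     \code{nNeutralReps} neutral replicates of \code{scenario}.
#' }
#' All requested statistics are evaluated on the same replicates, so
#' power/score comparisons between statistics are paired.
#'
#' @param scenario sweep scenario (its neutral version is used for the FDR
#'   arm).
#' @param nSweepReps,nNeutralReps,nNullReps replicate counts; 0 skips an
#'   arm.
#' @param nullSpec scenario for the null distribution; default: the
#'   panmictic neutral version of \code{scenario}.
#' @param alpha significance level.
#' @param statistics subset of \code{c("ihs", "wihs", "phs")}.
#' @param seed integer base seed.
#' @param halfWidth window half-width in SNPs (default 25).
#' @return a \code{powerFdrReport} list: per-statistic \code{cutoff},
#'   \code{power} with binomial CI, \code{fdr}, the per-replicate null and
#'   causal-window statistics, causal ranks, and all seeds.
#' @export
powerFdrStudy <- function(scenario, nSweepReps, nNeutralReps = 0L,
                          nullSpec = NULL, nNullReps = 200L, alpha = 0.01,
                          statistics = c("ihs", "wihs", "phs"), seed,
                          halfWidth = 25L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  if (nNullReps < 1L) stop("need null replicates")
  statistics <- match.arg(statistics, several.ok = TRUE)
  if (is.null(nullSpec)) {
    nullSpec <- asNeutral(scenario)
    nullSpec@model <- "panmictic"
  }
  seed <- as.integer(seed)

  # (1) null distribution, one random window per neutral panmictic replicate
  nullReps <- simulateReplicates(nullSpec, nNullReps, seed)
  nullStats <- matrix(NA_real_, nNullReps, length(statistics),
                      dimnames = list(NULL, statistics))
  for (i in seq_len(nNullReps)) {
    ds0 <- downsampleSnps(nullReps[[i]], seed = seed + 7L * i)
    ctr <- withSeed(seed + 13L * i,
                    sample.int(nSites(ds0@dataset), 1L))
    for (st in statistics) {
      sc <- scanByName(ds0@dataset, st, mafMin = nullSpec@mafMin)
      nullStats[i, st] <- windowAverage(sc, ctr, halfWidth,
                                        nSites(ds0@dataset))$mean_abs_score
    }
  }
  cutoff <- apply(nullStats, 2, stats::quantile, probs = 1 - alpha,
                  names = FALSE, na.rm = TRUE)

  # (2) power at the causal window of sweep replicates
  causalStats <- matrix(NA_real_, nSweepReps, length(statistics),
                        dimnames = list(NULL, statistics))
  ranks <- causalStats
  sweepSeeds <- integer(0)
  if (nSweepReps > 0L) {
    sweepReps <- simulateReplicates(scenario, nSweepReps, seed + 1000003L)
    sweepSeeds <- vapply(sweepReps, function(r) r@seed, 1L)
    for (i in seq_len(nSweepReps)) {
      ds0 <- downsampleSnps(sweepReps[[i]], seed = seed + 17L * i)
      for (st in statistics) {
        sc <- scanByName(ds0@dataset, st, mafMin = scenario@mafMin)
        causalStats[i, st] <- windowAverage(sc, ds0@causalIndex, halfWidth,
                                            nSites(ds0@dataset))$mean_abs_score
        ranks[i, st] <- causalRank(sc, ds0@causalIndex)
      }
    }
  }
  power <- colMeans(causalStats > rep(cutoff, each = nrow(causalStats)),
                    na.rm = TRUE)
  powerCI <- sapply(statistics, function(st) {
    k <- sum(causalStats[, st] > cutoff[st], na.rm = TRUE)
    n <- sum(!is.na(causalStats[, st]))
    if (n == 0) return(c(NA_real_, NA_real_))
    as.numeric(stats::binom.test(k, n)$conf.int)
  })

  # (3) FDR over all tiling windows of neutral replicates of the scenario
  fdr <- fdrCI <- NULL
  if (nNeutralReps > 0L) {
    neut <- simulateReplicates(asNeutral(scenario), nNeutralReps,
                               seed + 2000003L)
    hits <- tot <- stats::setNames(numeric(length(statistics)), statistics)
    for (i in seq_len(nNeutralReps)) {
      ds0 <- downsampleSnps(neut[[i]], seed = seed + 23L * i)
      for (st in statistics) {
        sc <- scanByName(ds0@dataset, st, mafMin = scenario@mafMin)
        w <- slidingWindows(sc, windowSize = 2L * halfWidth + 1L,
                            offset = 2L * halfWidth + 1L,
                            nSites = nSites(ds0@dataset))
        hits[st] <- hits[st] + sum(w$mean_abs_score > cutoff[st], na.rm = TRUE)
        tot[st] <- tot[st] + sum(!is.na(w$mean_abs_score))
      }
    }
    fdr <- hits / tot
    fdrCI <- sapply(statistics, function(st)
      as.numeric(stats::binom.test(hits[st], tot[st])$conf.int))
  }

  structure(list(
    alpha = alpha, halfWidth = halfWidth, statistics = statistics,
    cutoff = cutoff, nullStats = nullStats,
    causalStats = causalStats, causalRanks = ranks,
    power = power, powerCI = powerCI, fdr = fdr, fdrCI = fdrCI,
    scenario = scenario, nullSpec = nullSpec,
    seed = seed, sweepSeeds = sweepSeeds),
    class = "powerFdrReport")
}

#' @export
print.powerFdrReport <- function(x, ...) {
  cat("Power/FDR study (", x$scenario@model, " model, alpha = ", x$alpha,
      ")\n", sep = "")
  cat("  cutoff from", nrow(x$nullStats), "null replicates\n")
  for (st in x$statistics) {
    cat(sprintf("  %-5s cutoff %.4f", st, x$cutoff[st]))
    if (nrow(x$causalStats) > 0 && any(!is.na(x$causalStats[, st])))
      cat(sprintf("  power %.3f [%.3f, %.3f]", x$power[st],
                  x$powerCI[1, st], x$powerCI[2, st]))
    if (!is.null(x$fdr)) cat(sprintf("  FDR %.4f", x$fdr[st]))
    cat("\n")
  }
  invisible(x)
}
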