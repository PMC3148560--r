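#' Genome scans: iHS, WiHS and PHS
#'
#' Per-SNP selective-sweep scores over every site passing the
#' minor-allele-frequency filter (derived and ancestral frequency each at
#' least \code{mafMin}; sites with missing alleles are never cores).
#'
#' \code{ihsScan} is the classical integrated haplotype score: for each
#' core SNP the EHH decay of the derived and the ancestral allele is walked
#' with unit weights, integrated on the genetic map ([integrateEHH()]), and
#' the raw score is \code{log(iwEHH_A / iwEHH_D)}.
#'
#' \code{wihsScan} is the relatedness-weighted variant: the carriers of
#' each core allele are weighted by their uniqueness ([uniqueness()])
#' computed from a genome-wide distance matrix, so that near-duplicate
#' individuals contribute less and distinct individuals more. With a
#' constant (all off-diagonal entries equal) distance matrix it reproduces
#' \code{ihsScan} exactly.
#'
#' \code{phsScan} is the pairwise haplotype sharing comparator: for every
#' haplotype pair the genetic length of the maximal identical tract
#' containing each SNP is z-standardized within the pair across the
#' genome, and the score of a SNP's derived allele is the mean z over
#' derived-carrier pairs minus the mean z over all pairs. It costs
#' O(n^2) pair comparisons, against O(n) for the integrated scores.
#'
#' All three scans finish with the same allele-frequency standardization
#' ([standardize()]). Scores that cannot be computed (zero integral,
#' chromosome-boundary truncation, fewer than 2 carriers of an allele) are
#' kept as rows with \code{NA} and an explanatory \code{status}; they are
#' excluded from standardization moments and window means.
#'
#' The result carries an \code{opCount} attribute counting elementary
#' per-individual (iHS/WiHS) or per-pair (PHS) comparisons, which grows
#' linearly / quadratically with haplotype count.
#'
#' @param x a [HaplotypeDataset-class] with genetic positions assigned.
#' @param dm a [DistanceMatrix-class] over the same haplotypes
#'   (\code{wihsScan}).
#' @param mafMin core-site minor-allele-frequency floor (default 0.05).
#' @param truncation EHH integration threshold (default 0.05).
#' @param boundary what to do when a decay hits the chromosome end before
#'   dropping below \code{truncation}: \code{"missing"} (default; score
#'   NA, status \code{boundary_truncated}) or \code{"integrate"} (use the
#'   integral to the end).
#' @param binning frequency-bin specification for [standardize()];
#'   \code{NULL} for the default.
#' @param standardized if \code{FALSE}, skip standardization (raw scores
#'   only).
#' @return data.frame with one row per MAF-passing SNP: \code{snp_index},
#'   \code{chromosome}, \code{position}, \code{derived_freq},
#'   \code{iwEHH_A}, \code{iwEHH_D} (NA for PHS), \code{raw},
#'   \code{standardized}, \code{status}.
#' @examples
#' hd <- makeFixture("random", list(n = 20, S = 60), seed = 7)
#' sc <- ihsScan(hd)
#' head(sc)
#' @export
ihsScan <- function(x, mafMin = 0.05, truncation = 0.05,
                    boundary = c("missing", "integrate"),
                    binning = NULL, standardized = TRUE) {
  scanIntegrated(x, dm = NULL, mafMin = mafMin,
                 truncation = truncation, boundary = match.arg(boundary),
                 binning = binning, standardized = standardized)
}

#' @rdname ihsScan
#' @export
wihsScan <- function(x, dm, mafMin = 0.05, truncation = 0.05,
                     boundary = c("missing", "integrate"),
                     binning = NULL, standardized = TRUE) {
  if (nrow(dm@values) != nHaplotypes(x))
    stop("distance matrix dimension (", nrow(dm@values),
         ") does not match haplotype count (", nHaplotypes(x), ")")
  scanIntegrated(x, dm = dm@values, mafMin = mafMin,
                 truncation = truncation, boundary = match.arg(boundary),
                 binning = binning, standardized = standardized)
}

scanIntegrated <- function(x, dm, mafMin, truncation, boundary,
                           binning, standardized) {
  a <- alleles(x)
  g <- geneticPositions(x)
  if (all(is.na(g))) stop("genetic positions not assigned")
  res <- scan_integrated_cpp(a, g, mafMin, truncation, dm)
  pass <- res$snp_index
  n <- length(pass)

  status <- c("ok", "too_few_carriers", "boundary_truncated")[res$status + 1L]
  raw <- rep(NA_real_, n)
  canScore <- res$status == 0L |
    (res$status == 2L & boundary == "integrate")
  zero <- canScore & (res$iwEHH_A == 0 | res$iwEHH_D == 0)
  status[zero & res$status == 0L] <- "undefined_zero_integral"
  ok <- canScore & !zero
  raw[ok] <- log(res$iwEHH_A[ok] / res$iwEHH_D[ok])

  out <- data.frame(
    snp_index = pass,
    chromosome = rep(chromosomeId(x), n),
    position = physicalPositions(x)[pass],
    derived_freq = res$derived_freq,
    iwEHH_A = res$iwEHH_A, iwEHH_D = res$iwEHH_D,
    raw = raw, standardized = rep(NA_real_, n),
    status = status, stringsAsFactors = FALSE)
  if (standardized && n > 0) out <- standardize(out, binning)
  attr(out, "opCount") <- res$op_count
  out
}

#' @rdname ihsScan
#' @export
phsScan <- function(x, mafMin = 0.05, binning = NULL, standardized = TRUE) {
  a <- alleles(x)
  g <- geneticPositions(x)
  if (all(is.na(g))) stop("genetic positions not assigned")
  acc <- phs_accumulate_cpp(a, g)
  if (acc$n_zero_sd > 0)
    warning(acc$n_zero_sd,
            " haplotype pair(s) with zero tract-length SD; their z set to 0")
  f <- colMeans(a == 1L, na.rm = TRUE)
  hasNA <- colSums(is.na(a)) > 0L
  pass <- which(!hasNA & pmin(f, 1 - f) >= mafMin)

  raw <- rep(NA_real_, length(pass))
  status <- rep("ok", length(pass))
  dp <- acc$der_pairs[pass]
  ok <- dp >= 1
  raw[ok] <- acc$der_sum[pass][ok] / dp[ok] - acc$all_sum[pass][ok] / acc$n_pairs
  status[!ok] <- "too_few_carriers"

  out <- data.frame(
    snp_index = pass,
    chromosome = chromosomeId(x),
    position = physicalPositions(x)[pass],
    derived_freq = f[pass],
    iwEHH_A = NA_real_, iwEHH_D = NA_real_,
    raw = raw, standardized = NA_real_,
    status = status, stringsAsFactors = FALSE)
  if (standardized && nrow(out) > 0) out <- standardize(out, binning)
  attr(out, "opCount") <- acc$n_pairs
  out
}

#' Frequency-bin specification for score standardization
#'
#' @param mode \code{"auto"} (exact derived-allele count when the dataset
#'   has no missing data, 2\%-wide frequency bins otherwise),
#'   \code{"count"}, or \code{"width"}.
#' @param width bin width on the derived-frequency axis for
#'   \code{"width"} mode.
#' @param minBinCount bins with fewer defined scores are merged with the
#'   nearest bin (by frequency) before moments are taken.
#' @return a list understood by [standardize()]
#' @export
frequencyBins <- function(mode = c("auto", "count", "width"),
                          width = 0.02, minBinCount = 20L) {
  list(mode = match.arg(mode), width = width,
       minBinCount = as.integer(minBinCount))
}

#' Standardize raw scores within derived-allele-frequency bins
#'
#' Young, low-frequency alleles sit on systematically longer haplotypes
#' than old, high-frequency ones, so raw log-ratio scores are standardized
#' within frequency classes: \code{standardized = (raw - mean_f) / SD_f},
#' with the mean and sample SD taken over all defined raw scores in the
#' SNP's derived-frequency bin. Bins with fewer than
#' \code{binning$minBinCount} defined scores are merged with the nearest
#' bin. A (merged) bin with zero SD leaves its scores missing with a
#' warning.
#'
#' @param scores a scan result (see [ihsScan()]).
#' @param binning a [frequencyBins()] spec; \code{NULL} for defaults.
#' @return the scores with the \code{standardized} column filled in
#' @export
standardize <- function(scores, binning = NULL) {
  if (is.null(binning)) binning <- frequencyBins()
  mode <- binning$mode
  if (mode == "auto") mode <- "count"
  def <- !is.na(scores$raw)

  key <- if (mode == "count") scores$derived_freq
         else floor(scores$derived_freq / binning$width) * binning$width
  # merge underpopulated bins with the nearest bin on the frequency axis
  lv <- sort(unique(key[def]))
  if (!length(lv)) return(scores)
  counts <- vapply(lv, function(v) sum(def & key == v), 1L)
  repr <- lv  # representative frequency per bin
  grp <- seq_along(lv)
  while (length(unique(grp)) > 1L) {
    gs <- unique(grp)
    cnt <- vapply(gs, function(g) sum(counts[grp == g]), 1L)
    small <- gs[cnt < binning$minBinCount]
    if (!length(small)) break
    g <- small[which.min(cnt[match(small, gs)])]
    ctr <- vapply(gs, function(gg) mean(repr[grp == gg]), 1)
    me <- match(g, gs)
    other <- gs[-me]
    tgt <- other[which.min(abs(ctr[-me] - ctr[me]))]
    grp[grp == g] <- tgt
  }
  bin <- grp[match(key, lv)]

  scores$standardized <- NA_real_
  realized <- rep(NA_integer_, nrow(scores))
  zeroSd <- FALSE
  for (g in unique(grp)) {
    inBin <- which(def & !is.na(bin) & bin == g)
    if (length(inBin) < 2L) { zeroSd <- TRUE; next }
    mu <- mean(scores$raw[inBin])
    sdv <- stats::sd(scores$raw[inBin])
    if (!is.finite(sdv) || sdv == 0) { zeroSd <- TRUE; next }
    scores$standardized[inBin] <- (scores$raw[inBin] - mu) / sdv
    realized[inBin] <- g
  }
  if (zeroSd)
    warning("some frequency bin had zero SD or < 2 scores; left unstandardized")
  attr(scores, "bins") <- realized   # realized (merged) bin per row
  scores
}

#' Windowed score statistics
#'
#' \code{windowAverage} is the simulation-study statistic: the mean of
#' \code{|standardized|} over the SNPs within \code{halfWidth} indices of
#' \code{center} (a 51-SNP window at the default of 25), skipping
#' undefined scores; windows are clipped at chromosome ends.
#' \code{slidingWindows} tiles/strides the chromosome (defaults 50-SNP
#' windows, 20-SNP offset); a final partial window is kept when it covers
#' at least half the window size and otherwise merged into the previous
#' window.
#'
#' Window indices refer to the SNP grid of the scanned dataset (the
#' \code{snp_index} column), 1-based and inclusive.
#'
#' @param scores a scan result with standardized scores.
#' @param center SNP index at the window center.
#' @param halfWidth window half-width in SNPs.
#' @param nSites total SNP count of the scanned dataset (for end clipping);
#'   defaults to the largest scanned index.
#' @param windowSize,offset sliding-window size and stride in SNPs.
#' @return one-row (windowAverage) or multi-row (slidingWindows)
#'   data.frame with \code{window_start}, \code{window_end},
#'   \code{mean_abs_score}, \code{n_defined}.
#' @examples
#' hd <- makeFixture("random", list(n = 20, S = 120), seed = 8)
#' sc <- ihsScan(hd)
#' slidingWindows(sc, windowSize = 50, offset = 20)
#' @export
windowAverage <- function(scores, center, halfWidth = 25L,
                          nSites = max(scores$snp_index)) {
  lo <- max(1L, center - halfWidth)
  hi <- min(nSites, center + halfWidth)
  inWin <- scores$snp_index >= lo & scores$snp_index <= hi
  v <- scores$standardized[inWin]
  v <- v[!is.na(v)]
  data.frame(window_start = lo, window_end = hi,
             mean_abs_score = if (length(v)) mean(abs(v)) else NA_real_,
             n_defined = length(v))
}

#' @rdname windowAverage
#' @export
slidingWindows <- function(scores, windowSize = 50L, offset = 20L,
                           nSites = max(scores$snp_index)) {
  if (windowSize < 1L) stop("windowSize must be >= 1")
  if (offset < 1L) stop("offset must be >= 1")
  starts <- seq(1L, nSites, by = offset)
  ends <- pmin(starts + windowSize - 1L, nSites)
  keep <- (ends - starts + 1L) >= ceiling(windowSize / 2)
  starts <- starts[keep]; ends <- ends[keep]
  if (!length(starts)) { starts <- 1L; ends <- nSites }
  if (ends[length(ends)] < nSites) ends[length(ends)] <- nSites
  rows <- lapply(seq_along(starts), function(i) {
    inWin <- scores$snp_index >= starts[i] & scores$snp_index <= ends[i]
    v <- scores$standardized[inWin]
    v <- v[!is.na(v)]
    data.frame(window_start = starts[i], window_end = ends[i],
               mean_abs_score = if (length(v)) mean(abs(v)) else NA_real_,
               n_defined = length(v))
  })
  do.call(rbind, rows)
}

#' Empirical significance of window statistics against a null sample
#'
#' Adds to each window its rank (descending statistic, ties averaged), an
#' add-one empirical p-value \eqn{(1 + \#\{null \ge obs\}) / (1 + \#null)}
#' and a significance call \code{obs > quantile(null, 1 - alpha)}. The
#' cutoff used is stored in \code{attr(, "cutoff")}.
#'
#' @param windows data.frame from [slidingWindows()] or rows of
#'   [windowAverage()].
#' @param nullStats numeric sample of the statistic under the null
#'   (typically window statistics from neutral simulations).
#' @param alpha significance level.
#' @return the windows with \code{rank}, \code{empirical_p},
#'   \code{significant} columns
#' @export
empiricalSignificance <- function(windows, nullStats, alpha = 0.01) {
  if (!length(nullStats)) stop("nullStats must be non-empty")
  obs <- windows$mean_abs_score
  cutoff <- stats::quantile(nullStats, 1 - alpha, names = FALSE, na.rm = TRUE)
  windows$rank <- rank(-obs, ties.method = "average", na.last = "keep")
  windows$empirical_p <- vapply(obs, function(o) {
    if (is.na(o)) return(NA_real_)
    (1 + sum(nullStats >= o)) / (1 + length(nullStats))
  }, 1)
  windows$significant <- !is.na(obs) & obs > cutoff
  attr(windows, "cutoff") <- cutoff
  windows
}
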