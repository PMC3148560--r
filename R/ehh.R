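#' Weighted EHH decay around a core allele
#'
#' Walks outward SNP by SNP from the core site, partitioning the carriers
#' of the core allele into identity classes over the interval covered so
#' far. At each query SNP y the weighted extended haplotype homozygosity is
#' \deqn{wEHH(x, y) = \frac{\sum_{h \in H} W_h^2 - \sum_{I \in X} U(I)^2}
#'                         {m^2 - \sum_{I \in X} U(I)^2}}
#' with \eqn{W_h = \sum_{I \in h} U(I)} the total weight of identity class
#' h and m the carrier count. With unit weights this is the classical
#' sample EHH, the fraction of carrier pairs identical over the interval,
#' \eqn{\sum_h n_h (n_h - 1) / (m (m - 1))}. Each direction stops after the
#' first value below \code{truncation} or at the chromosome end. Missing
#' alleles break haplotype identity (a missing site matches nothing).
#'
#' The core site must be polymorphic among its own alleles with minor
#' allele frequency at least \code{mafMin}; sites failing that are not
#' valid cores.
#'
#' @param x a [HaplotypeDataset-class] with genetic positions assigned.
#' @param coreIndex SNP index of the core site (1-based column).
#' @param coreAllele 0 (ancestral) or 1 (derived).
#' @param weights a [UniquenessWeights-class] for the carriers of
#'   \code{coreAllele} at \code{coreIndex}, or \code{NULL} for unit
#'   weights.
#' @param truncation stop threshold for the outward walk (default 0.05).
#' @param mafMin minimum minor allele frequency for a valid core site.
#' @param maxGapBp optional guard against marker deserts: a physical gap
#'   larger than this between consecutive SNPs ends the walk there, and
#'   the direction is flagged like a chromosome-end truncation. Off
#'   (\code{Inf}) by default, since the design assumes a constant
#'   recombination rate without hotspots.
#' @return an [EHHDecay-class]
#' @examples
#' hd <- makeFixture("random", list(n = 12, S = 30), seed = 4)
#' d <- ehhDecay(hd, coreIndex = 15, coreAllele = 1)
#' integrateEHH(d)
#' @export
ehhDecay <- function(x, coreIndex, coreAllele, weights = NULL,
                     truncation = 0.05, mafMin = 0.05, maxGapBp = Inf) {
  a <- alleles(x)
  g <- geneticPositions(x)
  if (all(is.na(g))) stop("genetic positions not assigned; see assignGeneticPositions()")
  coreIndex <- as.integer(coreIndex)
  col <- a[, coreIndex]
  if (anyNA(col)) stop("core site has missing alleles and cannot be a core")
  f <- mean(col == 1L)
  if (f == 0 || f == 1) stop("monomorphic core site")
  if (min(f, 1 - f) < mafMin)
    stop(sprintf("core minor allele frequency %.3f below mafMin = %g", min(f, 1 - f), mafMin))
  carriers <- which(col == coreAllele)
  m <- length(carriers)
  if (m < 2L) stop("fewer than 2 carriers of the core allele")
  U <- if (is.null(weights)) rep(1, m) else {
    if (!identical(sort(weights@carriers), sort(carriers)))
      stop("weights carrier set does not match the core-allele carriers")
    weights@U[match(carriers, weights@carriers)]
  }

  right <- ehh_walk_cpp(a, carriers - 1L, U, coreIndex - 1L, 1L, truncation)
  left <- ehh_walk_cpp(a, carriers - 1L, U, coreIndex - 1L, -1L, truncation)

  reached <- c(left = attr(left, "reached_end"),
               right = attr(right, "reached_end"))
  mk <- function(v, step) {
    idx <- coreIndex + step * (seq_along(v) - 1L)
    data.frame(index = idx, cM = g[idx], ehh = as.numeric(v))
  }
  dirs <- list(left = mk(left, -1L), right = mk(right, 1L))
  if (is.finite(maxGapBp)) {
    pp <- physicalPositions(x)
    for (side in names(dirs)) {
      d <- dirs[[side]]
      if (nrow(d) < 2L) next
      gaps <- abs(diff(pp[d$index]))
      cut <- which(gaps > maxGapBp)
      if (length(cut)) {
        dirs[[side]] <- d[seq_len(cut[1]), , drop = FALSE]
        reached[side] <- TRUE   # unknowable tail, same as a chromosome end
      }
    }
  }
  new("EHHDecay",
      coreIndex = coreIndex, coreAllele = as.integer(coreAllele),
      left = dirs$left, right = dirs$right, reachedEnd = reached)
}

#' Integrate an EHH decay on the genetic map
#'
#' Trapezoidal sum over consecutive (cM, EHH) points in each direction, up
#' to and including the first point below the truncation threshold (the
#' crossing segment is integrated through its sampled endpoint; the exact
#' 0.05 crossing is not interpolated). The two directional integrals are
#' added. Units: cM.
#'
#' The returned value carries a \code{status} attribute: \code{"complete"},
#' or \code{"boundary_truncated"} when a direction hit the chromosome end
#' before decaying below the threshold (scores built from such integrals
#' are set to missing by default; see [ihsScan()]).
#'
#' @param decay an [EHHDecay-class]
#' @param truncation integration stop threshold (points below it beyond the
#'   first are ignored; normally the decay was already walked with the same
#'   threshold).
#' @return non-negative numeric with attribute \code{status}
#' @export
integrateEHH <- function(decay, truncation = 0.05) {
  oneSide <- function(d) {
    if (nrow(d) < 2L) return(0)
    below <- which(d$ehh < truncation)
    last <- if (length(below)) below[1] else nrow(d)
    if (last < 2L) return(0)
    cm <- abs(d$cM[seq_len(last)] - d$cM[1])
    e <- d$ehh[seq_len(last)]
    sum(diff(cm) * (utils::head(e, -1) + utils::tail(e, -1)) / 2)
  }
  val <- oneSide(decay@left) + oneSide(decay@right)
  status <- if (any(decay@reachedEnd)) "boundary_truncated" else "complete"
  attr(val, "status") <- status
  val
}

#' Raw (unstandardized) integrated haplotype score
#'
#' \code{log(iwEHH_A / iwEHH_D)}: negative when the derived haplotype is
#' longer than the ancestral one, positive when the ancestral haplotype is
#' longer. Undefined (NA, with attribute \code{status = "undefined"}) when
#' either integral is zero.
#'
#' @param iwEHH_A integrated EHH of the ancestral allele (>= 0)
#' @param iwEHH_D integrated EHH of the derived allele (>= 0)
#' @return numeric; NA with \code{status} attribute when undefined
#' @examples
#' rawScore(2, 1)   #  log(2): ancestral longer
#' rawScore(1, exp(1))  # -1
#' @export
rawScore <- function(iwEHH_A, iwEHH_D) {
  if (iwEHH_A < 0 || iwEHH_D < 0) stop("integrated EHH must be >= 0")
  if (iwEHH_A == 0 || iwEHH_D == 0) {
    out <- NA_real_
    attr(out, "status") <- "undefined"
    return(out)
  }
  log(iwEHH_A / iwEHH_D)
}

#' Flatten an EHH decay to a plottable table
#'
#' One row per sampled point: \code{direction} (left/right), \code{index},
#' \code{cM}, \code{ehh}, ordered outward from the core in each direction.
#' Write it with \code{write.table} to export a decay curve.
#'
#' @param decay an [EHHDecay-class]
#' @return a data.frame
#' @export
decayTable <- function(decay) {
  rbind(cbind(direction = "left", decay@left),
        cbind(direction = "right", decay@right))
}
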