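#' Genome-wide squared Hamming distance matrix
#'
#' For haplotypes i and j, the distance is \eqn{(h_{ij}/c_{ij})^2 L}, where
#' \eqn{h_{ij}} counts sites with differing non-missing alleles,
#' \eqn{c_{ij}} counts pairwise non-missing sites and L is the total SNP
#' count. The per-pair proportion is normalized for missingness first and
#' squared afterwards; with complete data the entry is \eqn{h_{ij}^2 / L}.
#' Squaring accentuates the contrast between close relatives and unrelated
#' individuals, which is what the downstream uniqueness weighting exploits.
#'
#' @param x a [HaplotypeDataset-class] (or plain 0/1/NA matrix, rows =
#'   haplotypes).
#' @param diploid when \code{TRUE}, consecutive haplotype rows (2k-1, 2k)
#'   are treated as one individual: distances are computed on 0/1/2 dosage
#'   rows, and the returned matrix has one row per individual.
#' @return a [DistanceMatrix-class]
#' @examples
#' hd <- makeFixture("random", list(n = 6, S = 40), seed = 1)
#' dm <- squaredHammingMatrix(hd)
#' @export
squaredHammingMatrix <- function(x, diploid = FALSE) {
  a <- if (is(x, "HaplotypeDataset")) alleles(x) else x
  if (nrow(a) < 2L) stop("need at least 2 sequences")
  L <- ncol(a)
  if (diploid) {
    if (nrow(a) %% 2L != 0L) stop("diploid mode needs an even number of haplotype rows")
    idx <- seq(1L, nrow(a), by = 2L)
    a <- a[idx, , drop = FALSE] + a[idx + 1L, , drop = FALSE]
  }
  M <- !is.na(a)
  storage.mode(M) <- "double"
  av <- a
  av[is.na(av)] <- 0
  storage.mode(av) <- "double"
  cmp <- tcrossprod(M)
  if (any(cmp[upper.tri(cmp)] == 0))
    stop("some sequence pair has no comparable (non-missing) sites")
  if (diploid) {
    # dosage difference |a_i - a_j| summed over comparable sites
    h <- matrix(0, nrow(a), nrow(a))
    for (d in 0:2) for (e in 0:2) if (d != e) {
      h <- h + abs(d - e) * tcrossprod((av == d & M) * 1, (av == e & M) * 1)
    }
    h <- (h + t(h)) / 2
  } else {
    A1 <- av * M          # 1 where derived and non-missing
    A0 <- (1 - av) * M    # 1 where ancestral and non-missing
    h <- tcrossprod(A1, A0) + tcrossprod(A0, A1)
  }
  v <- (h / cmp)^2 * L
  diag(v) <- 0
  labs <- if (is(x, "HaplotypeDataset")) {
    if (diploid) sequenceIds(x)[seq(1L, length(sequenceIds(x)), by = 2L)]
    else sequenceIds(x)
  } else rownames(a)
  dimnames(v) <- list(labs, labs)
  new("DistanceMatrix", values = v, sitesCompared = {
    s <- cmp; storage.mode(s) <- "integer"; s
  })
}

#' Uniqueness weights for a carrier set
#'
#' Given the genome-wide distance matrix and the set X of sequences
#' carrying a core allele, each carrier I gets
#' \deqn{U(I) = m \, \bar D(I) / \sum_{J \in X} \bar D(J)}
#' where \eqn{\bar D(I)} is I's average distance to the other carriers and
#' \eqn{m = |X|}. The weights sum to m, so only the relative weighting
#' between individuals changes, and unit weights (U = 1 for everyone)
#' recover the classical unweighted statistic. A carrier set in which every
#' pair is at distance zero falls back to unit weights with a warning.
#'
#' @param dm a [DistanceMatrix-class]
#' @param carriers integer indices (rows of \code{dm}) of the core-allele
#'   carriers; at least 2.
#' @return a [UniquenessWeights-class]
#' @examples
#' hd <- makeFixture("random", list(n = 8, S = 50), seed = 2)
#' dm <- squaredHammingMatrix(hd)
#' uniqueness(dm, c(1L, 3L, 5L, 7L))
#' @export
uniqueness <- function(dm, carriers) {
  carriers <- as.integer(carriers)
  m <- length(carriers)
  if (m < 2L) stop("carrier set needs at least 2 members")
  sub <- dm@values[carriers, carriers, drop = FALSE]
  dbar <- rowSums(sub) / (m - 1)
  tot <- sum(dbar)
  if (tot <= 0) {
    warning("all carriers identical genome-wide; falling back to unit weights")
    U <- rep(1, m)
  } else if (max(dbar) == min(dbar)) {
    U <- rep(1, m)   # equidistant carriers: exactly the unweighted case
  } else {
    U <- m * dbar / tot
  }
  new("UniquenessWeights", carriers = carriers, U = U, DBar = dbar)
}

#' Unit (classical) weights for a carrier set
#'
#' @param carriers integer carrier indices
#' @return a [UniquenessWeights-class] with U = 1 everywhere
#' @export
unitWeights <- function(carriers) {
  carriers <- as.integer(carriers)
  new("UniquenessWeights", carriers = carriers,
      U = rep(1, length(carriers)), DBar = rep(NA_real_, length(carriers)))
}
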