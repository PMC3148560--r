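#' Deterministic test fixtures
#'
#' Small haplotype datasets with analytically known properties, generated
#' reproducibly from a seed (the caller's RNG state is untouched):
#' \describe{
#'   \item{\code{random}}{seeded random alleles; per-SNP derived frequency
#'     drawn uniformly from \code{freqRange} (default (0.1, 0.9)).
#'     Parameters: \code{n}, \code{S}, \code{freqRange}.}
#'   \item{\code{mirror}}{at the center SNP, the derived and ancestral
#'     carrier groups have identical flanking haplotype structure (row k
#'     of one group equals row k of the other away from the core), so
#'     the derived and ancestral EHH decays coincide and the raw
#'     integrated score at the center is exactly 0. Parameters: \code{k}
#'     (haplotypes per group), \code{S} (odd SNP count).}
#'   \item{\code{identical-block}}{the \code{k} derived carriers of the
#'     center SNP share one identical haplotype across the block of
#'     \code{blockHalfWidth} SNPs either side of the center, so their EHH
#'     stays 1 across the whole block; the remaining haplotypes are
#'     random. Parameters: \code{n}, \code{S} (odd), \code{k},
#'     \code{blockHalfWidth}.}
#'   \item{\code{duplicated-individual}}{a random dataset with a copy of
#'     haplotype 1 appended as the last row, for weight-monotonicity
#'     checks. Parameters: \code{n} (before duplication), \code{S}.}
#' }
#' Physical positions are 1 kb apart and a uniform genetic map of
#' \code{cMperBp} (default 1e-5, i.e. 1 cM per 100 kb) is attached.
#'
#' @param kind fixture name (above).
#' @param params named list of parameters; unset ones take the defaults.
#' @param seed integer seed; the same (kind, params, seed) always yields a
#'   byte-identical dataset.
#' @return a [HaplotypeDataset-class]; block fixtures carry attributes
#'   \code{coreIndex} (and \code{blockRange} / \code{carrierRows} where
#'   applicable).
#' @examples
#' makeFixture("mirror", list(k = 5, S = 21), seed = 1)
#' @export
makeFixture <- function(kind, params = list(), seed) {
  p <- function(name, default)
    if (!is.null(params[[name]])) params[[name]] else default
  cMperBp <- p("cMperBp", 1e-5)
  build <- function(a, extra = list()) {
    pos <- (seq_len(ncol(a)) - 1) * 1000
    ds <- HaplotypeDataset(a, pos)
    ds <- assignUniformMap(ds, cMperBp)
    for (nm in names(extra)) attr(ds, nm) <- extra[[nm]]
    ds
  }

  withSeed(seed, switch(kind,
    "random" = {
      n <- p("n", 12L); S <- p("S", 30L); fr <- p("freqRange", c(0.1, 0.9))
      f <- stats::runif(S, fr[1], fr[2])
      a <- vapply(f, function(ff) stats::rbinom(n, 1L, ff), integer(n))
      build(a)
    },
    "mirror" = {
      k <- p("k", 6L); S <- p("S", 31L)
      if (S %% 2L == 0L) stop("mirror fixture needs an odd SNP count")
      core <- (S + 1L) %/% 2L
      flank <- matrix(stats::rbinom(k * (S - 1L), 1L, 0.5), k)
      a <- matrix(0L, 2L * k, S)
      a[seq_len(k), -core] <- flank
      a[k + seq_len(k), -core] <- flank
      a[seq_len(k), core] <- 1L
      build(a, list(coreIndex = core))
    },
    "identical-block" = {
      n <- p("n", 12L); S <- p("S", 41L); k <- p("k", 6L)
      b <- p("blockHalfWidth", 10L)
      if (S %% 2L == 0L) stop("identical-block fixture needs an odd SNP count")
      core <- (S + 1L) %/% 2L
      block <- max(1L, core - b):min(S, core + b)
      a <- matrix(stats::rbinom(n * S, 1L, 0.5), n)
      shared <- stats::rbinom(length(block), 1L, 0.5)
      for (i in seq_len(k)) a[i, block] <- shared
      a[seq_len(k), core] <- 1L
      a[(k + 1L):n, core] <- 0L
      build(a, list(coreIndex = core, blockRange = range(block),
                    carrierRows = seq_len(k)))
    },
    "duplicated-individual" = {
      n <- p("n", 8L); S <- p("S", 40L)
      a <- matrix(stats::rbinom(n * S, 1L, 0.5), n)
      a <- rbind(a, a[1L, ])
      build(a, list(duplicatedRows = c(1L, n + 1L)))
    },
    stop("unknown fixture kind: ", kind)))
}
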