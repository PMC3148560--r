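#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib haploSweep, .registration = TRUE
NULL

#' Phased, polarized haplotype data for one chromosome
#'
#' The universal scan input: a matrix of 0/1 alleles (rows = haplotypes,
#' columns = SNPs; 0 = ancestral, 1 = derived, \code{NA} = missing) together
#' with physical (bp) and genetic (cM) SNP coordinates. Physical positions
#' are 0-based internally; VCF input/output converts from/to 1-based.
#'
#' @slot alleles integer matrix of 0/1/\code{NA}; rows are haplotypes.
#' @slot physicalPositions numeric, strictly increasing bp per SNP.
#' @slot geneticPositions numeric, non-decreasing cM per SNP (may be all
#'   \code{NA} until a genetic map is applied).
#' @slot sequenceIds character label per haplotype.
#' @slot chromosomeId single character label.
#'
#' @seealso [HaplotypeDataset()], [readHaplotypes()], [assignGeneticPositions()]
#' @exportClass HaplotypeDataset
setClass("HaplotypeDataset",
  representation(
    alleles = "matrix",
    physicalPositions = "numeric",
    geneticPositions = "numeric",
    sequenceIds = "character",
    chromosomeId = "character"
  )
)

setValidity("HaplotypeDataset", function(object) {
  a <- object@alleles
  msg <- character(0)
  if (nrow(a) < 2L) msg <- c(msg, "need at least 2 haplotypes")
  if (ncol(a) < 2L) msg <- c(msg, "need at least 2 SNPs")
  vals <- a[!is.na(a)]
  if (length(vals) && !all(vals %in% c(0L, 1L)))
    msg <- c(msg, "alleles must be 0, 1 or NA")
  if (length(object@physicalPositions) != ncol(a))
    msg <- c(msg, "physicalPositions length must equal SNP count")
  if (is.unsorted(object@physicalPositions, strictly = TRUE))
    msg <- c(msg, "physicalPositions must be strictly increasing")
  g <- object@geneticPositions
  if (length(g) != ncol(a))
    msg <- c(msg, "geneticPositions length must equal SNP count")
  if (!all(is.na(g)) && (anyNA(g) || is.unsorted(g)))
    msg <- c(msg, "geneticPositions must be all-NA or non-decreasing with no NA")
  if (length(object@sequenceIds) != nrow(a))
    msg <- c(msg, "sequenceIds length must equal haplotype count")
  if (length(object@chromosomeId) != 1L)
    msg <- c(msg, "chromosomeId must be a single label")
  if (length(msg)) msg else TRUE
})

#' Construct a HaplotypeDataset
#'
#' @param alleles 0/1/\code{NA} matrix, rows = haplotypes, columns = SNPs.
#' @param physicalPositions strictly increasing bp coordinates (0-based).
#' @param geneticPositions cM coordinates; defaults to all \code{NA}
#'   (assign later with [assignGeneticPositions()]).
#' @param sequenceIds haplotype labels; default \code{hap1..hapn}.
#' @param chromosomeId chromosome label.
#' @return a [HaplotypeDataset-class] object.
#' @examples
#' hd <- HaplotypeDataset(matrix(c(0L,1L,0L,1L,1L,0L), 2), c(100, 200, 300))
#' nHaplotypes(hd)
#' @export
HaplotypeDataset <- function(alleles, physicalPositions,
                             geneticPositions = rep(NA_real_, ncol(alleles)),
                             sequenceIds = paste0("hap", seq_len(nrow(alleles))),
                             chromosomeId = "chr1") {
  storage.mode(alleles) <- "integer"
  new("HaplotypeDataset",
      alleles = alleles,
      physicalPositions = as.numeric(physicalPositions),
      geneticPositions = as.numeric(geneticPositions),
      sequenceIds = as.character(sequenceIds),
      chromosomeId = as.character(chromosomeId))
}

#' Physical-to-genetic coordinate map
#'
#' A least-squares polynomial fit to (bp, cM) anchor markers. When the
#' fitted polynomial is non-monotone anywhere on the anchored range the map
#' falls back to monotone piecewise-linear interpolation of the anchors,
#' because downstream EHH integration requires non-decreasing genetic
#' positions. Evaluation outside the anchored range extrapolates linearly
#' with the boundary slope.
#'
#' @slot anchors data.frame with columns \code{bp} (strictly increasing) and
#'   \code{cM} (non-decreasing).
#' @slot coefficients polynomial coefficients, ascending powers (empty when
#'   the piecewise fallback is active).
#' @slot degree integer polynomial degree.
#' @slot piecewise logical; \code{TRUE} when the monotone piecewise-linear
#'   fallback replaced the polynomial.
#' @seealso [fitGeneticMap()], [mapPosition()]
#' @exportClass GeneticMap
setClass("GeneticMap",
  representation(
    anchors = "data.frame",
    coefficients = "numeric",
    degree = "integer",
    piecewise = "logical"
  )
)

setValidity("GeneticMap", function(object) {
  a <- object@anchors
  msg <- character(0)
  if (!all(c("bp", "cM") %in% names(a))) msg <- c(msg, "anchors need bp and cM columns")
  else {
    if (is.unsorted(a$bp, strictly = TRUE)) msg <- c(msg, "anchor bp must be strictly increasing")
    if (is.unsorted(a$cM)) msg <- c(msg, "anchor cM must be non-decreasing")
  }
  if (length(msg)) msg else TRUE
})

#' Genome-wide pairwise distance matrix
#'
#' Symmetric squared-Hamming distances between haplotypes, with the count of
#' pairwise non-missing sites retained for missing-data normalization.
#'
#' @slot values symmetric n-by-n matrix, zero diagonal, entries >= 0.
#' @slot sitesCompared n-by-n integer matrix of pairwise non-missing site
#'   counts.
#' @seealso [squaredHammingMatrix()], [uniqueness()]
#' @exportClass DistanceMatrix
setClass("DistanceMatrix",
  representation(values = "matrix", sitesCompared = "matrix")
)

setValidity("DistanceMatrix", function(object) {
  v <- object@values
  msg <- character(0)
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  else {
    if (max(abs(v - t(v))) > 1e-8) msg <- c(msg, "values must be symmetric")
    if (any(diag(v) != 0)) msg <- c(msg, "diagonal must be zero")
    if (any(v < 0)) msg <- c(msg, "entries must be >= 0")
  }
  if (!identical(dim(object@sitesCompared), dim(v)))
    msg <- c(msg, "sitesCompared must match values in shape")
  if (length(msg)) msg else TRUE
})

#' Per-individual uniqueness weights for a core-allele carrier set
#'
#' For carriers X of a core allele, \eqn{U(I) = m D_x(I) / \sum_J D_x(J)}
#' where \eqn{D_x(I)} is I's average pairwise distance to the other
#' carriers and \eqn{m = |X|}; the weights sum to m, so unit weights
#' (all 1) recover the classical unweighted statistic.
#'
#' @slot carriers integer indices of the carriers in the distance matrix.
#' @slot U non-negative weights, one per carrier, summing to
#'   \code{length(carriers)}.
#' @slot DBar average pairwise distance per carrier.
#' @seealso [uniqueness()]
#' @exportClass UniquenessWeights
setClass("UniquenessWeights",
  representation(carriers = "integer", U = "numeric", DBar = "numeric")
)

setValidity("UniquenessWeights", function(object) {
  m <- length(object@carriers)
  msg <- character(0)
  if (length(object@U) != m || length(object@DBar) != m)
    msg <- c(msg, "carriers, U and DBar must have equal length")
  if (any(object@U < 0)) msg <- c(msg, "weights must be >= 0")
  if (m >= 2 && abs(sum(object@U) - m) > 1e-9)
    msg <- c(msg, "weights must sum to the carrier count")
  if (length(msg)) msg else TRUE
})

#' EHH decay around a core allele
#'
#' Extended haplotype homozygosity values walking outward from a core SNP in
#' both directions. Each direction starts at the core with ehh = 1 and is
#' non-increasing; the walk stops after the first value below the truncation
#' threshold or at the chromosome end.
#'
#' @slot coreIndex SNP index of the core site.
#' @slot coreAllele 0 (ancestral) or 1 (derived).
#' @slot left,right data.frames with columns \code{index}, \code{cM},
#'   \code{ehh}, ordered outward from the core (core first).
#' @slot reachedEnd named logical: did each direction hit the chromosome
#'   boundary before dropping below the truncation threshold?
#' @seealso [ehhDecay()], [integrateEHH()]
#' @exportClass EHHDecay
setClass("EHHDecay",
  representation(
    coreIndex = "integer",
    coreAllele = "integer",
    left = "data.frame",
    right = "data.frame",
    reachedEnd = "logical"
  )
)

#' Demographic and selection scenario for the simulation study
#'
#' Parameters of one coalescent simulation scenario: a demographic model
#' (panmictic, two-deme island with migration, exponential growth, or
#' bottleneck), population-scaled mutation/recombination rates, a selection
#' coefficient for the sweep site and the present-day frequency window it is
#' conditioned on. Times are in units of 2Ne generations.
#'
#' @slot model one of \code{"panmictic"}, \code{"island"}, \code{"growth"},
#'   \code{"bottleneck"}.
#' @slot sequenceLength simulated sequence length in bp.
#' @slot sampleSize number of sampled chromosomes.
#' @slot theta population-scaled mutation rate per site (4 Ne mu).
#' @slot rho population-scaled recombination rate per site (4 Ne r).
#' @slot Ne effective population size.
#' @slot selection2Ns population-scaled selection coefficient 2Ns of the
#'   sweep site; 0 means neutral.
#' @slot migration4Nm island-model scaled migration rate 4Nm.
#' @slot bottleneckDepth fraction of Ne during the bottleneck.
#' @slot bottleneckStart,bottleneckEnd recent/old edge of the bottleneck
#'   epoch, units of 2Ne generations before present.
#' @slot growthStart time before present at which exponential growth to the
#'   current size began (constant ancestral size before that).
#' @slot ancestralSizeFraction ancestral size as a fraction of Ne (growth
#'   model).
#' @slot sweepStartTime requested sweep start time (units of 2Ne
#'   generations); \code{NA} lets the backend determine the sweep duration
#'   from the selection coefficient.
#' @slot targetFreqRange length-2 numeric in (0,1): accepted window for the
#'   present-day derived frequency of the sweep site.
#' @slot nSampledSnps number of SNPs drawn from the simulated mutations.
#' @slot mafMin minor-allele-frequency floor for sampled SNPs and core
#'   sites.
#' @seealso [scenarioSpec()], [simulateReplicates()]
#' @exportClass ScenarioSpec
setClass("ScenarioSpec",
  representation(
    model = "character",
    sequenceLength = "numeric",
    sampleSize = "integer",
    theta = "numeric",
    rho = "numeric",
    Ne = "numeric",
    selection2Ns = "numeric",
    migration4Nm = "numeric",
    bottleneckDepth = "numeric",
    bottleneckStart = "numeric",
    bottleneckEnd = "numeric",
    growthStart = "numeric",
    ancestralSizeFraction = "numeric",
    sweepStartTime = "numeric",
    targetFreqRange = "numeric",
    nSampledSnps = "integer",
    mafMin = "numeric"
  )
)

setValidity("ScenarioSpec", function(object) {
  msg <- character(0)
  if (!object@model %in% c("panmictic", "island", "growth", "bottleneck"))
    msg <- c(msg, "unknown model")
  for (s in c("sequenceLength", "sampleSize", "theta", "rho", "Ne"))
    if (slot(object, s) <= 0) msg <- c(msg, paste(s, "must be positive"))
  if (object@selection2Ns < 0) msg <- c(msg, "selection2Ns must be >= 0")
  tr <- object@targetFreqRange
  if (length(tr) != 2L || tr[1] >= tr[2] || tr[1] <= 0 || tr[2] >= 1)
    msg <- c(msg, "targetFreqRange must be an increasing pair inside (0,1)")
  if (object@mafMin < 0 || object@mafMin >= 0.5)
    msg <- c(msg, "mafMin must be in [0, 0.5)")
  if (length(msg)) msg else TRUE
})

#' One simulated replicate
#'
#' A simulated haplotype dataset together with the index of the causal
#' (selected) SNP in the sampled grid, its present-day derived frequency,
#' the seed that produced it and the scenario it came from.
#'
#' @slot dataset the [HaplotypeDataset-class].
#' @slot causalIndex SNP index of the selected site (\code{NA} for neutral
#'   replicates).
#' @slot causalFreq sample derived frequency of the selected site.
#' @slot seed integer seed of the accepted simulation.
#' @slot scenario the [ScenarioSpec-class] that generated it.
#' @slot attempts simulation attempts used by frequency-rejection sampling.
#' @seealso [simulateReplicates()], [downsampleSnps()]
#' @exportClass SimReplicate
setClass("SimReplicate",
  representation(
    dataset = "HaplotypeDataset",
    causalIndex = "integer",
    causalFreq = "numeric",
    seed = "integer",
    scenario = "ScenarioSpec",
    attempts = "integer"
  )
)
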