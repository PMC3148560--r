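#' @describeIn HaplotypeDataset-class number of haplotypes (rows)
#' @param object,x a \code{HaplotypeDataset}
#' @export
setGeneric("nHaplotypes", function(x) standardGeneric("nHaplotypes"))

#' @describeIn HaplotypeDataset-class number of SNPs (columns)
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @describeIn HaplotypeDataset-class the 0/1 allele matrix
#' @export
setGeneric("alleles", function(x) standardGeneric("alleles"))

#' @describeIn HaplotypeDataset-class physical (bp) SNP positions
#' @export
setGeneric("physicalPositions", function(x) standardGeneric("physicalPositions"))

#' @describeIn HaplotypeDataset-class genetic (cM) SNP positions
#' @export
setGeneric("geneticPositions", function(x) standardGeneric("geneticPositions"))

#' @describeIn HaplotypeDataset-class haplotype labels
#' @export
setGeneric("sequenceIds", function(x) standardGeneric("sequenceIds"))

#' @describeIn HaplotypeDataset-class chromosome label
#' @export
setGeneric("chromosomeId", function(x) standardGeneric("chromosomeId"))

#' @describeIn HaplotypeDataset-class per-SNP derived allele frequency
#'   (missing alleles excluded from the denominator)
#' @export
setGeneric("derivedFreq", function(x) standardGeneric("derivedFreq"))

#' Evaluate a genetic map at physical positions
#'
#' @param map a [GeneticMap-class]
#' @param bp numeric vector of physical positions
#' @return cM positions, monotone non-decreasing in \code{bp}
#' @examples
#' gm <- fitGeneticMap(data.frame(bp = c(0, 1e6, 2e6), cM = c(0, 1, 2)), degree = 1)
#' mapPosition(gm, 5e5)
#' @export
setGeneric("mapPosition", function(map, bp) standardGeneric("mapPosition"))

setMethod("nHaplotypes", "HaplotypeDataset", function(x) nrow(x@alleles))
setMethod("nSites", "HaplotypeDataset", function(x) ncol(x@alleles))
setMethod("alleles", "HaplotypeDataset", function(x) x@alleles)
setMethod("physicalPositions", "HaplotypeDataset", function(x) x@physicalPositions)
setMethod("geneticPositions", "HaplotypeDataset", function(x) x@geneticPositions)
setMethod("sequenceIds", "HaplotypeDataset", function(x) x@sequenceIds)
setMethod("chromosomeId", "HaplotypeDataset", function(x) x@chromosomeId)
setMethod("derivedFreq", "HaplotypeDataset", function(x)
  colMeans(x@alleles == 1L, na.rm = TRUE))

setMethod("show", "HaplotypeDataset", function(object) {
  cat("HaplotypeDataset:", nrow(object@alleles), "haplotypes x",
      ncol(object@alleles), "SNPs on", object@chromosomeId, "\n")
  pp <- object@physicalPositions
  cat("  bp range:", format(pp[1], big.mark = ","), "-",
      format(pp[length(pp)], big.mark = ","), "\n")
  g <- object@geneticPositions
  if (all(is.na(g))) cat("  genetic positions: unassigned\n")
  else cat(sprintf("  cM range: %.4g - %.4g\n", g[1], g[length(g)]))
  nm <- sum(is.na(object@alleles))
  if (nm > 0) cat("  missing alleles:", nm, "\n")
})

setMethod("show", "GeneticMap", function(object) {
  cat("GeneticMap:", nrow(object@anchors), "anchors, ")
  if (object@piecewise)
    cat("monotone piecewise-linear (polynomial degree", object@degree,
        "fit was non-monotone)\n")
  else
    cat("polynomial degree", object@degree, "\n")
  cat(sprintf("  bp range: %g - %g; cM range: %g - %g\n",
              min(object@anchors$bp), max(object@anchors$bp),
              min(object@anchors$cM), max(object@anchors$cM)))
})

setMethod("show", "DistanceMatrix", function(object) {
  n <- nrow(object@values)
  off <- object@values[upper.tri(object@values)]
  cat("DistanceMatrix:", n, "x", n, "\n")
  if (length(off))
    cat(sprintf("  off-diagonal range: %.4g - %.4g (mean %.4g)\n",
                min(off), max(off), mean(off)))
})

setMethod("show", "UniquenessWeights", function(object) {
  cat("UniquenessWeights for", length(object@carriers), "carriers\n")
  cat(sprintf("  U range: %.4g - %.4g (sum = %g)\n",
              min(object@U), max(object@U), sum(object@U)))
})

setMethod("show", "EHHDecay", function(object) {
  cat("EHHDecay at core SNP", object@coreIndex, "allele", object@coreAllele, "\n")
  cat("  left:", nrow(object@left), "points; right:", nrow(object@right),
      "points\n")
  if (any(object@reachedEnd))
    cat("  reached chromosome end:", paste(names(object@reachedEnd)[object@reachedEnd],
                                           collapse = ", "), "\n")
})

setMethod("show", "ScenarioSpec", function(object) {
  cat("ScenarioSpec:", object@model, "model\n")
  cat(sprintf("  L = %g bp, n = %d chromosomes, theta = %g, rho = %g, Ne = %g\n",
              object@sequenceLength, object@sampleSize, object@theta,
              object@rho, object@Ne))
  if (object@selection2Ns > 0)
    cat(sprintf("  sweep: 2Ns = %g, target frequency %.2f - %.2f\n",
                object@selection2Ns, object@targetFreqRange[1],
                object@targetFreqRange[2]))
  else cat("  neutral (no selected site)\n")
  if (object@model == "island")
    cat(sprintf("  island: 4Nm = %g, two demes, 50/50 sampling\n",
                object@migration4Nm))
  cat(sprintf("  SNP sampling: %d SNPs with MAF >= %g\n",
              object@nSampledSnps, object@mafMin))
})

setMethod("show", "SimReplicate", function(object) {
  cat("SimReplicate (seed", object@seed, ",", object@scenario@model, "model)\n")
  if (is.na(object@causalIndex)) cat("  neutral replicate\n")
  else cat(sprintf("  causal SNP index %d, derived frequency %.3f\n",
                   object@causalIndex, object@causalFreq))
  cat("  ", nHaplotypes(object@dataset), "haplotypes x",
      nSites(object@dataset), "SNPs\n")
})
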