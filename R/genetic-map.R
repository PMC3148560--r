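#' Fit a physical-to-genetic map to anchor markers
#'
#' Least-squares polynomial fit of cM on bp over a set of anchor markers
#' with known positions in both coordinate systems. EHH integration needs a
#' monotone map, so if the fitted polynomial decreases anywhere on the
#' anchored range it is replaced by monotone piecewise-linear interpolation
#' of the anchors.
#'
#' @param anchors data.frame (or matrix) with columns bp (strictly
#'   increasing) and cM (non-decreasing), or a two-column object coercible
#'   to that.
#' @param degree polynomial degree; needs at least \code{degree + 1}
#'   anchors. The default of 3 captures the typical smooth large-scale
#'   variation of recombination rate along a chromosome without chasing
#'   marker noise.
#' @return a [GeneticMap-class]
#' @examples
#' gm <- fitGeneticMap(data.frame(bp = c(0, 1e6, 2e6), cM = c(0, 1, 2)), degree = 1)
#' mapPosition(gm, c(5e5, 1.5e6))
#' @export
fitGeneticMap <- function(anchors, degree = 3L) {
  anchors <- as.data.frame(anchors)
  names(anchors)[1:2] <- c("bp", "cM")
  anchors <- anchors[, c("bp", "cM")]
  degree <- as.integer(degree)
  if (degree < 0L) stop("degree must be >= 0")
  if (nrow(anchors) < degree + 1L)
    stop("need at least degree + 1 = ", degree + 1L, " anchors, got ",
         nrow(anchors))
  if (is.unsorted(anchors$bp, strictly = TRUE))
    stop("anchor bp must be strictly increasing")
  if (is.unsorted(anchors$cM))
    stop("anchor cM must be non-decreasing")

  if (degree == 0L) {
    coefs <- mean(anchors$cM)
  } else {
    # centered/scaled bp for numerical stability, back-transformed below
    sc <- max(abs(anchors$bp))
    if (sc == 0) sc <- 1
    fit <- stats::lm(cM ~ stats::poly(bp, degree, raw = TRUE),
                     data = data.frame(bp = anchors$bp / sc, cM = anchors$cM))
    coefs <- unname(stats::coef(fit)) / sc^(0:degree)
    coefs[is.na(coefs)] <- 0
  }

  gm <- new("GeneticMap", anchors = anchors, coefficients = coefs,
            degree = degree, piecewise = FALSE)
  if (!mapIsMonotone(gm)) {
    gm@piecewise <- TRUE
    gm@coefficients <- numeric(0)
  }
  gm
}

polyEval <- function(coefs, x) {
  y <- rep(0, length(x))
  for (k in rev(seq_along(coefs))) y <- y * x + coefs[k]
  y
}

# check monotonicity of the polynomial on a dense grid over the anchor range
mapIsMonotone <- function(gm) {
  a <- gm@anchors
  grid <- sort(unique(c(a$bp, seq(min(a$bp), max(a$bp), length.out = 512L))))
  vals <- polyEval(gm@coefficients, grid)
  !is.unsorted(vals)
}

#' @describeIn fitGeneticMap evaluate the map; inside the anchored range the
#'   polynomial (or piecewise-linear fallback) is used, outside it linear
#'   extrapolation with the boundary slope.
#' @param map a [GeneticMap-class]
#' @param bp physical positions to convert
#' @export
setMethod("mapPosition", "GeneticMap", function(map, bp) {
  a <- map@anchors
  lo <- min(a$bp); hi <- max(a$bp)
  if (map@piecewise) {
    inner <- function(x) stats::approx(a$bp, a$cM, xout = x, rule = 2)$y
    n <- nrow(a)
    sloLo <- if (n > 1) (a$cM[2] - a$cM[1]) / (a$bp[2] - a$bp[1]) else 0
    sloHi <- if (n > 1) (a$cM[n] - a$cM[n - 1]) / (a$bp[n] - a$bp[n - 1]) else 0
    vLo <- a$cM[1]; vHi <- a$cM[n]
  } else {
    inner <- function(x) polyEval(map@coefficients, x)
    dcoef <- if (map@degree >= 1)
      map@coefficients[-1] * seq_len(map@degree) else 0
    sloLo <- max(0, polyEval(dcoef, lo))
    sloHi <- max(0, polyEval(dcoef, hi))
    vLo <- inner(lo); vHi <- inner(hi)
  }
  out <- numeric(length(bp))
  below <- bp < lo; above <- bp > hi; mid <- !below & !above
  out[mid] <- inner(bp[mid])
  out[below] <- vLo - (lo - bp[below]) * sloLo
  out[above] <- vHi + (bp[above] - hi) * sloHi
  out
})

#' Assign genetic positions to a dataset from a genetic map
#'
#' Sets \code{geneticPositions(x)} to \code{mapPosition(map,
#' physicalPositions(x))}. SNP count and order are preserved; the map's
#' monotonicity guarantees non-decreasing genetic positions.
#'
#' @param x a [HaplotypeDataset-class]
#' @param map a [GeneticMap-class]
#' @return the dataset with genetic positions filled in
#' @export
assignGeneticPositions <- function(x, map) {
  g <- mapPosition(map, physicalPositions(x))
  g <- cummax(g)   # absorb float-level wiggles from extrapolation
  x@geneticPositions <- g
  validObject(x)
  x
}

#' Attach a uniform genetic map
#'
#' Convenience for simulated data with constant recombination: genetic
#' position = \code{cMperBp * physical position}.
#'
#' @param x a [HaplotypeDataset-class]
#' @param cMperBp map density in cM per bp
#' @return the dataset with genetic positions filled in
#' @export
assignUniformMap <- function(x, cMperBp) {
  x@geneticPositions <- physicalPositions(x) * cMperBp
  validObject(x)
  x
}
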