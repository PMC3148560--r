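#' Read phased haplotype data
#'
#' Reads a haplotype matrix from one of three formats into a
#' [HaplotypeDataset-class]:
#' \describe{
#'   \item{\code{tsv}}{header row of physical bp positions, then one row of
#'     0/1 alleles per haplotype (\code{.}, \code{NA} or \code{9} mark
#'     missing).}
#'   \item{\code{ms}}{coalescent-simulator output (\code{//},
#'     \code{segsites:}, \code{positions:} in (0,1), 0/1 rows); positions
#'     are scaled to integer bp by \code{sequenceLength}. Only the first
#'     replicate block is returned.}
#'   \item{\code{vcf}}{phased, biallelic VCF; alleles are polarized so that
#'     0 = ancestral using the INFO key named by \code{ancestralSource}
#'     (default \code{AA}). Sites whose ancestral state is missing or
#'     matches neither allele are dropped and counted in
#'     \code{attr(x, "droppedSites")}. Multiallelic sites are skipped with
#'     a warning; an unphased genotype is a hard error naming the record.}
#' }
#'
#' Physical positions are 0-based internally (VCF POS is converted from
#' 1-based). Duplicate bp positions are resolved by a deterministic +1 bp
#' jitter, left to right, with a warning.
#'
#' @param path input file.
#' @param format one of \code{"tsv"}, \code{"ms"}, \code{"vcf"}.
#' @param ancestralSource INFO key holding the ancestral allele (vcf only);
#'   \code{NULL} keeps the REF/ALT coding as 0/1 without polarization.
#' @param sequenceLength sequence length in bp used to scale ms positions.
#' @param chromosomeId chromosome label for tsv/ms input.
#' @return a [HaplotypeDataset-class]; for vcf input the attribute
#'   \code{droppedSites} reports per-reason dropped-site counts.
#' @examples
#' f <- tempfile()
#' writeLines(c("100\t200\t300", "0\t0\t1", "1\t0\t1", "0\t1\t0", "1\t1\t0"), f)
#' readHaplotypes(f, "tsv")
#' @export
readHaplotypes <- function(path, format = c("tsv", "ms", "vcf"),
                           ancestralSource = "AA", sequenceLength = NULL,
                           chromosomeId = "chr1") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         tsv = readHaplotypesTsv(path, chromosomeId),
         ms  = readHaplotypesMs(path, sequenceLength, chromosomeId),
         vcf = readHaplotypesVcf(path, ancestralSource))
}

readHaplotypesTsv <- function(path, chromosomeId) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("tsv needs a position header and >= 2 haplotype rows")
  pos <- as.numeric(strsplit(lines[1], "\t", fixed = TRUE)[[1]])
  rows <- lapply(lines[-1], function(l) {
    v <- strsplit(l, "\t", fixed = TRUE)[[1]]
    v[v %in% c(".", "NA", "9")] <- NA
    as.integer(v)
  })
  a <- do.call(rbind, rows)
  if (ncol(a) != length(pos)) stop("allele row length does not match position header")
  HaplotypeDataset(a, dedupPositions(pos), chromosomeId = chromosomeId)
}

# deterministic +1 bp jitter, left to right, for duplicate positions
dedupPositions <- function(pos) {
  if (is.unsorted(pos)) stop("positions must be sorted")
  out <- pos
  for (i in seq_along(out)[-1]) {
    if (out[i] <= out[i - 1]) out[i] <- out[i - 1] + 1
  }
  if (any(out != pos))
    warning(sum(out != pos), " duplicate position(s) jittered by +1 bp")
  out
}

# parse every replicate block of an ms-format file
parseMsBlocks <- function(lines) {
  starts <- which(trimws(lines) == "//")
  if (!length(starts)) stop("no '//' replicate block found in ms input")
  lapply(starts, function(s) {
    i <- s + 1L
    seg <- NA_integer_
    while (i <= length(lines)) {
      l <- trimws(lines[i])
      if (startsWith(l, "segsites:")) {
        seg <- as.integer(trimws(sub("segsites:", "", l, fixed = TRUE)))
        break
      }
      i <- i + 1L
    }
    if (is.na(seg)) stop("ms block without segsites line")
    if (seg == 0L) return(list(positions = numeric(0), rows = character(0)))
    pos <- numeric(0)
    i <- i + 1L
    while (i <= length(lines) && length(pos) < seg) {
      l <- trimws(lines[i])
      if (startsWith(l, "positions:")) l <- trimws(sub("positions:", "", l, fixed = TRUE))
      if (nzchar(l)) pos <- c(pos, as.numeric(strsplit(l, "\\s+")[[1]]))
      i <- i + 1L
    }
    rows <- character(0)
    while (i <= length(lines)) {
      l <- trimws(lines[i])
      if (!nzchar(l) || l == "//") break
      if (!grepl("^[01]+$", l)) break
      rows <- c(rows, l)
      i <- i + 1L
    }
    list(positions = pos, rows = rows)
  })
}

msBlockToDataset <- function(block, sequenceLength, chromosomeId) {
  if (!length(block$rows)) stop("ms block has no haplotype rows")
  pos <- round(block$positions * sequenceLength)
  a <- do.call(rbind, lapply(strsplit(block$rows, ""),
                             function(v) as.integer(v)))
  if (ncol(a) != length(pos)) stop("ms haplotype rows do not match segsites")
  HaplotypeDataset(a, dedupPositions(pos), chromosomeId = chromosomeId)
}

readHaplotypesMs <- function(path, sequenceLength, chromosomeId) {
  if (is.null(sequenceLength))
    stop("sequenceLength is required to scale ms positions to bp")
  blocks <- parseMsBlocks(readLines(path))
  msBlockToDataset(blocks[[1]], sequenceLength, chromosomeId)
}

readHaplotypesVcf <- function(path, ancestralSource) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))

  dropped <- c(multiallelic = 0L, no_ancestral = 0L)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    dropped["multiallelic"] <- sum(multi)
    warning(sum(multi), " multiallelic site(s) skipped")
  }

  aa <- if (!is.null(ancestralSource))
    vcfR::extract.info(vcf, element = ancestralSource) else NULL

  keep <- which(!multi)
  cols <- list(); pos <- numeric(0)
  for (k in keep) {
    g <- gt[k, ]
    bad <- grepl("/", g, fixed = TRUE)
    if (any(bad))
      stop("unphased genotype at ", fix[k, "CHROM"], ":", fix[k, "POS"],
           " sample ", names(g)[bad][1])
    hap <- unlist(strsplit(g, "|", fixed = TRUE), use.names = FALSE)
    hap[hap == "."] <- NA
    v <- as.integer(hap)
    if (!is.null(aa)) {
      anc <- toupper(aa[k])
      if (is.na(anc) || !anc %in% c(fix[k, "REF"], fix[k, "ALT"])) {
        dropped["no_ancestral"] <- dropped["no_ancestral"] + 1L
        next
      }
      if (anc == fix[k, "ALT"]) v <- 1L - v   # ALT ancestral: flip coding
    }
    cols[[length(cols) + 1L]] <- v
    pos <- c(pos, as.numeric(fix[k, "POS"]) - 1)  # to 0-based
  }
  if (length(cols) < 2L) stop("fewer than 2 usable sites in VCF")
  nh <- unique(vapply(cols, length, 1L))
  if (length(nh) != 1L) stop("inconsistent ploidy across sites")
  a <- matrix(unlist(cols), nrow = nh)
  ids <- paste0(rep(colnames(gt), each = nh / ncol(gt)), "_",
                seq_len(nh / ncol(gt)))
  ds <- HaplotypeDataset(a, dedupPositions(pos), sequenceIds = ids,
                         chromosomeId = unique(fix[keep, "CHROM"])[1])
  attr(ds, "droppedSites") <- dropped
  ds
}

#' Write a HaplotypeDataset in the plain TSV dialect
#'
#' Header row of physical positions, one 0/1 row per haplotype (missing as
#' \code{.}). \code{readHaplotypes(..., "tsv")} reads it back.
#'
#' @param x a [HaplotypeDataset-class]
#' @param path output file
#' @return the path, invisibly
#' @export
writeHaplotypes <- function(x, path) {
  a <- alleles(x)
  a[is.na(a)] <- "."
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(format(physicalPositions(x), scientific = FALSE, trim = TRUE),
                   collapse = "\t"), con)
  apply(a, 1, function(r) writeLines(paste(r, collapse = "\t"), con))
  invisible(path)
}

#' Read genetic-map anchors from a two-column TSV (bp, cM)
#'
#' A non-numeric first row is treated as a header.
#'
#' @param path input file
#' @return data.frame with columns \code{bp}, \code{cM}
#' @export
readGeneticMapAnchors <- function(path) {
  first <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  header <- anyNA(suppressWarnings(as.numeric(first)))
  d <- utils::read.table(path, header = header, sep = "\t")
  names(d)[1:2] <- c("bp", "cM")
  d[, c("bp", "cM")]
}

scoreColumns <- c("chromosome", "position", "derived_freq",
                  "iwEHH_A", "iwEHH_D", "raw", "standardized")
windowColumns <- c("window_start", "window_end", "mean_abs_score",
                   "rank", "empirical_p")

#' Write per-SNP or per-window scores as TSV
#'
#' Per-SNP output has columns chromosome, position, derived_freq, iwEHH_A,
#' iwEHH_D, raw, standardized; per-window output has window_start,
#' window_end, mean_abs_score, rank, empirical_p. The kind is detected from
#' the columns present. [readScores()] reads either back.
#'
#' @param scores a scan result ([ihsScan()] etc.) or window table
#'   ([slidingWindows()]).
#' @param path output file.
#' @return the path, invisibly
#' @export
writeScores <- function(scores, path) {
  cols <- if (all(windowColumns %in% c(names(scores), "rank", "empirical_p")) &&
              "mean_abs_score" %in% names(scores)) {
    for (c in c("rank", "empirical_p"))
      if (!c %in% names(scores)) scores[[c]] <- NA_real_
    windowColumns
  } else if (all(scoreColumns %in% names(scores))) {
    scoreColumns
  } else stop("unrecognized score table")
  ok <- tryCatch({
    utils::write.table(scores[, cols, drop = FALSE], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write scores to ", path)
  invisible(path)
}

#' @rdname writeScores
#' @export
readScores <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = NA, stringsAsFactors = FALSE)
}

#' Export / import a distance matrix as labeled TSV
#'
#' n+1 lines: a header of sequence labels, then one labeled row per
#' sequence.
#'
#' @param dm a [DistanceMatrix-class]
#' @param path file path
#' @return \code{writeDistanceMatrix}: the path invisibly;
#'   \code{readDistanceMatrix}: a [DistanceMatrix-class] (sitesCompared is
#'   not round-tripped and is set to 0).
#' @export
writeDistanceMatrix <- function(dm, path) {
  v <- dm@values
  labs <- rownames(v)
  if (is.null(labs)) labs <- paste0("hap", seq_len(nrow(v)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", labs), collapse = "\t"), con)
  for (i in seq_len(nrow(v)))
    writeLines(paste(c(labs[i], format(v[i, ], digits = 17)), collapse = "\t"), con)
  invisible(path)
}

#' @rdname writeDistanceMatrix
#' @export
readDistanceMatrix <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                         check.names = FALSE)
  v <- as.matrix(d)
  v <- (v + t(v)) / 2   # guard against asciification asymmetry
  new("DistanceMatrix", values = v,
      sitesCompared = matrix(0L, nrow(v), ncol(v)))
}
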