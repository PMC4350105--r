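#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<- queryHits subjectHits
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end width strand strand<-
#'   granges findOverlaps countOverlaps
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges colData
NULL

#' Cohort of bin-level methylation tracks
#'
#' `BinMethylome` holds per-sample methylation intensities (raw read counts
#' or linearly normalized values) on a fixed-width genomic bin grid, one
#' column per sample, together with a `group` label (`tumor` or `normal`)
#' per sample. It extends [SummarizedExperiment::RangedSummarizedExperiment],
#' so the full Bioconductor ecosystem of subsetting and overlap operations
#' applies; the only additions are the bin-grid invariants enforced by the
#' validity method.
#'
#' @slot ... see [SummarizedExperiment::RangedSummarizedExperiment].
#'
#' @details Invariants: a single assay named `"counts"`; all values finite
#' and non-negative; every row range has width equal to the common
#' `binWidth` stored in `metadata(x)$binWidth`; `colData(x)$group` is a
#' factor with levels `tumor` and `normal`.
#'
#' @seealso [BinMethylome()] for construction, [binWidth()],
#'   [sampleGroups()], [normalizeLinear()], [testBins()].
#' @export
setClass("BinMethylome", contains = "RangedSummarizedExperiment")

setValidity("BinMethylome", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    a <- assay(object, "counts")
    if (any(!is.finite(a)) || any(a < 0))
      msg <- c(msg, "intensities must be finite and >= 0")
  }
  bw <- metadata(object)$binWidth
  if (is.null(bw) || length(bw) != 1L || bw <= 0)
    msg <- c(msg, "metadata(x)$binWidth must be a single positive number")
  else if (length(object) && !all(width(rowRanges(object)) == bw))
    msg <- c(msg, "all bins must have width binWidth")
  grp <- colData(object)$group
  if (is.null(grp) || !all(grp %in% c("tumor", "normal")))
    msg <- c(msg, "colData(x)$group must be 'tumor' or 'normal'")
  if (length(msg)) msg else TRUE
})

#' Construct a BinMethylome
#'
#' @param counts numeric matrix, bins x samples, non-negative.
#' @param bins [GenomicRanges::GRanges] of the bin grid, one range per row
#'   of `counts`, all of width `binWidth`.
#' @param group character/factor of length `ncol(counts)` with values
#'   `"tumor"` / `"normal"`.
#' @param binWidth width of every bin in bp (default 100, the resolution
#'   at which MBDCap-seq methylomes are commonly binned).
#' @param sampleIds optional sample identifiers (defaults to
#'   `colnames(counts)`).
#'
#' @return a [BinMethylome-class] object.
#' @examples
#' bins <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 101), width = 100))
#' m <- matrix(rpois(8, 50), nrow = 2,
#'             dimnames = list(NULL, paste0("s", 1:4)))
#' bm <- BinMethylome(m, bins, group = c("tumor", "tumor", "normal", "normal"))
#' @export
BinMethylome <- function(counts, bins, group, binWidth = 100L,
                         sampleIds = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(sampleIds)) sampleIds <- paste0("sample", seq_len(ncol(counts)))
  colnames(counts) <- sampleIds
  cd <- DataFrame(group = factor(as.character(group),
                                 levels = c("tumor", "normal")),
                  row.names = sampleIds)
  se <- SummarizedExperiment(assays = list(counts = counts),
                             rowRanges = bins, colData = cd)
  metadata(se)$binWidth <- as.integer(binWidth)
  new("BinMethylome", se)
}

#' @describeIn BinMethylome width of the common bin grid, in bp.
#' @param x a `BinMethylome`.
#' @export
binWidth <- function(x) metadata(x)$binWidth

#' @describeIn BinMethylome per-sample group factor (`tumor`/`normal`).
#' @export
sampleGroups <- function(x) colData(x)$group

setMethod("show", "BinMethylome", function(object) {
  grp <- table(sampleGroups(object))
  cat(sprintf("BinMethylome: %d bins (%d bp) x %d samples (%d tumor, %d normal)%s\n",
              nrow(object), binWidth(object), ncol(object),
              grp[["tumor"]], grp[["normal"]],
              if (isTRUE(metadata(object)$normalized)) ", linearly normalized" else ""))
  invisible(callNextMethod())
})

#' Simulation configuration for the synthetic methylome generator
#'
#' Captures the study conditions emulated by the generator: a toy genome,
#' a gene complement of coding genes, lncRNAs and pri-miRNAs, a tumor and
#' a normal cohort of negative-binomial bin-count methylomes, and a spike
#' table of ground-truth differentially methylated promoters covering the
#' five CGI-context patterns.
#'
#' @slot nChrom number of chromosomes.
#' @slot chromLength length of each chromosome in bp; must be a multiple
#'   of `binWidth`.
#' @slot binWidth methylation bin width in bp.
#' @slot nCoding,nLncRNA,nMiRNA gene counts per class.
#' @slot cgiPromoterFraction fraction of promoters that carry a CpG island.
#' @slot biotypeMix length-3 numeric (intergenic, intragenic, overlapping)
#'   summing to 1: the ncRNA biotype composition to realize.
#' @slot nTumor,nNormal cohort sizes (>= 2 each).
#' @slot baselineMean expected reads per bin outside CGIs.
#' @slot dispersion negative-binomial size parameter (variance =
#'   mean + mean^2/dispersion).
#' @slot cgiEnrichment multiplicative mean elevation on CGI bins (both
#'   groups; MBD capture enriches CpG-dense DNA).
#' @slot libSizeRange range of per-sample library-size factors, drawn
#'   log-uniformly.
#' @slot spikes data.frame with columns `pattern` (1..5), `direction`
#'   (`hyper`/`hypo`), `foldChange` (> 1) and `coupling`
#'   (`silencing`/`activating`/`none`); targets are assigned
#'   deterministically to compatible intergenic ncRNAs.
#' @slot foldExpr expression fold change applied to coupled genes (> 2).
#' @slot exprNoiseSdLog2 per-sample expression noise, sd on the log2 scale.
#' @slot seed integer seed making every generator output reproducible.
#'
#' @seealso [simConfig()], [defaultSpikes()], [simulateAnnotation()].
#' @export
setClass("SimulationConfig", representation(
  nChrom = "integer", chromLength = "integer", binWidth = "integer",
  nCoding = "integer", nLncRNA = "integer", nMiRNA = "integer",
  cgiPromoterFraction = "numeric", biotypeMix = "numeric",
  nTumor = "integer", nNormal = "integer",
  baselineMean = "numeric", dispersion = "numeric",
  cgiEnrichment = "numeric", libSizeRange = "numeric",
  spikes = "data.frame", foldExpr = "numeric",
  exprNoiseSdLog2 = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@chromLength %% object@binWidth != 0)
    msg <- c(msg, "binWidth must divide chromLength")
  if (object@nTumor < 2L || object@nNormal < 2L)
    msg <- c(msg, "need >= 2 samples per group")
  if (abs(sum(object@biotypeMix) - 1) > 1e-8 || length(object@biotypeMix) != 3L)
    msg <- c(msg, "biotypeMix must be 3 fractions summing to 1")
  if (object@cgiPromoterFraction < 0 || object@cgiPromoterFraction > 1)
    msg <- c(msg, "cgiPromoterFraction must lie in [0,1]")
  if (nrow(object@spikes)) {
    if (!all(object@spikes$foldChange > 1))
      msg <- c(msg, "spike foldChange must be > 1")
    if (!all(object@spikes$pattern %in% 1:5))
      msg <- c(msg, "spike pattern must be in 1..5")
    if (!all(object@spikes$direction %in% c("hyper", "hypo")))
      msg <- c(msg, "spike direction must be hyper/hypo")
    if (!all(object@spikes$coupling %in% c("silencing", "activating", "none")))
      msg <- c(msg, "spike coupling must be silencing/activating/none")
  }
  if (length(object@libSizeRange) != 2L || any(object@libSizeRange <= 0))
    msg <- c(msg, "libSizeRange must be two positive numbers")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0(
    "SimulationConfig: %d x %.2g Mb chromosomes, %d-bp bins\n",
    "  genes: %d coding, %d lncRNA, %d miRNA; CGI promoter fraction %.2f\n",
    "  cohort: %d tumor vs %d normal; NB(mean %.4g, dispersion %.4g)\n",
    "  spikes: %d; seed %d\n"),
    object@nChrom, object@chromLength / 1e6, object@binWidth,
    object@nCoding, object@nLncRNA, object@nMiRNA,
    object@cgiPromoterFraction, object@nTumor, object@nNormal,
    object@baselineMean, object@dispersion, nrow(object@spikes),
    object@seed))
})

#' Default spike table covering all five patterns in both directions
#'
#' Two spikes per (pattern, direction) combination; hyper spikes of
#' patterns 1 and 5 are coupled to expression silencing, hypo spikes of
#' patterns 1 and 5 to activation, the rest are uncoupled.
#'
#' @param foldChange methylation fold change per spike (default 4).
#' @return a `data.frame` usable as the `spikes` slot of
#'   [SimulationConfig-class].
#' @export
defaultSpikes <- function(foldChange = 4) {
  g <- expand.grid(pattern = 1:5, direction = c("hyper", "hypo"),
                   rep = 1:2, stringsAsFactors = FALSE)
  g$foldChange <- foldChange
  g$coupling <- ifelse(g$pattern %in% c(1L, 5L),
                       ifelse(g$direction == "hyper", "silencing", "activating"),
                       "none")
  g[c("pattern", "direction", "foldChange", "coupling")]
}

#' Build a SimulationConfig
#'
#' Defaults describe the package's standard toy study: a 2 x 2 Mb genome,
#' 200 genes, a 10-normal vs 20-tumor cohort with baseline 100 reads/bin
#' and negative-binomial dispersion 10, and the [defaultSpikes()] table of
#' fold-4 promoter spikes.
#'
#' @param nChrom,chromLength,binWidth genome geometry.
#' @param nCoding,nLncRNA,nMiRNA gene counts.
#' @param cgiPromoterFraction,biotypeMix promoter CGI fraction and ncRNA
#'   biotype composition (intergenic, intragenic, overlapping).
#' @param nTumor,nNormal cohort sizes.
#' @param baselineMean,dispersion,cgiEnrichment,libSizeRange count model.
#' @param spikes spike table, see [defaultSpikes()].
#' @param foldExpr,exprNoiseSdLog2 expression coupling model.
#' @param seed integer seed.
#' @return a validated [SimulationConfig-class].
#' @export
simConfig <- function(nChrom = 2L, chromLength = 2e6, binWidth = 100L,
                      nCoding = 60L, nLncRNA = 100L, nMiRNA = 40L,
                      cgiPromoterFraction = 0.7,
                      biotypeMix = c(intergenic = 0.6, intragenic = 0.25,
                                     overlapping = 0.15),
                      nTumor = 20L, nNormal = 10L,
                      baselineMean = 100, dispersion = 10,
                      cgiEnrichment = 2, libSizeRange = c(0.8, 1.25),
                      spikes = defaultSpikes(),
                      foldExpr = 4, exprNoiseSdLog2 = 0.25,
                      seed = 1L) {
  new("SimulationConfig", nChrom = as.integer(nChrom),
      chromLength = as.integer(chromLength), binWidth = as.integer(binWidth),
      nCoding = as.integer(nCoding), nLncRNA = as.integer(nLncRNA),
      nMiRNA = as.integer(nMiRNA),
      cgiPromoterFraction = cgiPromoterFraction,
      biotypeMix = unname(biotypeMix),
      nTumor = as.integer(nTumor), nNormal = as.integer(nNormal),
      baselineMean = baselineMean, dispersion = dispersion,
      cgiEnrichment = cgiEnrichment, libSizeRange = libSizeRange,
      spikes = spikes, foldExpr = foldExpr,
      exprNoiseSdLog2 = exprNoiseSdLog2, seed = as.integer(seed))
}
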