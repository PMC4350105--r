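#' Linear library-size normalization
#'
#' Scales every sample so that all totals equal the across-sample mean
#' total: sample j is multiplied by `mean(totals) / totals[j]`.
#'
#' @param bm a [BinMethylome-class] of raw counts.
#' @return a `BinMethylome` with the `counts` assay rescaled;
#'   `metadata(x)$normalized` is set.
#' @export
normalizeLinear <- function(bm) {
  stopifnot(is(bm, "BinMethylome"))
  totals <- colSums(assay(bm, "counts"))
  if (any(totals == 0))
    stop("sample with zero total count: ",
         colnames(bm)[which(totals == 0)[1]])
  f <- mean(totals) / totals
  SummarizedExperiment::assay(bm, "counts") <-
    sweep(assay(bm, "counts"), 2L, f, `*`)
  metadata(bm)$normalized <- TRUE
  metadata(bm)$scaleFactors <- f
  bm
}

#' Per-bin differential methylation test
#'
#' For every bin passing a coverage floor, compares tumor against normal
#' samples with a two-sided Wilcoxon rank-sum test, adjusts the p-values
#' by Benjamini-Hochberg across all tested bins genome-wide, and calls a
#' bin `hyper` (`hypo`) when both criteria are met: fold change of the
#' pseudocounted group means at least `fcThreshold` (at most
#' `1/fcThreshold`) and adjusted p below `qThreshold`.
#'
#' @param bm a normalized [BinMethylome-class] (see [normalizeLinear()]).
#' @param fcThreshold fold-change criterion (default 2).
#' @param qThreshold adjusted-p criterion (default 0.01).
#' @param pseudocount added to both group means before the ratio
#'   (default 0.5 normalized units), keeping fold changes finite on
#'   empty bins without affecting well-covered ones.
#' @param minMean coverage floor: bins with both group means below this
#'   are excluded from testing and from the BH family (default 1).
#' @param exactLimit pooled-cohort size up to which the rank-sum test is
#'   computed by exact enumeration (default 12).
#' @return `GRanges` of all bins with metadata columns `tumorMean`,
#'   `normalMean`, `foldChange`, `tested`, `p`, `q` (NA for untested
#'   bins) and `call` (`hyper`/`hypo`/`none`).
#' @export
testBins <- function(bm, fcThreshold = 2, qThreshold = 0.01,
                     pseudocount = 0.5, minMean = 1, exactLimit = 12L) {
  stopifnot(is(bm, "BinMethylome"))
  grp <- sampleGroups(bm)
  if (any(table(grp) < 2L)) stop("need >= 2 samples in each group")
  isTumor <- grp == "tumor"
  a <- assay(bm, "counts")
  tumorMean <- rowMeans(a[, isTumor, drop = FALSE])
  normalMean <- rowMeans(a[, !isTumor, drop = FALSE])
  tested <- !(tumorMean < minMean & normalMean < minMean)
  foldChange <- (tumorMean + pseudocount) / (normalMean + pseudocount)
  p <- rep(NA_real_, nrow(a)); q <- rep(NA_real_, nrow(a))
  if (any(tested)) {
    p[tested] <- rowWilcoxonP(a[tested, , drop = FALSE], isTumor,
                              exactLimit = exactLimit)
    q[tested] <- adjustBH(p[tested])
  }
  call <- rep("none", nrow(a))
  call[tested & q < qThreshold & foldChange >= fcThreshold] <- "hyper"
  call[tested & q < qThreshold & foldChange <= 1 / fcThreshold] <- "hypo"
  out <- rowRanges(bm)
  mcols(out) <- DataFrame(tumorMean = tumorMean, normalMean = normalMean,
                          foldChange = foldChange, tested = tested,
                          p = p, q = q,
                          call = factor(call, c("hyper", "hypo", "none")))
  out
}

#' Merge consecutive same-direction significant bins into DMRs
#'
#' Bins merge only when genomically adjacent (no gap: the next bin on
#' the grid) and called in the same direction; any intervening bin,
#' uncalled or opposite-direction, starts a new DMR. Singleton DMRs are
#' allowed.
#'
#' @param stats the bin-level `GRanges` from [testBins()], sorted by
#'   (chrom, start).
#' @return `GRanges` of DMRs with `direction`, `n_bins`, `min_q` and
#'   `max_abs_l2fc` metadata columns, sorted by (chrom, start).
#' @export
mergeBinsToDmrs <- function(stats) {
  o <- order(as.character(seqnames(stats)), start(stats))
  if (is.unsorted(o)) stop("bin stats must be sorted by (chrom, start)")
  emptyOut <- emptyDmrGRanges()
  called <- stats[mcols(stats)$call != "none"]
  if (!length(called)) return(emptyOut)
  pieces <- lapply(c("hyper", "hypo"), function(dir) {
    b <- called[mcols(called)$call == dir]
    if (!length(b)) return(emptyOut)
    red <- GenomicRanges::reduce(granges(b), ignore.strand = TRUE,
                                 min.gapwidth = 1L)
    hits <- findOverlaps(red, b, ignore.strand = TRUE)
    qh <- queryHits(hits); sh <- subjectHits(hits)
    mcols(red) <- DataFrame(
      direction = factor(dir, c("hyper", "hypo")),
      n_bins = as.integer(tabulate(qh, length(red))),
      min_q = as.numeric(tapply(mcols(b)$q[sh], qh, min)),
      max_abs_l2fc = as.numeric(
        tapply(abs(log2(mcols(b)$foldChange[sh])), qh, max)))
    strand(red) <- "*"
    red
  })
  out <- do.call(c, pieces)
  out[order(as.character(seqnames(out)), start(out))]
}

# Zero-length DMR GRanges with the standard metadata columns.
emptyDmrGRanges <- function() {
  gr <- GRanges()
  mcols(gr) <- DataFrame(direction = factor(character(), c("hyper", "hypo")),
                         n_bins = integer(), min_q = numeric(),
                         max_abs_l2fc = numeric())
  gr
}

#' Full DMR-calling pipeline on a raw cohort
#'
#' Convenience wrapper: [normalizeLinear()] then [testBins()] then
#' [mergeBinsToDmrs()].
#'
#' @param bm a raw-count [BinMethylome-class].
#' @param ... passed to [testBins()].
#' @return list with `binStats` (per-bin `GRanges`) and `dmrs`.
#' @export
callDmrs <- function(bm, ...) {
  stats <- testBins(normalizeLinear(bm), ...)
  list(binStats = stats, dmrs = mergeBinsToDmrs(stats))
}
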