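#' Pairwise overlap length between parallel interval vectors
#'
#' @param a,b [GenomicRanges::GRanges] of equal length (or length 1,
#'   recycled); element `i` of `a` is compared with element `i` of `b`.
#'   Intervals on different chromosomes overlap by 0 bp. Strand is
#'   ignored.
#' @return integer vector of overlap lengths in bp.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 200))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 400))
#' overlapLength(a, b)  # 50
#' @export
overlapLength <- function(a, b) {
  if (length(a) != length(b)) {
    if (length(a) == 1L) a <- rep(a, length(b))
    else if (length(b) == 1L) b <- rep(b, length(a))
    else stop("a and b must have equal length (or length 1)")
  }
  ov <- pmax(0L, pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1L)
  ov[as.character(seqnames(a)) != as.character(seqnames(b))] <- 0L
  as.integer(ov)
}

#' Pairwise overlap fraction
#'
#' Overlap length divided by the length of a chosen denominator interval.
#' `denominator = "either_max"` returns the larger of the two
#' single-denominator fractions, the quantity behind the "greater than
#' 50\% of either region" rule used for CGI-confined pattern calls.
#'
#' @param a,b parallel [GenomicRanges::GRanges] as in [overlapLength()].
#' @param denominator one of `"a"`, `"b"`, `"shorter"`, `"either_max"`.
#' @return numeric vector of fractions in \[0, 1\].
#' @export
overlapFraction <- function(a, b,
                            denominator = c("a", "b", "shorter", "either_max")) {
  denominator <- match.arg(denominator)
  if (length(a) == 1L && length(b) > 1L) a <- rep(a, length(b))
  if (length(b) == 1L && length(a) > 1L) b <- rep(b, length(a))
  ov <- overlapLength(a, b)
  wa <- width(a); wb <- width(b)
  den <- switch(denominator,
                a = wa, b = wb,
                shorter = pmin(wa, wb),
                either_max = NULL)
  if (denominator == "either_max") {
    if (any(wa == 0) || any(wb == 0))
      stop("invalid interval: zero-length denominator")
    return(pmax(ov / wa, ov / wb))
  }
  if (any(den == 0)) stop("invalid interval: zero-length denominator")
  ov / den
}

#' TSS-anchored promoters
#'
#' The promoter of a gene is the `flank` bp on either side of its
#' transcription start site (the stranded 5' end: gene start on `+`,
#' gene end on `-`; for pri-miRNA loci the anchor is likewise the
#' stranded 5' end of the locus). Unstranded genes are treated as `+`
#' strand, with a message. Promoters running off the chromosome start
#' are clamped at position 1 and flagged `truncated`.
#'
#' @param genes stranded [GenomicRanges::GRanges] with a `gene_id`
#'   metadata column.
#' @param flank half-width in bp (default 2000, giving the +/-2-kb
#'   promoter definition).
#' @return `GRanges` of promoters carrying `gene_id`, `tss`, `flank` and
#'   `truncated` metadata columns; strand copied from the gene.
#' @export
buildPromoters <- function(genes, flank = 2000L) {
  flank <- as.integer(flank)
  if (any(strand(genes) == "*")) {
    message(sum(strand(genes) == "*"), " unstranded gene(s) treated as + strand")
    strand(genes)[strand(genes) == "*"] <- "+"
  }
  tss <- ifelse(as.character(strand(genes)) == "+", start(genes), end(genes))
  pr <- GenomicRanges::promoters(genes, upstream = flank, downstream = flank)
  truncated <- start(pr) < 1L
  newStart <- pmax(start(pr), 1L)
  out <- GRanges(seqnames(pr), IRanges(newStart, end(pr)), strand = strand(pr))
  mcols(out) <- DataFrame(gene_id = mcols(genes)$gene_id, tss = tss,
                          flank = flank, truncated = truncated)
  out
}

#' CpG-island shores
#'
#' The `shoreWidth` bp immediately flanking a CGI on either side, with no
#' gap. Laterality here is in genome coordinates (`leftShore` = lower
#' coordinates); 5'/3' orientation relative to a gene is applied
#' downstream using the gene's strand. Shores running off the chromosome
#' start are clamped and flagged.
#'
#' @param cgi unstranded [GenomicRanges::GRanges] of CGI bodies.
#' @param shoreWidth shore width in bp (default 2000).
#' @return list with elements `cgi`, `leftShore`, `rightShore`
#'   (parallel `GRanges`); left shores carry a `truncated` flag and both
#'   a `degenerate` flag when `shoreWidth` is 0.
#' @export
buildShores <- function(cgi, shoreWidth = 2000L) {
  shoreWidth <- as.integer(shoreWidth)
  degenerate <- shoreWidth == 0L
  leftStart <- start(cgi) - shoreWidth
  truncated <- leftStart < 1L
  left <- GRanges(seqnames(cgi),
                  IRanges(pmax(leftStart, 1L),
                          pmax(start(cgi) - 1L, pmax(leftStart, 1L) - 1L)))
  right <- GRanges(seqnames(cgi),
                   IRanges(end(cgi) + 1L, end(cgi) + shoreWidth))
  if (degenerate) {
    left <- GRanges(seqnames(cgi), IRanges(start(cgi), width = 0L))
    right <- GRanges(seqnames(cgi), IRanges(end(cgi) + 1L, width = 0L))
  }
  mcols(left)$truncated <- truncated
  mcols(left)$degenerate <- rep(degenerate, length(cgi))
  mcols(right)$degenerate <- rep(degenerate, length(cgi))
  list(cgi = cgi, leftShore = left, rightShore = right)
}

#' Classify ncRNAs by position relative to protein-coding gene bodies
#'
#' `intergenic`: no base-pair overlap with any coding gene body;
#' `intragenic`: fully contained in some coding gene body (the host is
#' the largest containing gene, ties broken by lexicographic `gene_id`);
#' `overlapping`: partial (>= 1 bp, not contained) overlap. Strand is
#' ignored throughout.
#'
#' @param ncrna [GenomicRanges::GRanges] of ncRNA loci with `gene_id`.
#' @param coding `GRanges` of protein-coding gene bodies with `gene_id`.
#' @return `ncrna` with `biotype` (factor) and `host_gene_id` (character,
#'   `NA` unless intragenic) metadata columns added.
#' @export
classifyBiotype <- function(ncrna, coding) {
  biotype <- rep("intergenic", length(ncrna))
  host <- rep(NA_character_, length(ncrna))
  if (length(coding) == 0L) {
    warning("empty coding-gene set: all ncRNAs classified intergenic")
  } else {
    anyHit <- countOverlaps(ncrna, coding, ignore.strand = TRUE) > 0L
    within <- findOverlaps(ncrna, coding, type = "within", ignore.strand = TRUE)
    isWithin <- logical(length(ncrna))
    if (length(within)) {
      qh <- queryHits(within); sh <- subjectHits(within)
      ord <- order(qh, -width(coding)[sh], mcols(coding)$gene_id[sh])
      keep <- !duplicated(qh[ord])
      isWithin[qh[ord][keep]] <- TRUE
      host[qh[ord][keep]] <- mcols(coding)$gene_id[sh[ord][keep]]
    }
    biotype[anyHit & !isWithin] <- "overlapping"
    biotype[isWithin] <- "intragenic"
  }
  mcols(ncrna)$biotype <- factor(biotype,
    levels = c("intergenic", "intragenic", "overlapping"))
  mcols(ncrna)$host_gene_id <- host
  ncrna
}
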