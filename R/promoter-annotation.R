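#' @importFrom IRanges IntegerList CharacterList
NULL

#' Map DMRs onto promoters: promoter-level differential calls
#'
#' A gene is called differentially methylated in a direction when at
#' least one DMR of that direction has at least `minDmrFraction` of its
#' own length inside the gene's promoter (the "at least 50\% of the DMR"
#' rule; the threshold is inclusive). A gene supported by DMRs of both
#' directions is reported twice and flagged ambiguous.
#'
#' @param dmrs DMR `GRanges` (from [mergeBinsToDmrs()]).
#' @param promoters promoter `GRanges` (from [buildPromoters()]).
#' @param minDmrFraction minimum fraction of the DMR inside the promoter
#'   (default 0.5).
#' @return [S4Vectors::DataFrame] with one row per (gene, direction):
#'   `gene_id`, `direction`, `dmrs` (IntegerList of supporting DMR
#'   indices into `dmrs`), `ambiguous`.
#' @export
mapDmrsToPromoters <- function(dmrs, promoters, minDmrFraction = 0.5) {
  empty <- DataFrame(gene_id = character(),
                     direction = factor(character(), c("hyper", "hypo")),
                     dmrs = IntegerList(), ambiguous = logical())
  if (length(dmrs) == 0L || length(promoters) == 0L) return(empty)
  hits <- findOverlaps(dmrs, promoters, ignore.strand = TRUE)
  if (!length(hits)) return(empty)
  qh <- queryHits(hits); sh <- subjectHits(hits)
  frac <- overlapLength(dmrs[qh], promoters[sh]) / width(dmrs)[qh]
  keep <- frac >= minDmrFraction
  qh <- qh[keep]; sh <- sh[keep]
  if (!length(qh)) return(empty)
  gene <- mcols(promoters)$gene_id[sh]
  dir <- as.character(mcols(dmrs)$direction)[qh]
  key <- paste(gene, dir, sep = "\r")
  rows <- !duplicated(key)
  supp <- split(qh, factor(key, levels = key[rows]))
  out <- DataFrame(gene_id = gene[rows],
                   direction = factor(dir[rows], c("hyper", "hypo")),
                   dmrs = IntegerList(supp))
  out$ambiguous <- out$gene_id %in% out$gene_id[duplicated(out$gene_id)]
  out[order(out$gene_id, out$direction), ]
}

#' Map DMRs onto CGI bodies and shores
#'
#' The promoter-mapping rule applied to CGI bodies and to each shore
#' independently: a region is called when >= `minDmrFraction` of some
#' DMR lies inside it. Shores are reported in genome-coordinate
#' laterality (`left_shore` / `right_shore`).
#'
#' @param dmrs DMR `GRanges`.
#' @param shores list from [buildShores()].
#' @param minDmrFraction minimum fraction of the DMR inside the region.
#' @return [S4Vectors::DataFrame] with `region_type`
#'   (`cgi`/`left_shore`/`right_shore`), `region_idx` (index into the
#'   corresponding `GRanges`), `direction` and `dmrs` (IntegerList).
#' @export
mapDmrsToCgis <- function(dmrs, shores, minDmrFraction = 0.5) {
  one <- function(regions, label) {
    empty <- DataFrame(region_type = character(), region_idx = integer(),
                       direction = factor(character(), c("hyper", "hypo")),
                       dmrs = IntegerList())
    if (length(dmrs) == 0L || length(regions) == 0L) return(empty)
    hits <- findOverlaps(dmrs, regions, ignore.strand = TRUE)
    if (!length(hits)) return(empty)
    qh <- queryHits(hits); sh <- subjectHits(hits)
    frac <- overlapLength(dmrs[qh], regions[sh]) / width(dmrs)[qh]
    keep <- frac >= minDmrFraction
    qh <- qh[keep]; sh <- sh[keep]
    if (!length(qh)) return(empty)
    dir <- as.character(mcols(dmrs)$direction)[qh]
    key <- paste(sh, dir, sep = "\r")
    rows <- !duplicated(key)
    DataFrame(region_type = rep(label, sum(rows)),
              region_idx = sh[rows],
              direction = factor(dir[rows], c("hyper", "hypo")),
              dmrs = IntegerList(split(qh, factor(key, levels = key[rows]))))
  }
  rbind(one(shores$cgi, "cgi"),
        one(shores$leftShore, "left_shore"),
        one(shores$rightShore, "right_shore"))
}

# Pattern of a single DMR within one promoter's CGI context.
# cgiIdx indexes promoter-overlapping CGIs; laterality is stranded.
.patternOfDmr <- function(dmr, prom, promCgis, shoreWidth) {
  if (length(promCgis) == 0L) return(5L)
  fracs <- overlapFraction(rep(dmr, length(promCgis)), promCgis,
                           denominator = "either_max")
  if (max(fracs) > 0.5) return(1L)
  ovs <- overlapLength(rep(dmr, length(promCgis)), promCgis)
  plus <- as.character(strand(prom)) != "-"
  if (all(ovs == 0)) {
    left <- end(dmr) < min(start(promCgis))
    right <- start(dmr) > max(end(promCgis))
    fivePrime <- if (plus) left else right
    threePrime <- if (plus) right else left
    tss <- mcols(prom)$tss
    d <- pmin(abs(start(promCgis) - tss), abs(end(promCgis) - tss))
    nearest <- promCgis[which.min(d)]
    sh <- buildShores(nearest, shoreWidth)
    fiveShore <- if (plus) sh$leftShore else sh$rightShore
    threeShore <- if (plus) sh$rightShore else sh$leftShore
    if (fivePrime && overlapLength(dmr, fiveShore) > 0) return(2L)
    if (threePrime && overlapLength(dmr, threeShore) > 0) return(3L)
    return(4L)
  }
  4L
}

#' Classify aberrantly methylated promoters into five CGI-context patterns
#'
#' For each promoter-level differential call, the supporting DMRs are
#' placed in the promoter's CGI context: (5) the promoter has no CGI;
#' (1) the DMR-CGI overlap exceeds 50\% of either region (CGI-confined);
#' (2) the DMR lies strictly 5' of every promoter CGI and touches the 5'
#' shore; (3) the mirror case on the 3' side; (4) everything else
#' (partial CGI overlap, or shore-adjacent placements that fit neither
#' strict case). 5'/3' laterality follows the gene's strand; for
#' multi-CGI promoters it is anchored on the CGI nearest the TSS. When
#' several supporting DMRs disagree, the DMR with the largest promoter
#' overlap decides; exact ties take the lowest pattern number and are
#' flagged.
#'
#' @param calls promoter-level calls from [mapDmrsToPromoters()].
#' @param promoters promoter `GRanges` with `gene_id`, `tss`, `flank`.
#' @param cgis unstranded CGI `GRanges`.
#' @param dmrs the DMR `GRanges` the calls refer to.
#' @param shoreWidth shore width in bp (default 2000).
#' @return `calls` with added columns `pattern` (integer 1..5),
#'   `patternName` and `tie` (logical).
#' @export
classifyPatterns <- function(calls, promoters, cgis, dmrs,
                             shoreWidth = 2000L) {
  patternNames <- c("cgi_confined", "five_prime_shore", "three_prime_shore",
                    "partial_overlap", "no_cgi")
  n <- nrow(calls)
  pattern <- integer(n); tie <- logical(n)
  pidx <- match(calls$gene_id, mcols(promoters)$gene_id)
  if (any(is.na(pidx))) stop("call for gene absent from promoter set")
  for (i in seq_len(n)) {
    prom <- promoters[pidx[i]]
    supp <- calls$dmrs[[i]]
    if (length(supp) == 0L)
      stop("internal consistency error: called gene with no supporting DMR")
    promCgis <- cgis[countOverlaps(cgis, prom, ignore.strand = TRUE) > 0L]
    pats <- vapply(supp, function(d)
      .patternOfDmr(dmrs[d], prom, promCgis, shoreWidth), integer(1))
    ovs <- overlapLength(dmrs[supp], rep(prom, length(supp)))
    best <- which(ovs == max(ovs))
    pattern[i] <- min(pats[best])
    tie[i] <- length(unique(pats[best])) > 1L
  }
  calls$pattern <- pattern
  calls$patternName <- factor(patternNames[pattern], levels = patternNames)
  calls$tie <- tie
  calls
}

#' TSS-centered aberrant-methylation frequency profile
#'
#' Divides each promoter into fixed windows (default 10 bp) in stranded
#' orientation (column 1 = most upstream of the TSS) and marks a window
#' 1 when it intersects at least one DMR of the requested direction.
#' Column means give the average aberrant-methylation frequency curve.
#'
#' @param promoters promoter `GRanges`, all with the same `flank`.
#' @param dmrs DMR `GRanges` with a `direction` column.
#' @param direction `"hyper"` or `"hypo"`.
#' @param window window width in bp; must divide `2 * flank`.
#' @return list with `profile` (binary matrix, promoters x windows;
#'   columns named by window-center offset from the TSS) and
#'   `frequency` (column means).
#' @export
tssProfile <- function(promoters, dmrs, direction = c("hyper", "hypo"),
                       window = 10L) {
  direction <- match.arg(direction)
  window <- as.integer(window)
  flank <- unique(mcols(promoters)$flank)
  if (length(flank) != 1L) stop("promoters must share one flank")
  if ((2L * flank) %% window != 0L) stop("window must divide 2*flank")
  ncolP <- (2L * flank) %/% window
  dmrsD <- dmrs[mcols(dmrs)$direction == direction]
  nP <- length(promoters)
  tss <- mcols(promoters)$tss
  plus <- as.character(strand(promoters)) != "-"
  j <- seq_len(ncolP)
  startsOf <- function(i) {
    if (plus[i]) tss[i] - flank + (j - 1L) * window
    else tss[i] + flank - j * window + 1L
  }
  starts <- unlist(lapply(seq_len(nP), startsOf))
  wins <- GRanges(rep(seqnames(promoters), each = ncolP),
                  IRanges(starts, width = window))
  hit <- IRanges::overlapsAny(wins, dmrsD, ignore.strand = TRUE)
  mat <- matrix(as.integer(hit), nrow = nP, ncol = ncolP, byrow = TRUE)
  rownames(mat) <- mcols(promoters)$gene_id
  colnames(mat) <- as.character(-flank + (j - 0.5) * window)
  list(profile = mat, frequency = colMeans(mat))
}

#' Concordance between intragenic ncRNAs and their host genes
#'
#' Classifies each (ncRNA, host) promoter pair by mutual overlap
#' (`either_max` fraction >= 0.5 versus < 0.5) and records whether both
#' members carry a differential call in the same direction. The summary
#' of interest is the concordance rate within the < 50\% class, where
#' shared promoter sequence cannot trivially explain agreement.
#'
#' @param ncrna ncRNA `GRanges` annotated by [classifyBiotype()].
#' @param calls promoter-level calls (ncRNA and coding genes together).
#' @param promoters promoter `GRanges` covering both ncRNAs and hosts.
#' @return [S4Vectors::DataFrame] of pairs with `overlapClass`
#'   (`ge50`/`lt50`) and `concordant`; the `metadata()` carries
#'   `concordanceLt50`.
#' @export
hostConcordance <- function(ncrna, calls, promoters) {
  intr <- ncrna[!is.na(mcols(ncrna)$host_gene_id)]
  dirOf <- function(g) as.character(calls$direction[calls$gene_id == g])
  pid <- mcols(promoters)$gene_id
  ncP <- match(mcols(intr)$gene_id, pid)
  hostP <- match(mcols(intr)$host_gene_id, pid)
  keep <- !is.na(ncP) & !is.na(hostP)
  intr <- intr[keep]; ncP <- ncP[keep]; hostP <- hostP[keep]
  frac <- if (length(intr)) overlapFraction(promoters[ncP], promoters[hostP],
                                            denominator = "either_max")
          else numeric(0)
  conc <- vapply(seq_along(intr), function(i) {
    a <- dirOf(mcols(intr)$gene_id[i]); b <- dirOf(mcols(intr)$host_gene_id[i])
    length(a) > 0 && length(b) > 0 && length(intersect(a, b)) > 0
  }, logical(1))
  out <- DataFrame(ncrna_id = mcols(intr)$gene_id,
                   host_id = mcols(intr)$host_gene_id,
                   overlapFraction = frac,
                   overlapClass = factor(ifelse(frac >= 0.5, "ge50", "lt50"),
                                         c("ge50", "lt50")),
                   concordant = conc)
  lt <- out$overlapClass == "lt50"
  metadata(out)$concordanceLt50 <- if (any(lt)) mean(out$concordant[lt]) else NA_real_
  out
}

#' Enrichment of differential calls in an annotated region set
#'
#' Two-sided Fisher's exact test on the 2x2 table of (gene called
#' differential) x (gene promoter overlaps the region set by >= 1 bp),
#' over a stated gene universe; odds ratio with Haldane correction when
#' a cell is zero.
#'
#' @param calledGenes character vector of called gene ids.
#' @param universe character vector of all eligible gene ids
#'   (superset of `calledGenes`).
#' @param regionSet `GRanges` of regions (e.g. polycomb-occupied or
#'   recurrently deleted regions).
#' @param promoters promoter `GRanges` covering the universe.
#' @return list with `oddsRatio`, `pValue`, `table`, and `degenerate`
#'   (TRUE when called set equals the universe).
#' @export
regionSetEnrichment <- function(calledGenes, universe, regionSet, promoters) {
  if (length(universe) == 0L) stop("empty universe")
  if (!all(calledGenes %in% universe))
    stop("calledGenes must be a subset of universe")
  degenerate <- setequal(calledGenes, universe)
  if (degenerate) warning("called set equals the universe; enrichment is degenerate")
  pidx <- match(universe, mcols(promoters)$gene_id)
  if (any(is.na(pidx))) stop("universe gene without promoter")
  inRegion <- countOverlaps(promoters[pidx], regionSet,
                            ignore.strand = TRUE) > 0L
  called <- universe %in% calledGenes
  tab <- table(called = factor(called, c(TRUE, FALSE)),
               inRegion = factor(inRegion, c(TRUE, FALSE)))
  res <- fisher2x2(unclass(tab))
  res$degenerate <- degenerate
  res
}
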