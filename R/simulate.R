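# Stranded promoter offsets (0-based, relative to the TSS) of the five
# spike geometries. Chosen so every pattern-defining overlap fraction
# clears its threshold with >= 10% margin (pattern 4: either_max 0.43
# vs the 0.5 cut) and every spike lies inside the +/-2-kb promoter.
.spikeOffsets <- list(
  `1` = c(200L, 1200L),    # the promoter CGI body
  `2` = c(-1000L, -200L),  # inside the 5' shore, clear of the CGI
  `3` = c(1300L, 1900L),   # inside the 3' shore, within the promoter
  `4` = c(-200L, 500L),    # straddles the CGI edge (300 bp overlap)
  `5` = c(-400L, 400L))    # TSS-centered, CGI-lacking promoter
.cgiOffset <- c(200L, 1200L)

# 0-based half-open stranded window around a TSS -> GRanges.
.strandedWindow <- function(chrom, tss0, strand, from, to) {
  s0 <- ifelse(strand == "-", tss0 - to, tss0 + from)
  e0 <- ifelse(strand == "-", tss0 - from, tss0 + to)
  GRanges(chrom, IRanges(s0 + 1L, e0))
}

#' Simulate a toy annotation: genes, CGIs, promoters
#'
#' Lays out non-overlapping protein-coding genes first on a fixed slot
#' grid, then places lncRNA and pri-miRNA loci to realize the requested
#' biotype mix (intergenic loci in their own slots, intragenic loci
#' inside a coding gene body, overlapping loci straddling a coding gene
#' boundary). A seeded fraction of promoters receives a CpG island at
#' stranded offset +200..+1200 bp from the TSS, so that each of the
#' five aberrant-methylation patterns is constructible. Deterministic
#' given `config@seed`.
#'
#' @param config a [SimulationConfig-class].
#' @return list with `genes` (GRanges; `gene_id`, `gene_class`,
#'   `biotype_truth`, `host_gene_id`, `hasCgi`), `cgis`, `promoters`,
#'   `shores` and `chromLengths`.
#' @export
simulateAnnotation <- function(config) {
  validObject(config)
  if (config@cgiPromoterFraction == 0 && any(config@spikes$pattern < 5L))
    stop("config conflict: patterns 1-4 need CGI promoters but ",
         "cgiPromoterFraction is 0")
  set.seed(config@seed)
  slotWidth <- 12000L
  chroms <- paste0("chr", seq_len(config@nChrom))
  chromLengths <- stats::setNames(rep(config@chromLength, config@nChrom),
                                  chroms)
  nSlot <- config@chromLength %/% slotWidth
  slots <- data.frame(chrom = rep(chroms, each = nSlot),
                      start0 = rep((seq_len(nSlot) - 1L) * slotWidth,
                                   config@nChrom))
  nNc <- config@nLncRNA + config@nMiRNA
  if (config@nCoding == 0L) {
    nIntra <- 0L; nOver <- 0L
  } else {
    nIntra <- round(config@biotypeMix[2] * nNc)
    nOver <- round(config@biotypeMix[3] * nNc)
  }
  nInter <- nNc - nIntra - nOver
  if (nIntra + nOver > config@nCoding)
    stop("capacity error: not enough coding genes to host ", nIntra + nOver,
         " intragenic/overlapping ncRNAs")
  if (config@nCoding + nInter > nrow(slots))
    stop("capacity error: genome too small for ",
         config@nCoding + nInter, " gene slots")
  ord <- sample(nrow(slots))
  codingSlots <- slots[ord[seq_len(config@nCoding)], , drop = FALSE]
  interSlots <- slots[ord[config@nCoding + seq_len(nInter)], , drop = FALSE]

  mkGene <- function(slotDf, bodyOffset, len, ids, class) {
    if (!nrow(slotDf)) {
      g <- GRanges()
      mcols(g) <- DataFrame(gene_id = character(), gene_class = character())
      return(g)
    }
    st <- sample(c("+", "-"), nrow(slotDf), replace = TRUE)
    g <- GRanges(slotDf$chrom,
                 IRanges(slotDf$start0 + bodyOffset + 1L,
                         slotDf$start0 + bodyOffset + len), strand = st)
    mcols(g) <- DataFrame(gene_id = ids, gene_class = class)
    g
  }
  coding <- mkGene(codingSlots, 4000L, 6000L,
                   sprintf("pc%04d", seq_len(config@nCoding)), "coding")

  ncClass <- rep(c("lncRNA", "miRNA"), c(config@nLncRNA, config@nMiRNA))
  ncIds <- ifelse(ncClass == "lncRNA",
                  sprintf("lnc%04d", cumsum(ncClass == "lncRNA")),
                  sprintf("mir%04d", cumsum(ncClass == "miRNA")))
  roles <- rep(c("intergenic", "intragenic", "overlapping"),
               c(nInter, nIntra, nOver))[sample(nNc)]
  ncLen <- ifelse(ncClass == "lncRNA", 2000L, 600L)

  interIdx <- which(roles == "intergenic")
  intraIdx <- which(roles == "intragenic")
  overIdx <- which(roles == "overlapping")
  hostIdx <- sample(config@nCoding)  # distinct host per hosted ncRNA
  ncChrom <- character(nNc); ncStart0 <- integer(nNc)
  host <- rep(NA_character_, nNc)
  for (k in seq_along(interIdx)) {
    i <- interIdx[k]
    ncChrom[i] <- interSlots$chrom[k]
    ncStart0[i] <- interSlots$start0[k] + 4000L
  }
  hosted <- c(intraIdx, overIdx)
  for (k in seq_along(hosted)) {
    i <- hosted[[k]]
    h <- coding[hostIdx[k]]
    ncChrom[i] <- as.character(seqnames(h))
    if (roles[i] == "intragenic") {
      ncStart0[i] <- start(h) - 1L + 2500L
      host[i] <- mcols(h)$gene_id
    } else {
      ncStart0[i] <- start(h) - 1L - 500L
    }
  }
  ncrna <- GRanges(ncChrom, IRanges(ncStart0 + 1L, ncStart0 + ncLen),
                   strand = sample(c("+", "-"), nNc, replace = TRUE))
  mcols(ncrna) <- DataFrame(gene_id = ncIds, gene_class = ncClass)
  mcols(coding)$biotype_truth <- rep(NA_character_, length(coding))
  mcols(coding)$host_gene_id <- rep(NA_character_, length(coding))
  mcols(ncrna)$biotype_truth <- roles
  mcols(ncrna)$host_gene_id <- host
  genes <- c(coding, ncrna)

  nCgi <- round(config@cgiPromoterFraction * length(genes))
  cgiGenes <- sort(sample(length(genes), nCgi))
  mcols(genes)$hasCgi <- seq_along(genes) %in% cgiGenes
  tss0 <- ifelse(as.character(strand(genes)) == "-",
                 end(genes), start(genes) - 1L)
  cgis <- .strandedWindow(as.character(seqnames(genes))[cgiGenes],
                          tss0[cgiGenes],
                          as.character(strand(genes))[cgiGenes],
                          .cgiOffset[1], .cgiOffset[2])
  strand(cgis) <- "*"
  mcols(cgis)$region_id <- sprintf("cgi_%s", mcols(genes)$gene_id[cgiGenes])
  promoters <- buildPromoters(genes, 2000L)
  list(genes = genes, cgis = cgis, promoters = promoters,
       shores = buildShores(cgis, 2000L), chromLengths = chromLengths)
}

# Resolve spike targets against an annotation: deterministic assignment
# of spikes to compatible intergenic ncRNAs (CGI promoters for patterns
# 1-4, CGI-lacking for pattern 5).
.resolveSpikes <- function(annotation, config) {
  spikes <- config@spikes
  if (!nrow(spikes)) {
    return(DataFrame(gene_id = character(), pattern = integer(),
                     direction = character(), foldChange = numeric(),
                     coupling = character()))
  }
  g <- annotation$genes
  nc <- g[!is.na(mcols(g)$biotype_truth) &
            mcols(g)$biotype_truth == "intergenic"]
  nc <- nc[order(mcols(nc)$gene_id)]
  withCgi <- mcols(nc)$gene_id[mcols(nc)$hasCgi]
  noCgi <- mcols(nc)$gene_id[!mcols(nc)$hasCgi]
  needCgi <- sum(spikes$pattern < 5L)
  needNone <- sum(spikes$pattern == 5L)
  if (needCgi > length(withCgi) || needNone > length(noCgi))
    stop("config conflict: not enough compatible intergenic ncRNA ",
         "promoters for the requested spike patterns")
  target <- character(nrow(spikes))
  target[spikes$pattern < 5L] <- withCgi[seq_len(needCgi)]
  target[spikes$pattern == 5L] <- noCgi[seq_len(needNone)]
  DataFrame(gene_id = target, pattern = as.integer(spikes$pattern),
            direction = spikes$direction, foldChange = spikes$foldChange,
            coupling = spikes$coupling)
}

#' Simulate a cohort methylome with spiked ground-truth DMRs
#'
#' Bin read counts are negative-binomial (mean m, size = dispersion,
#' variance m + m^2/dispersion) with per-sample library-size factors
#' drawn log-uniformly from `config@libSizeRange`. The mean is
#' `baselineMean`, elevated `cgiEnrichment`-fold on CGI bins in both
#' groups. Each spike multiplies (hyper) or divides (hypo) the tumor
#' group mean by its fold change over the bin-aligned promoter region
#' its pattern dictates.
#'
#' @param annotation output of [simulateAnnotation()].
#' @param config the same [SimulationConfig-class].
#' @return list with `bm` (a raw-count [BinMethylome-class]) and
#'   `truth`, itself a list: `spikes` (GRanges with `gene_id`,
#'   `pattern`, `direction`, `foldChange`, `coupling`), `silencing` and
#'   `activating` gene-id vectors.
#' @export
simulateMethylome <- function(annotation, config) {
  set.seed(config@seed + 1L)
  spk <- .resolveSpikes(annotation, config)
  g <- annotation$genes
  gi <- match(spk$gene_id, mcols(g)$gene_id)
  tss0 <- ifelse(as.character(strand(g)) == "-", end(g), start(g) - 1L)[gi]
  spikeGr <- GRanges()
  if (nrow(spk)) {
    offs <- do.call(rbind, .spikeOffsets[as.character(spk$pattern)])
    spikeGr <- .strandedWindow(as.character(seqnames(g))[gi], tss0,
                               as.character(strand(g))[gi],
                               offs[, 1], offs[, 2])
    mcols(spikeGr) <- spk
    promIdx <- match(spk$gene_id, mcols(annotation$promoters)$gene_id)
    inProm <- overlapLength(spikeGr, annotation$promoters[promIdx]) ==
      width(spikeGr)
    if (!all(inProm))
      stop("manifest consistency error: spike region outside its promoter")
  }
  bins <- binGrid(annotation$chromLengths, config@binWidth)
  mu <- rep(config@baselineMean, length(bins))
  onCgi <- IRanges::overlapsAny(bins, annotation$cgis, ignore.strand = TRUE)
  mu[onCgi] <- mu[onCgi] * config@cgiEnrichment
  muT <- mu
  if (length(spikeGr)) {
    hits <- findOverlaps(bins, spikeGr, ignore.strand = TRUE)
    qh <- queryHits(hits); sh <- subjectHits(hits)
    fac <- ifelse(spk$direction[sh] == "hyper",
                  spk$foldChange[sh], 1 / spk$foldChange[sh])
    muT[qh] <- muT[qh] * fac
  }
  n <- config@nTumor + config@nNormal
  groups <- rep(c("tumor", "normal"), c(config@nTumor, config@nNormal))
  sf <- exp(stats::runif(n, log(config@libSizeRange[1]),
                         log(config@libSizeRange[2])))
  counts <- vapply(seq_len(n), function(j) {
    m <- if (groups[j] == "tumor") muT else mu
    stats::rnbinom(length(bins), mu = m * sf[j], size = config@dispersion)
  }, numeric(length(bins)))
  ids <- c(sprintf("tumor%02d", seq_len(config@nTumor)),
           sprintf("normal%02d", seq_len(config@nNormal)))
  bm <- BinMethylome(counts, bins, groups, config@binWidth, sampleIds = ids)
  truth <- list(spikes = spikeGr,
                silencing = spk$gene_id[spk$coupling == "silencing"],
                activating = spk$gene_id[spk$coupling == "activating"])
  list(bm = bm, truth = truth)
}

#' Simulate expression tables coupled to the spiked methylation truth
#'
#' lncRNA FPKM: one control cell line and two tumor lines; genes flagged
#' `silencing` have tumor expression divided by `foldExpr`, `activating`
#' genes multiplied by it, all others centred on the control value, with
#' log-normal noise of sd `exprNoiseSdLog2` (log2 scale) per tumor line.
#' miRNA RPM: a cohort matrix (`nTumor` + `nNormal` columns) with the
#' same group-mean coupling plus per-sample noise, so a t-test is
#' meaningful.
#'
#' @param annotation output of [simulateAnnotation()].
#' @param truth the truth manifest from [simulateMethylome()].
#' @param config the same [SimulationConfig-class].
#' @return list with `lncFpkm` (matrix, columns `control`, `tumor1`,
#'   `tumor2`), `mirRpm` (matrix, cohort columns) and `mirGroups`.
#' @export
simulateExpression <- function(annotation, truth, config) {
  set.seed(config@seed + 2L)
  g <- annotation$genes
  effectOf <- function(ids) {
    eff <- rep(1, length(ids))
    eff[ids %in% truth$silencing] <- 1 / config@foldExpr
    eff[ids %in% truth$activating] <- config@foldExpr
    eff
  }
  noise <- function(n) exp(log(2) * config@exprNoiseSdLog2 * stats::rnorm(n))
  lncIds <- mcols(g)$gene_id[mcols(g)$gene_class == "lncRNA"]
  ctrl <- stats::rlnorm(length(lncIds), log(10), 0.5)
  eff <- effectOf(lncIds)
  lnc <- cbind(control = ctrl,
               tumor1 = ctrl * eff * noise(length(lncIds)),
               tumor2 = ctrl * eff * noise(length(lncIds)))
  rownames(lnc) <- lncIds
  mirIds <- mcols(g)$gene_id[mcols(g)$gene_class == "miRNA"]
  nT <- config@nTumor; nN <- config@nNormal
  groups <- factor(rep(c("tumor", "normal"), c(nT, nN)),
                   c("tumor", "normal"))
  base <- log2(stats::rlnorm(length(mirIds), log(50), 0.5))
  effLog2 <- log2(effectOf(mirIds))
  lm <- outer(base, rep(1, nT + nN)) +
    outer(effLog2, as.numeric(groups == "tumor")) +
    matrix(stats::rnorm(length(mirIds) * (nT + nN),
                        sd = config@exprNoiseSdLog2),
           nrow = length(mirIds))
  mir <- 2^lm
  rownames(mir) <- mirIds
  colnames(mir) <- c(sprintf("tumor%02d", seq_len(nT)),
                     sprintf("normal%02d", seq_len(nN)))
  list(lncFpkm = lnc, mirRpm = mir, mirGroups = groups)
}

#' Simulate histone-mark density tracks
#'
#' Two marks (H3K4me3, active; H3K27me3, repressive) for one control
#' and two tumor cell lines on the methylation bin grid. Promoters of
#' silencing-coupled (hypermethylated) genes get H3K4me3 reduced and
#' H3K27me3 elevated `markFold`-fold in the tumor lines; activating
#' promoters the inverse. Deterministic by seed.
#'
#' @param annotation output of [simulateAnnotation()].
#' @param truth truth manifest from [simulateMethylome()].
#' @param config the same [SimulationConfig-class].
#' @param markFold tumor/control density fold applied at coupled
#'   promoters (default 3).
#' @param noiseSdLog log-normal bin noise sd (default 0.1).
#' @return [SummarizedExperiment::SummarizedExperiment] on the bin grid
#'   with `colData` columns `mark`, `cellLine`, `group`.
#' @export
simulateHistoneTracks <- function(annotation, truth, config,
                                  markFold = 3, noiseSdLog = 0.1) {
  set.seed(config@seed + 3L)
  bins <- binGrid(annotation$chromLengths, config@binWidth)
  prom <- annotation$promoters
  silBins <- IRanges::overlapsAny(
    bins, prom[mcols(prom)$gene_id %in% truth$silencing])
  actBins <- IRanges::overlapsAny(
    bins, prom[mcols(prom)$gene_id %in% truth$activating])
  cd <- expand.grid(cellLine = c("control", "tumorA", "tumorB"),
                    mark = c("H3K4me3", "H3K27me3"),
                    stringsAsFactors = FALSE)
  cd$group <- ifelse(cd$cellLine == "control", "normal", "tumor")
  base <- 10
  dens <- vapply(seq_len(nrow(cd)), function(j) {
    m <- rep(base, length(bins))
    if (cd$group[j] == "tumor") {
      up <- if (cd$mark[j] == "H3K4me3") actBins else silBins
      dn <- if (cd$mark[j] == "H3K4me3") silBins else actBins
      m[up] <- m[up] * markFold
      m[dn] <- m[dn] / markFold
    }
    m * exp(stats::rnorm(length(bins), sd = noiseSdLog))
  }, numeric(length(bins)))
  colnames(dens) <- paste(cd$mark, cd$cellLine, sep = ".")
  SummarizedExperiment(assays = list(density = dens), rowRanges = bins,
                       colData = DataFrame(cd, row.names = colnames(dens)))
}

#' Mean promoter methylation per sample
#'
#' Per-promoter average of the (normalized) bin intensities over the
#' bins overlapping each promoter, one column per sample: the
#' feature-by-sample matrix used for methylation-based biomarker panels.
#'
#' @param bm a [BinMethylome-class] (normalized for comparability).
#' @param promoters promoter `GRanges` with `gene_id`.
#' @return numeric matrix, promoters x samples, rownames = gene ids.
#' @export
promoterMethylation <- function(bm, promoters) {
  hits <- findOverlaps(promoters, rowRanges(bm), ignore.strand = TRUE)
  a <- assay(bm, "counts")
  out <- matrix(0, length(promoters), ncol(bm),
                dimnames = list(mcols(promoters)$gene_id, colnames(bm)))
  if (length(hits)) {
    s <- rowsum(a[subjectHits(hits), , drop = FALSE], queryHits(hits))
    nb <- tabulate(queryHits(hits), length(promoters))
    idx <- as.integer(rownames(s))
    out[idx, ] <- s / nb[idx]
  }
  out
}
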