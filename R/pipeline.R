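#' Write a gene annotation as BED12+1
#'
#' Single-block BED12 rows with the gene class in a 13th column; the
#' format [readAnnotation()] reads back.
#'
#' @param genes `GRanges` with `gene_id` and `gene_class`.
#' @param path output file.
#' @export
writeAnnotationBed <- function(genes, path) {
  df <- data.frame(chrom = as.character(seqnames(genes)),
                   start = start(genes) - 1L, end = end(genes),
                   name = mcols(genes)$gene_id, score = 0L,
                   strand = as.character(strand(genes)),
                   thickStart = start(genes) - 1L, thickEnd = end(genes),
                   rgb = "0", blockCount = 1L, blockSizes = width(genes),
                   blockStarts = 0L,
                   gene_class = mcols(genes)$gene_class)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a region set as BED4
#'
#' @param regions `GRanges`, optionally with `region_id`.
#' @param path output file.
#' @export
writeRegionsBed <- function(regions, path) {
  nm <- mcols(regions)$region_id
  if (is.null(nm)) nm <- sprintf("region_%d", seq_along(regions))
  df <- data.frame(chrom = as.character(seqnames(regions)),
                   start = start(regions) - 1L, end = end(regions),
                   name = nm)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Write an expression matrix as the TSV layout readExpressionTable expects.
writeExpressionTable <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic-study pipeline, file formats included
#'
#' Generates a synthetic study from `config`, writes every input to
#' `outdir` in its on-disk format (bedGraph methylomes, BED annotation
#' and CGIs, TSV expression and manifest), reads everything back
#' through the package readers, then runs DMR calling, promoter mapping
#' and pattern classification, TSS profiling, expression integration
#' and biomarker-panel evaluation, writing each result as TSV/BED.
#' All outputs are deterministic functions of `config` (byte-identical
#' across runs with the same seed).
#'
#' @param config a [SimulationConfig-class].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the in-memory results: `annotation`,
#'   `truth`, `binStats`, `dmrs`, `calls`, `patterns`, `profiles`,
#'   `candidates`, `panels`.
#' @export
runPipeline <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)

  ann <- simulateAnnotation(config)
  sim <- simulateMethylome(ann, config)
  expr <- simulateExpression(ann, sim$truth, config)

  writeAnnotationBed(ann$genes, p("genes.bed"))
  writeRegionsBed(ann$cgis, p("cgi.bed"))
  writeExpressionTable(expr$lncFpkm, p("lncrna_fpkm.tsv"))
  writeExpressionTable(expr$mirRpm, p("mirna_rpm.tsv"))
  spikes <- sim$truth$spikes
  utils::write.table(
    data.frame(gene_id = mcols(spikes)$gene_id,
               chrom = as.character(seqnames(spikes)),
               start = start(spikes) - 1L, end = end(spikes),
               direction = mcols(spikes)$direction,
               pattern = mcols(spikes)$pattern,
               coupling = mcols(spikes)$coupling),
    p("truth_manifest.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  dir.create(p("tracks"), showWarnings = FALSE)
  a <- assay(sim$bm, "counts")
  chromLengths <- ann$chromLengths
  binsPer <- ceiling(chromLengths / config@binWidth)
  splitIdx <- rep(seq_along(binsPer), binsPer)
  # paths in the manifest are relative to outdir so that output trees
  # are portable (and byte-identical across runs in different locations)
  manifest <- data.frame(sample_id = colnames(sim$bm),
                         group = as.character(sampleGroups(sim$bm)),
                         path = file.path("tracks",
                                          paste0(colnames(sim$bm),
                                                 ".bedGraph")))
  for (j in seq_len(ncol(a)))
    writeBinTrack(split(a[, j], splitIdx) |>
                    stats::setNames(names(chromLengths)),
                  p(manifest$path[j]), config@binWidth)
  utils::write.table(manifest, p("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  genes <- readAnnotation(p("genes.bed"), "bed12")
  cgis <- readRegionsBed(p("cgi.bed"))
  mf <- utils::read.table(p("manifest.tsv"), header = TRUE, sep = "\t")
  mf$path <- p(mf$path)
  bm <- readBinTracks(mf, config@binWidth, chromLengths)
  lncFpkm <- readExpressionTable(p("lncrna_fpkm.tsv"), "fpkm_cell_lines")
  mirRpm <- readExpressionTable(p("mirna_rpm.tsv"), "rpm_cohort")

  res <- callDmrs(bm)
  writeDmrBed(res$dmrs, p("dmrs.bed"))
  promoters <- buildPromoters(genes, 2000L)
  calls <- mapDmrsToPromoters(res$dmrs, promoters)
  patterns <- classifyPatterns(calls, promoters, cgis, res$dmrs)
  utils::write.table(
    data.frame(gene_id = patterns$gene_id,
               direction = as.character(patterns$direction),
               pattern = patterns$pattern,
               patternName = as.character(patterns$patternName),
               n_dmrs = lengths(patterns$dmrs),
               ambiguous = patterns$ambiguous),
    p("pattern_calls.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  profiles <- lapply(c(hyper = "hyper", hypo = "hypo"), function(d)
    tssProfile(promoters, res$dmrs, d))
  for (d in names(profiles))
    utils::write.table(
      data.frame(gene_id = rownames(profiles[[d]]$profile),
                 profiles[[d]]$profile, check.names = FALSE),
      p(sprintf("tss_profile_%s.tsv", d)), sep = "\t", quote = FALSE,
      row.names = FALSE)

  lncChange <- lncrnaExpressionChange(lncFpkm, c("tumor1", "tumor2"),
                                      "control")
  mirDe <- mirnaDifferentialExpression(mirRpm, expr$mirGroups)
  mirChange <- DataFrame(gene_id = mirDe$gene_id,
                         label = ifelse(mirDe$significant,
                                        as.character(mirDe$direction),
                                        "none"))
  exprChanges <- rbind(as.data.frame(lncChange[c("gene_id", "label")]),
                       as.data.frame(mirChange))
  candidates <- callCandidates(calls, DataFrame(exprChanges))
  utils::write.table(as.data.frame(candidates), p("candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  normBm <- normalizeLinear(bm)
  meth <- promoterMethylation(normBm, promoters)
  panels <- list()
  for (d in c("hyper", "hypo")) {
    featureGenes <- patterns$gene_id[patterns$direction == d]
    if (length(featureGenes) >= 1L) {
      pm <- meth[featureGenes, , drop = FALSE]
      panels[[d]] <- evaluatePanel(pm, rep(d, nrow(pm)), sampleGroups(bm))
    }
  }
  aucs <- data.frame(panel = names(panels),
                     n_features = vapply(names(panels), function(d)
                       sum(patterns$direction == d), integer(1)),
                     auc = vapply(panels, `[[`, numeric(1), "auc"))
  utils::write.table(aucs, p("panel_auc.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  invisible(list(annotation = ann, truth = sim$truth,
                 binStats = res$binStats, dmrs = res$dmrs, calls = calls,
                 patterns = patterns, profiles = profiles,
                 candidates = candidates, panels = panels))
}
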