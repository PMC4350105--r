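test_that("simulateAnnotation realizes gene counts, biotype mix and CGIs", {
  cfg <- smallConfig(seed = 3L)
  ann <- simulateAnnotation(cfg)
  g <- ann$genes
  expect_equal(sum(mcols(g)$gene_class == "coding"), 12)
  expect_equal(sum(mcols(g)$gene_class == "lncRNA"), 20)
  expect_equal(sum(mcols(g)$gene_class == "miRNA"), 8)
  # coding genes do not overlap each other
  coding <- g[mcols(g)$gene_class == "coding"]
  expect_equal(sum(countOverlaps(coding, coding)), length(coding))
  # CGI fraction over all promoters
  expect_equal(length(ann$cgis), round(0.7 * length(g)))
  # each CGI lies inside its promoter
  expect_true(all(countOverlaps(ann$cgis, ann$promoters) >= 1))
})

test_that("designed biotypes agree with classifyBiotype (oracle cross-check)", {
  cfg <- smallConfig(seed = 7L)
  ann <- simulateAnnotation(cfg)
  g <- ann$genes
  nc <- g[mcols(g)$gene_class != "coding"]
  coding <- g[mcols(g)$gene_class == "coding"]
  out <- classifyBiotype(nc, coding)
  expect_equal(as.character(mcols(out)$biotype), mcols(nc)$biotype_truth)
  intr <- mcols(out)$biotype == "intragenic"
  expect_equal(mcols(out)$host_gene_id[intr], mcols(nc)$host_gene_id[intr])
})

test_that("annotation and methylome are deterministic given the seed", {
  a1 <- simulateAnnotation(smallConfig(seed = 11L))
  a2 <- simulateAnnotation(smallConfig(seed = 11L))
  expect_identical(a1$genes, a2$genes)
  expect_identical(a1$cgis, a2$cgis)
  m1 <- simulateMethylome(a1, smallConfig(seed = 11L))
  m2 <- simulateMethylome(a2, smallConfig(seed = 11L))
  expect_identical(SummarizedExperiment::assay(m1$bm),
                   SummarizedExperiment::assay(m2$bm))
  e1 <- simulateExpression(a1, m1$truth, smallConfig(seed = 11L))
  e2 <- simulateExpression(a2, m2$truth, smallConfig(seed = 11L))
  expect_identical(e1$lncFpkm, e2$lncFpkm)
  expect_identical(e1$mirRpm, e2$mirRpm)
  a3 <- simulateAnnotation(smallConfig(seed = 12L))
  expect_false(identical(start(a1$genes), start(a3$genes)))
})

test_that("config conflicts and capacity limits error out", {
  expect_error(simulateAnnotation(smallConfig(cgiPromoterFraction = 0)),
               "config conflict")
  # pattern-5-only spikes are fine without CGIs
  sp5 <- data.frame(pattern = 5L, direction = "hyper", foldChange = 4,
                    coupling = "none")
  ann0 <- simulateAnnotation(smallConfig(cgiPromoterFraction = 0,
                                         spikes = sp5))
  expect_equal(length(ann0$cgis), 0)
  expect_error(simulateAnnotation(simConfig(nChrom = 1L, chromLength = 1e5,
                                            seed = 1L)),
               "capacity")
  expect_error(simConfig(nTumor = 1L), "2 samples")
  expect_error(simConfig(spikes = data.frame(pattern = 1L,
                                             direction = "hyper",
                                             foldChange = 0.5,
                                             coupling = "none")),
               "foldChange")
  # nCoding = 0 forces an all-intergenic truth
  annI <- simulateAnnotation(smallConfig(nCoding = 0L, spikes = sp5,
                                         cgiPromoterFraction = 0))
  expect_true(all(mcols(annI$genes)$biotype_truth == "intergenic"))
})

test_that("every spike lies in its promoter and labels match the classifier", {
  cfg <- smallConfig(seed = 2L)
  ann <- simulateAnnotation(cfg)
  sim <- simulateMethylome(ann, cfg)
  sp <- sim$truth$spikes
  expect_equal(length(sp), nrow(cfg@spikes))
  pidx <- match(mcols(sp)$gene_id, mcols(ann$promoters)$gene_id)
  expect_true(all(overlapLength(sp, ann$promoters[pidx]) == width(sp)))
  # noiseless classification (spikes as DMRs) reproduces manifest labels
  dmrs <- granges(sp)
  mcols(dmrs)$direction <- factor(mcols(sp)$direction, c("hyper", "hypo"))
  calls <- mapDmrsToPromoters(dmrs, ann$promoters)
  pat <- classifyPatterns(calls, ann$promoters, ann$cgis, dmrs)
  got <- setNames(pat$pattern, pat$gene_id)
  want <- setNames(mcols(sp)$pattern, mcols(sp)$gene_id)
  expect_equal(got[names(want)], want)
})

test_that("spiked bins shift the tumor/normal mean ratio as designed", {
  cfg <- smallConfig(seed = 8L, nTumor = 10L, nNormal = 10L)
  ann <- simulateAnnotation(cfg)
  sim <- simulateMethylome(ann, cfg)
  sp <- sim$truth$spikes
  a <- SummarizedExperiment::assay(normalizeLinear(sim$bm))
  grp <- sampleGroups(sim$bm)
  hyperBins <- IRanges::overlapsAny(rowRanges(sim$bm),
                                    sp[mcols(sp)$direction == "hyper"])
  ratio <- mean(a[hyperBins, grp == "tumor"]) /
           mean(a[hyperBins, grp == "normal"])
  expect_true(ratio >= 3 && ratio <= 5)   # sampling band around fold 4
  farBins <- !IRanges::overlapsAny(
    rowRanges(sim$bm), sp, maxgap = 1000)
  ratio0 <- mean(a[farBins, grp == "tumor"]) /
            mean(a[farBins, grp == "normal"])
  expect_equal(ratio0, 1, tolerance = 0.05)
})

test_that("unit library-size factors give equal expected column totals", {
  cfg <- smallConfig(seed = 9L, libSizeRange = c(1, 1))
  ann <- simulateAnnotation(cfg)
  sim <- simulateMethylome(ann, cfg)
  tot <- colSums(SummarizedExperiment::assay(sim$bm))
  normals <- tot[sampleGroups(sim$bm) == "normal"]
  expect_true(all(abs(normals / mean(normals) - 1) < 0.05))
})

test_that("expression coupling follows the truth manifest", {
  cfg <- smallConfig(seed = 4L)
  ann <- simulateAnnotation(cfg)
  sim <- simulateMethylome(ann, cfg)
  expr <- simulateExpression(ann, sim$truth, cfg)
  sil <- intersect(sim$truth$silencing, rownames(expr$lncFpkm))
  if (length(sil)) {
    r <- expr$lncFpkm[sil, "tumor1"] / expr$lncFpkm[sil, "control"]
    expect_true(all(r > 1 / 5 / 2 & r < 1 / 2))  # around 1/4 with noise
  }
  act <- intersect(sim$truth$activating, rownames(expr$mirRpm))
  if (length(act)) {
    grp <- expr$mirGroups
    lr <- log2(rowMeans(expr$mirRpm[act, grp == "tumor", drop = FALSE]) /
               rowMeans(expr$mirRpm[act, grp == "normal", drop = FALSE]))
    expect_true(all(abs(lr - 2) < 1))   # fold 4 on the log2 scale
  }
  none <- setdiff(rownames(expr$lncFpkm),
                  c(sim$truth$silencing, sim$truth$activating))
  rn <- expr$lncFpkm[none, "tumor1"] / expr$lncFpkm[none, "control"]
  expect_true(all(rn > 1 / 2 & rn < 2))
})

test_that("histone tracks couple to methylation truth and share the grid", {
  cfg <- smallConfig(seed = 6L)
  ann <- simulateAnnotation(cfg)
  sim <- simulateMethylome(ann, cfg)
  se <- simulateHistoneTracks(ann, sim$truth, cfg, markFold = 3,
                              noiseSdLog = 0)
  expect_equal(granges(rowRanges(se)),
               granges(rowRanges(sim$bm)))
  prom <- ann$promoters
  silProm <- prom[mcols(prom)$gene_id %in% sim$truth$silencing]
  d <- SummarizedExperiment::assay(se)
  cd <- SummarizedExperiment::colData(se)
  k4t <- d[, cd$mark == "H3K4me3" & cd$group == "tumor"][, 1]
  k4c <- d[, cd$mark == "H3K4me3" & cd$group == "normal"]
  actProm <- prom[mcols(prom)$gene_id %in% sim$truth$activating]
  silBins <- IRanges::overlapsAny(rowRanges(se), silProm)
  actBins <- IRanges::overlapsAny(rowRanges(se), actProm)
  expect_equal(mean(k4t[silBins] / k4c[silBins]), 1 / 3, tolerance = 1e-9)
  expect_equal(mean(k4t[!silBins & !actBins] / k4c[!silBins & !actBins]), 1,
               tolerance = 1e-9)
  # uncoupled run: no spikes -> ratio 1 everywhere
  cfg0 <- smallConfig(seed = 6L, spikes = defaultSpikes()[0, ])
  ann0 <- simulateAnnotation(cfg0)
  sim0 <- simulateMethylome(ann0, cfg0)
  se0 <- simulateHistoneTracks(ann0, sim0$truth, cfg0, noiseSdLog = 0)
  d0 <- SummarizedExperiment::assay(se0)
  expect_equal(max(abs(d0[, 2] / d0[, 1] - 1)), 0, tolerance = 1e-9)
})
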