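# One promoter fixture: + strand gene, TSS at 0-based 10000, promoter
# [8000, 12000); CGI inside at [10200, 11200).
promFixture <- function(strand = "+", withCgi = TRUE, tss0 = 10000) {
  g <- geneGR("chr1", if (strand == "+") tss0 else tss0 - 2000,
              if (strand == "+") tss0 + 2000 else tss0, strand, "gene1")
  prom <- buildPromoters(g, 2000)
  cgi <- if (withCgi) {
    if (strand == "+") gr0("chr1", tss0 + 200, tss0 + 1200)
    else gr0("chr1", tss0 - 1200, tss0 - 200)
  } else gr0("chr1", 1, 1)[0]
  list(genes = g, prom = prom, cgi = cgi)
}

test_that("mapDmrsToPromoters applies the inclusive >=50%-of-DMR rule", {
  prom <- buildPromoters(geneGR("chr1", 2100, 6000, "+", "gA"), 2000)
  # promoter 0-based [100, 4100)
  exactly <- dmrGR("chr1", 0, 200, "hyper")     # 100/200 = 0.5 -> called
  more <- dmrGR("chr1", 0, 400, "hypo")         # 300/400 = 0.75 -> called
  outside <- dmrGR("chr1", 5000, 5400, "hyper") # no overlap
  below <- dmrGR("chr1", 0, 500, "hyper")       # 400/500 = 0.8 -> called
  under <- dmrGR("chr1", 0, 1000, "hyper")      # 900/1000 -> called
  justUnder <- dmrGR("chr1", 4000, 4300, "hyper") # 100/300 < 0.5
  dmrs <- suppressWarnings(c(exactly, more, outside, below, under, justUnder))
  calls <- mapDmrsToPromoters(dmrs, prom)
  expect_equal(nrow(calls), 2)
  hyper <- calls[calls$direction == "hyper", ]
  expect_equal(sort(hyper$dmrs[[1]]), c(1L, 4L, 5L))
  expect_true(all(calls$ambiguous))  # gA carries both directions
})

test_that("mapDmrsToPromoters agrees with a brute-force pair scan", {
  set.seed(31)
  genes <- GRanges("chr1", IRanges(sample(seq(5000, 4e5, 100), 40),
                                   width = 3000),
                   strand = sample(c("+", "-"), 40, TRUE))
  mcols(genes)$gene_id <- sprintf("g%02d", 1:40)
  prom <- buildPromoters(genes)
  starts <- sample(seq(0, 4e5, 100), 120)
  dmrs <- dmrGR("chr1", starts, starts + sample(c(100, 300, 800), 120, TRUE),
                sample(c("hyper", "hypo"), 120, TRUE))
  calls <- mapDmrsToPromoters(dmrs, prom)
  got <- paste(calls$gene_id, calls$direction)
  want <- character()
  for (i in seq_along(dmrs)) for (j in seq_along(prom)) {
    ov <- bruteOverlap("chr1", start(dmrs)[i], end(dmrs)[i],
                       "chr1", start(prom)[j], end(prom)[j])
    if (ov / width(dmrs)[i] >= 0.5)
      want <- c(want, paste(mcols(prom)$gene_id[j],
                            mcols(dmrs)$direction[i]))
  }
  expect_setequal(got, unique(want))
})

test_that("mapDmrsToCgis calls bodies and shores independently", {
  shores <- buildShores(gr0("chr1", 10000, 11000), 2000)
  # half inside the CGI body (and, symmetrically, half in the left
  # shore: the inclusive 50% rule calls both regions)
  half <- dmrGR("chr1", 9800, 10200, "hyper")
  expect_setequal(mapDmrsToCgis(half, shores)$region_type,
                  c("cgi", "left_shore"))
  # fully inside the right (3') shore
  inRight <- dmrGR("chr1", 11200, 11600, "hypo")
  res <- mapDmrsToCgis(inRight, shores)
  expect_equal(res$region_type, "right_shore")
  # straddling CGI and left shore with >=50% in neither is called nowhere,
  # with >=50% in the shore only the shore is called
  straddle <- dmrGR("chr1", 9400, 10400, "hyper")  # 600 in shore, 400 in CGI
  res2 <- mapDmrsToCgis(straddle, shores)
  expect_equal(res2$region_type, "left_shore")
})

test_that("pattern truth table: all five patterns on both strands", {
  for (st in c("+", "-")) {
    fx <- promFixture(st)
    s <- if (st == "+") 1 else -1
    tss <- 10000
    # stranded offset window in genome coordinates
    w <- function(a, b) if (st == "+") gr0("chr1", tss + a, tss + b)
                        else gr0("chr1", tss - b, tss - a)
    mk <- function(g, dir = "hyper") {
      d <- dmrGR("chr1", start(g) - 1, end(g), dir)
      d
    }
    cases <- list(
      list(dmr = mk(w(200, 1200)), want = 1L),    # full CGI: either_max 1
      list(dmr = mk(w(400, 900)), want = 1L),     # inside CGI: DMR frac 1
      list(dmr = mk(w(-1000, -200)), want = 2L),  # 5' shore only
      list(dmr = mk(w(1300, 1900)), want = 3L),   # 3' shore only
      list(dmr = mk(w(-200, 500)), want = 4L),    # partial, either_max 0.43
      list(dmr = mk(w(-800, 1200)), want = 1L))   # engulfs the CGI: frac 1
    for (cs in cases) {
      calls <- mapDmrsToPromoters(cs$dmr, fx$prom)
      expect_equal(nrow(calls), 1)
      pat <- classifyPatterns(calls, fx$prom, fx$cgi, cs$dmr)
      expect_equal(pat$pattern, cs$want,
                   label = sprintf("strand %s offsets [%d,%d)", st,
                                   start(cs$dmr), end(cs$dmr)))
    }
    # CGI-lacking promoter is always pattern 5
    fx5 <- promFixture(st, withCgi = FALSE)
    d5 <- mk(w(-400, 400))
    pat5 <- classifyPatterns(mapDmrsToPromoters(d5, fx5$prom), fx5$prom,
                             fx5$cgi, d5)
    expect_equal(pat5$pattern, 5L)
  }
})

test_that("either_max boundary: exactly 0.5 is pattern 4, just above is 1", {
  fx <- promFixture("+")
  # CGI [10200,11200) width 1000. DMR width 1000 with overlap 500:
  # fractions 0.5/0.5, either_max = 0.5 -> NOT pattern 1
  at <- dmrGR("chr1", 9700, 10700, "hyper")
  pat <- classifyPatterns(mapDmrsToPromoters(at, fx$prom), fx$prom, fx$cgi, at)
  expect_equal(pat$pattern, 4L)
  above <- dmrGR("chr1", 9690, 10700, "hyper")  # overlap 500/1010 vs 500/1000
  patA <- classifyPatterns(mapDmrsToPromoters(above, fx$prom), fx$prom,
                           fx$cgi, above)
  expect_equal(patA$pattern, 4L)  # still 0.5 of the CGI, not greater
  strictly <- dmrGR("chr1", 9690, 10710, "hyper") # 510/1000 = 0.51 of CGI
  patS <- classifyPatterns(mapDmrsToPromoters(strictly, fx$prom), fx$prom,
                           fx$cgi, strictly)
  expect_equal(patS$pattern, 1L)
})

test_that("multi-CGI promoters: between-CGI placement falls to pattern 4", {
  g <- geneGR("chr1", 10000, 12000, "+", "gM")
  prom <- buildPromoters(g, 2000)
  cgis <- gr0("chr1", c(8200, 11000), c(8800, 11600))
  between <- dmrGR("chr1", 9200, 9600, "hyper")  # 3' of CGI1, 5' of CGI2
  pat <- classifyPatterns(mapDmrsToPromoters(between, prom), prom, cgis,
                          between)
  expect_equal(pat$pattern, 4L)
  # strictly 5' of both CGIs and in the 5' shore of the TSS-nearest one
  cgis2 <- gr0("chr1", c(9400, 11400), c(9800, 11800))
  upstream <- dmrGR("chr1", 8200, 8600, "hyper")
  patU <- classifyPatterns(mapDmrsToPromoters(upstream, prom), prom, cgis2,
                           upstream)
  expect_equal(patU$pattern, 2L)
})

test_that("pattern assignment is exhaustive and exclusive", {
  set.seed(17)
  cfg <- smallConfig(seed = 5L)
  ann <- simulateAnnotation(cfg)
  sim <- simulateMethylome(ann, cfg)
  sp <- sim$truth$spikes
  dmrs <- granges(sp)
  mcols(dmrs)$direction <- factor(mcols(sp)$direction, c("hyper", "hypo"))
  calls <- mapDmrsToPromoters(dmrs, ann$promoters)
  pat <- classifyPatterns(calls, ann$promoters, ann$cgis, dmrs)
  expect_true(all(pat$pattern %in% 1:5))
  expect_equal(anyDuplicated(paste(pat$gene_id, pat$direction)), 0L)
  # called gene with no supporting DMR is an internal error
  broken <- calls
  broken$dmrs[[1]] <- integer(0)
  expect_error(classifyPatterns(broken, ann$promoters, ann$cgis, dmrs),
               "consistency")
})

test_that("tssProfile marks windows in stranded orientation", {
  genes <- c(geneGR("chr1", 10000, 12000, "+", "gP"),
             geneGR("chr1", 30000, 32000, "-", "gM"))
  prom <- buildPromoters(genes, 2000)
  # fully covering gP's promoter
  full <- dmrGR("chr1", 8000, 12000, "hyper")
  pr <- tssProfile(prom, full, "hyper")
  expect_equal(dim(pr$profile), c(2L, 400L))
  expect_equal(unname(pr$frequency), rep(0.5, 400))
  # downstream DMR for the minus-strand gene: genome-left of its TSS
  dn <- dmrGR("chr1", 31000, 31500, "hyper")   # stranded +500..+1000
  prm <- tssProfile(prom, dn, "hyper")
  hitCols <- which(prm$profile["gM", ] == 1)
  expect_true(all(hitCols > 200))              # downstream half
  expect_equal(length(hitCols), 50)
  # no DMRs of the requested direction -> all zero
  pr0 <- tssProfile(prom, full, "hypo")
  expect_true(all(pr0$profile == 0))
})

test_that("tssProfile is invariant under genome reflection with strand flip", {
  set.seed(23)
  L <- 1e6
  for (rep in 1:5) {
    s0 <- sample(seq(10000, 900000, 100), 6)
    st <- sample(c("+", "-"), 6, TRUE)
    genes <- GRanges("chr1", IRanges(s0 + 1, s0 + 2000), strand = st)
    mcols(genes)$gene_id <- sprintf("g%d", 1:6)
    prom <- buildPromoters(genes)
    d0 <- sample(seq(0, 998000, 100), 15)
    dmrs <- dmrGR("chr1", d0, d0 + sample(c(200, 400), 15, TRUE), "hyper")
    p1 <- tssProfile(prom, dmrs, "hyper")
    genesR <- GRanges("chr1", IRanges(L - end(genes) + 1, L - start(genes) + 1),
                      strand = ifelse(st == "+", "-", "+"))
    mcols(genesR)$gene_id <- mcols(genes)$gene_id
    dmrsR <- dmrGR("chr1", L - end(dmrs), L - start(dmrs) + 1, "hyper")
    p2 <- tssProfile(buildPromoters(genesR), dmrsR, "hyper")
    expect_equal(unname(p1$profile), unname(p2$profile))
  }
})

test_that("hostConcordance classes pairs by promoter overlap", {
  coding <- geneGR("chr1", 50000, 56000, "+", "host", "coding")
  nc1 <- geneGR("chr1", 50000, 52000, "+", "ncSame")   # same TSS
  nc2 <- geneGR("chr1", 52500, 53500, "+", "ncFar")    # inside, distinct TSS
  nc <- classifyBiotype(c(nc1, nc2), coding)
  prom <- buildPromoters(c(coding, nc1, nc2), 2000)
  calls <- DataFrame(gene_id = c("host", "ncSame", "ncFar"),
                     direction = factor(c("hyper", "hyper", "hypo"),
                                        c("hyper", "hypo")))
  out <- hostConcordance(nc, calls, prom)
  expect_equal(as.character(out$overlapClass), c("ge50", "lt50"))
  expect_true(out$concordant[1])
  expect_false(out$concordant[2])   # hypo vs hyper host
  expect_equal(metadata(out)$concordanceLt50, 0)
})

test_that("regionSetEnrichment builds the 2x2 table and Fisher statistics", {
  genes <- GRanges("chr1", IRanges(seq(10000, 200000, 10000)[1:20],
                                   width = 2000), strand = "+")
  mcols(genes)$gene_id <- sprintf("g%02d", 1:20)
  prom <- buildPromoters(genes)
  # region set covering the promoters of the first 10 genes exactly
  regions <- granges(prom[1:10])
  res <- regionSetEnrichment(sprintf("g%02d", 1:10), mcols(genes)$gene_id,
                             regions, prom)
  expect_equal(unclass(res$table)[1, ], c("TRUE" = 10L, "FALSE" = 0L))
  expect_equal(res$oddsRatio, (10.5 * 10.5) / (0.5 * 0.5))  # Haldane
  expect_equal(res$pValue, 2 / choose(20, 10), tolerance = 1e-9)
  expect_equal(res$pValue, bruteFisherP(unclass(res$table)), tolerance = 1e-9)
  ind <- regionSetEnrichment(sprintf("g%02d", c(1:5, 11:15)),
                             mcols(genes)$gene_id, regions, prom)
  expect_equal(ind$oddsRatio, 1)
  expect_equal(ind$pValue, 1)
  expect_warning(regionSetEnrichment(mcols(genes)$gene_id,
                                     mcols(genes)$gene_id, regions, prom),
                 "degenerate")
  expect_error(regionSetEnrichment("g01", character(), regions, prom),
               "empty")
})
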