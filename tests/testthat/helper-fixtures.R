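suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
  library(IRanges)
})

# GRanges from 0-based half-open coordinates, the convention of the
# BED-style inputs; keeps fixture arithmetic readable.
gr0 <- function(chrom, start0, end0, strand = "*") {
  GRanges(chrom, IRanges(start0 + 1L, end0), strand = strand)
}

geneGR <- function(chrom, start0, end0, strand, id, class = "lncRNA") {
  g <- gr0(chrom, start0, end0, strand)
  mcols(g) <- DataFrame(gene_id = id, gene_class = class)
  g
}

# DMR-shaped GRanges from 0-based coordinates.
dmrGR <- function(chrom, start0, end0, direction, q = 1e-6, fc = 4) {
  g <- gr0(chrom, start0, end0)
  mcols(g) <- DataFrame(direction = factor(direction, c("hyper", "hypo")),
                        n_bins = as.integer((end0 - start0) / 100),
                        min_q = q, max_abs_l2fc = abs(log2(fc)))
  g
}

# Bin-stat GRanges on a 100-bp grid from a vector of calls, as produced
# by testBins, for merge tests.
binStatsGR <- function(calls, chrom = "chr1", q = 1e-4, fc = 4) {
  n <- length(calls)
  g <- GRanges(chrom, IRanges((seq_len(n) - 1L) * 100L + 1L, width = 100L))
  fcv <- ifelse(calls == "hypo", 1 / fc, fc)
  mcols(g) <- DataFrame(tumorMean = 100, normalMean = 100 / fcv,
                        foldChange = fcv, tested = TRUE, p = q / 2, q = q,
                        call = factor(calls, c("hyper", "hypo", "none")))
  g
}

# Raw-count BinMethylome with given per-group bin means (no noise).
flatBinMethylome <- function(tumorMeans, normalMeans, nTumor = 6L,
                             nNormal = 6L, jitter = NULL) {
  nb <- length(tumorMeans)
  m <- cbind(matrix(rep(tumorMeans, nTumor), ncol = nTumor),
             matrix(rep(normalMeans, nNormal), ncol = nNormal))
  if (!is.null(jitter)) m <- m + jitter
  bins <- GRanges("chr1", IRanges((seq_len(nb) - 1L) * 100L + 1L,
                                  width = 100L))
  BinMethylome(m, bins, rep(c("tumor", "normal"), c(nTumor, nNormal)))
}

# Small, fast simulation config for pipeline-level tests.
smallConfig <- function(seed = 1L, ...) {
  args <- list(nChrom = 1L, chromLength = 6e5, nCoding = 12L,
               nLncRNA = 20L, nMiRNA = 8L, nTumor = 12L, nNormal = 10L,
               spikes = defaultSpikes()[1:10, ],  # one per (pattern, direction)
               seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(simConfig, args)
}

# Independent brute-force oracles -------------------------------------

# Per-base intersection count of two intervals.
bruteOverlap <- function(chrA, sA, eA, chrB, sB, eB) {
  if (chrA != chrB) return(0L)
  length(intersect(seq(sA, eA), seq(sB, eB)))
}

# Two-sided rank-sum p by direct enumeration of every group assignment.
bruteWilcoxon <- function(x, y) {
  N <- length(x) + length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_along(x)])
  mu <- length(x) * (N + 1) / 2
  splits <- utils::combn(N, length(x))
  Ws <- apply(splits, 2L, function(idx) sum(r[idx]))
  mean(abs(Ws - mu) >= abs(W - mu) - 1e-9)
}

# Reference step-up BH.
bruteBH <- function(p) stats::p.adjust(p, method = "BH")

# AUC by counting all (positive, negative) score pairs.
bruteAuc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Two-sided Fisher p by hypergeometric enumeration over all tables with
# the observed margins.
bruteFisherP <- function(tab) {
  k <- tab[1, 1]; K <- sum(tab[1, ]); n <- sum(tab[, 1]); N <- sum(tab)
  xs <- max(0, n - (N - K)):min(K, n)
  dens <- stats::dhyper(xs, K, N - K, n)
  sum(dens[dens <= stats::dhyper(k, K, N - K, n) * (1 + 1e-7)])
}
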