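#' Cell-line lncRNA expression change labels
#'
#' For each gene and each tumor cell line, the pseudocounted
#' tumor/control FPKM ratio labels the gene `up` when it exceeds `fold`,
#' `down` when below `1/fold`, otherwise `none`. A gene becomes a
#' differential-expression candidate only when every tumor line carries
#' the same non-`none` label (the two-cell-line intersection).
#'
#' @param fpkm numeric matrix, genes x cell lines.
#' @param tumorCols,controlCol column names (or indices) of the tumor
#'   lines and the single control line.
#' @param fold ratio threshold (default 2; the rule is strict, "greater
#'   than two-fold").
#' @param minFpkm pseudocount added to both sides of the ratio
#'   (default 0.1).
#' @return [S4Vectors::DataFrame] with `gene_id`, one label column per
#'   tumor line, and the consensus `label` (`up`/`down`/`none`).
#' @export
lncrnaExpressionChange <- function(fpkm, tumorCols, controlCol,
                                   fold = 2, minFpkm = 0.1) {
  if (missing(controlCol) || length(controlCol) != 1L)
    stop("exactly one control column is required")
  ctrl <- fpkm[, controlCol]
  labs <- vapply(tumorCols, function(tc) {
    r <- (fpkm[, tc] + minFpkm) / (ctrl + minFpkm)
    ifelse(r > fold, "up", ifelse(r < 1 / fold, "down", "none"))
  }, character(nrow(fpkm)))
  labs <- matrix(labs, nrow = nrow(fpkm),
                 dimnames = list(rownames(fpkm), tumorCols))
  consensus <- apply(labs, 1L, function(v)
    if (length(unique(v)) == 1L && v[1] != "none") v[1] else "none")
  out <- DataFrame(gene_id = rownames(fpkm), labs,
                   label = factor(consensus, c("up", "down", "none")))
  rownames(out) <- NULL
  out
}

#' Cohort miRNA differential expression
#'
#' Two-sided Student's t-test (pooled variance) per miRNA on
#' log2(RPM + 1), Benjamini-Hochberg adjustment across miRNAs,
#' significance at adjusted p below `alpha`.
#'
#' @param rpm numeric matrix, miRNAs x samples.
#' @param groups per-sample `tumor`/`normal` labels.
#' @param alpha adjusted-p threshold (default 0.05).
#' @return [S4Vectors::DataFrame] with `gene_id`, `t`, `p`, `q`,
#'   `direction` (`up`/`down`, tumor relative to normal) and
#'   `significant`.
#' @export
mirnaDifferentialExpression <- function(rpm, groups, alpha = 0.05) {
  isTumor <- as.character(groups) == "tumor"
  if (sum(isTumor) < 2L || sum(!isTumor) < 2L)
    stop("need >= 2 samples per group")
  lm2 <- log2(rpm + 1)
  tt <- rowStudentT(lm2, isTumor)
  q <- adjustBH(tt$p)
  DataFrame(gene_id = rownames(rpm), t = tt$t, p = tt$p, q = q,
            direction = factor(ifelse(tt$meanTumor >= tt$meanNormal,
                                      "up", "down"), c("up", "down")),
            significant = q < alpha)
}

#' Methylation-expression regulation candidates
#'
#' Intersects promoter methylation calls with expression changes and
#' keeps only opposing directions: hypermethylated + downregulated =
#' `silencing`; hypomethylated + upregulated = `activating`. Genes with
#' concordant directions are dropped (their count is reported in a
#' message).
#'
#' @param methCalls [S4Vectors::DataFrame] with `gene_id` and
#'   `direction` (`hyper`/`hypo`), e.g. from [mapDmrsToPromoters()].
#' @param exprChanges [S4Vectors::DataFrame] with `gene_id` and a
#'   `label` or `direction` column of `up`/`down` (genes with `none` or
#'   non-significant changes should be pre-filtered or carry `none`).
#' @return [S4Vectors::DataFrame] with `gene_id`, `scenario`
#'   (`silencing`/`activating`), `methDirection`, `exprDirection`.
#' @export
callCandidates <- function(methCalls, exprChanges) {
  exprDir <- if ("label" %in% colnames(exprChanges)) exprChanges$label
             else exprChanges$direction
  idx <- match(methCalls$gene_id, exprChanges$gene_id)
  meth <- as.character(methCalls$direction)
  expr <- as.character(exprDir)[idx]
  expr[is.na(expr)] <- "none"
  scenario <- rep(NA_character_, nrow(methCalls))
  scenario[meth == "hyper" & expr == "down"] <- "silencing"
  scenario[meth == "hypo" & expr == "up"] <- "activating"
  concordant <- (meth == "hyper" & expr == "up") |
                (meth == "hypo" & expr == "down")
  if (any(concordant))
    message(sum(concordant),
            " gene(s) with concordant methylation/expression dropped")
  keep <- !is.na(scenario)
  DataFrame(gene_id = methCalls$gene_id[keep],
            scenario = factor(scenario[keep], c("silencing", "activating")),
            methDirection = factor(meth[keep], c("hyper", "hypo")),
            exprDirection = factor(expr[keep], c("up", "down")))
}

#' Histone-mark concordance at promoters
#'
#' Sums each mark's density track over every promoter, per cell line,
#' and compares each tumor line against the control line; a pseudocount
#' enters only when the control sum is zero, so well-covered promoters
#' keep exact ratios. A promoter is labeled changed for a mark when
#' every tumor line's ratio is at least `fold` (up) or at most `1/fold`
#' (down); thresholds are inclusive.
#'
#' @param promoters promoter `GRanges` with `gene_id`.
#' @param tracks a [SummarizedExperiment::SummarizedExperiment] on the
#'   bin grid with one column per (mark, cell line);
#'   `colData(tracks)` must have `mark`, `cellLine` and `group`
#'   (`tumor`/`normal`; exactly one normal line per mark).
#' @param fold ratio threshold (default 2).
#' @param pseudocount added to both sums (default 0.5).
#' @return [S4Vectors::DataFrame] with `gene_id` and, per mark, the
#'   summed-ratio label (`up`/`down`/`none`) in a column named after
#'   the mark.
#' @export
histoneConcordance <- function(promoters, tracks, fold = 2,
                               pseudocount = 0.5) {
  cd <- colData(tracks)
  stopifnot(all(c("mark", "cellLine", "group") %in% colnames(cd)))
  hits <- findOverlaps(promoters, rowRanges(tracks), ignore.strand = TRUE)
  a <- assay(tracks)
  sums <- matrix(0, length(promoters), ncol(tracks))
  if (length(hits)) {
    s <- rowsum(a[subjectHits(hits), , drop = FALSE], queryHits(hits))
    sums[as.integer(rownames(s)), ] <- s
  }
  out <- DataFrame(gene_id = mcols(promoters)$gene_id)
  for (mk in unique(cd$mark)) {
    mcolsIdx <- which(cd$mark == mk)
    ctrl <- mcolsIdx[cd$group[mcolsIdx] == "normal"]
    if (length(ctrl) != 1L) stop("need exactly one control line for mark ", mk)
    tum <- mcolsIdx[cd$group[mcolsIdx] == "tumor"]
    pc <- pseudocount * (sums[, ctrl] == 0)
    ratios <- (sums[, tum, drop = FALSE] + pc) / (sums[, ctrl] + pc)
    lab <- ifelse(apply(ratios >= fold, 1L, all), "up",
                  ifelse(apply(ratios <= 1 / fold, 1L, all), "down", "none"))
    out[[mk]] <- factor(lab, c("up", "down", "none"))
  }
  out
}

#' Z-score biomarker panel scores
#'
#' Z-transforms each feature (methylation or expression level) across
#' samples (sample sd, ddof 1), flips the sign of features whose
#' cancer-associated direction is negative so that higher always means
#' more cancer-like, and averages the signed Z-scores into one score
#' per sample.
#'
#' @param mat numeric matrix, features x samples.
#' @param directions numeric (+1/-1) or character (`"hyper"`/`"up"` = +1,
#'   `"hypo"`/`"down"` = -1) per feature.
#' @return numeric vector of per-sample panel scores.
#' @export
zscorePanel <- function(mat, directions = rep(1, nrow(mat))) {
  if (ncol(mat) < 2L) stop("need >= 2 samples")
  if (is.character(directions) || is.factor(directions))
    directions <- ifelse(as.character(directions) %in% c("hyper", "up"), 1, -1)
  stopifnot(length(directions) == nrow(mat))
  sds <- apply(mat, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance feature(s) dropped")
    mat <- mat[sds > 0, , drop = FALSE]
    directions <- directions[sds > 0]
    sds <- sds[sds > 0]
  }
  if (nrow(mat) == 0L) stop("no feature with positive variance")
  z <- sweep(sweep(mat, 1L, rowMeans(mat)), 1L, sds, `/`)
  colMeans(z * directions)
}

#' Evaluate a biomarker panel by ROC analysis
#'
#' Convenience wrapper: panel scores from [zscorePanel()] evaluated with
#' [rocAuc()] against tumor/normal labels.
#'
#' @param mat features x samples matrix (methylation or expression).
#' @param directions per-feature cancer-associated directions.
#' @param groups per-sample `tumor`/`normal` labels.
#' @return list with `scores`, `auc` and `roc`.
#' @export
evaluatePanel <- function(mat, directions, groups) {
  scores <- zscorePanel(mat, directions)
  r <- rocAuc(scores, as.character(groups) == "tumor")
  list(scores = scores, auc = r$auc, roc = r$roc)
}
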